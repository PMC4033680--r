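template_placeholders <- function(template) {
  m <- gregexpr("\\[([^][]+)\\]", template)[[1L]]
  if (m[1L] == -1L) return(character(0))
  unique(substring(template, m + 1L, m + attr(m, "match.length") - 2L))
}

#' Define a workflow unit from a command template
#'
#' A unit is a typed wrapper around one command line: named input and
#' output slots with opaque format tags, optional parameters with
#' defaults, and a template in which `[slot]` placeholders are
#' substituted at run time.  Example: a SAM-to-BAM unit has
#' `inputs = c(input = "SAM")`, `outputs = c(output = "BAM")` and
#' template `"samtools view -bSo [output] [input]"`.
#'
#' @param name Unit name.
#' @param inputs Named character vector, slot -> format tag.
#' @param outputs Named character vector, slot -> format tag.
#' @param template Command template with `[slot]` placeholders.
#' @param parameters Named list, parameter -> `list(type, default)`.
#' @param output_multi Named logical, TRUE for output slots that emit a
#'   set of files (bound to a directory; downstream steps fan out per
#'   emitted file).  Defaults to FALSE for every output.
#' @return A `unit_definition` list.
#' @export
unit_definition <- function(name, inputs = character(0),
                            outputs = character(0), template,
                            parameters = list(),
                            output_multi = NULL) {
  if (is.null(output_multi)) {
    output_multi <- setNames(rep(FALSE, length(outputs)), names(outputs))
  }
  ph <- template_placeholders(template)
  declared <- c(names(inputs), names(outputs), names(parameters))
  undeclared <- setdiff(ph, declared)
  if (length(undeclared)) {
    stop("undeclared placeholder [", undeclared[1L], "] in template of unit ",
         name)
  }
  missing_slots <- setdiff(c(names(inputs), names(outputs)), ph)
  if (length(missing_slots)) {
    stop("declared slot [", missing_slots[1L],
         "] does not appear in template of unit ", name)
  }
  structure(list(name = name, inputs = inputs, outputs = outputs,
                 template = template, parameters = parameters,
                 output_multi = output_multi),
            class = "unit_definition")
}

#' Create an empty unit registry
#'
#' @return An environment used as a unit registry.
#' @export
unit_registry <- function() {
  new.env(parent = emptyenv())
}

#' Register a unit definition
#'
#' @param registry A [unit_registry()].
#' @param definition A [unit_definition()].
#' @return Invisibly, the validated definition.
#' @export
register_unit <- function(registry, definition) {
  stopifnot(inherits(definition, "unit_definition"))
  if (exists(definition$name, envir = registry, inherits = FALSE)) {
    stop("duplicate unit name: ", definition$name)
  }
  assign(definition$name, definition, envir = registry)
  invisible(definition)
}

#' Fetch a registered unit
#'
#' @param registry A [unit_registry()].
#' @param name Unit name.
#' @return The `unit_definition`.
#' @export
get_unit <- function(registry, name) {
  if (!exists(name, envir = registry, inherits = FALSE)) {
    stop("unknown unit: ", name)
  }
  get(name, envir = registry, inherits = FALSE)
}

#' Resolve a unit's command template against bindings
#'
#' All input and output slots must be bound; unbound parameters take
#' their declared defaults.
#'
#' @param unit A [unit_definition()].
#' @param bindings Named list/vector, slot or parameter -> value.
#' @return The fully substituted command string (no `[` remains).
#' @export
instantiate_command <- function(unit, bindings = list()) {
  vals <- lapply(unit$parameters, `[[`, "default")
  for (nm in names(bindings)) vals[[nm]] <- bindings[[nm]]
  slots <- c(names(unit$inputs), names(unit$outputs))
  unbound <- setdiff(slots, names(vals))
  if (length(unbound)) {
    stop("unbound slot [", unbound[1L], "] for unit ", unit$name)
  }
  cmd <- unit$template
  for (nm in names(vals)) {
    cmd <- gsub(paste0("[", nm, "]"), as.character(vals[[nm]]), cmd,
                fixed = TRUE)
  }
  if (grepl("[", cmd, fixed = TRUE)) {
    stop("unresolved placeholder remains in command: ", cmd)
  }
  cmd
}

#' Pair paired-end files by name
#'
#' Two files pair when their names are identical after removing the
#' read-end token; default token pairs are `_R1`/`_R2` and `_1`/`_2`.
#'
#' @param filenames Character vector of file names or paths.
#' @param token_pairs List of length-2 character vectors of read-end
#'   tokens.
#' @return List with `pairs` (data frame `R1`, `R2`) and `unpaired`
#'   (character vector).  Three or more files reducing to one stem is an
#'   ambiguity error.
#' @export
match_paired_files <- function(filenames,
                               token_pairs = list(c("_R1", "_R2"),
                                                  c("_1", "_2"))) {
  stem <- rep(NA_character_, length(filenames))
  end <- rep(NA_integer_, length(filenames))
  base <- basename(filenames)
  for (tp in token_pairs) {
    for (e in 1:2) {
      hit <- is.na(stem) & grepl(tp[e], base, fixed = TRUE)
      stem[hit] <- sub(tp[e], "", base[hit], fixed = TRUE)
      end[hit] <- e
    }
  }
  pairs <- data.frame(R1 = character(0), R2 = character(0),
                      stringsAsFactors = FALSE)
  unpaired <- filenames[is.na(stem)]
  for (s in unique(stem[!is.na(stem)])) {
    idx <- which(!is.na(stem) & stem == s)
    if (length(idx) > 2L) {
      stop("ambiguous pairing: ", length(idx), " files share stem ", s)
    }
    if (length(idx) == 2L && setequal(end[idx], 1:2)) {
      pairs <- rbind(pairs, data.frame(R1 = filenames[idx[end[idx] == 1L]],
                                       R2 = filenames[idx[end[idx] == 2L]],
                                       stringsAsFactors = FALSE))
    } else {
      unpaired <- c(unpaired, filenames[idx])
    }
  }
  list(pairs = pairs, unpaired = unpaired)
}

#' Assemble a workflow graph
#'
#' @param steps Named list mapping step name to a [unit_definition()]
#'   (the same unit may back several steps).
#' @param edges Data frame with columns `from_step`, `from_slot`,
#'   `to_step`, `to_slot` connecting producer output slots to consumer
#'   input slots.  Connected slots must carry the same format tag and
#'   the graph must be acyclic.
#' @return A `workflow_graph` list with a precomputed topological order.
#' @export
workflow_graph <- function(steps, edges = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from_step = character(0), from_slot = character(0),
                        to_step = character(0), to_slot = character(0),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.list(steps), !is.null(names(steps)))
  rownames(edges) <- NULL
  for (e in seq_len(nrow(edges))) {
    fu <- steps[[edges$from_step[e]]]
    tu <- steps[[edges$to_step[e]]]
    if (is.null(fu) || is.null(tu)) stop("edge references unknown step")
    ffmt <- fu$outputs[[edges$from_slot[e]]]
    tfmt <- tu$inputs[[edges$to_slot[e]]]
    if (is.null(ffmt) || is.null(tfmt)) stop("edge references unknown slot")
    if (!identical(ffmt, tfmt)) {
      stop("format mismatch on edge ", edges$from_step[e], ".",
           edges$from_slot[e], " (", ffmt, ") -> ", edges$to_step[e], ".",
           edges$to_slot[e], " (", tfmt, ")")
    }
  }
  order <- topo_order(names(steps), edges)
  structure(list(steps = steps, edges = edges, order = order),
            class = "workflow_graph")
}

topo_order <- function(step_names, edges) {
  indeg <- setNames(integer(length(step_names)), step_names)
  for (e in seq_len(nrow(edges))) {
    indeg[[edges$to_step[e]]] <- indeg[[edges$to_step[e]]] + 1L
  }
  order <- character(0)
  ready <- step_names[indeg == 0L]
  indeg2 <- indeg
  while (length(ready)) {
    s <- ready[1L]; ready <- ready[-1L]
    order <- c(order, s)
    outs <- edges$to_step[edges$from_step == s]
    for (t in outs) {
      indeg2[[t]] <- indeg2[[t]] - 1L
      if (indeg2[[t]] == 0L) ready <- c(ready, t)
    }
  }
  if (length(order) != length(step_names)) {
    stop("workflow graph contains a cycle")
  }
  order
}

default_output_path <- function(run_dir, step, inst_suffix, slot, fmt,
                                multi) {
  stem <- paste0(step, inst_suffix, ".", slot)
  if (multi) {
    file.path(run_dir, stem)
  } else {
    file.path(run_dir, paste0(stem, ".", tolower(fmt)))
  }
}

run_one_command <- function(cmd, run_dir) {
  out_f <- tempfile(); err_f <- tempfile()
  t0 <- Sys.time()
  status <- system2("sh", c("-c", shQuote(cmd)), stdout = out_f,
                    stderr = err_f)
  t1 <- Sys.time()
  list(exit = status,
       stdout = paste(readLines(out_f, warn = FALSE), collapse = "\n"),
       stderr = paste(readLines(err_f, warn = FALSE), collapse = "\n"),
       start = format(t0, "%Y-%m-%d %H:%M:%OS3"),
       end = format(t1, "%Y-%m-%d %H:%M:%OS3"),
       duration = as.numeric(difftime(t1, t0, units = "secs")))
}

file_sizes <- function(paths) {
  v <- unlist(paths)
  if (is.null(v) || !length(v)) return(numeric(0))
  setNames(as.numeric(file.size(v)), names(v))
}

#' Execute a workflow
#'
#' Steps run sequentially in topological order; a step with several
#' inputs runs only after all its producers finished.  When a producer's
#' output slot is marked multi (a file set), the downstream subgraph is
#' replicated once per emitted file (fan-out); slots with a single
#' binding broadcast across replicas, and multi-valued slots of equal
#' multiplicity are zipped in sorted-name order.  A nonzero exit status
#' halts the affected branch: its dependents are recorded as skipped.
#' Every executed step instance yields a provenance record (resolved
#' command, wall-clock times, exit code, input/output file sizes,
#' captured stdout/stderr).
#'
#' @param graph A [workflow_graph()].
#' @param inputs Named list `"step.slot" -> path` binding workflow-level
#'   inputs (input slots not fed by any edge).
#' @param run_dir Run directory; created if missing.  Outputs, the
#'   provenance JSON and a re-importable copy of the workflow are
#'   written here.
#' @param params Optional named list `"step.param" -> value` overriding
#'   unit parameter defaults.
#' @param keep_intermediate Keep intermediate files (default TRUE;
#'   deleting them is opt-in so a finished run stays inspectable).
#' @return A `workflow_run` list: `graph`, `run_dir`, `provenance`
#'   (list of per-instance records) and `outputs` (per step/slot emitted
#'   files).
#' @export
execute_workflow <- function(graph, inputs = list(), run_dir,
                             params = list(), keep_intermediate = TRUE) {
  stopifnot(inherits(graph, "workflow_graph"))
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  edges <- graph$edges
  # per step: list of instances; each instance: list(outputs = slot -> files,
  # failed = logical)
  instances <- setNames(vector("list", length(graph$steps)),
                        names(graph$steps))
  prov <- list()
  for (step in graph$order) {
    unit <- graph$steps[[step]]
    in_edges <- edges[edges$to_step == step, , drop = FALSE]
    # collect candidate bindings per input slot
    slot_bind <- list()
    slot_failed <- list()
    for (slot in names(unit$inputs)) {
      ie <- in_edges[in_edges$to_slot == slot, , drop = FALSE]
      if (nrow(ie) == 1L) {
        files <- character(0); failed <- logical(0)
        for (pi in instances[[ie$from_step]]) {
          fs <- pi$outputs[[ie$from_slot]]
          files <- c(files, fs)
          failed <- c(failed, rep(pi$failed, length(fs)))
        }
        slot_bind[[slot]] <- files
        slot_failed[[slot]] <- failed
      } else if (nrow(ie) > 1L) {
        stop("input slot ", step, ".", slot, " fed by multiple edges")
      } else {
        key <- paste0(step, ".", slot)
        if (is.null(inputs[[key]])) {
          stop("missing workflow input binding for ", key)
        }
        if (!file.exists(inputs[[key]])) {
          stop("input file does not exist: ", inputs[[key]])
        }
        slot_bind[[slot]] <- inputs[[key]]
        slot_failed[[slot]] <- FALSE
      }
    }
    mult <- vapply(slot_bind, length, 0L)
    if (length(mult) && any(mult == 0L)) {
      # producer emitted nothing (e.g. failed branch): no instances
      instances[[step]] <- list()
      next
    }
    m <- if (length(mult)) max(mult, 1L) else 1L
    if (any(mult != 1L & mult != m)) {
      stop("mismatched fan-out multiplicities for step ", step, ": ",
           paste(mult, collapse = ", "))
    }
    step_instances <- vector("list", m)
    for (r in seq_len(m)) {
      suffix <- if (m > 1L) sprintf("__r%d", r) else ""
      bind <- lapply(slot_bind, function(v) if (length(v) == 1L) v else v[r])
      upstream_failed <- any(vapply(names(bind), function(slot) {
        f <- slot_failed[[slot]]
        if (length(f) == 1L) f else f[r]
      }, TRUE))
      out_bind <- list()
      for (slot in names(unit$outputs)) {
        p <- default_output_path(run_dir, step, suffix, slot,
                                 unit$outputs[[slot]],
                                 unit$output_multi[[slot]])
        if (unit$output_multi[[slot]]) {
          dir.create(p, showWarnings = FALSE, recursive = TRUE)
        }
        out_bind[[slot]] <- p
      }
      p_over <- list()
      for (pn in names(unit$parameters)) {
        key <- paste0(step, ".", pn)
        if (!is.null(params[[key]])) p_over[[pn]] <- params[[key]]
      }
      rec <- list(step = step, instance = r, unit = unit$name,
                  inputs = bind, input_sizes = file_sizes(bind))
      if (upstream_failed) {
        rec$status <- "skipped"
        rec$command <- NA_character_
        rec$exit <- NA_integer_
        step_instances[[r]] <- list(outputs = lapply(out_bind,
                                                     function(x) character(0)),
                                    failed = TRUE)
        prov[[length(prov) + 1L]] <- rec
        next
      }
      cmd <- instantiate_command(unit, c(bind, out_bind, p_over))
      run <- run_one_command(cmd, run_dir)
      emitted <- lapply(names(out_bind), function(slot) {
        p <- out_bind[[slot]]
        if (unit$output_multi[[slot]]) {
          sort(list.files(p, full.names = TRUE))
        } else p
      })
      names(emitted) <- names(out_bind)
      rec$command <- cmd
      rec$start <- run$start; rec$end <- run$end
      rec$duration <- run$duration
      rec$exit <- run$exit
      rec$stdout <- run$stdout; rec$stderr <- run$stderr
      rec$outputs <- emitted
      rec$output_sizes <- file_sizes(emitted)
      rec$status <- if (run$exit == 0L) "ok" else "failed"
      prov[[length(prov) + 1L]] <- rec
      step_instances[[r]] <- list(outputs = emitted, failed = run$exit != 0L)
    }
    instances[[step]] <- step_instances
  }
  run <- structure(list(graph = graph, run_dir = run_dir, provenance = prov,
                        outputs = lapply(instances, function(ins) {
                          lapply(ins, `[[`, "outputs")
                        })),
                   class = "workflow_run")
  write_workflow(graph, file.path(run_dir, "workflow.copy.yaml"))
  write_json(provenance_json(run), file.path(run_dir, "provenance.json"),
             auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null",
             na = "null")
  run
}

provenance_json <- function(run) {
  lapply(run$provenance, function(r) {
    r$inputs <- as.list(r$inputs)
    r$outputs <- as.list(r$outputs)
    r$input_sizes <- as.list(r$input_sizes)
    r$output_sizes <- as.list(r$output_sizes)
    r
  })
}

#' Serialize a workflow graph to a YAML file
#'
#' @param graph A [workflow_graph()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_workflow <- function(graph, path) {
  doc <- list(
    steps = lapply(graph$steps, function(u) {
      list(unit = u$name, inputs = as.list(u$inputs),
           outputs = as.list(u$outputs), template = u$template,
           parameters = lapply(u$parameters, function(p) {
             list(type = p$type, default = p$default)
           }),
           output_multi = as.list(u$output_multi))
    }),
    edges = lapply(seq_len(nrow(graph$edges)), function(e) {
      as.list(graph$edges[e, , drop = FALSE])
    }))
  write_yaml(doc, path)
  invisible(path)
}

#' Re-import a workflow serialized by [write_workflow()]
#'
#' @param path YAML file path.
#' @return A validated `workflow_graph` equal to the original.
#' @export
read_workflow <- function(path) {
  doc <- read_yaml(path)
  steps <- lapply(doc$steps, function(s) {
    unit_definition(
      name = s$unit,
      inputs = unlist2chr(s$inputs),
      outputs = unlist2chr(s$outputs),
      template = s$template,
      parameters = s$parameters,
      output_multi = setNames(as.logical(unlist(s$output_multi)),
                              names(s$output_multi)))
  })
  edges <- if (length(doc$edges)) {
    do.call(rbind, lapply(doc$edges, function(e) {
      data.frame(from_step = e$from_step, from_slot = e$from_slot,
                 to_step = e$to_step, to_slot = e$to_slot,
                 stringsAsFactors = FALSE)
    }))
  } else NULL
  workflow_graph(steps, edges)
}

unlist2chr <- function(x) {
  if (!length(x)) return(character(0))
  setNames(as.character(unlist(x)), names(x))
}

#' Render a run report
#'
#' Writes an HTML page listing every executed step with its resolved
#' command, duration, exit status and file sizes, next to the
#' machine-readable provenance JSON and the embedded workflow copy
#' already present in the run directory.  Re-importing the copy with
#' [read_workflow()] and re-executing it on the same inputs reproduces
#' the outputs of deterministic units byte-identically.
#'
#' @param run A [execute_workflow()] result.
#' @return Path of the written `index.html`.
#' @export
render_report <- function(run) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  rows <- vapply(run$provenance, function(r) {
    outs <- unlist(r$outputs)
    links <- paste(sprintf("<a href=\"%s\">%s</a>", esc(outs),
                           esc(basename(outs))), collapse = ", ")
    sprintf(paste0("<tr><td>%s</td><td>%d</td><td><code>%s</code></td>",
                   "<td>%s</td><td>%s</td><td>%s</td><td>%s</td></tr>"),
            esc(r$step), r$instance,
            esc(ifelse(is.na(r$command), "", r$command)),
            r$status,
            if (is.null(r$duration)) "" else sprintf("%.3f s", r$duration),
            paste(unlist(r$output_sizes), collapse = ", "),
            links)
  }, "")
  html <- c(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\">",
    "<title>cagekit workflow run</title></head><body>",
    "<h1>Workflow run report</h1>",
    sprintf("<p>Run directory: <code>%s</code></p>", esc(run$run_dir)),
    "<p>Workflow copy: <a href=\"workflow.copy.yaml\">workflow.copy.yaml</a>,",
    " provenance: <a href=\"provenance.json\">provenance.json</a></p>",
    "<table border=\"1\"><tr><th>step</th><th>instance</th><th>command</th>",
    "<th>status</th><th>duration</th><th>output sizes</th><th>outputs</th></tr>",
    rows,
    "</table></body></html>")
  path <- file.path(run$run_dir, "index.html")
  writeLines(html, path)
  path
}
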