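sam2bam_unit <- function() {
  unit_definition("sam2bam", inputs = c(input = "SAM"),
                  outputs = c(output = "BAM"),
                  template = "samtools view -bSo [output] [input]")
}

bwa_unit <- function() {
  unit_definition("bwa_aln",
                  inputs = c(input = "FASTQ", reference = "FASTA"),
                  outputs = c(output = "SAI"),
                  template = "bwa aln -n [error-rate] [reference] [input] > [output]",
                  parameters = list(`error-rate` = list(type = "NUMBER",
                                                        default = 0.04)))
}

test_that("unit definitions validate their placeholders", {
  expect_s3_class(sam2bam_unit(), "unit_definition")
  expect_s3_class(bwa_unit(), "unit_definition")
  expect_error(unit_definition("bad", inputs = c(input = "TXT"),
                               outputs = c(output = "TXT"),
                               template = "cp [input] [missing]"),
               "\\[missing\\]")
  expect_error(unit_definition("bad2", inputs = c(input = "TXT", extra = "TXT"),
                               outputs = c(output = "TXT"),
                               template = "cp [input] [output]"),
               "\\[extra\\]")
})

test_that("the registry rejects duplicates and resolves by name", {
  reg <- unit_registry()
  register_unit(reg, sam2bam_unit())
  expect_error(register_unit(reg, sam2bam_unit()), "duplicate")
  expect_equal(get_unit(reg, "sam2bam")$name, "sam2bam")
  expect_error(get_unit(reg, "nope"), "unknown unit")
})

test_that("command instantiation substitutes slots and parameter defaults", {
  expect_equal(instantiate_command(sam2bam_unit(),
                                   list(input = "a.sam", output = "a.bam")),
               "samtools view -bSo a.bam a.sam")
  cmd <- instantiate_command(bwa_unit(), list(input = "r.fq",
                                              reference = "g.fa",
                                              output = "o.sai"))
  expect_match(cmd, "-n 0.04", fixed = TRUE)
  cmd2 <- instantiate_command(bwa_unit(), list(input = "r.fq",
                                               reference = "g.fa",
                                               output = "o.sai",
                                               `error-rate` = 0.02))
  expect_match(cmd2, "-n 0.02", fixed = TRUE)
  expect_false(grepl("[", cmd2, fixed = TRUE))
  expect_error(instantiate_command(bwa_unit(), list(input = "r.fq")),
               "unbound slot")
})

test_that("paired files match by stem after removing read-end tokens", {
  mp <- match_paired_files(c("s1_R1.fq", "s1_R2.fq"))
  expect_equal(nrow(mp$pairs), 1L)
  expect_equal(mp$pairs$R1, "s1_R1.fq")

  mp2 <- match_paired_files(c("s1_R1.fq", "s2_R2.fq"))
  expect_equal(nrow(mp2$pairs), 0L)
  expect_equal(sort(mp2$unpaired), c("s1_R1.fq", "s2_R2.fq"))

  mixed <- as.vector(outer(paste0("lib", 1:4), c("_R1.fastq", "_R2.fastq"),
                           paste0))
  mp3 <- match_paired_files(sample(mixed))
  expect_equal(nrow(mp3$pairs), 4L)
  expect_equal(length(mp3$unpaired), 0L)

  expect_error(match_paired_files(c("s_R1.fq", "s_R2.fq", "s_1.fq")),
               "ambiguous")
})

test_that("graphs reject cycles and mismatched formats", {
  copy <- unit_definition("copy", inputs = c(input = "TXT"),
                          outputs = c(output = "TXT"),
                          template = "cp [input] [output]")
  expect_error(workflow_graph(
    steps = list(a = copy, b = copy),
    edges = data.frame(from_step = c("a", "b"), from_slot = "output",
                       to_step = c("b", "a"), to_slot = "input")),
    "cycle")
  tobam <- sam2bam_unit()
  expect_error(workflow_graph(
    steps = list(a = copy, b = tobam),
    edges = data.frame(from_step = "a", from_slot = "output",
                       to_step = "b", to_slot = "input")),
    "format mismatch")
})

wf_fixture <- function() {
  copy <- unit_definition("copy", inputs = c(input = "TXT"),
                          outputs = c(output = "TXT"),
                          template = "cp [input] [output]")
  split3 <- unit_definition("split3", inputs = c(input = "TXT"),
                            outputs = c(outdir = "TXT"),
                            template = "split -l 2 [input] [outdir]/part_",
                            output_multi = c(outdir = TRUE))
  count <- unit_definition("count", inputs = c(input = "TXT"),
                           outputs = c(output = "TXT"),
                           template = "wc -l < [input] > [output]")
  workflow_graph(
    steps = list(stage = copy, splitter = split3, counter = count),
    edges = data.frame(
      from_step = c("stage", "splitter"), from_slot = c("output", "outdir"),
      to_step = c("splitter", "counter"), to_slot = c("input", "input")))
}

test_that("execution fans out per emitted file with full provenance", {
  wf <- wf_fixture()
  inp <- tmp_lines(sprintf("line%d", 1:6), ext = ".txt")
  rd <- file.path(tempfile("run"), "out")
  run <- execute_workflow(wf, inputs = list("stage.input" = inp),
                          run_dir = rd)
  # 1 stage + 1 split + 3 fan-out counters
  expect_equal(length(run$provenance), 5L)
  counters <- Filter(function(p) p$step == "counter", run$provenance)
  expect_equal(length(counters), 3L)
  expect_true(all(vapply(counters, `[[`, 0L, "exit") == 0L))
  expect_true(all(vapply(run$provenance, function(p)
    p$duration >= 0, TRUE)))
  expect_true(file.exists(file.path(rd, "provenance.json")))
  expect_true(file.exists(file.path(rd, "workflow.copy.yaml")))
})

test_that("a failing unit halts its branch and captures stderr", {
  boom <- unit_definition("boom", inputs = c(input = "TXT"),
                          outputs = c(output = "TXT"),
                          template = "ls /definitely-not-here-42 > [output] # [input]")
  count <- unit_definition("count", inputs = c(input = "TXT"),
                           outputs = c(output = "TXT"),
                           template = "wc -l < [input] > [output]")
  wf <- workflow_graph(steps = list(b = boom, c = count),
                       edges = data.frame(from_step = "b",
                                          from_slot = "output",
                                          to_step = "c", to_slot = "input"))
  inp <- tmp_lines("x", ext = ".txt")
  run <- execute_workflow(wf, inputs = list("b.input" = inp),
                          run_dir = tempfile("runf"))
  st <- vapply(run$provenance, `[[`, "", "status")
  expect_equal(st, c("failed", "skipped"))
  expect_true(nzchar(run$provenance[[1L]]$stderr))
})

test_that("reports embed a re-importable workflow that reproduces outputs", {
  wf <- wf_fixture()
  inp <- tmp_lines(sprintf("row%d", 1:6), ext = ".txt")
  rd1 <- tempfile("runA")
  run <- execute_workflow(wf, inputs = list("stage.input" = inp),
                          run_dir = rd1)
  report <- render_report(run)
  html <- readLines(report)
  expect_true(any(grepl("wc -l", html, fixed = TRUE)))

  wf2 <- read_workflow(file.path(rd1, "workflow.copy.yaml"))
  expect_equal(wf2, wf)
  rd2 <- tempfile("runB")
  run2 <- execute_workflow(wf2, inputs = list("stage.input" = inp),
                           run_dir = rd2)
  f1 <- sort(list.files(rd1, pattern = "^counter.*txt$", full.names = TRUE))
  f2 <- sort(list.files(rd2, pattern = "^counter.*txt$", full.names = TRUE))
  expect_equal(length(f1), 3L)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("workflow-level inputs are checked before execution", {
  wf <- wf_fixture()
  expect_error(execute_workflow(wf, inputs = list(),
                                run_dir = tempfile()),
               "missing workflow input")
  expect_error(execute_workflow(wf,
                                inputs = list("stage.input" = "/nope.txt"),
                                run_dir = tempfile()),
               "does not exist")
})
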