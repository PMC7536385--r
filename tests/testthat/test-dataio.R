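test_that("runs round-trip through TSV + sidecar exactly", {
  set.seed(1)
  run <- makeRun(matrix(rnorm(6), 3, 2), subject = "sub01",
                 session = "B", condition = "movie", tr = 2.2)
  f <- file.path(tempdir(), "run_roundtrip.tsv")
  writeRun(run, f)
  back <- readRun(f)
  expect_identical(runValues(back), runValues(run))
  expect_identical(back@subject, "sub01")
  expect_identical(back@session, "B")
  expect_identical(back@condition, "movie")
  expect_equal(back@trSeconds, 2.2)
})

test_that("malformed run files fail with located errors", {
  f <- file.path(tempdir(), "bad_run.tsv")
  writeLines(c("a\tb", "1\t2", "3\tNaN"), f)
  expect_error(readRun(f), "row 2, column b")
  writeLines(c("a\tb", "1\t2\t3"), f)
  expect_error(readRun(f), "ragged row")
  writeLines(c("a\ta", "1\t2"), f)
  expect_error(readRun(f), "duplicate network labels")
})

test_that("volume dropping and z-scoring follow the declared contract", {
  set.seed(2)
  run <- makeRun(matrix(rnorm(220 * 3), 220, 3))
  prep <- prepareRun(run, dropN = 5, band = NULL)
  expect_equal(nrow(runValues(prep)), 215)
  expect_lt(max(abs(colMeans(runValues(prep)))), 1e-8)
  expect_lt(max(abs(apply(runValues(prep), 2, sd) - 1)), 1e-6)
  expect_identical(prep@provenance$volumesDropped, 5L)
  expect_false(prep@provenance$filtered)
  # z-scoring is idempotent
  prep2 <- prepareRun(prep, dropN = 0, band = NULL)
  expect_lt(max(abs(runValues(prep2) - runValues(prep))), 1e-8)
  # constant columns are named in the error
  runC <- makeRun(cbind(BN01 = rnorm(30), BN02 = rep(1, 30)))
  expect_error(prepareRun(runC, dropN = 0, band = NULL), "BN02")
})

test_that("band-pass keeps in-band and rejects out-of-band sinusoids", {
  # 1 s sampling: Nyquist 0.5 Hz, so both probes are representable
  t <- seq_len(400)
  inBand <- sin(2 * pi * 0.05 * t)
  outBand <- sin(2 * pi * 0.30 * t)
  run <- makeRun(cbind(BN01 = inBand, BN02 = outBand), tr = 1)
  prep <- prepareRun(run, dropN = 0, band = c(0.01, 0.15), zscore = FALSE)
  v <- runValues(prep)
  expect_gt(var(v[, 1]) / var(inBand), 0.9)
  expect_lt(var(v[, 2]) / var(outBand), 0.1)
  expect_error(prepareRun(run, dropN = 0, band = c(0.01, 0.6)), "Nyquist")
})

test_that("confound regression removes the confound direction", {
  set.seed(3)
  conf <- rnorm(100)
  run <- makeRun(cbind(BN01 = 2 * conf + rnorm(100, sd = 0.1),
                       BN02 = rnorm(100)))
  prep <- prepareRun(run, dropN = 0, band = NULL, confounds = conf,
                     zscore = FALSE)
  expect_lt(abs(cor(runValues(prep)[, 1], conf)), 0.05)
  expect_true(prep@provenance$confoundsRegressed)
})

test_that("concatenation preserves rows and the segment index", {
  set.seed(4)
  runs <- list(makeRun(matrix(rnorm(20), 10, 2), subject = "s1"),
               makeRun(matrix(rnorm(12), 6, 2), subject = "s2"),
               makeRun(matrix(rnorm(16), 8, 2), subject = "s3"))
  d <- concatenateRuns(runs)
  expect_equal(nrow(runValues(d)), 24)
  seg <- segmentTable(d)
  expect_equal(seg$start, c(1L, 11L, 17L))
  expect_equal(seg$length, c(10L, 6L, 8L))
  expect_identical(segmentValues(d, 2), runValues(runs[[2]]))
  # single run: one segment equal to the run
  d1 <- concatenateRuns(runs[1])
  expect_identical(runValues(d1), runValues(runs[[1]]))
  # shuffled order: same multiset of rows, segments follow the given order
  d2 <- concatenateRuns(runs[c(3, 1, 2)])
  expect_identical(segmentValues(d2, 1), runValues(runs[[3]]))
  expect_equal(sort(runValues(d2)[, 1]), sort(runValues(d)[, 1]))
  # label-order mismatch names the offending run
  bad <- makeRun(matrix(rnorm(10), 5, 2))
  colnames(bad@values) <- c("BN02", "BN01")
  expect_error(concatenateRuns(list(runs[[1]], bad)), "run 2")
})

test_that("simulated cohorts are readable with the declared shapes", {
  cfg <- simConfig(nSubjects = 2, nSessions = 2, seed = 5)
  co <- generateCohort(cfg)
  dir <- file.path(tempdir(), "cohortio")
  unlink(dir, recursive = TRUE)
  writeCohort(co, dir, questionnaire = attachQuestionnaire(co$truth))
  files <- list.files(file.path(dir, "runs"), pattern = "\\.tsv$",
                      full.names = TRUE)
  expect_length(files, 8)
  for (f in files) {
    r <- readRun(f)
    expect_equal(nrow(runValues(r)), if (r@condition == "rest") 220 else 535)
    expect_equal(ncol(runValues(r)), 14)
  }
  q <- readQuestionnaire(file.path(dir, "questionnaire.csv"))
  expect_equal(nrow(q), 2)
  ann <- readAnnotations(file.path(dir, "annotations.tsv"))
  expect_true(all(ann$offset_s > ann$onset_s))
})

test_that("physio traces round-trip", {
  v <- c(70.5, 71.2, 69.9)
  f <- file.path(tempdir(), "trace.tsv")
  writePhysioTrace(v, f)
  expect_equal(readPhysioTrace(f), v)
})
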