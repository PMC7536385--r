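test_that("identical configurations generate identical cohorts", {
  cfg <- simConfig(nSubjects = 2, kTrue = 4, D = 6, tRest = 40, tMovie = 60,
                   seed = 99)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(a$truth$masterMoviePath, b$truth$masterMoviePath)
  expect_identical(a$truth$engagement, b$truth$engagement)
  for (i in seq_along(a$runs)) {
    expect_identical(runValues(a$runs[[i]]), runValues(b$runs[[i]]))
  }
})

test_that("noise-free locking copies the master path to every subject", {
  cfg <- simConfig(nSubjects = 3, kTrue = 4, D = 6, tRest = 30, tMovie = 50,
                   jitterTr = 0, flipProb = 0, engagementCoupling = 0,
                   seed = 7)
  co <- generateCohort(cfg)
  for (sub in names(co$truth$paths)) {
    for (ses in c("A", "B")) {
      expect_identical(co$truth$paths[[sub]][[ses]]$movie,
                       co$truth$masterMoviePath)
    }
  }
})

test_that("rest dynamics concentrate on the dominant states", {
  cfg <- simConfig(nSubjects = 1, nSessions = 1, kTrue = 4, D = 6,
                   tRest = 10000, tMovie = 20, restSelfProb = 0.9,
                   restDominantStates = c(1, 2), seed = 21)
  co <- generateCohort(cfg)
  path <- co$truth$paths$sub01$A$rest
  dom <- path[-length(path)] %in% c(1L, 2L)
  selfRate <- mean(path[-length(path)][dom] == path[-1L][dom])
  expect_lt(abs(selfRate - 0.9), 0.02)
  expect_gt(mean(path %in% c(1L, 2L)), 0.8)
})

test_that("long simulated chains converge to the configured matrix", {
  set.seed(31)
  A <- matrix(c(0.9, 0.05, 0.05,
                0.1, 0.8, 0.1,
                0.2, 0.2, 0.6), 3, 3, byrow = TRUE)
  s <- simulateMarkovChain(1e5, A)
  emp <- empiricalTransitions(s, 3)
  expect_lt(max(abs(emp - A)), 0.02)
})

test_that("degenerate covariance and invalid probabilities are rejected", {
  expect_error(simConfig(covScale = 0), "covScale")
  expect_error(simConfig(flipProb = 1.5), "probabilities")
  expect_error(simConfig(kTrue = 1), "kTrue")
  expect_error(simConfig(restDominantStates = 99), "restDominantStates")
})

test_that("annotation intervals cover exactly the assigned master epochs", {
  fake <- list(masterMoviePath = c(1L, 1L, 2L, 2L, 1L),
               config = list(kTrue = 2L, trSeconds = 2.2))
  iv <- attachAnnotations(fake, list(catB = 2))
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$onset_s, 4.4)
  expect_equal(iv$offset_s, 8.8)
  # all states -> one interval covering the whole run
  ivAll <- attachAnnotations(fake, list(all = c(1, 2)))
  expect_equal(nrow(ivAll), 1L)
  expect_equal(ivAll$onset_s, 0)
  expect_equal(ivAll$offset_s, 5 * 2.2)
  # never-visited state -> zero intervals, flagged not errored
  fake3 <- list(masterMoviePath = rep(1L, 5),
                config = list(kTrue = 3L, trSeconds = 2.2))
  ivNone <- attachAnnotations(fake3, list(ghost = 3))
  expect_equal(nrow(ivNone), 0L)
  expect_identical(attr(ivNone, "empty"), "ghost")
})

test_that("physio traces step through the configured offsets", {
  path <- c(1L, 1L, 2L, 2L, 2L, 1L)
  fake <- list(
    config = list(kTrue = 2L, seed = 1L),
    physioOffsets = data.frame(state = 1:2, dHR = c(0, 5), dPD = c(0.2, -0.1)),
    paths = list(sub01 = list(A = list(movie = path))))
  ph <- attachPhysio(fake, noiseSd = 0, arCoeff = 0.3, seed = 1)
  expect_equal(ph$sub01$hr, 70 + c(0, 0, 5, 5, 5, 0))
  expect_equal(ph$sub01$pd, 3 + c(0.2, 0.2, -0.1, -0.1, -0.1, 0.2))
  expect_error(attachPhysio(fake, arCoeff = 1), "stationary")
})

test_that("planted heart-rate offsets are recoverable from long traces", {
  set.seed(12)
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  path <- simulateMarkovChain(5000, A)
  fake <- list(
    config = list(kTrue = 2L, seed = 1L),
    physioOffsets = data.frame(state = 1:2, dHR = c(0, 5), dPD = c(0, 0)),
    paths = list(sub01 = list(A = list(movie = path))))
  ph <- attachPhysio(fake, noiseSd = 1, arCoeff = 0.3, seed = 4)
  dev <- physioStateDeviation(ph$sub01$hr, path, 2)
  fo <- fractionalOccupancy(path, 2)
  recovered <- dev[2] / (1 - fo[2])  # occupancy-adjusted offset estimate
  expect_lt(abs(recovered - 5), 0.3)
  # all-zero offsets give deviations near zero
  fake$physioOffsets$dHR <- c(0, 0)
  ph0 <- attachPhysio(fake, noiseSd = 1, arCoeff = 0.3, seed = 4)
  dev0 <- physioStateDeviation(ph0$sub01$hr, path, 2)
  expect_lt(max(abs(dev0)), 0.3)
})

test_that("questionnaire ratings are monotone in engagement at full coupling", {
  cfg <- simConfig(nSubjects = 8, kTrue = 4, D = 6, tRest = 30, tMovie = 40,
                   seed = 17)
  truth <- generateCohort(cfg)$truth
  q <- attachQuestionnaire(truth, coupling = 1)
  e <- truth$engagement
  ord <- order(e)
  expect_true(all(diff(q$boredom[ord]) <= 0))
  expect_true(all(diff(q$enjoyment[ord]) >= 0))
  expect_true(all(q$boredom %in% 1:5))
  # coupling = 1 is deterministic: no dependence on the noise seed
  q2 <- attachQuestionnaire(truth, coupling = 1, seed = 999)
  expect_identical(q, q2)
})

test_that("HMM-distributed segments carry their generating paths", {
  p <- randomParams(3, 4, seed = 88)
  g <- generateHMMSegments(p, 3, 50, seed = 2)
  expect_s4_class(g$data, "ConcatDataset")
  expect_equal(nrow(runValues(g$data)), 150)
  expect_equal(lengths(g$paths), rep(50L, 3))
  g2 <- generateHMMSegments(p, 3, 50, seed = 2)
  expect_identical(runValues(g$data), runValues(g2$data))
})
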