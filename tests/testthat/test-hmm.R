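test_that("forward-backward matches brute-force path enumeration", {
  # K = 1: posterior trivially 1, loglik is the sum of Gaussian log-densities
  p1 <- new("HMMParams", K = 1L, initialProbs = 1,
            transitionMatrix = matrix(1, 1, 1),
            stateMeans = matrix(0.5, 1, 1),
            stateCovariances = array(2, c(1, 1, 1)))
  x <- matrix(c(-0.3, 0.9, 2.1), 3, 1)
  fb <- forwardBackward(p1, x)
  expect_equal(as.numeric(fb$posteriors), rep(1, 3))
  expect_equal(fb$loglik, sum(dnorm(x, 0.5, sqrt(2), log = TRUE)),
               tolerance = 1e-12)

  # K = 2, T = 2: direct summation over the 4 paths
  p2 <- randomParams(2, 2, seed = 41)
  X <- matrix(rnorm(4), 2, 2)
  fb2 <- forwardBackward(p2, X)
  expect_equal(fb2$loglik, enumLoglik(p2, X), tolerance = 1e-10)

  # larger random instances
  for (s in 1:10) {
    K <- sample(2:3, 1)
    p <- randomParams(K, 3, seed = 500 + s)
    X <- matrix(rnorm(5 * 3), 5, 3)
    expect_equal(forwardBackward(p, X)$loglik, enumLoglik(p, X),
                 tolerance = 1e-10)
  }
})

test_that("posterior rows always sum to one", {
  for (s in 1:5) {
    p <- randomParams(3, 4, seed = 600 + s)
    X <- matrix(rnorm(40 * 4), 40, 4)
    fb <- forwardBackward(p, X)
    expect_lt(max(abs(rowSums(fb$posteriors) - 1)), 1e-8)
  }
})

test_that("viterbi equals exhaustive enumeration and breaks ties low", {
  # identical emission densities + uniform transitions: all-ones by tie rule
  mu <- matrix(0, 3, 2)
  covs <- array(rep(diag(2), 3), c(2, 2, 3))
  pTie <- new("HMMParams", K = 3L, initialProbs = rep(1 / 3, 3),
              transitionMatrix = matrix(1 / 3, 3, 3), stateMeans = mu,
              stateCovariances = covs)
  expect_equal(viterbiPath(pTie, matrix(rnorm(10), 5, 2)), rep(1L, 5))

  # randomized equivalence with the enumeration oracle
  for (s in 1:25) {
    K <- sample(2:3, 1)
    T <- sample(4:7, 1)
    p <- randomParams(K, 2, seed = 700 + s)
    X <- matrix(rnorm(T * 2), T, 2)
    expect_identical(viterbiPath(p, X), enumViterbi(p, X))
  }
})

test_that("single-state fit reduces to the closed form", {
  X <- matrix(rnorm(200), 100, 2)
  colnames(X) <- c("a", "b")
  d <- concatenateRuns(list(makeRun(X)))
  f <- fitHMM(d, K = 1)
  expect_equal(as.numeric(stateMeans(f)), unname(colMeans(X)),
               tolerance = 1e-10)
  expect_equal(transitionMatrix(f), matrix(1, 1, 1))
  expect_true(f@converged)
})

test_that("EM recovers fast alternation between separated clusters", {
  set.seed(3)
  T <- 400
  path <- rep(c(1L, 2L), T / 2)
  mu <- rbind(c(-4, -4), c(4, 4))
  X <- mu[path, ] + matrix(rnorm(2 * T, sd = 0.5), T, 2)
  colnames(X) <- c("a", "b")
  d <- concatenateRuns(list(makeRun(X)))
  f <- fitHMM(d, K = 2, restarts = 3, seed = 1)
  A <- transitionMatrix(f)
  expect_gt(A[1, 2], 0.95)
  expect_gt(A[2, 1], 0.95)
  # reported loglik must equal an independent forward evaluation
  expect_equal(f@loglik, forwardBackward(hmmParams(f), X)$loglik,
               tolerance = 1e-6)
  # EM trace is monotone non-decreasing
  expect_true(all(diff(f@loglikTrace) > -1e-6 * abs(f@loglikTrace[-1])))
})

test_that("segment-aware fitting keeps probability within runs", {
  set.seed(11)
  # two segments generated from very different initial states; a shared
  # initial distribution must be re-used at each segment start
  p <- randomParams(2, 2, seed = 900)
  X1 <- matrix(rnorm(20), 10, 2)
  X2 <- matrix(rnorm(20), 10, 2)
  d <- concatenateRuns(list(makeRun(X1, subject = "s1"),
                            makeRun(X2, subject = "s2")))
  f1 <- forwardBackward(p, X1)$loglik
  f2 <- forwardBackward(p, X2)$loglik
  dec <- decodeStates(p, d)
  expect_equal(dec@loglik, f1 + f2, tolerance = 1e-10)
  expect_identical(statePaths(dec)[[1L]], viterbiPath(p, X1))
})

test_that("AIC follows the closed form and penalises states", {
  expect_equal(hmmFreeParameters(1, 1), 2L)
  expect_equal(hmmAIC(0, 1, 1), 4)
  expect_equal(hmmFreeParameters(10, 14), 1289L)
  expect_equal(hmmAIC(-10000, 10, 14), 22578)
  expect_lt(hmmAIC(-50, 2, 5), hmmAIC(-50, 3, 5))
})

test_that("fitHMM validates its inputs", {
  X <- matrix(rnorm(20), 10, 2)
  colnames(X) <- c("a", "b")
  d <- concatenateRuns(list(makeRun(X)))
  expect_error(fitHMM(d, K = 0), "K must be")
  expect_error(fitHMM(d, K = 5), "too few timepoints")
})

test_that("optimal assignment matches brute force on random costs", {
  for (s in 1:20) {
    set.seed(1500 + s)
    n <- sample(3:5, 1)
    cost <- matrix(rnorm(n * n), n, n)
    a <- brainStateDyn:::.solveAssignment(cost)
    b <- bruteAssignment(cost)
    expect_equal(sum(cost[cbind(seq_len(n), a)]),
                 sum(cost[cbind(seq_len(n), b)]), tolerance = 1e-12)
  }
})

test_that("state alignment recovers known permutations", {
  p <- randomParams(4, 6, seed = 2000)
  expect_identical(alignStates(p, p), 1:4)
  rev4 <- 4:1
  pr <- applyStatePermutation(p, rev4)
  expect_identical(alignStates(p, pr), rev4)
  # noisy refit: perturb means slightly, shuffle, recover
  set.seed(5)
  perm <- sample(4)
  noisy <- applyStatePermutation(p, perm)
  noisy@stateMeans <- noisy@stateMeans + matrix(rnorm(24, sd = 0.05), 4, 6)
  # aligning back must undo the relabelling: the inverse permutation
  rec <- alignStates(p, noisy)
  expect_identical(rec, order(perm))
  expect_equal(stateMeans(applyStatePermutation(noisy, rec)),
               stateMeans(p), tolerance = 0.2)
})

test_that("relabelling states permutes decodings consistently", {
  p <- randomParams(3, 3, seed = 2100)
  X <- matrix(rnorm(60), 20, 3)
  path <- viterbiPath(p, X)
  perm <- c(3L, 1L, 2L)
  p2 <- applyStatePermutation(p, perm)
  inv <- integer(3)
  inv[perm] <- 1:3
  expect_identical(viterbiPath(p2, X), inv[path])
  fb <- forwardBackward(p, X)
  fb2 <- forwardBackward(p2, X)
  expect_equal(fb2$posteriors, fb$posteriors[, perm], tolerance = 1e-12)
  expect_equal(fb2$loglik, fb$loglik, tolerance = 1e-10)
})

test_that("HMM parameters round-trip through JSON", {
  p <- randomParams(3, 4, seed = 2200)
  f <- file.path(tempdir(), "params.json")
  writeHMMParams(p, f)
  q <- readHMMParams(f)
  expect_equal(stateMeans(q), stateMeans(p), tolerance = 1e-14)
  expect_equal(transitionMatrix(q), transitionMatrix(p), tolerance = 1e-14)
  expect_equal(stateCovariances(q), stateCovariances(p), tolerance = 1e-14)
})
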