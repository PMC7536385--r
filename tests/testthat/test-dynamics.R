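test_that("fractional occupancy counts states and sums to one", {
  expect_equal(fractionalOccupancy(c(1, 1, 2, 2), 2), c(0.5, 0.5))
  expect_equal(fractionalOccupancy(c(1, 1, 1, 2), 3), c(0.75, 0.25, 0))
  expect_equal(fractionalOccupancy(rep(2L, 7), 3), c(0, 1, 0))
  expect_error(fractionalOccupancy(c(1, 4), 3), "outside")
  set.seed(1)
  for (i in 1:5) {
    p <- sample.int(4, 50, replace = TRUE)
    expect_equal(sum(fractionalOccupancy(p, 4)), 1, tolerance = 1e-10)
  }
})

test_that("dwell times follow run-length arithmetic", {
  d <- dwellTimes(rep(1L, 10), 2.2, 2)
  expect_equal(d$meanDwellSeconds[1], 22)
  expect_true(is.na(d$meanDwellSeconds[2]))
  d2 <- dwellTimes(c(1, 1, 2, 1, 1, 1), 2.2, 2)
  expect_equal(sort(as.numeric(d2$visits[[1]])), c(2, 3))
  expect_equal(d2$meanDwellSeconds, c(5.5, 2.2))
  # conservation: FO * T = total visit length, per state
  set.seed(2)
  p <- sample.int(3, 80, replace = TRUE)
  d3 <- dwellTimes(p, 1, 3)
  fo <- fractionalOccupancy(p, 3)
  expect_equal(vapply(d3$visits, sum, numeric(1), USE.NAMES = FALSE),
               fo * 80)
})

test_that("empirical transitions count consecutive pairs", {
  expect_equal(empiricalTransitions(c(1, 2, 1, 2, 1), 2),
               matrix(c(0, 1, 1, 0), 2, 2))
  M <- empiricalTransitions(c(1, 1, 2, 2), 2)
  expect_equal(M[1, ], c(0.5, 0.5))
  expect_equal(M[2, ], c(0, 1))
  # unvisited source rows are masked
  M3 <- empiricalTransitions(c(1, 1, 2, 2), 3)
  expect_true(all(is.na(M3[3, ])))
  expect_equal(unname(rowSums(M3)[1:2]), c(1, 1))
})

test_that("transition thresholding keeps the top fifth with ties", {
  set.seed(3)
  M <- matrix(runif(100), 10, 10)  # distinct off-diagonal weights
  kept <- thresholdTransitions(M)
  expect_equal(nrow(kept), 18)   # 20% of 90 directed edges
  expect_true(all(kept$weight >= sort(M[row(M) != col(M)],
                                      decreasing = TRUE)[18]))
  # all-equal weights: everything is tied at the boundary, all retained
  Meq <- matrix(1, 4, 4)
  expect_equal(nrow(thresholdTransitions(Meq)), 12)
  # a dominant edge is always retained
  Md <- matrix(0.01, 5, 5)
  Md[2, 4] <- 0.9
  expect_true(any(thresholdTransitions(Md)$from == 2 &
                  thresholdTransitions(Md)$to == 4))
})

test_that("paired state contrasts flag planted occupancy shifts only", {
  set.seed(4)
  n <- 14; K <- 4
  mk <- function(shift) do.call(rbind, lapply(seq_len(n), function(s) {
    fo <- c(0.25, 0.25, 0.25, 0.25) + rnorm(K, sd = 0.01)
    fo[1] <- fo[1] + shift
    fo <- fo / sum(fo)
    data.frame(subject = sprintf("s%02d", s), condition = NA, state = 1:K,
               fo = fo)
  }))
  rest <- mk(0); rest$condition <- "rest"
  movie <- mk(0.1); movie$condition <- "movie"
  res <- pairedStateContrast(rbind(rest, movie), "fo")
  expect_true(res$significant[1])
  # identical conditions: t = 0, nothing significant
  movie0 <- rest; movie0$condition <- "movie"
  res0 <- pairedStateContrast(rbind(rest, movie0), "fo")
  expect_true(all(res0$t == 0))
  expect_false(any(res0$significant))
})

test_that("transition-graph contrast detects a planted coherent component", {
  set.seed(5)
  K <- 5; n <- 14
  mkMat <- function(bump) {
    M <- matrix(runif(K * K, 0.05, 0.15), K, K)
    if (bump) {
      M[1, 2] <- M[1, 2] + 0.12
      M[2, 3] <- M[2, 3] + 0.12
      M[3, 4] <- M[3, 4] + 0.12
    }
    diag(M) <- 0
    M / rowSums(M)
  }
  A <- replicate(n, mkMat(FALSE), simplify = FALSE)
  B <- replicate(n, mkMat(TRUE), simplify = FALSE)
  res <- nbsTransitionContrast(A, B, primaryT = 3, nPerm = 500, seed = 9)
  expect_gt(nrow(res$BgtA$components), 0)
  top <- res$BgtA$components[1, ]
  expect_gte(top$size, 3)
  expect_lt(top$pFWE, 0.05)
  expect_error(nbsTransitionContrast(A, B, primaryT = 3, nPerm = 50),
               "nPerm")
})

test_that("sign-flip p-values match exhaustive enumeration at n = 6", {
  set.seed(6)
  K <- 4; n <- 6
  A <- replicate(n, {
    M <- matrix(runif(K * K, 0.1, 0.3), K, K); diag(M) <- 0; M / rowSums(M)
  }, simplify = FALSE)
  B <- replicate(n, {
    M <- matrix(runif(K * K, 0.1, 0.3), K, K); diag(M) <- 0
    M[1, 2] <- M[1, 2] + 0.3
    M / rowSums(M)
  }, simplify = FALSE)
  res <- nbsTransitionContrast(A, B, primaryT = 2, nPerm = 500, seed = 3)
  expect_true(res$BgtA$exhaustive)
  if (nrow(res$BgtA$components)) {
    # oracle: enumerate all 2^6 sign patterns by hand
    off <- which(row(diag(K)) != col(diag(K)))
    Dm <- t(sapply(seq_len(n), function(i) B[[i]][off] - A[[i]][off]))
    tstat <- function(Dx) {
      m <- colMeans(Dx); s <- apply(Dx, 2, sd)
      t <- m / (s / sqrt(n)); t[!is.finite(t)] <- 0; t
    }
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    fromI <- row(diag(K))[off]; toI <- col(diag(K))[off]
    maxComp <- function(t) brainStateDyn:::.maxComponentSize(t > 2, fromI,
                                                             toI, K)
    nullMax <- apply(signs, 1, function(s) maxComp(tstat(s * Dm)))
    for (i in seq_len(nrow(res$BgtA$components))) {
      expected <- mean(nullMax >= res$BgtA$components$size[i])
      expect_equal(res$BgtA$components$pFWE[i], expected, tolerance = 1e-12)
    }
  }
})
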