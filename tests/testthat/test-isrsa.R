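test_that("questionnaire distances are Euclidean and metric", {
  q <- data.frame(subject_id = c("a", "b", "c"),
                  boredom = c(1, 2, 5), enjoyment = c(1, 2, 5),
                  emotion = c(1, 2, 5), audio_quality = c(1, 2, 5))
  D <- questionnaireDistance(q)
  expect_equal(D["a", "b"], 2)       # sqrt(4 * 1)
  expect_equal(diag(D), c(a = 0, b = 0, c = 0))
  expect_equal(D, t(D))
  # triangle inequality on random tables
  set.seed(1)
  R <- matrix(sample(1:5, 20, replace = TRUE), 5, 4)
  Dr <- questionnaireDistance(as.data.frame(R))
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    expect_lte(Dr[i, j], Dr[i, k] + Dr[k, j] + 1e-12)
  }
})

test_that("correlation distances span [0, 2] as expected", {
  fo <- rbind(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2), c(0.2, 0.3, 0.5))
  D <- foDistance(fo)
  expect_equal(D[1, 2], 0, tolerance = 1e-12)
  expect_gt(D[1, 3], 1)
  # perfectly anti-correlated feature vectors at distance 2
  f2 <- rbind(c(1, 2, 3), c(3, 2, 1))
  mats <- list(matrix(c(0, 1, 2, 0, 3, 0, 1, 2, 0), 3, 3),
               matrix(c(0, 2, 1, 0, 3, 0, 2, 1, 0), 3, 3))
  expect_equal(dim(transitionDistance(mats)), c(2L, 2L))
  expect_error(foDistance(rbind(c(1, 1, 1), c(1, 2, 3))),
               "zero-variance")
})

test_that("transition distance flattens off-diagonal entries only", {
  # craft two matrices identical off-diagonal but different diagonals
  M1 <- matrix(runif(16), 4, 4)
  M2 <- M1
  diag(M2) <- diag(M2) + 5
  D <- transitionDistance(list(M1, M2, M1 * 0.5 + 0.1))
  expect_equal(D[1, 2], 0, tolerance = 1e-12)  # diagonals ignored
})

test_that("path distance matrices delegate to the pairwise dissimilarity", {
  set.seed(2)
  paths <- lapply(1:3, function(i) sample.int(3, 20, replace = TRUE))
  D <- pathDistanceMatrix(paths, 3)
  expect_equal(D[1, 2], pathDissimilarity(paths[[1]], paths[[2]], 3))
  expect_equal(unname(diag(D)), rep(0, 3))
  expect_equal(D, t(D))
})

test_that("classical MDS reproduces exactly embeddable geometries", {
  # equilateral triangle with side 1
  D3 <- matrix(1, 3, 3) - diag(3)
  emb <- classicalMds(D3)
  d <- as.matrix(dist(emb$points))
  expect_lt(max(abs(d[upper.tri(d)] - 1)), 1e-10)
  # distances from true 2-D points are reproduced
  set.seed(3)
  P <- matrix(rnorm(12), 6, 2)
  embP <- classicalMds(as.matrix(dist(P)))
  expect_lt(max(abs(dist(embP$points) - dist(P))), 1e-8)
  expect_true(all(embP$eigenvalues > -1e-8))
  # deterministic sign convention
  emb2 <- classicalMds(as.matrix(dist(P)))
  expect_identical(embP$points, emb2$points)
  expect_error(classicalMds(matrix(0, 2, 2)), "at least 3")
})

test_that("mantel correlation is exact for identical matrices", {
  set.seed(4)
  P <- matrix(rnorm(20), 10, 2)
  D1 <- as.matrix(dist(P))
  res <- mantelCorrelation(D1, D1, nPerm = 200, seed = 1)
  expect_equal(res$r, 1)
  expect_lt(res$p, 0.02)
})

test_that("small-n mantel p-values match exhaustive relabelling", {
  set.seed(5)
  D1 <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
  D2 <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
  res <- mantelCorrelation(D1, D2, nPerm = 5000, seed = 2)
  expect_true(res$exhaustive)
  # oracle: direct enumeration of all 24 relabellings
  lower <- function(M) M[lower.tri(M)]
  perms <- brainStateDyn:::.allPermutations(4)
  nullR <- vapply(perms, function(p) cor(lower(D1), lower(D2[p, p])),
                  numeric(1))
  expect_equal(res$p, mean(nullR >= res$r - 1e-12), tolerance = 1e-12)
  expect_equal(res$nPerm, 24L)
})

test_that("mantel agrees with an independent implementation", {
  set.seed(6)
  D1 <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
  D2 <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
  ours <- mantelCorrelation(D1, D2, nPerm = 200, seed = 3)
  ref <- vegan::mantel(D1, D2, permutations = 199)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("mantel is invariant to jointly relabelling both matrices", {
  set.seed(7)
  D1 <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
  D2 <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
  p <- sample(8)
  a <- mantelCorrelation(D1, D2, nPerm = 300, seed = 4)
  b <- mantelCorrelation(D1[p, p], D2[p, p], nPerm = 300, seed = 4)
  expect_equal(a$r, b$r, tolerance = 1e-12)
})
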