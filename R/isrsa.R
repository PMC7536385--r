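#' @importFrom stats dist cmdscale cor sd
NULL

.asDistanceMatrix <- function(M, metric, subjects = NULL) {
  M <- as.matrix(M)
  if (is.null(subjects)) subjects <- rownames(M) %||% as.character(seq_len(nrow(M)))
  dimnames(M) <- list(subjects, subjects)
  attr(M, "metric") <- metric
  M
}

#' Euclidean distance between subjects' questionnaire ratings
#'
#' @param ratings n x 4 numeric matrix or questionnaire data.frame (the
#'   `subject_id` column, if present, becomes the subject ordering).
#' @return symmetric, hollow n x n distance matrix with attribute `metric`.
#' @export
questionnaireDistance <- function(ratings) {
  subjects <- NULL
  if (is.data.frame(ratings)) {
    if ("subject_id" %in% names(ratings)) {
      subjects <- ratings$subject_id
      ratings <- ratings[setdiff(names(ratings), "subject_id")]
    }
    ratings <- as.matrix(ratings)
  }
  .asDistanceMatrix(as.matrix(dist(ratings)), "euclidean", subjects)
}

.correlationDistance <- function(F, metric) {
  s <- apply(F, 1L, sd)
  if (any(s == 0))
    stop("zero-variance feature vector for subject(s): ",
         paste(which(s == 0), collapse = ", "))
  D <- 1 - cor(t(F))
  diag(D) <- 0
  .asDistanceMatrix(D, metric, rownames(F))
}

#' Correlation distance between subjects' fractional-occupancy profiles
#'
#' `1 - Pearson r` between the length-K FO vectors of each subject pair.
#'
#' @param fo n x K matrix of per-subject fractional occupancies.
#' @return n x n distance matrix.
#' @export
foDistance <- function(fo) {
  .correlationDistance(as.matrix(fo), "correlation_distance")
}

#' Correlation distance between subjects' transition matrices
#'
#' Each subject's K x K transition matrix is flattened over the
#' off-diagonal entries only (K x (K-1) values; with 10 states, 90), then
#' `1 - Pearson r` is taken between subject pairs. Masked (`NA`) rows
#' contribute zeros.
#'
#' @param mats list (one per subject) of K x K transition matrices.
#' @return n x n distance matrix.
#' @export
transitionDistance <- function(mats) {
  K <- nrow(mats[[1L]])
  off <- which(row(diag(K)) != col(diag(K)))
  F <- t(vapply(mats, function(M) {
    v <- M[off]
    v[!is.finite(v)] <- 0
    v
  }, numeric(length(off))))
  .correlationDistance(F, "correlation_distance")
}

#' Jaccard path dissimilarity between all subject pairs
#'
#' Applies [pathDissimilarity()] to every pair of subjects' movie state
#' paths.
#'
#' @param paths list (one per subject) of equal-length integer state paths.
#' @param K number of states.
#' @return n x n distance matrix.
#' @export
pathDistanceMatrix <- function(paths, K) {
  n <- length(paths)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- pathDissimilarity(paths[[i]], paths[[j]], K)
    }
  }
  .asDistanceMatrix(D, "jaccard_dissimilarity", names(paths))
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centred Gram-matrix eigendecomposition of a distance matrix,
#' returning the top `dims` coordinates with a deterministic sign
#' convention: on each axis the coordinate of largest magnitude is made
#' positive.
#'
#' @param D symmetric distance matrix (n >= 3).
#' @param dims embedding dimension (default 2).
#' @return list with `points` (n x dims) and `eigenvalues` (all n).
#' @export
classicalMds <- function(D, dims = 2L) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least 3 subjects")
  fit <- cmdscale(D, k = dims, eig = TRUE)
  pts <- fit$points
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  list(points = pts, eigenvalues = fit$eig)
}

.lowerTri <- function(M) M[lower.tri(M, diag = FALSE)]

#' Mantel-style permutation test between two distance matrices
#'
#' Pearson correlation between the strictly-lower triangles, with
#' significance from jointly permuting the rows and columns of the second
#' matrix (the subject relabelling null). When `n! <= nPerm` all `n!`
#' relabellings are enumerated and the p-value is exact; otherwise `nPerm`
#' random relabellings are drawn and `p = (1 + #\{null r >= r\}) /
#' (nPerm + 1)`. One-sided (positive association) alternative.
#'
#' @param D1,D2 n x n distance matrices over the same subjects in the same
#'   order (n >= 4).
#' @param nPerm number of permutations (default 5000).
#' @param seed integer seed.
#' @return list with `r`, `z`, `p`, `nPerm`, `exhaustive`.
#' @export
mantelCorrelation <- function(D1, D2, nPerm = 5000L, seed = 1L) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  n <- nrow(D1)
  if (n < 4L) stop("need at least 4 subjects")
  stopifnot(all(dim(D2) == n))
  x <- .lowerTri(D1)
  r <- cor(x, .lowerTri(D2))
  exhaustive <- factorial(n) <= nPerm
  set.seed(as.integer(seed))
  perms <- if (exhaustive) .allPermutations(n)
           else replicate(nPerm, sample.int(n), simplify = FALSE)
  nullR <- vapply(perms, function(p) cor(x, .lowerTri(D2[p, p])),
                  numeric(1))
  z <- (r - mean(nullR)) / sd(nullR)
  p <- if (exhaustive) mean(nullR >= r - 1e-12)
       else (1 + sum(nullR >= r)) / (nPerm + 1)
  list(r = r, z = z, p = p,
       nPerm = if (exhaustive) length(perms) else as.integer(nPerm),
       exhaustive = exhaustive)
}

.allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .allPermutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      i <- i + 1L
      out[[i]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}
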