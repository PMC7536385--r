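#' Binary state-expression vectors of a path
#'
#' One indicator vector per state: 1 where the path expresses the state.
#' The K vectors partition time (each TR has exactly one 1).
#'
#' @inheritParams fractionalOccupancy
#' @return T x K binary matrix.
#' @export
expressionVectors <- function(path, K) {
  path <- .checkPath(path, K)
  E <- matrix(0L, length(path), K)
  E[cbind(seq_along(path), path)] <- 1L
  E
}

#' Sliding-window consistency of state paths across subjects
#'
#' For every TR a centred window of `windowVolumes` consecutive volumes
#' (truncated at the run edges) is examined: for each state the number of
#' subjects expressing it at least once within the window is counted.
#' Consistency is the maximum such count as a percentage of subjects; the
#' modal state is the state attaining it (lowest index on ties).
#'
#' @param paths list (>= 2 subjects) of equal-length integer state paths,
#'   or an n x T matrix with one row per subject.
#' @param K number of states.
#' @param windowVolumes window width in volumes (default 9; at TR 2.2 s
#'   this spans 19.8 s).
#' @return data.frame with columns `time_index` (0-based), `percent`,
#'   `modal_state`.
#' @export
slidingConsistency <- function(paths, K, windowVolumes = 9L) {
  if (is.matrix(paths)) paths <- split(paths, row(paths))
  n <- length(paths)
  if (n < 2L) stop("need at least 2 subjects")
  Tn <- unique(lengths(paths))
  if (length(Tn) != 1L) stop("paths must have equal length")
  if (windowVolumes > Tn) stop("window longer than the run")
  P <- do.call(rbind, lapply(paths, .checkPath, K = K))
  half <- (windowVolumes - 1L) %/% 2L
  halfUp <- windowVolumes - 1L - half
  percent <- numeric(Tn)
  modal <- integer(Tn)
  for (t in seq_len(Tn)) {
    lo <- max(1L, t - half)
    hi <- min(Tn, t + halfUp)
    W <- P[, lo:hi, drop = FALSE]
    counts <- vapply(seq_len(K), function(k)
      sum(apply(W == k, 1L, any)), integer(1))
    modal[t] <- which.max(counts)
    percent[t] <- 100 * max(counts) / n
  }
  data.frame(time_index = seq_len(Tn) - 1L, percent = percent,
             modal_state = modal)
}

.jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}

#' Cross-session Jaccard overlap of state expression
#'
#' For one subject and condition, compares the binary expression vectors of
#' each state between session A and session B with the Jaccard index and
#' averages over states; states absent in both sessions are excluded from
#' the mean.
#'
#' @param pathA,pathB equal-length integer state paths from the two
#'   sessions.
#' @param K number of states.
#' @return list with `perState` (length-K, `NA` where absent in both) and
#'   `mean`.
#' @export
crossSessionJaccard <- function(pathA, pathB, K) {
  if (length(pathA) != length(pathB))
    stop("session paths must have equal length")
  Ea <- expressionVectors(pathA, K)
  Eb <- expressionVectors(pathB, K)
  J <- vapply(seq_len(K), function(k) .jaccard(Ea[, k] == 1L, Eb[, k] == 1L),
              numeric(1))
  list(perState = J, mean = mean(J, na.rm = TRUE))
}

#' Paired contrast of cross-session consistency
#'
#' Two-sided paired t-test of per-subject mean Jaccard overlap, movie
#' versus rest.
#'
#' @param jaccardMovie,jaccardRest per-subject mean Jaccard values, same
#'   subject order.
#' @return list with `t`, `df`, `p`, `meanMovie`, `meanRest`, `direction`.
#' @export
consistencyContrast <- function(jaccardMovie, jaccardRest) {
  if (length(jaccardMovie) != length(jaccardRest))
    stop("paired vectors must have equal length")
  if (length(jaccardMovie) < 2L) stop("need at least 2 subjects")
  ht <- t.test(jaccardMovie, jaccardRest, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       meanMovie = mean(jaccardMovie), meanRest = mean(jaccardRest),
       direction = if (mean(jaccardMovie) > mean(jaccardRest))
         "movie more consistent" else "rest more consistent")
}

#' Jaccard dissimilarity between two subjects' state paths
#'
#' Mean per-state Jaccard index over states expressed by at least one of
#' the two subjects, subtracted from 1. Zero iff the paths are identical;
#' 1 when the subjects never co-express any state.
#'
#' @param pathI,pathJ equal-length integer state paths.
#' @param K number of states.
#' @return dissimilarity in \[0, 1\].
#' @export
pathDissimilarity <- function(pathI, pathJ, K) {
  if (length(pathI) != length(pathJ))
    stop("paths must have equal length")
  Ei <- expressionVectors(pathI, K)
  Ej <- expressionVectors(pathJ, K)
  J <- vapply(seq_len(K), function(k) .jaccard(Ei[, k] == 1L, Ej[, k] == 1L),
              numeric(1))
  1 - mean(J, na.rm = TRUE)
}
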