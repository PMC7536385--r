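#' @importFrom stats cor.test
NULL

#' Binarize annotation intervals onto the TR grid
#'
#' TR `t` (0-based) is marked 1 iff its half-open window
#' `[t*TR, (t+1)*TR)` intersects any of the category's half-open intervals
#' `[onset_s, offset_s)`.
#'
#' @param intervals data.frame with columns `onset_s`, `offset_s` (seconds).
#' @param trSeconds repetition time in seconds.
#' @param T number of TRs.
#' @return integer 0/1 vector of length `T`.
#' @export
binarizeAnnotations <- function(intervals, trSeconds, T) {
  if (nrow(intervals) && any(intervals$offset_s <= intervals$onset_s))
    stop("intervals must satisfy onset < offset")
  v <- integer(T)
  for (i in seq_len(nrow(intervals))) {
    lo <- intervals$onset_s[i]
    hi <- intervals$offset_s[i]
    first <- max(0L, floor(lo / trSeconds))
    last <- min(T - 1L, ceiling(hi / trSeconds) - 1L)
    if (last >= first) {
      idx <- first:last
      hit <- (idx * trSeconds < hi) & ((idx + 1) * trSeconds > lo)
      v[idx[hit] + 1L] <- 1L
    }
  }
  v
}

#' Szymkiewicz-Simpson overlap of two binary vectors
#'
#' `|a AND b| / min(|a|, |b|)`. Undefined (returns `NA`) when either vector
#' has no set elements; undefined overlaps are reported as missing, never
#' as zero.
#'
#' @param a,b equal-length binary (0/1 or logical) vectors.
#' @return overlap in \[0, 1\], or `NA`.
#' @export
szymkiewiczSimpson <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  a <- as.logical(a); b <- as.logical(b)
  na <- sum(a); nb <- sum(b)
  if (na == 0L || nb == 0L) return(NA_real_)
  sum(a & b) / min(na, nb)
}

#' Permutation test of state-annotation overlap
#'
#' The observed statistic is the subject-mean Szymkiewicz-Simpson overlap
#' between each subject's binary state-expression vector and the annotation
#' track. The null distribution shuffles the annotation vector uniformly at
#' random -- one shared shuffle per iteration, applied against every
#' subject -- and recomputes the subject mean. A circular-shift mode (one
#' shared random rotation per iteration) is available as an
#' autocorrelation-preserving alternative, off by default. The z score is
#' `(obs - null mean) / null SD`; the one-sided enrichment p-value is
#' `(1 + #\{null >= obs\}) / (nPerm + 1)`.
#'
#' @param stateVectors list (one per subject) of equal-length binary state
#'   expression vectors.
#' @param track binary annotation vector of the same length.
#' @param nPerm number of permutations (default 5000, minimum 100).
#' @param seed integer seed.
#' @param shuffle `"permute"` (default) or `"circular"`.
#' @return list with `observed`, `nullMean`, `nullSd`, `z`, `p`,
#'   `nSubjects`, `nPerm`.
#' @export
overlapPermutationTest <- function(stateVectors, track, nPerm = 5000L,
                                   seed = 1L,
                                   shuffle = c("permute", "circular")) {
  shuffle <- match.arg(shuffle)
  if (nPerm < 100L) stop("nPerm must be >= 100")
  Tn <- length(track)
  stopifnot(all(lengths(stateVectors) == Tn))
  A <- do.call(rbind, lapply(stateVectors, as.integer))
  sizes <- rowSums(A)
  ok <- sizes > 0L
  if (sum(ok) < 2L) stop("need >= 2 subjects with a defined overlap")
  A <- A[ok, , drop = FALSE]
  sizes <- sizes[ok]
  tb <- sum(track)
  if (tb == 0L) stop("annotation track is empty; overlap undefined")
  denom <- pmin(sizes, tb)
  obs <- mean((A %*% as.integer(track)) / denom)
  set.seed(as.integer(seed))
  B <- matrix(0L, Tn, nPerm)
  tri <- as.integer(track)
  for (r in seq_len(nPerm)) {
    B[, r] <- if (shuffle == "permute") tri[sample.int(Tn)]
              else .circShift(tri, sample.int(Tn, 1L))
  }
  nullMeans <- colMeans((A %*% B) / denom)
  z <- (obs - mean(nullMeans)) / sd(nullMeans)
  p <- (1 + sum(nullMeans >= obs)) / (nPerm + 1)
  list(observed = obs, nullMean = mean(nullMeans), nullSd = sd(nullMeans),
       z = z, p = p, nSubjects = nrow(A), nPerm = as.integer(nPerm))
}

#' State-annotation coupling over the full family
#'
#' Runs [overlapPermutationTest()] for every state x category pair and
#' applies Bonferroni control over the whole family (K states times the
#' number of categories); with 10 states and 6 categories the per-test
#' threshold at 0.05 is 0.05/60.
#'
#' @param pathsBySubject list (one per subject) of equal-length state paths.
#' @param tracks named list of binary annotation vectors.
#' @param K number of states.
#' @param alpha family-wise error level (default 0.05).
#' @inheritParams overlapPermutationTest
#' @return data.frame with one row per state x category: `state`,
#'   `category`, `observed`, `z`, `p`, `pThreshold`, `significant`.
#' @export
couplingAnalysis <- function(pathsBySubject, tracks, K, nPerm = 5000L,
                             seed = 1L, alpha = 0.05) {
  nTests <- K * length(tracks)
  thr <- alpha / nTests
  rows <- list()
  for (k in seq_len(K)) {
    sv <- lapply(pathsBySubject, function(p) as.integer(p == k))
    for (cat in names(tracks)) {
      res <- tryCatch(
        overlapPermutationTest(sv, tracks[[cat]], nPerm = nPerm,
                               seed = seed + k * 1000L),
        error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        state = k, category = cat,
        observed = if (is.null(res)) NA_real_ else res$observed,
        z = if (is.null(res)) NA_real_ else res$z,
        p = if (is.null(res)) NA_real_ else res$p,
        pThreshold = thr,
        significant = !is.null(res) && res$p < thr)
    }
  }
  do.call(rbind, rows)
}

#' State-conditioned physiological deviation for one subject
#'
#' Segments a TR-aligned physiological trace by the decoded state path and
#' returns, per state, the mean trace value during that state minus the
#' mean over the whole run. By construction the occupancy-weighted sum of
#' deviations is exactly zero. States never visited are `NA`.
#'
#' @param trace numeric trace aligned to the path's TRs.
#' @param path integer state path.
#' @param K number of states.
#' @return length-K numeric vector of deviations.
#' @export
physioStateDeviation <- function(trace, path, K) {
  path <- .checkPath(path, K)
  if (length(trace) != length(path))
    stop("trace and path must be aligned (equal length)")
  base <- mean(trace)
  vapply(seq_len(K), function(k) {
    sel <- path == k
    if (!any(sel)) NA_real_ else mean(trace[sel]) - base
  }, numeric(1))
}

#' Group test of physiological deviations
#'
#' One-sample two-sided t-test per state of the per-subject deviations
#' against zero, Bonferroni-corrected over K states.
#'
#' @param deviations n x K matrix (subjects x states) of
#'   [physioStateDeviation()] values.
#' @param alpha family-wise error level (default 0.05).
#' @return data.frame with columns `state`, `meanDelta`, `t`, `df`, `p`,
#'   `significant`.
#' @export
physioGroupTest <- function(deviations, alpha = 0.05) {
  K <- ncol(deviations)
  rows <- lapply(seq_len(K), function(k) {
    d <- deviations[, k]
    d <- d[is.finite(d)]
    if (length(d) < 3L || sd(d) == 0) {
      out <- data.frame(state = k, meanDelta = mean(d), t = 0,
                        df = length(d) - 1L, p = 1)
    } else {
      ht <- t.test(d)
      out <- data.frame(state = k, meanDelta = mean(d),
                        t = unname(ht$statistic),
                        df = unname(ht$parameter), p = ht$p.value)
    }
    out$significant <- out$p < alpha / K
    out
  })
  do.call(rbind, rows)
}

#' Pearson correlation between two TR-aligned traces
#'
#' @param x,y equal-length numeric traces (length >= 3, non-constant).
#' @return list with `r`, `t`, `df`, `p` (two-sided, exact t-based).
#' @export
correlateTraces <- function(x, y) {
  if (length(x) != length(y)) stop("traces must have equal length")
  if (length(x) < 3L) stop("need at least 3 timepoints")
  if (sd(x) == 0 || sd(y) == 0) stop("traces must not be constant")
  ht <- cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), t = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value)
}
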