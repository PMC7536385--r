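#' @importFrom stats pt qt t.test quantile
NULL

.checkPath <- function(path, K) {
  path <- as.integer(path)
  if (length(path) == 0L) stop("state path must be non-empty")
  if (any(path < 1L) || any(path > K))
    stop("state path contains values outside 1..K")
  path
}

#' Fractional occupancy of a state path
#'
#' Proportion of timepoints spent in each state.
#'
#' @param path integer state path with values in 1..K.
#' @param K number of states.
#' @return length-K numeric simplex (sums to 1).
#' @export
fractionalOccupancy <- function(path, K) {
  path <- .checkPath(path, K)
  tabulate(path, nbins = K) / length(path)
}

#' Dwell times of a state path
#'
#' Maximal runs of identical state labels. Mean dwell is the mean visit
#' length times the TR; states never visited are `NA`.
#'
#' @inheritParams fractionalOccupancy
#' @param trSeconds repetition time in seconds.
#' @return list with `visits` (per-state list of visit lengths in TRs),
#'   `visitCounts`, and `meanDwellSeconds` (length-K, `NA` where unvisited).
#' @export
dwellTimes <- function(path, trSeconds, K) {
  path <- .checkPath(path, K)
  r <- rle(path)
  visits <- split(r$lengths, factor(r$values, levels = seq_len(K)))
  counts <- lengths(visits)
  meanDwell <- vapply(visits, function(v)
    if (length(v)) mean(v) * trSeconds else NA_real_, numeric(1))
  list(visits = visits, visitCounts = counts,
       meanDwellSeconds = unname(meanDwell))
}

#' Empirical transition matrix of one run's path
#'
#' Counts consecutive state pairs within a single run (never across
#' concatenation boundaries) and row-normalises. Rows of states with no
#' outgoing transition are masked (`NA`).
#'
#' @inheritParams fractionalOccupancy
#' @return K x K matrix; unmasked rows sum to 1, masked rows are `NA`.
#' @export
empiricalTransitions <- function(path, K) {
  path <- .checkPath(path, K)
  M <- matrix(0, K, K)
  if (length(path) > 1L) {
    from <- path[-length(path)]
    to <- path[-1L]
    for (i in seq_along(from)) M[from[i], to[i]] <- M[from[i], to[i]] + 1
  }
  rs <- rowSums(M)
  out <- M / rs
  out[rs == 0, ] <- NA_real_
  out
}

#' Per-subject, per-condition dynamics summary table
#'
#' Computes fractional occupancy, mean dwell time and visit counts for each
#' decoded segment, one row per segment x state.
#'
#' @param decoding a [StateDecoding-class].
#' @param K number of states.
#' @param trSeconds repetition time in seconds.
#' @return data.frame with columns `subject`, `session`, `condition`,
#'   `state`, `fo`, `meanDwellSeconds`, `visitCount`.
#' @export
dynamicsSummary <- function(decoding, K, trSeconds) {
  seg <- decoding@segments
  rows <- lapply(seq_len(nrow(seg)), function(s) {
    p <- decoding@paths[[s]]
    dw <- dwellTimes(p, trSeconds, K)
    data.frame(subject = seg$subject[s], session = seg$session[s],
               condition = seg$condition[s], state = seq_len(K),
               fo = fractionalOccupancy(p, K),
               meanDwellSeconds = dw$meanDwellSeconds,
               visitCount = as.integer(dw$visitCounts))
  })
  do.call(rbind, rows)
}

#' Retain the most frequent transitions of a group-mean matrix
#'
#' Keeps the top 20\% (by default) of off-diagonal transition weights: edges
#' whose weight reaches the `1 - fraction` quantile boundary, with all ties
#' at the boundary retained.
#'
#' @param M K x K group-mean transition matrix.
#' @param fraction fraction of off-diagonal edges to retain (default 0.2).
#' @return data.frame with columns `from`, `to`, `weight` of retained
#'   edges.
#' @export
thresholdTransitions <- function(M, fraction = 0.2) {
  K <- nrow(M)
  off <- which(row(M) != col(M))
  w <- M[off]
  keepN <- ceiling(fraction * length(w))
  thr <- sort(w, decreasing = TRUE)[keepN]
  sel <- off[w >= thr]
  data.frame(from = row(M)[sel], to = col(M)[sel], weight = M[sel])
}

#' Paired rest-vs-movie contrast of a per-state metric
#'
#' Two-sided paired t-test per state across subjects, Bonferroni-corrected
#' over the K states. Subjects missing either condition are dropped with a
#' warning.
#'
#' @param tab data.frame with columns `subject`, `condition`, `state`, and
#'   the metric named by `metric`.
#' @param metric column name of the metric (e.g. `"fo"`).
#' @param conditions length-2 character: the contrast is
#'   `conditions[2] - conditions[1]`.
#' @param alpha family-wise error level (default 0.05).
#' @return data.frame with columns `state`, `meanDiff`, `t`, `df`, `p`,
#'   `significant` (p < alpha / K).
#' @export
pairedStateContrast <- function(tab, metric = "fo",
                                conditions = c("rest", "movie"),
                                alpha = 0.05) {
  K <- max(tab$state)
  subjects <- unique(tab$subject)
  have <- vapply(subjects, function(s)
    all(conditions %in% tab$condition[tab$subject == s]), logical(1))
  if (any(!have)) {
    warning("dropping subjects without both conditions: ",
            paste(subjects[!have], collapse = ", "))
    subjects <- subjects[have]
  }
  if (length(subjects) < 3L) stop("need at least 3 paired subjects")
  rows <- lapply(seq_len(K), function(k) {
    val <- function(cond) vapply(subjects, function(s) {
      v <- tab[[metric]][tab$subject == s & tab$condition == cond &
                           tab$state == k]
      mean(v)  # average over sessions if several
    }, numeric(1))
    d <- val(conditions[2L]) - val(conditions[1L])
    d <- d[is.finite(d)]
    if (length(d) < 3L || sd(d) == 0) {
      tt <- list(statistic = 0, parameter = length(d) - 1L, p.value = 1)
      if (sd(d) == 0 && mean(d) != 0) tt$p.value <- 0
    } else {
      ht <- t.test(d)
      tt <- list(statistic = unname(ht$statistic),
                 parameter = unname(ht$parameter), p.value = ht$p.value)
    }
    data.frame(state = k, meanDiff = mean(d), t = tt$statistic,
               df = tt$parameter, p = tt$p.value,
               significant = tt$p.value < alpha / K)
  })
  do.call(rbind, rows)
}

.pairedEdgeT <- function(Dmat) {
  # Dmat: n x E matrix of per-subject differences; returns per-edge t
  n <- nrow(Dmat)
  m <- colMeans(Dmat)
  s <- sqrt((colSums(Dmat^2) - n * m^2) / (n - 1))
  t <- m / (s / sqrt(n))
  t[!is.finite(t)] <- 0
  t
}

.signMatrix <- function(n, nPerm) {
  if (2^n <= nPerm) {
    # exhaustive enumeration of all sign assignments
    S <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    dimnames(S) <- NULL
    list(S = S, exhaustive = TRUE)
  } else {
    S <- matrix(sample(c(1, -1), n * nPerm, replace = TRUE), nPerm, n)
    list(S = S, exhaustive = FALSE)
  }
}

#' Network-based permutation statistic on transition graphs
#'
#' Tests, edge by edge and then at the connected-component level, whether
#' directed state-to-state transition probabilities differ between two
#' paired conditions. Per directed edge (diagonal excluded) a paired t
#' statistic is computed on the condition B - condition A differences;
#' edges exceeding `primaryT` form a graph whose weakly connected
#' components are scored by edge count. The family-wise-error p-value of
#' each component is the fraction of null maximum component sizes at least
#' as large, under a null that flips the condition labels within subjects
#' (all `2^n` sign patterns enumerated when `2^n <= nPerm`, otherwise
#' `nPerm` random flips). Both contrast directions are returned.
#'
#' @param matsA,matsB lists (length n subjects) of K x K per-subject
#'   transition matrices for the two conditions; `NA` (masked) entries are
#'   treated as 0.
#' @param primaryT primary edge-level t threshold (required; the
#'   cluster-forming height).
#' @param nPerm number of permutations (default 5000, minimum 100).
#' @param seed integer seed.
#' @return list with elements `BgtA` and `AgtB`, each a list with
#'   `edges` (data.frame from, to, t), `components` (data.frame component,
#'   size, pFWE), `exhaustive`; plus `nPerm` and `seed`.
#' @export
nbsTransitionContrast <- function(matsA, matsB, primaryT, nPerm = 5000L,
                                  seed = 1L) {
  if (nPerm < 100L) stop("nPerm must be >= 100")
  n <- length(matsA)
  stopifnot(length(matsB) == n, n >= 3L)
  K <- nrow(matsA[[1L]])
  off <- which(row(diag(K)) != col(diag(K)))
  fromIdx <- row(diag(K))[off]
  toIdx <- col(diag(K))[off]
  Dmat <- t(vapply(seq_len(n), function(i) {
    a <- matsA[[i]][off]; b <- matsB[[i]][off]
    a[!is.finite(a)] <- 0; b[!is.finite(b)] <- 0
    b - a
  }, numeric(length(off))))
  set.seed(as.integer(seed))
  sm <- .signMatrix(n, nPerm)
  nullMax <- function(S, sign) {
    vapply(seq_len(nrow(S)), function(r) {
      t <- sign * .pairedEdgeT(S[r, ] * Dmat)
      .maxComponentSize(t > primaryT, fromIdx, toIdx, K)
    }, numeric(1))
  }
  oneDirection <- function(sign) {
    tObs <- sign * .pairedEdgeT(Dmat)
    supra <- tObs > primaryT
    comps <- .componentTable(supra, fromIdx, toIdx, K)
    nm <- nullMax(sm$S, sign)
    if (nrow(comps)) {
      comps$pFWE <- vapply(comps$size, function(sz) {
        if (sm$exhaustive) mean(nm >= sz)
        else (1 + sum(nm >= sz)) / (length(nm) + 1)
      }, numeric(1))
    }
    list(edges = data.frame(from = fromIdx, to = toIdx, t = tObs),
         components = comps, exhaustive = sm$exhaustive)
  }
  list(BgtA = oneDirection(1), AgtB = oneDirection(-1),
       nPerm = as.integer(nPerm), seed = as.integer(seed))
}

#' @importFrom igraph graph_from_data_frame components
.componentTable <- function(supra, fromIdx, toIdx, K) {
  if (!any(supra))
    return(data.frame(component = integer(0), size = integer(0),
                      edges = I(list()), pFWE = numeric(0)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = fromIdx[supra], to = toIdx[supra]),
    directed = TRUE, vertices = data.frame(name = seq_len(K)))
  memb <- igraph::components(g, mode = "weak")$membership
  edgeComp <- memb[as.character(fromIdx[supra])]
  sizes <- table(edgeComp)
  ord <- order(-as.integer(sizes))
  data.frame(component = seq_along(sizes),
             size = as.integer(sizes)[ord],
             edges = I(lapply(names(sizes)[ord], function(cid) {
               sel <- which(supra)[edgeComp == as.integer(cid)]
               data.frame(from = fromIdx[sel], to = toIdx[sel])
             })),
             pFWE = NA_real_)
}

.maxComponentSize <- function(supra, fromIdx, toIdx, K) {
  if (!any(supra)) return(0)
  g <- igraph::graph_from_data_frame(
    data.frame(from = fromIdx[supra], to = toIdx[supra]),
    directed = TRUE, vertices = data.frame(name = seq_len(K)))
  memb <- igraph::components(g, mode = "weak")$membership
  max(table(memb[as.character(fromIdx[supra])]))
}
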