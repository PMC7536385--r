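#' @import methods
#' @importFrom stats sd
NULL

#' One network-averaged fMRI run
#'
#' A single acquisition run reduced to one BOLD time series per canonical
#' brain network: a T x D numeric matrix (rows = TRs, columns = networks)
#' plus run-level metadata. The `provenance` slot records which temporal
#' preprocessing stages have been applied (see [prepareRun()]).
#'
#' @slot subject subject identifier.
#' @slot session session label, `"A"` or `"B"`.
#' @slot condition `"rest"` or `"movie"`.
#' @slot trSeconds repetition time (sampling interval) in seconds.
#' @slot values T x D numeric matrix; column names are the network labels.
#' @slot provenance list with elements `volumesDropped`, `filtered`, `band`,
#'   `confoundsRegressed`, `zscored`.
#' @exportClass RunTimeSeries
setClass("RunTimeSeries",
  representation(
    subject = "character",
    session = "character",
    condition = "character",
    trSeconds = "numeric",
    values = "matrix",
    provenance = "list"
  )
)

setValidity("RunTimeSeries", function(object) {
  v <- object@values
  msg <- character()
  if (length(object@subject) != 1L) msg <- c(msg, "subject must be a single label")
  if (!object@session %in% c("A", "B")) msg <- c(msg, "session must be 'A' or 'B'")
  if (!object@condition %in% c("rest", "movie"))
    msg <- c(msg, "condition must be 'rest' or 'movie'")
  if (length(object@trSeconds) != 1L || !is.finite(object@trSeconds) ||
      object@trSeconds <= 0)
    msg <- c(msg, "trSeconds must be a single positive number")
  if (nrow(v) < 1L) msg <- c(msg, "run must contain at least one timepoint")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "network labels (column names) must be present and unique")
  if (!all(is.finite(v))) msg <- c(msg, "values must be finite")
  prov <- object@provenance
  if (isTRUE(prov$zscored)) {
    mu <- colMeans(v)
    s <- apply(v, 2L, sd)
    if (any(abs(mu) > 1e-8) || any(abs(s - 1) > 1e-6))
      msg <- c(msg, "zscored runs must have column means ~0 and SDs ~1")
  }
  if (length(msg)) msg else TRUE
})

#' Concatenated multi-run observation matrix
#'
#' All prepared runs stacked row-wise into one N x D matrix, together with a
#' segment index recording which rows belong to which run. The HMM is fitted
#' to this object so every subject and condition shares one set of states;
#' probability never flows across segment boundaries during inference.
#'
#' @slot values N x D numeric matrix.
#' @slot segments data.frame with columns `subject`, `session`, `condition`,
#'   `start` (1-based first row), `length`; segments tile the rows exactly.
#' @exportClass ConcatDataset
setClass("ConcatDataset",
  representation(values = "matrix", segments = "data.frame")
)

setValidity("ConcatDataset", function(object) {
  seg <- object@segments
  msg <- character()
  need <- c("subject", "session", "condition", "start", "length")
  if (!all(need %in% names(seg))) {
    return(sprintf("segments must have columns %s", paste(need, collapse = ", ")))
  }
  if (nrow(seg) == 0L) msg <- c(msg, "at least one segment required")
  else {
    ends <- seg$start + seg$length - 1L
    if (seg$start[1L] != 1L || any(seg$length < 1L) ||
        (nrow(seg) > 1L && any(seg$start[-1L] != ends[-nrow(seg)] + 1L)) ||
        ends[nrow(seg)] != nrow(object@values))
      msg <- c(msg, "segments must contiguously tile the rows of values")
  }
  if (!all(is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (is.null(colnames(object@values)))
    msg <- c(msg, "values must carry network labels as column names")
  if (length(msg)) msg else TRUE
})

#' Gaussian-emission HMM parameters
#'
#' K hidden brain states, each a multivariate Gaussian over the D networks
#' (mean activation pattern + covariance), with a shared initial-state
#' distribution and a time-invariant row-stochastic transition matrix.
#'
#' @slot K number of states.
#' @slot initialProbs length-K simplex.
#' @slot transitionMatrix K x K row-stochastic matrix.
#' @slot stateMeans K x D matrix of state mean patterns.
#' @slot stateCovariances D x D x K array of symmetric positive-definite
#'   emission covariances.
#' @exportClass HMMParams
setClass("HMMParams",
  representation(
    K = "integer",
    initialProbs = "numeric",
    transitionMatrix = "matrix",
    stateMeans = "matrix",
    stateCovariances = "array"
  )
)

setValidity("HMMParams", function(object) {
  K <- object@K
  msg <- character()
  if (K < 1L) return("K must be >= 1")
  if (length(object@initialProbs) != K ||
      abs(sum(object@initialProbs) - 1) > 1e-8 || any(object@initialProbs < 0))
    msg <- c(msg, "initialProbs must be a length-K simplex (sum 1 +/- 1e-8)")
  A <- object@transitionMatrix
  if (!all(dim(A) == c(K, K)) || any(A < 0) ||
      any(abs(rowSums(A) - 1) > 1e-8))
    msg <- c(msg, "transitionMatrix must be K x K row-stochastic (rows sum 1 +/- 1e-8)")
  D <- ncol(object@stateMeans)
  if (nrow(object@stateMeans) != K) msg <- c(msg, "stateMeans must be K x D")
  S <- object@stateCovariances
  if (length(dim(S)) != 3L || !all(dim(S) == c(D, D, K))) {
    msg <- c(msg, "stateCovariances must be D x D x K")
  } else {
    for (k in seq_len(K)) {
      Sk <- S[, , k, drop = TRUE]
      if (K == 1L && D == 1L) Sk <- matrix(S[1L], 1L, 1L)
      if (max(abs(Sk - t(Sk))) > 1e-8 || min(eigen(Sk, symmetric = TRUE,
          only.values = TRUE)$values) <= 0) {
        msg <- c(msg, sprintf("state %d covariance must be symmetric positive-definite", k))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Result of one HMM fit
#'
#' Best-of-restarts maximum-likelihood EM fit, with the per-iteration
#' log-likelihood trace of the winning restart and the AIC.
#'
#' @slot params the fitted [HMMParams-class].
#' @slot loglikTrace per-iteration log-likelihood of the winning restart
#'   (non-decreasing up to 1e-6).
#' @slot loglik final log-likelihood.
#' @slot converged whether the relative-change tolerance was reached.
#' @slot nIter number of EM iterations run.
#' @slot restartIndex which restart won (1-based).
#' @slot seed seed the fit was launched with.
#' @slot nFreeParams number of free parameters used by the AIC penalty.
#' @slot aic Akaike Information Criterion, 2k - 2 lnL.
#' @exportClass HMMFit
setClass("HMMFit",
  representation(
    params = "HMMParams",
    loglikTrace = "numeric",
    loglik = "numeric",
    converged = "logical",
    nIter = "integer",
    restartIndex = "integer",
    seed = "integer",
    nFreeParams = "integer",
    aic = "numeric"
  )
)

setValidity("HMMFit", function(object) {
  tr <- object@loglikTrace
  if (length(tr) > 1L && any(diff(tr) < -1e-6 * pmax(1, abs(tr[-length(tr)]))))
    return("log-likelihood trace must be non-decreasing (tolerance 1e-6)")
  TRUE
})

#' Decoded state paths and posteriors
#'
#' Per-segment Viterbi state paths and forward-backward posterior
#' probabilities for a fitted model applied to a [ConcatDataset-class].
#'
#' @slot segments the segment index the decoding refers to.
#' @slot paths list (one per segment) of integer state paths in 1..K.
#' @slot posteriors list (one per segment) of T x K posterior matrices,
#'   rows summing to 1.
#' @slot loglik total log-likelihood over all segments.
#' @exportClass StateDecoding
setClass("StateDecoding",
  representation(
    segments = "data.frame",
    paths = "list",
    posteriors = "list",
    loglik = "numeric"
  )
)

setValidity("StateDecoding", function(object) {
  if (length(object@paths) != nrow(object@segments) ||
      length(object@posteriors) != nrow(object@segments))
    return("one path and one posterior matrix required per segment")
  for (i in seq_along(object@paths)) {
    g <- object@posteriors[[i]]
    if (max(abs(rowSums(g) - 1)) > 1e-8)
      return("posterior rows must sum to 1 +/- 1e-8")
    if (any(object@paths[[i]] < 1L) || any(object@paths[[i]] > ncol(g)))
      return("path values must lie in 1..K")
  }
  TRUE
})

setMethod("show", "RunTimeSeries", function(object) {
  cat(sprintf("RunTimeSeries: subject %s, session %s, %s (%d TRs x %d networks, TR %.1f s)\n",
    object@subject, object@session, object@condition,
    nrow(object@values), ncol(object@values), object@trSeconds))
  p <- object@provenance
  if (length(p))
    cat(sprintf("  preprocessing: dropped=%s filtered=%s confounds=%s zscored=%s\n",
      p$volumesDropped %||% 0L, isTRUE(p$filtered),
      isTRUE(p$confoundsRegressed), isTRUE(p$zscored)))
  invisible(NULL)
})

setMethod("show", "ConcatDataset", function(object) {
  cat(sprintf("ConcatDataset: %d x %d (%d segments, %d subjects)\n",
    nrow(object@values), ncol(object@values), nrow(object@segments),
    length(unique(object@segments$subject))))
  invisible(NULL)
})

setMethod("show", "HMMParams", function(object) {
  cat(sprintf("HMMParams: %d Gaussian states over %d networks\n",
    object@K, ncol(object@stateMeans)))
  invisible(NULL)
})

setMethod("show", "HMMFit", function(object) {
  cat(sprintf("HMMFit: K=%d, logL=%.2f, AIC=%.2f, %s in %d iterations (restart %d)\n",
    object@params@K, object@loglik, object@aic,
    if (object@converged) "converged" else "max iterations reached",
    object@nIter, object@restartIndex))
  invisible(NULL)
})

setMethod("show", "StateDecoding", function(object) {
  cat(sprintf("StateDecoding: %d segments, total logL=%.2f\n",
    nrow(object@segments), object@loglik))
  invisible(NULL)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
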