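#' @useDynLib brainStateDyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cov kmeans cor
NULL

# N x K matrix of log N(x_t; mu_k, Sigma_k) via Cholesky factors.
.emissionLogDensities <- function(X, params) {
  K <- params@K
  D <- ncol(X)
  out <- matrix(NA_real_, nrow(X), K)
  for (k in seq_len(K)) {
    S <- matrix(params@stateCovariances[, , k], D, D)
    R <- chol(S)
    logdet <- 2 * sum(log(diag(R)))
    Xc <- sweep(X, 2L, params@stateMeans[k, ], "-")
    W <- backsolve(R, t(Xc), transpose = TRUE)
    out[, k] <- -0.5 * (D * log(2 * pi) + logdet + colSums(W^2))
  }
  out
}

.asConcatValues <- function(data) {
  if (is(data, "ConcatDataset")) data@values else as.matrix(data)
}

#' Forward-backward inference for one segment
#'
#' Runs the numerically scaled forward-backward recursion (per-timepoint
#' normalisation) of a Gaussian-emission HMM on a single continuous segment,
#' returning the posterior state probabilities and the exact log-likelihood.
#'
#' @param params an [HMMParams-class] object.
#' @param segment T x D numeric matrix (one continuous run; no
#'   concatenation boundaries inside).
#' @return list with `posteriors` (T x K matrix, rows summing to 1) and
#'   `loglik`.
#' @export
forwardBackward <- function(params, segment) {
  segment <- as.matrix(segment)
  stopifnot(all(is.finite(segment)), ncol(segment) == ncol(params@stateMeans))
  logB <- .emissionLogDensities(segment, params)
  fb <- .cpp_forward_backward(logB, params@initialProbs, params@transitionMatrix)
  list(posteriors = fb$gamma, loglik = fb$loglik)
}

#' Viterbi state path for one segment
#'
#' Computes the single most probable hidden-state sequence. Ties are broken
#' toward the lowest state index, consistently during the forward
#' maximisation and in the backtracking.
#'
#' @inheritParams forwardBackward
#' @return integer vector of length T with values in 1..K.
#' @export
viterbiPath <- function(params, segment) {
  segment <- as.matrix(segment)
  stopifnot(all(is.finite(segment)), ncol(segment) == ncol(params@stateMeans))
  logB <- .emissionLogDensities(segment, params)
  .cpp_viterbi(logB, log(params@initialProbs), log(params@transitionMatrix))
}

.covRidge <- function(S) {
  D <- ncol(S)
  diag(D) * (1e-6 * sum(diag(S)) / D + 1e-12)
}

# One EM run from a given initialisation; segment-aware E-step.
.emRun <- function(X, segStarts, segLens, params, maxIter, tol) {
  N <- nrow(X); D <- ncol(X); K <- params@K
  trace <- numeric(0)
  llPrev <- -Inf
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    logB <- .emissionLogDensities(X, params)
    Gamma <- matrix(0, N, K)
    xiSum <- matrix(0, K, K)
    gamma1 <- numeric(K)
    ll <- 0
    for (s in seq_along(segStarts)) {
      idx <- segStarts[s]:(segStarts[s] + segLens[s] - 1L)
      fb <- .cpp_forward_backward(logB[idx, , drop = FALSE],
                                  params@initialProbs, params@transitionMatrix)
      Gamma[idx, ] <- fb$gamma
      xiSum <- xiSum + fb$xi
      gamma1 <- gamma1 + as.numeric(fb$gamma1)
      ll <- ll + fb$loglik
    }
    trace <- c(trace, ll)
    if (is.finite(llPrev) && abs(ll - llPrev) < tol * max(1, abs(llPrev))) {
      converged <- TRUE
      break
    }
    llPrev <- ll
    # M-step
    pi <- gamma1 / sum(gamma1)
    rs <- rowSums(xiSum)
    A <- params@transitionMatrix
    ok <- rs > 1e-12
    A[ok, ] <- xiSum[ok, , drop = FALSE] / rs[ok]
    w <- colSums(Gamma)
    mu <- params@stateMeans
    covs <- params@stateCovariances
    for (k in seq_len(K)) {
      if (w[k] < 1e-8) next  # empty state: keep previous parameters
      mu[k, ] <- colSums(Gamma[, k] * X) / w[k]
      Xc <- sweep(X, 2L, mu[k, ], "-")
      S <- crossprod(Xc * Gamma[, k], Xc) / w[k]
      covs[, , k] <- (S + t(S)) / 2 + .covRidge(S)
    }
    params <- new("HMMParams", K = K, initialProbs = pi / sum(pi),
                  transitionMatrix = A / rowSums(A), stateMeans = mu,
                  stateCovariances = covs)
  }
  # evaluate the log-likelihood of the returned parameters themselves, so the
  # reported value matches an independent forward pass exactly
  logB <- .emissionLogDensities(X, params)
  llFinal <- 0
  for (s in seq_along(segStarts)) {
    idx <- segStarts[s]:(segStarts[s] + segLens[s] - 1L)
    llFinal <- llFinal + .cpp_forward_backward(logB[idx, , drop = FALSE],
      params@initialProbs, params@transitionMatrix)$loglik
  }
  trace <- c(trace, llFinal)
  list(params = params, trace = trace, loglik = llFinal,
       converged = converged, nIter = length(trace) - 1L)
}

.initParams <- function(X, K) {
  N <- nrow(X); D <- ncol(X)
  sub <- X[sample.int(N, min(N, 2000L)), , drop = FALSE]
  km <- tryCatch(kmeans(sub, centers = K, nstart = 1L, iter.max = 25L),
                 error = function(e) NULL)
  if (is.null(km)) {
    centers <- X[sample.int(N, K), , drop = FALSE]
    S0 <- cov(X) * (N - 1) / N
  } else {
    centers <- km$centers
    # pooled within-cluster covariance: the mean structure is removed so the
    # initial emissions can discriminate between well-separated states
    S0 <- cov(sub - centers[km$cluster, , drop = FALSE]) *
      (nrow(sub) - 1) / nrow(sub)
  }
  S0 <- (S0 + t(S0)) / 2 + .covRidge(S0)
  covs <- array(rep(S0, K), dim = c(D, D, K))
  A <- matrix(if (K > 1L) 0.1 / (K - 1L) else 0, K, K)
  diag(A) <- if (K > 1L) 0.9 else 1
  new("HMMParams", K = as.integer(K), initialProbs = rep(1 / K, K),
      transitionMatrix = A, stateMeans = unname(centers),
      stateCovariances = covs)
}

#' Number of free parameters of a K-state Gaussian HMM
#'
#' K mean vectors (K D), K symmetric covariances (K D(D+1)/2), the
#' transition matrix (K(K-1) free entries) and the initial distribution
#' (K-1).
#'
#' @param K number of states.
#' @param D number of networks (observation dimension).
#' @return integer count of free parameters.
#' @export
hmmFreeParameters <- function(K, D) {
  as.integer(K * D + K * D * (D + 1) / 2 + K * (K - 1) + (K - 1))
}

#' Akaike Information Criterion for a Gaussian HMM
#'
#' `AIC = 2k - 2 lnL` with `k = hmmFreeParameters(K, D)`. For a fitted model
#' use `AIC(fit)` on the [HMMFit-class] object.
#'
#' @param loglik maximised log-likelihood.
#' @inheritParams hmmFreeParameters
#' @return the AIC value.
#' @export
hmmAIC <- function(loglik, K, D) {
  2 * hmmFreeParameters(K, D) - 2 * loglik
}

#' Fit a Gaussian-emission HMM to concatenated runs
#'
#' Maximum-likelihood EM (Baum-Welch) with segment-aware inference: the
#' forward-backward recursion restarts at every run boundary and all
#' segments share one initial-state distribution, so no probability flows
#' across the concatenation seams. Each restart is initialised from a
#' k-means assignment of a seeded subsample (means = cluster centres,
#' covariances = pooled within-cluster covariance, transitions 0.9
#' self-persistent with uniform off-diagonal); a small ridge
#' (1e-6 trace(S)/D on the diagonal) stabilises every covariance update.
#' The restart with the highest final log-likelihood is returned, and the
#' reported log-likelihood is re-evaluated at the returned parameters so it
#' matches an independent forward pass.
#'
#' @param data a [ConcatDataset-class] (or plain numeric matrix treated as a
#'   single segment).
#' @param K number of hidden states (>= 1).
#' @param restarts number of EM restarts (default 15).
#' @param maxIter maximum EM iterations per restart (default 500).
#' @param tol relative log-likelihood change declaring convergence.
#' @param seed integer seed; restart r uses seed + r - 1.
#' @return an [HMMFit-class] object.
#' @export
fitHMM <- function(data, K, restarts = 15L, maxIter = 500L, tol = 1e-6,
                   seed = 1L) {
  X <- .asConcatValues(data)
  if (is(data, "ConcatDataset")) {
    segStarts <- data@segments$start
    segLens <- data@segments$length
  } else {
    segStarts <- 1L
    segLens <- nrow(X)
  }
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  N <- nrow(X); D <- ncol(X)
  if (N < K * (D + 2)) {
    stop(sprintf("too few timepoints: need at least K*(D+2) = %d rows, got %d",
                 K * (D + 2), N))
  }
  if (!all(is.finite(X))) stop("data must be finite")

  if (K == 1L) {
    mu <- matrix(colMeans(X), 1L, D)
    S <- cov(X) * (N - 1) / N
    S <- (S + t(S)) / 2 + .covRidge(S)
    params <- new("HMMParams", K = 1L, initialProbs = 1,
                  transitionMatrix = matrix(1, 1, 1), stateMeans = mu,
                  stateCovariances = array(S, c(D, D, 1L)))
    ll <- sum(.emissionLogDensities(X, params))
    return(new("HMMFit", params = params, loglikTrace = ll, loglik = ll,
               converged = TRUE, nIter = 1L, restartIndex = 1L,
               seed = as.integer(seed),
               nFreeParams = hmmFreeParameters(1L, D),
               aic = hmmAIC(ll, 1L, D)))
  }

  best <- NULL
  fails <- character(0)
  for (r in seq_len(restarts)) {
    fit <- tryCatch({
      set.seed(as.integer(seed) + r - 1L)
      init <- .initParams(X, K)
      .emRun(X, segStarts, segLens, init, maxIter, tol)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      fails <- c(fails, conditionMessage(fit))
      next
    }
    if (is.null(best) || fit$loglik > best$loglik) {
      best <- fit
      best$restartIndex <- r
    }
  }
  if (is.null(best)) {
    stop("all EM restarts failed: ", paste(unique(fails), collapse = "; "))
  }
  new("HMMFit", params = best$params, loglikTrace = best$trace,
      loglik = best$loglik, converged = best$converged,
      nIter = as.integer(best$nIter),
      restartIndex = as.integer(best$restartIndex), seed = as.integer(seed),
      nFreeParams = hmmFreeParameters(K, D),
      aic = hmmAIC(best$loglik, K, D))
}

#' Decode state paths and posteriors for every segment
#'
#' Applies Viterbi decoding and forward-backward posterior inference
#' segment by segment, so each run is decoded independently under the
#' shared parameters.
#'
#' @param params an [HMMParams-class] or [HMMFit-class].
#' @param data a [ConcatDataset-class].
#' @return a [StateDecoding-class].
#' @export
decodeStates <- function(params, data) {
  if (is(params, "HMMFit")) params <- params@params
  stopifnot(is(data, "ConcatDataset"))
  seg <- data@segments
  paths <- vector("list", nrow(seg))
  posts <- vector("list", nrow(seg))
  ll <- 0
  for (s in seq_len(nrow(seg))) {
    idx <- seg$start[s]:(seg$start[s] + seg$length[s] - 1L)
    Xs <- data@values[idx, , drop = FALSE]
    fb <- forwardBackward(params, Xs)
    paths[[s]] <- viterbiPath(params, Xs)
    posts[[s]] <- fb$posteriors
    ll <- ll + fb$loglik
  }
  new("StateDecoding", segments = seg, paths = paths, posteriors = posts,
      loglik = ll)
}

#' Choose the number of states by AIC with an occupancy guard
#'
#' Fits the HMM for each candidate K and tabulates the AIC together with
#' the minimum fractional occupancy over states (from the Viterbi decoding
#' of the full dataset). The recommended K minimises AIC among models whose
#' every state is occupied above `occupancyFloor`; models with effectively
#' empty states are excluded because additional states no longer describe
#' the data.
#'
#' @inheritParams fitHMM
#' @param kList integer vector of candidate state counts.
#' @param occupancyFloor minimum fractional occupancy (default 0.005) for a
#'   state to count as occupied.
#' @return list with `table` (data.frame: K, aic, minFO, converged, sorted
#'   by K) and `recommendedK`.
#' @export
selectStates <- function(data, kList, restarts = 5L, occupancyFloor = 0.005,
                         maxIter = 500L, tol = 1e-6, seed = 1L) {
  if (length(kList) == 0L) stop("kList must be non-empty")
  kList <- sort(unique(as.integer(kList)))
  rows <- lapply(kList, function(K) {
    fit <- fitHMM(data, K, restarts = restarts, maxIter = maxIter, tol = tol,
                  seed = seed)
    dec <- decodeStates(fit, data)
    path <- unlist(statePaths(dec))
    fo <- fractionalOccupancy(path, K)
    data.frame(K = K, aic = fit@aic, minFO = min(fo),
               converged = fit@converged)
  })
  tab <- do.call(rbind, rows)
  eligible <- tab$minFO > occupancyFloor
  pool <- if (any(eligible)) tab[eligible, ] else tab
  list(table = tab, recommendedK = pool$K[which.min(pool$aic)])
}

# Exact minimum-cost assignment (Jonker-Volgenant shortest augmenting path).
# Returns a[i] = column assigned to row i.
.solveAssignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans
}

#' Match states between two fitted models
#'
#' Repeated decodes (or a fit versus a generating truth) label states
#' arbitrarily. This finds the permutation of `other`'s states that
#' maximises the total Pearson correlation between matched state-mean
#' vectors, by exact optimal assignment.
#'
#' @param reference,other [HMMParams-class] (or [HMMFit-class]) objects with
#'   equal K.
#' @return integer permutation `perm` such that `other` state `perm[k]`
#'   corresponds to `reference` state `k`. Apply it with
#'   [applyStatePermutation()].
#' @export
alignStates <- function(reference, other) {
  if (is(reference, "HMMFit")) reference <- reference@params
  if (is(other, "HMMFit")) other <- other@params
  if (reference@K != other@K) stop("state counts differ between the models")
  K <- reference@K
  if (K == 1L) return(1L)
  C <- matrix(NA_real_, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      C[i, j] <- suppressWarnings(
        cor(reference@stateMeans[i, ], other@stateMeans[j, ]))
    }
  }
  C[!is.finite(C)] <- -1
  .solveAssignment(-C)
}

#' Apply a state permutation to parameters or decodings
#'
#' Relabels states so that permuted state k is the input's state `perm[k]`:
#' means, covariances, transition matrix and initial probabilities are
#' reindexed for [HMMParams-class]; Viterbi labels are remapped and
#' posterior columns reordered for [StateDecoding-class].
#'
#' @param x an [HMMParams-class] or [StateDecoding-class].
#' @param perm integer permutation of 1..K as returned by [alignStates()].
#' @return object of the same class with relabelled states.
#' @export
applyStatePermutation <- function(x, perm) {
  perm <- as.integer(perm)
  if (is(x, "HMMFit")) x <- x@params
  if (is(x, "HMMParams")) {
    if (!identical(sort(perm), seq_len(x@K))) stop("perm must permute 1..K")
    return(new("HMMParams", K = x@K,
               initialProbs = x@initialProbs[perm],
               transitionMatrix = x@transitionMatrix[perm, perm, drop = FALSE],
               stateMeans = x@stateMeans[perm, , drop = FALSE],
               stateCovariances = x@stateCovariances[, , perm, drop = FALSE]))
  }
  if (is(x, "StateDecoding")) {
    K <- ncol(x@posteriors[[1L]])
    if (!identical(sort(perm), seq_len(K))) stop("perm must permute 1..K")
    inv <- integer(K)
    inv[perm] <- seq_len(K)
    new("StateDecoding", segments = x@segments,
        paths = lapply(x@paths, function(p) inv[p]),
        posteriors = lapply(x@posteriors, function(g) g[, perm, drop = FALSE]),
        loglik = x@loglik)
  } else {
    stop("unsupported class: ", class(x)[1L])
  }
}
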