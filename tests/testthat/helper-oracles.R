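# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's recursion code paths: likelihoods
# are computed by explicit enumeration over all K^T state paths.

mvnLogDensity <- function(x, mu, Sigma) {
  D <- length(mu)
  R <- chol(Sigma)
  z <- backsolve(R, x - mu, transpose = TRUE)
  -0.5 * (D * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
}

allPathsMatrix <- function(K, T) {
  as.matrix(expand.grid(rep(list(seq_len(K)), T)))
}

# log-likelihood by summation over all K^T paths
enumLoglik <- function(params, X) {
  K <- nStates(params)
  T <- nrow(X)
  paths <- allPathsMatrix(K, T)
  logB <- sapply(seq_len(K), function(k)
    sapply(seq_len(T), function(t)
      mvnLogDensity(X[t, ], stateMeans(params)[k, ],
                    matrix(stateCovariances(params)[, , k], ncol(X), ncol(X)))))
  logB <- matrix(logB, nrow = T)
  lp <- apply(paths, 1L, function(p) {
    v <- log(initialProbs(params)[p[1L]]) + logB[1L, p[1L]]
    if (T > 1L) for (t in 2:T) {
      v <- v + log(transitionMatrix(params)[p[t - 1L], p[t]]) + logB[t, p[t]]
    }
    v
  })
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# most probable path by enumeration (unique argmax assumed)
enumViterbi <- function(params, X) {
  K <- nStates(params)
  T <- nrow(X)
  paths <- allPathsMatrix(K, T)
  logB <- sapply(seq_len(K), function(k)
    sapply(seq_len(T), function(t)
      mvnLogDensity(X[t, ], stateMeans(params)[k, ],
                    matrix(stateCovariances(params)[, , k], ncol(X), ncol(X)))))
  logB <- matrix(logB, nrow = T)
  lp <- apply(paths, 1L, function(p) {
    v <- log(initialProbs(params)[p[1L]]) + logB[1L, p[1L]]
    if (T > 1L) for (t in 2:T) {
      v <- v + log(transitionMatrix(params)[p[t - 1L], p[t]]) + logB[t, p[t]]
    }
    v
  })
  as.integer(paths[which.max(lp), ])
}

randomParams <- function(K, D, seed) {
  set.seed(seed)
  mu <- matrix(rnorm(K * D, sd = 2), K, D)
  covs <- array(0, c(D, D, K))
  for (k in seq_len(K)) {
    A <- matrix(rnorm(D * D, sd = 0.4), D, D)
    covs[, , k] <- crossprod(A) + diag(D)
  }
  A <- matrix(stats::rgamma(K * K, 1), K, K)
  A <- A / rowSums(A)
  pi0 <- stats::rgamma(K, 1)
  new("HMMParams", K = as.integer(K), initialProbs = pi0 / sum(pi0),
      transitionMatrix = A, stateMeans = mu, stateCovariances = covs)
}

# brute-force best assignment over all permutations (small n)
bruteAssignment <- function(cost) {
  n <- nrow(cost)
  perms <- brainStateDyn:::.allPermutations(n)
  vals <- vapply(perms, function(p)
    sum(cost[cbind(seq_len(n), p)]), numeric(1))
  perms[[which.min(vals)]]
}

makeRun <- function(values, subject = "s1", session = "A",
                    condition = "rest", tr = 2.2) {
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("BN%02d", seq_len(ncol(values)))
  new("RunTimeSeries", subject = subject, session = session,
      condition = condition, trSeconds = tr, values = values,
      provenance = list())
}
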