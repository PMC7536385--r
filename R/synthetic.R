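#' @importFrom stats runif rnorm
NULL

#' Configuration for a synthetic brain-state cohort
#'
#' Bundles the generator settings emulating the study design the package
#' targets: a cohort of subjects scanned in two sessions, each with an
#' eyes-closed rest run and a movie-viewing run. Rest dynamics are
#' subject-idiosyncratic Markov chains concentrated on a small set of
#' dominant states (bistable by default); movie dynamics follow one shared
#' stimulus-locked master state sequence, degraded per subject by a small
#' circular time shift (jitter) and sporadic flips toward the dominant rest
#' states (attention lapses re-engaging the intrinsic regime). Emissions are
#' state-specific multivariate Gaussians over D networks.
#'
#' Engagement: each subject receives a latent engagement score in \[0,1\].
#' With `engagementCoupling > 0`, less engaged subjects deviate more often
#' from the master movie sequence (their effective flip probability is
#' `flipProb + 0.4 * engagementCoupling * (1 - engagement)`), which couples
#' individual differences in movie-state dynamics to the engagement score
#' that also drives the questionnaire in [attachQuestionnaire()]. With
#' coupling 0 all subjects share one flip probability and are exchangeable.
#'
#' @param nSubjects number of subjects (default 14).
#' @param nSessions number of sessions (default 2, labelled A and B).
#' @param kTrue number of generating states (>= 2; default 10).
#' @param D number of networks (default 14).
#' @param tRest,tMovie acquired volumes per rest / movie run (defaults 220
#'   and 535; >= 20).
#' @param trSeconds repetition time in seconds (default 2.2).
#' @param restSelfProb self-transition probability of the dominant rest
#'   states (default 0.9).
#' @param restDominantStates non-empty subset of 1..kTrue dominating rest
#'   (default: states 5 and 9 when kTrue >= 9, mirroring the bistable rest
#'   regime; states 1 and 2 otherwise).
#' @param jitterTr maximum per-subject circular shift of the master movie
#'   path, in TRs (default 2).
#' @param flipProb baseline per-TR probability that a subject's movie state
#'   deviates from the (shifted) master state (default 0.05).
#' @param meanSeparation amplitude of the +/- state mean patterns in
#'   pooled-SD units (default 2); two states differing in h pattern entries
#'   have means `2 * meanSeparation * sqrt(h)` pooled SDs apart.
#' @param covScale emission covariance scale (> 0; default 1).
#' @param physioOffsets data.frame with columns `state`, `dHR` (bpm), `dPD`
#'   (a.u.): the state-conditioned physiological offsets. Default mirrors
#'   the signs seen in naturalistic-viewing physiology: lower heart rate in
#'   one state, pupil constriction in one visually driven state and
#'   dilation in two others.
#' @param engagementCoupling strength in \[0,1\] of the engagement effect on
#'   movie dynamics (default 0.5).
#' @param seed integer seed; identical configurations generate identical
#'   cohorts.
#' @return a list of class `simConfig`.
#' @export
simConfig <- function(nSubjects = 14L, nSessions = 2L, kTrue = 10L, D = 14L,
                      tRest = 220L, tMovie = 535L, trSeconds = 2.2,
                      restSelfProb = 0.9, restDominantStates = NULL,
                      jitterTr = 2L, flipProb = 0.05, meanSeparation = 2,
                      covScale = 1, physioOffsets = NULL,
                      engagementCoupling = 0.5, seed = 1L) {
  kTrue <- as.integer(kTrue)
  if (kTrue < 2L) stop("kTrue must be >= 2")
  if (tRest < 20L || tMovie < 20L) stop("run lengths must be >= 20 timepoints")
  for (p in c(restSelfProb, flipProb, engagementCoupling)) {
    if (!is.finite(p) || p < 0 || p > 1) stop("probabilities must lie in [0,1]")
  }
  if (is.null(restDominantStates))
    restDominantStates <- if (kTrue >= 9L) c(5L, 9L) else c(1L, 2L)
  restDominantStates <- as.integer(restDominantStates)
  if (length(restDominantStates) == 0L ||
      !all(restDominantStates %in% seq_len(kTrue)))
    stop("restDominantStates must be a non-empty subset of 1..kTrue")
  if (!is.finite(covScale) || covScale <= 0)
    stop("covScale must be > 0 (degenerate covariance requested)")
  if (D < kTrue)
    stop("D must be >= kTrue so state mean patterns are distinct")
  if (is.null(physioOffsets)) {
    dHR <- numeric(kTrue); dPD <- numeric(kTrue)
    dHR[min(3L, kTrue)] <- -3
    dPD[1L] <- 0.3
    dPD[2L] <- 0.3
    dPD[min(4L, kTrue)] <- -0.4
    physioOffsets <- data.frame(state = seq_len(kTrue), dHR = dHR, dPD = dPD)
  }
  if (!all(c("state", "dHR", "dPD") %in% names(physioOffsets)) ||
      !setequal(physioOffsets$state, seq_len(kTrue)))
    stop("physioOffsets must define dHR and dPD for every state 1..kTrue")
  structure(list(
    nSubjects = as.integer(nSubjects), nSessions = as.integer(nSessions),
    kTrue = kTrue, D = as.integer(D), tRest = as.integer(tRest),
    tMovie = as.integer(tMovie), trSeconds = trSeconds,
    restSelfProb = restSelfProb, restDominantStates = restDominantStates,
    jitterTr = as.integer(jitterTr), flipProb = flipProb,
    meanSeparation = meanSeparation, covScale = covScale,
    physioOffsets = physioOffsets[order(physioOffsets$state), ],
    engagementCoupling = engagementCoupling, seed = as.integer(seed)
  ), class = "simConfig")
}

# Walsh-type +/- sign patterns, rescaled so the minimum pairwise distance
# between state means equals meanSeparation pooled SDs.
.statePatterns <- function(K, D, meanSeparation, covScale) {
  popcount <- function(x) {
    n <- 0L
    while (any(x > 0L)) { n <- n + (x %% 2L); x <- x %/% 2L }
    n
  }
  # rows 2..K+1 of the Walsh system: balanced +/- patterns, never constant,
  # so state means are distinguishable by pattern correlation
  P <- outer(seq_len(K), seq_len(D) - 1L,
             function(k, d) (-1)^popcount(bitwAnd(k, d)))
  if (any(apply(P, 1L, function(r) length(unique(r)) == 1L)))
    stop("degenerate (constant) state pattern; increase D")
  dm <- as.matrix(stats::dist(P))
  if (min(dm[upper.tri(dm)]) == 0) stop("degenerate state patterns; increase D")
  P * meanSeparation * sqrt(covScale)
}

.movieTransitions <- function(K) {
  A <- matrix(if (K > 2L) 0.10 / (K - 2L) else 0, K, K)
  for (k in seq_len(K)) A[k, (k %% K) + 1L] <- if (K > 2L) 0.10 else 0.20
  diag(A) <- 0.80
  A / rowSums(A)
}

.restTransitions <- function(K, selfProb, dom) {
  A <- matrix(0, K, K)
  nondom <- setdiff(seq_len(K), dom)
  for (k in dom) {
    A[k, k] <- selfProb
    leak <- 1 - selfProb
    otherDom <- setdiff(dom, k)
    if (length(otherDom) && length(nondom)) {
      A[k, otherDom] <- 0.9 * leak / length(otherDom)
      A[k, nondom] <- 0.1 * leak / length(nondom)
    } else if (length(otherDom)) {
      A[k, otherDom] <- leak / length(otherDom)
    } else {
      A[k, nondom] <- leak / length(nondom)
    }
  }
  for (k in nondom) {
    A[k, k] <- 0.2
    A[k, dom] <- 0.75 / length(dom)
    if (length(nondom) > 1L)
      A[k, setdiff(nondom, k)] <- 0.05 / (length(nondom) - 1L)
    else A[k, dom] <- A[k, dom] + 0.05 / length(dom)
  }
  A / rowSums(A)
}

#' Simulate a first-order Markov chain
#'
#' @param n length of the chain.
#' @param A K x K row-stochastic transition matrix.
#' @param init length-K initial distribution (default uniform).
#' @return integer vector of states in 1..K.
#' @export
simulateMarkovChain <- function(n, A, init = NULL) {
  K <- nrow(A)
  if (is.null(init)) init <- rep(1 / K, K)
  s <- integer(n)
  s[1L] <- sample.int(K, 1L, prob = init)
  for (t in seq_len(n - 1L)) {
    s[t + 1L] <- sample.int(K, 1L, prob = A[s[t], ])
  }
  s
}

.circShift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0L) x else c(x[(n - k + 1L):n], x[seq_len(n - k)])
}

#' Generate a synthetic multi-session rest + movie cohort
#'
#' Draws the cohort described by a [simConfig()]: per subject and session
#' one rest run (independent Markov chain concentrated on the dominant rest
#' states) and one movie run (shared master state sequence, circularly
#' shifted per subject-session by at most `jitterTr` TRs, with per-TR flips
#' toward the dominant rest states at the subject's effective flip
#' probability), each
#' emitted through state-specific Gaussians with means from orthogonal
#' +/- patterns and covariance `covScale * I`.
#'
#' @param config a [simConfig()].
#' @return list with `runs` (list of [RunTimeSeries-class], ordered subject,
#'   session, rest-then-movie) and `truth`: the ground truth (`trueParams`
#'   [HMMParams-class] carrying the movie-regime transition matrix,
#'   `restTransitions`, `masterMoviePath`, realized `paths` nested
#'   subject/session/condition, `engagement`, `flipProbs`, `jitters`,
#'   `physioOffsets`, `config`).
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  K <- config$kTrue; D <- config$D
  mu <- .statePatterns(K, D, config$meanSeparation, config$covScale)
  covs <- array(0, c(D, D, K))
  for (k in seq_len(K)) covs[, , k] <- diag(D) * config$covScale
  Amovie <- .movieTransitions(K)
  Arest <- .restTransitions(K, config$restSelfProb, config$restDominantStates)
  trueParams <- new("HMMParams", K = K, initialProbs = rep(1 / K, K),
                    transitionMatrix = Amovie, stateMeans = mu,
                    stateCovariances = covs)
  master <- simulateMarkovChain(config$tMovie, Amovie)
  engagement <- runif(config$nSubjects)
  flipProbs <- pmin(0.95, config$flipProb +
    0.4 * config$engagementCoupling * (1 - engagement))
  labels <- sprintf("BN%02d", seq_len(D))
  sd0 <- sqrt(config$covScale)
  subjects <- sprintf("sub%02d", seq_len(config$nSubjects))
  sessions <- LETTERS[seq_len(config$nSessions)]
  runs <- list()
  paths <- list()
  jitters <- list()
  emit <- function(path) {
    X <- mu[path, , drop = FALSE] +
      matrix(rnorm(length(path) * D, sd = sd0), length(path), D)
    colnames(X) <- labels
    X
  }
  for (i in seq_len(config$nSubjects)) {
    paths[[subjects[i]]] <- list()
    jitters[[subjects[i]]] <- list()
    for (ses in sessions) {
      restPath <- simulateMarkovChain(config$tRest, Arest,
        init = as.numeric(seq_len(K) %in% config$restDominantStates) /
          length(config$restDominantStates))
      shift <- sample(seq(-config$jitterTr, config$jitterTr), 1L)
      moviePath <- .circShift(master, shift)
      flips <- runif(config$tMovie) < flipProbs[i]
      if (any(flips)) {
        # deviations drift toward the intrinsic (rest-dominant) states:
        # attention lapses re-engage the idiosyncratic resting regime, so a
        # subject's occupancy profile shifts with (1 - engagement)
        dom <- config$restDominantStates
        moviePath[flips] <- dom[sample.int(length(dom), sum(flips),
                                           replace = TRUE)]
      }
      paths[[subjects[i]]][[ses]] <- list(rest = restPath, movie = moviePath)
      jitters[[subjects[i]]][[ses]] <- shift
      runs[[length(runs) + 1L]] <- new("RunTimeSeries",
        subject = subjects[i], session = ses, condition = "rest",
        trSeconds = config$trSeconds, values = emit(restPath),
        provenance = list())
      runs[[length(runs) + 1L]] <- new("RunTimeSeries",
        subject = subjects[i], session = ses, condition = "movie",
        trSeconds = config$trSeconds, values = emit(moviePath),
        provenance = list())
    }
  }
  truth <- list(trueParams = trueParams, restTransitions = Arest,
                masterMoviePath = master, paths = paths,
                engagement = engagement, flipProbs = flipProbs,
                jitters = jitters, physioOffsets = config$physioOffsets,
                config = config)
  list(runs = runs, truth = truth)
}

#' Sample independent segments from a Gaussian-emission HMM
#'
#' Draws `nSegments` independent state chains of length `T` from the
#' model's transition matrix (each started from its initial distribution)
#' and emits observations from the state Gaussians. This is the ground
#' truth for parameter-recovery tests: unlike [generateCohort()]'s movie
#' runs, segments share no master sequence, so the data are exactly
#' HMM-distributed.
#'
#' @param params an [HMMParams-class].
#' @param nSegments number of independent segments.
#' @param T timepoints per segment.
#' @param seed integer seed.
#' @return list with `data` (a [ConcatDataset-class]) and `paths` (list of
#'   the true state chains).
#' @export
generateHMMSegments <- function(params, nSegments, T, seed = 1L) {
  set.seed(as.integer(seed))
  K <- params@K
  D <- ncol(params@stateMeans)
  chols <- lapply(seq_len(K), function(k)
    chol(matrix(params@stateCovariances[, , k], D, D)))
  labels <- sprintf("BN%02d", seq_len(D))
  runs <- vector("list", nSegments)
  paths <- vector("list", nSegments)
  for (s in seq_len(nSegments)) {
    path <- simulateMarkovChain(T, params@transitionMatrix,
                                params@initialProbs)
    Z <- matrix(rnorm(T * D), T, D)
    X <- params@stateMeans[path, , drop = FALSE] +
      t(vapply(seq_len(T), function(t) drop(Z[t, ] %*% chols[[path[t]]]),
               numeric(D)))
    colnames(X) <- labels
    paths[[s]] <- path
    runs[[s]] <- new("RunTimeSeries", subject = sprintf("seg%02d", s),
                     session = "A", condition = "movie", trSeconds = 2.2,
                     values = X, provenance = list())
  }
  list(data = concatenateRuns(runs), paths = paths)
}

#' Derive annotation intervals from the master movie path
#'
#' Builds one annotation track per category, covering exactly the epochs of
#' the master state sequence spent in the category's assigned states,
#' expressed in seconds as half-open intervals `[onset, offset)`. Contiguous
#' epochs merge into one interval. A category assigned to states the master
#' path never visits yields zero intervals (flagged via the `empty`
#' attribute, not an error).
#'
#' @param truth ground truth from [generateCohort()].
#' @param categoryMap named list mapping category labels to state subsets.
#' @return data.frame with columns `category`, `onset_s`, `offset_s`;
#'   attribute `empty` names categories without intervals.
#' @export
attachAnnotations <- function(truth, categoryMap) {
  K <- truth$config$kTrue
  tr <- truth$config$trSeconds
  states <- unlist(categoryMap)
  if (length(states) && !all(states %in% seq_len(K)))
    stop("categoryMap references states outside 1..kTrue")
  master <- truth$masterMoviePath
  out <- list()
  empty <- character(0)
  for (cat in names(categoryMap)) {
    b <- master %in% categoryMap[[cat]]
    r <- rle(b)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- r$values
    if (!any(on)) {
      empty <- c(empty, cat)
      next
    }
    out[[cat]] <- data.frame(category = cat,
                             onset_s = (starts[on] - 1L) * tr,
                             offset_s = ends[on] * tr)
  }
  res <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
         else data.frame(category = character(0), onset_s = numeric(0),
                         offset_s = numeric(0))
  attr(res, "empty") <- empty
  res
}

.ar1 <- function(n, ar, marginalSd) {
  if (marginalSd == 0) return(numeric(n))
  innov <- rnorm(n, sd = marginalSd * sqrt(1 - ar^2))
  as.numeric(stats::filter(innov, ar, method = "recursive"))
}

#' Attach state-coupled physiological traces
#'
#' Generates TR-aligned heart-rate, pupil-diameter and luminance traces for
#' each subject's movie run (session A): baseline + state-conditioned offset
#' + stationary AR(1) noise of marginal SD `noiseSd`. Luminance is an
#' independent smooth trace whose mean-centred value is subtracted from the
#' pupil trace with weight `lumCoupling`, reproducing the negative
#' pupil-luminance association of naturalistic viewing. Baselines are
#' 70 bpm (HR), 3.0 a.u. (PD) and 1.0 a.u. (luminance).
#'
#' @param truth ground truth from [generateCohort()].
#' @param noiseSd marginal SD of the AR(1) noise (same units as each trace;
#'   0 gives a pure step function through the offsets).
#' @param arCoeff AR(1) coefficient in \[0, 1).
#' @param lumCoupling weight b >= 0 of the negative luminance effect on PD.
#' @param seed seed for the trace noise (default derived from the cohort
#'   seed).
#' @return named list (one element per subject) of lists with `hr`, `pd`,
#'   `luminance` numeric vectors of length `tMovie`.
#' @export
attachPhysio <- function(truth, noiseSd = 1, arCoeff = 0.3, lumCoupling = 0.5,
                         seed = truth$config$seed + 1L) {
  if (!is.finite(arCoeff) || arCoeff < 0 || arCoeff >= 1)
    stop("arCoeff must lie in [0, 1) for a stationary trace")
  off <- truth$physioOffsets
  K <- truth$config$kTrue
  if (!setequal(off$state, seq_len(K)))
    stop("physio offsets must be defined for all states")
  dHR <- off$dHR[order(off$state)]
  dPD <- off$dPD[order(off$state)]
  set.seed(as.integer(seed))
  out <- list()
  for (sub in names(truth$paths)) {
    path <- truth$paths[[sub]][["A"]]$movie
    n <- length(path)
    lum <- 1 + .ar1(n, max(arCoeff, 0.5), noiseSd)
    hr <- 70 + dHR[path] + .ar1(n, arCoeff, noiseSd)
    pd <- 3.0 + dPD[path] - lumCoupling * (lum - mean(lum)) +
      .ar1(n, arCoeff, noiseSd)
    out[[sub]] <- list(hr = hr, pd = pd, luminance = lum)
  }
  out
}

#' Attach engagement-coupled questionnaire ratings
#'
#' Produces the four post-movie ratings (boredom, enjoyment, emotion, audio
#' quality) on a 1-5 scale: a convex combination of the deterministic
#' monotone mapping of the subject's engagement score (boredom decreasing,
#' the other three increasing) and an independent uniform draw, with weight
#' `coupling` on the engagement component, then rounded and clipped to 1..5.
#' `coupling = 1` gives deterministic monotone ratings; `coupling = 0` gives
#' ratings independent of engagement (a null construction for calibration).
#'
#' @param truth ground truth from [generateCohort()].
#' @param coupling weight in \[0,1\] on the engagement signal (default 0.9).
#' @param seed seed for the rating noise.
#' @return data.frame with columns `subject_id`, `boredom`, `enjoyment`,
#'   `emotion`, `audio_quality` (integers in 1..5).
#' @export
attachQuestionnaire <- function(truth, coupling = 0.9,
                                seed = truth$config$seed + 2L) {
  if (!is.finite(coupling) || coupling < 0 || coupling > 1)
    stop("coupling must lie in [0,1]")
  e <- truth$engagement
  n <- length(e)
  set.seed(as.integer(seed))
  mix <- function(ideal) {
    raw <- coupling * ideal + (1 - coupling) * runif(n, 1, 5)
    pmin(5L, pmax(1L, as.integer(round(raw))))
  }
  data.frame(
    subject_id = names(truth$paths),
    boredom = mix(1 + 4 * (1 - e)),
    enjoyment = mix(1 + 4 * e),
    emotion = mix(1 + 4 * e),
    audio_quality = mix(1 + 4 * e)
  )
}
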