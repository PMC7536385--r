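#' Pipeline configuration
#'
#' Assembles every setting of a full analysis run. All stochastic stages
#' take their seed from here, and the configuration is echoed verbatim
#' into the output directory so a run can be reproduced byte for byte.
#'
#' @param outputDir artifact directory (created if needed).
#' @param sim a [simConfig()] to simulate the cohort, or `NULL` to read
#'   runs from `inputDir`.
#' @param inputDir cohort directory (layout of [writeCohort()]) when
#'   `sim` is `NULL`.
#' @param dropN initial volumes to drop per run (default 5).
#' @param band band-pass edges in Hz or `NULL` to skip filtering (default
#'   `NULL`: synthetic emissions carry no scanner drift or aliased
#'   physiological noise).
#' @param zscore z-score each network per run (default TRUE).
#' @param K number of HMM states; `NULL` selects by AIC over `kList`.
#' @param kList candidate state counts for model selection.
#' @param restarts EM restarts (default 5).
#' @param maxIter,tol EM stopping rule.
#' @param nPerm permutations for all permutation tests (default 1000).
#' @param primaryT primary threshold for the transition-graph statistic;
#'   `NULL` skips that stage.
#' @param categoryMap named list of state subsets defining annotation
#'   categories (default: one category per state when simulating).
#' @param questionnaireCoupling coupling passed to [attachQuestionnaire()].
#' @param seed master seed; stage seeds are derived as documented offsets.
#' @return list of class `runConfig`.
#' @export
runConfig <- function(outputDir, sim = NULL, inputDir = NULL, dropN = 5L,
                      band = NULL, zscore = TRUE, K = 10L, kList = NULL,
                      restarts = 5L, maxIter = 500L, tol = 1e-6,
                      nPerm = 1000L, primaryT = NULL, categoryMap = NULL,
                      questionnaireCoupling = 0.9, seed = 1L) {
  if (is.null(sim) && is.null(inputDir))
    stop("either a simulation config or an input directory is required")
  structure(list(outputDir = outputDir, sim = sim, inputDir = inputDir,
                 dropN = as.integer(dropN), band = band, zscore = zscore,
                 K = if (is.null(K)) NULL else as.integer(K),
                 kList = kList, restarts = as.integer(restarts),
                 maxIter = as.integer(maxIter), tol = tol,
                 nPerm = as.integer(nPerm), primaryT = primaryT,
                 categoryMap = categoryMap,
                 questionnaireCoupling = questionnaireCoupling,
                 seed = as.integer(seed)),
            class = "runConfig")
}

#' Run the full brain-state dynamics pipeline
#'
#' Orchestrates simulate (or load) -> preprocess -> concatenate -> fit ->
#' decode -> dynamics -> consistency -> coupling -> IS-RSA, writing every
#' artifact (TSV/JSON) plus a plain-text report into the output directory.
#' Stages communicate only through the serialized artifacts, and every
#' output is stamped with the MD5 of the echoed configuration and the
#' master seed, so identical configurations reproduce identical outputs.
#'
#' @param config a [runConfig()].
#' @return invisibly, a list with the main in-memory results (`concat`,
#'   `fit`, `decoding`, `dynamics`, `consistency`, `coupling`, `isrsa`,
#'   `report` path).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  out <- config$outputDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # --- config echo + stamp -------------------------------------------------
  cfgEcho <- config
  class(cfgEcho) <- NULL
  cfgEcho$sim <- if (is.null(config$sim)) NULL else unclass(config$sim)
  writeLines(yaml::as.yaml(cfgEcho), file.path(out, "config.yaml"))
  # stamp covers the analysis settings, not the artifact location, so two
  # runs of one configuration into different directories compare equal
  tf <- tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(cfgEcho[setdiff(names(cfgEcho), "outputDir")]), tf)
  stamp <- unname(tools::md5sum(tf))
  unlink(tf)

  # --- cohort --------------------------------------------------------------
  truth <- NULL
  questionnaire <- NULL
  physio <- NULL
  if (!is.null(config$sim)) {
    cohort <- stage("simulate", generateCohort(config$sim))
    truth <- cohort$truth
    runs <- cohort$runs
    physio <- stage("simulate", attachPhysio(truth))
    questionnaire <- stage("simulate",
      attachQuestionnaire(truth, coupling = config$questionnaireCoupling))
    categoryMap <- config$categoryMap
    if (is.null(categoryMap)) {
      categoryMap <- as.list(seq_len(config$sim$kTrue))
      names(categoryMap) <- sprintf("state%02d", seq_len(config$sim$kTrue))
    }
    annotations <- stage("simulate", attachAnnotations(truth, categoryMap))
    stage("simulate", writeCohort(cohort, file.path(out, "cohort"),
      categoryMap = categoryMap, physio = physio,
      questionnaire = questionnaire))
  } else {
    runDir <- file.path(config$inputDir, "runs")
    files <- sort(list.files(runDir, pattern = "\\.tsv$", full.names = TRUE))
    runs <- stage("load", lapply(files, readRun))
    annPath <- file.path(config$inputDir, "annotations.tsv")
    annotations <- if (file.exists(annPath)) readAnnotations(annPath) else NULL
    qPath <- file.path(config$inputDir, "questionnaire.csv")
    questionnaire <- if (file.exists(qPath)) readQuestionnaire(qPath) else NULL
    physioDir <- file.path(config$inputDir, "physio")
    if (dir.exists(physioDir)) {
      physio <- list()
      for (f in list.files(physioDir, pattern = "_(hr|pd|luminance)\\.tsv$")) {
        sub <- sub("_(hr|pd|luminance)\\.tsv$", "", f)
        kind <- sub("^.*_", "", sub("\\.tsv$", "", f))
        physio[[sub]][[kind]] <- readPhysioTrace(file.path(physioDir, f))
      }
    }
  }

  # --- preprocess + concatenate -------------------------------------------
  prepared <- stage("preprocess", lapply(runs, prepareRun,
    dropN = config$dropN, band = config$band, zscore = config$zscore))
  concat <- stage("concatenate", concatenateRuns(prepared))
  tr <- runs[[1L]]@trSeconds

  # --- fit + decode --------------------------------------------------------
  K <- config$K
  selection <- NULL
  if (is.null(K)) {
    selection <- stage("fit", selectStates(concat, config$kList,
      restarts = config$restarts, maxIter = config$maxIter,
      tol = config$tol, seed = config$seed))
    K <- selection$recommendedK
    utils::write.table(selection$table, file.path(out, "model_selection.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  fit <- stage("fit", fitHMM(concat, K, restarts = config$restarts,
    maxIter = config$maxIter, tol = config$tol, seed = config$seed))
  writeHMMParams(fit@params, file.path(out, "params.json"))
  decoding <- stage("decode", decodeStates(fit, concat))
  writeStatePaths(decoding, file.path(out, "state_paths.tsv"))

  seg <- decoding@segments
  pick <- function(cond, ses = NULL) {
    sel <- seg$condition == cond
    if (!is.null(ses)) sel <- sel & seg$session == ses
    idx <- which(sel)
    stats::setNames(decoding@paths[idx], seg$subject[idx])
  }

  # --- dynamics ------------------------------------------------------------
  dyn <- stage("dynamics", dynamicsSummary(decoding, K, tr))
  utils::write.table(dyn, file.path(out, "dynamics_summary.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  foContrast <- stage("dynamics", pairedStateContrast(dyn, "fo"))
  dwellContrast <- stage("dynamics",
    pairedStateContrast(dyn, "meanDwellSeconds"))
  trans <- lapply(seq_len(nrow(seg)), function(s)
    empiricalTransitions(decoding@paths[[s]], K))
  groupMean <- function(cond) {
    ms <- trans[seg$condition == cond]
    M <- Reduce(`+`, lapply(ms, function(x) { x[!is.finite(x)] <- 0; x }))
    M / length(ms)
  }
  topMovie <- thresholdTransitions(groupMean("movie"))
  nbs <- NULL
  if (!is.null(config$primaryT)) {
    bySub <- function(cond) {
      subjects <- unique(seg$subject)
      lapply(subjects, function(su) {
        ms <- trans[seg$subject == su & seg$condition == cond]
        M <- Reduce(`+`, lapply(ms, function(x) { x[!is.finite(x)] <- 0; x }))
        M / length(ms)
      })
    }
    nbs <- stage("dynamics", nbsTransitionContrast(bySub("rest"),
      bySub("movie"), primaryT = config$primaryT, nPerm = config$nPerm,
      seed = config$seed + 1L))
  }

  # --- consistency ---------------------------------------------------------
  consMovie <- stage("consistency",
    slidingConsistency(pick("movie", "A"), K))
  consRest <- stage("consistency", slidingConsistency(pick("rest", "A"), K))
  utils::write.table(consMovie, file.path(out, "consistency_movie.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(consRest, file.path(out, "consistency_rest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  subjects <- unique(seg$subject)
  jacc <- function(cond) vapply(subjects, function(su) {
    pA <- decoding@paths[[which(seg$subject == su & seg$session == "A" &
                                  seg$condition == cond)[1L]]]
    pB <- decoding@paths[[which(seg$subject == su & seg$session == "B" &
                                  seg$condition == cond)[1L]]]
    crossSessionJaccard(pA, pB, K)$mean
  }, numeric(1))
  consContrast <- NULL
  if (all(c("A", "B") %in% seg$session)) {
    consContrast <- stage("consistency",
      consistencyContrast(jacc("movie"), jacc("rest")))
  }

  # --- coupling ------------------------------------------------------------
  couplingTab <- NULL
  if (!is.null(annotations) && nrow(annotations)) {
    moviePaths <- pick("movie", "A")
    Tdec <- length(moviePaths[[1L]])
    tracks <- lapply(split(annotations, annotations$category), function(iv) {
      full <- binarizeAnnotations(iv, tr, Tdec + config$dropN)
      if (config$dropN > 0L) full[-seq_len(config$dropN)] else full
    })
    tracks <- Filter(function(v) sum(v) > 0L, tracks)
    couplingTab <- stage("coupling", couplingAnalysis(moviePaths, tracks, K,
      nPerm = config$nPerm, seed = config$seed + 2L))
    utils::write.table(couplingTab, file.path(out, "coupling.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  physioTab <- NULL
  if (!is.null(physio)) {
    moviePaths <- pick("movie", "A")
    common <- intersect(names(moviePaths), names(physio))
    devFor <- function(kind) do.call(rbind, lapply(common, function(su) {
      v <- physio[[su]][[kind]]
      if (config$dropN > 0L) v <- v[-seq_len(config$dropN)]
      physioStateDeviation(v, moviePaths[[su]], K)
    }))
    physioTab <- stage("coupling", list(
      hr = physioGroupTest(devFor("hr")),
      pd = physioGroupTest(devFor("pd"))))
  }

  # --- IS-RSA --------------------------------------------------------------
  isrsa <- NULL
  if (!is.null(questionnaire)) {
    moviePaths <- pick("movie", "A")
    qd <- stage("isrsa", questionnaireDistance(questionnaire))
    foMat <- do.call(rbind, lapply(moviePaths, fractionalOccupancy, K = K))
    fd <- stage("isrsa", foDistance(foMat))
    td <- stage("isrsa", transitionDistance(
      lapply(moviePaths, empiricalTransitions, K = K)))
    pd <- stage("isrsa", pathDistanceMatrix(moviePaths, K))
    mant <- function(Dbrain) mantelCorrelation(Dbrain, qd,
      nPerm = config$nPerm, seed = config$seed + 3L)
    isrsa <- stage("isrsa", list(
      foVsQuestionnaire = mant(fd),
      transitionsVsQuestionnaire = mant(td),
      pathVsQuestionnaire = mant(pd),
      mds = classicalMds(qd)))
    jsonlite::write_json(list(
      fo_vs_questionnaire = isrsa$foVsQuestionnaire,
      transitions_vs_questionnaire = isrsa$transitionsVsQuestionnaire,
      path_vs_questionnaire = isrsa$pathVsQuestionnaire,
      mds_points = isrsa$mds$points, mds_eigenvalues = isrsa$mds$eigenvalues,
      config_md5 = stamp, seed = config$seed
    ), file.path(out, "isrsa.json"), auto_unbox = TRUE, digits = NA)
  }

  # --- report --------------------------------------------------------------
  reportPath <- file.path(out, "report.txt")
  rl <- c(
    sprintf("brainStateDyn pipeline report (config md5 %s, seed %d)",
            stamp, config$seed),
    sprintf("concatenated matrix: %d x %d (%d segments)",
            nrow(concat@values), ncol(concat@values), nrow(seg)),
    sprintf("HMM: K=%d, logL=%.2f, AIC=%.2f, converged=%s",
            K, fit@loglik, fit@aic, fit@converged),
    if (!is.null(selection))
      sprintf("model selection over {%s}: recommended K=%d",
              paste(selection$table$K, collapse = ","), selection$recommendedK),
    sprintf("mean sliding consistency: movie %.1f%%, rest %.1f%%",
            mean(consMovie$percent), mean(consRest$percent)),
    if (!is.null(consContrast))
      sprintf("cross-session Jaccard: movie %.3f vs rest %.3f (t=%.2f, p=%.4g)",
              consContrast$meanMovie, consContrast$meanRest,
              consContrast$t, consContrast$p),
    sprintf("FO contrast: %d/%d states significant (Bonferroni over K)",
            sum(foContrast$significant), K),
    sprintf("top movie transitions retained: %d edges", nrow(topMovie)),
    if (!is.null(couplingTab))
      sprintf("state-annotation coupling: %d/%d significant at p < %.2g",
              sum(couplingTab$significant, na.rm = TRUE), nrow(couplingTab),
              couplingTab$pThreshold[1L]),
    if (!is.null(isrsa))
      sprintf("IS-RSA FO vs questionnaire: r=%.3f, p=%.4g",
              isrsa$foVsQuestionnaire$r, isrsa$foVsQuestionnaire$p))
  writeLines(rl, reportPath)

  invisible(list(concat = concat, fit = fit, decoding = decoding,
                 selection = selection,
                 dynamics = list(summary = dyn, foContrast = foContrast,
                                 dwellContrast = dwellContrast,
                                 topMovie = topMovie, nbs = nbs),
                 consistency = list(movie = consMovie, rest = consRest,
                                    contrast = consContrast),
                 coupling = list(annotations = couplingTab,
                                 physio = physioTab),
                 isrsa = isrsa, report = reportPath, truth = truth))
}
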