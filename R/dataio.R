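#' @importFrom utils read.csv write.csv read.delim write.table
NULL

.fmtNum <- function(x) sprintf("%.17g", x)

#' Write / read one network time-series run
#'
#' Runs are stored as TSV (header row = network labels, one row per TR,
#' full `%.17g` precision) with a JSON sidecar (same path, `.json`
#' extension) carrying subject, session, condition, TR and preprocessing
#' provenance, so `readRun(writeRun(x))` round-trips exactly.
#'
#' @param run a [RunTimeSeries-class].
#' @param path TSV file path (sidecar written next to it).
#' @return `writeRun` returns `path` invisibly; `readRun` returns the
#'   [RunTimeSeries-class].
#' @export
writeRun <- function(run, path) {
  stopifnot(is(run, "RunTimeSeries"))
  v <- run@values
  lines <- c(paste(colnames(v), collapse = "\t"),
             apply(v, 1L, function(r) paste(.fmtNum(r), collapse = "\t")))
  writeLines(lines, path)
  meta <- list(subject = run@subject, session = run@session,
               condition = run@condition, tr_seconds = run@trSeconds,
               provenance = run@provenance)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

.sidecarPath <- function(path) sub("\\.tsv$", ".json", path)

#' @rdname writeRun
#' @export
readRun <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("run file has no data rows: ", path)
  labels <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (anyDuplicated(labels))
    stop(sprintf("duplicate network labels in %s: %s", path,
                 paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  D <- length(labels)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  lens <- lengths(rows)
  if (any(lens != D))
    stop(sprintf("ragged row in %s: line %d has %d cells, expected %d",
                 path, which(lens != D)[1L] + 1L, lens[lens != D][1L], D))
  v <- matrix(suppressWarnings(as.numeric(unlist(rows))), ncol = D,
              byrow = TRUE)
  bad <- which(!is.finite(v), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or non-finite cell in %s: row %d, column %s",
                 path, bad[1L, 1L], labels[bad[1L, 2L]]))
  }
  colnames(v) <- labels
  metaPath <- .sidecarPath(path)
  meta <- if (file.exists(metaPath)) jsonlite::read_json(metaPath,
    simplifyVector = TRUE) else list()
  prov <- meta$provenance
  if (is.null(prov)) prov <- list()
  new("RunTimeSeries",
      subject = meta$subject %||% "unknown",
      session = meta$session %||% "A",
      condition = meta$condition %||% "rest",
      trSeconds = meta$tr_seconds %||% 2.2,
      values = v, provenance = as.list(prov))
}

#' Temporal preprocessing of one run
#'
#' Applies the fixed stage order drop -> band-pass filter -> confound
#' regression -> z-score, each stage recorded in the run's provenance:
#' \enumerate{
#'   \item drop the first `dropN` volumes (scanner equilibration);
#'   \item zero-phase (forward-backward) 4th-order Butterworth band-pass
#'     between `band[1]` and `band[2]` Hz (skip with `band = NULL`);
#'   \item ordinary-least-squares residualisation against the confound
#'     columns plus an intercept (skip with `confounds = NULL`);
#'   \item per-network z-scoring to zero mean, unit SD.
#' }
#'
#' @param run a [RunTimeSeries-class].
#' @param dropN number of initial volumes to discard (default 5; must be
#'   < T).
#' @param band length-2 numeric (low, high) in Hz, strictly inside
#'   (0, Nyquist); default c(0.01, 0.15). `NULL` skips filtering.
#' @param confounds optional numeric matrix of confound time series with
#'   either T (pre-drop; the first `dropN` rows are discarded alongside) or
#'   T - dropN rows.
#' @param zscore z-score each network (default TRUE).
#' @return the prepared [RunTimeSeries-class] with provenance filled in.
#' @export
prepareRun <- function(run, dropN = 5L, band = c(0.01, 0.15),
                       confounds = NULL, zscore = TRUE) {
  stopifnot(is(run, "RunTimeSeries"))
  v <- run@values
  Tfull <- nrow(v)
  dropN <- as.integer(dropN)
  if (dropN < 0L || dropN >= Tfull)
    stop("dropN must be non-negative and smaller than the run length")
  if (dropN > 0L) v <- v[-seq_len(dropN), , drop = FALSE]
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) == Tfull && dropN > 0L)
      confounds <- confounds[-seq_len(dropN), , drop = FALSE]
    if (nrow(confounds) != nrow(v))
      stop("confounds must have T or T - dropN rows")
  }
  if (!is.null(band)) {
    nyq <- 1 / (2 * run@trSeconds)
    if (length(band) != 2L || band[1L] <= 0 || band[2L] <= band[1L] ||
        band[2L] >= nyq)
      stop(sprintf("band must satisfy 0 < low < high < Nyquist (%.4f Hz)", nyq))
    bf <- signal::butter(4, band / nyq, type = "pass")
    v <- apply(v, 2L, function(x) signal::filtfilt(bf, x))
  }
  if (!is.null(confounds)) {
    X <- cbind(1, confounds)
    v <- v - X %*% qr.coef(qr(X), v)
  }
  if (zscore) {
    s <- apply(v, 2L, sd)
    if (any(s == 0)) {
      stop("constant network at z-score stage: ",
           paste(colnames(run@values)[s == 0], collapse = ", "))
    }
    v <- scale(v)
    attr(v, "scaled:center") <- NULL
    attr(v, "scaled:scale") <- NULL
  }
  colnames(v) <- colnames(run@values)
  new("RunTimeSeries", subject = run@subject, session = run@session,
      condition = run@condition, trSeconds = run@trSeconds,
      values = v,
      provenance = list(volumesDropped = dropN,
                        filtered = !is.null(band),
                        band = if (is.null(band)) NULL else as.numeric(band),
                        confoundsRegressed = !is.null(confounds),
                        zscored = isTRUE(zscore)))
}

#' Stack prepared runs into one observation matrix
#'
#' Concatenates runs row-wise in the given order into a
#' [ConcatDataset-class], recording a segment index so every row maps back
#' to its subject, session and condition. All runs must share the network
#' labels in the same order.
#'
#' @param runs list of [RunTimeSeries-class] objects.
#' @return a [ConcatDataset-class].
#' @export
concatenateRuns <- function(runs) {
  stopifnot(length(runs) >= 1L)
  labels <- colnames(runs[[1L]]@values)
  for (i in seq_along(runs)) {
    li <- colnames(runs[[i]]@values)
    if (!identical(li, labels)) {
      r <- runs[[i]]
      stop(sprintf(
        "network label order mismatch in run %d (subject %s, session %s, %s)",
        i, r@subject, r@session, r@condition))
    }
  }
  lens <- vapply(runs, function(r) nrow(r@values), integer(1))
  seg <- data.frame(
    subject = vapply(runs, function(r) r@subject, character(1)),
    session = vapply(runs, function(r) r@session, character(1)),
    condition = vapply(runs, function(r) r@condition, character(1)),
    start = c(1L, cumsum(lens)[-length(lens)] + 1L),
    length = lens)
  new("ConcatDataset", values = do.call(rbind,
      lapply(runs, function(r) r@values)), segments = seg)
}

#' Extract one segment's rows from a concatenated dataset
#'
#' @param data a [ConcatDataset-class].
#' @param i segment index (row of `segmentTable(data)`).
#' @return T x D numeric matrix.
#' @export
segmentValues <- function(data, i) {
  seg <- data@segments[i, ]
  data@values[seg$start:(seg$start + seg$length - 1L), , drop = FALSE]
}

#' Read and write annotation interval tables
#'
#' TSV with columns `category`, `onset_s`, `offset_s`; intervals are
#' half-open `[onset, offset)` in seconds.
#'
#' @param x data.frame of intervals.
#' @param path file path.
#' @return `readAnnotations` returns the data.frame.
#' @export
writeAnnotations <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeAnnotations
#' @export
readAnnotations <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("category", "onset_s", "offset_s") %in% names(x)))
    stop("annotation table must have columns category, onset_s, offset_s")
  if (any(x$offset_s <= x$onset_s))
    stop("annotation intervals must satisfy onset < offset")
  x
}

#' Read and write TR-aligned physiological traces
#'
#' One TSV per signal kind with columns `time_index` (0-based TR) and
#' `value`.
#'
#' @param values numeric vector aligned to TRs.
#' @param path file path.
#' @return `readPhysioTrace` returns the numeric vector.
#' @export
writePhysioTrace <- function(values, path) {
  utils::write.table(
    data.frame(time_index = seq_along(values) - 1L,
               value = .fmtNum(values)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePhysioTrace
#' @export
readPhysioTrace <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  as.numeric(x$value[order(x$time_index)])
}

#' Read and write questionnaire tables
#'
#' CSV with columns `subject_id`, `boredom`, `enjoyment`, `emotion`,
#' `audio_quality` (ratings 1-5).
#'
#' @param x questionnaire data.frame.
#' @param path file path.
#' @return `readQuestionnaire` returns the data.frame.
#' @export
writeQuestionnaire <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeQuestionnaire
#' @export
readQuestionnaire <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "boredom", "enjoyment", "emotion", "audio_quality")
  if (!all(need %in% names(x)))
    stop("questionnaire must have columns ", paste(need, collapse = ", "))
  x
}

#' Serialize HMM parameters to JSON
#'
#' Full-precision, schema-versioned JSON representation of an
#' [HMMParams-class].
#'
#' @param params an [HMMParams-class].
#' @param path JSON file path.
#' @return `readHMMParams` returns the [HMMParams-class].
#' @export
writeHMMParams <- function(params, path) {
  stopifnot(is(params, "HMMParams"))
  jsonlite::write_json(list(
    schema = "brainStateDyn/hmm-params/1",
    K = params@K,
    initial_probs = params@initialProbs,
    transition_matrix = params@transitionMatrix,
    state_means = params@stateMeans,
    state_covariances = lapply(seq_len(params@K), function(k)
      matrix(params@stateCovariances[, , k], ncol(params@stateMeans),
             ncol(params@stateMeans)))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeHMMParams
#' @export
readHMMParams <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  K <- as.integer(x$K)
  D <- ncol(x$state_means)
  covs <- array(0, c(D, D, K))
  sc <- x$state_covariances
  for (k in seq_len(K)) {
    covs[, , k] <- if (is.array(sc) && length(dim(sc)) == 3L)
      sc[k, , ] else as.matrix(sc[[k]])
  }
  new("HMMParams", K = K, initialProbs = as.numeric(x$initial_probs),
      transitionMatrix = as.matrix(x$transition_matrix),
      stateMeans = as.matrix(x$state_means), stateCovariances = covs)
}

#' Write decoded state paths as TSV
#'
#' Long-format table with columns `segment`, `subject`, `session`,
#' `condition`, `time_index` (0-based within segment) and `state`.
#'
#' @param decoding a [StateDecoding-class].
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeStatePaths <- function(decoding, path) {
  seg <- decoding@segments
  rows <- lapply(seq_len(nrow(seg)), function(s) {
    p <- decoding@paths[[s]]
    data.frame(segment = s, subject = seg$subject[s],
               session = seg$session[s], condition = seg$condition[s],
               time_index = seq_along(p) - 1L, state = p)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated cohort to a directory
#'
#' Lays out one directory per cohort: `runs/*.tsv` (+ JSON sidecars),
#' `annotations.tsv`, `physio/<subject>_<kind>.tsv`, `questionnaire.csv`,
#' `ground_truth.json` and `config.yaml` (echo of the generating
#' configuration).
#'
#' @param cohort output of [generateCohort()].
#' @param dir target directory (created if needed).
#' @param categoryMap optional category map for [attachAnnotations()];
#'   default assigns each state its own category.
#' @param physio optional output of [attachPhysio()].
#' @param questionnaire optional output of [attachQuestionnaire()].
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir, categoryMap = NULL, physio = NULL,
                        questionnaire = NULL) {
  dir.create(file.path(dir, "runs"), recursive = TRUE, showWarnings = FALSE)
  for (run in cohort$runs) {
    f <- sprintf("%s_ses-%s_%s.tsv", run@subject, run@session, run@condition)
    writeRun(run, file.path(dir, "runs", f))
  }
  truth <- cohort$truth
  cfg <- truth$config
  if (is.null(categoryMap)) {
    categoryMap <- as.list(seq_len(cfg$kTrue))
    names(categoryMap) <- sprintf("state%02d", seq_len(cfg$kTrue))
  }
  writeAnnotations(attachAnnotations(truth, categoryMap),
                   file.path(dir, "annotations.tsv"))
  if (!is.null(physio)) {
    dir.create(file.path(dir, "physio"), showWarnings = FALSE)
    for (sub in names(physio)) {
      for (kind in names(physio[[sub]])) {
        writePhysioTrace(physio[[sub]][[kind]],
          file.path(dir, "physio", sprintf("%s_%s.tsv", sub, kind)))
      }
    }
  }
  if (!is.null(questionnaire))
    writeQuestionnaire(questionnaire, file.path(dir, "questionnaire.csv"))
  jsonlite::write_json(list(
    schema = "brainStateDyn/ground-truth/1",
    master_movie_path = truth$masterMoviePath,
    engagement = truth$engagement,
    flip_probs = truth$flipProbs,
    physio_offsets = truth$physioOffsets,
    paths = truth$paths,
    transition_matrix_movie = truth$trueParams@transitionMatrix,
    transition_matrix_rest = truth$restTransitions,
    state_means = truth$trueParams@stateMeans
  ), file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  cfgOut <- cfg
  class(cfgOut) <- NULL
  writeLines(yaml::as.yaml(cfgOut), file.path(dir, "config.yaml"))
  invisible(dir)
}
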