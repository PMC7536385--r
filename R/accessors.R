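#' Accessors for brainStateDyn classes
#'
#' Slot access for the package's S4 containers. `runValues()` returns the
#' T x D matrix of a run, `networkLabels()` its column labels,
#' `segmentTable()` the segment index of a concatenated dataset or decoding,
#' `nStates()` the number of hidden states, `stateMeans()` /
#' `stateCovariances()` / `transitionMatrix()` / `initialProbs()` the
#' Gaussian-HMM parameters, `statePaths()` the per-segment Viterbi paths and
#' `statePosteriors()` the per-segment posterior matrices.
#'
#' @param object an object of the documented class.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases runValues networkLabels segmentTable nStates stateMeans
#'   stateCovariances transitionMatrix initialProbs statePaths
#'   statePosteriors hmmParams
NULL

#' @rdname accessors
#' @export
setGeneric("runValues", function(object) standardGeneric("runValues"))
#' @rdname accessors
#' @export
setGeneric("networkLabels", function(object) standardGeneric("networkLabels"))
#' @rdname accessors
#' @export
setGeneric("segmentTable", function(object) standardGeneric("segmentTable"))
#' @rdname accessors
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))
#' @rdname accessors
#' @export
setGeneric("stateMeans", function(object) standardGeneric("stateMeans"))
#' @rdname accessors
#' @export
setGeneric("stateCovariances", function(object) standardGeneric("stateCovariances"))
#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(object) standardGeneric("transitionMatrix"))
#' @rdname accessors
#' @export
setGeneric("initialProbs", function(object) standardGeneric("initialProbs"))
#' @rdname accessors
#' @export
setGeneric("statePaths", function(object) standardGeneric("statePaths"))
#' @rdname accessors
#' @export
setGeneric("statePosteriors", function(object) standardGeneric("statePosteriors"))
#' @rdname accessors
#' @export
setGeneric("hmmParams", function(object) standardGeneric("hmmParams"))

#' @rdname accessors
setMethod("runValues", "RunTimeSeries", function(object) object@values)
#' @rdname accessors
setMethod("runValues", "ConcatDataset", function(object) object@values)
#' @rdname accessors
setMethod("networkLabels", "RunTimeSeries", function(object) colnames(object@values))
#' @rdname accessors
setMethod("networkLabels", "ConcatDataset", function(object) colnames(object@values))
#' @rdname accessors
setMethod("segmentTable", "ConcatDataset", function(object) object@segments)
#' @rdname accessors
setMethod("segmentTable", "StateDecoding", function(object) object@segments)
#' @rdname accessors
setMethod("nStates", "HMMParams", function(object) object@K)
#' @rdname accessors
setMethod("nStates", "HMMFit", function(object) object@params@K)
#' @rdname accessors
setMethod("stateMeans", "HMMParams", function(object) object@stateMeans)
#' @rdname accessors
setMethod("stateMeans", "HMMFit", function(object) object@params@stateMeans)
#' @rdname accessors
setMethod("stateCovariances", "HMMParams", function(object) object@stateCovariances)
#' @rdname accessors
setMethod("stateCovariances", "HMMFit", function(object) object@params@stateCovariances)
#' @rdname accessors
setMethod("transitionMatrix", "HMMParams", function(object) object@transitionMatrix)
#' @rdname accessors
setMethod("transitionMatrix", "HMMFit", function(object) object@params@transitionMatrix)
#' @rdname accessors
setMethod("initialProbs", "HMMParams", function(object) object@initialProbs)
#' @rdname accessors
setMethod("initialProbs", "HMMFit", function(object) object@params@initialProbs)
#' @rdname accessors
setMethod("statePaths", "StateDecoding", function(object) object@paths)
#' @rdname accessors
setMethod("statePosteriors", "StateDecoding", function(object) object@posteriors)
#' @rdname accessors
setMethod("hmmParams", "HMMFit", function(object) object@params)

#' @rdname accessors
#' @importFrom stats AIC
#' @export
setMethod("AIC", "HMMFit", function(object, ..., k = 2) object@aic)
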