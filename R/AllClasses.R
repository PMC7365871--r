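#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Two-set fNIRS probe montage
#'
#' Describes the fixed montage used throughout the package: two 3 x 5 optode
#' probe sets, each holding eight emitters and seven detectors in a
#' checkerboard arrangement, yielding 22 source-detector channels per set
#' (44 in total). The nominal source-detector separation is 3 cm.
#'
#' @slot nSets number of probe sets (2).
#' @slot gridRows,gridCols optode grid dimensions within a set (3 x 5).
#' @slot separation nominal source-detector distance in cm.
#' @slot channels data.frame with one row per channel: \code{channel}
#'   (1--44), \code{set}, \code{channelInSet} (1--22), \code{emitter},
#'   \code{detector} (optode ids within the set), and the grid coordinates
#'   \code{erow}, \code{ecol}, \code{drow}, \code{dcol}.
#'
#' @seealso [buildProbeLayout()]
#' @exportClass ProbeLayout
setClass("ProbeLayout",
    representation(
        nSets = "integer",
        gridRows = "integer",
        gridCols = "integer",
        separation = "numeric",
        channels = "data.frame"
    )
)

setValidity("ProbeLayout", function(object) {
    ch <- object@channels
    msg <- NULL
    if (nrow(ch) != object@nSets * 22L)
        msg <- c(msg, "expected 22 channels per probe set")
    if (!identical(ch$channel, seq_len(nrow(ch))))
        msg <- c(msg, "channel indices must be 1..n in order")
    adj <- abs(ch$erow - ch$drow) + abs(ch$ecol - ch$dcol)
    if (any(adj != 1L))
        msg <- c(msg, "every channel must pair grid-adjacent optodes")
    if (is.null(msg)) TRUE else msg
})

#' One participant's multichannel fNIRS recording
#'
#' Holds chromophore concentration-change time series (columns = channels,
#' rows = samples) for oxy- and deoxy-hemoglobin together with the trial
#' schedule that generated or accompanies them.
#'
#' @slot participantId character scalar.
#' @slot samplingRate sampling rate in Hz.
#' @slot oxy,deoxy numeric matrices, time x channel, identical dimensions.
#' @slot schedule data.frame of trials (see [generateSchedule()]).
#'
#' @seealso [simulateParticipant()], [bandpassRecording()], [extractBlocks()]
#' @exportClass NirsRecording
setClass("NirsRecording",
    representation(
        participantId = "character",
        samplingRate = "numeric",
        oxy = "matrix",
        deoxy = "matrix",
        schedule = "data.frame"
    )
)

setValidity("NirsRecording", function(object) {
    msg <- NULL
    if (!identical(dim(object@oxy), dim(object@deoxy)))
        msg <- c(msg, "oxy and deoxy must have identical dimensions")
    if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
        msg <- c(msg, "samplingRate must be a positive scalar")
    if (anyNA(object@oxy) || anyNA(object@deoxy))
        msg <- c(msg, "missing samples are not allowed")
    if (is.null(msg)) TRUE else msg
})

#' Epoched language blocks for one participant
#'
#' Fixed-length epochs time-locked to question onset, one per
#' (trial, channel, chromophore), stored as dense arrays. A 5-s pre-onset
#' margin is retained alongside each block so that linear baseline
#' correction can anchor on pre-task signal.
#'
#' @slot participantId character scalar.
#' @slot samplingRate Hz.
#' @slot samples numeric array \code{[block, time, channel, chromophore]}
#'   covering \code{[0, 33)} s from question onset; chromophore 1 = oxy,
#'   2 = deoxy.
#' @slot pre numeric array \code{[block, time, channel, chromophore]}
#'   covering \code{[-5, 0)} s.
#' @slot info data.frame with one row per block: \code{block}, \code{run},
#'   \code{trial}, \code{language}, \code{onset}.
#' @slot baselineCorrected logical flag.
#'
#' @seealso [extractBlocks()], [baselineCorrect()], [windowAverage()]
#' @exportClass NirsBlockSet
setClass("NirsBlockSet",
    representation(
        participantId = "character",
        samplingRate = "numeric",
        samples = "array",
        pre = "array",
        info = "data.frame",
        baselineCorrected = "logical"
    )
)

setValidity("NirsBlockSet", function(object) {
    msg <- NULL
    d <- dim(object@samples)
    if (length(d) != 4L || d[4] != 2L)
        msg <- c(msg, "samples must be a [block, time, channel, 2] array")
    if (d[1] != nrow(object@info))
        msg <- c(msg, "info must have one row per block")
    if (d[2] != round(33 * object@samplingRate))
        msg <- c(msg, "block length must be round(33 * samplingRate) samples")
    if (is.null(msg)) TRUE else msg
})

#' Participant-by-channel activation feature matrix
#'
#' A \linkS4class{SummarizedExperiment} whose single assay
#' (\code{"indicators"}) holds the 44 per-channel activation indicators for
#' each participant (rows = channels, columns = participants). Column data
#' carry the proficiency label (\code{"high"}/\code{"low"}) and the
#' behavioral correct-answer rate; metadata records the language the
#' features were computed for.
#'
#' @seealso [buildFeatureMatrix()], [activationIndicator()]
#' @exportClass FeatureMatrix
setClass("FeatureMatrix", contains = "SummarizedExperiment")

setValidity("FeatureMatrix", function(object) {
    msg <- NULL
    if (nrow(object) != 44L)
        msg <- c(msg, "a FeatureMatrix has exactly 44 channel rows")
    if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'label' column")
    else if (!all(object$label %in% c("high", "low")))
        msg <- c(msg, "labels must be 'high' or 'low'")
    a <- SummarizedExperiment::assay(object, "indicators")
    if (!all(is.finite(a)))
        msg <- c(msg, "all activation indicators must be finite")
    if (is.null(msg)) TRUE else msg
})

#' Stability-selection profile from leave-one-out sparse CCA
#'
#' Records, for each of the 44 channels, in how many leave-one-out folds the
#' channel entered the sparse CCA support, plus the derived set of common
#' informative features (channels selected in more than
#' \code{floor(fraction * N)} folds).
#'
#' @slot counts integer vector of length 44.
#' @slot n number of folds (= participants).
#' @slot fraction selection-frequency cutoff (default 0.95).
#' @slot threshold integer count cutoff, \code{floor(fraction * n)}.
#' @slot commonFeatures integer vector of channels with
#'   \code{counts > threshold}.
#' @slot lambdaX per-fold L1 budgets used for the feature side.
#'
#' @seealso [loocvSelectionProfile()], [commonFeatures()]
#' @exportClass SelectionProfile
setClass("SelectionProfile",
    representation(
        counts = "integer",
        n = "integer",
        fraction = "numeric",
        threshold = "integer",
        commonFeatures = "integer",
        lambdaX = "numeric"
    )
)

setValidity("SelectionProfile", function(object) {
    msg <- NULL
    if (any(object@counts < 0L) || any(object@counts > object@n))
        msg <- c(msg, "counts must lie in [0, n]")
    expected <- which(object@counts > object@threshold)
    if (!identical(object@commonFeatures, as.integer(expected)))
        msg <- c(msg, "commonFeatures must equal {c : counts[c] > threshold}")
    if (is.null(msg)) TRUE else msg
})

#' Leave-one-out classification result
#'
#' Per-fold predictions together with the aggregated confusion matrix. The
#' positive class is \code{"high"} proficiency.
#'
#' @slot folds data.frame with columns \code{id}, \code{truth},
#'   \code{predicted}, one row per participant.
#' @slot classifier name of the classifier ("svm", "slr" or "knn").
#' @slot features integer vector of channel indices the model was
#'   restricted to.
#'
#' @seealso [loocvClassify()], [confusionCounts()], [accuracy()]
#' @exportClass ClassificationResult
setClass("ClassificationResult",
    representation(
        folds = "data.frame",
        classifier = "character",
        features = "integer"
    )
)

setValidity("ClassificationResult", function(object) {
    msg <- NULL
    need <- c("id", "truth", "predicted")
    if (!all(need %in% names(object@folds)))
        msg <- c(msg, "folds needs columns id, truth, predicted")
    if (anyDuplicated(object@folds$id))
        msg <- c(msg, "each participant must be predicted exactly once")
    if (is.null(msg)) TRUE else msg
})
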