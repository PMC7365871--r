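#' Accessors for fnirsCCA objects
#'
#' Small accessor generics following Bioconductor conventions: slot access
#' goes through these, never through `@`.
#'
#' @param object an fnirsCCA object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("participantId", function(object) standardGeneric("participantId"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("oxySeries", function(object) standardGeneric("oxySeries"))

#' @rdname accessors
#' @export
setGeneric("deoxySeries", function(object) standardGeneric("deoxySeries"))

#' @rdname accessors
#' @export
setGeneric("trialSchedule", function(object) standardGeneric("trialSchedule"))

#' @rdname accessors
#' @export
setGeneric("channelTable", function(object) standardGeneric("channelTable"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("blockInfo", function(object) standardGeneric("blockInfo"))

#' @rdname accessors
#' @export
setGeneric("nBlocks", function(object) standardGeneric("nBlocks"))

#' @rdname accessors
#' @export
setGeneric("isBaselineCorrected",
    function(object) standardGeneric("isBaselineCorrected"))

#' @rdname accessors
#' @export
setGeneric("selectionCounts",
    function(object) standardGeneric("selectionCounts"))

#' @rdname accessors
#' @export
setGeneric("commonFeatures",
    function(object, ...) standardGeneric("commonFeatures"))

#' @rdname accessors
#' @export
setGeneric("foldPredictions",
    function(object) standardGeneric("foldPredictions"))

#' @rdname accessors
#' @export
setGeneric("confusionCounts",
    function(object) standardGeneric("confusionCounts"))

#' @rdname accessors
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))

## ---- methods ----

#' @rdname accessors
setMethod("participantId", "NirsRecording", function(object)
    object@participantId)

#' @rdname accessors
setMethod("participantId", "NirsBlockSet", function(object)
    object@participantId)

#' @rdname accessors
setMethod("samplingRate", "NirsRecording", function(object)
    object@samplingRate)

#' @rdname accessors
setMethod("samplingRate", "NirsBlockSet", function(object)
    object@samplingRate)

#' @rdname accessors
setMethod("oxySeries", "NirsRecording", function(object) object@oxy)

#' @rdname accessors
setMethod("deoxySeries", "NirsRecording", function(object) object@deoxy)

#' @rdname accessors
setMethod("trialSchedule", "NirsRecording", function(object) object@schedule)

#' @rdname accessors
setMethod("channelTable", "ProbeLayout", function(object) object@channels)

#' @rdname accessors
setMethod("nChannels", "ProbeLayout", function(object)
    nrow(object@channels))

#' @rdname accessors
setMethod("nChannels", "NirsRecording", function(object) ncol(object@oxy))

#' @rdname accessors
setMethod("blockInfo", "NirsBlockSet", function(object) object@info)

#' @rdname accessors
setMethod("nBlocks", "NirsBlockSet", function(object)
    dim(object@samples)[1L])

#' @rdname accessors
setMethod("isBaselineCorrected", "NirsBlockSet", function(object)
    object@baselineCorrected)

#' @rdname accessors
setMethod("selectionCounts", "SelectionProfile", function(object)
    object@counts)

#' @rdname accessors
setMethod("commonFeatures", "SelectionProfile", function(object, ...)
    object@commonFeatures)

#' @rdname accessors
setMethod("foldPredictions", "ClassificationResult", function(object)
    object@folds)

#' @rdname accessors
setMethod("confusionCounts", "ClassificationResult", function(object) {
    truth <- object@folds$truth
    pred <- object@folds$predicted
    c(
        TP = sum(truth == "high" & pred == "high"),
        TN = sum(truth == "low" & pred == "low"),
        FP = sum(truth == "low" & pred == "high"),
        FN = sum(truth == "high" & pred == "low")
    )
})

#' @rdname accessors
setMethod("accuracy", "ClassificationResult", function(object)
    accuracyFromConfusion(confusionCounts(object)))

## ---- show ----

setMethod("show", "ProbeLayout", function(object) {
    cat(sprintf(
        "ProbeLayout: %d sets of %dx%d optodes, %d channels (%g cm separation)\n",
        object@nSets, object@gridRows, object@gridCols,
        nChannels(object), object@separation))
})

setMethod("show", "NirsRecording", function(object) {
    cat(sprintf(
        "NirsRecording '%s': %d channels x %d samples at %g Hz, %d trials\n",
        object@participantId, ncol(object@oxy), nrow(object@oxy),
        object@samplingRate, nrow(object@schedule)))
})

setMethod("show", "NirsBlockSet", function(object) {
    d <- dim(object@samples)
    cat(sprintf(
        "NirsBlockSet '%s': %d blocks x %d samples x %d channels, baseline %s\n",
        object@participantId, d[1], d[2], d[3],
        if (object@baselineCorrected) "corrected" else "raw"))
})

setMethod("show", "SelectionProfile", function(object) {
    cat(sprintf(
        "SelectionProfile: N = %d folds, keep counts > %d (%.0f%% rule)\n",
        object@n, object@threshold, 100 * object@fraction))
    cat("common informative features:",
        if (length(object@commonFeatures))
            paste(object@commonFeatures, collapse = ", ") else "(none)",
        "\n")
})

setMethod("show", "ClassificationResult", function(object) {
    cc <- confusionCounts(object)
    cat(sprintf(
        "ClassificationResult (%s, %d features): accuracy %.3f (TP %d TN %d FP %d FN %d)\n",
        object@classifier, length(object@features), accuracy(object),
        cc["TP"], cc["TN"], cc["FP"], cc["FN"]))
})
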