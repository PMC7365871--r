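#' Per-channel activation indicator
#'
#' Standardised contrast between the oxy- and deoxy-hemoglobin block
#' amplitudes of one channel:
#' \deqn{(\bar{oxy} - \bar{deoxy}) /
#'       \sqrt{S_{oxy}^2 / n + S_{deoxy}^2 / m},}
#' with sample means, sample (n-1) standard deviations and sample sizes
#' \code{n}, \code{m} -- identical to a Welch two-sample t statistic. The
#' inputs are the per-block 5--18 s window averages for one (participant,
#' channel, language).
#'
#' @param oxyValues,deoxyValues numeric vectors of block window averages,
#'   each of length at least 2.
#' @return the scalar indicator.
#' @examples
#' activationIndicator(c(1, 1, 1, 1) + rnorm(4), rnorm(4))
#' @export
activationIndicator <- function(oxyValues, deoxyValues) {
    n <- length(oxyValues)
    m <- length(deoxyValues)
    if (n < 2L || m < 2L)
        stop("need at least two block amplitudes per chromophore")
    se2 <- stats::var(oxyValues) / n + stats::var(deoxyValues) / m
    if (se2 <= 0)
        stop("zero variance in both chromophores; indicator undefined")
    (mean(oxyValues) - mean(deoxyValues)) / sqrt(se2)
}

#' Assemble the participant-by-channel feature matrix
#'
#' Computes, for one language, the 44-dimensional activation vector
#' \code{A = (a_1, ..., a_44)} of every participant (one
#' [activationIndicator()] per channel from that participant's block window
#' averages) and packs them into a \linkS4class{FeatureMatrix}.
#'
#' @param windowAverages tidy data.frame as returned by [windowAverage()] /
#'   [preprocessRecording()], rows covering all participants.
#' @param language which language's blocks to use ("L1", "L2" or "L3").
#' @param participants character vector fixing the participant (column)
#'   order.
#' @param labels named character vector ("high"/"low") covering
#'   \code{participants}.
#' @param behavioralRates optional named numeric vector of correct-answer
#'   rates.
#' @return a \linkS4class{FeatureMatrix} (44 channels x N participants).
#' @export
buildFeatureMatrix <- function(windowAverages, language, participants,
                               labels, behavioralRates = NULL) {
    wa <- windowAverages[windowAverages$language == language, ]
    X <- matrix(NA_real_, nrow = 44L, ncol = length(participants),
                dimnames = list(paste0("Ch", 1:44), participants))
    missing <- character()
    for (p in participants) {
        wp <- wa[wa$participant == p, ]
        for (ch in 1:44) {
            oxy <- wp$value[wp$channel == ch & wp$chromophore == "oxy"]
            deoxy <- wp$value[wp$channel == ch & wp$chromophore == "deoxy"]
            if (length(oxy) < 2L || length(deoxy) < 2L) {
                missing <- c(missing, sprintf("%s/Ch%d", p, ch))
                next
            }
            X[ch, p] <- activationIndicator(oxy, deoxy)
        }
    }
    if (length(missing))
        stop("insufficient blocks for: ",
             paste(utils::head(missing, 10L), collapse = ", "))

    cd <- S4Vectors::DataFrame(
        id = participants,
        label = unname(labels[participants]),
        row.names = participants)
    if (!is.null(behavioralRates))
        cd$behavioralRate <- unname(behavioralRates[participants])

    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(indicators = X),
        rowData = S4Vectors::DataFrame(channel = 1:44),
        colData = cd)
    S4Vectors::metadata(se)$language <- language
    new("FeatureMatrix", se)
}

#' Feature matrix as participants-by-channels numeric matrix
#'
#' Convenience accessor: transposes the assay into the N x 44 orientation
#' classifiers expect, with a parallel label vector.
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @return list with \code{X} (N x 44 matrix) and \code{y} (character
#'   labels).
#' @export
featureData <- function(fm) {
    stopifnot(is(fm, "FeatureMatrix"))
    list(X = t(SummarizedExperiment::assay(fm, "indicators")),
         y = fm$label)
}

#' Participant-consistency exclusion
#'
#' Retains participants whose behavioral correct-answer rate does not
#' contradict their proficiency label: high-proficiency participants must
#' score at least \code{highThreshold}, low-proficiency participants at
#' most \code{lowThreshold}.
#'
#' @param labels named character vector ("high"/"low").
#' @param behavioralRates named numeric vector aligned with \code{labels}.
#' @param highThreshold,lowThreshold rate cutoffs (default 0.5).
#' @return character vector of retained participant ids.
#' @export
selectConsistentParticipants <- function(labels, behavioralRates,
                                         highThreshold = 0.5,
                                         lowThreshold = 0.5) {
    if (!all(names(labels) %in% names(behavioralRates)))
        stop("every labeled participant needs a behavioral rate")
    rates <- behavioralRates[names(labels)]
    keep <- (labels == "high" & rates >= highThreshold) |
            (labels == "low" & rates <= lowThreshold)
    names(labels)[keep]
}
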