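#' Write and read recordings as long-format CSV
#'
#' One row per (time point, channel) with both chromophores:
#' \code{time_s, channel, oxy, deoxy}. Events go to a BIDS-style TSV via
#' [writeEventsTSV()].
#'
#' @param recording a \linkS4class{NirsRecording}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeRecordingCSV <- function(recording, path) {
    fs <- samplingRate(recording)
    oxy <- oxySeries(recording)
    nT <- nrow(oxy)
    nCh <- ncol(oxy)
    dt <- data.table::data.table(
        time_s = rep((seq_len(nT) - 1) / fs, nCh),
        channel = rep(seq_len(nCh), each = nT),
        oxy = as.vector(oxy),
        deoxy = as.vector(deoxySeries(recording)))
    data.table::fwrite(dt, path)
    invisible(path)
}

#' @rdname writeRecordingCSV
#' @param eventsPath path of the events TSV accompanying the series CSV.
#' @param participantId participant identifier for the rebuilt object.
#' @param samplingRate sampling rate in Hz of the stored series.
#' @return \code{readRecordingCSV}: a \linkS4class{NirsRecording}.
#' @export
readRecordingCSV <- function(path, eventsPath, participantId,
                             samplingRate) {
    dt <- data.table::fread(path)
    nCh <- length(unique(dt$channel))
    nT <- nrow(dt) / nCh
    oxy <- matrix(dt$oxy, nrow = nT, ncol = nCh)
    deoxy <- matrix(dt$deoxy, nrow = nT, ncol = nCh)
    colnames(oxy) <- colnames(deoxy) <- paste0("Ch", seq_len(nCh))
    new("NirsRecording",
        participantId = participantId, samplingRate = samplingRate,
        oxy = oxy, deoxy = deoxy, schedule = readEventsTSV(eventsPath))
}

#' Write and read trial schedules as BIDS-style events TSV
#'
#' Columns \code{onset}, \code{duration} (question period),
#' \code{trial_type} (language), \code{run}, \code{reaction_dur},
#' \code{rest_dur}.
#'
#' @param schedule a [generateSchedule()] data.frame.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeEventsTSV <- function(schedule, path) {
    ev <- data.frame(
        onset = schedule$onset,
        duration = schedule$questionDur,
        trial_type = schedule$language,
        run = schedule$run,
        reaction_dur = schedule$reactionDur,
        rest_dur = schedule$restDur)
    utils::write.table(ev, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeEventsTSV
#' @return \code{readEventsTSV}: a schedule data.frame.
#' @export
readEventsTSV <- function(path) {
    ev <- utils::read.delim(path, stringsAsFactors = FALSE)
    sched <- data.frame(
        run = ev$run,
        trial = stats::ave(ev$onset, ev$run, FUN = seq_along),
        onset = ev$onset,
        language = ev$trial_type,
        questionDur = ev$duration,
        reactionDur = ev$reaction_dur,
        restDur = ev$rest_dur)
    sched
}

#' Write a cohort manifest as JSON
#'
#' Records ids, labels, behavioral rates, the master seed and an echo of
#' the simulation configuration.
#'
#' @param cohort a [simulateCohort()] result.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeCohortManifest <- function(cohort, path) {
    manifest <- list(
        ids = names(cohort$labels),
        labels = unname(cohort$labels),
        behavioralRates = unname(cohort$behavioralRates),
        seed = cohort$config$seed,
        config = cohort$config[setdiff(names(cohort$config), "seed")])
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
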