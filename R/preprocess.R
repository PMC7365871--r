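#' Default extinction coefficients for a 695/830 nm system
#'
#' Molar extinction coefficients (1/(mM*cm)) of oxy- and deoxy-hemoglobin
#' at the two measurement wavelengths, rows = wavelengths (695, 830 nm),
#' columns = chromophores (oxy, deoxy). Literature values; override with
#' instrument-specific coefficients where available.
#'
#' @return 2 x 2 numeric matrix.
#' @export
defaultExtinction <- function() {
    matrix(c(0.350, 1.989,
             1.058, 0.740),
           nrow = 2, byrow = TRUE,
           dimnames = list(c("od695", "od830"), c("oxy", "deoxy")))
}

#' Modified Lambert-Beer conversion
#'
#' Converts optical-density changes at two wavelengths into oxy-/deoxy-
#' hemoglobin concentration changes by inverting the two-wavelength linear
#' forward model \code{OD = L * E \%*\% c(oxy, deoxy)} sample by sample,
#' where \code{E} is the extinction matrix and \code{L} the (differential)
#' pathlength factor.
#'
#' @param od695,od830 optical-density change series, equal length.
#' @param extinction 2 x 2 extinction matrix, rows = wavelengths
#'   (695, 830 nm), columns = chromophores (oxy, deoxy).
#' @param pathlengthFactor dimensionless pathlength scaling.
#' @return list with numeric vectors \code{oxy} and \code{deoxy}.
#' @examples
#' mbllConvert(c(0, 0.1), c(0, 0.2))
#' @export
mbllConvert <- function(od695, od830, extinction = defaultExtinction(),
                        pathlengthFactor = 1) {
    if (length(od695) != length(od830))
        stop("od695 and od830 must have the same length")
    E <- extinction * pathlengthFactor
    if (abs(det(E)) < .Machine$double.eps * 100)
        stop("extinction matrix is singular; cannot invert the MBLL system")
    conc <- solve(E, rbind(od695, od830))
    list(oxy = conc[1, ], deoxy = conc[2, ])
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward-backward
#' (\code{signal::filtfilt}), so the output has no group delay and block
#' timing is preserved. Output length equals input length. The default
#' 0.01--0.8 Hz band removes drift and cardiac pulsation while keeping the
#' task-locked hemodynamic response.
#'
#' @param x numeric vector or time x channel matrix.
#' @param samplingRate Hz.
#' @param low,high band edges in Hz; must satisfy
#'   \code{0 < low < high < samplingRate / 2}.
#' @param order Butterworth order.
#' @return filtered vector or matrix of the same shape.
#' @export
bandpass <- function(x, samplingRate, low = 0.01, high = 0.8, order = 3) {
    if (!(low > 0 && low < high && high < samplingRate / 2))
        stop("band edges must satisfy 0 < low < high < samplingRate/2")
    bf <- signal::butter(order, c(low, high) / (samplingRate / 2),
                         type = "pass")
    vec <- !is.matrix(x)
    if (vec) x <- matrix(x, ncol = 1)
    y <- filtfiltMatrix(x, as.numeric(bf$b), as.numeric(bf$a))
    if (vec) drop(y) else y
}

## forward-backward filtering with odd (reflect-and-flip) edge extension,
## compiled inner loop; zero phase by construction
filtfiltMatrix <- function(x, b, a) {
    nT <- nrow(x)
    npad <- min(3L * (max(length(a), length(b)) - 1L), nT - 1L)
    head <- 2 * matrix(x[1, ], npad, ncol(x), byrow = TRUE) -
        x[(npad + 1):2, , drop = FALSE]
    tail <- 2 * matrix(x[nT, ], npad, ncol(x), byrow = TRUE) -
        x[(nT - 1):(nT - npad), , drop = FALSE]
    xp <- rbind(head, x, tail)
    y <- iirFilterMatrix(xp, b, a)
    y <- iirFilterMatrix(y[nrow(y):1, , drop = FALSE], b, a)
    y <- y[nrow(y):1, , drop = FALSE]
    out <- y[(npad + 1):(npad + nT), , drop = FALSE]
    dimnames(out) <- dimnames(x)
    out
}

#' Band-pass filter a recording
#'
#' Applies [bandpass()] to every channel of both chromophores of a
#' \linkS4class{NirsRecording}, returning a new recording.
#'
#' @inheritParams bandpass
#' @param recording a \linkS4class{NirsRecording}.
#' @return a filtered \linkS4class{NirsRecording}.
#' @export
bandpassRecording <- function(recording, low = 0.01, high = 0.8,
                              order = 3) {
    fs <- samplingRate(recording)
    new("NirsRecording",
        participantId = participantId(recording),
        samplingRate = fs,
        oxy = bandpass(oxySeries(recording), fs, low, high, order),
        deoxy = bandpass(deoxySeries(recording), fs, low, high, order),
        schedule = trialSchedule(recording))
}

#' Epoch a recording into fixed-length language blocks
#'
#' Cuts one 33-s block per trial, per channel, per chromophore, time-locked
#' to the trial's question onset, labelling each block with the trial's
#' language. A 5-s pre-onset margin is stored alongside each block for
#' baseline correction. The block spans \code{[0, 33)} s from onset
#' regardless of the trial's actual reaction/rest durations.
#'
#' @param recording a \linkS4class{NirsRecording}.
#' @param blockDur block duration in s.
#' @param preDur pre-onset margin in s.
#' @return a \linkS4class{NirsBlockSet}.
#' @export
extractBlocks <- function(recording, blockDur = 33, preDur = 5) {
    fs <- samplingRate(recording)
    sched <- trialSchedule(recording)
    nSamp <- round(blockDur * fs)
    nPre <- round(preDur * fs)
    nT <- nrow(oxySeries(recording))
    nCh <- nChannels(recording)
    nB <- nrow(sched)

    samples <- array(NA_real_, c(nB, nSamp, nCh, 2L))
    pre <- array(NA_real_, c(nB, nPre, nCh, 2L))
    series <- list(oxySeries(recording), deoxySeries(recording))

    for (b in seq_len(nB)) {
        i0 <- round(sched$onset[b] * fs) + 1L
        if (i0 - nPre < 1L)
            stop(sprintf(
                "trial %d (run %d): %g s pre-onset margin not available",
                sched$trial[b], sched$run[b], preDur))
        if (i0 + nSamp - 1L > nT)
            stop(sprintf(
                "trial %d (run %d): 33-s window exceeds the recording end",
                sched$trial[b], sched$run[b]))
        for (k in 1:2) {
            samples[b, , , k] <- series[[k]][i0:(i0 + nSamp - 1L), ]
            pre[b, , , k] <- series[[k]][(i0 - nPre):(i0 - 1L), ]
        }
    }

    new("NirsBlockSet",
        participantId = participantId(recording),
        samplingRate = fs, samples = samples, pre = pre,
        info = data.frame(
            block = seq_len(nB), run = sched$run, trial = sched$trial,
            language = sched$language, onset = sched$onset),
        baselineCorrected = FALSE)
}

#' Linear baseline correction of language blocks
#'
#' For each block (per channel, per chromophore), fits the straight line
#' through two anchor points -- the mean over the 5 s before question onset
#' and the mean over a 5-s tail window -- and subtracts it. The anchor
#' abscissae are the mean sample times of the two windows, so a block that
#' is exactly a straight line maps to zero. With \code{tail = "block"}
#' (default) the tail window is the last 5 s of the 33-s block; with
#' \code{tail = "task"} it is the last 5 s of the 18-s question period.
#'
#' @param blockset a \linkS4class{NirsBlockSet} with pre-onset margins.
#' @param tailWindowDur tail anchor window length in s.
#' @param tail anchor convention, \code{"block"} or \code{"task"}.
#' @return a baseline-corrected \linkS4class{NirsBlockSet}.
#' @export
baselineCorrect <- function(blockset, tailWindowDur = 5,
                            tail = c("block", "task")) {
    tail <- match.arg(tail)
    fs <- samplingRate(blockset)
    d <- dim(blockset@samples)
    nSamp <- d[2]
    nPre <- dim(blockset@pre)[2]
    if (nPre < round(tailWindowDur * fs))
        stop("insufficient pre-task margin for baseline correction")

    tBlock <- (seq_len(nSamp) - 1) / fs      # time from onset
    tPre <- -rev(seq_len(nPre)) / fs         # [-5, 0)
    nTail <- round(tailWindowDur * fs)
    tailIdx <- if (tail == "block") (nSamp - nTail + 1L):nSamp
               else which(tBlock >= 18 - tailWindowDur & tBlock < 18)
    t1 <- mean(tPre)
    t2 <- mean(tBlock[tailIdx])

    samples <- blockset@samples
    pre <- blockset@pre
    for (k in 1:2) {
        for (ch in seq_len(d[3])) {
            pm <- pre[, , ch, k, drop = FALSE]
            dim(pm) <- dim(pm)[1:2]
            sm <- samples[, tailIdx, ch, k, drop = FALSE]
            dim(sm) <- dim(sm)[1:2]
            m1 <- rowMeans(pm)
            m2 <- rowMeans(sm)
            slope <- (m2 - m1) / (t2 - t1)
            intercept <- m1 - slope * t1
            samples[, , ch, k] <- samples[, , ch, k] -
                (outer(slope, tBlock) + intercept)
            pre[, , ch, k] <- pre[, , ch, k] -
                (outer(slope, tPre) + intercept)
        }
    }

    new("NirsBlockSet",
        participantId = participantId(blockset),
        samplingRate = fs, samples = samples, pre = pre,
        info = blockInfo(blockset), baselineCorrected = TRUE)
}

#' Window-average block amplitudes
#'
#' Averages each baseline-corrected block over the post-onset window
#' (default 5--18 s, half-open \code{[5, 18)} on the sample grid),
#' capturing the delayed hemodynamic response to the question period. One
#' amplitude per (block, channel, chromophore).
#'
#' @param blockset a baseline-corrected \linkS4class{NirsBlockSet}.
#' @param window numeric length-2, window in s from question onset.
#' @param requireBaseline error if the blockset is not baseline-corrected.
#' @return tidy data.frame: \code{participant}, \code{block}, \code{run},
#'   \code{language}, \code{channel}, \code{chromophore}, \code{value}.
#' @export
windowAverage <- function(blockset, window = c(5, 18),
                          requireBaseline = TRUE) {
    if (requireBaseline && !isBaselineCorrected(blockset))
        stop("blockset must be baseline-corrected before window averaging")
    fs <- samplingRate(blockset)
    d <- dim(blockset@samples)
    tBlock <- (seq_len(d[2]) - 1) / fs
    idx <- which(tBlock >= window[1] & tBlock < window[2])
    info <- blockInfo(blockset)

    vals <- apply(blockset@samples[, idx, , , drop = FALSE],
                  c(1, 3, 4), mean)
    out <- expand.grid(
        block = seq_len(d[1]), channel = seq_len(d[3]),
        chromophore = c("oxy", "deoxy"), KEEP.OUT.ATTRS = FALSE,
        stringsAsFactors = FALSE)
    out$value <- as.vector(vals)
    out$participant <- participantId(blockset)
    out$run <- info$run[out$block]
    out$language <- info$language[out$block]
    out[, c("participant", "block", "run", "language", "channel",
            "chromophore", "value")]
}

#' In-window sample table (time-point mode)
#'
#' Alternative to [windowAverage()]: returns every in-window sample
#' rather than one amplitude per block, so the downstream activation
#' indicator pools time points over blocks (n = m = samples-per-window x
#' blocks) instead of using block amplitudes. [buildFeatureMatrix()]
#' accepts either table.
#'
#' @inheritParams windowAverage
#' @return tidy data.frame with the same columns as [windowAverage()],
#'   one row per (block, in-window sample, channel, chromophore).
#' @export
windowSamples <- function(blockset, window = c(5, 18),
                          requireBaseline = TRUE) {
    if (requireBaseline && !isBaselineCorrected(blockset))
        stop("blockset must be baseline-corrected")
    fs <- samplingRate(blockset)
    d <- dim(blockset@samples)
    tBlock <- (seq_len(d[2]) - 1) / fs
    idx <- which(tBlock >= window[1] & tBlock < window[2])
    info <- blockInfo(blockset)
    sub <- blockset@samples[, idx, , , drop = FALSE]
    out <- expand.grid(
        block = seq_len(d[1]), sample = idx, channel = seq_len(d[3]),
        chromophore = c("oxy", "deoxy"), KEEP.OUT.ATTRS = FALSE,
        stringsAsFactors = FALSE)
    out$value <- as.vector(sub)
    out$participant <- participantId(blockset)
    out$run <- info$run[out$block]
    out$language <- info$language[out$block]
    out[, c("participant", "block", "run", "language", "channel",
            "chromophore", "value")]
}

#' Full per-participant preprocessing chain
#'
#' Filter, epoch, baseline-correct and window-average one recording in the
#' fixed order the block design requires.
#'
#' @param recording a \linkS4class{NirsRecording}.
#' @param low,high,order band-pass settings, see [bandpass()].
#' @param tail baseline tail-anchor convention, see [baselineCorrect()].
#' @param window averaging window, see [windowAverage()].
#' @return the tidy window-average data.frame of [windowAverage()].
#' @export
preprocessRecording <- function(recording, low = 0.01, high = 0.8,
                                order = 3, tail = "block",
                                window = c(5, 18)) {
    filtered <- bandpassRecording(recording, low = low, high = high,
                                  order = order)
    blocks <- baselineCorrect(extractBlocks(filtered), tail = tail)
    windowAverage(blocks, window = window)
}
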