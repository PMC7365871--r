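#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma HRF: a positive lobe peaking at \code{peakTime}
#' seconds minus a scaled undershoot peaking at \code{undershootTime}
#' seconds. With rate 1, a gamma density with shape \code{a} peaks at
#' \code{a - 1}, so the shapes are \code{peakTime + 1} and
#' \code{undershootTime + 1}.
#'
#' @param t time points in s (values for \code{t < 0} are 0).
#' @param peakTime time-to-peak of the positive lobe, s.
#' @param undershootTime time-to-peak of the undershoot, s.
#' @param undershootRatio amplitude ratio of undershoot to main lobe.
#' @return numeric vector of HRF values.
#' @export
hrfDoubleGamma <- function(t, peakTime = 6, undershootTime = 16,
                           undershootRatio = 1 / 6) {
    h <- stats::dgamma(t, shape = peakTime + 1, rate = 1) -
        undershootRatio *
            stats::dgamma(t, shape = undershootTime + 1, rate = 1)
    h[t < 0] <- 0
    h
}

#' Simulation configuration
#'
#' Collects every tunable of the synthetic cohort generator. Defaults encode
#' the study paradigm this package targets: 10 Hz two-chromophore
#' recordings over 44 channels, two runs of 15 trials (5 per language),
#' 18-s questions, and a balanced high/low-proficiency cohort of 20 + 20.
#'
#' The activation model: on each informative channel, a trial of language
#' \code{l} adds an HRF-convolved 18-s boxcar with peak amplitude
#' \deqn{a = A_0 (g(group, l) + e) s,}
#' where \code{A_0} = \code{baseAmplitude}, \code{e ~ N(0, individualSd^2)}
#' is a per-(participant, channel, language) individual difference,
#' \code{s ~ N(1, sharedOffsetSd^2)} is a shared per-participant vascular
#' scaling, and the group gain is \code{g = 1} for L2/low, \code{1 +
#' effectSize * individualSd} for L2/high, \code{l1Effect} for L1 (both
#' groups) and \code{l3Effect} for L3 (both groups). \code{effectSize} is
#' therefore the separation of the group mean amplitudes in units of the
#' between-participant amplitude SD. Deoxy-hemoglobin responds with
#' \code{-deoxyRatio} times the oxy response plus independent noise.
#'
#' Noise is white Gaussian plus a random linear drift plus sinusoidal
#' physiological components (cardiac ~1 Hz, respiratory ~0.3 Hz, Mayer
#' waves ~0.1 Hz) with random phase per channel.
#'
#' @param nPerGroup participants per proficiency group.
#' @param informativeChannels channels carrying the activation effect.
#' @param effectSize standardised high-vs-low separation of L2 amplitudes.
#' @param l1Effect,l3Effect group-independent gains for L1 and L3.
#' @param baseAmplitude response amplitude unit (arbitrary concentration
#'   units).
#' @param individualSd SD of per-channel individual amplitude differences,
#'   relative to \code{baseAmplitude}.
#' @param sharedOffsetSd SD of the shared per-participant scaling.
#' @param deoxyRatio magnitude of the deoxy response relative to oxy.
#' @param deoxyNoiseScale deoxy noise SD relative to oxy noise SD.
#' @param samplingRate Hz.
#' @param hrf list of [hrfDoubleGamma()] parameters.
#' @param noise list: \code{white} (SD per sample), \code{driftSd} (SD of
#'   the drift slope, units/s), \code{sinusoids} (data.frame with
#'   \code{freq} Hz and \code{amp}).
#' @param contradictFraction fraction of each group whose behavioral rate
#'   is planted on the wrong side of 0.5 (exercises the consistency
#'   exclusion).
#' @param tailPad seconds of recording kept after the last trial.
#' @param seed master seed; per-participant substreams are derived from it.
#' @return a list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nPerGroup = 20L,
                             informativeChannels = c(1L, 6L, 16L, 22L),
                             effectSize = 1.5,
                             l1Effect = 1,
                             l3Effect = 0,
                             baseAmplitude = 1,
                             individualSd = 0.3,
                             sharedOffsetSd = 0.05,
                             deoxyRatio = 1 / 3,
                             deoxyNoiseScale = 0.5,
                             samplingRate = 10,
                             hrf = list(peakTime = 6, undershootTime = 16,
                                        undershootRatio = 1 / 6),
                             noise = list(
                                 white = 0.2,
                                 driftSd = 0.002,
                                 sinusoids = data.frame(
                                     freq = c(1.0, 0.3, 0.1),
                                     amp = c(0.15, 0.15, 0.2))),
                             contradictFraction = 0,
                             tailPad = 15,
                             seed = 1L) {
    cfg <- list(
        nPerGroup = as.integer(nPerGroup),
        informativeChannels = as.integer(informativeChannels),
        effectSize = effectSize, l1Effect = l1Effect, l3Effect = l3Effect,
        baseAmplitude = baseAmplitude, individualSd = individualSd,
        sharedOffsetSd = sharedOffsetSd, deoxyRatio = deoxyRatio,
        deoxyNoiseScale = deoxyNoiseScale, samplingRate = samplingRate,
        hrf = hrf, noise = noise,
        contradictFraction = contradictFraction,
        tailPad = tailPad, seed = as.integer(seed))
    class(cfg) <- "SimulationConfig"
    validateSimulationConfig(cfg)
    cfg
}

validateSimulationConfig <- function(cfg) {
    if (cfg$samplingRate <= 0) stop("samplingRate must be positive")
    if (nrow(cfg$noise$sinusoids) &&
        cfg$samplingRate <= 2 * max(cfg$noise$sinusoids$freq))
        stop("samplingRate must exceed twice the highest sinusoid frequency")
    if (cfg$noise$white < 0 || cfg$noise$driftSd < 0 ||
        any(cfg$noise$sinusoids$amp < 0))
        stop("noise magnitudes must be non-negative")
    if (any(cfg$informativeChannels < 1L | cfg$informativeChannels > 44L))
        stop("informative channels must lie in 1..44")
    invisible(cfg)
}

#' Build one participant's activation profile
#'
#' Draws the per-(channel, language) response amplitudes and the shared
#' individual scaling for one participant under the model described in
#' [simulationConfig()]. Amplitudes are nonzero only on the configured
#' informative channels.
#'
#' @param id participant identifier.
#' @param group \code{"high"} or \code{"low"}.
#' @param behavioralRate fraction of questions answered correctly.
#' @param config a [simulationConfig()].
#' @return list of class \code{"ParticipantProfile"} with elements
#'   \code{id}, \code{group}, \code{behavioralRate},
#'   \code{effectAmplitudes} (44 x 3 matrix, columns L1/L2/L3) and
#'   \code{individualOffset}. Uses the current RNG state.
#' @export
participantProfile <- function(id, group = c("high", "low"),
                               behavioralRate, config) {
    group <- match.arg(group)
    gains <- c(
        L1 = config$l1Effect,
        L2 = if (group == "high")
            1 + config$effectSize * config$individualSd else 1,
        L3 = config$l3Effect)
    amp <- matrix(0, nrow = 44L, ncol = 3L,
                  dimnames = list(NULL, c("L1", "L2", "L3")))
    ic <- config$informativeChannels
    offset <- max(0.2, stats::rnorm(1, 1, config$sharedOffsetSd))
    for (l in colnames(amp)) {
        e <- stats::rnorm(length(ic), 0, config$individualSd)
        amp[ic, l] <- config$baseAmplitude * (gains[[l]] + e) * offset
    }
    structure(
        list(id = id, group = group, behavioralRate = behavioralRate,
             effectAmplitudes = amp, individualOffset = offset),
        class = "ParticipantProfile")
}

## HRF kernel scaled so an 18-s boxcar response has unit peak amplitude
hrfKernel <- function(config, boxcarDur = 18) {
    dt <- 1 / config$samplingRate
    tk <- seq(0, 32, by = dt)
    h <- do.call(hrfDoubleGamma, c(list(t = tk), config$hrf))
    box <- rep(1, round(boxcarDur * config$samplingRate))
    ref <- convolveOpen(box, h) * dt
    h / max(ref)
}

## linear convolution, first length(x) samples
convolveOpen <- function(x, kernel) {
    stats::convolve(x, rev(kernel), type = "open")[seq_along(x)]
}

#' Simulate one participant's recording
#'
#' Synthesises the 44-channel oxy/deoxy concentration time series implied by
#' a schedule and an activation profile: each trial contributes an
#' HRF-convolved 18-s boxcar scaled by the profile's amplitude for that
#' (channel, language); deoxy carries \code{-deoxyRatio} times the oxy
#' response; white, drift and sinusoidal physiological noise are added per
#' channel. Deterministic for a fixed seed.
#'
#' @param profile a [participantProfile()].
#' @param schedule a [generateSchedule()] data.frame.
#' @param config a [simulationConfig()].
#' @param seed integer seed for the noise draws.
#' @return a \linkS4class{NirsRecording}.
#' @export
simulateParticipant <- function(profile, schedule, config, seed) {
    validateSchedule(schedule,
        trialsPerLanguage = max(table(schedule$language, schedule$run)))
    fs <- config$samplingRate
    dt <- 1 / fs
    lastEnd <- max(schedule$onset + schedule$questionDur +
                   schedule$reactionDur + schedule$restDur)
    duration <- max(lastEnd, max(schedule$onset) + 33) + config$tailPad
    nT <- ceiling(duration * fs)
    if (max(schedule$onset) + 33 > nT * dt)
        stop("schedule extends beyond the generated recording")

    kernel <- hrfKernel(config)
    tgrid <- (seq_len(nT) - 1) * dt

    ## one convolved regressor per language, shared across channels
    regs <- sapply(c("L1", "L2", "L3"), function(l) {
        u <- numeric(nT)
        for (i in which(schedule$language == l)) {
            i0 <- round(schedule$onset[i] * fs) + 1L
            i1 <- i0 + round(schedule$questionDur[i] * fs) - 1L
            u[i0:i1] <- u[i0:i1] + 1
        }
        convolveOpen(u, kernel) * dt
    })

    signal <- regs %*% t(profile$effectAmplitudes)  # time x 44

    withLocalSeed(seed, {
        oxy <- signal + channelNoise(nT, 44L, tgrid, config, scale = 1)
        deoxy <- -config$deoxyRatio * signal +
            channelNoise(nT, 44L, tgrid, config,
                         scale = config$deoxyNoiseScale)
    })
    colnames(oxy) <- colnames(deoxy) <- paste0("Ch", 1:44)

    new("NirsRecording",
        participantId = as.character(profile$id),
        samplingRate = fs, oxy = oxy, deoxy = deoxy, schedule = schedule)
}

channelNoise <- function(nT, nCh, tgrid, config, scale = 1) {
    nz <- config$noise
    out <- matrix(stats::rnorm(nT * nCh, 0, nz$white * scale), nT, nCh)
    slopes <- stats::rnorm(nCh, 0, nz$driftSd * scale)
    out <- out + outer(tgrid, slopes)
    if (nrow(nz$sinusoids)) {
        for (j in seq_len(nrow(nz$sinusoids))) {
            phase <- stats::runif(nCh, 0, 2 * pi)
            f <- nz$sinusoids$freq[j]
            a <- nz$sinusoids$amp[j] * scale
            ## a sin(wt + phi) = a cos(phi) sin(wt) + a sin(phi) cos(wt):
            ## two rank-1 updates instead of elementwise sin on T x C
            w <- 2 * pi * f * tgrid
            out <- out + sin(w) %o% (a * cos(phase)) +
                cos(w) %o% (a * sin(phase))
        }
    }
    out
}

#' Simulate a balanced high/low-proficiency cohort
#'
#' Generates \code{2 * nPerGroup} participants: individual schedules,
#' activation profiles and recordings, plus behavioral correct-answer rates
#' consistent with the group label (high-proficiency rates above 0.5, low
#' below) except for a configurable fraction of planted "contradicting"
#' participants. One master seed spawns per-participant substreams, so the
#' cohort is reproducible while participants stay independent.
#'
#' @param config a [simulationConfig()].
#' @return list of class \code{"NirsCohort"}: \code{recordings} (list of
#'   \linkS4class{NirsRecording}), \code{labels} (named character,
#'   high/low), \code{behavioralRates} (named numeric), \code{profiles},
#'   \code{config}.
#' @export
simulateCohort <- function(config) {
    stopifnot(config$nPerGroup >= 2L)
    n <- 2L * config$nPerGroup
    withLocalSeed(config$seed, {
        ids <- c(sprintf("H%02d", seq_len(config$nPerGroup)),
                 sprintf("L%02d", seq_len(config$nPerGroup)))
        labels <- rep(c("high", "low"), each = config$nPerGroup)
        names(labels) <- ids
        subSeeds <- matrix(sample.int(.Machine$integer.max, 2L * n), ncol = 2)
        rates <- drawBehavioralRates(labels, config$contradictFraction)
        profiles <- lapply(seq_len(n), function(i)
            participantProfile(ids[i], labels[i], rates[i], config))
        recordings <- lapply(seq_len(n), function(i) {
            sched <- generateSchedule(seed = subSeeds[i, 1])
            simulateParticipant(profiles[[i]], sched, config,
                                seed = subSeeds[i, 2])
        })
        names(recordings) <- ids
        structure(
            list(recordings = recordings, labels = labels,
                 behavioralRates = rates, profiles = profiles,
                 config = config),
            class = "NirsCohort")
    })
}

## rates strictly above 0.5 for (consistent) high, strictly below for low;
## contradictors get the opposite group's distribution
drawBehavioralRates <- function(labels, contradictFraction) {
    n <- length(labels)
    highRate <- function(k) 0.5 + 0.45 * stats::rbeta(k, 4, 2)
    lowRate <- function(k) 0.05 + 0.44 * stats::rbeta(k, 2, 4)
    rates <- numeric(n)
    for (g in c("high", "low")) {
        idx <- which(labels == g)
        nContr <- round(contradictFraction * length(idx))
        contr <- idx[seq_len(nContr)]
        keep <- setdiff(idx, contr)
        rates[keep] <- if (g == "high") highRate(length(keep))
                       else lowRate(length(keep))
        rates[contr] <- if (g == "high") lowRate(length(contr))
                        else highRate(length(contr))
    }
    names(rates) <- names(labels)
    rates
}

#' @export
print.NirsCohort <- function(x, ...) {
    cat(sprintf(
        "NirsCohort: %d participants (%d high / %d low), effect size %.2g on channels %s\n",
        length(x$recordings), sum(x$labels == "high"),
        sum(x$labels == "low"), x$config$effectSize,
        paste(x$config$informativeChannels, collapse = ", ")))
    invisible(x)
}
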