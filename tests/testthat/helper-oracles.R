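# Independent oracles and small fixture builders used across the suite.

## Welch two-sample t statistic straight from stats::t.test
oracleWelch <- function(x, y) {
    unname(stats::t.test(x, y, var.equal = FALSE)$statistic)
}

## closed-form single-response sparse CCA direction: soft-threshold X'y,
## L2-normalise, threshold located by an independent bisection on the L1
## norm (written without reference to the package's solver internals)
oracleSingleResponse <- function(X, y, lambdaX) {
    a <- drop(crossprod(X, y))
    soft <- function(v, d) sign(v) * pmax(abs(v) - d, 0)
    norm1of <- function(d) {
        v <- soft(a, d)
        n2 <- sqrt(sum(v^2))
        if (n2 == 0) Inf else sum(abs(v)) / n2
    }
    v <- a / sqrt(sum(a^2))
    if (sum(abs(v)) > lambdaX) {
        lo <- 0; hi <- max(abs(a))
        for (i in 1:80) {
            mid <- (lo + hi) / 2
            if (norm1of(mid) > lambdaX) lo <- mid else hi <- mid
        }
        v <- soft(a, hi)
        v <- v / sqrt(sum(v^2))
    }
    v
}

## exact maximum of a . v over {||v||_2 <= 1, ||v||_1 <= lambda}, one value
## per row of A, solved algebraically: on each active-set segment the
## binding-L1 threshold solves a quadratic in the soft-threshold delta
oracleMaxLinear <- function(A, lambda) {
    d <- ncol(A)
    out <- numeric(nrow(A))
    l2 <- sqrt(rowSums(A^2))
    easy <- rowSums(abs(A)) <= lambda * l2 + 1e-14
    out[easy] <- l2[easy]
    for (i in which(!easy)) {
        a <- sort(abs(A[i, ]), decreasing = TRUE)
        val <- -Inf
        for (k in seq_len(d)) {
            s <- sum(a[1:k]); q <- sum(a[1:k]^2)
            qa <- k^2 - lambda^2 * k
            qb <- -2 * s * k + 2 * lambda^2 * s
            qc <- s^2 - lambda^2 * q
            disc <- qb^2 - 4 * qa * qc
            if (disc < 0) next
            roots <- if (abs(qa) < 1e-14) -qc / qb
                     else (-qb + c(1, -1) * sqrt(disc)) / (2 * qa)
            lo <- if (k < d) a[k + 1] else 0
            for (delta in roots) {
                if (!is.finite(delta) || delta < max(lo, 0) - 1e-10 ||
                    delta > a[k] + 1e-10) next
                nrm <- sqrt(max(q - 2 * delta * s + k * delta^2, 0))
                if (nrm <= 1e-10) next
                ## keep only roots where the L1 constraint truly binds
                if (abs((s - k * delta) / nrm - lambda) > 1e-6) next
                val <- max(val, (q - delta * s) / nrm)
            }
        }
        out[i] <- val
    }
    out
}

## grid search of the rank-one sparse CCA objective: exhaustive (then
## twice-refined) grid over the label-side vector, feature side solved
## exactly per grid point by oracleMaxLinear
oracleGridSCCA <- function(M, lambdaX, lambdaY) {
    gridBall <- function(center, half, step, lambda) {
        axes <- lapply(center, function(c0)
            seq(c0 - half, c0 + half, by = step))
        V <- as.matrix(expand.grid(axes))
        keep <- rowSums(V^2) <= 1 + 1e-12 &
            rowSums(abs(V)) <= lambda + 1e-12
        V[keep, , drop = FALSE]
    }
    d2 <- ncol(M)
    by <- rep(0, d2); best <- -Inf
    stages <- list(c(half = 1, step = 0.01),
                   c(half = 0.015, step = 0.001),
                   c(half = 0.0015, step = 0.0001))
    for (st in stages) {
        Vy <- gridBall(by, st["half"], st["step"], lambdaY)
        if (!nrow(Vy)) next
        vals <- oracleMaxLinear(Vy %*% t(M), lambdaX)
        i <- which.max(vals)
        if (vals[i] > best) {
            best <- vals[i]
            by <- Vy[i, ]
        }
    }
    list(objective = best, vY = by)
}

## fine-grid convolution oracle: time of the peak response of an 18-s
## boxcar pushed through the double-gamma HRF
oracleBoxcarPeakTime <- function(peakTime = 6, undershootTime = 16,
                                 undershootRatio = 1 / 6,
                                 boxcarDur = 18, dt = 0.01) {
    tt <- seq(0, 60, by = dt)
    h <- hrfDoubleGamma(tt, peakTime, undershootTime, undershootRatio)
    u <- as.numeric(tt < boxcarDur)
    y <- stats::convolve(u, rev(h), type = "open")[seq_along(tt)] * dt
    tt[which.max(y)]
}

## noise-free simulation settings
quietConfig <- function(...) {
    simulationConfig(
        noise = list(white = 0, driftSd = 0,
                     sinusoids = data.frame(freq = numeric(),
                                            amp = numeric())),
        sharedOffsetSd = 0, individualSd = 0, ...)
}

## hand-built profile with explicit amplitudes (bypasses the random draws)
fixedProfile <- function(id = "T01", amp = matrix(0, 44, 3,
                             dimnames = list(NULL, c("L1", "L2", "L3")))) {
    structure(
        list(id = id, group = "high", behavioralRate = 0.9,
             effectAmplitudes = amp, individualOffset = 1),
        class = "ParticipantProfile")
}

## minimal 3-trial schedule with well-separated onsets (one trial per
## language); gaps larger than the rest period so responses do not overlap
sparseSchedule <- function(onsets = c(15, 120, 240),
                           languages = c("L2", "L1", "L3")) {
    data.frame(run = 1L, trial = 1:3, onset = onsets,
               language = languages, questionDur = 18,
               reactionDur = 2, restDur = 15)
}

## deterministic recording built from a function of time (all channels)
functionRecording <- function(f, schedule, duration = NULL, fs = 10,
                              id = "F01", deoxyF = NULL) {
    if (is.null(duration))
        duration <- max(schedule$onset) + 33 + 15
    tt <- seq(0, duration - 1 / fs, by = 1 / fs)
    oxy <- matrix(rep(f(tt), 44), ncol = 44)
    deoxy <- if (is.null(deoxyF)) -oxy / 3
             else matrix(rep(deoxyF(tt), 44), ncol = 44)
    colnames(oxy) <- colnames(deoxy) <- paste0("Ch", 1:44)
    new("NirsRecording", participantId = id, samplingRate = fs,
        oxy = oxy, deoxy = deoxy, schedule = schedule)
}

## synthetic window-average table with prescribed per-channel block means
## (10 blocks per language, tiny fixed jitter so variances are nonzero)
syntheticWindowAverages <- function(participants, channelMeans,
                                    language = "L2", nBlocks = 10) {
    jitter <- seq(-0.45, 0.45, length.out = nBlocks) * 0.1
    out <- list()
    for (p in participants) {
        for (ch in 1:44) {
            m <- channelMeans[[p]][ch]
            out[[length(out) + 1L]] <- data.frame(
                participant = p, block = rep(seq_len(nBlocks), 2),
                run = rep(rep(1:2, each = nBlocks / 2), 2),
                language = language, channel = ch,
                chromophore = rep(c("oxy", "deoxy"), each = nBlocks),
                value = c(m + jitter, -m / 3 + jitter))
        }
    }
    do.call(rbind, out)
}
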