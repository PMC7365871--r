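test_that("MBLL conversion inverts the forward model", {
    z <- mbllConvert(rep(0, 5), rep(0, 5))
    expect_equal(z$oxy, rep(0, 5))
    expect_equal(z$deoxy, rep(0, 5))

    set.seed(1)
    E <- defaultExtinction()
    L <- 2.5
    oxy <- rnorm(50)
    deoxy <- rnorm(50)
    od <- L * E %*% rbind(oxy, deoxy)   # forward model, computed here
    back <- mbllConvert(od[1, ], od[2, ], extinction = E,
                        pathlengthFactor = L)
    expect_equal(back$oxy, oxy, tolerance = 1e-10)
    expect_equal(back$deoxy, deoxy, tolerance = 1e-10)

    ## linearity: scaling both OD series scales both outputs
    scaled <- mbllConvert(3 * od[1, ], 3 * od[2, ], extinction = E,
                          pathlengthFactor = L)
    expect_equal(scaled$oxy, 3 * oxy, tolerance = 1e-10)

    singular <- matrix(c(1, 2, 2, 4), 2, 2)
    expect_error(mbllConvert(od[1, ], od[2, ], extinction = singular),
                 "singular")
})

test_that("band-pass rejects DC, passes 0.1 Hz, attenuates 2 Hz", {
    fs <- 10
    tt <- (0:11999) / fs
    mid <- 4000:8000
    dc <- bandpass(rep(1, length(tt)), fs)
    expect_lt(max(abs(dc[mid])), 0.01)
    pass <- bandpass(sin(2 * pi * 0.1 * tt), fs)
    expect_lt(abs(max(abs(pass[mid])) - 1), 0.05)
    stop2 <- bandpass(sin(2 * pi * 2 * tt), fs)
    expect_lt(max(abs(stop2[mid])), 0.1)

    ## zero phase: a passband sinusoid keeps its alignment
    xc <- sin(2 * pi * 0.1 * tt)
    yc <- bandpass(xc, fs)
    lagCor <- cor(xc[mid], yc[mid])
    expect_gt(lagCor, 0.999)

    expect_error(bandpass(rnorm(100), fs, low = 0, high = 0.8), "band")
    expect_error(bandpass(rnorm(100), fs, low = 0.01, high = 6), "band")
    expect_length(bandpass(rnorm(500), fs), 500)
})

test_that("blocks are 330 samples at 10 Hz, onset-aligned and complete", {
    sched <- generateSchedule(5)
    rec <- functionRecording(function(t) t, sched)
    bs <- extractBlocks(rec)
    d <- dim(bs@samples)
    expect_equal(d[2], 330L)
    expect_equal(d[1] * d[3] * d[4], 2640L)  # 30 trials x 44 ch x 2 chrom
    ## block sample 0 equals the recording at the trial onset
    for (b in c(1L, 17L)) {
        expect_equal(bs@samples[b, 1, 1, 1],
                     round(sched$onset[b] * 10) / 10, tolerance = 1e-9)
    }
    ## window past the recording end errors, naming the trial
    short <- functionRecording(function(t) t, sched,
                               duration = max(sched$onset) + 10)
    expect_error(extractBlocks(short), "trial 15")
})

test_that("linear baseline correction removes straight lines exactly", {
    sched <- sparseSchedule()
    rec <- functionRecording(function(t) 2.5 - 0.3 * t, sched,
                             deoxyF = function(t) -1 + 0.2 * t)
    bc <- baselineCorrect(extractBlocks(rec))
    expect_lt(max(abs(bc@samples)), 1e-9)
    expect_true(isBaselineCorrected(bc))
})

test_that("baseline correction is identity when both anchor means are zero", {
    sched <- sparseSchedule(onsets = c(15, 120, 240))
    ## pulse confined to 5-18 s after each onset: anchors see only zeros
    pulse <- function(t) {
        on <- rep(0, length(t))
        for (o in sched$onset) on <- on + as.numeric(t >= o + 5 & t < o + 18)
        2 * on
    }
    rec <- functionRecording(pulse, sched, deoxyF = function(t) 0 * t)
    bs <- extractBlocks(rec)
    bc <- baselineCorrect(bs)
    expect_equal(bc@samples, bs@samples, tolerance = 1e-12)
})

test_that("line plus in-window pulse corrects to the pulse alone", {
    sched <- sparseSchedule()
    pulse <- function(t) {
        on <- rep(0, length(t))
        for (o in sched$onset) on <- on + as.numeric(t >= o + 5 & t < o + 18)
        1.7 * on
    }
    rec <- functionRecording(function(t) 0.4 + 0.05 * t + pulse(t), sched,
                             deoxyF = function(t) 0 * t)
    bc <- baselineCorrect(extractBlocks(rec))
    tBlock <- (0:329) / 10
    want <- 1.7 * as.numeric(tBlock >= 5 & tBlock < 18)
    expect_equal(bc@samples[1, , 1, 1], want, tolerance = 1e-9)
})

test_that("window averaging uses the half-open [5, 18) s sample grid", {
    sched <- sparseSchedule()
    recC <- functionRecording(function(t) rep(3, length(t)), sched,
                              deoxyF = function(t) rep(3, length(t)))
    bsC <- extractBlocks(recC)
    waC <- windowAverage(bsC, requireBaseline = FALSE)
    expect_true(all(abs(waC$value - 3) < 1e-12))

    ## ramp re-based at each onset: mean of 5.0, 5.1, ..., 17.9 = 11.45
    ramp <- function(t) {
        out <- rep(0, length(t))
        for (o in sched$onset) {
            idx <- t >= o & t < o + 33
            out[idx] <- t[idx] - o
        }
        out
    }
    recR <- functionRecording(ramp, sched, deoxyF = function(t) 0 * t)
    waR <- windowAverage(extractBlocks(recR), requireBaseline = FALSE)
    oxyVals <- waR$value[waR$chromophore == "oxy"]
    expect_equal(unique(round(oxyVals, 10)), 11.45)

    expect_error(windowAverage(bsC), "baseline")
})

test_that("time-point mode pools every in-window sample", {
    sched <- sparseSchedule()
    rec <- functionRecording(function(t) rep(2, length(t)), sched,
                             deoxyF = function(t) rep(-1, length(t)))
    bs <- extractBlocks(rec)
    ws <- windowSamples(bs, requireBaseline = FALSE)
    expect_equal(nrow(ws), 3L * 130L * 44L * 2L)
    expect_true(all(ws$value[ws$chromophore == "oxy"] == 2))
    expect_true(all(ws$value[ws$chromophore == "deoxy"] == -1))
    ## constant samples leave the indicator degenerate, by design
    labels <- c(F01 = "high")
    expect_error(buildFeatureMatrix(ws, "L2", "F01", labels),
                 "zero variance")

    ## with varying signal the pooled table feeds the feature matrix
    rec2 <- functionRecording(function(t) sin(t), sched,
                              deoxyF = function(t) cos(t))
    ws2 <- windowSamples(extractBlocks(rec2), requireBaseline = FALSE)
    fm <- buildFeatureMatrix(ws2, "L2", "F01", labels)
    expect_s4_class(fm, "FeatureMatrix")
})

test_that("pipeline order matters: averaging before baseline differs", {
    cfg <- simulationConfig(nPerGroup = 2, seed = 31)
    rec <- simulateCohort(cfg)$recordings[[1]]
    bs <- extractBlocks(bandpassRecording(rec))
    before <- windowAverage(bs, requireBaseline = FALSE)
    after <- windowAverage(baselineCorrect(bs))
    expect_false(isTRUE(all.equal(before$value, after$value)))
})

test_that("epoching a pre-filtered record matches filtering then epoching", {
    cfg <- simulationConfig(nPerGroup = 2, seed = 33)
    rec <- simulateCohort(cfg)$recordings[[1]]
    a <- extractBlocks(bandpassRecording(rec))
    filtered <- new("NirsRecording",
        participantId = participantId(rec),
        samplingRate = samplingRate(rec),
        oxy = bandpass(oxySeries(rec), samplingRate(rec)),
        deoxy = bandpass(deoxySeries(rec), samplingRate(rec)),
        schedule = trialSchedule(rec))
    b <- extractBlocks(filtered)
    expect_identical(a@samples, b@samples)
})
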