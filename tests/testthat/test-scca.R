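test_that("standardization centres, scales and round-trips", {
    expect_equal(standardizeFit(cbind(x = c(1, 2, 3)))$X[, 1],
                 c(-1, 0, 1))
    set.seed(1)
    X <- matrix(rnorm(60, mean = 3, sd = 2), 20, 3)
    fit <- standardizeFit(X)
    expect_equal(colMeans(fit$X), rep(0, 3), tolerance = 1e-12)
    expect_equal(apply(fit$X, 2, sd), rep(1, 3), tolerance = 1e-12)
    ## idempotence on already-standardized data
    again <- standardizeFit(fit$X)
    expect_equal(again$X, fit$X, tolerance = 1e-12)
    ## apply(params) reproduces the fit on the training data
    expect_equal(standardizeApply(X, fit$params), fit$X)

    Xbad <- cbind(Ch1 = rnorm(5), Ch2 = rep(2, 5))
    expect_error(standardizeFit(Xbad), "Ch2")
})

test_that("single-response fits equal the closed-form oracle", {
    set.seed(11)
    for (i in 1:200) {
        n <- sample(6:30, 1)
        p <- sample(3:15, 1)
        X <- standardizeFit(matrix(rnorm(n * p), n, p))$X
        y <- matrix(sample(c(-1, 1), n, replace = TRUE), ncol = 1)
        lam <- runif(1, 1, sqrt(p))
        fit <- sccaFit(X, y, lambdaX = lam)
        want <- oracleSingleResponse(X, drop(y), lam)
        expect_equal(fit$vX, sign(sum(want * fit$vX) + 1e-30) * want,
                     tolerance = 1e-8)
        ## constraint invariants
        expect_lte(sum(fit$vX^2), 1 + 1e-8)
        expect_lte(sum(abs(fit$vX)), lam + 1e-8)
        expect_lte(abs(fit$vY), 1 + 1e-8)
    }
})

test_that("a perfectly informative column is the whole support", {
    set.seed(3)
    n <- 20
    y <- rep(c(1, -1), 10)
    X <- cbind(y, matrix(rnorm(n * 5), n, 5))
    X <- standardizeFit(X)$X
    fit <- sccaFit(X, matrix(y, ncol = 1), lambdaX = 1)
    expect_equal(fit$support, 1L)
})

test_that("fits match exhaustive grid search on small problems", {
    set.seed(21)
    for (i in 1:4) {
        X <- standardizeFit(matrix(rnorm(18), 6, 3))$X
        Y <- matrix(rnorm(12), 6, 2)
        lamX <- runif(1, 1, 1.6)
        lamY <- runif(1, 1, 1.3)
        fit <- sccaFit(X, Y, lambdaX = lamX, lambdaY = lamY)
        grid <- oracleGridSCCA(crossprod(X, Y), lamX, lamY)
        expect_equal(fit$objective, grid$objective, tolerance = 1e-3)
        ## objective never decreases along the alternating iterations
        expect_true(all(diff(fit$trace) > -1e-10))
        ## constraint invariants at convergence
        expect_lte(sum(fit$vX^2), 1 + 1e-8)
        expect_lte(sum(fit$vY^2), 1 + 1e-8)
        expect_lte(sum(abs(fit$vX)), lamX + 1e-8)
        expect_lte(sum(abs(fit$vY)), lamY + 1e-8)
    }
})

test_that("support shrinks as the L1 budget tightens", {
    set.seed(5)
    X <- standardizeFit(matrix(rnorm(40 * 10), 40, 10))$X
    y <- matrix(sample(c(-1, 1), 40, replace = TRUE), ncol = 1)
    lams <- seq(sqrt(10), 1, length.out = 8)
    sizes <- vapply(lams, function(l)
        length(sccaFit(X, y, lambdaX = l)$support), integer(1))
    expect_true(all(diff(sizes) <= 0))
    ## generous budget keeps every correlated channel
    expect_equal(sizes[1], 10L)
})

test_that("lambdaForSupport hits the requested support size", {
    set.seed(9)
    X <- standardizeFit(matrix(rnorm(30 * 44), 30, 44))$X
    y <- matrix(sample(c(-1, 1), 30, replace = TRUE), ncol = 1)
    a <- drop(crossprod(X, y))
    for (k in c(3L, 5L, 10L)) {
        lam <- lambdaForSupport(a, k)
        fit <- sccaFit(X, y, lambdaX = lam)
        expect_equal(length(fit$support), k)
    }
})

test_that("leave-one-out stability selection counts folds correctly", {
    set.seed(33)
    n <- 12
    y <- rep(c("high", "low"), each = 6)
    yNum <- ifelse(y == "high", 1, -1)
    X <- matrix(rnorm(n * 44, sd = 0.5), n, 44)
    X[, 7] <- X[, 7] + 3 * yNum   # dominant channel in every fold
    prof <- loocvSelectionProfile(X, y, targetSupport = 2L)
    expect_s4_class(prof, "SelectionProfile")
    expect_equal(prof@n, n)
    expect_equal(sum(selectionCounts(prof)), 2L * n)  # 2 per fold
    expect_equal(selectionCounts(prof)[7], n)
    expect_true(7L %in% commonFeatures(prof))
})

test_that("the >95% rule reproduces the printed count thresholds", {
    counts <- c(rep(40L, 3), 39L, 38L, 20L, rep(0L, 38))
    expect_equal(commonFeatures(counts, n = 40), c(1:4))
    counts38 <- c(38L, 37L, 36L, 35L, rep(0L, 40))
    expect_equal(commonFeatures(counts38, n = 38), c(1:2))
    ## all channels at the maximum are all returned
    expect_equal(commonFeatures(rep(10, 44), n = 10), 1:44)
})

test_that("permuting labels destroys the identity of selected channels", {
    ## with intact labels the planted channels are selected every time;
    ## with permuted labels whatever survives the threshold is spurious
    ## and no single channel recurs across cohorts
    n <- 20
    yNum <- rep(c(1, -1), each = n / 2)
    hitsPerChannel <- integer(44)
    plantedHits <- 0L
    for (s in 1:20) {
        set.seed(100 + s)
        X <- matrix(rnorm(n * 44, sd = 0.5), n, 44)
        X[, c(2, 9)] <- X[, c(2, 9)] + 1.5 * yNum
        intact <- commonFeatures(loocvSelectionProfile(X, yNum))
        if (all(c(2L, 9L) %in% intact)) plantedHits <- plantedHits + 1L
        yPerm <- sample(yNum)
        perm <- commonFeatures(loocvSelectionProfile(X, yPerm))
        hitsPerChannel[perm] <- hitsPerChannel[perm] + 1L
    }
    expect_gte(plantedHits, 19L)
    expect_lt(max(hitsPerChannel), 19L)
})
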