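twoClusters <- function(n = 20, sep = 4, p = 2, seed = 1) {
    set.seed(seed)
    X <- rbind(matrix(rnorm(n / 2 * p), ncol = p) + sep / 2,
               matrix(rnorm(n / 2 * p), ncol = p) - sep / 2)
    y <- rep(c("high", "low"), each = n / 2)
    list(X = X, y = y)
}

test_that("linear SVM separates well-separated clusters", {
    d <- twoClusters()
    m <- fitLinearSvm(d$X, d$y)
    expect_equal(predictLinearSvm(m, d$X), d$y)
    ## a point clearly on the positive side gets the positive label
    expect_equal(predictLinearSvm(m, matrix(c(5, 5), 1)), "high")
    expect_error(fitLinearSvm(d$X[1:10, ], d$y[1:10]), "both classes")
})

test_that("SVM agrees with an independent QP solution of the dual", {
    skip_if_not_installed("kernlab")
    ## small nonseparable toy: solve the soft-margin dual exactly
    X <- matrix(c(1, 1, 2, 0, 0.5, 1.5,
                  -1, -1, -2, 0, -0.5, -1), ncol = 2, byrow = FALSE)
    X <- cbind(c(1, 1.5, 2, -1, -1.5, -0.4),
               c(1, 0.5, 1.8, -1, -0.5, 0.6))
    y <- c(1, 1, 1, -1, -1, -1)
    C <- 1
    K <- X %*% t(X)
    H <- (y %o% y) * K
    qp <- kernlab::ipop(c = rep(-1, 6), H = H, A = matrix(y, 1),
                        b = 0, l = rep(0, 6), u = rep(C, 6), r = 0)
    alpha <- kernlab::primal(qp)
    wOracle <- colSums(alpha * y * X)

    m <- fitLinearSvm(X, ifelse(y > 0, "high", "low"), C = C)
    wSvm <- colSums(m$coefs[, 1] * X[m$index, , drop = FALSE])
    ## e1071 codes the first factor level as +1; align the sign
    s <- sign(sum(wSvm * wOracle))
    expect_equal(s * wSvm, wOracle, tolerance = 1e-3)
})

test_that("ARD prunes most pure-noise features and keeps the strong one", {
    ## evidence-based relevance determination includes a null feature with
    ## probability ~ P(chi2_1 > 1) ~ 0.32, so complete pruning of several
    ## independent noise features cannot be demanded per run; what ARD
    ## guarantees is that the informative weight survives and irrelevant
    ## weights are mostly set to exactly zero
    keptInformative <- 0L
    halfPruned <- 0L
    zeroFrac <- numeric(20)
    for (s in 1:20) {
        set.seed(200 + s)
        n <- 40
        y <- rep(c("high", "low"), each = n / 2)
        X <- matrix(rnorm(n * 5), n, 5)
        X[, 1] <- X[, 1] + 2 * ifelse(y == "high", 1, -1)
        m <- fitSparseLogistic(X, y)
        if (m$weights[1] != 0) keptInformative <- keptInformative + 1L
        zeroFrac[s] <- mean(m$weights[2:5] == 0)
        if (zeroFrac[s] >= 0.5) halfPruned <- halfPruned + 1L
    }
    expect_gte(keptInformative, 18L)
    expect_gte(halfPruned, 18L)
    expect_gte(mean(zeroFrac), 0.6)
})

test_that("a single informative feature yields a perfect separable fit", {
    y <- rep(c("high", "low"), each = 10)
    X <- cbind(ifelse(y == "high", 1, -1) + rnorm(20, sd = 0.05),
               rnorm(20))
    m <- fitSparseLogistic(X, y)
    expect_true(m$weights[1] != 0)
    expect_equal(predictSparseLogistic(m, X), y)
})

test_that("with ARD off the fit matches a penalized-likelihood oracle", {
    set.seed(17)
    n <- 30
    y <- rep(c("high", "low"), each = n / 2)
    t01 <- ifelse(y == "high", 1, 0)
    X <- matrix(rnorm(n * 3), n, 3)
    X[, 1] <- X[, 1] + ifelse(y == "high", 1, -1)
    alpha0 <- 2
    m <- fitSparseLogistic(X, y, ard = FALSE, alpha0 = alpha0)

    ## independent optimizer of the same ridge-penalized likelihood
    nll <- function(w) {
        eta <- drop(cbind(1, X) %*% w)
        sum(pmax(eta, 0) + log1p(exp(-abs(eta))) - t01 * eta) +
            0.5 * alpha0 * sum(w[-1]^2) + 0.5 * 1e-6 * w[1]^2
    }
    opt <- optim(rep(0, 4), nll, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14))
    expect_equal(c(m$intercept, m$weights), opt$par, tolerance = 1e-4)
})

test_that("KNN votes its neighbourhood and matches a reference", {
    ## query on a training point with a single-class 5-neighbourhood
    X <- rbind(matrix(rnorm(10, sd = 0.1), 5, 2) + 3,
               matrix(rnorm(10, sd = 0.1), 5, 2) - 3)
    y <- rep(c("high", "low"), each = 5)
    expect_equal(knnPredict(X, y, X[1, ]), "high")

    ## 3-vs-2 split decides by majority
    Xm <- matrix(c(0, 0.1, 0.2, 0.3, 0.4, 10), ncol = 1)
    ym <- c("high", "high", "high", "low", "low", "low")
    expect_equal(knnPredict(Xm, ym, matrix(0, 1, 1), k = 5), "high")

    skip_if_not_installed("class")
    set.seed(71)
    Xtr <- matrix(rnorm(60 * 4), 60, 4)
    ytr <- sample(c("high", "low"), 60, replace = TRUE)
    Xte <- matrix(rnorm(200 * 4), 200, 4)
    mine <- knnPredict(Xtr, ytr, Xte, k = 5)
    ref <- as.character(class::knn(Xtr, Xte, ytr, k = 5))
    expect_equal(mine, ref)
})

test_that("LOOCV predicts each participant exactly once from the rest", {
    d <- twoClusters(n = 12, sep = 3, seed = 5)
    rownames(d$X) <- sprintf("P%02d", 1:12)
    res <- loocvClassify(d$X, d$y, "knn", k = 3)
    folds <- foldPredictions(res)
    expect_equal(sort(folds$id), sort(rownames(d$X)))
    expect_equal(nrow(folds), 12L)
    cc <- confusionCounts(res)
    expect_equal(sum(cc), 12)
    expect_equal(accuracy(res),
                 unname((cc["TP"] + cc["TN"]) / sum(cc)))
})

test_that("feature restriction applies inside every fold", {
    set.seed(23)
    n <- 16
    y <- rep(c("high", "low"), each = n / 2)
    X <- matrix(rnorm(n * 3, sd = 0.2), n, 3)
    X[, 3] <- ifelse(y == "high", 1, -1)   # perfect channel
    perfect <- loocvClassify(X, y, "svm", features = 3L)
    expect_equal(accuracy(perfect), 1)
    blind <- loocvClassify(X, y, "svm", features = c(1L, 2L))
    expect_lt(accuracy(blind), 0.9)
    expect_error(loocvClassify(X, y, "svm", features = integer()),
                 "non-empty")
})

test_that("permuted labels give chance-level accuracy for every classifier", {
    set.seed(61)
    n <- 20
    X <- matrix(rnorm(n * 6), n, 6)
    for (clf in c("svm", "slr", "knn")) {
        accs <- vapply(1:20, function(s) {
            set.seed(300 + s)
            y <- sample(rep(c("high", "low"), each = n / 2))
            accuracy(loocvClassify(X, y, clf))
        }, numeric(1))
        expect_gt(mean(accs), 0.3)
        expect_lt(mean(accs), 0.6)
    }
})

test_that("accuracy follows the confusion-matrix formula", {
    expect_equal(accuracyFromConfusion(c(TP = 3, TN = 2, FP = 1, FN = 2)),
                 0.625)
    expect_equal(accuracyFromConfusion(c(TP = 5, TN = 5, FP = 0, FN = 0)),
                 1)
    expect_equal(accuracyFromConfusion(c(TP = 0, TN = 0, FP = 3, FN = 1)),
                 0)
    expect_error(accuracyFromConfusion(c(TP = 0, TN = 0, FP = 0, FN = 0)),
                 "empty")
})
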