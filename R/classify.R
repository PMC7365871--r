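#' Linear support vector machine
#'
#' Thin wrappers around \pkg{e1071}'s libsvm interface: a soft-margin SVM
#' with a linear kernel and cost \code{C}, no internal feature scaling
#' (the activation indicators are used as-is), deterministic for fixed
#' data.
#'
#' @param X N x p training matrix.
#' @param y training labels ("high"/"low").
#' @param C soft-margin cost.
#' @return fitted model object.
#' @export
fitLinearSvm <- function(X, y, C = 1) {
    y <- factor(y, levels = c("low", "high"))
    if (length(unique(y)) < 2L)
        stop("training set must contain both classes")
    e1071::svm(x = X, y = y, kernel = "linear", cost = C, scale = FALSE)
}

#' @rdname fitLinearSvm
#' @param model a fitted model.
#' @param newX matrix of rows to predict.
#' @return character labels.
#' @export
predictLinearSvm <- function(model, newX) {
    as.character(predict(model, newX))
}

#' Sparse logistic regression via automatic relevance determination
#'
#' Bayesian logistic regression with an individual Gaussian prior precision
#' \code{alpha_j} on every weight, the bias included. The fit alternates
#' (i) a Newton/IRLS inner loop for the MAP weights given the precisions
#' with (ii) MacKay evidence updates \code{alpha_j <- gamma_j / w_j^2},
#' where \code{gamma_j = 1 - alpha_j * Sigma_jj} is the effective number
#' of well-determined parameters and \code{Sigma} the Laplace posterior
#' covariance. Weights whose precision diverges past
#' \code{pruneThreshold} are pruned to exactly zero, yielding a sparse
#' weight vector. On label-independent data every weight (bias included,
#' since the classes are balanced) may be pruned; the model then scores
#' every input 0, and prediction resolves the zero score to the positive
#' class deterministically -- giving exact chance-level accuracy on a
#' balanced cohort rather than the anti-correlated majority vote a
#' leave-one-out split would otherwise produce.
#'
#' @param X N x p training matrix.
#' @param y training labels ("high"/"low").
#' @param maxOuter maximum ARD (outer) iterations.
#' @param pruneThreshold precision above which a weight is pruned.
#' @param ard if \code{FALSE}, precisions stay fixed at \code{alpha0}
#'   (ridge-penalised logistic regression; used for cross-checks).
#' @param alpha0 initial / fixed prior precision.
#' @return list of class \code{"slrModel"}: \code{weights} (length p,
#'   pruned entries exactly 0), \code{intercept}, \code{alpha},
#'   \code{active} (indices of surviving weights), \code{iterations}.
#' @export
fitSparseLogistic <- function(X, y, maxOuter = 200L, pruneThreshold = 1e8,
                              ard = TRUE, alpha0 = 1) {
    yy <- encodeLabels(y)
    if (length(unique(yy)) < 2L)
        stop("training set must contain both classes")
    t01 <- (yy + 1) / 2
    n <- nrow(X)
    p <- ncol(X)
    Xa <- cbind(Intercept = 1, X)
    ## weak prior on the bias; under ARD it is updated (and prunable)
    ## like any other weight
    alpha <- c(1e-6, rep(alpha0, p))
    active <- seq_len(p + 1L)
    w <- numeric(p + 1L)
    iterations <- 0L

    for (outer in seq_len(maxOuter)) {
        iterations <- outer
        if (!length(active)) break
        Xs <- Xa[, active, drop = FALSE]
        as <- alpha[active]
        ws <- w[active]
        ## Newton iterations (with step halving) for the MAP under fixed
        ## precisions; stable penalised negative log-likelihood
        pnll <- function(wv) {
            eta <- drop(Xs %*% wv)
            sum(pmax(eta, 0) + log1p(exp(-abs(eta))) - t01 * eta) +
                0.5 * sum(as * wv^2)
        }
        fcur <- pnll(ws)
        for (inner in 1:100) {
            eta <- drop(Xs %*% ws)
            mu <- 1 / (1 + exp(-eta))
            g <- drop(crossprod(Xs, mu - t01)) + as * ws
            r <- pmax(mu * (1 - mu), 1e-10)
            H <- crossprod(Xs * r, Xs) + diag(as, length(as))
            step <- solve(H, g)
            s <- 1
            repeat {
                wNew <- ws - s * step
                fNew <- pnll(wNew)
                if (fNew <= fcur || s < 1e-6) break
                s <- s / 2
            }
            if (fNew > fcur) break
            converged <- fcur - fNew < 1e-12 * max(1, abs(fcur))
            ws <- wNew
            fcur <- fNew
            if (converged || max(abs(s * step)) < 1e-10) break
        }
        w[] <- 0
        w[active] <- ws
        if (!ard) break

        Sigma <- solve(H)
        gamma <- 1 - as * diag(Sigma)
        if (any(!is.finite(ws)))
            stop("sparse logistic fit diverged; degenerate training data")
        alphaNew <- as
        nz <- which(ws^2 > 0)
        alphaNew[nz] <- pmax(pmax(gamma[nz], 1e-12) / ws[nz]^2, 1e-8)
        alphaNew[ws == 0] <- pruneThreshold   # flat direction, prune
        change <- max(abs(log(alphaNew) - log(as)))
        alpha[active] <- alphaNew
        newActive <- which(alpha < pruneThreshold)
        w[setdiff(active, newActive)] <- 0
        active <- intersect(active, newActive)
        ## every weight (bias included) may legitimately be pruned on
        ## label-independent data; the model then scores all inputs 0
        if (!length(active) || change < 1e-4) break
    }

    structure(
        list(weights = w[-1], intercept = w[1], alpha = alpha[-1],
             active = setdiff(active, 1L) - 1L, iterations = iterations),
        class = "slrModel")
}

#' @rdname fitSparseLogistic
#' @param model a fitted \code{"slrModel"}.
#' @param newX matrix of rows to predict.
#' @return character labels.
#' @export
predictSparseLogistic <- function(model, newX) {
    eta <- drop(newX %*% model$weights) + model$intercept
    ## a fully pruned model scores 0; resolve to the positive class
    ifelse(eta >= 0, "high", "low")
}

#' K-nearest-neighbour prediction
#'
#' Majority vote of the K training rows nearest to the query in Euclidean
#' distance of the (unscaled) input features. Distance ties at the K-th
#' neighbour are all included before voting; a tied vote (impossible for
#' odd K with binary labels and no distance ties) raises an error rather
#' than being broken arbitrarily, keeping predictions deterministic.
#'
#' @param X N x p training matrix.
#' @param y training labels.
#' @param newX query row(s), vector or matrix.
#' @param k neighbourhood size.
#' @return character labels.
#' @export
knnPredict <- function(X, y, newX, k = 5L) {
    if (is.null(dim(newX))) newX <- matrix(newX, nrow = 1)
    stopifnot(k <= nrow(X))
    apply(newX, 1, function(q) {
        d <- sqrt(colSums((t(X) - q)^2))
        kth <- sort(d)[k]
        votes <- table(y[d <= kth + 1e-12])
        top <- names(votes)[votes == max(votes)]
        if (length(top) > 1L)
            stop("tied K-nearest-neighbour vote; increase k or break ties upstream")
        top
    })
}

#' Leave-one-out cross-validated classification
#'
#' Evaluates a classifier by N-fold leave-one-out: each participant is
#' predicted exactly once by a model trained on the other N-1, with the
#' feature restriction applied identically to training and test rows
#' inside every fold. Predictions are aggregated into a confusion matrix
#' ("high" = positive class).
#'
#' @param X N x 44 activation-indicator matrix with participant rownames.
#' @param y labels ("high"/"low"), aligned with rows of \code{X}.
#' @param classifier one of "svm", "slr", "knn".
#' @param features channel indices to restrict to (default all columns).
#' @param C SVM cost.
#' @param k KNN neighbourhood size.
#' @return a \linkS4class{ClassificationResult}.
#' @export
loocvClassify <- function(X, y, classifier = c("svm", "slr", "knn"),
                          features = NULL, C = 1, k = 5L) {
    classifier <- match.arg(classifier)
    n <- nrow(X)
    stopifnot(n >= 3L)
    if (is.null(features)) features <- seq_len(ncol(X))
    features <- as.integer(features)
    if (!length(features)) stop("feature subset must be non-empty")
    ids <- rownames(X)
    if (is.null(ids)) ids <- sprintf("P%02d", seq_len(n))

    Xs <- X[, features, drop = FALSE]
    pred <- character(n)
    for (fold in seq_len(n)) {
        train <- setdiff(seq_len(n), fold)
        Xtr <- Xs[train, , drop = FALSE]
        ytr <- y[train]
        xte <- Xs[fold, , drop = FALSE]
        pred[fold] <- tryCatch(
            switch(classifier,
                svm = predictLinearSvm(fitLinearSvm(Xtr, ytr, C = C), xte),
                slr = predictSparseLogistic(
                    fitSparseLogistic(Xtr, ytr), xte),
                knn = knnPredict(Xtr, ytr, xte, k = k)),
            error = function(e)
                stop("fold ", fold, " (", ids[fold], "): ",
                     conditionMessage(e)))
    }

    new("ClassificationResult",
        folds = data.frame(id = ids, truth = as.character(y),
                           predicted = pred),
        classifier = classifier, features = features)
}

#' Accuracy from a confusion matrix
#'
#' \code{(TP + TN) / (TP + TN + FP + FN)}, the fraction of correctly
#' classified participants.
#'
#' @param confusion named numeric vector with elements TP, TN, FP, FN.
#' @return accuracy as a fraction in [0, 1].
#' @export
accuracyFromConfusion <- function(confusion) {
    total <- sum(confusion[c("TP", "TN", "FP", "FN")])
    if (is.na(total) || total == 0)
        stop("empty confusion matrix")
    unname((confusion["TP"] + confusion["TN"]) / total)
}
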