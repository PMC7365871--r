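#' Column standardization with training-set parameters
#'
#' \code{standardizeFit} centres each column to mean 0 and scales to unit
#' sample variance, returning the parameters; \code{standardizeApply}
#' applies previously fitted parameters to new rows (no test-set leakage).
#'
#' @param X numeric matrix (rows = observations).
#' @return \code{standardizeFit}: list with \code{X} (standardized matrix)
#'   and \code{params} (list of \code{center}, \code{scale}).
#' @export
standardizeFit <- function(X) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    bad <- which(scale == 0)
    if (length(bad))
        stop("zero-variance column(s): ",
             paste(if (is.null(colnames(X))) bad else colnames(X)[bad],
                   collapse = ", "))
    list(X = sweep(sweep(X, 2, center), 2, scale, `/`),
         params = list(center = center, scale = scale))
}

#' @rdname standardizeFit
#' @param params parameters from \code{standardizeFit}.
#' @return \code{standardizeApply}: the standardized matrix.
#' @export
standardizeApply <- function(X, params) {
    sweep(sweep(X, 2, params$center), 2, params$scale, `/`)
}

## argmax of a . v over {||v||_2 <= 1, ||v||_1 <= lambda} by
## soft-thresholding + L2 normalization, threshold found by bisection
l1l2Project <- function(a, lambda, iter = 60L) {
    if (all(a == 0)) return(numeric(length(a)))
    soft <- function(x, d) sign(x) * pmax(abs(x) - d, 0)
    unitL1 <- function(d) {
        v <- soft(a, d)
        nv <- sqrt(sum(v^2))
        if (nv == 0) return(Inf)
        sum(abs(v)) / nv
    }
    if (lambda < 1) {
        ## the L1 ball cuts inside the unit sphere everywhere: best point
        ## is lambda on the single largest coordinate
        j <- which.max(abs(a))
        v <- numeric(length(a))
        v[j] <- lambda * sign(a[j])
        return(v)
    }
    v0 <- a / sqrt(sum(a^2))
    if (sum(abs(v0)) <= lambda) return(unname(v0))
    lo <- 0
    hi <- max(abs(a))
    for (i in seq_len(iter)) {
        mid <- (lo + hi) / 2
        if (unitL1(mid) > lambda) lo <- mid else hi <- mid
    }
    v <- soft(a, hi)
    v <- v / sqrt(sum(v^2))
    ## snap bisection residue (~2^-60 of max) to exact zeros
    v[abs(v) < 1e-12 * max(abs(v))] <- 0
    unname(v / sqrt(sum(v^2)))
}

#' Fit L1-penalised sparse canonical correlation analysis
#'
#' Solves \deqn{\max_{v_X, v_Y} v_X^T X^T Y v_Y \quad \mathrm{s.t.}\quad
#' \|v_X\|_1 \le \lambda_X,\ \|v_Y\|_1 \le \lambda_Y,\ \|v_X\|_2 \le 1,\
#' \|v_Y\|_2 \le 1} by penalised-matrix-decomposition-style alternating
#' maximization: with \code{vY} fixed, \code{vX} is the L1/L2-constrained
#' maximizer of \code{vX . (X^T Y vY)} obtained by soft-thresholding
#' followed by L2 normalization, the threshold located by bisection so that
#' the L1 budget binds; symmetrically for \code{vY}. The objective is
#' non-decreasing across iterations. For a single-column \code{Y} the
#' normalised all-ones start converges immediately; for wider \code{Y} the
#' alternating scheme is only locally optimal, so a fixed deterministic set
#' of starts is tried (all-ones, each canonical basis vector, the leading
#' right singular vector of the cross-product matrix) and the best
#' objective kept.
#'
#' @param X N x d1 feature matrix, already standardized (training
#'   convention: columns mean 0, unit variance).
#' @param Y N x d2 label matrix (binary +/-1 column, or one-hot).
#' @param lambdaX,lambdaY L1 budgets (must be >= 1 for a unit-L2 vector to
#'   be feasible in the usual regime; values < 1 shrink the L2 norm too).
#' @param maxIter,tol convergence controls (relative objective change).
#' @return list of class \code{"SCCAResult"}: \code{vX}, \code{vY},
#'   \code{objective}, \code{support} (indices of nonzero \code{vX}),
#'   \code{iterations}, \code{trace} (objective per iteration).
#' @export
sccaFit <- function(X, Y, lambdaX, lambdaY = 1, maxIter = 500L,
                    tol = 1e-6) {
    Y <- as.matrix(Y)
    stopifnot(nrow(X) == nrow(Y), lambdaX > 0, lambdaY > 0)
    M <- unname(crossprod(X, Y))              # d1 x d2
    d2 <- ncol(Y)

    starts <- list(rep(1, d2) / sqrt(d2))
    if (d2 > 1L) {
        for (j in seq_len(d2)) {
            e <- numeric(d2); e[j] <- 1
            starts[[length(starts) + 1L]] <- e
        }
        starts[[length(starts) + 1L]] <- svd(M, nu = 0, nv = 1)$v[, 1]
    }

    best <- NULL
    for (v0 in starts) {
        vY <- v0
        obj <- -Inf
        trace <- numeric(0)
        for (it in seq_len(maxIter)) {
            vX <- l1l2Project(drop(M %*% vY), lambdaX)
            vY <- l1l2Project(drop(crossprod(M, vX)), lambdaY)
            objNew <- drop(t(vX) %*% M %*% vY)
            trace <- c(trace, objNew)
            if (is.finite(obj) &&
                abs(objNew - obj) <= tol * max(1e-12, abs(obj))) {
                obj <- objNew
                break
            }
            obj <- objNew
            if (it == maxIter)
                stop("sparse CCA did not converge in ", maxIter,
                     " iterations; last objective ", signif(objNew, 6))
        }
        if (is.null(best) || obj > best$objective)
            best <- list(vX = vX, vY = vY, objective = obj,
                         trace = trace)
    }

    structure(
        list(vX = best$vX, vY = best$vY, objective = best$objective,
             support = which(best$vX != 0),
             iterations = length(best$trace), trace = best$trace),
        class = "SCCAResult")
}

#' @export
print.SCCAResult <- function(x, ...) {
    cat(sprintf(
        "SCCAResult: objective %.4f, |support| = %d, %d iteration(s)\n",
        x$objective, length(x$support), x$iterations))
    invisible(x)
}

#' L1 budget for a target support size
#'
#' Picks \code{lambdaX} so that the feature-side projection vector for the
#' current correlation vector \code{a = X^T Y vY} has (approximately)
#' \code{k} nonzero entries: the soft threshold is placed between the k-th
#' and (k+1)-th largest \code{|a|}, and the implied L1 norm of the
#' normalised vector is returned.
#'
#' @param a correlation vector \code{X^T y} on the training fold.
#' @param k target support size.
#' @return the L1 budget.
#' @export
lambdaForSupport <- function(a, k) {
    k <- min(k, sum(a != 0))
    ord <- sort(abs(a), decreasing = TRUE)
    delta <- if (k < length(a)) (ord[k] + ord[k + 1]) / 2 else 0
    v <- sign(a) * pmax(abs(a) - delta, 0)
    sum(abs(v)) / sqrt(sum(v^2))
}

#' Leave-one-out stability selection with sparse CCA
#'
#' For each of the N leave-one-out folds: standardize the N-1 training rows
#' (training parameters only), encode the labels as a +/-1 column, fit
#' [sccaFit()] and record which channels enter the support. Counts are
#' aggregated over folds; channels selected in more than
#' \code{floor(fraction * N)} folds are the common informative features.
#'
#' @param X N x 44 activation-indicator matrix (unstandardized).
#' @param y labels, "high"/"low" or +/-1.
#' @param lambdaX fixed feature-side L1 budget, or \code{NULL} to choose
#'   per fold via [lambdaForSupport()].
#' @param lambdaY label-side L1 budget.
#' @param targetSupport per-fold support size used when \code{lambdaX} is
#'   \code{NULL}.
#' @param fraction selection-frequency cutoff.
#' @return a \linkS4class{SelectionProfile}.
#' @export
loocvSelectionProfile <- function(X, y, lambdaX = NULL, lambdaY = 1,
                                  targetSupport = 5L, fraction = 0.95) {
    n <- nrow(X)
    stopifnot(n >= 3L)
    yNum <- encodeLabels(y)
    counts <- integer(ncol(X))
    lambdas <- numeric(n)
    for (fold in seq_len(n)) {
        train <- setdiff(seq_len(n), fold)
        std <- tryCatch(standardizeFit(X[train, , drop = FALSE]),
                        error = function(e)
                            stop("fold ", fold, ": ", conditionMessage(e)))
        Ytr <- matrix(yNum[train], ncol = 1)
        lam <- lambdaX
        if (is.null(lam))
            lam <- lambdaForSupport(drop(crossprod(std$X, Ytr)),
                                    targetSupport)
        fit <- tryCatch(sccaFit(std$X, Ytr, lambdaX = lam,
                                lambdaY = lambdaY),
                        error = function(e)
                            stop("fold ", fold, ": ", conditionMessage(e)))
        counts[fit$support] <- counts[fit$support] + 1L
        lambdas[fold] <- lam
    }
    threshold <- as.integer(floor(fraction * n))
    new("SelectionProfile",
        counts = counts, n = as.integer(n), fraction = fraction,
        threshold = threshold,
        commonFeatures = as.integer(which(counts > threshold)),
        lambdaX = lambdas)
}

#' Common informative features from selection counts
#'
#' Applies the "selected in more than 95 percent of participants" rule:
#' channels whose count strictly exceeds \code{floor(fraction * N)}. For
#' N = 40 the count threshold is 38; for N = 38 it is 36.
#'
#' @param counts integer vector of per-channel selection counts.
#' @param n number of leave-one-out folds.
#' @param fraction frequency cutoff (default 0.95).
#' @return integer vector of channel indices.
#' @export
#' @rdname commonFeatures
setMethod("commonFeatures", "numeric", function(object, n,
                                                fraction = 0.95) {
    which(object > floor(fraction * n))
})

encodeLabels <- function(y) {
    if (is.numeric(y)) {
        stopifnot(all(y %in% c(-1, 1)))
        return(as.numeric(y))
    }
    stopifnot(all(y %in% c("high", "low")))
    ifelse(y == "high", 1, -1)
}
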