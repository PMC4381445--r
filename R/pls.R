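#' @include preprocess.R
NULL

## coerce predictor/response inputs to plain numeric matrices
.as_X <- function(x) {
    if (is(x, "SpectraMatrix")) absorbance(x)
    else {
        x <- as.matrix(x)
        storage.mode(x) <- "double"
        x
    }
}

.as_Y <- function(y) {
    if (is(y, "ConstituentTable")) constituentValues(y)
    else if (is.null(dim(y))) matrix(as.numeric(y), ncol = 1L,
                                     dimnames = list(names(y), "y"))
    else {
        y <- as.matrix(y)
        storage.mode(y) <- "double"
        y
    }
}

.resolve_weights <- function(spec, mat, what) {
    if (is.null(spec) || identical(spec, "none"))
        return(rep(1, ncol(mat)))
    if (identical(spec, "inv_sd"))
        return(unname(columnWeights(mat)))
    w <- as.numeric(spec)
    if (length(w) != ncol(mat))
        stop("length of ", what, " weights (", length(w),
             ") does not match the number of columns (", ncol(mat), ")")
    if (any(!is.finite(w) | w <= 0))
        stop(what, " weights must be finite and positive")
    w
}

## NIPALS with X (and Y) deflation. Xc/Yc are centered and weighted.
## Factors are extracted sequentially, so the first a factors do not
## depend on maxFactors -- truncated coefficients are exact.
.nipals <- function(Xc, Yc, A, tol = 1e-12, maxIter = 500L) {
    n <- nrow(Xc); p <- ncol(Xc); m <- ncol(Yc)
    W <- matrix(0, p, A); P <- matrix(0, p, A)
    Q <- matrix(0, m, A); Tt <- matrix(0, n, A)
    ssx0 <- sum(Xc^2); ssy0 <- sum(Yc^2)
    xVar <- numeric(A); yVar <- numeric(A)
    notes <- character(0)
    a <- 0L
    while (a < A) {
        if (sum(Xc^2) <= ssx0 * 1e-24 || sum(Yc^2) <= ssy0 * 1e-24) {
            notes <- c(notes, sprintf(
                "early stop at %d factors: residual rank exhausted", a))
            break
        }
        u <- Yc[, which.max(colSums(Yc^2)), drop = FALSE]
        w <- NULL
        for (it in seq_len(maxIter)) {
            w_new <- crossprod(Xc, u)
            nw <- sqrt(sum(w_new^2))
            if (nw == 0) break
            w_new <- w_new / nw
            tvec <- Xc %*% w_new
            q <- crossprod(Yc, tvec) / c(crossprod(tvec))
            u <- Yc %*% q / c(crossprod(q))
            if (!is.null(w) && sqrt(sum((w_new - w)^2)) < tol) {
                w <- w_new
                break
            }
            w <- w_new
        }
        if (is.null(w) || sqrt(sum(w^2)) == 0) {
            notes <- c(notes, sprintf(
                "early stop at %d factors: degenerate weight vector", a))
            break
        }
        tvec <- Xc %*% w
        tt <- c(crossprod(tvec))
        if (tt <= ssx0 * 1e-24) {
            notes <- c(notes, sprintf(
                "early stop at %d factors: negligible score variance", a))
            break
        }
        pvec <- crossprod(Xc, tvec) / tt
        q <- crossprod(Yc, tvec) / tt
        # deterministic sign: largest-magnitude loading weight positive
        if (w[which.max(abs(w))] < 0) {
            w <- -w; tvec <- -tvec; pvec <- -pvec; q <- -q
        }
        a <- a + 1L
        W[, a] <- w; P[, a] <- pvec; Q[, a] <- q; Tt[, a] <- tvec
        Xc <- Xc - tcrossprod(tvec, pvec)
        Yc <- Yc - tcrossprod(tvec, q)
        xVar[a] <- 100 * (1 - sum(Xc^2) / ssx0)
        yVar[a] <- 100 * (1 - sum(Yc^2) / ssy0)
    }
    keep <- seq_len(a)
    list(W = W[, keep, drop = FALSE], P = P[, keep, drop = FALSE],
         Q = Q[, keep, drop = FALSE], Tt = Tt[, keep, drop = FALSE],
         xVar = xVar[keep], yVar = yVar[keep], nFactors = a, notes = notes)
}

## regression coefficients (weighted, centered scale) using the first a factors
.coef_weighted <- function(W, P, Q, a) {
    if (a == 0L)
        return(matrix(0, nrow(W), nrow(Q)))
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    Qa <- Q[, seq_len(a), drop = FALSE]
    Wa %*% solve(crossprod(Pa, Wa), t(Qa))
}

#' Fit a PLS-1/PLS-2 calibration model
#'
#' NIPALS partial least squares with per-factor X deflation. Both blocks
#' are mean-centered; optional 1/SD column weighting standardizes the
#' predictors (spectra) and/or the responses (constituents). A single
#' response column gives PLS-1; several give PLS-2 (the same algorithm,
#' with the inner loop iterating between blocks). Predictions are always
#' returned in the original (unweighted, uncentered) response units.
#'
#' @param x predictors: a preprocessed [SpectraMatrix-class] or a
#'   numeric matrix (samples in rows)
#' @param y responses: a [ConstituentTable-class], numeric matrix, or
#'   vector
#' @param nFactors number of latent factors to extract; must satisfy
#'   `nFactors <= min(n - 1, p)`. If the data rank is exhausted earlier
#'   the fit stops and records a note in the model.
#' @param xWeights,yWeights `NULL`/`"none"`, `"inv_sd"` (fit 1/SD weights
#'   on these data), or a positive numeric vector per column
#' @param tol NIPALS inner-loop convergence tolerance on the loading
#'   weight vector
#' @param maxIter inner-loop iteration cap
#' @return a [PLSModel-class]
#' @examples
#' X <- matrix(rnorm(60), 20, 3)
#' y <- X %*% c(1, -1, 0.5)
#' fit <- fitPLS(X, y, nFactors = 3)
#' max(abs(fitted(fit) - y)) < 1e-8
#' @export
fitPLS <- function(x, y, nFactors, xWeights = NULL, yWeights = NULL,
                   tol = 1e-12, maxIter = 500L) {
    wn <- if (is(x, "SpectraMatrix")) wavenumbers(x) else numeric(0)
    X <- .as_X(x); Y <- .as_Y(y)
    if (is.null(colnames(Y)))
        colnames(Y) <- paste0("y", seq_len(ncol(Y)))
    if (nrow(X) != nrow(Y))
        stop("x and y must have the same number of samples")
    if (anyNA(X) || anyNA(Y))
        stop("missing values are not supported")
    n <- nrow(X); p <- ncol(X); m <- ncol(Y)
    nFactors <- as.integer(nFactors)
    if (nFactors < 0L || nFactors > min(n - 1L, p))
        stop("nFactors must lie in [0, min(n - 1, p)] = [0, ",
             min(n - 1L, p), "]")
    xW <- .resolve_weights(xWeights, X, "predictor")
    yW <- .resolve_weights(yWeights, Y, "response")
    xCenter <- colMeans(X); yCenter <- colMeans(Y)
    Xc <- sweep(sweep(X, 2L, xCenter), 2L, xW, `*`)
    Yc <- sweep(sweep(Y, 2L, yCenter), 2L, yW, `*`)
    if (sum(Yc^2) == 0 || nFactors == 0L) {
        # constant response (or 0-factor request): the model is the mean
        fit <- list(W = matrix(0, p, 0L), P = matrix(0, p, 0L),
                    Q = matrix(0, m, 0L), Tt = matrix(0, n, 0L),
                    xVar = numeric(0), yVar = numeric(0), nFactors = 0L,
                    notes = if (nFactors > 0L) "response block is constant; mean model returned"
                            else character(0))
    } else {
        fit <- .nipals(Xc, Yc, nFactors, tol = tol, maxIter = maxIter)
        if (fit$nFactors < nFactors)
            warning("requested ", nFactors, " factors; stopped at ",
                    fit$nFactors, " (rank exhausted)")
    }
    Bw <- .coef_weighted(fit$W, fit$P, fit$Q, fit$nFactors)
    B <- (xW * Bw) / matrix(yW, p, m, byrow = TRUE)
    dimnames(B) <- list(colnames(X), colnames(Y))
    fitted <- sweep(sweep(X, 2L, xCenter) %*% B, 2L, yCenter, `+`)
    dimnames(fitted) <- list(rownames(X), colnames(Y))
    new("PLSModel",
        nFactors = fit$nFactors,
        xCenter = xCenter, yCenter = yCenter,
        xWeights = xW, yWeights = yW,
        loadingWeights = fit$W, xLoadings = fit$P, yLoadings = fit$Q,
        scores = fit$Tt,
        coefficients = B, fitted = fitted,
        constituents = colnames(Y),
        predictorWavenumbers = wn,
        xVariance = fit$xVar, yVariance = fit$yVar,
        provenance = list(), notes = fit$notes)
}

#' @rdname accessors
#' @export
setMethod("nFactors", "PLSModel", function(x) x@nFactors)

#' @rdname accessors
#' @export
setMethod("loadingWeights", "PLSModel", function(x) x@loadingWeights)

#' @rdname accessors
#' @export
setMethod("xLoadings", "PLSModel", function(x) x@xLoadings)

#' @rdname accessors
#' @export
setMethod("yLoadings", "PLSModel", function(x) x@yLoadings)

#' @rdname accessors
#' @export
setMethod("plsScores", "PLSModel", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("constituentNames", "PLSModel", function(x) x@constituents)

#' Regression coefficients of a fitted model
#'
#' @param object a [PLSModel-class]
#' @param ... unused
#' @return p x m coefficient matrix on the original (unweighted,
#'   uncentered) scale: `yhat = yCenter + (x - xCenter) %*% coef`
#' @export
setMethod("coef", "PLSModel", function(object, ...) object@coefficients)

#' Fitted responses of a calibration model
#'
#' @param object a [PLSModel-class]
#' @param ... unused
#' @return n x m matrix in original response units
#' @export
setMethod("fitted", "PLSModel", function(object, ...) object@fitted)

#' Predict constituents for new spectra
#'
#' Applies the stored centers and column weights; the result is in the
#' original response units. Prediction is affine in the spectra.
#'
#' @param object a fitted [PLSModel-class]
#' @param newdata a [SpectraMatrix-class] preprocessed identically to the
#'   calibration spectra, or a numeric matrix on the same predictor axis
#' @param ... unused
#' @return n_new x m matrix of predicted responses
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
    if (is(newdata, "SpectraMatrix") && length(object@predictorWavenumbers)) {
        if (nWavenumbers(newdata) != length(object@predictorWavenumbers) ||
            max(abs(wavenumbers(newdata) - object@predictorWavenumbers)) > 1e-6)
            stop("new spectra are not on the model's predictor axis")
    }
    X <- .as_X(newdata)
    if (ncol(X) != length(object@xCenter))
        stop("new data have ", ncol(X), " predictors; the model expects ",
             length(object@xCenter))
    out <- sweep(sweep(X, 2L, object@xCenter) %*% object@coefficients,
                 2L, object@yCenter, `+`)
    dimnames(out) <- list(rownames(X), object@constituents)
    out
})

#' Cumulative explained variance of a fitted model
#'
#' Percent of the (centered, weighted) predictor- and response-block
#' variance captured by the first 1..A factors.
#'
#' @param x a [PLSModel-class]
#' @param ... unused
#' @return list with components `x` and `y`, cumulative percentages
#' @export
setMethod("explainedVariance", "PLSModel", function(x, ...)
    list(x = x@xVariance, y = x@yVariance))

setMethod("show", "PLSModel", function(object) {
    cat(sprintf("PLSModel: %d factor%s, %d predictors -> %d constituent%s\n",
                object@nFactors, if (object@nFactors == 1L) "" else "s",
                length(object@xCenter), length(object@yCenter),
                if (length(object@yCenter) == 1L) "" else "s"))
    cat("  constituents:", paste(object@constituents, collapse = ", "), "\n")
    if (length(object@yVariance))
        cat(sprintf("  explained variance at %d factors: X %.1f%%, Y %.1f%%\n",
                    object@nFactors, utils::tail(object@xVariance, 1L),
                    utils::tail(object@yVariance, 1L)))
    if (length(object@notes))
        cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

## Predictions of `X` at every factor count in `aVec`, reusing one fitted
## model (exact truncation of the NIPALS sequence).
.predict_at_factors <- function(model, X, aVec) {
    p <- length(model@xCenter); m <- length(model@yCenter)
    out <- array(NA_real_, c(nrow(X), m, length(aVec)))
    Xc <- sweep(X, 2L, model@xCenter)
    for (k in seq_along(aVec)) {
        a <- min(aVec[k], model@nFactors)
        Bw <- .coef_weighted(model@loadingWeights, model@xLoadings,
                             model@yLoadings, a)
        B <- (model@xWeights * Bw) / matrix(model@yWeights, p, m, byrow = TRUE)
        out[, , k] <- sweep(Xc %*% B, 2L, model@yCenter, `+`)
    }
    out
}
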