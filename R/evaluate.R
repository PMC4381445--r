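#' @include pls.R
NULL

#' Leave-one-out cross-validation of a PLS calibration
#'
#' For every left-out sample the entire fit is redone on the remaining
#' samples: column means and any 1/SD weights are recomputed inside the
#' fold (no information leakage), the NIPALS sequence is re-extracted,
#' and the held-out spectrum is predicted at every factor count
#' `0..maxFactors` (0 = the mean model). The per-factor curves are
#'
#' \deqn{RMSECV_f = \sqrt{\frac{1}{n}\sum_i (y_i - \hat y_{-i,f})^2}}
#'
#' together with the calibration curve RMSEC from the full-data fit.
#'
#' @param x predictors ([SpectraMatrix-class] or matrix)
#' @param y responses ([ConstituentTable-class], matrix, or vector)
#' @param maxFactors largest factor count to evaluate; must satisfy
#'   `maxFactors <= min(n - 2, p)` so every fold can support it
#' @param xWeights,yWeights weighting options as in [fitPLS()]
#'   (`"inv_sd"` weights are refitted inside every fold)
#' @param tol,maxIter NIPALS controls, as in [fitPLS()]
#' @return a [PLSCrossValidation-class]
#' @export
looCV <- function(x, y, maxFactors, xWeights = NULL, yWeights = NULL,
                  tol = 1e-12, maxIter = 500L) {
    X <- .as_X(x); Y <- .as_Y(y)
    ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
    n <- nrow(X); m <- ncol(Y)
    if (n < 3L)
        stop("leave-one-out cross-validation needs at least 3 samples")
    maxFactors <- as.integer(maxFactors)
    if (maxFactors < 0L || maxFactors > min(n - 2L, ncol(X)))
        stop("maxFactors must lie in [0, min(n - 2, p)] = [0, ",
             min(n - 2L, ncol(X)), "]")
    factors <- 0:maxFactors
    preds <- array(NA_real_, c(n, m, length(factors)))
    for (i in seq_len(n)) {
        fit <- suppressWarnings(
            fitPLS(X[-i, , drop = FALSE], Y[-i, , drop = FALSE], maxFactors,
                   xWeights = xWeights, yWeights = yWeights,
                   tol = tol, maxIter = maxIter))
        preds[i, , ] <- .predict_at_factors(fit, X[i, , drop = FALSE], factors)
    }
    full <- suppressWarnings(
        fitPLS(X, Y, maxFactors, xWeights = xWeights, yWeights = yWeights,
               tol = tol, maxIter = maxIter))
    calPred <- .predict_at_factors(full, X, factors)
    rmsec <- t(apply(calPred, 3L, function(P) sqrt(colMeans((Y - P)^2))))
    rmsecv <- t(apply(preds, 3L, function(P) sqrt(colMeans((Y - P)^2))))
    dim(rmsec) <- dim(rmsecv) <- c(length(factors), m)
    tss <- colSums(sweep(Y, 2L, colMeans(Y))^2)
    calExp <- 100 * (1 - sweep(nrow(Y) * rmsec^2, 2L, tss, `/`))
    cvExp <- 100 * (1 - sweep(nrow(Y) * rmsecv^2, 2L, tss, `/`))
    cn <- colnames(Y) %||% paste0("y", seq_len(m))
    dimnames(rmsec) <- dimnames(rmsecv) <- dimnames(calExp) <-
        dimnames(cvExp) <- list(paste0("f", factors), cn)
    new("PLSCrossValidation", factors = factors,
        rmsec = rmsec, rmsecv = rmsecv,
        calExplained = calExp, cvExplained = cvExp,
        predictions = preds, constituents = cn, sampleIDs = ids)
}

#' Per-factor error curves of a cross-validation
#'
#' @param cv a [PLSCrossValidation-class]
#' @param which `"rmsecv"`, `"rmsec"`, `"cvExplained"` or `"calExplained"`
#' @return matrix, factor counts (0..max) in rows, constituents in columns
#' @export
cvCurve <- function(cv, which = c("rmsecv", "rmsec", "cvExplained",
                                  "calExplained")) {
    stopifnot(is(cv, "PLSCrossValidation"))
    which <- match.arg(which)
    slot(cv, which)
}

#' Leave-one-out predictions at a factor count
#'
#' @param cv a [PLSCrossValidation-class]
#' @param factors a single factor count present in `cv`
#' @return n x m matrix of held-out predictions
#' @export
looPredictions <- function(cv, factors) {
    stopifnot(is(cv, "PLSCrossValidation"))
    k <- match(as.integer(factors), cv@factors)
    if (is.na(k))
        stop("factor count ", factors, " was not evaluated")
    out <- cv@predictions[, , k, drop = FALSE]
    dim(out) <- dim(out)[1:2]
    dimnames(out) <- list(cv@sampleIDs, cv@constituents)
    out
}

setMethod("show", "PLSCrossValidation", function(object) {
    cat("PLSCrossValidation over factor counts",
        min(object@factors), "..", max(object@factors), "\n")
    cat("  constituents:", paste(object@constituents, collapse = ", "), "\n")
    k <- length(object@factors)
    cat("  RMSECV at max factors:",
        paste(sprintf("%s %.4g", object@constituents, object@rmsecv[k, ]),
              collapse = ", "), "\n")
})

#' Summary statistics for a (reference, predicted) pairing
#'
#' The statistics printed in calibration/validation summary tables:
#' RMSE, the squared Pearson correlation R^2, and the slope and
#' intercept of the least-squares line of predicted (ordinate) on
#' measured (abscissa).
#'
#' @param yRef reference values (primary method)
#' @param yPred predicted values, same length
#' @return one-row data.frame with columns `n`, `rmse`, `r2`, `slope`,
#'   `intercept`
#' @examples
#' summaryStats(c(1, 2, 3), c(1, 3, 2))  # rmse sqrt(2/3), r2 0.25
#' @export
summaryStats <- function(yRef, yPred) {
    yRef <- as.numeric(yRef); yPred <- as.numeric(yPred)
    if (length(yRef) != length(yPred))
        stop("reference and predicted vectors must have equal length")
    if (length(yRef) < 2L)
        stop("at least 2 pairs are required")
    if (stats::sd(yRef) == 0)
        stop("reference values are constant: R^2 and slope undefined")
    rmse <- sqrt(mean((yRef - yPred)^2))
    r2 <- stats::cor(yRef, yPred)^2
    slope <- stats::cov(yRef, yPred) / stats::var(yRef)
    intercept <- mean(yPred) - slope * mean(yRef)
    data.frame(n = length(yRef), rmse = rmse, r2 = r2,
               slope = slope, intercept = intercept)
}

#' Choose the number of latent factors from a cross-validation
#'
#' Returns the smallest factor count whose cross-validated explained
#' Y-variance, averaged over constituents, lies within `tolerance`
#' percentage points of its maximum over `1..maxFactors`. This encodes
#' the usual judgement call -- stop adding factors once cross-validated
#' performance has plateaued -- as an explicit rule; pass a manual
#' choice downstream to override it.
#'
#' @param cv a [PLSCrossValidation-class]
#' @param tolerance percentage points below the plateau that still
#'   counts as "at the maximum" (default 0.5)
#' @return integer factor count, >= 1
#' @export
selectFactors <- function(cv, tolerance = 0.5) {
    stopifnot(is(cv, "PLSCrossValidation"))
    pos <- cv@factors >= 1L
    if (!any(pos))
        stop("cross-validation was not run past 0 factors")
    avg <- rowMeans(cv@cvExplained[pos, , drop = FALSE])
    best <- max(avg)
    cv@factors[pos][which(avg >= best - tolerance)[1L]]
}

#' External validation of a calibration model
#'
#' Predicts a held-out sample set and reports RMSEP together with R^2,
#' slope and intercept per constituent. The validation samples must be
#' disjoint from the calibration samples.
#'
#' @param model a fitted [PLSModel-class]
#' @param x validation spectra, preprocessed identically to calibration
#' @param y validation reference values
#' @param calibrationIDs IDs the model was calibrated on; defaults to the
#'   row names of the model's fitted values
#' @return data.frame with one row per constituent: `constituent`, `n`,
#'   `factors`, `rmsep`, `r2`, `slope`, `intercept`
#' @export
validateExternal <- function(model, x, y, calibrationIDs = rownames(fitted(model))) {
    stopifnot(is(model, "PLSModel"))
    X <- .as_X(x); Y <- .as_Y(y)
    valIDs <- rownames(X)
    if (!is.null(valIDs) && !is.null(calibrationIDs)) {
        overlap <- intersect(valIDs, calibrationIDs)
        if (length(overlap))
            stop("validation samples overlap the calibration set ",
                 "(e.g. '", overlap[1L], "')")
    }
    pred <- predict(model, X)
    out <- do.call(rbind, lapply(seq_len(ncol(Y)), function(j) {
        s <- summaryStats(Y[, j], pred[, j])
        data.frame(constituent = colnames(Y)[j] %||% paste0("y", j),
                   n = s$n, factors = model@nFactors, rmsep = s$rmse,
                   r2 = s$r2, slope = s$slope, intercept = s$intercept)
    }))
    rownames(out) <- NULL
    out
}
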