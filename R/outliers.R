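#' @include split.R
NULL

## default cutoffs: composition (and the separate ash screen) 1.5,
## release/yield models 2.0
.OUTLIER_CUTOFFS <- c(composition = 1.5, ash = 1.5, reactivity = 2.0)

#' Normalized prediction error
#'
#' The outlier statistic: the absolute difference between reference and
#' predicted value, normalized by the calibration RMSE of that
#' constituent, `|y_ref - y_pred| / RMSEC`. Dimensionless, so errors are
#' comparable across constituents with different units and spreads.
#'
#' @param yRef reference value(s)
#' @param yPred predicted value(s)
#' @param rmsec calibration RMSE of the constituent, > 0
#' @return non-negative dimensionless error(s)
#' @examples
#' normalizedError(30.0, 27.28, 1.7)  # 1.6
#' @export
normalizedError <- function(yRef, yPred, rmsec) {
    if (any(rmsec <= 0))
        stop("RMSEC must be positive")
    abs(yRef - yPred) / rmsec
}

#' Build a per-sample, per-constituent outlier assessment
#'
#' @param yRef n x m reference matrix (or [ConstituentTable-class])
#' @param yPred n x m predictions from the base model
#' @param rmsec named per-constituent calibration RMSE
#' @return data.frame in long form: `sample_id`, `constituent`, `y_ref`,
#'   `y_pred`, `rmsec`, `error`
#' @export
assessOutliers <- function(yRef, yPred, rmsec) {
    Y <- .as_Y(yRef); P <- .as_Y(yPred)
    stopifnot(identical(dim(Y), dim(P)))
    ids <- rownames(Y) %||% as.character(seq_len(nrow(Y)))
    cons <- colnames(Y)
    if (!is.null(names(rmsec))) rmsec <- rmsec[cons]
    out <- data.frame(
        sample_id = rep(ids, times = ncol(Y)),
        constituent = rep(cons, each = nrow(Y)),
        y_ref = as.vector(Y), y_pred = as.vector(P),
        rmsec = rep(unname(rmsec), each = nrow(Y)))
    out$error <- normalizedError(out$y_ref, out$y_pred, out$rmsec)
    out
}

#' Flag outlying samples from an assessment
#'
#' Modes implement the screening rules used for each model family:
#' * `composition` -- flag when the mean of the glucan, xylan and lignin
#'   normalized errors exceeds 1.5 (ash is screened separately);
#' * `ash` -- flag when the ash normalized error exceeds 1.5;
#' * `reactivity` -- flag when any modeled constituent's normalized
#'   error exceeds 2.0.
#'
#' @param assessments long-form data.frame from [assessOutliers()]
#' @param mode `"composition"`, `"ash"` or `"reactivity"`
#' @param cutoff overrides the mode's default cutoff
#' @return named logical vector, one flag per sample (in first-appearance
#'   order), with attribute `"aggregate"` carrying the per-sample
#'   aggregated error that was compared to the cutoff
#' @export
flagOutliers <- function(assessments, mode = c("composition", "ash",
                                               "reactivity"),
                         cutoff = NULL) {
    mode <- match.arg(mode)
    if (is.null(cutoff)) cutoff <- .OUTLIER_CUTOFFS[[mode]]
    if (cutoff <= 0) stop("cutoff must be positive")
    need <- switch(mode,
                   composition = c("glucan", "xylan", "lignin"),
                   ash = "ash",
                   reactivity = unique(assessments$constituent))
    miss <- setdiff(need, unique(assessments$constituent))
    if (length(miss))
        stop("assessment lacks constituent '", miss[1L], "' required for ",
             mode, " screening")
    sub <- assessments[assessments$constituent %in% need, , drop = FALSE]
    ids <- unique(assessments$sample_id)
    agg <- switch(mode,
        composition = tapply(sub$error, factor(sub$sample_id, levels = ids),
                             mean),
        ash = tapply(sub$error, factor(sub$sample_id, levels = ids), mean),
        reactivity = tapply(sub$error, factor(sub$sample_id, levels = ids),
                            max))
    flags <- as.vector(agg) > cutoff
    names(flags) <- ids
    attr(flags, "aggregate") <- stats::setNames(as.vector(agg), ids)
    attr(flags, "cutoff") <- cutoff
    flags
}

#' Screen calibration outliers and refit
#'
#' Fits a base model on the full calibration set, computes normalized
#' prediction errors against the base model's per-constituent RMSEC,
#' removes every flagged sample, and refits. For `mode = "composition"`
#' the mean-of-glucan/xylan/lignin rule and the separate ash screen are
#' both applied (a sample flagged by either is removed). With
#' `maxRounds > 1` the rule is re-applied to the refitted model.
#' Flagged samples are always removed -- no discretionary exceptions --
#' and unflagged samples are never dropped.
#'
#' @param x calibration predictors (preprocessed spectra)
#' @param y calibration responses
#' @param nFactors factor count for the base (and refitted) model
#' @param mode screening mode, as in [flagOutliers()]
#' @param cutoff overrides the mode default (1.5 composition/ash,
#'   2.0 reactivity)
#' @param maxRounds screening passes (default 1, the usual single
#'   base-model pass)
#' @param xWeights,yWeights weighting options passed to [fitPLS()]
#' @return list with `model` (refit on the cleaned set), `assessments`
#'   (long-form data.frame incl. `flagged` and `cutoff_used`),
#'   `removedIDs`, `keptIDs`, and `baseModel`
#' @export
screenAndRefit <- function(x, y, nFactors, mode = c("composition", "ash",
                                                    "reactivity"),
                           cutoff = NULL, maxRounds = 1L,
                           xWeights = NULL, yWeights = NULL) {
    mode <- match.arg(mode)
    X <- .as_X(x); Y <- .as_Y(y)
    ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
    rownames(X) <- rownames(Y) <- ids
    removed <- character(0)
    assessments <- NULL
    base <- NULL
    for (round in seq_len(max(1L, as.integer(maxRounds)))) {
        keep <- setdiff(ids, removed)
        model <- fitPLS(X[keep, , drop = FALSE], Y[keep, , drop = FALSE],
                        nFactors, xWeights = xWeights, yWeights = yWeights)
        if (is.null(base)) base <- model
        pred <- fitted(model)
        rmsec <- sqrt(colMeans((Y[keep, , drop = FALSE] - pred)^2))
        names(rmsec) <- colnames(Y)
        a <- assessOutliers(Y[keep, , drop = FALSE], pred, rmsec)
        flags <- flagOutliers(a, mode = mode, cutoff = cutoff)
        if (mode == "composition" && "ash" %in% colnames(Y)) {
            ashFlags <- flagOutliers(a, mode = "ash", cutoff = cutoff)
            flags <- flags | ashFlags
        }
        a$flagged <- flags[a$sample_id]
        a$cutoff_used <- attr(flags, "cutoff")
        assessments <- a
        newly <- names(flags)[flags]
        if (!length(newly)) break
        if (length(newly) == length(keep))
            stop("every calibration sample was flagged as an outlier")
        removed <- c(removed, newly)
    }
    keep <- setdiff(ids, removed)
    model <- fitPLS(X[keep, , drop = FALSE], Y[keep, , drop = FALSE],
                    nFactors, xWeights = xWeights, yWeights = yWeights)
    list(model = model, assessments = assessments, removedIDs = removed,
         keptIDs = keep, baseModel = base)
}
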