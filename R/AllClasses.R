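#' @include AllGenerics.R
NULL

## relative tolerance for declaring the wavenumber axis uniformly spaced
.AXIS_RTOL <- 1e-6

.validSpectraMatrix <- function(object) {
    msg <- character(0)
    a <- object@absorbance
    wn <- object@wavenumbers
    ids <- object@sampleIDs
    if (length(ids) != nrow(a))
        msg <- c(msg, "number of sample IDs must equal number of spectra rows")
    if (anyDuplicated(ids))
        msg <- c(msg, sprintf("duplicate sample id: '%s'",
                              ids[duplicated(ids)][1L]))
    if (length(wn) != ncol(a))
        msg <- c(msg, "wavenumber axis length must equal number of columns")
    if (length(wn) < 2L)
        msg <- c(msg, "a spectrum needs at least 2 wavenumbers")
    if (anyNA(a) || any(!is.finite(a)))
        msg <- c(msg, "absorbance matrix contains missing or non-finite values")
    if (length(wn) >= 2L) {
        d <- diff(wn)
        if (!all(d > 0) && !all(d < 0)) {
            msg <- c(msg, "wavenumber axis must be strictly monotone")
        } else {
            spacing <- mean(d)
            if (any(abs(d - spacing) > .AXIS_RTOL * abs(spacing)))
                msg <- c(msg, "wavenumber axis is not uniformly spaced")
        }
    }
    if (length(msg)) msg else TRUE
}

#' SpectraMatrix: a samples-by-wavenumbers absorbance grid
#'
#' Container for a set of NIR absorbance spectra sharing a common,
#' uniformly spaced, strictly monotone wavenumber axis (cm^-1). Row
#' order is the sample order; sample IDs are unique.
#'
#' @slot absorbance numeric matrix, n_samples x n_wavenumbers
#' @slot wavenumbers numeric axis in cm^-1, strictly monotone, uniform
#' @slot sampleIDs character vector of unique sample identifiers
#' @export
setClass("SpectraMatrix",
         representation(absorbance = "matrix",
                        wavenumbers = "numeric",
                        sampleIDs = "character"),
         validity = .validSpectraMatrix)

#' Construct a SpectraMatrix
#'
#' @param absorbance numeric matrix (samples in rows). Row names are used
#'   as sample IDs when `sampleIDs` is missing.
#' @param wavenumbers numeric wavenumber axis (cm^-1); strictly monotone
#'   and uniformly spaced (relative tolerance 1e-6)
#' @param sampleIDs character sample identifiers, unique
#' @return a validated [SpectraMatrix-class] object
#' @examples
#' s <- SpectraMatrix(matrix(rnorm(6), 2, 3), c(4000, 4004, 4008),
#'                    c("a", "b"))
#' nSamples(s)
#' @export
SpectraMatrix <- function(absorbance, wavenumbers, sampleIDs = rownames(absorbance)) {
    absorbance <- as.matrix(absorbance)
    storage.mode(absorbance) <- "double"
    if (is.null(sampleIDs))
        stop("sample IDs are required (or supply row names)")
    sampleIDs <- as.character(sampleIDs)
    dimnames(absorbance) <- list(sampleIDs, format(wavenumbers, trim = TRUE))
    new("SpectraMatrix", absorbance = absorbance,
        wavenumbers = as.numeric(wavenumbers), sampleIDs = sampleIDs)
}

.validConstituentTable <- function(object) {
    msg <- character(0)
    v <- object@values
    ids <- object@sampleIDs
    un <- object@units
    if (length(ids) != nrow(v))
        msg <- c(msg, "number of sample IDs must equal number of rows")
    if (anyDuplicated(ids))
        msg <- c(msg, sprintf("duplicate sample id: '%s'",
                              ids[duplicated(ids)][1L]))
    if (length(un) != ncol(v))
        msg <- c(msg, "one unit tag per constituent required")
    bad <- setdiff(un, c("wt%_dry", "g_per_g", "fraction"))
    if (length(bad))
        msg <- c(msg, sprintf("unknown unit tag '%s'", bad[1L]))
    if (anyNA(v))
        msg <- c(msg, "constituent values contain missing entries")
    for (j in seq_len(ncol(v))) {
        cn <- colnames(v)[j]
        if (un[j] == "wt%_dry" && any(v[, j] < 0 | v[, j] > 100))
            msg <- c(msg, sprintf("constituent '%s' (wt%%_dry) outside [0, 100]", cn))
        if (un[j] %in% c("g_per_g", "fraction") && any(v[, j] < 0))
            msg <- c(msg, sprintf("constituent '%s' (%s) must be >= 0", cn, un[j]))
    }
    if (length(msg)) msg else TRUE
}

#' ConstituentTable: per-sample reference values with units
#'
#' Reference (primary-method) values for each sample: composition on a
#' dry-weight percent basis, carbohydrate release in g per g dry biomass,
#' and yields as dimensionless fractions of theoretical.
#'
#' @slot values numeric matrix, n_samples x n_constituents, named columns
#' @slot units character unit tag per column, one of
#'   `"wt%_dry"`, `"g_per_g"`, `"fraction"`
#' @slot sampleIDs character vector of unique sample identifiers
#' @export
setClass("ConstituentTable",
         representation(values = "matrix",
                        units = "character",
                        sampleIDs = "character"),
         validity = .validConstituentTable)

#' Construct a ConstituentTable
#'
#' @param values numeric matrix with one named column per constituent
#' @param units named character vector of unit tags (one of `"wt%_dry"`,
#'   `"g_per_g"`, `"fraction"`), aligned with the columns of `values`
#' @param sampleIDs character sample identifiers (default: row names)
#' @return a validated [ConstituentTable-class]
#' @examples
#' ConstituentTable(matrix(c(33.2, 17.8), 1, 2,
#'                         dimnames = list("s1", c("glucan", "xylan"))),
#'                  units = c(glucan = "wt%_dry", xylan = "wt%_dry"))
#' @export
ConstituentTable <- function(values, units, sampleIDs = rownames(values)) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(colnames(values)))
        stop("constituent columns must be named")
    if (!is.null(names(units)))
        units <- units[colnames(values)]
    if (anyNA(units))
        stop("a unit tag is required for every constituent")
    if (is.null(sampleIDs))
        stop("sample IDs are required (or supply row names)")
    sampleIDs <- as.character(sampleIDs)
    rownames(values) <- sampleIDs
    new("ConstituentTable", values = values, units = as.character(units),
        sampleIDs = sampleIDs)
}

.validPreprocessChain <- function(object) {
    msg <- character(0)
    if (object@derivative) {
        if (object@window %% 2L == 0L)
            msg <- c(msg, "smoothing window must be odd")
        if (object@window <= object@polyorder)
            msg <- c(msg, "smoothing window must exceed the polynomial order")
        if (object@derivOrder > object@polyorder)
            msg <- c(msg, "derivative order cannot exceed the polynomial order")
    }
    if (length(object@range) == 2L && object@range[1L] >= object@range[2L])
        msg <- c(msg, "range lower bound must be below the upper bound")
    if (!object@weighting %in% c("none", "inv_sd"))
        msg <- c(msg, "weighting must be 'none' or 'inv_sd'")
    if (length(object@fittedWeights) &&
        any(!is.finite(object@fittedWeights) | object@fittedWeights <= 0))
        msg <- c(msg, "fitted column weights must be finite and positive")
    if (length(msg)) msg else TRUE
}

#' PreprocessChain: ordered spectral pretreatment
#'
#' Describes (and, once fitted, carries the state of) the pretreatment
#' chain applied before latent-variable modelling: SNV scatter
#' correction, Savitzky-Golay derivative, wavenumber range restriction,
#' and optional 1/SD column weighting fitted on calibration spectra only.
#'
#' @slot snv logical; apply standard normal variate per spectrum
#' @slot derivative logical; apply the Savitzky-Golay derivative
#' @slot window odd integer smoothing window (points)
#' @slot polyorder integer local polynomial order
#' @slot derivOrder integer derivative order (<= polyorder)
#' @slot range numeric length-2 inclusive wavenumber bounds (cm^-1), or
#'   length-0 to skip range restriction
#' @slot weighting `"none"` or `"inv_sd"`
#' @slot fittedWeights per-wavenumber 1/SD weights (length 0 until fitted)
#' @slot fittedWavenumbers axis the fitted weights refer to
#' @export
setClass("PreprocessChain",
         representation(snv = "logical",
                        derivative = "logical",
                        window = "integer",
                        polyorder = "integer",
                        derivOrder = "integer",
                        range = "numeric",
                        weighting = "character",
                        fittedWeights = "numeric",
                        fittedWavenumbers = "numeric"),
         validity = .validPreprocessChain)

#' Construct a preprocessing chain
#'
#' Defaults follow routine NIR practice for ground herbaceous biomass:
#' SNV, then a Savitzky-Golay first derivative (2nd-order polynomial,
#' 21-point window), then restriction to 4,000-8,998 cm^-1.
#'
#' @param snv logical, apply SNV scatter correction first
#' @param derivative logical, apply the SG derivative second
#' @param window odd integer SG window in points
#' @param polyorder SG polynomial order
#' @param derivOrder SG derivative order
#' @param range inclusive wavenumber bounds in cm^-1, or `NULL` to keep
#'   the full axis
#' @param weighting `"none"` or `"inv_sd"`; with `"inv_sd"`,
#'   [fitChain()] stores per-wavenumber 1/SD weights that
#'   [applyChain()] then reuses for any new spectra
#' @return an (unfitted) [PreprocessChain-class]
#' @examples
#' chain <- preprocessChain()
#' chain
#' @export
preprocessChain <- function(snv = TRUE, derivative = TRUE, window = 21L,
                            polyorder = 2L, derivOrder = 1L,
                            range = c(4000, 8998), weighting = "none") {
    new("PreprocessChain", snv = isTRUE(snv), derivative = isTRUE(derivative),
        window = as.integer(window), polyorder = as.integer(polyorder),
        derivOrder = as.integer(derivOrder),
        range = if (is.null(range)) numeric(0) else as.numeric(range),
        weighting = weighting,
        fittedWeights = numeric(0), fittedWavenumbers = numeric(0))
}

.validPLSModel <- function(object) {
    msg <- character(0)
    p <- length(object@xCenter)
    m <- length(object@yCenter)
    A <- object@nFactors
    if (A < 0L) msg <- c(msg, "factor count must be >= 0")
    if (!identical(dim(object@coefficients), c(p, m)))
        msg <- c(msg, "coefficient matrix dimensions are inconsistent")
    if (A > 0L) {
        if (ncol(object@loadingWeights) != A || ncol(object@xLoadings) != A ||
            ncol(object@yLoadings) != A || ncol(object@scores) != A)
            msg <- c(msg, "per-factor matrices must have nFactors columns")
        tt <- crossprod(object@scores)
        off <- tt - diag(diag(tt), nrow = A)
        scale <- max(diag(tt))
        if (scale > 0 && max(abs(off)) > 1e-8 * scale)
            msg <- c(msg, "score vectors are not mutually orthogonal")
    }
    if (length(msg)) msg else TRUE
}

#' PLSModel: a fitted latent-variable regression
#'
#' NIPALS partial least squares fit relating preprocessed spectra to one
#' (PLS-1) or several (PLS-2) constituents. Centers and any 1/SD column
#' weights are stored so that prediction of new spectra reproduces the
#' calibration-time transformation exactly; regression coefficients are
#' kept on the original (unweighted, uncentered) scale.
#'
#' @slot nFactors number of latent factors retained
#' @slot xCenter,yCenter column means of predictors and responses
#' @slot xWeights,yWeights column weights applied during fitting (all 1
#'   when no weighting was requested)
#' @slot loadingWeights,xLoadings p x A matrices (W and P)
#' @slot yLoadings m x A matrix (Q)
#' @slot scores n x A calibration score matrix (T), mutually orthogonal
#' @slot coefficients p x m regression coefficients on the original scale
#' @slot fitted n x m fitted responses in original units
#' @slot constituents response names
#' @slot predictorWavenumbers wavenumber axis of the predictors (cm^-1)
#' @slot xVariance,yVariance cumulative percent variance explained per
#'   factor in the (weighted, centered) predictor and response blocks
#' @slot provenance list describing the preprocessing that produced the
#'   predictor matrix
#' @slot notes character; fitting diagnostics (e.g. early rank stop)
#' @export
setClass("PLSModel",
         representation(nFactors = "integer",
                        xCenter = "numeric",
                        yCenter = "numeric",
                        xWeights = "numeric",
                        yWeights = "numeric",
                        loadingWeights = "matrix",
                        xLoadings = "matrix",
                        yLoadings = "matrix",
                        scores = "matrix",
                        coefficients = "matrix",
                        fitted = "matrix",
                        constituents = "character",
                        predictorWavenumbers = "numeric",
                        xVariance = "numeric",
                        yVariance = "numeric",
                        provenance = "list",
                        notes = "character"),
         validity = .validPLSModel)

#' PLSCrossValidation: leave-one-out cross-validation results
#'
#' Per-factor-count calibration and cross-validation error curves plus
#' the per-sample leave-one-out predictions they derive from. Factor
#' count 0 (the mean model) is included as the baseline row.
#'
#' @slot factors integer factor counts, `0:maxFactors`
#' @slot rmsec matrix (length(factors) x m) of calibration RMS errors
#' @slot rmsecv matrix of leave-one-out RMS errors
#' @slot calExplained cumulative percent Y-variance explained in
#'   calibration, per factor count and constituent
#' @slot cvExplained percent Y-variance explained by the leave-one-out
#'   predictions (1 - PRESS/TSS), per factor count and constituent
#' @slot predictions n x m x length(factors) array of LOO predictions
#' @slot constituents response names
#' @slot sampleIDs calibration sample identifiers
#' @export
setClass("PLSCrossValidation",
         representation(factors = "integer",
                        rmsec = "matrix",
                        rmsecv = "matrix",
                        calExplained = "matrix",
                        cvExplained = "matrix",
                        predictions = "array",
                        constituents = "character",
                        sampleIDs = "character"))

.validCalibrationSplit <- function(object) {
    msg <- character(0)
    if (length(intersect(object@calibrationIDs, object@validationIDs)))
        msg <- c(msg, "calibration and validation sets overlap")
    if (length(object@calibrationIDs) + length(object@validationIDs) !=
        nrow(object@scores))
        msg <- c(msg, "split does not cover all scored samples")
    if (object@nPC < 1L) msg <- c(msg, "at least one principal component required")
    if (length(msg)) msg else TRUE
}

#' CalibrationSplit: a Kennard-Stone calibration/validation partition
#'
#' @slot calibrationIDs sample IDs selected for calibration, in selection
#'   order (first two are the farthest pair)
#' @slot validationIDs remaining sample IDs, in input order
#' @slot scores PCA score matrix the selection was run on
#' @slot nPC number of principal components used
#' @export
setClass("CalibrationSplit",
         representation(calibrationIDs = "character",
                        validationIDs = "character",
                        scores = "matrix",
                        nPC = "integer"),
         validity = .validCalibrationSplit)
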