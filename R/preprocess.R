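#' @include spectra.R
NULL

#' Standard normal variate (SNV) scatter correction
#'
#' Centers and scales each spectrum to mean 0 and unit sample standard
#' deviation (n-1 denominator). SNV removes multiplicative and constant
#' additive scatter exactly: `snv(a*x + b) == snv(x)` for any `a > 0`.
#'
#' @param spectra a [SpectraMatrix-class]
#' @return a [SpectraMatrix-class] of SNV-corrected spectra
#' @export
snv <- function(spectra) {
    stopifnot(is(spectra, "SpectraMatrix"))
    a <- absorbance(spectra)
    mu <- rowMeans(a)
    sdev <- sqrt(rowSums((a - mu)^2) / (ncol(a) - 1L))
    zero <- which(sdev == 0)
    if (length(zero))
        stop("zero-variance spectrum for sample '",
             sampleIDs(spectra)[zero[1L]], "': SNV undefined")
    SpectraMatrix((a - mu) / sdev, wavenumbers(spectra), sampleIDs(spectra))
}

#' Savitzky-Golay derivative of spectra
#'
#' Local least-squares polynomial differentiation on the uniform
#' wavenumber grid. Interior points carry the derivative of the local
#' degree-`polyorder` fit, expressed per cm^-1 (i.e. scaled by the grid
#' spacing); the axis is trimmed by `(window-1)/2` points at each edge
#' rather than using asymmetric edge fits. Filter coefficients come from
#' [signal::sgolay()] (central row).
#'
#' @param spectra a [SpectraMatrix-class]
#' @param window odd integer smoothing window in points
#' @param polyorder local polynomial order (< window)
#' @param derivOrder derivative order (<= polyorder)
#' @return a [SpectraMatrix-class] on the trimmed axis, units
#'   absorbance per cm^-1 (for `derivOrder = 1`)
#' @export
sgDerivative <- function(spectra, window = 21L, polyorder = 2L,
                         derivOrder = 1L) {
    stopifnot(is(spectra, "SpectraMatrix"))
    window <- as.integer(window)
    polyorder <- as.integer(polyorder)
    derivOrder <- as.integer(derivOrder)
    if (window %% 2L == 0L || window <= polyorder)
        stop("window must be odd and greater than the polynomial order")
    if (derivOrder > polyorder)
        stop("derivative order cannot exceed the polynomial order")
    wn <- wavenumbers(spectra)
    if (length(wn) < window)
        stop("need at least ", window, " wavenumbers for a ", window,
             "-point filter")
    h <- abs(mean(diff(wn)))
    filt <- signal::sgolay(p = polyorder, n = window, m = derivOrder, ts = h)
    half <- (window - 1L) %/% 2L
    cc <- filt[half + 1L, ]
    a <- absorbance(spectra)
    p <- ncol(a)
    out <- matrix(0, nrow(a), p - 2L * half)
    # convolution as a running weighted sum over the window offsets
    for (k in seq_len(window)) {
        cols <- k:(p - window + k)
        out <- out + cc[k] * a[, cols, drop = FALSE]
    }
    # an ascending-vs-descending axis flips the sign of odd derivatives
    if (mean(diff(wn)) < 0 && derivOrder %% 2L == 1L)
        out <- -out
    SpectraMatrix(out, wn[(half + 1L):(length(wn) - half)],
                  sampleIDs(spectra))
}

#' Restrict spectra to a wavenumber range
#'
#' Keeps the wavenumbers `lo <= nu <= hi` (bounds inclusive), preserving
#' axis order. The default window removes the noisy ends of a
#' 3,300-12,000 cm^-1 acquisition grid.
#'
#' @param spectra a [SpectraMatrix-class]
#' @param lo,hi inclusive bounds in cm^-1 (`lo < hi`)
#' @return the restricted [SpectraMatrix-class]
#' @export
restrictRange <- function(spectra, lo = 4000, hi = 8998) {
    stopifnot(is(spectra, "SpectraMatrix"))
    if (lo >= hi)
        stop("range lower bound must be below the upper bound")
    wn <- wavenumbers(spectra)
    keep <- wn >= lo & wn <= hi
    if (!any(keep))
        stop("no wavenumbers inside [", lo, ", ", hi, "]")
    SpectraMatrix(absorbance(spectra)[, keep, drop = FALSE], wn[keep],
                  sampleIDs(spectra))
}

#' @describeIn columnWeights 1/SD weights of a numeric matrix's columns
#'   (sample SD, n-1 denominator)
#' @export
setMethod("columnWeights", "matrix", function(x, ...) {
    sdev <- apply(x, 2L, stats::sd)
    zero <- which(sdev == 0)
    if (length(zero)) {
        nm <- colnames(x)[zero[1L]] %||% as.character(zero[1L])
        stop("zero-variance column at wavenumber '", nm,
             "': 1/SD weight undefined")
    }
    1 / sdev
})

#' Per-wavenumber 1/SD column weights
#'
#' Standardization weights used to give every wavenumber equal leverage
#' in the latent-variable fit: `weight_j = 1 / sd(column_j)` with the
#' sample (n-1) standard deviation over the calibration spectra.
#'
#' @param x a [SpectraMatrix-class], numeric matrix, or fitted
#'   [PreprocessChain-class]
#' @param ... unused
#' @return positive numeric vector, one weight per wavenumber
#' @export
setMethod("columnWeights", "SpectraMatrix", function(x, ...) {
    w <- columnWeights(absorbance(x))
    stats::setNames(w, format(wavenumbers(x), trim = TRUE))
})

#' @describeIn columnWeights the weights stored in a fitted chain
#' @export
setMethod("columnWeights", "PreprocessChain", function(x, ...) {
    if (!length(x@fittedWeights))
        stop("chain has no fitted column weights; call fitChain() first")
    x@fittedWeights
})

.chain_transform <- function(chain, spectra) {
    out <- spectra
    if (chain@snv) out <- snv(out)
    if (chain@derivative)
        out <- sgDerivative(out, chain@window, chain@polyorder,
                            chain@derivOrder)
    if (length(chain@range) == 2L)
        out <- restrictRange(out, chain@range[1L], chain@range[2L])
    out
}

#' Fit a preprocessing chain on calibration spectra
#'
#' Applies the chain's steps in order (SNV, then Savitzky-Golay
#' derivative, then range restriction) and, when the chain requests
#' `inv_sd` weighting, fits the per-wavenumber 1/SD weights on these
#' calibration spectra. The returned chain carries that state so
#' [applyChain()] reuses the stored weights for held-out spectra.
#'
#' @param chain a [PreprocessChain-class] from [preprocessChain()]
#' @param spectra calibration [SpectraMatrix-class]
#' @return list with elements `chain` (the fitted chain) and `spectra`
#'   (the transformed calibration spectra)
#' @export
fitChain <- function(chain, spectra) {
    stopifnot(is(chain, "PreprocessChain"), is(spectra, "SpectraMatrix"))
    out <- .chain_transform(chain, spectra)
    if (chain@weighting == "inv_sd") {
        w <- unname(columnWeights(out))
        chain@fittedWeights <- w
        chain@fittedWavenumbers <- wavenumbers(out)
        out <- SpectraMatrix(sweep(absorbance(out), 2L, w, `*`),
                             wavenumbers(out), sampleIDs(out))
    }
    validObject(chain)
    list(chain = chain, spectra = out)
}

#' Apply a preprocessing chain to (new) spectra
#'
#' Steps run in the fitted order; if the chain carries fitted 1/SD
#' weights they are applied as stored, never refitted, so predictions on
#' held-out spectra see exactly the calibration-time transformation.
#'
#' @param chain a [PreprocessChain-class]; must be fitted when
#'   `weighting = "inv_sd"`
#' @param spectra a [SpectraMatrix-class]
#' @return the transformed [SpectraMatrix-class]
#' @export
applyChain <- function(chain, spectra) {
    stopifnot(is(chain, "PreprocessChain"), is(spectra, "SpectraMatrix"))
    out <- .chain_transform(chain, spectra)
    if (chain@weighting == "inv_sd") {
        if (!length(chain@fittedWeights))
            stop("chain requests inv_sd weighting but has no fitted weights; ",
                 "call fitChain() on the calibration spectra first")
        if (length(chain@fittedWavenumbers) != nWavenumbers(out) ||
            max(abs(chain@fittedWavenumbers - wavenumbers(out))) > 1e-6)
            stop("spectra axis does not match the axis the weights were fitted on")
        out <- SpectraMatrix(sweep(absorbance(out), 2L, chain@fittedWeights, `*`),
                             wavenumbers(out), sampleIDs(out))
    }
    out
}

setMethod("show", "PreprocessChain", function(object) {
    steps <- c(
        if (object@snv) "SNV",
        if (object@derivative)
            sprintf("SG derivative (window %d, order %d, deriv %d)",
                    object@window, object@polyorder, object@derivOrder),
        if (length(object@range) == 2L)
            sprintf("range [%g, %g] cm^-1", object@range[1L], object@range[2L]),
        if (object@weighting == "inv_sd")
            sprintf("1/SD column weighting (%s)",
                    if (length(object@fittedWeights)) "fitted" else "unfitted"))
    if (!length(steps)) steps <- "identity (no steps)"
    cat("PreprocessChain:\n")
    cat(paste0("  ", seq_along(steps), ". ", steps, collapse = "\n"), "\n")
})

.chain_provenance <- function(chain) {
    list(snv = chain@snv,
         derivative = chain@derivative,
         window = chain@window,
         polyorder = chain@polyorder,
         derivOrder = chain@derivOrder,
         range = chain@range,
         weighting = chain@weighting)
}
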