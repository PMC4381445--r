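#' @include AllClasses.R
NULL

#' @rdname accessors
#' @export
setMethod("absorbance", "SpectraMatrix", function(x) x@absorbance)

#' @rdname accessors
#' @export
setMethod("wavenumbers", "SpectraMatrix", function(x) x@wavenumbers)

#' @rdname accessors
#' @export
setMethod("sampleIDs", "SpectraMatrix", function(x) x@sampleIDs)

#' @rdname accessors
#' @export
setMethod("nSamples", "SpectraMatrix", function(x) nrow(x@absorbance))

#' @rdname accessors
#' @export
setMethod("nWavenumbers", "SpectraMatrix", function(x) ncol(x@absorbance))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "ConstituentTable", function(x) x@sampleIDs)

#' @rdname accessors
#' @export
setMethod("nSamples", "ConstituentTable", function(x) nrow(x@values))

#' @rdname accessors
#' @export
setMethod("constituentNames", "ConstituentTable", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("constituentUnits", "ConstituentTable",
          function(x) stats::setNames(x@units, colnames(x@values)))

#' @rdname accessors
#' @export
setMethod("constituentValues", "ConstituentTable", function(x) x@values)

setMethod("show", "SpectraMatrix", function(object) {
    wn <- object@wavenumbers
    cat("SpectraMatrix with", nrow(object@absorbance), "spectra x",
        ncol(object@absorbance), "wavenumbers\n")
    cat(sprintf("  axis: %.3f .. %.3f cm^-1 (spacing %.4f)\n",
                wn[1L], wn[length(wn)], mean(diff(wn))))
    ids <- object@sampleIDs
    cat("  samples:", paste(utils::head(ids, 4L), collapse = ", "),
        if (length(ids) > 4L) "..." else "", "\n")
})

setMethod("show", "ConstituentTable", function(object) {
    cat("ConstituentTable with", nrow(object@values), "samples x",
        ncol(object@values), "constituents\n")
    u <- constituentUnits(object)
    cat(" ", paste(sprintf("%s [%s]", names(u), u), collapse = ", "), "\n")
})

#' Subset a SpectraMatrix by sample
#'
#' @param x a [SpectraMatrix-class]
#' @param i sample IDs (character) or indices
#' @param j,...,drop ignored (spectra keep their full axis)
#' @return a [SpectraMatrix-class] with the selected spectra
#' @export
setMethod("[", "SpectraMatrix", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) {
        miss <- setdiff(i, x@sampleIDs)
        if (length(miss))
            stop("unknown sample id: '", miss[1L], "'")
        i <- match(i, x@sampleIDs)
    }
    SpectraMatrix(x@absorbance[i, , drop = FALSE], x@wavenumbers,
                  x@sampleIDs[i])
})

#' Subset a ConstituentTable by sample and constituent
#'
#' @param x a [ConstituentTable-class]
#' @param i sample IDs (character) or indices
#' @param j constituent names (character) or indices
#' @param ...,drop ignored
#' @export
setMethod("[", "ConstituentTable", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_along(x@sampleIDs)
    if (is.character(i)) {
        miss <- setdiff(i, x@sampleIDs)
        if (length(miss))
            stop("unknown sample id: '", miss[1L], "'")
        i <- match(i, x@sampleIDs)
    }
    if (missing(j)) j <- seq_len(ncol(x@values))
    if (is.character(j)) {
        miss <- setdiff(j, colnames(x@values))
        if (length(miss))
            stop("unknown constituent: '", miss[1L], "'")
        j <- match(j, colnames(x@values))
    }
    ConstituentTable(x@values[i, j, drop = FALSE], x@units[j], x@sampleIDs[i])
})

#' Average duplicate scans into one spectrum per sample
#'
#' NIR acquisition scans each sample from two separate samplings; the two
#' absorbance spectra are averaged before any preprocessing. Replicates
#' are recognized either through an explicit `replicateMap` or, by
#' default, by stripping a trailing `"_rep<k>"` suffix from the sample
#' ID.
#'
#' @param spectra a [SpectraMatrix-class] whose rows are replicate scans
#' @param replicateMap optional named character vector mapping each
#'   replicate sample ID to its base sample ID; defaults to removing a
#'   `_rep1`/`_rep2`/... suffix (IDs without the suffix map to themselves)
#' @return a [SpectraMatrix-class] with one row per base ID (order of
#'   first appearance), each the arithmetic mean of its replicates
#' @examples
#' s <- SpectraMatrix(rbind(a_rep1 = c(1, 1, 1), a_rep2 = c(3, 3, 3)),
#'                    c(4000, 4004, 4008))
#' absorbance(averageDuplicates(s))  # 2 2 2
#' @export
averageDuplicates <- function(spectra, replicateMap = NULL) {
    stopifnot(is(spectra, "SpectraMatrix"))
    ids <- sampleIDs(spectra)
    if (is.null(replicateMap)) {
        base <- sub("_rep[0-9]+$", "", ids)
    } else {
        if (is.null(names(replicateMap)))
            stop("replicateMap must be named by replicate sample id")
        miss <- setdiff(ids, names(replicateMap))
        if (length(miss))
            stop("replicateMap has no entry for sample '", miss[1L], "'")
        base <- unname(replicateMap[ids])
    }
    keep <- unique(base)
    a <- absorbance(spectra)
    avg <- rowsum(a, group = base, reorder = FALSE) /
        as.vector(table(factor(base, levels = unique(base))))
    avg <- avg[keep, , drop = FALSE]
    SpectraMatrix(avg, wavenumbers(spectra), keep)
}
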