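#' @include AllGenerics.R
NULL

#' Accessor generics
#'
#' Small family of accessors used across the spectra, constituent-table and
#' model classes. All return copies; slots are never reached into directly.
#'
#' @param x an object of one of the package classes
#' @param object an object of one of the package classes
#' @param ... further arguments for methods
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @rdname accessors
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("nWavenumbers", function(x) standardGeneric("nWavenumbers"))

#' @rdname accessors
#' @export
setGeneric("constituentNames", function(x) standardGeneric("constituentNames"))

#' @rdname accessors
#' @export
setGeneric("constituentUnits", function(x) standardGeneric("constituentUnits"))

#' @rdname accessors
#' @export
setGeneric("constituentValues", function(x) standardGeneric("constituentValues"))

#' @rdname accessors
#' @export
setGeneric("nFactors", function(x) standardGeneric("nFactors"))

#' @rdname accessors
#' @export
setGeneric("loadingWeights", function(x) standardGeneric("loadingWeights"))

#' @rdname accessors
#' @export
setGeneric("xLoadings", function(x) standardGeneric("xLoadings"))

#' @rdname accessors
#' @export
setGeneric("yLoadings", function(x) standardGeneric("yLoadings"))

#' @rdname accessors
#' @export
setGeneric("plsScores", function(x) standardGeneric("plsScores"))

#' @rdname accessors
#' @export
setGeneric("calibrationIDs", function(x) standardGeneric("calibrationIDs"))

#' @rdname accessors
#' @export
setGeneric("validationIDs", function(x) standardGeneric("validationIDs"))

#' @rdname accessors
#' @export
setGeneric("columnWeights", function(x, ...) standardGeneric("columnWeights"))

#' @rdname accessors
#' @export
setGeneric("explainedVariance", function(x, ...) standardGeneric("explainedVariance"))
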