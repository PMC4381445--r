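#' @include spectra.R
NULL

.num17 <- function(x) sprintf("%.17g", x)

#' Read a spectra CSV
#'
#' Dialect: one row per sample; first column `sample_id`; every remaining
#' header is a wavenumber in cm^-1 (printed with 3 decimals by
#' [writeSpectraCSV()]); `.` decimal separator; UTF-8.
#'
#' @param path path to the CSV file
#' @return a validated [SpectraMatrix-class]
#' @seealso [writeSpectraCSV()] for the exact round-trip guarantee
#' @export
readSpectraCSV <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    dt <- data.table::fread(path, header = TRUE, sep = ",",
                            colClasses = list(character = 1L),
                            data.table = FALSE, encoding = "UTF-8")
    if (ncol(dt) < 3L)
        stop("malformed header in ", path,
             ": need sample_id plus at least 2 wavenumber columns")
    if (names(dt)[1L] != "sample_id")
        stop("malformed header in ", path, ": first column must be 'sample_id'")
    wn <- suppressWarnings(as.numeric(names(dt)[-1L]))
    if (anyNA(wn)) {
        bad <- names(dt)[-1L][which(is.na(wn))[1L]]
        stop("malformed header in ", path,
             ": non-numeric wavenumber column '", bad, "'")
    }
    for (j in 2:ncol(dt)) {
        if (!is.numeric(dt[[j]])) {
            conv <- suppressWarnings(as.numeric(dt[[j]]))
            row <- which(is.na(conv) & !is.na(dt[[j]]))[1L]
            stop("non-numeric cell in ", path, " at row ", row,
                 ", column '", names(dt)[j], "'")
        }
    }
    SpectraMatrix(as.matrix(dt[, -1L, drop = FALSE]), wn, dt[[1L]])
}

#' Write a spectra CSV
#'
#' Absorbances are rendered with 17 significant digits so that
#' `readSpectraCSV(writeSpectraCSV(s))` reproduces `s` bit-exactly;
#' wavenumber headers carry 3 decimals.
#'
#' @param spectra a [SpectraMatrix-class] with at least one sample
#' @param path output path
#' @return `path`, invisibly
#' @export
writeSpectraCSV <- function(spectra, path) {
    stopifnot(is(spectra, "SpectraMatrix"))
    if (nSamples(spectra) == 0L)
        stop("no samples to write")
    header <- paste(c("sample_id", sprintf("%.3f", wavenumbers(spectra))),
                    collapse = ",")
    a <- absorbance(spectra)
    body <- vapply(seq_len(nrow(a)), function(i)
        paste(c(sampleIDs(spectra)[i], .num17(a[i, ])), collapse = ","),
        character(1))
    writeLines(c(header, body), path, useBytes = TRUE)
    invisible(path)
}

#' Read a constituent table CSV
#'
#' First column `sample_id`; every remaining header must appear in
#' `unitsMap`, which assigns each constituent its unit tag. Values are
#' range-checked per unit (`wt%_dry` within \[0, 100\]; `g_per_g` and
#' `fraction` non-negative).
#'
#' @param path path to the CSV file
#' @param unitsMap named character vector, constituent -> unit tag
#' @return a validated [ConstituentTable-class]
#' @export
readConstituentsCSV <- function(path, unitsMap) {
    if (!file.exists(path))
        stop("file not found: ", path)
    dt <- data.table::fread(path, header = TRUE, sep = ",",
                            colClasses = list(character = 1L),
                            data.table = FALSE, encoding = "UTF-8")
    if (names(dt)[1L] != "sample_id")
        stop("malformed header in ", path, ": first column must be 'sample_id'")
    cons <- names(dt)[-1L]
    unknown <- setdiff(cons, names(unitsMap))
    if (length(unknown))
        stop("unknown constituent '", unknown[1L], "' in ", path)
    ConstituentTable(as.matrix(dt[, -1L, drop = FALSE]),
                     unitsMap[cons], dt[[1L]])
}

#' Write a constituent table CSV
#'
#' @param table a [ConstituentTable-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeConstituentsCSV <- function(table, path) {
    stopifnot(is(table, "ConstituentTable"))
    if (nSamples(table) == 0L)
        stop("no samples to write")
    v <- constituentValues(table)
    header <- paste(c("sample_id", colnames(v)), collapse = ",")
    body <- vapply(seq_len(nrow(v)), function(i)
        paste(c(sampleIDs(table)[i], .num17(v[i, ])), collapse = ","),
        character(1))
    writeLines(c(header, body), path, useBytes = TRUE)
    invisible(path)
}

.MODEL_SCHEMA <- "feedstockNIR/PLSModel/1"

.pack_matrix <- function(m) {
    dn <- dimnames(m)
    if (is.null(dn)) dn <- list(character(0), character(0))
    # empty vectors (not NULL) survive the JSON round trip unambiguously
    dn <- lapply(dn, function(d) if (is.null(d)) character(0)
                 else as.character(d))
    list(dim = dim(m), data = as.vector(m), dimnames = dn)
}

.unpack_matrix <- function(x) {
    m <- matrix(as.numeric(unlist(x$data)),
                nrow = x$dim[1L], ncol = x$dim[2L])
    dn <- lapply(x$dimnames, function(d)
        if (is.null(d) || !length(d)) NULL else as.character(d))
    if (!all(vapply(dn, is.null, logical(1))) && length(dn) == 2L)
        dimnames(m) <- dn
    m
}

#' Serialize a fitted PLS model to JSON
#'
#' Numbers are written at full precision so that predictions from the
#' reloaded model equal the original bit-exactly. The preprocessing
#' provenance travels with the model.
#'
#' @param model a fitted [PLSModel-class]
#' @param path output path (`.json`)
#' @return `path`, invisibly
#' @export
saveModel <- function(model, path) {
    stopifnot(is(model, "PLSModel"))
    obj <- list(
        schema = .MODEL_SCHEMA,
        nFactors = model@nFactors,
        xCenter = model@xCenter, yCenter = model@yCenter,
        xWeights = model@xWeights, yWeights = model@yWeights,
        loadingWeights = .pack_matrix(model@loadingWeights),
        xLoadings = .pack_matrix(model@xLoadings),
        yLoadings = .pack_matrix(model@yLoadings),
        scores = .pack_matrix(model@scores),
        coefficients = .pack_matrix(model@coefficients),
        fitted = .pack_matrix(model@fitted),
        constituents = model@constituents,
        predictorWavenumbers = model@predictorWavenumbers,
        xVariance = model@xVariance, yVariance = model@yVariance,
        provenance = model@provenance,
        notes = model@notes)
    # I(17) significant digits: doubles survive the decimal round trip
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                         null = "null")
    invisible(path)
}

#' Load a PLS model serialized by [saveModel()]
#'
#' @param path path to the JSON file
#' @return a [PLSModel-class]
#' @export
loadModel <- function(path) {
    obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e)
                        stop("cannot parse model file ", path, ": ",
                             conditionMessage(e)))
    if (!identical(obj$schema, .MODEL_SCHEMA))
        stop("schema-version mismatch in ", path, ": found '",
             obj$schema %||% "<none>", "', expected '", .MODEL_SCHEMA, "'")
    new("PLSModel",
        nFactors = as.integer(obj$nFactors),
        xCenter = as.numeric(obj$xCenter), yCenter = as.numeric(obj$yCenter),
        xWeights = as.numeric(obj$xWeights), yWeights = as.numeric(obj$yWeights),
        loadingWeights = .unpack_matrix(obj$loadingWeights),
        xLoadings = .unpack_matrix(obj$xLoadings),
        yLoadings = .unpack_matrix(obj$yLoadings),
        scores = .unpack_matrix(obj$scores),
        coefficients = .unpack_matrix(obj$coefficients),
        fitted = .unpack_matrix(obj$fitted),
        constituents = as.character(obj$constituents),
        predictorWavenumbers = as.numeric(obj$predictorWavenumbers),
        xVariance = as.numeric(obj$xVariance),
        yVariance = as.numeric(obj$yVariance),
        provenance = as.list(obj$provenance),
        notes = as.character(obj$notes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
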