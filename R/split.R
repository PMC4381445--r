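#' @include evaluate.R
NULL

#' PCA scores of preprocessed spectra
#'
#' Mean-centered principal component scores via [stats::prcomp()]
#' (no variance scaling), with a deterministic sign convention: the
#' largest-magnitude element of each rotation vector is made positive.
#'
#' @param x a preprocessed [SpectraMatrix-class] or numeric matrix
#' @param nPC number of leading components to keep (default 2)
#' @return n x nPC score matrix (sample IDs in row names), ordered by
#'   decreasing explained variance, with attribute `"varExplained"`
#'   (percent per component)
#' @export
pcaScores <- function(x, nPC = 2L) {
    X <- .as_X(x)
    nPC <- as.integer(nPC)
    if (nPC < 1L)
        stop("at least one principal component is required")
    if (nrow(X) <= nPC)
        stop("need more samples (", nrow(X), ") than components (", nPC, ")")
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    if (ncol(pc$rotation) < nPC)
        stop("requested ", nPC, " components but the data support only ",
             ncol(pc$rotation))
    flip <- vapply(seq_len(nPC), function(j) {
        r <- pc$rotation[, j]
        if (r[which.max(abs(r))] < 0) -1 else 1
    }, numeric(1))
    scores <- sweep(pc$x[, seq_len(nPC), drop = FALSE], 2L, flip, `*`)
    rownames(scores) <- rownames(X)
    attr(scores, "varExplained") <-
        100 * pc$sdev[seq_len(nPC)]^2 / sum(pc$sdev^2)
    scores
}

#' Kennard-Stone calibration/validation split
#'
#' Deterministic max-min-distance selection in score space: the first
#' two picks are the pair at maximum Euclidean distance; every later
#' pick maximizes its minimum distance to the already-selected set.
#' Ties are broken by the lowest sample index (then lexicographic ID),
#' so the split is reproducible and invariant to row permutation up to
#' that rule. Unselected samples form the external validation set.
#'
#' @param scores n x k score matrix (rows named by sample ID), e.g. from
#'   [pcaScores()]
#' @param nSelect number of calibration samples, `2 <= nSelect <= n`
#' @return a [CalibrationSplit-class]; calibration IDs are in selection
#'   order, validation IDs in input order
#' @export
kennardStone <- function(scores, nSelect) {
    scores <- as.matrix(scores)
    n <- nrow(scores)
    if (n < 2L)
        stop("Kennard-Stone needs at least 2 samples")
    nSelect <- as.integer(nSelect)
    if (nSelect < 2L || nSelect > n)
        stop("nSelect must lie in [2, ", n, "]")
    ids <- rownames(scores) %||% as.character(seq_len(n))
    D <- as.matrix(stats::dist(scores))
    # seed pair: maximum distance; ties -> smallest (i, then j)
    best <- c(1L, 2L); bestD <- -Inf
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        if (D[i, j] > bestD) { bestD <- D[i, j]; best <- c(i, j) }
    }
    selected <- best
    remaining <- setdiff(seq_len(n), selected)
    minDist <- pmin(D[, selected[1L]], D[, selected[2L]])
    while (length(selected) < nSelect) {
        cand <- remaining[which.max(minDist[remaining])]  # first max = lowest index
        selected <- c(selected, cand)
        remaining <- setdiff(remaining, cand)
        minDist <- pmin(minDist, D[, cand])
    }
    new("CalibrationSplit",
        calibrationIDs = ids[selected],
        validationIDs = ids[sort(setdiff(seq_len(n), selected))],
        scores = scores, nPC = ncol(scores))
}

#' @rdname accessors
#' @export
setMethod("calibrationIDs", "CalibrationSplit", function(x) x@calibrationIDs)

#' @rdname accessors
#' @export
setMethod("validationIDs", "CalibrationSplit", function(x) x@validationIDs)

#' @rdname accessors
#' @export
setMethod("plsScores", "CalibrationSplit", function(x) x@scores)

setMethod("show", "CalibrationSplit", function(object) {
    cat("CalibrationSplit:", length(object@calibrationIDs), "calibration /",
        length(object@validationIDs), "validation samples over",
        object@nPC, "PCs\n")
})

#' Write a split as a two-column role CSV
#'
#' @param split a [CalibrationSplit-class]
#' @param path output path; columns `sample_id`, `role`
#'   (`calibration`/`validation`), rows in score order
#' @return `path`, invisibly
#' @export
writeSplitCSV <- function(split, path) {
    stopifnot(is(split, "CalibrationSplit"))
    ids <- rownames(split@scores)
    role <- ifelse(ids %in% split@calibrationIDs, "calibration", "validation")
    writeLines(c("sample_id,role", paste(ids, role, sep = ",")), path,
               useBytes = TRUE)
    invisible(path)
}
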