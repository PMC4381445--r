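#' @include reactivity.R
NULL

.DEFAULT_CONSTITUENTS <- data.frame(
    row.names = c("glucan", "xylan", "lignin", "ash"),
    mean = c(33.2, 17.8, 15.2, 6.7),
    sd   = c(6.3, 3.4, 3.8, 3.6),
    min  = c(21.4, 9.5, 6.7, 0.9),
    max  = c(47.8, 28.7, 29.0, 16.4))

## Gaussian absorption bands (center cm^-1, width cm^-1, amplitude AU)
## per constituent; "other" is the unmodeled remainder of the dry mass
.DEFAULT_BANDS <- list(
    glucan = cbind(center = c(4390, 5180, 6890),
                   width = c(110, 160, 210), amplitude = c(1.3, 0.9, 0.55)),
    xylan  = cbind(center = c(4250, 5590, 7350),
                   width = c(95, 150, 260), amplitude = c(1.1, 0.85, 0.35)),
    lignin = cbind(center = c(4660, 5970, 8750),
                   width = c(105, 170, 320), amplitude = c(1.2, 0.7, 0.4)),
    ash    = cbind(center = c(5310, 7150),
                   width = c(240, 230), amplitude = c(0.55, 0.5)),
    other  = cbind(center = c(4900, 6420, 8200),
                   width = c(300, 340, 400), amplitude = c(0.65, 0.5, 0.3)))

#' Configuration of the synthetic feedstock study generator
#'
#' Describes a simulated population with the statistical structure the
#' calibration pipeline assumes: per-constituent truncated-normal
#' composition distributions, Beer-Lambert mixture spectra built from
#' Gaussian band bases with multiplicative/additive scatter and
#' instrument noise, duplicate scans per sample, reference-measurement
#' (wet-chemistry) uncertainty, and a linear-in-composition reactivity
#' response with assay noise.
#'
#' @param nSamples population size (default 279)
#' @param seed integer RNG seed used by [simulateFeedstockStudy()]
#' @param grid named numeric `c(lo, hi, spacing)` in cm^-1
#' @param constituents data.frame with rows per constituent and columns
#'   `mean`, `sd`, `min`, `max` (wt% dry basis)
#' @param bands named list (one entry per constituent plus `"other"`) of
#'   matrices with columns `center`, `width`, `amplitude`
#' @param scatter named numeric `c(mult, add)`: SDs of the per-sample
#'   multiplicative gain (around 1) and constant additive offset
#' @param noiseSD instrument noise SD in absorbance units, iid per point
#'   and per replicate scan
#' @param nReplicates scans per sample (default 2)
#' @param referenceNoiseSD named per-constituent SD (wt%) of the
#'   reference-method error added to the true compositions; emulates the
#'   wet-chemistry uncertainty that dominates real calibration errors
#' @param reactivity list with linear coefficient vectors `G`
#'   (`intercept`, `glucan`, `lignin`) and `X` (`intercept`, `xylan`,
#'   `lignin`) mapping composition (wt%) to release (g/g), and
#'   `noiseSD = c(G, X)` assay noise
#' @param bimodal optional named list (constituent -> list(`means`,
#'   `sds`, `weights`)) replacing the single truncated normal by a
#'   two-component mixture, for stress tests of non-normal populations
#' @return a list of class `"SimConfig"`
#' @export
simConfig <- function(nSamples = 279L, seed = 1L,
                      grid = c(lo = 3300, hi = 12000, spacing = 3.857),
                      constituents = .DEFAULT_CONSTITUENTS,
                      bands = .DEFAULT_BANDS,
                      scatter = c(mult = 0.05, add = 0.02),
                      noiseSD = 5e-4,
                      nReplicates = 2L,
                      referenceNoiseSD = c(glucan = 1.1, xylan = 0.7,
                                           lignin = 0.75, ash = 0.85),
                      reactivity = list(
                          G = c(intercept = 0.035, glucan = 0.008,
                                lignin = -0.004),
                          X = c(intercept = 0, xylan = 0.009,
                                lignin = -0.002),
                          noiseSD = c(G = 0.02, X = 0.015)),
                      bimodal = NULL) {
    if (grid[["spacing"]] <= 0) stop("grid spacing must be positive")
    if (grid[["lo"]] >= grid[["hi"]]) stop("grid lo must be below hi")
    if (any(constituents$sd < 0)) stop("constituent SDs must be >= 0")
    if (any(constituents$min > constituents$mean |
            constituents$mean > constituents$max))
        stop("constituent bounds must satisfy min <= mean <= max")
    if (any(vapply(bands, function(b) any(b[, "amplitude"] <= 0), logical(1))))
        stop("band amplitudes must be positive")
    if (any(scatter < 0) || noiseSD < 0) stop("noise SDs must be >= 0")
    structure(list(nSamples = as.integer(nSamples), seed = as.integer(seed),
                   grid = grid, constituents = constituents, bands = bands,
                   scatter = scatter, noiseSD = noiseSD,
                   nReplicates = as.integer(nReplicates),
                   referenceNoiseSD = referenceNoiseSD,
                   reactivity = reactivity, bimodal = bimodal),
              class = "SimConfig")
}

.sim_axis <- function(config)
    seq(config$grid[["lo"]], config$grid[["hi"]], by = config$grid[["spacing"]])

## center of a truncated normal adjusted so the truncated mean equals the
## stated population mean
.trunc_center <- function(target, sd, lo, hi) {
    if (sd == 0) return(target)
    truncMean <- function(mu) {
        a <- (lo - mu) / sd; b <- (hi - mu) / sd
        z <- stats::pnorm(b) - stats::pnorm(a)
        mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
    }
    stats::uniroot(function(mu) truncMean(mu) - target,
                   lower = target - 3 * sd, upper = target + 3 * sd,
                   tol = 1e-10)$root
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
    if (sd == 0) return(rep(mean, n))
    out <- stats::rnorm(n, mean, sd)
    bad <- which(out < lo | out > hi)
    while (length(bad)) {
        out[bad] <- stats::rnorm(length(bad), mean, sd)
        bad <- bad[out[bad] < lo | out[bad] > hi]
    }
    out
}

#' Draw a synthetic feedstock composition population
#'
#' Per-constituent truncated-normal draws whose truncated means match
#' the configured population means (the generating center is adjusted
#' for the truncation); the truncation itself shrinks the SD a few
#' percent, which is accepted. Rows whose four constituents total more
#' than 100 wt% are redrawn so the unmodeled "other" remainder stays
#' non-negative. An optional two-component mixture per constituent is
#' available through `config$bimodal`.
#'
#' Uses the current RNG state; seed once per study
#' (see [simulateFeedstockStudy()]).
#'
#' @param config a [simConfig()] object
#' @return a [ConstituentTable-class] of true compositions (wt% dry)
#' @export
sampleCompositions <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    cp <- config$constituents
    n <- config$nSamples
    drawRow <- function(nm, k) {
        bi <- config$bimodal[[nm]]
        if (!is.null(bi)) {
            comp <- sample.int(length(bi$weights), k, replace = TRUE,
                               prob = bi$weights)
            .rtruncnorm_mix(k, comp, bi$means, bi$sds,
                            cp[nm, "min"], cp[nm, "max"])
        } else {
            ctr <- .trunc_center(cp[nm, "mean"], cp[nm, "sd"],
                                 cp[nm, "min"], cp[nm, "max"])
            .rtruncnorm(k, ctr, cp[nm, "sd"], cp[nm, "min"], cp[nm, "max"])
        }
    }
    v <- vapply(rownames(cp), drawRow, numeric(n), k = n)
    bad <- which(rowSums(v) > 100)
    while (length(bad)) {
        v[bad, ] <- vapply(rownames(cp), drawRow, numeric(length(bad)),
                           k = length(bad))
        bad <- bad[rowSums(v[bad, , drop = FALSE]) > 100]
    }
    ids <- sprintf("FS%04d", seq_len(n))
    ConstituentTable(v, units = stats::setNames(rep("wt%_dry", ncol(v)),
                                                colnames(v)),
                     sampleIDs = ids)
}

.rtruncnorm_mix <- function(n, comp, means, sds, lo, hi) {
    out <- numeric(n)
    for (c in unique(comp)) {
        idx <- which(comp == c)
        out[idx] <- .rtruncnorm(length(idx), means[c], sds[c], lo, hi)
    }
    out
}

#' Pure-component basis spectra on the simulation grid
#'
#' Each constituent's basis is a sum of Gaussian absorption bands. The
#' bases must be linearly independent (checked through the singular
#' values of the basis matrix) or mixtures would not identify the
#' constituents.
#'
#' @param config a [simConfig()] object
#' @return matrix n_wavenumbers x n_constituents (including `"other"`),
#'   with attribute `"wavenumbers"`
#' @export
makeBasisSpectra <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    wn <- .sim_axis(config)
    basis <- vapply(config$bands, function(b) {
        if (any(b[, "center"] < min(wn) | b[, "center"] > max(wn)))
            stop("band center outside the wavenumber grid")
        rowSums(vapply(seq_len(nrow(b)), function(i)
            b[i, "amplitude"] *
                exp(-0.5 * ((wn - b[i, "center"]) / b[i, "width"])^2),
            numeric(length(wn))))
    }, numeric(length(wn)))
    sv <- svd(basis, nu = 0, nv = 0)$d
    if (min(sv) <= 1e-6 * max(sv))
        stop("degenerate (collinear) basis spectra: constituent bands are ",
             "not linearly independent")
    attr(basis, "wavenumbers") <- wn
    basis
}

#' Generate Beer-Lambert mixture spectra with scatter and noise
#'
#' Each sample's ideal spectrum is the composition-weighted sum of the
#' constituent bases (mass fractions, with the remainder to 100 wt%
#' entering through the `"other"` basis). Scatter applies per sample as
#' a multiplicative gain `a ~ 1 + N(0, mult)` and a constant additive
#' offset `b ~ N(0, add)` -- the distortion SNV removes exactly --
#' while instrument noise is drawn independently per replicate scan.
#'
#' @param compositions true compositions ([ConstituentTable-class], wt%)
#' @param basis basis matrix from [makeBasisSpectra()]
#' @param config a [simConfig()] object
#' @return a [SpectraMatrix-class] with `nReplicates` rows per sample,
#'   IDs suffixed `_rep1`, `_rep2`, ...
#' @export
generateSpectra <- function(compositions, basis, config) {
    stopifnot(inherits(config, "SimConfig"),
              is(compositions, "ConstituentTable"))
    wn <- attr(basis, "wavenumbers")
    v <- constituentValues(compositions)
    if (!all(colnames(v) %in% colnames(basis)))
        stop("basis lacks a column for some constituent")
    frac <- cbind(v, other = pmax(0, 100 - rowSums(v))) / 100
    frac <- frac[, colnames(basis), drop = FALSE]
    ideal <- frac %*% t(basis)          # n x p
    n <- nrow(ideal); p <- ncol(ideal); R <- config$nReplicates
    out <- matrix(0, n * R, p)
    ids <- character(n * R)
    for (i in seq_len(n)) {
        a <- 1 + stats::rnorm(1L, 0, config$scatter[["mult"]])
        b <- stats::rnorm(1L, 0, config$scatter[["add"]])
        for (r in seq_len(R)) {
            k <- (i - 1L) * R + r
            out[k, ] <- a * ideal[i, ] + b +
                stats::rnorm(p, 0, config$noiseSD)
            ids[k] <- sprintf("%s_rep%d", sampleIDs(compositions)[i], r)
        }
    }
    SpectraMatrix(out, wn, ids)
}

#' Overlay reference-method (wet-chemistry) uncertainty
#'
#' The reported reference values are the true compositions plus
#' independent normal measurement error (per-constituent SDs from the
#' configuration), truncated to the physical range. This is the error
#' floor a spectroscopic calibration inherits from its primary method.
#'
#' @param compositions true compositions ([ConstituentTable-class])
#' @param config a [simConfig()] object
#' @return a [ConstituentTable-class] of reference values
#' @export
addReferenceNoise <- function(compositions, config) {
    stopifnot(inherits(config, "SimConfig"))
    v <- constituentValues(compositions)
    for (nm in colnames(v)) {
        sdn <- config$referenceNoiseSD[[nm]]
        if (is.null(sdn) || sdn == 0) next
        v[, nm] <- pmin(100, pmax(0, v[, nm] + stats::rnorm(nrow(v), 0, sdn)))
    }
    ConstituentTable(v, constituentUnits(compositions),
                     sampleIDs(compositions))
}

#' Generate reactivity constituents from compositions
#'
#' Release is linear in composition plus assay noise -- the weakest
#' structure under which a latent-variable calibration can succeed --
#' with lignin entering negatively (recalcitrance). Yields are computed
#' exactly from the simulated releases by the yield arithmetic of
#' [reactivityTable()], so the yield columns are internally consistent
#' with the release columns by construction.
#'
#' @param compositions true compositions ([ConstituentTable-class], wt%)
#' @param config a [simConfig()] object
#' @return a [ConstituentTable-class] with the six reactivity columns
#' @export
generateReactivity <- function(compositions, config) {
    stopifnot(inherits(config, "SimConfig"))
    v <- constituentValues(compositions)
    n <- nrow(v)
    cg <- config$reactivity$G; cx <- config$reactivity$X
    g <- cg[["intercept"]] + cg[["glucan"]] * v[, "glucan"] +
        cg[["lignin"]] * v[, "lignin"] +
        stats::rnorm(n, 0, config$reactivity$noiseSD[["G"]])
    x <- cx[["intercept"]] + cx[["xylan"]] * v[, "xylan"] +
        cx[["lignin"]] * v[, "lignin"] +
        stats::rnorm(n, 0, config$reactivity$noiseSD[["X"]])
    g <- pmax(0, g); x <- pmax(0, x)
    reactivityTable(g, x, glucanFrac = v[, "glucan"] / 100,
                    xylanFrac = v[, "xylan"] / 100,
                    sampleIDs = sampleIDs(compositions))
}

#' Simulate a complete feedstock study
#'
#' Seeds the RNG once, then draws the true composition population,
#' builds the basis spectra, acquires duplicate noisy scans, overlays
#' reference-method uncertainty on the composition table, and generates
#' reactivity responses. Everything downstream of the seed is
#' deterministic: the same configuration reproduces the same study
#' bit-for-bit.
#'
#' @param config a [simConfig()] object (its `seed` is used)
#' @return list with `spectra` (replicate scans), `composition`
#'   (reference values, the modelling targets), `reactivity`,
#'   `trueComposition`, `basis` and `config`
#' @export
simulateFeedstockStudy <- function(config = simConfig()) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed)
    trueComp <- sampleCompositions(config)
    basis <- makeBasisSpectra(config)
    spectra <- generateSpectra(trueComp, basis, config)
    reference <- addReferenceNoise(trueComp, config)
    reactivity <- generateReactivity(trueComp, config)
    list(spectra = spectra, composition = reference,
         reactivity = reactivity, trueComposition = trueComp,
         basis = basis, config = config)
}
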