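test_that("the study generator is deterministic under a fixed seed", {
    a <- simulateFeedstockStudy(simConfig(nSamples = 10, seed = 5))
    b <- simulateFeedstockStudy(simConfig(nSamples = 10, seed = 5))
    expect_identical(absorbance(a$spectra), absorbance(b$spectra))
    expect_identical(constituentValues(a$composition),
                     constituentValues(b$composition))
    expect_identical(constituentValues(a$reactivity),
                     constituentValues(b$reactivity))
    c <- simulateFeedstockStudy(simConfig(nSamples = 10, seed = 6))
    expect_gt(max(abs(absorbance(a$spectra) - absorbance(c$spectra))), 0)
})

test_that("composition draws respect their bounds and target moments", {
    cfg <- simConfig(nSamples = 10000L, seed = 2)
    set.seed(cfg$seed)
    comp <- sampleCompositions(cfg)
    v <- constituentValues(comp)
    cp <- cfg$constituents
    for (nm in rownames(cp)) {
        expect_true(all(v[, nm] >= cp[nm, "min"] & v[, nm] <= cp[nm, "max"]))
        expect_lt(abs(mean(v[, nm]) - cp[nm, "mean"]), 0.3)
    }
    expect_true(all(rowSums(v) <= 100))
    # degenerate SD pins every draw at the mean
    cp0 <- cp; cp0$sd <- 0
    cfg0 <- simConfig(nSamples = 50L, seed = 3, constituents = cp0)
    set.seed(3)
    v0 <- constituentValues(sampleCompositions(cfg0))
    for (nm in rownames(cp0))
        expect_true(all(v0[, nm] == cp0[nm, "mean"]))
})

test_that("an optional mixture distribution produces bimodal draws", {
    bi <- list(glucan = list(means = c(26, 40), sds = c(2, 2),
                             weights = c(0.5, 0.5)))
    cfg <- simConfig(nSamples = 2000L, seed = 4, bimodal = bi)
    set.seed(4)
    v <- constituentValues(sampleCompositions(cfg))[, "glucan"]
    expect_true(all(v >= 21.4 & v <= 47.8))
    # clear antimode between the two components
    expect_lt(mean(v > 31 & v < 35), 0.12)
})

test_that("basis spectra are independent Gaussian-band sums on the grid", {
    cfg <- simConfig(nSamples = 5, seed = 1)
    basis <- makeBasisSpectra(cfg)
    wn <- attr(basis, "wavenumbers")
    expect_equal(ncol(basis), 5L)  # four constituents plus "other"
    expect_equal(qr(basis)$rank, 5L)
    # one isolated band peaks at the grid point nearest its center
    one <- cfg
    one$bands <- list(x = cbind(center = 5000, width = 80, amplitude = 1),
                      y = cbind(center = 7000, width = 80, amplitude = 1))
    b1 <- makeBasisSpectra(one)
    expect_equal(which.max(b1[, "x"]), which.min(abs(wn - 5000)))
    # duplicated constituent definitions are rejected as collinear
    dup <- cfg
    dup$bands <- list(a = cbind(center = 5000, width = 100, amplitude = 1),
                      b = cbind(center = 5000, width = 100, amplitude = 1))
    expect_error(makeBasisSpectra(dup), "collinear")
    off <- cfg
    off$bands <- list(a = cbind(center = 100, width = 50, amplitude = 1))
    expect_error(makeBasisSpectra(off), "outside")
})

test_that("spectra follow the mixture model; SNV cancels the scatter exactly", {
    clean <- simConfig(nSamples = 6, seed = 9,
                       scatter = c(mult = 0, add = 0), noiseSD = 0)
    set.seed(9)
    comp <- sampleCompositions(clean)
    basis <- makeBasisSpectra(clean)
    spec <- generateSpectra(comp, basis, clean)
    v <- constituentValues(comp)
    frac <- cbind(v, other = 100 - rowSums(v)) / 100
    ideal <- frac[, colnames(basis)] %*% t(basis)
    expect_equal(unname(absorbance(spec)[seq(1, 11, 2), ]), unname(ideal),
                 tolerance = 1e-12)
    # replicates are identical when noise is off
    expect_identical(unname(absorbance(spec)[1, ]),
                     unname(absorbance(spec)[2, ]))
    # multiplicative + additive scatter is removed exactly by SNV
    scat <- simConfig(nSamples = 6, seed = 9,
                      scatter = c(mult = 0.2, add = 0.1), noiseSD = 0)
    set.seed(9)
    specScat <- generateSpectra(comp, basis, scat)
    pure <- SpectraMatrix(ideal, attr(basis, "wavenumbers"),
                          sampleIDs(comp))
    expect_equal(unname(absorbance(snv(specScat))[seq(1, 11, 2), ]),
                 unname(absorbance(snv(pure))), tolerance = 1e-10)
})

test_that("reactivity is linear in composition with the configured moments", {
    cfg <- simConfig(nSamples = 20, seed = 15)
    cfg$reactivity$noiseSD <- c(G = 0, X = 0)
    set.seed(15)
    comp <- sampleCompositions(cfg)
    tab <- generateReactivity(comp, cfg)
    v <- constituentValues(comp); r <- constituentValues(tab)
    cg <- cfg$reactivity$G
    expect_equal(unname(r[, "G.Release"]),
                 unname(cg[["intercept"]] + cg[["glucan"]] * v[, "glucan"] +
                        cg[["lignin"]] * v[, "lignin"]),
                 tolerance = 1e-12)
    # yield columns reproduce the reactivity arithmetic bit-exactly
    redo <- reactivityTable(r[, "G.Release"], r[, "X.Release"],
                            v[, "glucan"] / 100, v[, "xylan"] / 100,
                            sampleIDs = sampleIDs(comp))
    expect_identical(constituentValues(redo), constituentValues(tab))
    # population moments approach the configured targets
    big <- simConfig(nSamples = 10000L, seed = 16)
    set.seed(16)
    compBig <- sampleCompositions(big)
    rBig <- constituentValues(generateReactivity(compBig, big))
    expect_lt(abs(mean(rBig[, "G.Release"]) - 0.24), 0.01)
    expect_lt(abs(mean(rBig[, "X.Release"]) - 0.13), 0.01)
    expect_true(all(rBig >= 0))
})

test_that("reference noise perturbs the table without leaving the physical range", {
    cfg <- simConfig(nSamples = 200, seed = 18)
    set.seed(18)
    comp <- sampleCompositions(cfg)
    ref <- addReferenceNoise(comp, cfg)
    d <- constituentValues(ref) - constituentValues(comp)
    expect_gt(max(abs(d)), 0)
    for (nm in colnames(d))
        expect_lt(sd(d[, nm]), 2 * cfg$referenceNoiseSD[[nm]])
    expect_true(all(constituentValues(ref) >= 0 &
                        constituentValues(ref) <= 100))
})
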