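wn3 <- c(4000, 4004, 4008)

test_that("SNV centers and scales each spectrum, and is affine-invariant", {
    s <- SpectraMatrix(rbind(a = c(3, 4, 5)), wn3)
    expect_equal(unname(absorbance(snv(s))[1, ]), c(-1, 0, 1))
    expect_error(snv(SpectraMatrix(rbind(flat = c(2, 2, 2)), wn3)),
                 "zero-variance spectrum for sample 'flat'")
    set.seed(21)
    for (rep in 1:10) {
        x <- rnorm(50)
        a <- runif(1, 0.1, 5); b <- rnorm(1, sd = 3)
        wn <- seq(4000, by = 4, length.out = 50)
        s1 <- snv(SpectraMatrix(rbind(r = x), wn))
        s2 <- snv(SpectraMatrix(rbind(r = a * x + b), wn))
        expect_equal(absorbance(s1), absorbance(s2), tolerance = 1e-10)
        z <- absorbance(s1)[1, ]
        expect_lt(abs(mean(z)), 1e-10)
        expect_lt(abs(sd(z) - 1), 1e-10)
        # idempotence
        expect_equal(absorbance(snv(s1)), absorbance(s1), tolerance = 1e-10)
    }
})

test_that("SG derivative is exact on polynomials up to the fit order", {
    wn <- seq(4000, by = 3.857, length.out = 60)
    const <- SpectraMatrix(rbind(c = rep(2.5, 60)), wn)
    dconst <- sgDerivative(const)
    expect_equal(nWavenumbers(dconst), 60 - 20)  # half-window trim each side
    expect_equal(max(abs(absorbance(dconst))), 0, tolerance = 1e-12)
    lin <- SpectraMatrix(rbind(l = 0.003 * wn - 5), wn)
    expect_equal(unname(absorbance(sgDerivative(lin))[1, ]),
                 rep(0.003, 40), tolerance = 1e-9)
    quad <- SpectraMatrix(rbind(q = 1e-6 * wn^2), wn)
    dq <- sgDerivative(quad)
    expect_equal(unname(absorbance(dq)[1, ]), 2e-6 * wavenumbers(dq),
                 tolerance = 1e-9)
    # a descending acquisition axis gives the same derivative w.r.t. nu
    lin_desc <- SpectraMatrix(rbind(l = 0.003 * rev(wn) - 5), rev(wn))
    expect_equal(unname(absorbance(sgDerivative(lin_desc))[1, ]),
                 rep(0.003, 40), tolerance = 1e-9)
})

test_that("SG derivative is linear and validates its window", {
    wn <- seq(4000, by = 3.857, length.out = 40)
    set.seed(4)
    X <- SpectraMatrix(rbind(x = rnorm(40)), wn)
    Y <- SpectraMatrix(rbind(y = rnorm(40)), wn)
    comb <- SpectraMatrix(2 * absorbance(X) - 3 * absorbance(Y), wn, "z")
    expect_equal(absorbance(sgDerivative(comb)),
                 2 * absorbance(sgDerivative(X)) -
                     3 * absorbance(sgDerivative(Y)),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_error(sgDerivative(X, window = 20L), "odd")
    expect_error(sgDerivative(X, window = 3L, polyorder = 3L), "odd and greater")
    expect_error(sgDerivative(X, derivOrder = 3L), "cannot exceed")
    expect_error(sgDerivative(SpectraMatrix(rbind(s = rnorm(10)),
                                            wn[1:10])),
                 "at least 21 wavenumbers")
})

test_that("range restriction is inclusive, order-preserving and composable", {
    wn <- seq(3300, 12000, by = 3.857)
    s <- SpectraMatrix(matrix(rnorm(2 * length(wn)), 2), wn, c("a", "b"))
    r <- restrictRange(s)
    expect_true(all(wavenumbers(r) >= 4000 & wavenumbers(r) <= 8998))
    expect_false(is.unsorted(wavenumbers(r)))
    # nested restriction equals the inner restriction
    r2 <- restrictRange(restrictRange(s, 3500, 10000), 4000, 8998)
    expect_identical(absorbance(r2), absorbance(r))
    # full-span bounds are the identity
    expect_identical(absorbance(restrictRange(s, 0, 2e4)), absorbance(s))
    expect_error(restrictRange(s, 5000, 4999), "lower bound")
    expect_error(restrictRange(s, 12500, 13000), "no wavenumbers inside")
})

test_that("1/SD column weights respond to column scale and flag zero variance", {
    set.seed(9)
    X <- matrix(rnorm(60), 20, 3)
    X[, 1] <- X[, 1] / sd(X[, 1]) * 2   # SD exactly 2
    X[, 2] <- X[, 2] / sd(X[, 2])       # SD exactly 1
    w <- columnWeights(X)
    expect_equal(unname(w[1]), 0.5)
    expect_equal(unname(w[2]), 1)
    # scaling a column by c scales its weight by 1/c
    X2 <- X; X2[, 3] <- 4 * X[, 3]
    expect_equal(columnWeights(X2)[3], columnWeights(X)[3] / 4)
    s <- SpectraMatrix(rbind(a = c(1, 5, 2), b = c(1, 7, 3)), wn3)
    expect_error(columnWeights(s), "zero-variance column at wavenumber '4000'")
})

test_that("the chain applies its steps in the documented order", {
    # on a scatter-perturbed quadratic the order SNV->SG differs from SG->SNV
    wn <- seq(4000, by = 3.857, length.out = 80)
    base <- 1e-6 * wn^2
    s <- SpectraMatrix(rbind(a = 1.3 * base + 0.2, b = 0.8 * base - 0.1), wn)
    chainOrder <- absorbance(sgDerivative(snv(s)))
    swapped <- absorbance(snv(sgDerivative(s)))
    expect_gt(max(abs(chainOrder - swapped)), 1e-6)
    full <- applyChain(preprocessChain(range = NULL), s)
    expect_equal(absorbance(full), chainOrder)
    # the empty chain is the identity
    idchain <- preprocessChain(snv = FALSE, derivative = FALSE, range = NULL)
    expect_identical(absorbance(applyChain(idchain, s)), absorbance(s))
})

test_that("fitted column weights are reused for held-out spectra, not refit", {
    sim <- tinyStudy(n = 12, seed = 5)
    avg <- averageDuplicates(sim$spectra)
    cal <- avg[1:9]; hold <- avg[10:12]
    chain <- preprocessChain(weighting = "inv_sd")
    expect_error(applyChain(chain, cal), "no fitted weights")
    fit <- fitChain(chain, cal)
    # calibration transform: plain chain output times the stored weights
    plain <- applyChain(preprocessChain(), cal)
    w <- columnWeights(fit$chain)
    expect_equal(absorbance(fit$spectra),
                 sweep(absorbance(plain), 2, w, `*`))
    # held-out samples see the calibration weights, not their own
    heldPlain <- applyChain(preprocessChain(), hold)
    held <- applyChain(fit$chain, hold)
    expect_equal(absorbance(held), sweep(absorbance(heldPlain), 2, w, `*`))
    wOwn <- columnWeights(heldPlain)
    expect_gt(max(abs(w - wOwn)), 1e-8)  # they differ, so reuse is observable
})
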