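test_that("SpectraMatrix enforces its invariants", {
    expect_error(SpectraMatrix(matrix(1:6, 2, 3), c(4000, 4004, 4008),
                               c("a", "a")),
                 "duplicate sample id")
    expect_error(SpectraMatrix(matrix(1:6, 2, 3), c(4000, 4004, 4010),
                               c("a", "b")),
                 "uniformly spaced")
    expect_error(SpectraMatrix(matrix(1:6, 2, 3), c(4000, 4004, 4002),
                               c("a", "b")),
                 "monotone")
    expect_error(SpectraMatrix(matrix(1:2, 2, 1), 4000, c("a", "b")),
                 "at least 2 wavenumbers")
    m <- matrix(c(1, NA, 3, 4, 5, 6), 2, 3)
    expect_error(SpectraMatrix(m, c(4000, 4004, 4008), c("a", "b")),
                 "missing")
    # descending axes are valid too
    s <- SpectraMatrix(matrix(rnorm(6), 2, 3), c(4008, 4004, 4000),
                       c("a", "b"))
    expect_s4_class(s, "SpectraMatrix")
})

test_that("spectra CSV round-trips bit-exactly", {
    set.seed(11)
    wn <- seq(4000, by = 3.857, length.out = 7)
    a <- matrix(rnorm(21) * 10^sample(-5:3, 21, TRUE), 3, 7)
    s <- SpectraMatrix(a, wn, c("s1", "s2", "s3"))
    f <- tempfile(fileext = ".csv")
    writeSpectraCSV(s, f)
    r <- readSpectraCSV(f)
    expect_identical(absorbance(r), absorbance(s))
    expect_identical(sampleIDs(r), sampleIDs(s))
    expect_equal(wavenumbers(r), wavenumbers(s), tolerance = 1e-3)
    # single sample is a valid file
    f1 <- tempfile(fileext = ".csv")
    writeSpectraCSV(s[1L], f1)
    expect_identical(absorbance(readSpectraCSV(f1)), absorbance(s[1L]))
})

test_that("malformed spectra CSVs fail with named diagnostics", {
    f <- tempfile(fileext = ".csv")
    writeLines(c("sample_id,4000.000,4004.000,4008.000",
                 "a,1,2,3", "a,4,5,6"), f)
    expect_error(readSpectraCSV(f), "duplicate sample id")
    writeLines(c("sample_id,4000.000,4004.000,4018.000",
                 "a,1,2,3"), f)
    expect_error(readSpectraCSV(f), "uniformly spaced")
    writeLines(c("sample_id,4000.000,4004.000,4008.000",
                 "a,1,x,3"), f)
    expect_error(readSpectraCSV(f), "non-numeric cell.*row 1.*4004")
    writeLines(c("id,4000.000,4004.000,4008.000", "a,1,2,3"), f)
    expect_error(readSpectraCSV(f), "sample_id")
    expect_error(readSpectraCSV(tempfile()), "not found")
    expect_error(writeSpectraCSV(
        SpectraMatrix(matrix(numeric(0), 0, 3),
                      c(4000, 4004, 4008), character(0)), f),
        "no samples")
})

test_that("constituent CSV honours the units map and its ranges", {
    units <- c(glucan = "wt%_dry", G.Release = "g_per_g")
    f <- tempfile(fileext = ".csv")
    writeLines(c("sample_id,glucan,G.Release", "s1,33.2,0.24"), f)
    tab <- readConstituentsCSV(f, units)
    expect_equal(constituentValues(tab)[1, "glucan"], 33.2)
    expect_equal(unname(constituentUnits(tab)["G.Release"]), "g_per_g")
    writeLines(c("sample_id,glucan,G.Release", "s1,101,0.24"), f)
    expect_error(readConstituentsCSV(f, units), "glucan.*\\[0, 100\\]")
    writeLines(c("sample_id,glucan,G.Release", "s1,33.2,-0.1"), f)
    expect_error(readConstituentsCSV(f, units), "G.Release.*>= 0")
    writeLines(c("sample_id,glucan,starch", "s1,33.2,1"), f)
    expect_error(readConstituentsCSV(f, units), "unknown constituent 'starch'")
    # round trip
    tab <- ConstituentTable(matrix(c(33.2, 0.24), 1, 2,
                                   dimnames = list("s1", names(units))),
                            units)
    writeConstituentsCSV(tab, f)
    expect_identical(constituentValues(readConstituentsCSV(f, units)),
                     constituentValues(tab))
})

test_that("duplicate scans average arithmetically and idempotently", {
    wn <- c(4000, 4004, 4008)
    s <- SpectraMatrix(rbind(a_rep1 = c(1, 1, 1), a_rep2 = c(3, 3, 3),
                             b_rep1 = c(2, 4, 6)), wn)
    avg <- averageDuplicates(s)
    expect_equal(sampleIDs(avg), c("a", "b"))
    expect_equal(unname(absorbance(avg)["a", ]), c(2, 2, 2))
    # a single replicate passes through unchanged
    expect_equal(unname(absorbance(avg)["b", ]), c(2, 4, 6))
    # symmetry: r and 2m - r average to m for any r
    set.seed(3)
    r <- rnorm(3); m <- rnorm(3)
    s2 <- SpectraMatrix(rbind(x_rep1 = r, x_rep2 = 2 * m - r), wn)
    expect_equal(unname(absorbance(averageDuplicates(s2))[1, ]), m)
    # idempotent once averaged
    expect_equal(absorbance(averageDuplicates(avg)), absorbance(avg))
    # explicit map overrides the suffix convention
    s3 <- SpectraMatrix(rbind(u = c(0, 0, 0), v = c(2, 2, 2)), wn)
    avg3 <- averageDuplicates(s3, replicateMap = c(u = "w", v = "w"))
    expect_equal(unname(absorbance(avg3)[1, ]), c(1, 1, 1))
    expect_error(averageDuplicates(s3, replicateMap = c(u = "w")),
                 "no entry for sample 'v'")
})

test_that("model JSON serialization round-trips predictions bit-exactly", {
    inst <- randomInstance(5, m = 2L)
    fit <- fitPLS(inst$X, inst$Y, nFactors = min(4L, inst$p))
    fit@provenance <- list(snv = TRUE, window = 21L, range = c(4000, 8998))
    f <- tempfile(fileext = ".json")
    saveModel(fit, f)
    back <- loadModel(f)
    Xnew <- matrix(rnorm(3 * inst$p), 3, inst$p)
    expect_identical(predict(back, Xnew), predict(fit, Xnew))
    expect_equal(back@provenance$window, 21L)
    expect_identical(coef(back), coef(fit))
    # truncated file fails loudly
    txt <- readLines(f)
    writeLines(substr(paste(txt, collapse = ""), 1, 50), f)
    expect_error(loadModel(f), "cannot parse|schema")
    # schema mismatch
    jsonlite::write_json(list(schema = "other/2"), f, auto_unbox = TRUE)
    expect_error(loadModel(f), "schema-version mismatch")
})
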