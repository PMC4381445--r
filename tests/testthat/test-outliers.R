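test_that("normalized error is the RMSEC-scaled absolute residual", {
    expect_equal(normalizedError(30.0, 27.28, 1.7), 1.6)
    expect_equal(normalizedError(5, 5, 0.3), 0)
    # scale invariance
    set.seed(8)
    for (i in 1:5) {
        a <- runif(1, 0.1, 10)
        yr <- rnorm(1, 20); yp <- rnorm(1, 20); rm <- runif(1, 0.5, 2)
        expect_equal(normalizedError(a * yr, a * yp, a * rm),
                     normalizedError(yr, yp, rm), tolerance = 1e-12)
    }
    expect_error(normalizedError(1, 2, 0), "positive")
    expect_error(normalizedError(1, 2, -1), "positive")
})

test_that("flagging rules follow the per-mode aggregation and cutoffs", {
    mk <- function(errors) {
        cons <- names(errors)
        data.frame(sample_id = "s1", constituent = cons,
                   y_ref = 0, y_pred = errors, rmsec = 1, error = errors)
    }
    # mean of glucan/xylan/lignin = 1.533 > 1.5
    a <- mk(c(glucan = 2.0, xylan = 1.0, lignin = 1.6, ash = 0.2))
    expect_true(flagOutliers(a, "composition")[["s1"]])
    expect_equal(unname(attr(flagOutliers(a, "composition"), "aggregate")),
                 mean(c(2, 1, 1.6)))
    # ash is screened separately
    expect_false(flagOutliers(a, "ash")[["s1"]])
    expect_true(flagOutliers(mk(c(glucan = 0, xylan = 0, lignin = 0,
                                  ash = 1.6)), "ash")[["s1"]])
    # zero errors never flag
    expect_false(flagOutliers(mk(c(glucan = 0, xylan = 0, lignin = 0)),
                              "composition")[["s1"]])
    # reactivity cutoff is 2.0: 1.9 passes, 2.1 flags
    expect_false(flagOutliers(mk(c(G.Release = 1.9)), "reactivity")[["s1"]])
    expect_true(flagOutliers(mk(c(G.Release = 2.1, X.Release = 0.1)),
                             "reactivity")[["s1"]])
    expect_error(flagOutliers(mk(c(glucan = 1, xylan = 1)), "composition"),
                 "lacks constituent 'lignin'")
})

test_that("the flagged set shrinks monotonically as the cutoff rises", {
    set.seed(13)
    n <- 30
    a <- data.frame(sample_id = rep(sprintf("s%02d", 1:n), 3),
                    constituent = rep(c("glucan", "xylan", "lignin"),
                                      each = n),
                    y_ref = 0, y_pred = 0, rmsec = 1,
                    error = abs(rnorm(3 * n)))
    cuts <- c(0.5, 1.0, 1.5, 2.0)
    counts <- vapply(cuts, function(ct)
        sum(flagOutliers(a, "composition", cutoff = ct)), integer(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("screening flags planted gross reference errors and refits", {
    # calibration-scale n keeps the leverage of any single sample low, so
    # a gross reference error cannot be absorbed by the fit
    sim <- tinyStudy(n = 120, seed = 33)
    pp <- preprocessedStudy(sim)
    # base fit on clean data gives the RMSEC scale for planting
    base <- fitPLS(pp$X, pp$Y, nFactors = 5L, xWeights = "inv_sd")
    rmsec <- sqrt(colMeans((pp$Y - fitted(base))^2))
    bad <- c(3L, 57L, 101L)
    Ybad <- pp$Y
    for (con in c("glucan", "xylan", "lignin"))
        Ybad[bad, con] <- Ybad[bad, con] +
            5 * rmsec[con] * sample(c(-1, 1), 3, TRUE)
    res <- screenAndRefit(pp$X, Ybad, nFactors = 5L, mode = "composition",
                          xWeights = "inv_sd")
    expect_true(all(rownames(pp$Y)[bad] %in% res$removedIDs))
    # unflagged samples are never removed
    flagged <- unique(res$assessments$sample_id[res$assessments$flagged])
    expect_true(all(res$removedIDs %in%
                        c(flagged, rownames(pp$Y)[bad])))
    expect_equal(sort(c(res$removedIDs, res$keptIDs)), sort(rownames(pp$Y)))
})

test_that("a clean calibration set passes through screening unchanged", {
    inst <- randomInstance(44, nMax = 25L, pMax = 6L, m = 3L)
    colnames(inst$Y) <- c("glucan", "xylan", "lignin")
    # huge cutoff: nothing can be flagged
    res <- screenAndRefit(inst$X, inst$Y, nFactors = 3L,
                          mode = "composition", cutoff = 100)
    expect_length(res$removedIDs, 0L)
    expect_identical(coef(res$model), coef(res$baseModel))
    # all-flagged degenerate case aborts
    expect_error(screenAndRefit(inst$X, inst$Y, nFactors = 3L,
                                mode = "composition", cutoff = 1e-12),
                 "every calibration sample")
})

test_that("a second screening round re-applies the rule to the refit", {
    sim <- tinyStudy(n = 30, seed = 61)
    pp <- preprocessedStudy(sim)
    one <- screenAndRefit(pp$X, pp$Y, nFactors = 4L, mode = "composition",
                          xWeights = "inv_sd", maxRounds = 1L)
    two <- screenAndRefit(pp$X, pp$Y, nFactors = 4L, mode = "composition",
                          xWeights = "inv_sd", maxRounds = 2L)
    # round 2 can only remove further samples, starting from round 1's set
    expect_true(all(one$removedIDs %in% two$removedIDs))
    expect_gte(length(two$removedIDs), length(one$removedIDs))
})
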