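# fixtures and independent oracles shared across test files

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small, fast synthetic study: full instrument grid, default noise
# structure, n samples
tinyStudy <- function(n = 40L, seed = 7L, ...) {
    simulateFeedstockStudy(simConfig(nSamples = n, seed = seed, ...))
}

# preprocessed calibration matrices from a study (duplicates averaged,
# SNV + SG derivative + range restriction; no column weighting)
preprocessedStudy <- function(sim) {
    avg <- averageDuplicates(sim$spectra)
    pp <- applyChain(preprocessChain(), avg)
    list(X = absorbance(pp), Y = constituentValues(sim$composition),
         spectra = pp)
}

# random regression instance with full column rank
randomInstance <- function(seed, nMax = 30L, pMax = 10L, m = 1L) {
    set.seed(seed)
    p <- sample(3:pMax, 1L)
    n <- sample((p + 3L):nMax, 1L)
    X <- matrix(rnorm(n * p), n, p)
    B <- matrix(rnorm(p * m), p, m)
    Y <- X %*% B + rnorm(n * m, sd = 0.1)
    rownames(X) <- rownames(Y) <- sprintf("s%02d", seq_len(n))
    list(X = X, Y = Y, n = n, p = p)
}

# independent OLS predictions (QR, with intercept), the rank-complete
# reference PLS must reproduce
olsPredictions <- function(X, Y) {
    Xi <- cbind(1, X)
    Xi %*% qr.solve(Xi, Y)
}

# naive leave-one-out: refit the exported model once per left-out sample
# and per factor count -- the brute-force oracle looCV must match
naiveLooRMSECV <- function(X, Y, maxFactors, ...) {
    n <- nrow(X); m <- ncol(Y)
    factors <- 0:maxFactors
    preds <- array(NA_real_, c(n, m, length(factors)))
    for (i in seq_len(n)) {
        for (k in seq_along(factors)) {
            fit <- suppressWarnings(
                fitPLS(X[-i, , drop = FALSE], Y[-i, , drop = FALSE],
                       factors[k], ...))
            preds[i, , k] <- predict(fit, X[i, , drop = FALSE])
        }
    }
    rmsecv <- t(apply(preds, 3L, function(P) sqrt(colMeans((Y - P)^2))))
    dim(rmsecv) <- c(length(factors), m)
    list(rmsecv = rmsecv, predictions = preds)
}

# exhaustive greedy Kennard-Stone, written independently with explicit
# loops over candidate points
bruteKennardStone <- function(scores, nSelect) {
    n <- nrow(scores)
    d <- function(i, j) sqrt(sum((scores[i, ] - scores[j, ])^2))
    best <- NULL; bestD <- -1
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        dij <- d(i, j)
        if (dij > bestD) { bestD <- dij; best <- c(i, j) }
    }
    sel <- best
    while (length(sel) < nSelect) {
        cand <- setdiff(seq_len(n), sel)
        md <- vapply(cand, function(c)
            min(vapply(sel, function(s) d(c, s), numeric(1))), numeric(1))
        sel <- c(sel, cand[which.max(md)])
    }
    sel
}
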