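#' @include simulate.R
NULL

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Assemble a workflow configuration
#'
#' Two presets mirror the two model families:
#' * `"composition"` -- one PLS-2 model for glucan, xylan, lignin and
#'   ash; spectra weighted 1/SD per wavenumber, constituents not
#'   weighted; factor cap 9; outlier screening with the
#'   mean-of-glucan/xylan/lignin rule (cutoff 1.5) plus the separate ash
#'   screen.
#' * `"reactivity"` -- PLS-2 pairs (G.Release, X.Release) and (G.Yield,
#'   X.Yield) plus PLS-1 models for the sums GX.Release and GX.Yield;
#'   spectra weighted 1/SD, constituents weighted 1/SD in the PLS-2
#'   models; factor caps 11/8/9/8; per-constituent screening at
#'   cutoff 2.0.
#'
#' @param preset `"composition"` or `"reactivity"`
#' @param seed RNG seed for simulation (and the run's provenance)
#' @param nSamples population size when simulating
#' @param nSelect Kennard-Stone calibration subset size
#' @param nPC principal components for the selection scores
#' @param maxFactors named or scalar override of the preset factor caps
#' @param factorTolerance plateau tolerance (percentage points of
#'   cross-validated explained variance) for [selectFactors()]
#' @param outlierCutoff override of the preset screening cutoff
#' @param outlierRounds screening passes (default 1)
#' @param spectraPath,constituentsPath optional CSV inputs; when `NULL`
#'   the study is simulated from `simulation`
#' @param simulation a [simConfig()] object used when simulating
#' @param preprocess a [preprocessChain()] describing the pretreatment
#' @param outDir optional directory for run artifacts (split CSV,
#'   assessments, model JSON, report CSVs, metadata)
#' @return list of class `"WorkflowConfig"`
#' @export
workflowConfig <- function(preset = c("composition", "reactivity"),
                           seed = 1L, nSamples = 279L, nSelect = 245L,
                           nPC = 2L, maxFactors = NULL,
                           factorTolerance = 0.5, outlierCutoff = NULL,
                           outlierRounds = 1L, spectraPath = NULL,
                           constituentsPath = NULL, simulation = NULL,
                           preprocess = preprocessChain(), outDir = NULL) {
    preset <- match.arg(preset)
    if (!is.null(outlierCutoff) && outlierCutoff <= 0)
        stop("outlier cutoff must be positive")
    if (is.null(simulation))
        simulation <- simConfig(nSamples = nSamples, seed = seed)
    structure(list(preset = preset, seed = as.integer(seed),
                   nSamples = as.integer(nSamples),
                   nSelect = as.integer(nSelect), nPC = as.integer(nPC),
                   maxFactors = maxFactors,
                   factorTolerance = factorTolerance,
                   outlierCutoff = outlierCutoff,
                   outlierRounds = as.integer(outlierRounds),
                   spectraPath = spectraPath,
                   constituentsPath = constituentsPath,
                   simulation = simulation, preprocess = preprocess,
                   outDir = outDir),
              class = "WorkflowConfig")
}

#' Read a workflow configuration from YAML
#'
#' Recognized keys mirror the arguments of [workflowConfig()]; the
#' `preprocess` block takes `snv`, `window`, `polyorder`, `deriv` and
#' `range`.
#'
#' @param path YAML file path
#' @return a `"WorkflowConfig"` list
#' @export
readWorkflowConfig <- function(path) {
    y <- yaml::read_yaml(path)
    pp <- y$preprocess %||% list()
    chain <- preprocessChain(
        snv = pp$snv %||% TRUE,
        derivative = pp$derivative %||% TRUE,
        window = pp$window %||% 21L,
        polyorder = pp$polyorder %||% 2L,
        derivOrder = pp$deriv %||% 1L,
        range = unlist(pp$range) %||% c(4000, 8998))
    workflowConfig(preset = y$preset %||% "composition",
                   seed = y$seed %||% 1L,
                   nSamples = y$nSamples %||% 279L,
                   nSelect = y$nSelect %||% 245L,
                   nPC = y$nPC %||% 2L,
                   maxFactors = y$maxFactors,
                   factorTolerance = y$factorTolerance %||% 0.5,
                   outlierCutoff = y$outlierCutoff,
                   outlierRounds = y$outlierRounds %||% 1L,
                   spectraPath = y$spectraPath,
                   constituentsPath = y$constituentsPath,
                   preprocess = chain, outDir = y$outDir)
}

## model plans per preset: response columns, factor cap, weighting, mode
.workflow_plan <- function(config) {
    if (config$preset == "composition") {
        list(composition = list(
            constituents = c("glucan", "xylan", "lignin", "ash"),
            maxFactors = 9L, yWeights = NULL, mode = "composition"))
    } else {
        list(release_pls2 = list(constituents = c("G.Release", "X.Release"),
                                 maxFactors = 11L, yWeights = "inv_sd",
                                 mode = "reactivity"),
             yield_pls2 = list(constituents = c("G.Yield", "X.Yield"),
                               maxFactors = 8L, yWeights = "inv_sd",
                               mode = "reactivity"),
             gx_release_pls1 = list(constituents = "GX.Release",
                                    maxFactors = 9L, yWeights = NULL,
                                    mode = "reactivity"),
             gx_yield_pls1 = list(constituents = "GX.Yield",
                                  maxFactors = 8L, yWeights = NULL,
                                  mode = "reactivity"))
    }
}

.plan_cap <- function(config, name, default) {
    mf <- config$maxFactors
    if (is.null(mf)) return(default)
    if (!is.null(names(mf))) {
        if (name %in% names(mf)) return(as.integer(mf[[name]]))
        return(default)
    }
    as.integer(mf)
}

#' Run the full calibration workflow
#'
#' Executes the study end to end: load or simulate spectra and reference
#' tables; average duplicate scans; preprocess (SNV, Savitzky-Golay
#' first derivative, range restriction); Kennard-Stone select the
#' calibration subset on two PCA score dimensions; screen calibration
#' outliers by normalized prediction error and refit; leave-one-out
#' cross-validate and pick the factor count at the cross-validated
#' explained-variance plateau; and validate externally on the
#' non-selected samples. Deterministic given the configuration seed.
#'
#' @param config a `"WorkflowConfig"` from [workflowConfig()] or
#'   [readWorkflowConfig()], or a path to a YAML config
#' @return list of class `"feedstockReport"`: `calibration` and
#'   `validation` summary data.frames (schemas
#'   Constituent/Samples/Factors/RMSEC/RMSECV/R2/Slope/Intercept and
#'   Constituent/Samples/Factors/RMSEP/R2/Slope/Intercept),
#'   `removedOutliers`, `split`, `models`, `cv`, and `metadata`;
#'   artifacts are written to `config$outDir` when set
#' @export
runCalibrationWorkflow <- function(config) {
    if (is.character(config)) config <- readWorkflowConfig(config)
    stopifnot(inherits(config, "WorkflowConfig"))
    dat <- .stage("load", {
        if (!is.null(config$spectraPath)) {
            spectra <- readSpectraCSV(config$spectraPath)
            units <- if (config$preset == "composition")
                stats::setNames(rep("wt%_dry", 4L),
                                c("glucan", "xylan", "lignin", "ash"))
            else c(G.Release = "g_per_g", X.Release = "g_per_g",
                   GX.Release = "g_per_g", G.Yield = "fraction",
                   X.Yield = "fraction", GX.Yield = "fraction")
            cons <- readConstituentsCSV(config$constituentsPath, units)
            list(spectra = spectra, constituents = cons)
        } else {
            sim <- simulateFeedstockStudy(config$simulation)
            list(spectra = sim$spectra,
                 constituents = if (config$preset == "composition")
                     sim$composition else sim$reactivity)
        }
    })
    averaged <- .stage("average_duplicates", averageDuplicates(dat$spectra))
    pp <- .stage("preprocess", {
        fit <- fitChain(config$preprocess, averaged)
        applyChain(fit$chain, averaged)
    })
    ids <- sampleIDs(pp)
    consIDs <- sampleIDs(dat$constituents)
    if (!setequal(ids, consIDs))
        stop("stage 'align' failed: spectra and constituent tables cover ",
             "different samples")
    split <- .stage("split", {
        scores <- pcaScores(pp, nPC = config$nPC)
        kennardStone(scores, config$nSelect)
    })
    calIDs <- calibrationIDs(split); valIDs <- validationIDs(split)
    plan <- .workflow_plan(config)
    calRows <- list(); valRows <- list(); models <- list(); cvs <- list()
    removed <- list(); assessments <- list()
    for (nm in names(plan)) {
        pl <- plan[[nm]]
        cap <- .plan_cap(config, nm, pl$maxFactors)
        Xcal <- absorbance(pp[calIDs])
        Ycal <- constituentValues(dat$constituents[calIDs, pl$constituents])
        screened <- .stage(paste0("screen_outliers:", nm),
            screenAndRefit(Xcal, Ycal, nFactors = cap, mode = pl$mode,
                           cutoff = config$outlierCutoff,
                           maxRounds = config$outlierRounds,
                           xWeights = "inv_sd", yWeights = pl$yWeights))
        keep <- screened$keptIDs
        cv <- .stage(paste0("crossval:", nm),
            looCV(Xcal[keep, , drop = FALSE],
                  Ycal[keep, , drop = FALSE], maxFactors = cap,
                  xWeights = "inv_sd", yWeights = pl$yWeights))
        nf <- selectFactors(cv, tolerance = config$factorTolerance)
        model <- .stage(paste0("train:", nm),
            fitPLS(Xcal[keep, , drop = FALSE], Ycal[keep, , drop = FALSE],
                   nFactors = nf, xWeights = "inv_sd",
                   yWeights = pl$yWeights))
        model@predictorWavenumbers <- wavenumbers(pp)
        model@provenance <- c(.chain_provenance(config$preprocess),
                              list(model = nm, calibrationIDs = keep))
        loo <- looPredictions(cv, nf)
        fit <- fitted(model)
        for (con in pl$constituents) {
            yv <- Ycal[keep, con]
            sCV <- summaryStats(yv, loo[, con])
            calRows[[length(calRows) + 1L]] <- data.frame(
                Constituent = con, Samples = length(keep), Factors = nf,
                RMSEC = sqrt(mean((yv - fit[, con])^2)),
                RMSECV = sCV$rmse, R2 = sCV$r2, Slope = sCV$slope,
                Intercept = sCV$intercept, Model = nm)
        }
        val <- .stage(paste0("validate:", nm), {
            Xval <- absorbance(pp[valIDs])
            Yval <- constituentValues(dat$constituents[valIDs, pl$constituents])
            validateExternal(model, Xval, Yval, calibrationIDs = keep)
        })
        for (j in seq_len(nrow(val))) {
            valRows[[length(valRows) + 1L]] <- data.frame(
                Constituent = val$constituent[j], Samples = val$n[j],
                Factors = val$factors[j], RMSEP = val$rmsep[j],
                R2 = val$r2[j], Slope = val$slope[j],
                Intercept = val$intercept[j], Model = nm)
        }
        models[[nm]] <- model; cvs[[nm]] <- cv
        removed[[nm]] <- screened$removedIDs
        assessments[[nm]] <- screened$assessments
    }
    report <- structure(list(
        calibration = do.call(rbind, calRows),
        validation = do.call(rbind, valRows),
        removedOutliers = removed,
        assessments = assessments,
        split = split, models = models, cv = cvs,
        metadata = list(preset = config$preset, seed = config$seed,
                        nSamples = length(ids), nSelect = config$nSelect,
                        nPC = config$nPC,
                        package = as.character(utils::packageVersion("feedstockNIR")))),
        class = "feedstockReport")
    if (!is.null(config$outDir))
        .stage("report", writeReport(report, config$outDir))
    report
}

.format_report <- function(df, digitsFor) {
    out <- df
    for (col in names(df)) {
        if (col %in% c("Constituent", "Model", "Samples", "Factors")) next
        out[[col]] <- vapply(seq_len(nrow(df)), function(i)
            formatC(df[[col]][i], format = "f",
                    digits = digitsFor(df$Constituent[i])), character(1))
    }
    out
}

.constituent_digits <- function(con) {
    # composition models print wt% at 2 decimals; g/g and fraction
    # models need 3 to resolve their smaller errors
    if (con %in% c("glucan", "xylan", "lignin", "ash")) 2L else 3L
}

#' Write the run artifacts of a workflow report
#'
#' Emits `calibration_report.csv` and `validation_report.csv` (table
#' schemas as in [runCalibrationWorkflow()]), `split.csv`,
#' `outlier_assessments.csv`, one serialized model JSON per fitted
#' model, and `metadata.json`. All output is deterministic for a given
#' report.
#'
#' @param report a `"feedstockReport"`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
writeReport <- function(report, dir) {
    stopifnot(inherits(report, "feedstockReport"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(.format_report(report$calibration, .constituent_digits),
                     file.path(dir, "calibration_report.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(report$validation) && nrow(report$validation)) {
        utils::write.csv(.format_report(report$validation, .constituent_digits),
                         file.path(dir, "validation_report.csv"),
                         row.names = FALSE, quote = FALSE)
    } else {
        message("validation set empty: validation table omitted")
    }
    writeSplitCSV(report$split, file.path(dir, "split.csv"))
    ass <- do.call(rbind, lapply(names(report$assessments), function(nm) {
        a <- report$assessments[[nm]]
        a$model <- nm
        a
    }))
    utils::write.csv(ass, file.path(dir, "outlier_assessments.csv"),
                     row.names = FALSE, quote = FALSE)
    for (nm in names(report$models))
        saveModel(report$models[[nm]],
                  file.path(dir, paste0("model_", nm, ".json")))
    jsonlite::write_json(report$metadata,
                         file.path(dir, "metadata.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(dir)
}

#' @export
print.feedstockReport <- function(x, ...) {
    cat("Feedstock calibration report (preset:", x$metadata$preset,
        "; seed", x$metadata$seed, ")\n\n")
    cat("Calibration summary:\n")
    print(.format_report(x$calibration, .constituent_digits),
          row.names = FALSE)
    if (!is.null(x$validation) && nrow(x$validation)) {
        cat("\nExternal validation:\n")
        print(.format_report(x$validation, .constituent_digits),
              row.names = FALSE)
    }
    nrem <- sum(lengths(x$removedOutliers))
    cat("\nOutliers removed:", nrem, "\n")
    invisible(x)
}
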