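## End-to-end orchestration: simulate -> resample -> cluster -> fractions
## -> train -> evaluate -> report, from one configuration list (or YAML
## file), with all randomness funneled through one root seed expanded per
## stage. Reruns with the same configuration produce identical artifacts.

#' Default pipeline configuration
#'
#' Returns the configuration list accepted by [runPipeline()]:
#' a 60-patient synthetic cohort at the default grade-conditional
#' parameters, resampling to 1 x 1 x 3 mm, habitat clustering on training
#' voxels with k fixed at 4 (set `cluster$k` to `NULL` for elbow
#' selection over `cluster$kRange`), univariate screen at 0.1, backward-LR
#' stepwise at 0.10, and a stratified 7:3 split.
#'
#' @param seed Root seed; per-stage seeds are derived from it.
#' @return Named list of stage settings.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
    list(
        seed = as.integer(seed),
        cohort = list(nPatients = 60L),
        resample = list(targetSpacing = c(1, 1, 3)),
        cluster = list(k = 4L, kRange = 2:8, nInit = 10,
                       scope = "train_only"),
        split = list(ratio = 0.7),
        screen = list(alphaKeep = 0.1),
        stepwise = list(pRemove = 0.10),
        evaluate = list(nGroups = 10,
                        thresholds = seq(0.01, 0.60, by = 0.01))
    )
}

stageSeed <- function(root, offset) as.integer((root + offset) %% .Machine$integer.max)

mergeConfig <- function(base, override) {
    for (nm in names(override)) {
        if (is.list(base[[nm]]) && is.list(override[[nm]])) {
            base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
        } else {
            base[[nm]] <- override[[nm]]
        }
    }
    base
}

#' Run the full habitat-grading pipeline
#'
#' Executes the study workflow on a synthetic cohort: cohort generation,
#' resampling to the analysis grid, voxel-matrix extraction, stratified
#' train/validation split, pooled habitat clustering (training voxels by
#' default), per-patient volume fractions, univariate screening plus
#' backward-LR stepwise logistic selection, nomogram construction, and
#' evaluation (AUC with DeLong CI, Hosmer-Lemeshow, decision curve) on both
#' partitions. All artifacts are written under `outDir` as CSV/JSON plus a
#' markdown report.
#'
#' @param config Configuration list (see [defaultPipelineConfig()]), or a
#'   path to a YAML file with the same structure; partial lists are merged
#'   over the defaults.
#' @param outDir Output directory (created; default a fresh directory under
#'   `tempdir()`).
#' @return Invisibly, a list with the run artifacts (`cohort`, `model`,
#'   `fractions`, `screen`, `fit`, `nomogram`, `evaluation`, `outDir`).
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir = NULL) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    config <- mergeConfig(defaultPipelineConfig(), config)
    if (is.null(outDir)) {
        outDir <- file.path(tempdir(),
                            paste0("habitatCT-run-",
                                   format(Sys.time(), "%Y%m%d-%H%M%S")))
    }
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    logFile <- file.path(outDir, "log.txt")
    logLines <- character()
    say <- function(...) {
        msg <- paste0(...)
        logLines <<- c(logLines, msg)
        message(msg)
    }
    root <- as.integer(config$seed)
    yaml::write_yaml(config, file.path(outDir, "config.yaml"))

    ## stage 1: synthetic cohort
    say("[cohort] generating ", config$cohort$nPatients, " patients")
    csArgs <- config$cohort
    csArgs$seed <- stageSeed(root, 101L)
    spec <- do.call(cohortSpec, csArgs)
    cohort <- generateCohort(spec, volumes = TRUE)
    tab <- cohort$table

    ## stage 2: resample to the analysis grid
    target <- config$resample$targetSpacing
    say("[resample] target spacing ", paste(target, collapse = " x "), " mm")
    stacks <- lapply(cohort$patients, function(p) {
        resampleStack(p$stack, targetSpacing = target)
    })

    ## stage 3: voxel matrices
    matrices <- lapply(seq_along(stacks), function(i) {
        extractVoxelMatrix(stacks[[i]], patientId = tab$patientId[i])
    })
    names(matrices) <- tab$patientId

    ## stage 4: split
    split <- stratifiedSplit(tab$grade, ratio = config$split$ratio,
                             seed = stageSeed(root, 202L))
    say("[split] ", length(split$train), " training / ",
        length(split$test), " validation patients")

    ## stage 5: habitat model
    fitRes <- fitCohortHabitats(
        matrices, k = config$cluster$k, kRange = config$cluster$kRange,
        scope = config$cluster$scope, trainIdx = split$train,
        nInit = config$cluster$nInit, seed = stageSeed(root, 303L)
    )
    say("[cluster] k = ", fitRes$model@k, " habitats, SSE = ",
        format(fitRes$model@sse))
    writeHabitatModel(fitRes$model, file.path(outDir, "habitat_model.json"))
    if (!is.null(fitRes$sseCurve)) {
        write.csv(fitRes$sseCurve, file.path(outDir, "sse_curve.csv"),
                  row.names = FALSE)
    }

    ## stage 6: fractions
    fractions <- cohortFractions(fitRes$model, matrices)
    tab <- merge(tab, fractions, by = "patientId", sort = FALSE)
    write.csv(tab, file.path(outDir, "cohort.csv"), row.names = FALSE)

    ## stage 7: screen + stepwise on the training partition
    fracCols <- setdiff(grep("^F[0-9]+$", names(tab), value = TRUE),
                        paste0("F", fitRes$model@k))
    candidates <- c("sex", "diameterMm", fracCols)
    train <- tab[split$train, , drop = FALSE]
    test <- tab[split$test, , drop = FALSE]
    screen <- univariateScreen(train, "grade", candidates,
                               alphaKeep = config$screen$alphaKeep)
    write.csv(screen, file.path(outDir, "screen.csv"), row.names = FALSE)
    kept <- screen$variable[screen$retained & is.na(screen$error)]
    say("[screen] retained: ", paste(kept, collapse = ", "))
    fit <- if (length(kept)) {
        stepwiseBackward(train, "grade", kept,
                         pRemove = config$stepwise$pRemove)
    } else {
        fitLogistic(train, "grade")
    }
    say("[stepwise] final model: ",
        if (length(fit@variables)) paste(fit@variables, collapse = ", ")
        else "(intercept only)")
    writeLogisticFit(fit, file.path(outDir, "fit.json"))

    ## stage 8: nomogram
    nomogram <- NULL
    if (length(fit@variables)) {
        nomogram <- buildNomogram(fit)
        writeNomogram(nomogram, file.path(outDir, "nomogram.json"))
    }

    ## stage 9: evaluation on both partitions
    evalOne <- function(d) {
        pr <- predictLogistic(fit, d)
        roc <- rocAuc(pr, d$grade)
        hl <- tryCatch(
            hosmerLemeshow(pmin(pmax(pr, 1e-12), 1 - 1e-12), d$grade,
                           nGroups = config$evaluate$nGroups),
            error = function(e) list(chi2 = NA, df = NA, p = NA)
        )
        dca <- decisionCurve(pr, d$grade,
                             thresholds = config$evaluate$thresholds)
        list(auc = roc$auc, aucCI = roc$ci, hlChi2 = hl$chi2, hlDf = hl$df,
             hlP = hl$p, dca = dca)
    }
    evaluation <- list(train = evalOne(train), validation = evalOne(test))
    say("[evaluate] training AUC = ", round(evaluation$train$auc, 3),
        ", validation AUC = ", round(evaluation$validation$auc, 3))
    evalJson <- lapply(evaluation, function(e) {
        e$dca <- NULL
        e
    })
    jsonlite::write_json(evalJson, file.path(outDir, "evaluation.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    write.csv(evaluation$train$dca, file.path(outDir, "dca_train.csv"),
              row.names = FALSE)
    write.csv(evaluation$validation$dca,
              file.path(outDir, "dca_validation.csv"), row.names = FALSE)

    ## habitat summary table (pooled over the clustering scope)
    pooledVals <- do.call(rbind, lapply(matrices[names(fitRes$assignments)],
                                        voxelValues))
    habSummary <- summarizeHabitats(pooledVals,
                                    unlist(fitRes$assignments,
                                           use.names = FALSE),
                                    k = fitRes$model@k)
    write.csv(habSummary, file.path(outDir, "habitat_summary.csv"),
              row.names = FALSE)

    writeLines(logLines, logFile)
    res <- list(cohort = tab, split = split, model = fitRes$model,
                sseCurve = fitRes$sseCurve, fractions = fractions,
                screen = screen, fit = fit, nomogram = nomogram,
                evaluation = evaluation, habitatSummary = habSummary,
                outDir = outDir)
    pipelineReport(outDir, res)
    invisible(res)
}

#' Write a human-readable run report
#'
#' Summarizes a completed [runPipeline()] run directory as markdown:
#' habitat characteristics (mean +/- SD HU per phase), the screening and
#' selection tables, and the evaluation summary. Every number is re-read
#' from the run artifacts; missing artifacts are listed as absent.
#'
#' @param runDir The run directory.
#' @param artifacts Optional in-memory artifact list (as returned by
#'   [runPipeline()]); if `NULL`, everything is read from `runDir`.
#' @return The report path, invisibly.
#' @export
pipelineReport <- function(runDir, artifacts = NULL) {
    lines <- c("# Habitat-grading pipeline report", "")
    absent <- function(f) !file.exists(file.path(runDir, f))

    if (!absent("habitat_summary.csv")) {
        hs <- read.csv(file.path(runDir, "habitat_summary.csv"))
        lines <- c(lines, "## Habitat characteristics (HU, mean ± SD)", "")
        for (h in sort(unique(hs$habitat))) {
            row <- hs[hs$habitat == h, ]
            cells <- sprintf("%s = %.3f ± %.3f", row$phase, row$mean,
                             row$sd)
            lines <- c(lines, sprintf("- Habitat %d: %s (n = %d voxels)", h,
                                      paste(cells, collapse = ", "),
                                      row$n[1]))
        }
        lines <- c(lines, "")
    } else {
        lines <- c(lines, "- habitat_summary.csv: absent", "")
    }

    if (!absent("screen.csv")) {
        sc <- read.csv(file.path(runDir, "screen.csv"))
        lines <- c(lines, "## Univariate screen", "",
                   "| variable | OR | 95% CI | P | retained |",
                   "|---|---|---|---|---|",
                   sprintf("| %s | %.3f | %.3f-%.3f | %.4g | %s |",
                           sc$variable, sc$OR, sc$ciLow, sc$ciHigh, sc$p,
                           ifelse(sc$retained, "yes", "no")), "")
    } else {
        lines <- c(lines, "- screen.csv: absent", "")
    }

    if (!absent("fit.json")) {
        fit <- readLogisticFit(file.path(runDir, "fit.json"))
        if (length(fit@variables) == 0L) {
            lines <- c(lines, "## Final model", "",
                       "No predictors retained (intercept-only model).", "")
        } else {
            or <- oddsRatios(fit)
            lines <- c(lines, "## Final multivariate model", "",
                       "| variable | OR | 95% CI | P |", "|---|---|---|---|",
                       sprintf("| %s | %.3f | %.3f-%.3f | %.4g |",
                               or$variable, or$OR, or$ciLow, or$ciHigh,
                               or$p), "")
        }
    } else {
        lines <- c(lines, "- fit.json: absent", "")
    }

    if (!absent("evaluation.json")) {
        ev <- jsonlite::read_json(file.path(runDir, "evaluation.json"),
                                  simplifyVector = TRUE)
        lines <- c(lines, "## Evaluation", "",
                   "| set | AUC (95% CI) | HL chi2 (df) | HL P |",
                   "|---|---|---|---|")
        for (nm in names(ev)) {
            e <- ev[[nm]]
            lines <- c(lines, sprintf(
                "| %s | %.3f (%.3f-%.3f) | %.3f (%d) | %.3f |", nm, e$auc,
                e$aucCI[1], e$aucCI[2], e$hlChi2, e$hlDf, e$hlP))
        }
        lines <- c(lines, "")
    } else {
        lines <- c(lines, "- evaluation.json: absent", "")
    }

    path <- file.path(runDir, "report.md")
    writeLines(lines, path)
    invisible(path)
}
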