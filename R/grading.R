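## Grade modeling: univariate screening, stepwise backward multivariate
## logistic regression (likelihood-ratio removal), odds ratios and a
## points-based nomogram. Maximum-likelihood fitting is delegated to
## stats::glm (IRLS with observed-information covariance); this module adds
## separation detection, the selection procedure and the nomogram algebra.

#' Fit a binary logistic regression
#'
#' Maximum-likelihood logistic fit of `outcome ~ predictors` by iteratively
#' reweighted least squares (convergence when the deviance change is below
#' 1e-12, at most 100 iterations), with Wald standard errors from the
#' observed information. Complete or quasi-complete separation (fitted
#' probabilities numerically 0/1) is detected and flagged rather than
#' treated as an error.
#'
#' @param data data.frame holding outcome and predictors.
#' @param outcome Name of the binary (0/1) outcome column.
#' @param predictors Character vector of predictor column names; empty for
#'   an intercept-only model.
#' @return A [LogisticFit-class].
#' @examples
#' d <- data.frame(y = rbinom(100, 1, 0.5), x = rnorm(100))
#' fitLogistic(d, "y", "x")
#' @export
fitLogistic <- function(data, outcome, predictors = character()) {
    y <- data[[outcome]]
    if (is.null(y)) stop("outcome column '", outcome, "' not found")
    if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
    for (p in predictors) {
        v <- data[[p]]
        if (is.null(v)) stop("predictor column '", p, "' not found")
        if (length(unique(v)) < 2L) {
            stop("collinearity error: predictor '", p, "' has zero variance")
        }
    }
    rhs <- if (length(predictors)) {
        paste(sprintf("`%s`", predictors), collapse = " + ")
    } else "1"
    form <- as.formula(paste(sprintf("`%s`", outcome), "~", rhs))
    separation <- FALSE
    fit <- withCallingHandlers(
        glm(form, family = binomial(), data = data,
            control = list(epsilon = 1e-12, maxit = 100)),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1",
                      conditionMessage(w))) {
                separation <<- TRUE
                invokeRestart("muffleWarning")
            }
        }
    )
    if (any(is.na(coef(fit)))) {
        stop("collinearity error: singular design matrix")
    }
    if (separation) {
        warning("separation detected: coefficient estimates diverge")
    }
    cf <- coef(fit)
    vn <- names(cf)[-1]
    # strip backtick quoting from term labels
    vn <- gsub("`", "", vn)
    names(cf) <- gsub("`", "", names(cf))
    vc <- vcov(fit)
    dimnames(vc) <- list(names(cf), names(cf))
    new("LogisticFit", variables = vn, coefficients = cf, vcov = vc,
        logLik = as.numeric(logLik(fit)), nObs = length(y),
        converged = fit$converged, separation = separation,
        selection = list(), glmFit = fit)
}

#' Predicted probabilities from a logistic fit
#'
#' @param fit A [LogisticFit-class].
#' @param newdata data.frame with the fit's predictor columns.
#' @return Numeric vector of probabilities.
#' @export
predictLogistic <- function(fit, newdata) {
    stopifnot(is(fit, "LogisticFit"))
    lp <- rep(fit@coefficients[["(Intercept)"]], nrow(newdata))
    for (v in fit@variables) lp <- lp + fit@coefficients[[v]] * newdata[[v]]
    plogis(lp)
}

#' Univariate logistic screen
#'
#' Fits one single-predictor logistic regression per candidate and retains
#' predictors whose Wald P-value is below `alphaKeep` (default 0.1, the
#' conventional lenient screen before multivariate modeling). Fit failures
#' are recorded per variable without aborting the screen; separation-flagged
#' perfect predictors are retained.
#'
#' @param data data.frame.
#' @param outcome Binary outcome column name.
#' @param candidates Character vector of candidate predictor names.
#' @param alphaKeep Retention threshold on the Wald P-value.
#' @return data.frame with columns `variable`, `OR`, `ciLow`, `ciHigh`,
#'   `p`, `separation`, `error`, `retained`.
#' @export
univariateScreen <- function(data, outcome, candidates, alphaKeep = 0.1) {
    stopifnot(alphaKeep > 0, alphaKeep < 1)
    rows <- lapply(candidates, function(v) {
        res <- tryCatch(
            withCallingHandlers(
                fitLogistic(data, outcome, v),
                warning = function(w) invokeRestart("muffleWarning")
            ),
            error = function(e) e
        )
        if (inherits(res, "error")) {
            return(data.frame(variable = v, OR = NA_real_, ciLow = NA_real_,
                              ciHigh = NA_real_, p = NA_real_,
                              separation = NA, error = conditionMessage(res),
                              retained = FALSE, stringsAsFactors = FALSE))
        }
        b <- res@coefficients[[v]]
        se <- sqrt(res@vcov[v, v])
        p <- 2 * pnorm(-abs(b / se))
        keep <- isTRUE(p < alphaKeep) || res@separation
        data.frame(variable = v, OR = exp(b), ciLow = exp(b - 1.96 * se),
                   ciHigh = exp(b + 1.96 * se), p = p,
                   separation = res@separation, error = NA_character_,
                   retained = keep, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Stepwise backward logistic selection by likelihood-ratio tests
#'
#' Starting from the model with all supplied predictors, repeatedly refits
#' and removes the predictor with the largest likelihood-ratio-test P-value
#' at or above `pRemove` (default 0.10, the Backward:LR convention) until
#' every remaining predictor tests below the threshold. The removal order is
#' recorded in the fit's `selection` slot. If everything is removed the
#' intercept-only fit is returned with a warning.
#'
#' @param data data.frame.
#' @param outcome Binary outcome column name.
#' @param candidates Predictors entering the full model (typically the
#'   screen's retained set).
#' @param pRemove Removal threshold for the LRT P-value.
#' @return A [LogisticFit-class]; `@selection$removed` lists dropped
#'   variables in order, `@selection$path` the per-round LRT tables.
#' @export
stepwiseBackward <- function(data, outcome, candidates, pRemove = 0.10) {
    current <- candidates
    removed <- character()
    path <- list()
    repeat {
        fit <- fitLogistic(data, outcome, current)
        if (length(current) == 0L) break
        lrt <- suppressWarnings(drop1(fit@glmFit, test = "LRT"))
        p <- lrt[["Pr(>Chi)"]][-1]
        names(p) <- gsub("`", "", rownames(lrt)[-1])
        path[[length(path) + 1L]] <- data.frame(
            round = length(path) + 1L, variable = names(p), lrtP = unname(p),
            stringsAsFactors = FALSE
        )
        worst <- which.max(p)
        if (p[worst] >= pRemove) {
            removed <- c(removed, names(p)[worst])
            current <- setdiff(current, names(p)[worst])
        } else {
            break
        }
    }
    if (length(current) == 0L && length(candidates) > 0L) {
        warning("all variables removed; returning intercept-only fit")
    }
    fit@selection <- list(removed = removed,
                          path = do.call(rbind, path))
    fit
}

#' Odds-ratio table of a logistic fit
#'
#' `OR = exp(beta)` with Wald 95% confidence intervals
#' `exp(beta +/- 1.96 SE)` and Wald P-values, per predictor.
#'
#' @param fit A [LogisticFit-class].
#' @return data.frame with columns `variable`, `beta`, `se`, `OR`, `ciLow`,
#'   `ciHigh`, `p`.
#' @export
oddsRatios <- function(fit) {
    stopifnot(is(fit, "LogisticFit"))
    vars <- fit@variables
    idx <- match(vars, names(fit@coefficients))
    b <- fit@coefficients[idx]
    se <- sqrt(diag(fit@vcov))[idx]
    data.frame(variable = vars, beta = unname(b), se = unname(se),
               OR = unname(exp(b)), ciLow = unname(exp(b - 1.96 * se)),
               ciHigh = unname(exp(b + 1.96 * se)),
               p = unname(2 * pnorm(-abs(b / se))),
               stringsAsFactors = FALSE)
}

#' Build a points-based nomogram from a logistic fit
#'
#' Each predictor's contribution `beta_j * x` over its observed range is
#' rescaled so the predictor with the largest `|beta_j| * range_j` spans
#' exactly 0-100 points; the reference value (0 points) is the range end
#' with the smallest contribution, so points are nonnegative over the range.
#' The points total maps back to a probability through the reconstructed
#' linear predictor, making [nomogramPredict()] numerically identical to
#' the source fit.
#'
#' @param fit A converged [LogisticFit-class] with at least one predictor.
#' @param ranges Named list (or 2-row data.frame) giving `c(lo, hi)` per
#'   predictor; defaults to the observed range in the fitting data.
#' @return A [Nomogram-class].
#' @export
buildNomogram <- function(fit, ranges = NULL) {
    stopifnot(is(fit, "LogisticFit"))
    vars <- fit@variables
    if (length(vars) == 0L) stop("nomogram needs at least one predictor")
    if (is.null(ranges)) {
        mf <- fit@glmFit$model
        ranges <- lapply(vars, function(v) range(mf[[sprintf("`%s`", v)]] %||%
                                                 mf[[v]]))
        names(ranges) <- vars
    }
    lo <- vapply(vars, function(v) ranges[[v]][1], 0)
    hi <- vapply(vars, function(v) ranges[[v]][2], 0)
    if (!all(is.finite(c(lo, hi)))) stop("predictor ranges must be finite")
    beta <- fit@coefficients[vars]
    span <- abs(beta) * (hi - lo)
    M <- max(span)
    if (M <= 0) stop("all predictor contributions are zero over the ranges")
    ref <- ifelse(beta >= 0, lo, hi)
    pointsPerUnit <- 100 * beta / M
    new("Nomogram", variables = vars, beta = unname(beta), ref = unname(ref),
        lo = unname(lo), hi = unname(hi),
        pointsPerUnit = unname(pointsPerUnit), scalePerPoint = M / 100,
        intercept = fit@coefficients[["(Intercept)"]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score covariates through a nomogram
#'
#' Computes per-predictor points, the points total, and the predicted
#' probability via the reconstructed linear predictor. Covariates outside
#' the nomogram's stated ranges are scored by extrapolation with a warning.
#'
#' @param nomogram A [Nomogram-class].
#' @param newdata data.frame with the nomogram's predictor columns.
#' @return data.frame with one row per observation: per-predictor points
#'   columns (`points.<var>`), `totalPoints`, `probability`.
#' @export
nomogramPredict <- function(nomogram, newdata) {
    stopifnot(is(nomogram, "Nomogram"))
    vars <- nomogram@variables
    pts <- vapply(seq_along(vars), function(j) {
        x <- newdata[[vars[j]]]
        if (is.null(x)) stop("missing covariate: ", vars[j])
        if (any(x < nomogram@lo[j] - 1e-12 | x > nomogram@hi[j] + 1e-12)) {
            warning("covariate '", vars[j],
                    "' outside the nomogram range; extrapolating")
        }
        nomogram@pointsPerUnit[j] * (x - nomogram@ref[j])
    }, numeric(nrow(newdata)))
    pts <- matrix(pts, nrow = nrow(newdata))
    total <- rowSums(pts)
    lp <- nomogram@intercept + sum(nomogram@beta * nomogram@ref) +
        nomogram@scalePerPoint * total
    out <- data.frame(pts, totalPoints = total, probability = plogis(lp))
    names(out)[seq_along(vars)] <- paste0("points.", vars)
    out
}

#' Persist and restore logistic fits and nomograms
#'
#' JSON serialization of the model pieces needed for prediction (the
#' embedded `glm` object is not serialized; a restored fit supports
#' [predictLogistic()], [oddsRatios()] and [buildNomogram()] with explicit
#' ranges, but not further stepwise selection).
#'
#' @param fit A [LogisticFit-class]; `nomogram` a [Nomogram-class].
#' @param path JSON file path.
#' @return Writers return the path invisibly; readers the restored object.
#' @export
writeLogisticFit <- function(fit, path) {
    stopifnot(is(fit, "LogisticFit"))
    obj <- list(variables = fit@variables,
                coefficients = as.list(fit@coefficients),
                vcov = fit@vcov, logLik = fit@logLik, nObs = fit@nObs,
                converged = fit@converged, separation = fit@separation,
                removed = fit@selection$removed)
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeLogisticFit
#' @export
readLogisticFit <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    cf <- unlist(obj$coefficients)
    vc <- matrix(as.numeric(unlist(obj$vcov)), nrow = length(cf),
                 dimnames = list(names(cf), names(cf)))
    new("LogisticFit", variables = as.character(obj$variables),
        coefficients = cf, vcov = vc, logLik = as.numeric(obj$logLik),
        nObs = as.integer(obj$nObs), converged = isTRUE(obj$converged),
        separation = isTRUE(obj$separation),
        selection = list(removed = obj$removed), glmFit = NULL)
}

#' @rdname writeLogisticFit
#' @param nomogram A [Nomogram-class].
#' @export
writeNomogram <- function(nomogram, path) {
    stopifnot(is(nomogram, "Nomogram"))
    obj <- list(variables = nomogram@variables, beta = nomogram@beta,
                ref = nomogram@ref, lo = nomogram@lo, hi = nomogram@hi,
                pointsPerUnit = nomogram@pointsPerUnit,
                scalePerPoint = nomogram@scalePerPoint,
                intercept = nomogram@intercept)
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeLogisticFit
#' @export
readNomogram <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("Nomogram", variables = as.character(obj$variables),
        beta = as.numeric(obj$beta), ref = as.numeric(obj$ref),
        lo = as.numeric(obj$lo), hi = as.numeric(obj$hi),
        pointsPerUnit = as.numeric(obj$pointsPerUnit),
        scalePerPoint = as.numeric(obj$scalePerPoint),
        intercept = as.numeric(obj$intercept))
}
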