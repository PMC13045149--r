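## Model evaluation: ROC/AUC with DeLong variance and paired test,
## Hosmer-Lemeshow calibration, decision-curve analysis, ICC(2,1)
## reproducibility, habitat-fraction subgroup comparison, and the
## stratified train/validation split.

## DeLong structural components: for each positive, the mean of the
## Mann-Whitney kernel over all negatives (V10), and vice versa (V01).
delongComponents <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    m <- length(pos); n <- length(neg)
    if (m == 0L || n == 0L) stop("both classes must be present")
    psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi),
         m = m, n = n)
}

#' ROC curve and AUC with DeLong variance
#'
#' The AUC is the Mann-Whitney estimate: the mean over all
#' (positive, negative) pairs of the indicator that the positive scores
#' higher, ties counted 1/2. Its variance comes from the DeLong structural
#' components, and the 95% CI is `auc +/- 1.96 * sqrt(var)`, clipped to
#' `[0, 1]`.
#'
#' @param scores Numeric risk scores (higher = more likely positive).
#' @param labels Binary 0/1 outcome labels.
#' @return List with `auc`, `var`, `ci` (length 2), and `curve`
#'   (data.frame `threshold`, `fpr`, `tpr` over the score thresholds).
#' @examples
#' rocAuc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))$auc
#' @export
rocAuc <- function(scores, labels) {
    stopifnot(length(scores) == length(labels))
    if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
    if (length(unique(labels)) < 2L) {
        stop("single-class labels: AUC undefined")
    }
    comp <- delongComponents(scores, labels)
    v <- 0
    if (comp$m > 1) v <- v + var(comp$v10) / comp$m
    if (comp$n > 1) v <- v + var(comp$v01) / comp$n
    ci <- comp$auc + c(-1, 1) * 1.96 * sqrt(v)
    ci <- pmin(pmax(ci, 0), 1)
    thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
    curve <- data.frame(
        threshold = thr,
        fpr = vapply(thr, function(t) mean(scores[labels == 0] >= t), 0),
        tpr = vapply(thr, function(t) mean(scores[labels == 1] >= t), 0)
    )
    list(auc = comp$auc, var = v, ci = ci, curve = curve)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors on the same subjects via the
#' DeLong structural-component covariance; returns the two AUCs, their
#' covariance matrix, the z statistic and the two-sided normal P-value.
#' A model compared with itself (zero variance of the difference) returns
#' `z = 0`, `p = 1` with a warning.
#'
#' @param scoresA,scoresB Paired score vectors on identical subjects.
#' @param labels Binary 0/1 outcome labels.
#' @return List with `aucA`, `aucB`, `S` (2x2 covariance of the AUCs),
#'   `z`, `p`.
#' @export
delongTest <- function(scoresA, scoresB, labels) {
    if (length(scoresA) != length(scoresB) ||
        length(scoresA) != length(labels)) {
        stop("length mismatch between scores and labels")
    }
    ca <- delongComponents(scoresA, labels)
    cb <- delongComponents(scoresB, labels)
    m <- ca$m; n <- ca$n
    s10 <- cov(cbind(ca$v10, cb$v10))
    s01 <- cov(cbind(ca$v01, cb$v01))
    S <- s10 / m + s01 / n
    vd <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
    if (vd <= .Machine$double.eps) {
        warning("zero variance of the AUC difference; p set to 1")
        return(list(aucA = ca$auc, aucB = cb$auc, S = S, z = 0, p = 1))
    }
    z <- (ca$auc - cb$auc) / sqrt(vd)
    list(aucA = ca$auc, aucB = cb$auc, S = S, z = z,
         p = 2 * pnorm(-abs(z)))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Subjects are ranked by predicted probability into `nGroups` near-equal
#' bins (tied probabilities stay in one bin); the statistic sums
#' `(O - E)^2 / E` over both outcome cells of every bin, with
#' `df = nGroups - 2` (the fitted-model convention) and an upper-tail
#' chi-square P-value. Bins whose expected count is 0 in either cell are
#' merged with their neighbor (recorded in the output).
#'
#' @param probs Predicted probabilities in (0, 1).
#' @param outcomes Binary 0/1 outcomes.
#' @param nGroups Number of risk bins (default 10, minimum 3).
#' @return List with `chi2`, `df`, `p`, `bins` (data.frame `n`, `observed`,
#'   `expected`, `meanProb`), and `merged` (number of merges applied).
#' @export
hosmerLemeshow <- function(probs, outcomes, nGroups = 10) {
    stopifnot(length(probs) == length(outcomes), nGroups >= 3)
    if (any(probs <= 0 | probs >= 1)) stop("probs must lie in (0, 1)")
    if (!all(outcomes %in% c(0, 1))) stop("outcomes must be 0/1")
    n <- length(probs)
    ord <- order(probs)
    p <- probs[ord]; y <- outcomes[ord]
    # quantile-rank bins with ties kept together
    grp <- ceiling(seq_len(n) * nGroups / n)
    for (i in 2:n) if (p[i] == p[i - 1]) grp[i] <- grp[i - 1]
    grp <- match(grp, unique(grp))
    bins <- data.frame(
        n = as.vector(tapply(y, grp, length)),
        observed = as.vector(tapply(y, grp, sum)),
        expected = as.vector(tapply(p, grp, sum)),
        meanProb = as.vector(tapply(p, grp, mean))
    )
    merged <- 0L
    repeat {
        bad <- which(bins$expected <= 0 | (bins$n - bins$expected) <= 0)
        if (length(bad) == 0L || nrow(bins) <= 2L) break
        i <- bad[1]
        j <- if (i == 1L) 2L else i - 1L
        bins$n[j] <- bins$n[j] + bins$n[i]
        bins$observed[j] <- bins$observed[j] + bins$observed[i]
        bins$expected[j] <- bins$expected[j] + bins$expected[i]
        bins$meanProb[j] <- bins$expected[j] / bins$n[j]
        bins <- bins[-i, , drop = FALSE]
        merged <- merged + 1L
    }
    chi2 <- sum((bins$observed - bins$expected)^2 / bins$expected +
                ((bins$n - bins$observed) - (bins$n - bins$expected))^2 /
                    (bins$n - bins$expected))
    df <- nrow(bins) - 2L
    list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
         bins = bins, merged = merged)
}

#' Decision-curve analysis
#'
#' Net benefit of treating at probability threshold `t`:
#' `NB(t) = TP/n - FP/n * t/(1-t)`, treating every subject with predicted
#' probability `>= t`. The treat-all curve is
#' `prevalence - (1 - prevalence) * t/(1-t)`; treat-none is identically 0.
#'
#' @param probs Predicted probabilities.
#' @param outcomes Binary 0/1 outcomes.
#' @param thresholds Threshold grid strictly inside (0, 1); default
#'   0.01-0.60 in steps of 0.01.
#' @return data.frame with columns `threshold`, `netBenefit`, `treatAll`,
#'   `treatNone`.
#' @export
decisionCurve <- function(probs, outcomes,
                          thresholds = seq(0.01, 0.60, by = 0.01)) {
    stopifnot(length(probs) == length(outcomes))
    if (any(thresholds <= 0 | thresholds >= 1)) {
        stop("thresholds must lie strictly inside (0, 1)")
    }
    n <- length(probs)
    prev <- mean(outcomes)
    nb <- vapply(thresholds, function(t) {
        treat <- probs >= t
        tp <- sum(treat & outcomes == 1)
        fp <- sum(treat & outcomes == 0)
        tp / n - fp / n * t / (1 - t)
    }, 0)
    data.frame(threshold = thresholds, netBenefit = nb,
               treatAll = prev - (1 - prev) * thresholds / (1 - thresholds),
               treatNone = 0)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation from the ANOVA mean squares:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` for `n`
#' subjects and `k` raters. Agreement is flagged "good" at ICC >= 0.85.
#'
#' @param ratings Numeric matrix, subjects x raters, complete.
#' @return List with `icc`, `msr`, `msc`, `mse`, `n`, `k`,
#'   `goodAgreement`.
#' @export
iccAgreement <- function(ratings) {
    ratings <- as.matrix(ratings)
    n <- nrow(ratings); k <- ncol(ratings)
    if (k < 2L) stop("need at least 2 raters")
    if (n < 3L) stop("need at least 3 subjects")
    if (any(!is.finite(ratings))) stop("ratings must be complete")
    rowM <- rowMeans(ratings); colM <- colMeans(ratings)
    grand <- mean(ratings)
    msr <- k * sum((rowM - grand)^2) / (n - 1)
    msc <- n * sum((colM - grand)^2) / (k - 1)
    sse <- sum((ratings - outer(rowM, rep(1, k)) -
                outer(rep(1, n), colM) + grand)^2)
    mse <- sse / ((n - 1) * (k - 1))
    if (msr <= .Machine$double.eps) {
        stop("zero between-subject variance: ICC undefined")
    }
    icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    list(icc = icc, msr = msr, msc = msc, mse = mse, n = n, k = k,
         goodAgreement = icc >= 0.85)
}

#' Compare habitat fractions between grades
#'
#' Per habitat-fraction column, a single-predictor logistic regression of
#' the outcome on the fraction (odds ratio, Wald CI and P), together with
#' the per-grade mean +/- SD of the fraction.
#'
#' @param data data.frame holding outcome and fraction columns.
#' @param outcome Binary 0/1 outcome column name (1 = high grade).
#' @param fractionCols Fraction column names; defaults to every column
#'   matching `^F[0-9]+$`.
#' @return data.frame with one row per fraction: group means/SDs, OR, CI,
#'   P.
#' @export
compareFractions <- function(data, outcome = "grade", fractionCols = NULL) {
    if (is.null(fractionCols)) {
        fractionCols <- grep("^F[0-9]+$", names(data), value = TRUE)
    }
    if (length(fractionCols) == 0L) stop("no fraction columns found")
    scr <- univariateScreen(data, outcome, fractionCols, alphaKeep = 0.5)
    y <- data[[outcome]]
    stats <- lapply(fractionCols, function(v) {
        x <- data[[v]]
        data.frame(
            meanLow = mean(x[y == 0]), sdLow = sd(x[y == 0]),
            meanHigh = mean(x[y == 1]), sdHigh = sd(x[y == 1])
        )
    })
    cbind(data.frame(variable = fractionCols, stringsAsFactors = FALSE),
          do.call(rbind, stats),
          scr[match(fractionCols, scr$variable),
              c("OR", "ciLow", "ciHigh", "p")],
          row.names = NULL)
}

#' Stratified train/validation split
#'
#' Seeded random split stratified by the outcome: the total training size
#' is `round(ratio * n)` exactly, allocated across strata by largest
#' remainder, then sampled without replacement within each stratum.
#'
#' @param labels Stratification labels (e.g. the grade column).
#' @param ratio Training fraction (default 0.7).
#' @param seed Optional RNG seed.
#' @return List with integer index vectors `train` and `test`.
#' @examples
#' sp <- stratifiedSplit(rep(0:1, c(184, 88)), ratio = 0.7, seed = 1)
#' length(sp$train)
#' @export
stratifiedSplit <- function(labels, ratio = 0.7, seed = NULL) {
    stopifnot(ratio > 0, ratio < 1)
    if (!is.null(seed)) set.seed(seed)
    n <- length(labels)
    nTrain <- round(ratio * n)
    strata <- split(seq_len(n), labels)
    sizes <- lengths(strata)
    raw <- ratio * sizes
    alloc <- floor(raw)
    rem <- nTrain - sum(alloc)
    if (rem > 0) {
        extra <- order(raw - alloc, decreasing = TRUE)[seq_len(rem)]
        alloc[extra] <- alloc[extra] + 1
    } else if (rem < 0) {
        cut <- order(raw - alloc)[seq_len(-rem)]
        alloc[cut] <- alloc[cut] - 1
    }
    train <- unlist(lapply(seq_along(strata), function(i) {
        idx <- strata[[i]]
        if (alloc[i] >= length(idx)) idx
        else sample(idx, alloc[i])
    }), use.names = FALSE)
    train <- sort(train)
    list(train = train, test = setdiff(seq_len(n), train))
}
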