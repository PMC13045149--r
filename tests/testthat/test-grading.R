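test_that("logistic fits match closed forms", {
    # balanced outcome, intercept-only: intercept is logit(1/2) = 0
    d <- data.frame(y = rep(0:1, each = 25))
    f0 <- fitLogistic(d, "y")
    expect_equal(unname(f0@coefficients), 0, tolerance = 1e-10)
    # 2x2 table a=10, b=10, c=5, d=20: slope = log odds ratio = ln 4
    d2 <- data.frame(
        x = c(rep(1, 15), rep(0, 30)),
        y = c(rep(1, 10), rep(0, 5), rep(1, 10), rep(0, 20))
    )
    f2 <- fitLogistic(d2, "y", "x")
    expect_equal(unname(f2@coefficients["x"]), log(4), tolerance = 1e-8)
    expect_equal(unname(f2@coefficients["(Intercept)"]), log(10 / 20),
                 tolerance = 1e-8)
    expect_true(f2@converged)
    expect_false(f2@separation)
})

test_that("logistic parameter recovery at n = 5000", {
    set.seed(20)
    n <- 5000
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + 0.5 * x))
    f <- fitLogistic(data.frame(x = x, y = y), "y", "x")
    se <- sqrt(diag(f@vcov))
    expect_lt(abs(f@coefficients["(Intercept)"] - (-1)),
              3 * se["(Intercept)"])
    expect_lt(abs(f@coefficients["x"] - 0.5), 3 * se["x"])
})

test_that("degenerate designs are flagged or rejected", {
    d <- data.frame(y = rep(0:1, each = 10), z = 1)
    expect_error(fitLogistic(d, "y", "z"), "zero variance")
    # perfect predictor: separation flagged, not an error
    d2 <- data.frame(y = rep(0:1, each = 10), x = rep(0:1, each = 10))
    expect_warning(f <- fitLogistic(d2, "y", "x"), "separation")
    expect_true(f@separation)
    # exact collinearity is a collinearity error
    d3 <- data.frame(y = rep(0:1, 10), a = rnorm(20))
    d3$b <- d3$a
    expect_error(suppressWarnings(fitLogistic(d3, "y", c("a", "b"))),
                 "collinearity")
})

test_that("univariate screen retains by Wald P at the 0.1 default", {
    set.seed(21)
    n <- 800
    d <- data.frame(
        strong = rnorm(n), noise = rnorm(n)
    )
    d$y <- rbinom(n, 1, plogis(-0.5 + 1.2 * d$strong))
    scr <- univariateScreen(d, "y", c("strong", "noise"))
    expect_true(scr$retained[scr$variable == "strong"])
    expect_lt(scr$p[scr$variable == "strong"], 1e-6)
    expect_equal(scr$retained, scr$p < 0.1 | scr$separation)
    # a deterministic predictor is retained with a separation flag
    d$perfect <- d$y
    scr2 <- univariateScreen(d, "y", "perfect")
    expect_true(scr2$retained[1] && scr2$separation[1])
    # errors propagate per variable without aborting the screen
    d$const <- 1
    scr3 <- univariateScreen(d, "y", c("strong", "const"))
    expect_false(scr3$retained[scr3$variable == "const"])
    expect_match(scr3$error[scr3$variable == "const"], "zero variance")
    expect_true(scr3$retained[scr3$variable == "strong"])
})

test_that("screen type-I retention rate approximates the threshold", {
    set.seed(22)
    hits <- 0
    reps <- 200
    for (i in seq_len(reps)) {
        n <- 400
        d <- data.frame(y = rbinom(n, 1, 0.4), x = rnorm(n))
        scr <- univariateScreen(d, "y", "x")
        if (scr$retained[1]) hits <- hits + 1
    }
    # binomial(200, 0.1): 3 SE band around the nominal rate
    expect_gt(hits / reps, 0.1 - 3 * sqrt(0.1 * 0.9 / reps))
    expect_lt(hits / reps, 0.1 + 3 * sqrt(0.1 * 0.9 / reps))
})

test_that("backward stepwise keeps strong signals and drops duplicates", {
    set.seed(23)
    n <- 1000
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.5 + 2 * x))
    d <- data.frame(y = y, x = x)
    f <- stepwiseBackward(d, "y", "x")
    expect_equal(f@variables, "x")
    # near-duplicate predictors: exactly one of the pair survives
    d$x2 <- x + rnorm(n, sd = sqrt(1 - 0.99^2) / 0.99)
    f2 <- stepwiseBackward(d, "y", c("x", "x2"))
    expect_equal(length(intersect(c("x", "x2"), f2@variables)), 1L)
    expect_equal(length(f2@selection$removed), 1L)
    # removal path is recorded round by round
    expect_true(all(c("round", "variable", "lrtP") %in%
                    names(f2@selection$path)))
    # pure-noise candidates collapse to the intercept-only fit
    d3 <- data.frame(y = rbinom(200, 1, 0.5), a = rnorm(200), b = rnorm(200))
    f3 <- tryCatch(stepwiseBackward(d3, "y", c("a", "b")),
                   warning = function(w) suppressWarnings(
                       stepwiseBackward(d3, "y", c("a", "b"))))
    expect_true(length(f3@variables) <= 2)
})

test_that("stepwise path is deterministic given the table", {
    d <- simulateSelectionCohort(500, seed = 24)
    f1 <- stepwiseBackward(d, "grade",
                           c("sex", "diameterMm", "F1", "F2", "hematuria"))
    f2 <- stepwiseBackward(d, "grade",
                           c("sex", "diameterMm", "F1", "F2", "hematuria"))
    expect_identical(f1@variables, f2@variables)
    expect_identical(f1@coefficients, f2@coefficients)
})

test_that("fitted grade-model signs follow the cohort structure", {
    # male sex and diameter increase high-grade odds, habitat-1 fraction
    # decreases them, matching the generator's grade-conditional structure
    ok <- 0
    for (s in 1:10) {
        coh <- generateCohort(cohortSpec(nPatients = 1000, seed = 600 + s),
                              volumes = FALSE)
        tab <- coh$table
        names(tab) <- sub("^trueF", "F", names(tab))
        f <- fitLogistic(tab, "grade", c("sex", "diameterMm", "F1"))
        b <- f@coefficients
        if (b[["sex"]] > 0 && b[["diameterMm"]] > 0 && b[["F1"]] < 0) {
            ok <- ok + 1
        }
    }
    expect_gte(ok, 9)
})

test_that("odds ratios follow the closed-form Wald arithmetic", {
    fit <- new("LogisticFit", variables = "x",
               coefficients = c("(Intercept)" = 0, x = log(4)),
               vcov = diag(c(0.1, 0.25)), logLik = -10, nObs = 50L,
               converged = TRUE, separation = FALSE, selection = list(),
               glmFit = NULL)
    or <- oddsRatios(fit)
    expect_equal(or$OR, 4)
    expect_equal(or$ciLow, exp(log(4) - 1.96 * 0.5), tolerance = 1e-12)
    expect_equal(or$ciHigh, exp(log(4) + 1.96 * 0.5), tolerance = 1e-12)
    expect_equal(round(c(or$ciLow, or$ciHigh), 2), c(1.50, 10.66))
    # null effect: OR 1, CI contains 1
    fit0 <- new("LogisticFit", variables = "x",
                coefficients = c("(Intercept)" = 0, x = 0),
                vcov = diag(c(0.1, 0.2)), logLik = -10, nObs = 50L,
                converged = TRUE, separation = FALSE, selection = list(),
                glmFit = NULL)
    or0 <- oddsRatios(fit0)
    expect_equal(or0$OR, 1)
    expect_true(or0$ciLow < 1 && or0$ciHigh > 1)
    # CI always contains the point OR
    set.seed(25)
    d <- simulateSelectionCohort(400, seed = 25)
    f <- fitLogistic(d, "grade", c("sex", "diameterMm", "F1"))
    orf <- oddsRatios(f)
    expect_true(all(orf$ciLow <= orf$OR & orf$OR <= orf$ciHigh))
})

test_that("nomogram anchors and round-trip prediction", {
    d <- simulateSelectionCohort(600, seed = 26)
    f <- fitLogistic(d, "grade", c("sex", "diameterMm", "F1", "F2"))
    nom <- buildNomogram(f)
    # reference value scores 0 points; the max |beta * range| predictor
    # spans exactly 100
    ref <- as.data.frame(as.list(setNames(nom@ref, nom@variables)))
    p0 <- nomogramPredict(nom, ref)
    expect_equal(p0$totalPoints, 0, tolerance = 1e-10)
    spans <- abs(nom@pointsPerUnit) * (nom@hi - nom@lo)
    expect_equal(max(spans), 100, tolerance = 1e-10)
    # probability equals the direct logistic prediction
    pr <- nomogramPredict(nom, d)
    expect_equal(pr$probability, predictLogistic(f, d), tolerance = 1e-9)
    # monotone in each covariate with the coefficient's sign
    base <- d[3, , drop = FALSE]
    for (v in nom@variables) {
        up <- base; up[[v]] <- base[[v]] + 0.1 * (nom@hi - nom@lo)[match(v, nom@variables)]
        dp <- suppressWarnings(nomogramPredict(nom, up)$probability -
                               nomogramPredict(nom, base)$probability)
        expect_equal(sign(dp), sign(f@coefficients[[v]]))
    }
    # extrapolation warning outside the stated range
    out <- base; out$diameterMm <- max(d$diameterMm) + 50
    expect_warning(nomogramPredict(nom, out), "extrapolat")
})

test_that("fits and nomograms persist through JSON", {
    d <- simulateSelectionCohort(300, seed = 27)
    f <- fitLogistic(d, "grade", c("sex", "F1"))
    dir <- withr::local_tempdir()
    writeLogisticFit(f, file.path(dir, "fit.json"))
    back <- readLogisticFit(file.path(dir, "fit.json"))
    expect_equal(back@coefficients, f@coefficients)
    expect_equal(back@vcov, f@vcov)
    expect_equal(predictLogistic(back, d), predictLogistic(f, d))
    nom <- buildNomogram(f)
    writeNomogram(nom, file.path(dir, "nom.json"))
    nom2 <- readNomogram(file.path(dir, "nom.json"))
    expect_equal(nomogramPredict(nom2, d), nomogramPredict(nom, d))
})
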