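test_that("k-means closed-form cases: k = 1, tight pairs, k = N", {
    set.seed(1)
    x <- matrix(rnorm(60, 100, 25), ncol = 3)
    # k = 1: centroid is the coordinate-wise mean, SSE the total SS
    f1 <- kmeansFit(x, 1, seed = 2)
    expect_equal(unname(f1$model@centroids[1, ]), colMeans(x))
    expect_equal(f1$model@sse, sum(sweep(x, 2, colMeans(x))^2))
    # two tight well-separated pairs: centroids at the pair means
    pairs <- rbind(c(0, 0, 0), c(0.2, 0, 0), c(50, 50, 50), c(50.2, 50, 50))
    f2 <- kmeansFit(pairs, 2, nInit = 10, seed = 3)
    cen <- f2$model@centroids[order(f2$model@centroids[, 1]), ]
    expect_equal(unname(cen), rbind(c(0.1, 0, 0), c(50.1, 50, 50)),
                 tolerance = 1e-8)
    expect_equal(f2$model@sse, enumKmeansSSE(pairs, 2), tolerance = 1e-10)
    # k = N: zero SSE
    f3 <- kmeansFit(x[1:5, ], 5, seed = 4)
    expect_equal(f3$model@sse, 0)
    expect_error(kmeansFit(x[1:3, ], 4), "size error")
})

test_that("best-of-restarts reaches the enumerated global optimum", {
    # exhaustive-partition oracle on tiny instances
    set.seed(10)
    hits <- 0
    nCase <- 40
    for (i in seq_len(nCase)) {
        n <- sample(5:8, 1)
        k <- sample(2:3, 1)
        x <- matrix(rnorm(3 * n), ncol = 3)
        ours <- kmeansFit(x, k, nInit = 20)$model@sse
        opt <- enumKmeansSSE(x, k)
        expect_gte(ours, opt - 1e-9) # never below the global optimum
        if (ours <= opt + 1e-6) hits <- hits + 1
    }
    expect_gte(hits / nCase, 0.95)
})

test_that("kmeansSSE computes exact squared distances and optimality", {
    x <- rbind(c(0, 0, 0), c(2, 0, 0))
    expect_equal(kmeansSSE(x, rbind(c(1, 0, 0)), c(1, 1)), 2)
    expect_equal(kmeansSSE(x, x, c(1, 2)), 0)
    expect_error(kmeansSSE(x, rbind(c(1, 0, 0)), c(1, 2)), "out of range")
    # nearest-centroid assignment minimizes SSE over all assignments
    set.seed(11)
    for (i in 1:10) {
        x <- matrix(rnorm(18), ncol = 3)
        cen <- matrix(rnorm(6), ncol = 3)
        near <- bruteAssign(cen, x)
        sseNear <- kmeansSSE(x, cen, near)
        grid <- do.call(expand.grid, rep(list(1:2), nrow(x)))
        alt <- apply(grid, 1, function(a) kmeansSSE(x, cen, as.integer(a)))
        expect_true(all(sseNear <= alt + 1e-12))
    }
})

test_that("elbowPoint finds breakpoints and applies the smallest-k tie rule", {
    # piecewise-linear curve with a single breakpoint at k = 3
    eb <- elbowPoint(1:6, c(10, 6, 2, 1.8, 1.6, 1.4))
    expect_equal(eb$kStar, 3)
    # hand-computed geometry for the breakpoint curve 10,6,2,1.5,1 over 1..5:
    # normalized points (0,1),(0.25,5/9),(0.5,1/9),(0.75,1/18),(1,0);
    # chord from (0,1) to (1,0): distance = |kn + sn - 1| / sqrt(2)
    kn <- (1:5 - 1) / 4; sn <- (c(10, 6, 2, 1.5, 1) - 1) / 9
    handD <- abs(kn + sn - 1) / sqrt(2)
    eb2 <- elbowPoint(1:5, c(10, 6, 2, 1.5, 1))
    expect_equal(eb2$chordDistance, handD, tolerance = 1e-12)
    expect_equal(eb2$kStar, 3)
    # exactly linear curve: all distances 0, smallest k returned
    lin <- elbowPoint(2:8, seq(100, 40, by = -10))
    expect_equal(lin$kStar, 2)
    expect_true(all(abs(lin$chordDistance) < 1e-12))
})

test_that("selectKElbow recovers the habitat count on separated mixtures", {
    fix <- smallVoxelFixture(n = 3000)
    sel <- selectKElbow(fix$values, kRange = 2:6, nInit = 5, seed = 5)
    expect_equal(sel$kStar, 3)
    expect_equal(sel$sseCurve$k, 2:6)
    expect_true(all(diff(sel$sseCurve$sse) <= 1e-6))
    expect_error(selectKElbow(fix$values[1:4, ], kRange = 2:8), "size error")
})

test_that("canonicalization orders by CMP and is permutation invariant", {
    kin <- defaultHabitatKinetics()
    model <- new("HabitatModel", k = 4L,
                 centroids = kin@meanHU[c(3, 1, 4, 2), ], sse = 1,
                 fitMeta = list(canonical = FALSE))
    can <- canonicalizeModel(model, assignments = c(1L, 2L, 3L, 4L))
    expect_equal(unname(can$model@centroids), unname(kin@meanHU))
    # assignments remapped consistently: old cluster 2 (CMP 148.8) -> 1
    expect_equal(can$assignments, c(3L, 1L, 4L, 2L))
    # idempotent
    again <- canonicalizeModel(can$model)
    expect_equal(again$model@centroids, can$model@centroids)
    # any permutation yields the identical canonical model
    for (p in list(c(2, 1, 4, 3), c(4, 3, 2, 1), c(1, 3, 2, 4))) {
        m <- new("HabitatModel", k = 4L, centroids = kin@meanHU[p, ],
                 sse = 1, fitMeta = list(canonical = FALSE))
        expect_equal(unname(canonicalizeModel(m)$model@centroids),
                     unname(kin@meanHU))
    }
})

test_that("assignHabitats matches brute force and breaks ties low", {
    set.seed(6)
    cen <- matrix(rnorm(12, 100, 30), ncol = 3,
                  dimnames = list(NULL, c("CMP", "NP", "EP")))
    cen <- cen[order(-cen[, 1]), ]
    model <- new("HabitatModel", k = 4L, centroids = cen, sse = 0,
                 fitMeta = list(canonical = TRUE))
    x <- matrix(rnorm(300, 100, 30), ncol = 3)
    expect_equal(assignHabitats(model, x), unname(bruteAssign(cen, x)))
    # exact centroid match
    expect_equal(assignHabitats(model, cen[2, , drop = FALSE]), 2L)
    # equidistant voxel between centroids 1 and 3 goes to 1
    mid <- matrix((cen[1, ] + cen[3, ]) / 2, nrow = 1)
    d <- rowSums(sweep(rbind(cen), 2, mid[1, ])^2)
    if (which.min(d) %in% c(1, 3)) {
        expect_true(assignHabitats(model, mid) <= 3)
    }
    tie <- new("HabitatModel", k = 2L,
               centroids = rbind(c(1, 0, 0), c(-1, 0, 0)), sse = 0,
               fitMeta = list())
    expect_equal(assignHabitats(tie, matrix(0, 1, 3)), 1L)
    expect_error(assignHabitats(model, matrix(0, 2, 2)), "dimension")
})

test_that("habitat fractions are decimal, complete and sum to one", {
    expect_equal(habitatFractions(c(1, 1, 2, 3), 4),
                 c(F1 = 0.5, F2 = 0.25, F3 = 0.25, F4 = 0))
    expect_equal(habitatFractions(rep(1, 9), 4),
                 c(F1 = 1, F2 = 0, F3 = 0, F4 = 0))
    expect_error(habitatFractions(integer(), 4), "empty-VOI")
    set.seed(7)
    for (i in 1:20) {
        lab <- sample(1:4, sample(5:200, 1), replace = TRUE)
        f <- habitatFractions(lab, 4)
        expect_lt(abs(sum(f) - 1), 1e-9)
        expect_true(all(f >= 0 & f <= 1))
    }
})

test_that("cohort pooling concatenates, canonicalizes and recovers means", {
    # pooled matrix has the concatenated row count
    m1 <- matrix(rnorm(30, 100, 10), ncol = 3)
    m2 <- matrix(rnorm(60, 40, 10), ncol = 3)
    res <- fitCohortHabitats(list(a = m1, b = m2), k = 2, seed = 8)
    expect_equal(sum(lengths(res$assignments)), 30)
    expect_equal(lengths(res$assignments), c(a = 10L, b = 20L))
    # zero-noise cohort: pooled centroids equal the generator means exactly
    kin <- habitatKinetics(
        meanHU = rbind(c(150, 140, 115), c(90, 110, 98), c(37, 34, 36)),
        sdHU = matrix(0, 3, 3)
    )
    phs <- lapply(1:3, function(s) {
        generatePhantom(phantomSpec(semiAxes = c(8, 7, 6),
                                    composition = c(0.4, 0.35, 0.25),
                                    kinetics = kin, seed = s))
    })
    mats <- lapply(phs, function(p) extractVoxelMatrix(p$stack))
    fit <- fitCohortHabitats(mats, k = 3, nInit = 5, seed = 9)
    expect_equal(unname(fit$model@centroids), unname(kin@meanHU),
                 tolerance = 1e-9)
    expect_true(fit$model@fitMeta$canonical)
    # leakage warning when pooling everything despite a training subset
    expect_warning(
        fitCohortHabitats(list(m1, m2), k = 2, scope = "all_patients",
                          trainIdx = 1L, seed = 1),
        "leakage"
    )
    expect_error(fitCohortHabitats(list(), k = 2), "empty")
})

test_that("summarizeHabitats reproduces member means and SDs", {
    fix <- smallVoxelFixture(n = 900)
    fit <- kmeansFit(fix$values, 3, nInit = 5, seed = 12)
    can <- canonicalizeModel(fit$model, fit$assignments)
    summ <- summarizeHabitats(fix$values, can$assignments, k = 3)
    # means equal centroids computed over the same assignment (one Lloyd
    # update identity)
    for (h in 1:3) {
        members <- fix$values[can$assignments == h, ]
        row <- summ[summ$habitat == h & summ$phase == "CMP", ]
        expect_equal(row$mean, mean(members[, "CMP"]))
        expect_equal(row$sd, sd(members[, "CMP"]))
        expect_equal(row$mean, unname(can$model@centroids[h, "CMP"]),
                     tolerance = 1e-6)
    }
    # zero-noise data: SD column all zero
    z <- matrix(rep(c(10, 20, 30), each = 5), ncol = 3)
    sz <- summarizeHabitats(z, rep(1L, 5), k = 1)
    expect_true(all(sz$sd == 0))
})

test_that("habitat models persist through JSON round-trips", {
    fix <- smallVoxelFixture()
    fit <- kmeansFit(fix$values, 3, nInit = 5, seed = 13)
    can <- canonicalizeModel(fit$model)$model
    d <- withr::local_tempdir()
    p <- file.path(d, "model.json")
    writeHabitatModel(can, p)
    back <- readHabitatModel(p)
    expect_equal(back@centroids, can@centroids)
    expect_equal(back@k, can@k)
    expect_equal(back@sse, can@sse)
    # assignments from the restored model are identical
    expect_equal(assignHabitats(back, fix$values),
                 assignHabitats(can, fix$values))
})

test_that("fitted K-means matches stats::kmeans quality on moderate data", {
    # cross-check against the independent implementation: equal-or-better
    # SSE within a small relative slack on a mixture fixture
    fix <- smallVoxelFixture(n = 1200, seed = 77)
    ours <- kmeansFit(fix$values, 3, nInit = 10, seed = 14)$model@sse
    ref <- stats::kmeans(fix$values, 3, nstart = 10, iter.max = 100)
    expect_lt(abs(ours - ref$tot.withinss) / ref$tot.withinss, 0.02)
})
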