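## Independent oracles used across the suite. These deliberately use
## different algorithms (enumeration, double loops, ANOVA via aov) than the
## package implementation they check.

## Global-optimum K-means by exhaustive partition enumeration (tiny n only).
enumKmeansSSE <- function(x, k) {
    n <- nrow(x)
    stopifnot(n <= 10)
    best <- Inf
    # enumerate all assignments of n points to k labels
    grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
    for (r in seq_len(nrow(grid))) {
        a <- as.integer(grid[r, ])
        if (length(unique(a)) < k) next
        s <- 0
        for (c in seq_len(k)) {
            pts <- x[a == c, , drop = FALSE]
            ctr <- colMeans(pts)
            s <- s + sum(sweep(pts, 2, ctr)^2)
        }
        if (s < best) best <- s
    }
    best
}

## Mann-Whitney AUC by explicit pair enumeration.
enumAuc <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg) {
        tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    }
    tot / (length(pos) * length(neg))
}

## DeLong structural components by definition (explicit double loop).
loopDelongComponents <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    v10 <- vapply(pos, function(p) {
        mean(vapply(neg, function(q) (p > q) + 0.5 * (p == q), 0))
    }, 0)
    v01 <- vapply(neg, function(q) {
        mean(vapply(pos, function(p) (p > q) + 0.5 * (p == q), 0))
    }, 0)
    list(v10 = v10, v01 = v01)
}

## Nearest-centroid labels by brute-force distance scan.
bruteAssign <- function(centroids, x) {
    apply(x, 1, function(row) {
        d <- apply(centroids, 1, function(c) sum((row - c)^2))
        which.min(d)
    })
}

## Grade cohort for selection-recovery: active effects on sex, diameter,
## F1, F2; two truly null extras (binary "hematuria", continuous "age").
simulateSelectionCohort <- function(n, seed) {
    set.seed(seed)
    sex <- rbinom(n, 1, 0.7)
    diameterMm <- rnorm(n, 50, 18)
    comp <- t(replicate(n, {
        g <- rgamma(4, shape = c(3, 7, 5, 4))
        g / sum(g)
    }))
    F1 <- comp[, 1]; F2 <- comp[, 2]; F3 <- comp[, 3]
    hematuria <- rbinom(n, 1, 0.15)
    age <- rnorm(n, 62, 11)
    lp <- -3.2 + 1.0 * sex + 0.05 * diameterMm - 6 * F1 + 3.5 * F2
    grade <- rbinom(n, 1, plogis(lp))
    data.frame(grade, sex, diameterMm, F1, F2, hematuria, age)
}

## Small deterministic voxel fixture (three well-separated habitats).
smallVoxelFixture <- function(n = 600, seed = 42) {
    set.seed(seed)
    mu <- rbind(c(150, 140, 115), c(90, 110, 98), c(37, 34, 36))
    lab <- sample(1:3, n, replace = TRUE)
    vals <- matrix(rnorm(3 * n, mean = t(mu)[, lab], sd = 8), ncol = 3,
                   byrow = TRUE, dimnames = list(NULL, c("CMP", "NP", "EP")))
    list(values = vals, labels = lab, mu = mu)
}
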