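## Synthetic phantom and cohort generation.
##
## The generators emulate the statistical structure the downstream analysis
## assumes: ellipsoidal tumors containing spatially coherent habitat
## subregions whose per-phase HU values are Gaussian around habitat-specific
## enhancement kinetics, and grade-conditional clinical covariates
## (high-grade tumors: fewer strongly-enhancing Habitat-1 voxels, larger
## diameters, more often male).

#' Construct habitat enhancement kinetics
#'
#' @param meanHU,sdHU k x 3 matrices (columns CMP, NP, EP) in Hounsfield
#'   units.
#' @return A [HabitatKinetics-class] object.
#' @export
habitatKinetics <- function(meanHU, sdHU) {
    meanHU <- as.matrix(meanHU); sdHU <- as.matrix(sdHU)
    colnames(meanHU) <- colnames(sdHU) <- c("CMP", "NP", "EP")
    new("HabitatKinetics", meanHU = meanHU, sdHU = sdHU)
}

#' Default four-habitat enhancement kinetics
#'
#' The reference tri-phase enhancement parameters of the four ccRCC
#' habitats (mean +/- SD HU per phase), in canonical CMP-descending order:
#' habitat 1 shows strong corticomedullary enhancement with washout,
#' habitat 4 is persistently hypo-enhancing.
#'
#' @return A [HabitatKinetics-class] with 4 rows.
#' @export
defaultHabitatKinetics <- function() {
    habitatKinetics(
        meanHU = rbind(
            c(148.776, 141.015, 113.560),
            c(90.916, 110.258, 97.906),
            c(58.965, 76.482, 72.128),
            c(36.851, 34.450, 35.833)
        ),
        sdHU = rbind(
            c(31.368, 27.948, 23.338),
            c(20.907, 20.344, 18.737),
            c(17.397, 16.554, 17.023),
            c(18.669, 27.000, 24.619)
        )
    )
}

#' Simulate tri-phase voxel HU triplets from habitat kinetics
#'
#' Draws `n` voxels: each voxel first draws a habitat class with the given
#' proportions, then an independent Normal HU value per phase from that
#' habitat's kinetics. This is the pooled-voxel study condition used for
#' habitat-model recovery checks.
#'
#' @param n Number of voxels.
#' @param kinetics A [HabitatKinetics-class]; defaults to
#'   [defaultHabitatKinetics()].
#' @param proportions Habitat sampling probabilities (default equal).
#' @param seed Optional RNG seed.
#' @return List with `values` (n x 3 matrix, columns CMP/NP/EP) and
#'   `labels` (integer habitat of each voxel).
#' @examples
#' vox <- simulateHabitatVoxels(1000, seed = 1)
#' colMeans(vox$values[vox$labels == 1, ])
#' @export
simulateHabitatVoxels <- function(n, kinetics = defaultHabitatKinetics(),
                                  proportions = NULL, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    k <- nrow(kinetics@meanHU)
    if (is.null(proportions)) proportions <- rep(1 / k, k)
    stopifnot(length(proportions) == k, all(proportions >= 0))
    labels <- sample.int(k, n, replace = TRUE, prob = proportions)
    values <- matrix(
        rnorm(3L * n,
              mean = t(kinetics@meanHU)[, labels],
              sd = t(kinetics@sdHU)[, labels]),
        ncol = 3L, byrow = TRUE, dimnames = list(NULL, c("CMP", "NP", "EP"))
    )
    list(values = values, labels = labels)
}

#' Construct a phantom specification
#'
#' @param gridDim Grid size in voxels (default sized to fit the tumor).
#' @param spacing Voxel spacing in mm; default `c(1, 1, 3)`, the analysis
#'   grid used throughout the pipeline.
#' @param semiAxes Tumor ellipsoid semi-axes in mm.
#' @param composition Habitat volume-fraction targets (must sum to 1).
#' @param kinetics A [HabitatKinetics-class].
#' @param coherence Spatial coherence scale in mm (default 4).
#' @param seed RNG seed.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(semiAxes = c(20, 16, 14), spacing = c(1, 1, 3),
                        gridDim = NULL,
                        composition = c(0.209, 0.365, 0.259, 0.167),
                        kinetics = defaultHabitatKinetics(),
                        coherence = 4, seed = 1L) {
    if (is.null(gridDim)) {
        gridDim <- as.integer(ceiling(2 * (semiAxes + 2 * spacing) / spacing))
    }
    new("PhantomSpec", gridDim = as.integer(gridDim),
        spacing = as.numeric(spacing), semiAxes = as.numeric(semiAxes),
        composition = as.numeric(composition), kinetics = kinetics,
        coherence = as.numeric(coherence), seed = as.integer(seed))
}

#' Construct a cohort specification
#'
#' Defaults encode the grade-conditional structure of a two-center ccRCC
#' cohort: high-grade prevalence 88/272; male proportion 0.606 (low grade)
#' vs 0.841 (high); maximum diameter 43.46 +/- 14.22 mm (low) vs
#' 60.98 +/- 26.35 mm (high); habitat composition centers
#' (0.209, 0.365, 0.259, 0.167) for low grade and (normalized)
#' (0.068, 0.393, 0.317, 0.221) for high grade in canonical habitat order,
#' Dirichlet concentration 20.
#'
#' @param nPatients Number of patients.
#' @param prevalence Probability of high grade.
#' @param compositionLow,compositionHigh Grade-conditional habitat-fraction
#'   centers.
#' @param concentration Dirichlet concentration parameter.
#' @param sexMaleProb,diameterMean,diameterSd Length-2 `c(low, high)`
#'   parameters.
#' @param kinetics Habitat kinetics shared by the cohort.
#' @param spacing Voxel spacing of generated volumes (mm).
#' @param coherence Habitat layout coherence (mm).
#' @param seed RNG seed.
#' @return A [CohortSpec-class].
#' @export
cohortSpec <- function(nPatients = 60L, prevalence = 88 / 272,
                       compositionLow = c(0.209, 0.365, 0.259, 0.167),
                       compositionHigh = c(0.068, 0.393, 0.317, 0.221) / 0.999,
                       concentration = 20,
                       sexMaleProb = c(77 / 127, 53 / 63),
                       diameterMean = c(43.46, 60.98),
                       diameterSd = c(14.22, 26.35),
                       kinetics = defaultHabitatKinetics(),
                       spacing = c(1, 1, 3), coherence = 4, seed = 1L) {
    new("CohortSpec", nPatients = as.integer(nPatients),
        prevalence = prevalence,
        compositionLow = compositionLow / sum(compositionLow),
        compositionHigh = compositionHigh / sum(compositionHigh),
        concentration = concentration, sexMaleProb = sexMaleProb,
        diameterMean = diameterMean, diameterSd = diameterSd,
        kinetics = kinetics, spacing = as.numeric(spacing),
        coherence = as.numeric(coherence), seed = as.integer(seed))
}

## Dirichlet draw via normalized gammas.
rdirichlet1 <- function(alpha) {
    g <- rgamma(length(alpha), shape = alpha, rate = 1)
    if (sum(g) == 0) g[which.max(alpha)] <- 1
    g / sum(g)
}

## Separable Gaussian smoothing of a 3-D array with edge renormalization.
## sigmaVox: per-axis sigma in voxels.
gaussianSmooth3D <- function(arr, sigmaVox) {
    d <- dim(arr)
    ones <- array(1, d)
    for (ax in 1:3) {
        s <- sigmaVox[ax]
        if (s <= 0) next
        r <- max(1L, ceiling(3 * s))
        kern <- exp(-(seq(-r, r))^2 / (2 * s^2))
        smooth_axis <- function(a) {
            out <- array(0, d)
            for (i in seq_along(kern)) {
                off <- i - r - 1L
                src <- seq_len(d[ax]) - off
                keep <- src >= 1L & src <= d[ax]
                idx_to <- which(keep); idx_from <- src[keep]
                if (ax == 1) {
                    out[idx_to, , ] <- out[idx_to, , ] +
                        kern[i] * a[idx_from, , ]
                } else if (ax == 2) {
                    out[, idx_to, ] <- out[, idx_to, ] +
                        kern[i] * a[, idx_from, ]
                } else {
                    out[, , idx_to] <- out[, , idx_to] +
                        kern[i] * a[, , idx_from]
                }
            }
            out
        }
        arr <- smooth_axis(arr)
        ones <- smooth_axis(ones)
    }
    arr / ones
}

## Largest-remainder apportionment of n among proportions p (sums to n).
apportion <- function(p, n) {
    raw <- p * n
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
    }
    as.integer(base)
}

#' Generate a synthetic triphasic-CT tumor phantom
#'
#' Builds an ellipsoidal tumor mask on the requested grid, lays out
#' spatially coherent habitat subregions whose within-mask proportions match
#' the spec's composition exactly (largest-remainder apportionment), and
#' draws per-voxel HU values independently per phase from each habitat's
#' Normal kinetics. Background voxels are 0 HU. Fully reproducible given the
#' spec seed.
#'
#' Habitat layout: one seeded smooth Gaussian random field per habitat
#' (white noise low-pass filtered at the coherence scale); habitats claim
#' their apportioned voxel counts in order, each taking the unclaimed mask
#' voxels where its field is highest. Coherence 0 gives spatially
#' independent labels.
#'
#' @param spec A [PhantomSpec-class].
#' @return List with `stack` (a [PhaseStack-class]) and `truth` (integer
#'   array of ground-truth habitat labels, 0 outside the mask).
#' @examples
#' ph <- generatePhantom(phantomSpec(semiAxes = c(10, 8, 8), seed = 7))
#' table(ph$truth[ph$truth > 0]) / sum(ph$truth > 0)
#' @export
generatePhantom <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    validObject(spec)
    set.seed(spec@seed)
    d <- spec@gridDim
    k <- length(spec@composition)

    center <- (d + 1) / 2
    halfExtent <- (d - 1) / 2 * spec@spacing
    if (any(spec@semiAxes > halfExtent)) {
        stop("geometry error: tumor ellipsoid not contained in the grid")
    }

    cx <- (seq_len(d[1]) - center[1]) * spec@spacing[1]
    cy <- (seq_len(d[2]) - center[2]) * spec@spacing[2]
    cz <- (seq_len(d[3]) - center[3]) * spec@spacing[3]
    r2 <- outer(outer((cx / spec@semiAxes[1])^2,
                      (cy / spec@semiAxes[2])^2, `+`),
                (cz / spec@semiAxes[3])^2, `+`)
    mask <- array(as.numeric(r2 <= 1), d)
    inMask <- which(mask == 1)
    nMask <- length(inMask)
    if (nMask < k) stop("geometry error: fewer mask voxels than habitats")

    # habitat layout fields
    sigmaVox <- spec@coherence / spec@spacing
    fields <- lapply(seq_len(k), function(h) {
        f <- array(rnorm(prod(d)), d)
        if (spec@coherence > 0) f <- gaussianSmooth3D(f, sigmaVox)
        f[inMask]
    })
    counts <- apportion(spec@composition, nMask)
    labels <- integer(nMask)
    unassigned <- rep(TRUE, nMask)
    for (h in seq_len(k)) {
        if (counts[h] == 0L) next
        cand <- which(unassigned)
        take <- cand[order(fields[[h]][cand], decreasing = TRUE)[seq_len(counts[h])]]
        labels[take] <- h
        unassigned[take] <- FALSE
    }

    truth <- array(0L, d)
    truth[inMask] <- labels

    drawPhase <- function(phase) {
        v <- array(0, d)
        v[inMask] <- rnorm(nMask,
                           mean = spec@kinetics@meanHU[labels, phase],
                           sd = spec@kinetics@sdHU[labels, phase])
        v
    }
    stack <- new("PhaseStack",
        cmp = drawPhase(1L), np = drawPhase(2L), ep = drawPhase(3L),
        mask = mask, spacing = spec@spacing, origin = c(0, 0, 0),
        orientation = diag(3))
    list(stack = stack, truth = truth)
}

#' Generate a synthetic patient cohort
#'
#' Per patient: grade is Bernoulli(prevalence); the habitat composition is
#' Dirichlet with concentration `spec@concentration` around the grade's
#' composition center; sex and maximum diameter come from the
#' grade-conditional distributions; the tumor ellipsoid semi-axes are scaled
#' so the maximum diameter equals the drawn diameter (axis ratios
#' 1 : 0.8 : 0.7). Volumes are optional so large table-level cohorts can be
#' drawn cheaply.
#'
#' @param spec A [CohortSpec-class].
#' @param volumes If `TRUE` (default) generate the phantom volumes; if
#'   `FALSE` only the covariate table (with the drawn ground-truth
#'   compositions in columns `trueF1..trueFk`).
#' @return List with `table` (data.frame: `patientId`, `grade` (1 = high),
#'   `sex` (1 = male), `diameterMm`, `trueF*`) and `patients` (list of
#'   `generatePhantom()` outputs, or `NULL`).
#' @examples
#' coh <- generateCohort(cohortSpec(nPatients = 5, seed = 3), volumes = FALSE)
#' coh$table
#' @export
generateCohort <- function(spec, volumes = TRUE) {
    stopifnot(is(spec, "CohortSpec"))
    validObject(spec)
    if (spec@nPatients < 1L) stop("spec error: nPatients < 1")
    set.seed(spec@seed)
    n <- spec@nPatients
    k <- length(spec@compositionLow)

    grade <- rbinom(n, 1L, spec@prevalence)
    comp <- t(vapply(seq_len(n), function(i) {
        center <- if (grade[i] == 1L) spec@compositionHigh else spec@compositionLow
        rdirichlet1(spec@concentration * center)
    }, numeric(k)))
    sex <- rbinom(n, 1L, spec@sexMaleProb[grade + 1L])
    diameter <- pmax(12, rnorm(n, spec@diameterMean[grade + 1L],
                               spec@diameterSd[grade + 1L]))
    patientSeeds <- sample.int(.Machine$integer.max, n)

    tab <- data.frame(
        patientId = sprintf("P%03d", seq_len(n)),
        grade = grade, sex = sex, diameterMm = diameter,
        stringsAsFactors = FALSE
    )
    compDf <- as.data.frame(comp)
    names(compDf) <- paste0("trueF", seq_len(k))
    tab <- cbind(tab, compDf)

    patients <- NULL
    if (volumes) {
        patients <- lapply(seq_len(n), function(i) {
            a <- diameter[i] / 2
            generatePhantom(phantomSpec(
                semiAxes = a * c(1, 0.8, 0.7), spacing = spec@spacing,
                composition = comp[i, ], kinetics = spec@kinetics,
                coherence = spec@coherence, seed = patientSeeds[i]
            ))
        })
        names(patients) <- tab$patientId
    }
    list(table = tab, patients = patients)
}
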