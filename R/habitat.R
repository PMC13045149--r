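## Habitat mapping: pooled K-means over (CMP, NP, EP) HU triplets, SSE-based
## elbow selection of the number of habitats, canonical habitat ordering and
## volume-fraction quantification.

asVoxelValues <- function(x) {
    if (is(x, "VoxelMatrix")) x <- x@values
    x <- as.matrix(x)
    if (!is.double(x)) storage.mode(x) <- "double"
    x
}

#' Fit K-means habitats to a voxel matrix
#'
#' Lloyd iterations from k-means++ initializations, best of `nInit` runs by
#' SSE. Assignments are nearest-centroid in squared Euclidean distance;
#' empty clusters are re-seeded at the point farthest from its centroid; a
#' run converges when the largest centroid shift drops below `tol` (HU).
#' The returned model is in fit order; see [canonicalizeModel()].
#'
#' @param x A [VoxelMatrix-class] or N x 3 numeric matrix.
#' @param k Number of clusters (1 <= k <= N).
#' @param nInit Number of k-means++ restarts (default 10).
#' @param maxIter Maximum Lloyd iterations per restart (default 300).
#' @param tol Convergence tolerance on centroid shift, HU (default 1e-4).
#' @param seed Optional RNG seed (stored in the model metadata).
#' @return List with `model` (a [HabitatModel-class]) and `assignments`
#'   (integer vector, 1..k).
#' @examples
#' vox <- simulateHabitatVoxels(2000, seed = 1)
#' fit <- kmeansFit(vox$values, k = 4, seed = 1)
#' centroids(fit$model)
#' @export
kmeansFit <- function(x, k, nInit = 10, maxIter = 300, tol = 1e-4,
                      seed = NULL) {
    x <- asVoxelValues(x)
    if (k < 1) stop("size error: k must be >= 1")
    if (nrow(x) < k) stop("size error: fewer voxels (", nrow(x),
                          ") than clusters (", k, ")")
    if (!is.null(seed)) set.seed(seed)
    res <- cpp_kmeans(x, as.integer(k), as.integer(nInit),
                      as.integer(maxIter), tol)
    cen <- res$centroids
    colnames(cen) <- c("CMP", "NP", "EP")[seq_len(ncol(cen))]
    model <- new("HabitatModel", k = as.integer(k), centroids = cen,
                 sse = res$sse,
                 fitMeta = list(nInit = nInit, maxIter = maxIter, tol = tol,
                                seed = seed, nVoxelsFit = nrow(x),
                                converged = res$converged,
                                canonical = FALSE))
    list(model = model, assignments = as.integer(res$assignments))
}

#' Within-cluster sum of squared errors
#'
#' `SSE = sum_i || x_i - mu_{c_i} ||^2`: the exact sum of squared Euclidean
#' distances of each row to its assigned centroid.
#'
#' @param x Voxel matrix (or [VoxelMatrix-class]).
#' @param centroids k x p centroid matrix.
#' @param assignments Integer vector in 1..k, one per row.
#' @return Numeric scalar.
#' @export
kmeansSSE <- function(x, centroids, assignments) {
    x <- asVoxelValues(x)
    if (length(assignments) != nrow(x)) stop("assignment length mismatch")
    if (any(assignments < 1L | assignments > nrow(centroids))) {
        stop("assignment index out of range")
    }
    sum((x - centroids[assignments, , drop = FALSE])^2)
}

#' Select the number of habitats by the elbow rule
#'
#' Fits K-means for every k in `kRange` (best of `nInit` restarts each) and
#' formalizes the elbow as the k whose point on the min-max-normalized
#' (k, SSE) curve lies farthest (perpendicular distance) from the chord
#' joining the curve's endpoints. Ties break toward the smallest k, so an
#' exactly linear SSE curve returns `min(kRange)`. A non-monotone SSE curve
#' (restarts too few) triggers a warning but selection proceeds.
#'
#' @param x Voxel matrix (or [VoxelMatrix-class]).
#' @param kRange Candidate k values (default `2:8`).
#' @inheritParams kmeansFit
#' @return List with `kStar` (selected k), `sseCurve` (data.frame `k`,
#'   `sse`, `chordDistance`), and `fits` (per-k [kmeansFit()] results).
#' @examples
#' vox <- simulateHabitatVoxels(5000, seed = 1)
#' sel <- selectKElbow(vox$values, kRange = 2:6, nInit = 3, seed = 1)
#' sel$kStar
#' @export
selectKElbow <- function(x, kRange = 2:8, nInit = 10, maxIter = 300,
                         tol = 1e-4, seed = NULL) {
    x <- asVoxelValues(x)
    kRange <- sort(unique(as.integer(kRange)))
    if (length(kRange) < 2L) stop("need at least two candidate k values")
    if (nrow(x) < max(kRange)) stop("size error: fewer voxels than max(kRange)")
    if (!is.null(seed)) set.seed(seed)
    fits <- lapply(kRange, function(k) {
        kmeansFit(x, k, nInit = nInit, maxIter = maxIter, tol = tol)
    })
    sse <- vapply(fits, function(f) f$model@sse, 0)
    if (any(diff(sse) > 0)) {
        warning("SSE curve is not monotone non-increasing; ",
                "consider more restarts")
    }
    eb <- elbowPoint(kRange, sse)
    names(fits) <- paste0("k", kRange)
    list(kStar = eb$kStar,
         sseCurve = data.frame(k = kRange, sse = sse,
                               chordDistance = eb$chordDistance),
         fits = fits)
}

#' Locate the elbow of an SSE curve
#'
#' Normalizes both axes of the (k, SSE) curve to `[0, 1]` (min-max) and
#' returns the k whose point lies at maximum perpendicular distance from
#' the chord joining the curve's endpoints. Ties break toward the smallest
#' k; for an exactly linear curve every distance is 0 and the smallest k is
#' returned.
#'
#' @param kValues Increasing integer vector of candidate k.
#' @param sse SSE value per k.
#' @return List with `kStar` and `chordDistance` (per candidate).
#' @examples
#' elbowPoint(1:5, c(10, 6, 2, 1.5, 1))$kStar
#' @export
elbowPoint <- function(kValues, sse) {
    stopifnot(length(kValues) == length(sse), length(kValues) >= 2,
              !is.unsorted(kValues))
    kn <- (kValues - min(kValues)) / max(max(kValues) - min(kValues), 1)
    rng <- max(sse) - min(sse)
    sn <- if (rng > 0) (sse - min(sse)) / rng else rep(0, length(sse))
    # perpendicular distance of each normalized point to the endpoint chord
    x1 <- kn[1]; y1 <- sn[1]
    x2 <- kn[length(kn)]; y2 <- sn[length(sn)]
    chordLen <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    dist <- abs((y2 - y1) * kn - (x2 - x1) * sn + x2 * y1 - y2 * x1) /
        max(chordLen, .Machine$double.eps)
    list(kStar = kValues[which.max(dist)], # first max = smallest k on ties
         chordDistance = dist)
}

#' Canonicalize habitat ordering
#'
#' Reorders centroid rows by strictly descending CMP mean (ties broken by
#' descending NP, then EP) and remaps assignments accordingly, so habitat 1
#' is always the most strongly corticomedullary-enhancing subregion. The
#' result is independent of input row order; an already-canonical model is
#' returned unchanged.
#'
#' @param model A [HabitatModel-class].
#' @param assignments Optional integer assignments to remap.
#' @return List with `model` and (if supplied) remapped `assignments`.
#' @export
canonicalizeModel <- function(model, assignments = NULL) {
    stopifnot(is(model, "HabitatModel"))
    cen <- model@centroids
    ord <- order(-cen[, 1], -cen[, 2], -cen[, 3])
    cen <- cen[ord, , drop = FALSE]
    rownames(cen) <- paste0("H", seq_len(model@k))
    meta <- model@fitMeta
    meta$canonical <- TRUE
    newModel <- new("HabitatModel", k = model@k, centroids = cen,
                    sse = model@sse, fitMeta = meta)
    out <- list(model = newModel)
    if (!is.null(assignments)) {
        remap <- integer(model@k)
        remap[ord] <- seq_len(model@k)
        out$assignments <- remap[assignments]
    }
    out
}

#' Fit a pooled habitat model over a cohort
#'
#' Concatenates the voxel matrices of the selected patients into one pooled
#' N x 3 matrix, runs [selectKElbow()] when `k` is not fixed, fits K-means,
#' and returns the canonicalized model together with per-patient
#' assignments. `scope = "all_patients"` pools every patient (the
#' convention of fitting centroids on the whole cohort) and emits a
#' data-leakage warning, since validation voxels then inform the centroids;
#' the default `"train_only"` pools only `trainIdx`.
#'
#' @param matrices List of [VoxelMatrix-class] objects (or N x 3 matrices).
#' @param k Fixed number of habitats, or `NULL` to select by elbow.
#' @param kRange Candidate range when `k` is `NULL`.
#' @param scope `"train_only"` (default) or `"all_patients"`.
#' @param trainIdx Indices of training patients (defaults to all, in which
#'   case the two scopes coincide).
#' @inheritParams kmeansFit
#' @return List with `model` (canonical [HabitatModel-class]), `kStar`,
#'   `sseCurve` (`NULL` when `k` was fixed), and `assignments` (list, one
#'   integer vector per *pooled* patient, named by patient).
#' @export
fitCohortHabitats <- function(matrices, k = NULL, kRange = 2:8,
                              scope = c("train_only", "all_patients"),
                              trainIdx = NULL, nInit = 10, maxIter = 300,
                              tol = 1e-4, seed = NULL) {
    scope <- match.arg(scope)
    if (length(matrices) == 0L) stop("empty cohort")
    if (is.null(trainIdx)) trainIdx <- seq_along(matrices)
    use <- if (scope == "all_patients") seq_along(matrices) else trainIdx
    if (scope == "all_patients" &&
        length(trainIdx) < length(matrices)) {
        warning("scope = 'all_patients' pools validation voxels into ",
                "centroid fitting (information leakage)")
    }
    vals <- lapply(matrices[use], asVoxelValues)
    pooled <- do.call(rbind, vals)
    nPer <- vapply(vals, nrow, 0L)

    sseCurve <- NULL
    if (is.null(k)) {
        sel <- selectKElbow(pooled, kRange = kRange, nInit = nInit,
                            maxIter = maxIter, tol = tol, seed = seed)
        k <- sel$kStar
        sseCurve <- sel$sseCurve
        fit <- sel$fits[[paste0("k", k)]]
    } else {
        fit <- kmeansFit(pooled, k, nInit = nInit, maxIter = maxIter,
                         tol = tol, seed = seed)
    }
    can <- canonicalizeModel(fit$model, fit$assignments)
    splitIdx <- rep(seq_along(use), nPer)
    assignments <- split(can$assignments, splitIdx)
    nms <- names(matrices)[use]
    if (!is.null(nms)) names(assignments) <- nms
    list(model = can$model, kStar = k, sseCurve = sseCurve,
         assignments = assignments)
}

#' Assign voxels to habitats of a fitted model
#'
#' Nearest-centroid assignment in squared Euclidean distance; ties go to
#' the lowest habitat index.
#'
#' @param model A canonical [HabitatModel-class].
#' @param x Voxel matrix (or [VoxelMatrix-class]).
#' @return Integer vector of habitat labels (1..k).
#' @export
assignHabitats <- function(model, x) {
    stopifnot(is(model, "HabitatModel"))
    x <- asVoxelValues(x)
    if (ncol(x) != ncol(model@centroids)) {
        stop("dimension mismatch: voxels have ", ncol(x), " phases, model ",
             ncol(model@centroids))
    }
    d2 <- vapply(seq_len(model@k), function(c) {
        rowSums(sweep(x, 2, model@centroids[c, ])^2)
    }, numeric(nrow(x)))
    d2 <- matrix(d2, nrow = nrow(x))
    max.col(-d2, ties.method = "first")
}

#' Habitat volume fractions of one VOI
#'
#' `F_i = (# voxels in habitat i within the VOI) / (# voxels within the
#' VOI)`, stored as decimals in `[0, 1]` (multiply by 100 at report time for
#' percentages). Habitats absent from the VOI get fraction 0.
#'
#' @param labels Integer habitat labels (1..k) of the VOI voxels.
#' @param k Number of habitats.
#' @return Named numeric vector `F1..Fk` summing to 1.
#' @examples
#' habitatFractions(c(1, 1, 2, 3), k = 4)
#' @export
habitatFractions <- function(labels, k) {
    if (length(labels) == 0L) stop("empty-VOI error: no labels")
    if (any(labels < 1L | labels > k)) stop("labels outside 1..k")
    f <- tabulate(labels, nbins = k) / length(labels)
    names(f) <- paste0("F", seq_len(k))
    f
}

#' Habitat fractions for a list of patients
#'
#' Applies [assignHabitats()] and [habitatFractions()] per patient.
#'
#' @param model A canonical [HabitatModel-class].
#' @param matrices List of [VoxelMatrix-class] objects or matrices.
#' @return data.frame with `patientId` and columns `F1..Fk`.
#' @export
cohortFractions <- function(model, matrices) {
    ids <- names(matrices)
    if (is.null(ids)) ids <- as.character(seq_along(matrices))
    rows <- lapply(seq_along(matrices), function(i) {
        labs <- assignHabitats(model, matrices[[i]])
        habitatFractions(labs, model@k)
    })
    out <- data.frame(patientId = ids, do.call(rbind, rows),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Per-habitat per-phase HU summary
#'
#' Mean and SD of member-voxel HU per habitat and phase, the quantitative
#' characterization that accompanies a habitat model.
#'
#' @param x Pooled voxel matrix (or [VoxelMatrix-class]).
#' @param assignments Integer habitat labels, one per row of `x`.
#' @param k Number of habitats (default `max(assignments)`).
#' @return data.frame with columns `habitat`, `phase`, `mean`, `sd`, `n`.
#' @export
summarizeHabitats <- function(x, assignments, k = max(assignments)) {
    x <- asVoxelValues(x)
    phases <- colnames(x)
    if (is.null(phases)) phases <- c("CMP", "NP", "EP")[seq_len(ncol(x))]
    out <- expand.grid(habitat = seq_len(k), phase = phases,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out$mean <- NA_real_; out$sd <- NA_real_; out$n <- 0L
    for (h in seq_len(k)) {
        rows <- assignments == h
        for (p in seq_along(phases)) {
            i <- which(out$habitat == h & out$phase == phases[p])
            out$n[i] <- sum(rows)
            if (any(rows)) {
                out$mean[i] <- mean(x[rows, p])
                out$sd[i] <- if (sum(rows) > 1) sd(x[rows, p]) else 0
            }
        }
    }
    out
}

#' Persist and restore habitat models
#'
#' JSON serialization of k, canonical centroids, SSE and fit metadata.
#'
#' @param model A [HabitatModel-class].
#' @param path JSON file path.
#' @return `writeHabitatModel()`: the path, invisibly;
#'   `readHabitatModel()`: the model.
#' @export
writeHabitatModel <- function(model, path) {
    stopifnot(is(model, "HabitatModel"))
    obj <- list(k = model@k, centroids = model@centroids,
                phases = colnames(model@centroids), sse = model@sse,
                fitMeta = model@fitMeta)
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeHabitatModel
#' @export
readHabitatModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    cen <- matrix(as.numeric(obj$centroids), nrow = obj$k)
    colnames(cen) <- obj$phases
    rownames(cen) <- paste0("H", seq_len(obj$k))
    meta <- obj$fitMeta
    meta$canonical <- isTRUE(meta$canonical)
    new("HabitatModel", k = as.integer(obj$k), centroids = cen,
        sse = as.numeric(obj$sse), fitMeta = meta)
}
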