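## Central S4 containers for the habitat-imaging pipeline.

#' Aligned triphasic CT volumes with a tumor mask
#'
#' Holds the three contrast-enhancement phases (corticomedullary `cmp`,
#' nephrographic `np`, excretory `ep`) of one patient as 3-D Hounsfield-unit
#' arrays, together with a binary volume-of-interest mask and the shared
#' voxel geometry. All four arrays must live on one grid: the pipeline
#' assumes rigid registration was done upstream and enforces geometric
#' identity instead.
#'
#' @slot cmp,np,ep 3-D numeric arrays, Hounsfield units.
#' @slot mask 3-D array with values 0/1; 1 marks tumor voxels.
#' @slot spacing Voxel spacing in mm (length 3).
#' @slot origin World coordinate of the first voxel in mm (length 3).
#' @slot orientation 3x3 direction-cosine matrix mapping voxel axes to
#'   world axes.
#' @seealso [readPhaseStack()], [extractVoxelMatrix()], [generatePhantom()]
#' @export
setClass("PhaseStack",
    representation(
        cmp = "array", np = "array", ep = "array", mask = "array",
        spacing = "numeric", origin = "numeric", orientation = "matrix"
    )
)

setValidity("PhaseStack", function(object) {
    msgs <- character()
    d <- dim(object@cmp)
    if (length(d) != 3L) msgs <- c(msgs, "volumes must be 3-D arrays")
    for (nm in c("np", "ep", "mask")) {
        if (!identical(dim(slot(object, nm)), d)) {
            msgs <- c(msgs, sprintf("'%s' dimensions differ from 'cmp'", nm))
        }
    }
    mv <- unique(as.vector(object@mask))
    if (any(abs(mv - round(mv)) > 1e-6) || !all(round(mv) %in% c(0, 1))) {
        msgs <- c(msgs, "mask values must be 0/1")
    }
    if (length(object@spacing) != 3L || any(object@spacing <= 0)) {
        msgs <- c(msgs, "spacing must be 3 positive values (mm)")
    }
    if (length(object@origin) != 3L) msgs <- c(msgs, "origin must have length 3")
    if (!identical(dim(object@orientation), c(3L, 3L))) {
        msgs <- c(msgs, "orientation must be a 3x3 matrix")
    }
    if (length(msgs)) msgs else TRUE
})

#' Masked-voxel HU matrix of one patient
#'
#' The N x 3 matrix of Hounsfield-unit triplets (columns `CMP`, `NP`, `EP`)
#' for the N voxels inside the tumor mask, in a fixed traversal order
#' (x fastest, then y, then z), with the voxel coordinates retained so
#' labels can be mapped back into the volume.
#'
#' @slot values N x 3 numeric matrix, columns `CMP`, `NP`, `EP`.
#' @slot coords N x 3 integer matrix of 1-based voxel indices (x, y, z).
#' @slot patientId Character scalar.
#' @seealso [extractVoxelMatrix()], [assignHabitats()]
#' @export
setClass("VoxelMatrix",
    representation(values = "matrix", coords = "matrix", patientId = "character")
)

setValidity("VoxelMatrix", function(object) {
    msgs <- character()
    if (ncol(object@values) != 3L) msgs <- c(msgs, "'values' must have 3 columns")
    if (!all(is.finite(object@values))) msgs <- c(msgs, "non-finite HU values")
    if (nrow(object@coords) != nrow(object@values)) {
        msgs <- c(msgs, "'coords' and 'values' row counts differ")
    }
    if (length(msgs)) msgs else TRUE
})

#' Fitted habitat clustering model
#'
#' K-means centroids over (CMP, NP, EP) HU triplets in canonical order
#' (strictly non-increasing CMP column; ties broken by NP then EP), the
#' within-cluster sum of squared errors on the fitting data, and the fit
#' metadata needed to reproduce the model.
#'
#' @slot k Number of habitats.
#' @slot centroids k x 3 matrix (rows = habitats, columns `CMP`,`NP`,`EP`).
#' @slot sse Within-cluster sum of squared Euclidean distances at the fit.
#' @slot fitMeta List: `nInit`, `maxIter`, `tol`, `seed`, `nVoxelsFit`,
#'   `converged`, and `canonical` (logical).
#' @seealso [kmeansFit()], [fitCohortHabitats()], [assignHabitats()]
#' @export
setClass("HabitatModel",
    representation(k = "integer", centroids = "matrix", sse = "numeric",
                   fitMeta = "list")
)

setValidity("HabitatModel", function(object) {
    msgs <- character()
    if (object@k < 1L) msgs <- c(msgs, "k must be >= 1")
    if (nrow(object@centroids) != object@k || ncol(object@centroids) != 3L) {
        msgs <- c(msgs, "centroids must be k x 3")
    }
    if (!all(is.finite(object@centroids))) msgs <- c(msgs, "non-finite centroids")
    if (length(object@sse) != 1L || object@sse < 0) {
        msgs <- c(msgs, "sse must be a single nonnegative number")
    }
    if (length(msgs)) msgs else TRUE
})

#' Maximum-likelihood logistic regression fit
#'
#' Thin, serializable container around a binomial GLM: coefficient vector
#' (log-odds scale), observed-information covariance, log-likelihood and
#' convergence/separation diagnostics. The underlying [stats::glm] object is
#' kept in `glmFit` for downstream likelihood-ratio tests.
#'
#' @slot variables Predictor names (excluding the intercept).
#' @slot coefficients Named coefficient vector including `(Intercept)`.
#' @slot vcov Covariance matrix of the coefficients.
#' @slot logLik Maximized log-likelihood.
#' @slot nObs Number of observations.
#' @slot converged,separation Logical flags; `separation` marks fits where
#'   fitted probabilities reached 0/1 numerically (complete or
#'   quasi-complete separation).
#' @slot selection List describing a stepwise selection path (empty for
#'   direct fits): `removed`, `path`.
#' @slot glmFit The underlying `glm` object.
#' @seealso [fitLogistic()], [stepwiseBackward()], [oddsRatios()]
#' @export
setClass("LogisticFit",
    representation(variables = "character", coefficients = "numeric",
                   vcov = "matrix", logLik = "numeric", nObs = "integer",
                   converged = "logical", separation = "logical",
                   selection = "list", glmFit = "ANY")
)

setValidity("LogisticFit", function(object) {
    msgs <- character()
    if (length(object@coefficients) != length(object@variables) + 1L) {
        msgs <- c(msgs, "coefficient count must equal variable count + 1")
    }
    v <- object@vcov
    if (nrow(v) != length(object@coefficients)) {
        msgs <- c(msgs, "vcov dimension mismatch")
    } else if (any(abs(v - t(v)) > 1e-8 * (1 + max(abs(v))))) {
        msgs <- c(msgs, "vcov must be symmetric")
    }
    if (length(msgs)) msgs else TRUE
})

#' Points-based nomogram representation of a logistic model
#'
#' Maps each predictor's value to a points score (the predictor with the
#' largest coefficient-times-range spans exactly 0-100 points) and the
#' points total back to a predicted probability through the reconstructed
#' linear predictor; predictions are therefore identical to the source
#' logistic fit.
#'
#' @slot variables Predictor names.
#' @slot beta Coefficients of the predictors (log-odds per unit).
#' @slot ref Reference value per predictor (the range end scoring 0 points).
#' @slot lo,hi Observed predictor ranges used to scale the points.
#' @slot pointsPerUnit Points awarded per unit increase of each predictor.
#' @slot scalePerPoint Log-odds per point (common scale).
#' @slot intercept Intercept of the source fit.
#' @seealso [buildNomogram()], [nomogramPredict()]
#' @export
setClass("Nomogram",
    representation(variables = "character", beta = "numeric", ref = "numeric",
                   lo = "numeric", hi = "numeric", pointsPerUnit = "numeric",
                   scalePerPoint = "numeric", intercept = "numeric")
)

setValidity("Nomogram", function(object) {
    p <- length(object@variables)
    ok <- all(lengths(list(object@beta, object@ref, object@lo, object@hi,
                           object@pointsPerUnit)) == p)
    if (!ok) return("per-predictor slots must share one length")
    if (any(object@hi < object@lo)) return("hi < lo in predictor ranges")
    TRUE
})

#' Per-habitat tri-phase enhancement kinetics
#'
#' Mean and standard deviation of the Hounsfield-unit value of each habitat
#' in each contrast phase; rows are habitats (canonical CMP-descending
#' order), columns `CMP`, `NP`, `EP`. These parameters drive the synthetic
#' voxel and phantom generators.
#'
#' @slot meanHU,sdHU k x 3 matrices in HU.
#' @seealso [defaultHabitatKinetics()], [simulateHabitatVoxels()]
#' @export
setClass("HabitatKinetics",
    representation(meanHU = "matrix", sdHU = "matrix")
)

setValidity("HabitatKinetics", function(object) {
    msgs <- character()
    if (!identical(dim(object@meanHU), dim(object@sdHU))) {
        msgs <- c(msgs, "meanHU and sdHU dimensions differ")
    }
    if (ncol(object@meanHU) != 3L) msgs <- c(msgs, "need 3 phase columns")
    if (!all(is.finite(object@meanHU))) msgs <- c(msgs, "non-finite means")
    if (any(object@sdHU < 0)) msgs <- c(msgs, "sdHU must be >= 0")
    if (length(msgs)) msgs else TRUE
})

#' Specification of one synthetic tumor phantom
#'
#' @slot gridDim Grid size in voxels (length 3).
#' @slot spacing Voxel spacing in mm (length 3).
#' @slot semiAxes Ellipsoid tumor semi-axes in mm (length 3).
#' @slot composition Habitat volume-fraction targets (sums to 1).
#' @slot kinetics A [HabitatKinetics-class] with one row per habitat.
#' @slot coherence Spatial coherence scale in mm (Gaussian smoothing of the
#'   habitat layout fields; 0 gives spatially independent labels).
#' @slot seed RNG seed.
#' @seealso [phantomSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec",
    representation(gridDim = "integer", spacing = "numeric",
                   semiAxes = "numeric", composition = "numeric",
                   kinetics = "HabitatKinetics", coherence = "numeric",
                   seed = "integer")
)

setValidity("PhantomSpec", function(object) {
    msgs <- character()
    if (length(object@gridDim) != 3L || any(object@gridDim < 1L)) {
        msgs <- c(msgs, "gridDim must be 3 positive integers")
    }
    if (any(object@spacing <= 0) || any(object@semiAxes <= 0)) {
        msgs <- c(msgs, "spacing and semiAxes must be positive")
    }
    if (abs(sum(object@composition) - 1) > 1e-9) {
        msgs <- c(msgs, "composition must sum to 1 (tolerance 1e-9)")
    }
    if (any(object@composition < 0)) msgs <- c(msgs, "composition must be >= 0")
    if (length(object@composition) != nrow(object@kinetics@meanHU)) {
        msgs <- c(msgs, "composition length must match kinetics rows")
    }
    if (object@coherence < 0) msgs <- c(msgs, "coherence must be >= 0")
    if (length(msgs)) msgs else TRUE
})

#' Specification of a synthetic patient cohort
#'
#' Grade-conditional generative parameters for a two-grade (low/high WHO/ISUP)
#' ccRCC cohort: prevalence of high grade, per-grade habitat composition
#' centers (Dirichlet-distributed per patient), sex and maximum-diameter
#' distributions.
#'
#' @slot nPatients Number of patients.
#' @slot prevalence Probability of high grade.
#' @slot compositionLow,compositionHigh Habitat-fraction centers per grade
#'   (each sums to 1, canonical habitat order).
#' @slot concentration Dirichlet concentration (larger = less per-patient
#'   variability around the grade's center).
#' @slot sexMaleProb Length-2 vector `c(low, high)` of male probabilities.
#' @slot diameterMean,diameterSd Length-2 vectors `c(low, high)` of maximum
#'   tumor diameter parameters in mm.
#' @slot kinetics Habitat enhancement kinetics shared by the cohort.
#' @slot spacing Voxel spacing of generated volumes in mm.
#' @slot coherence Spatial coherence in mm for habitat layouts.
#' @slot seed RNG seed.
#' @seealso [cohortSpec()], [generateCohort()]
#' @export
setClass("CohortSpec",
    representation(nPatients = "integer", prevalence = "numeric",
                   compositionLow = "numeric", compositionHigh = "numeric",
                   concentration = "numeric", sexMaleProb = "numeric",
                   diameterMean = "numeric", diameterSd = "numeric",
                   kinetics = "HabitatKinetics", spacing = "numeric",
                   coherence = "numeric", seed = "integer")
)

setValidity("CohortSpec", function(object) {
    msgs <- character()
    if (object@nPatients < 1L) msgs <- c(msgs, "nPatients must be >= 1")
    if (object@prevalence <= 0 || object@prevalence >= 1) {
        msgs <- c(msgs, "prevalence must be in (0,1)")
    }
    for (nm in c("compositionLow", "compositionHigh")) {
        v <- slot(object, nm)
        if (abs(sum(v) - 1) > 1e-9 || any(v < 0)) {
            msgs <- c(msgs, sprintf("'%s' must be nonnegative and sum to 1", nm))
        }
    }
    if (any(object@sexMaleProb < 0) || any(object@sexMaleProb > 1)) {
        msgs <- c(msgs, "sexMaleProb must be probabilities")
    }
    if (object@concentration <= 0) msgs <- c(msgs, "concentration must be > 0")
    if (length(msgs)) msgs else TRUE
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "PhaseStack", function(object) {
    d <- dim(object@cmp)
    cat("PhaseStack:", paste(d, collapse = " x "), "voxels,",
        "spacing", paste(format(object@spacing), collapse = " x "), "mm\n")
    cat("  tumor voxels:", sum(object@mask != 0), "\n")
})

setMethod("show", "VoxelMatrix", function(object) {
    cat("VoxelMatrix (patient ", object@patientId, "): ",
        nrow(object@values), " voxels x 3 phases (CMP, NP, EP)\n", sep = "")
})

setMethod("show", "HabitatModel", function(object) {
    cat("HabitatModel: k =", object@k, "habitats",
        if (isTRUE(object@fitMeta$canonical)) "(canonical order)" else "", "\n")
    cat("  SSE =", format(object@sse), "on", object@fitMeta$nVoxelsFit,
        "voxels\n")
    print(round(object@centroids, 3))
})

setMethod("show", "LogisticFit", function(object) {
    cat("LogisticFit:", length(object@variables), "predictor(s),",
        object@nObs, "observations\n")
    if (!object@converged) cat("  WARNING: IRLS did not converge\n")
    if (object@separation) cat("  WARNING: separation detected\n")
    print(round(object@coefficients, 4))
})

setMethod("show", "Nomogram", function(object) {
    cat("Nomogram over", length(object@variables), "predictor(s):\n")
    pts <- abs(object@pointsPerUnit) * (object@hi - object@lo)
    df <- data.frame(variable = object@variables, ref = object@ref,
                     maxPoints = round(pts, 1))
    print(df, row.names = FALSE)
})

## ---- accessors -------------------------------------------------------------

#' Accessors for habitat models
#'
#' `centroids()` returns the k x 3 centroid matrix, `nHabitats()` the number
#' of habitats, `modelSSE()` the within-cluster sum of squared errors of the
#' fit.
#'
#' @param object A [HabitatModel-class].
#' @return `centroids()`: numeric matrix; `nHabitats()`: integer;
#'   `modelSSE()`: numeric scalar.
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))

#' @rdname centroids
#' @export
setMethod("centroids", "HabitatModel", function(object) object@centroids)

#' @rdname centroids
#' @export
setGeneric("nHabitats", function(object) standardGeneric("nHabitats"))

#' @rdname centroids
#' @export
setMethod("nHabitats", "HabitatModel", function(object) object@k)

#' @rdname centroids
#' @export
setGeneric("modelSSE", function(object) standardGeneric("modelSSE"))

#' @rdname centroids
#' @export
setMethod("modelSSE", "HabitatModel", function(object) object@sse)

#' Accessors for phase stacks
#'
#' `phaseVolume()` extracts one phase (or the mask) as a plain array;
#' `maskVolume()` is shorthand for the mask; `voxelSpacing()` returns the
#' spacing in mm.
#'
#' @param object A [PhaseStack-class].
#' @param phase One of `"cmp"`, `"np"`, `"ep"`, `"mask"`.
#' @return An array, or a numeric spacing vector.
#' @export
setGeneric("phaseVolume", function(object, phase) standardGeneric("phaseVolume"))

#' @rdname phaseVolume
#' @export
setMethod("phaseVolume", "PhaseStack", function(object, phase) {
    slot(object, match.arg(phase, c("cmp", "np", "ep", "mask")))
})

#' @rdname phaseVolume
#' @export
setGeneric("maskVolume", function(object) standardGeneric("maskVolume"))

#' @rdname phaseVolume
#' @export
setMethod("maskVolume", "PhaseStack", function(object) object@mask)

#' @rdname phaseVolume
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))

#' @rdname phaseVolume
#' @export
setMethod("voxelSpacing", "PhaseStack", function(object) object@spacing)

#' Values and coordinates of a voxel matrix
#'
#' @param object A [VoxelMatrix-class].
#' @return `voxelValues()`: the N x 3 HU matrix; `voxelCoords()`: the N x 3
#'   integer coordinate matrix.
#' @export
setGeneric("voxelValues", function(object) standardGeneric("voxelValues"))

#' @rdname voxelValues
#' @export
setMethod("voxelValues", "VoxelMatrix", function(object) object@values)

#' @rdname voxelValues
#' @export
setGeneric("voxelCoords", function(object) standardGeneric("voxelCoords"))

#' @rdname voxelValues
#' @export
setMethod("voxelCoords", "VoxelMatrix", function(object) object@coords)
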