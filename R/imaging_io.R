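## Volume I/O (NIfTI-1 via RNifti), grid resampling and voxel-matrix
## extraction. Registration is assumed done upstream; geometry equality
## across the four volumes of a patient is enforced instead.

geometryFromNifti <- function(img) {
    xf <- RNifti::xform(img)
    dirs <- xf[1:3, 1:3]
    spacing <- sqrt(colSums(dirs^2))
    if (any(spacing == 0)) {
        spacing <- RNifti::pixdim(img)[1:3]
        dirs <- diag(3) * spacing
    }
    list(spacing = as.numeric(spacing),
         origin = as.numeric(xf[1:3, 4]),
         orientation = sweep(dirs, 2, spacing, "/"))
}

#' Read and write single volumes
#'
#' `writeVolume()` writes a 3-D array as NIfTI-1 with the given geometry
#' (spacing in mm, world origin, direction cosines); `readVolume()` returns
#' the array plus its geometry.
#'
#' @param arr 3-D array.
#' @param path File path (`.nii` or `.nii.gz`).
#' @param spacing,origin,orientation Voxel geometry.
#' @param datatype NIfTI datatype passed to [RNifti::writeNifti()].
#' @return `readVolume()`: list with `data`, `spacing`, `origin`,
#'   `orientation`. `writeVolume()`: the path, invisibly.
#' @export
writeVolume <- function(arr, path, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        orientation = diag(3), datatype = "auto") {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- spacing
    xf <- diag(4)
    xf[1:3, 1:3] <- orientation %*% diag(spacing)
    xf[1:3, 4] <- origin
    RNifti::sform(img) <- structure(xf, code = 2L)
    RNifti::writeNifti(img, path, datatype = datatype)
    invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    img <- RNifti::readNifti(path)
    geo <- geometryFromNifti(img)
    arr <- array(as.numeric(img), dim = dim(img))
    c(list(data = arr), geo)
}

geometryMatches <- function(a, b, tolSpacing = 1e-3, tolOrigin = 1e-3,
                            tolOrient = 1e-5) {
    identical(dim(a$data), dim(b$data)) &&
        all(abs(a$spacing - b$spacing) <= tolSpacing) &&
        all(abs(a$origin - b$origin) <= tolOrigin) &&
        all(abs(a$orientation - b$orientation) <= tolOrient)
}

#' Read an aligned triphasic phase stack
#'
#' Reads the three phase volumes and the tumor mask and validates that all
#' four share one geometry (dims exactly; spacing and origin within 1e-3 mm;
#' orientation within 1e-5) and that the mask is binary (values within 1e-6
#' of 0/1). An all-zero mask is accepted here and only rejected when voxels
#' are extracted.
#'
#' @param cmpPath,npPath,epPath,maskPath NIfTI file paths.
#' @return A [PhaseStack-class].
#' @seealso [writePhaseStack()], [extractVoxelMatrix()]
#' @export
readPhaseStack <- function(cmpPath, npPath, epPath, maskPath) {
    vols <- lapply(c(cmpPath, npPath, epPath, maskPath), readVolume)
    for (i in 2:4) {
        if (!geometryMatches(vols[[1]], vols[[i]])) {
            stop("alignment error: volume geometries differ (",
                 c(npPath, epPath, maskPath)[i - 1], ")")
        }
    }
    m <- vols[[4]]$data
    if (any(abs(m - round(m)) > 1e-6) || !all(round(m) %in% c(0, 1))) {
        stop("mask error: mask is not binary")
    }
    new("PhaseStack", cmp = vols[[1]]$data, np = vols[[2]]$data,
        ep = vols[[3]]$data, mask = array(round(m), dim(m)),
        spacing = vols[[1]]$spacing, origin = vols[[1]]$origin,
        orientation = vols[[1]]$orientation)
}

#' Write a phase stack to NIfTI files
#'
#' @param stack A [PhaseStack-class].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the four file paths, invisibly.
#' @export
writePhaseStack <- function(stack, dir, prefix = "") {
    stopifnot(is(stack, "PhaseStack"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, paste0(prefix, c("cmp", "np", "ep", "mask"),
                                   ".nii.gz"))
    names(paths) <- c("cmp", "np", "ep", "mask")
    for (nm in c("cmp", "np", "ep")) {
        writeVolume(slot(stack, nm), paths[[nm]], stack@spacing,
                    stack@origin, stack@orientation, datatype = "double")
    }
    writeVolume(stack@mask, paths[["mask"]], stack@spacing, stack@origin,
                stack@orientation, datatype = "uint8")
    invisible(paths)
}

#' Resample a volume to a target spacing
#'
#' Regular-grid resampling with voxel centers at `(index - 1) * spacing` in
#' each axis: intensities by trilinear interpolation (`mode = "linear"`),
#' masks and label maps by nearest neighbor (`mode = "nearest"`). Output
#' dimensions are `ceiling(dim * spacing / targetSpacing)` so the physical
#' extent is preserved; sampling positions outside the source grid clamp to
#' the edge. Resampling to the source spacing returns the input unchanged.
#'
#' @param arr 3-D array.
#' @param spacing Source voxel spacing (mm).
#' @param targetSpacing Target spacing (mm); the analysis default is
#'   `c(1, 1, 3)`.
#' @param mode `"linear"` or `"nearest"`.
#' @return The resampled array.
#' @export
resampleVolume <- function(arr, spacing, targetSpacing = c(1, 1, 3),
                           mode = c("linear", "nearest")) {
    mode <- match.arg(mode)
    if (any(targetSpacing <= 0)) stop("spec error: nonpositive target spacing")
    d <- dim(arr)
    if (all(abs(spacing - targetSpacing) < 1e-12)) return(arr)
    newDim <- pmax(1L, as.integer(ceiling(d * spacing / targetSpacing)))

    # continuous source index (1-based) of each target voxel center, clamped
    ci <- lapply(1:3, function(ax) {
        pos <- (seq_len(newDim[ax]) - 1) * targetSpacing[ax] / spacing[ax] + 1
        pmin(pmax(pos, 1), d[ax])
    })

    if (mode == "nearest") {
        idx <- lapply(1:3, function(ax) pmin(pmax(round(ci[[ax]]), 1), d[ax]))
        return(array(arr[idx[[1]], idx[[2]], idx[[3]]], newDim))
    }

    lo <- lapply(1:3, function(ax) pmax(pmin(floor(ci[[ax]]), d[ax] - 1L), 1L))
    fr <- lapply(1:3, function(ax) ci[[ax]] - lo[[ax]])

    out <- array(0, newDim)
    for (dz in 0:1) {
        wz <- if (dz == 0) 1 - fr[[3]] else fr[[3]]
        iz <- pmin(lo[[3]] + dz, d[3])
        for (dy in 0:1) {
            wy <- if (dy == 0) 1 - fr[[2]] else fr[[2]]
            iy <- pmin(lo[[2]] + dy, d[2])
            for (dx in 0:1) {
                wx <- if (dx == 0) 1 - fr[[1]] else fr[[1]]
                ix <- pmin(lo[[1]] + dx, d[1])
                w <- outer(outer(wx, wy), wz)
                out <- out + w * array(arr[ix, iy, iz], newDim)
            }
        }
    }
    out
}

#' Resample a phase stack to the analysis grid
#'
#' Applies [resampleVolume()] to all three phases (trilinear) and the mask
#' (nearest neighbor, so labels stay binary).
#'
#' @param stack A [PhaseStack-class].
#' @param targetSpacing Target spacing in mm (default `c(1, 1, 3)`).
#' @return A resampled [PhaseStack-class].
#' @export
resampleStack <- function(stack, targetSpacing = c(1, 1, 3)) {
    stopifnot(is(stack, "PhaseStack"))
    new("PhaseStack",
        cmp = resampleVolume(stack@cmp, stack@spacing, targetSpacing, "linear"),
        np = resampleVolume(stack@np, stack@spacing, targetSpacing, "linear"),
        ep = resampleVolume(stack@ep, stack@spacing, targetSpacing, "linear"),
        mask = resampleVolume(stack@mask, stack@spacing, targetSpacing,
                              "nearest"),
        spacing = as.numeric(targetSpacing), origin = stack@origin,
        orientation = stack@orientation)
}

#' Extract the N x 3 masked-voxel HU matrix
#'
#' One row per nonzero mask voxel, columns (CMP, NP, EP), in the fixed
#' traversal order with x varying fastest, then y, then z (R's native array
#' order), so repeated calls and label back-mapping are deterministic.
#'
#' @param stack A [PhaseStack-class].
#' @param patientId Identifier stored with the matrix.
#' @return A [VoxelMatrix-class].
#' @export
extractVoxelMatrix <- function(stack, patientId = "patient") {
    stopifnot(is(stack, "PhaseStack"))
    idx <- which(stack@mask != 0)
    if (length(idx) == 0L) stop("empty-VOI error: mask has no nonzero voxels")
    values <- cbind(CMP = stack@cmp[idx], NP = stack@np[idx],
                    EP = stack@ep[idx])
    if (!all(is.finite(values))) {
        stop("data error: non-finite HU values under the mask")
    }
    coords <- arrayInd(idx, dim(stack@mask))
    storage.mode(coords) <- "integer"
    colnames(coords) <- c("x", "y", "z")
    new("VoxelMatrix", values = values, coords = coords,
        patientId = as.character(patientId))
}

#' Write and read habitat label maps
#'
#' `writeHabitatMap()` embeds per-voxel habitat labels (one per masked
#' voxel, in [extractVoxelMatrix()] order) into the reference geometry with
#' 0 outside the mask and writes an unsigned 8-bit NIfTI volume.
#' `readHabitatMap()` reads it back as an integer array.
#'
#' @param labels Integer habitat labels, one per nonzero mask voxel.
#' @param reference The [PhaseStack-class] supplying mask and geometry.
#' @param path Output path.
#' @return `writeHabitatMap()`: the label array, invisibly.
#'   `readHabitatMap()`: integer array.
#' @export
writeHabitatMap <- function(labels, reference, path) {
    stopifnot(is(reference, "PhaseStack"))
    idx <- which(reference@mask != 0)
    if (length(labels) != length(idx)) {
        stop("label/mask length mismatch: ", length(labels), " labels for ",
             length(idx), " mask voxels")
    }
    vol <- array(0L, dim(reference@mask))
    vol[idx] <- as.integer(labels)
    writeVolume(vol, path, reference@spacing, reference@origin,
                reference@orientation, datatype = "uint8")
    invisible(vol)
}

#' @rdname writeHabitatMap
#' @export
readHabitatMap <- function(path) {
    v <- readVolume(path)
    array(as.integer(round(v$data)), dim(v$data))
}
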