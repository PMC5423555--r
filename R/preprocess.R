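#' Resample a volume to isotropic voxel size
#'
#' The output grid is isotropic at \code{targetSpacing} and covers the
#' input's physical extent.  Intensities use the requested interpolation
#' (cubic spline is the conventional choice for MR preprocessing); the FOV
#' mask is resampled with nearest neighbour and re-binarised so that no
#' partial-volume FOV values appear.
#'
#' @param vol a \code{ScalarVolume}.
#' @param targetSpacing isotropic voxel size in mm (> 0).
#' @param interpolation \code{"nearest"}, \code{"linear"} or
#'   \code{"cubic_spline"} (default).
#' @return a \code{ScalarVolume} on the isotropic grid.
#' @export
resampleIsotropic <- function(vol, targetSpacing,
                              interpolation = "cubic_spline") {
  if (!is.finite(targetSpacing) || targetSpacing <= 0)
    stop("targetSpacing must be > 0")
  g <- vol@grid
  extent <- g@shape * g@spacing
  newShape <- pmax(1L, as.integer(round(extent / targetSpacing)))
  # keep voxel-centre alignment of the first voxel corner
  newGrid <- imageGrid3(newShape, targetSpacing,
                        origin = as.numeric(
                          g@origin + g@direction %*%
                            ((targetSpacing - g@spacing) / 2)),
                        direction = g@direction)
  resampleToGrid(vol, newGrid, interpolation)
}

# Resample a volume onto an arbitrary grid (no transform, shared world
# space).  Values outside the source FOV/grid come back as 0 with FOV 0.
resampleToGrid <- function(vol, newGrid, interpolation = "linear") {
  pts <- gridWorldCoords(newGrid)
  vox <- worldToVoxel(vol@grid, pts)
  sv <- sampleAtVoxels(vol, vox, interpolation, useFov = FALSE)
  fv <- sampleAtVoxels(scalarVolume(vol@fov, vol@grid), vox, "nearest",
                       useFov = FALSE)
  # a voxel is inside the new FOV only if its value could actually be
  # interpolated there AND the source FOV covers it
  fov <- array(as.numeric(sv$valid & fv$valid & fv$values > 0.5),
               newGrid@shape)
  vals <- array(sv$values, newGrid@shape)
  vals[fov < 0.5 & !array(sv$valid, newGrid@shape)] <- 0
  scalarVolume(vals, grid = newGrid, fov = fov, modality = vol@modality)
}

#' Intensity non-uniformity correction hook
#'
#' Bias-field correction itself is delegated to a caller-supplied
#' corrector (e.g. an external N4 implementation); the hook only enforces
#' the contract that correction must not change the grid.
#'
#' @param vol a \code{ScalarVolume}.
#' @param corrector a function \code{ScalarVolume -> ScalarVolume}
#'   (default: identity).
#' @return the corrected \code{ScalarVolume}.
#' @export
biasCorrectionHook <- function(vol, corrector = identity) {
  out <- corrector(vol)
  if (!is(out, "ScalarVolume"))
    stop("corrector must return a ScalarVolume")
  if (!sameGrid(out@grid, vol@grid) ||
      !identical(dim(out@values), dim(vol@values)))
    stop("corrector changed the grid; correction must preserve geometry")
  out
}

#' Left-right flip a volume about the mid-sagittal grid plane
#'
#' @param vol a \code{ScalarVolume}.
#' @param axis grid axis representing left-right (default 1).
#' @return the mirrored volume.
#' @export
flipVolume <- function(vol, axis = 1L) {
  scalarVolume(flipArray(vol@values, axis), grid = vol@grid,
               fov = flipArray(vol@fov, axis), modality = vol@modality)
}

flipArray <- function(a, axis = 1L) {
  idx <- rep(list(quote(expr = )), length(dim(a)))
  idx[[axis]] <- rev(seq_len(dim(a)[axis]))
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

#' Left-right flip augmentation of an atlas record
#'
#' All four volumes are mirrored about the mid-sagittal grid plane and the
#' left/right homologous label indices declared in the label dictionary
#' are swapped in the segmentation, so a left femur head voxel becomes a
#' right femur head voxel at the mirrored column.  Flipping twice restores
#' the original record.
#'
#' @param record an \code{AtlasRecord}.
#' @param dict the database \code{\link{labelDictionary}}.
#' @param axis grid axis representing left-right (default 1).
#' @return the flipped \code{AtlasRecord} (id suffixed \code{"_flip"},
#'   flag toggled).
#' @export
leftRightFlip <- function(record, dict = labelDictionary(), axis = 1L) {
  L <- nLabels(record@seg)
  perm <- seq_len(L)
  for (p in dict$lateralPairs) {
    i <- dict$index[[p[1]]] + 1L
    j <- dict$index[[p[2]]] + 1L
    if (i > L || j > L)
      stop("lateral pair ", paste(p, collapse = "/"),
           " outside the record's label range")
    perm[c(i, j)] <- perm[c(j, i)]
  }
  # any lateralised label (by naming convention) must have a declared twin
  lat <- grepl("^(L|R)[A-Z]|left|right", dict$names, ignore.case = FALSE)
  declared <- unlist(dict$lateralPairs)
  if (any(lat & !dict$names %in% declared))
    stop("lateralised label without a declared left/right homologue: ",
         paste(dict$names[lat & !dict$names %in% declared], collapse = ", "))
  probs <- record@seg@probs[, , , perm, drop = FALSE]
  probs <- flipArray(probs, axis)
  newId <- if (record@flipped) sub("_flip$", "", record@id)
           else paste0(record@id, "_flip")
  atlasRecord(newId,
              t2 = flipVolume(record@t2, axis),
              t1 = flipVolume(record@t1, axis),
              ct = flipVolume(record@ct, axis),
              seg = probSegVolume(probs, record@seg@grid),
              flipped = !record@flipped)
}
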