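#' Construct spatial transforms
#'
#' \code{identityTransform} returns the identity mapping;
#' \code{affineTransform} wraps a 4x4 homogeneous matrix;
#' \code{translationTransform} a pure mm translation;
#' \code{displacementTransform} couples an affine with a dense mm
#' displacement field sampled on \code{dispGrid} (pull-back convention:
#' target point x reads the moving image at \code{A x + u(x)}).
#'
#' @param affine 4x4 homogeneous matrix.
#' @param shift numeric(3) translation in mm.
#' @param disp 4-D array (nx, ny, nz, 3) of mm displacements.
#' @param dispGrid the \code{ImageGrid} the displacement lives on.
#' @return a \code{SpatialTransform}.
#' @export
identityTransform <- function() {
  new("SpatialTransform", affine = diag(4), disp = NULL, dispGrid = NULL)
}

#' @rdname identityTransform
#' @export
affineTransform <- function(affine) {
  new("SpatialTransform", affine = affine, disp = NULL, dispGrid = NULL)
}

#' @rdname identityTransform
#' @export
translationTransform <- function(shift) {
  a <- diag(4)
  a[1:3, 4] <- shift
  affineTransform(a)
}

#' @rdname identityTransform
#' @export
displacementTransform <- function(disp, dispGrid, affine = diag(4)) {
  new("SpatialTransform", affine = affine, disp = disp,
      dispGrid = dispGrid)
}

#' Map target-space points through a transform
#'
#' @param transform a \code{SpatialTransform}.
#' @param pts n x 3 matrix of mm points in target space.
#' @return n x 3 matrix of mm points in moving space.
#' @export
transformPoints <- function(transform, pts) {
  pts <- matrix(pts, ncol = 3L)
  A <- transform@affine
  out <- pts %*% t(A[1:3, 1:3]) +
    matrix(A[1:3, 4], nrow(pts), 3L, byrow = TRUE)
  if (!is.null(transform@disp)) {
    out <- out + sampleDisplacement(transform, pts)
  }
  out
}

# Linear interpolation of the displacement field at target points
# (zero displacement outside the stated field grid).
sampleDisplacement <- function(transform, pts) {
  vox <- worldToVoxel(transform@dispGrid, pts)
  u <- matrix(0, nrow(pts), 3L)
  for (c in 1:3) {
    s <- sampleArrayAtVoxels(transform@disp[, , , c], vox, "linear")
    u[, c] <- s$values
  }
  u
}

#' Resample a volume through a spatial transform (pull-back)
#'
#' Every voxel of the output grid reads the moving volume at its
#' transformed location.  Reads outside the moving grid or FOV yield FOV 0
#' in the output (masks never invent data).  Nearest-neighbour
#' interpolation is mandatory for categorical labels and preserves
#' one-hot segmentations.
#'
#' @param vol a \code{ScalarVolume}, \code{ProbSegVolume} or
#'   \code{CategoricalSegVolume} (the moving image).
#' @param transform a \code{SpatialTransform} mapping target to moving
#'   space.
#' @param targetGrid output \code{ImageGrid} (default: the transform's
#'   displacement grid, else the input grid).
#' @param interpolation \code{"nearest"}, \code{"linear"} or
#'   \code{"cubic_spline"}.
#' @return the propagated volume on \code{targetGrid}.
#' @export
applyTransform <- function(vol, transform, targetGrid = NULL,
                           interpolation = "linear") {
  if (is.null(targetGrid))
    targetGrid <- if (!is.null(transform@disp)) transform@dispGrid
                  else imageGrid(vol)
  pts <- transformPoints(transform, gridWorldCoords(targetGrid))
  if (is(vol, "ScalarVolume")) {
    vox <- worldToVoxel(vol@grid, pts)
    sv <- sampleAtVoxels(vol, vox, interpolation, useFov = TRUE)
    vals <- array(sv$values, targetGrid@shape)
    fov <- array(as.numeric(sv$valid), targetGrid@shape)
    return(scalarVolume(vals, grid = targetGrid, fov = fov,
                        modality = vol@modality))
  }
  if (is(vol, "CategoricalSegVolume")) {
    if (interpolation != "nearest")
      stop("categorical labels must be propagated with nearest neighbour")
    vox <- worldToVoxel(vol@grid, pts)
    s <- sampleArrayAtVoxels(vol@labels + 0.0, vox, "nearest")
    lab <- array(as.integer(s$values), targetGrid@shape)
    lab[!array(s$valid, targetGrid@shape)] <- 0L
    return(categoricalSegVolume(lab, vol@nLabels, targetGrid))
  }
  if (is(vol, "ProbSegVolume")) {
    L <- nLabels(vol)
    vox <- worldToVoxel(vol@grid, pts)
    out <- matrix(0, prod(targetGrid@shape), L)
    if (interpolation == "nearest") {
      srcLab <- array(max.col(matrix(vol@probs, ncol = L), "first") - 1,
                      gridShape(vol@grid))
      s <- sampleArrayAtVoxels(srcLab, vox, "nearest")
      lab <- as.integer(s$values)
      lab[!s$valid] <- 0L
      out[cbind(seq_len(nrow(out)), lab + 1L)] <- 1
    } else {
      for (l in seq_len(L)) {
        s <- sampleArrayAtVoxels(vol@probs[, , , l], vox, interpolation)
        out[, l] <- pmax(0, s$values)
      }
      bad <- rowSums(out) <= 1e-12
      out[bad, ] <- 0
      out[bad, 1] <- 1
      out <- out / rowSums(out)
    }
    return(probSegVolume(array(out, c(targetGrid@shape, L)), targetGrid))
  }
  stop("unsupported volume type for applyTransform")
}

#' Jacobian determinant of a transform's total map
#'
#' Finite-difference Jacobian of \eqn{x \mapsto A x + u(x)} on the
#' displacement grid; used to guard against folding.
#'
#' @param transform a \code{SpatialTransform} with a displacement field.
#' @return 3-D array of determinants.
#' @export
jacobianDeterminant <- function(transform) {
  if (is.null(transform@disp)) stop("transform has no displacement field")
  g <- transform@dispGrid
  u <- transform@disp
  A <- transform@affine[1:3, 1:3]
  sh <- g@shape
  grad <- vector("list", 9L)
  k <- 1L
  for (c in 1:3) {
    for (ax in 1:3) {
      grad[[k]] <- centralDiff(u[, , , c], ax) / g@spacing[ax]
      k <- k + 1L
    }
  }
  # det of (A + du/dx) per voxel; du given in world mm per world mm
  # (direction assumed axis-aligned for this diagnostic)
  J11 <- A[1, 1] + grad[[1]]; J12 <- A[1, 2] + grad[[2]]; J13 <- A[1, 3] + grad[[3]]
  J21 <- A[2, 1] + grad[[4]]; J22 <- A[2, 2] + grad[[5]]; J23 <- A[2, 3] + grad[[6]]
  J31 <- A[3, 1] + grad[[7]]; J32 <- A[3, 2] + grad[[8]]; J33 <- A[3, 3] + grad[[9]]
  J11 * (J22 * J33 - J23 * J32) - J12 * (J21 * J33 - J23 * J31) +
    J13 * (J21 * J32 - J22 * J31)
}

centralDiff <- function(a, axis) {
  d <- dim(a)
  n <- d[axis]
  idxP <- rep(list(quote(expr = )), length(d))
  idxM <- idxP
  idxP[[axis]] <- c(2:n, n)
  idxM[[axis]] <- c(1L, 1:(n - 1L))
  diff <- do.call(`[`, c(list(a), idxP, list(drop = FALSE))) -
    do.call(`[`, c(list(a), idxM, list(drop = FALSE)))
  # interior: central difference over 2 voxels; edges: one-sided over 1
  den <- array(2, d)
  idxE <- rep(list(quote(expr = )), length(d))
  idxE[[axis]] <- c(1L, n)
  den <- do.call(`[<-`, c(list(den), idxE, list(1)))
  diff / den
}

# Dense displacement of a transform resampled onto another grid (linear),
# used for pyramid level changes and warm starts.
resampleDisplacement <- function(transform, newGrid) {
  if (is.null(transform@disp)) {
    return(array(0, c(newGrid@shape, 3L)))
  }
  pts <- gridWorldCoords(newGrid)
  u <- sampleDisplacement(transform, pts)
  array(u, c(newGrid@shape, 3L))
}

#' Compose two transforms
#'
#' Returns the transform equivalent to applying \code{outer} after
#' \code{inner} in pull-back terms: a target point x is first mapped by
#' \code{inner}, the result by \code{outer}; i.e. sampling a volume with
#' the composition equals sampling through \code{inner} a volume already
#' propagated through \code{outer}.
#'
#' @param outer,inner \code{SpatialTransform}s.
#' @param grid grid on which to sample the composed displacement (default:
#'   \code{inner}'s displacement grid, required if both are affine-free).
#' @return a \code{SpatialTransform} with a dense displacement.
#' @export
composeTransforms <- function(outer, inner, grid = NULL) {
  if (is.null(grid)) grid <- inner@dispGrid
  if (is.null(grid)) {
    if (is.null(outer@disp) && is.null(inner@disp))
      return(affineTransform(outer@affine %*% inner@affine))
    grid <- outer@dispGrid
  }
  pts <- gridWorldCoords(grid)
  mapped <- transformPoints(outer, transformPoints(inner, pts))
  disp <- mapped - pts
  displacementTransform(array(disp, c(grid@shape, 3L)), grid,
                        affine = diag(4))
}

#' Write / read a spatial transform on disk
#'
#' The dense displacement field is stored as a 3-vector NIfTI (a 4-D
#' volume with three components, mm, pull-back convention, noted in the
#' header description); the 4x4 affine goes to a plain text file next to
#' it (\code{<prefix>_affine.txt}).
#'
#' @param transform a \code{SpatialTransform}.
#' @param prefix output path prefix; files are
#'   \code{<prefix>_disp.nii.gz} and \code{<prefix>_affine.txt}.
#' @return \code{prefix}, invisibly.
#' @export
writeTransform <- function(transform, prefix) {
  utils::write.table(transform@affine, paste0(prefix, "_affine.txt"),
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(transform@disp)) {
    disp <- transform@disp
    attr(disp, "pixdim") <- transform@dispGrid@spacing
    img <- RNifti::asNifti(disp, datatype = "double")
    xf <- structure(xformFromGrid(transform@dispGrid), code = 2L)
    RNifti::qform(img) <- xf
    RNifti::sform(img) <- xf
    img$descrip <- "displacement mm, pull-back"
    RNifti::writeNifti(img, paste0(prefix, "_disp.nii.gz"),
                       datatype = "double")
  }
  invisible(prefix)
}

#' @rdname writeTransform
#' @export
readTransform <- function(prefix) {
  affine <- as.matrix(utils::read.table(paste0(prefix, "_affine.txt")))
  dimnames(affine) <- NULL
  dispPath <- paste0(prefix, "_disp.nii.gz")
  if (!file.exists(dispPath)) return(affineTransform(affine))
  img <- RNifti::readNifti(dispPath)
  d <- dim(img)
  grid <- gridFromXform(RNifti::xform(img), d[1:3])
  displacementTransform(array(as.numeric(img), d), grid, affine = affine)
}
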