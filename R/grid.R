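#' Construct an image grid
#'
#' @param shape integer(3): voxels per axis.
#' @param spacing numeric(3) or scalar: voxel size in mm.
#' @param origin numeric(3): world position (mm) of voxel (0,0,0).
#' @param direction 3x3 direction-cosine matrix.
#' @return an \code{ImageGrid}.
#' @examples
#' g <- imageGrid3(c(64, 64, 64), 2.5)
#' @export
imageGrid3 <- function(shape, spacing = 1, origin = c(0, 0, 0),
                       direction = diag(3)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("ImageGrid", shape = as.integer(shape), spacing = as.numeric(spacing),
      origin = as.numeric(origin), direction = direction)
}

#' @describeIn imageGrid3 grid accessor (identity on a grid).
#' @param x an object with a grid.
#' @export
setMethod("imageGrid", "ImageGrid", function(x) x)

#' @export
setMethod("gridShape", "ImageGrid", function(x) x@shape)
#' @export
setMethod("gridSpacing", "ImageGrid", function(x) x@spacing)
#' @export
setMethod("gridOrigin", "ImageGrid", function(x) x@origin)
#' @export
setMethod("gridDirection", "ImageGrid", function(x) x@direction)

setMethod("show", "ImageGrid", function(object) {
  cat(sprintf("ImageGrid %s, spacing %s mm, origin (%s)\n",
              paste(object@shape, collapse = "x"),
              paste(format(object@spacing, digits = 4), collapse = "x"),
              paste(format(object@origin, digits = 4), collapse = ", ")))
})

#' Test whether two grids coincide
#'
#' Shape must match exactly; spacing, origin and direction within a
#' relative tolerance.  Operations combining two volumes voxelwise require
#' \code{sameGrid} to hold (no silent resampling).
#'
#' @param a,b \code{ImageGrid}s.
#' @param tol relative tolerance (default 1e-5).
#' @return logical scalar.
#' @export
sameGrid <- function(a, b, tol = 1e-5) {
  if (!identical(a@shape, b@shape)) return(FALSE)
  sc <- max(abs(a@spacing), abs(b@spacing), 1)
  isTRUE(all(abs(a@spacing - b@spacing) <= tol * sc) &&
         all(abs(a@origin - b@origin) <= tol * max(sc, max(abs(a@origin), abs(b@origin)))) &&
         all(abs(a@direction - b@direction) <= tol))
}

stopIfGridMismatch <- function(a, b, what = "volumes") {
  if (!sameGrid(imageGrid(a), imageGrid(b)))
    stop(what, " are not on the same grid; resample or transform explicitly",
         call. = FALSE)
  invisible(TRUE)
}

#' Convert 0-based voxel indices to world coordinates (mm)
#'
#' @param grid an \code{ImageGrid}.
#' @param vox n x 3 matrix of (possibly fractional) 0-based voxel indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxelToWorld <- function(grid, vox) {
  vox <- matrix(vox, ncol = 3L)
  sweep(vox, 2L, grid@spacing, "*") %*% t(grid@direction) +
    matrix(grid@origin, nrow(vox), 3L, byrow = TRUE)
}

#' Convert world coordinates (mm) to 0-based voxel indices
#'
#' @param grid an \code{ImageGrid}.
#' @param pts n x 3 matrix of mm coordinates.
#' @return n x 3 matrix of fractional voxel indices.
#' @export
worldToVoxel <- function(grid, pts) {
  pts <- matrix(pts, ncol = 3L)
  rel <- pts - matrix(grid@origin, nrow(pts), 3L, byrow = TRUE)
  sweep(rel %*% t(solve(grid@direction)), 2L, grid@spacing, "/")
}

# All voxel centres of a grid as an n x 3 matrix of world coordinates,
# voxel index order column-major (matches array storage order).
gridWorldCoords <- function(grid) {
  s <- grid@shape
  vox <- cbind(
    rep.int(seq_len(s[1]) - 1L, s[2] * s[3]),
    rep.int(rep(seq_len(s[2]) - 1L, each = s[1]), s[3]),
    rep(seq_len(s[3]) - 1L, each = s[1] * s[2]))
  voxelToWorld(grid, vox)
}

# Physical extent (mm) spanned by voxel centres along each axis.
gridExtent <- function(grid) (grid@shape - 1L) * grid@spacing
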