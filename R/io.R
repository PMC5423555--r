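#' Read a 3-D volume from a NIfTI-1 file
#'
#' Grid geometry (spacing, origin, direction cosines) is taken from the
#' NIfTI xform.  If a sidecar mask named \code{<image>_fov.nii.gz} (or
#' \code{.nii}) exists next to the file it is loaded as the FOV mask;
#' otherwise the FOV defaults to all-ones.
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @param modality modality tag for the volume.
#' @return a \code{ScalarVolume}.
#' @export
readVolume <- function(path, modality = "other") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3-D NIfTI payload, got ", length(d), "-D: ", path)
  grid <- gridFromXform(RNifti::xform(img), d)
  fov <- NULL
  fovPath <- fovSidecarPath(path)
  if (!is.null(fovPath)) {
    fimg <- RNifti::readNifti(fovPath)
    if (!identical(dim(fimg), d))
      stop("FOV sidecar shape mismatch for ", path)
    fov <- array(as.numeric(fimg) > 0.5, d)
  }
  scalarVolume(array(as.numeric(img), d), grid = grid, fov = fov,
               modality = modality)
}

#' Write a volume to a NIfTI-1 file
#'
#' Values are stored as float64 so that a write-then-read round trip is
#' exact.  If the FOV mask is not all-ones it is written alongside as
#' \code{<image>_fov.nii.gz}.
#'
#' @param vol a \code{ScalarVolume}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path) {
  writeOneNifti(vol@values, vol@grid, path, "double")
  if (any(vol@fov < 0.5))
    writeOneNifti(vol@fov, vol@grid, defaultFovPath(path), "uint8")
  invisible(path)
}

writeOneNifti <- function(values, grid, path, datatype) {
  # the pixdim attribute must be in place before header creation or the
  # qform assignment silently keeps unit spacings
  attr(values, "pixdim") <- grid@spacing
  img <- RNifti::asNifti(values, datatype = datatype)
  xf <- structure(xformFromGrid(grid), code = 2L)
  RNifti::qform(img) <- xf
  RNifti::sform(img) <- xf
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

fovSidecarPath <- function(path) {
  p <- defaultFovPath(path)
  if (file.exists(p)) return(p)
  alt <- sub("\\.nii\\.gz$|\\.nii$", "_fov.nii", path)
  if (file.exists(alt)) return(alt)
  NULL
}

defaultFovPath <- function(path) {
  sub("\\.nii\\.gz$|\\.nii$", "_fov.nii.gz", path)
}

# NIfTI xform (voxel -> mm, 4x4) to/from ImageGrid.
gridFromXform <- function(xf, shape) {
  xf <- unclass(xf)
  m <- xf[1:3, 1:3]
  spacing <- sqrt(colSums(m^2))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("non-finite or non-positive voxel spacing in NIfTI header")
  direction <- sweep(m, 2L, spacing, "/")
  imageGrid3(shape, spacing, origin = xf[1:3, 4], direction = direction)
}

xformFromGrid <- function(grid) {
  xf <- diag(4)
  xf[1:3, 1:3] <- sweep(grid@direction, 2L, grid@spacing, "*")
  xf[1:3, 4] <- grid@origin
  xf
}

#' Read / write a label dictionary as YAML
#'
#' The file stores a \code{labels} name-to-index map and a
#' \code{lateral_pairs} list of left/right homologues.
#'
#' @param path YAML file path.
#' @return \code{readLabelDictionary}: a \code{\link{labelDictionary}}.
#' @export
readLabelDictionary <- function(path) {
  y <- yaml::read_yaml(path)
  idx <- unlist(y$labels)
  nm <- names(sort(idx))
  labelDictionary(names = nm,
                  lateralPairs = lapply(y$lateral_pairs, unlist))
}

#' @rdname readLabelDictionary
#' @param dict a label dictionary.
#' @export
writeLabelDictionary <- function(dict, path) {
  yaml::write_yaml(list(labels = as.list(dict$index),
                        lateral_pairs = dict$lateralPairs), path)
  invisible(path)
}

#' Write a similarity volume as NIfTI with its validity mask
#'
#' The score image stores 0 at invalid voxels (NIfTI has no -Inf-safe
#' integer representation across tools); the definitive validity mask is
#' written as the \code{_fov} sidecar.
#'
#' @param sim a \code{SimilarityVolume}.
#' @param path output path.
#' @export
writeSimilarityVolume <- function(sim, path) {
  sc <- sim@score
  sc[!sim@valid] <- 0
  vol <- scalarVolume(sc, grid = sim@grid, fov = sim@valid)
  writeVolume(vol, path)
}
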