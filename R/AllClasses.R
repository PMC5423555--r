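#' @import methods
NULL

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' Geometric image grid
#'
#' Describes the sampling geometry shared by all volumes: voxel counts per
#' axis, voxel spacing in mm, the world-space position of voxel (0,0,0) and
#' the axis direction cosines.  Voxel indices are 0-based; the world
#' position of voxel \code{v} is \code{origin + direction \%*\% (spacing * v)}.
#'
#' @slot shape integer(3), voxels per axis.
#' @slot spacing numeric(3), mm per voxel, strictly positive.
#' @slot origin numeric(3), mm.
#' @slot direction 3x3 direction-cosine matrix.
#' @export
setClass("ImageGrid",
  representation(shape = "integer", spacing = "numeric",
                 origin = "numeric", direction = "matrix"))

setValidity("ImageGrid", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 1L))
    return("shape must be three positive integers")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be three strictly positive finite numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be three finite numbers")
  if (!all(dim(object@direction) == c(3L, 3L)) ||
      abs(det(object@direction)) < 1e-8)
    return("direction must be a non-singular 3x3 matrix")
  TRUE
})

#' A 3-D scalar intensity volume with a field-of-view mask
#'
#' Carries an image (MR in arbitrary units, CT/pseudo-CT in Hounsfield
#' units) together with its grid geometry and a binary field-of-view (FOV)
#' mask \eqn{\Omega} marking where the image actually contains data.  MR and
#' CT acquisitions of the same subject typically have different FOVs
#' (different couches and extents), so every volume carries its own mask.
#'
#' @slot grid an \code{ImageGrid}.
#' @slot values 3-D numeric array; finite inside the FOV.
#' @slot fov 3-D 0/1 numeric array, same shape as \code{values}.
#' @slot modality one of \code{"T1"}, \code{"T2"}, \code{"CT"}, \code{"pCT"},
#'   or \code{"other"}.
#' @export
setClass("ScalarVolume",
  representation(grid = "ImageGrid", values = "array", fov = "array",
                 modality = "character"))

setValidity("ScalarVolume", function(object) {
  if (!identical(dim(object@values), gridShape(object@grid)))
    return("values dimensions do not match the grid shape")
  if (!identical(dim(object@fov), gridShape(object@grid)))
    return("fov dimensions do not match the grid shape")
  if (!all(object@fov %in% c(0, 1)))
    return("fov must be binary (0/1)")
  if (any(!is.finite(object@values[object@fov > 0.5])))
    return("values must be finite inside the FOV")
  if (!object@modality %in% c("T1", "T2", "CT", "pCT", "other"))
    return("modality must be one of T1, T2, CT, pCT, other")
  TRUE
})

#' Per-voxel probabilistic segmentation
#'
#' Stores, for each voxel, a length-L vector of label probabilities
#' (label 1 in storage = background, i.e. 0-based label index 0).  Manual
#' contours enter as one-hot encodings; fusion outputs are genuinely
#' probabilistic.  Probabilities sum to 1 per voxel.
#'
#' @slot grid an \code{ImageGrid}.
#' @slot probs 4-D array (x, y, z, L), non-negative.
#' @export
setClass("ProbSegVolume",
  representation(grid = "ImageGrid", probs = "array"))

setValidity("ProbSegVolume", function(object) {
  d <- dim(object@probs)
  if (length(d) != 4L || !identical(d[1:3], gridShape(object@grid)))
    return("probs must be a 4-D array on the grid")
  if (d[4] < 2L) return("at least two labels (background + 1) required")
  if (any(object@probs < -1e-9)) return("probabilities must be non-negative")
  s <- rowSums(matrix(object@probs, ncol = d[4]))
  if (any(abs(s - 1) > 1e-6))
    return("per-voxel probabilities must sum to 1 (within 1e-6)")
  TRUE
})

#' Categorical (hard) segmentation
#'
#' @slot grid an \code{ImageGrid}.
#' @slot labels 3-D integer array of 0-based label indices (0 = background).
#' @slot nLabels total number of labels L including background.
#' @export
setClass("CategoricalSegVolume",
  representation(grid = "ImageGrid", labels = "array", nLabels = "integer"))

setValidity("CategoricalSegVolume", function(object) {
  if (!identical(dim(object@labels), gridShape(object@grid)))
    return("labels dimensions do not match the grid shape")
  if (any(object@labels < 0L) || any(object@labels >= object@nLabels))
    return("label indices must lie in [0, nLabels)")
  TRUE
})

#' One atlas subject: co-registered T2, T1, CT and segmentation
#'
#' @slot id character scalar, unique within a database.
#' @slot t2,t1,ct \code{ScalarVolume}s sharing one grid.
#' @slot seg a \code{ProbSegVolume} on the same grid (one-hot for manual
#'   contours).
#' @slot flipped logical; TRUE for left-right flip-augmented records.
#' @export
setClass("AtlasRecord",
  representation(id = "character", t2 = "ScalarVolume", t1 = "ScalarVolume",
                 ct = "ScalarVolume", seg = "ProbSegVolume",
                 flipped = "logical"))

setValidity("AtlasRecord", function(object) {
  g <- imageGrid(object@t2)
  for (v in list(object@t1, object@ct, object@seg)) {
    if (!sameGrid(g, imageGrid(v)))
      return("all four volumes of an atlas record must share one grid")
  }
  TRUE
})

#' An ordered collection of atlas records with a shared label dictionary
#'
#' @slot records list of \code{AtlasRecord}s with unique ids.
#' @slot labelDict label dictionary as returned by \code{\link{labelDictionary}}.
#' @export
setClass("AtlasDatabase",
  representation(records = "list", labelDict = "list"))

setValidity("AtlasDatabase", function(object) {
  if (!all(vapply(object@records, is, logical(1), "AtlasRecord")))
    return("records must all be AtlasRecord objects")
  ids <- vapply(object@records, function(r) r@id, character(1))
  if (anyDuplicated(ids)) return("record ids must be unique")
  L <- length(object@labelDict$names)
  ok <- vapply(object@records, function(r) dim(r@seg@probs)[4] == L,
               logical(1))
  if (!all(ok)) return("all records must use the database label dictionary")
  TRUE
})

#' An intensity image paired with its manual segmentation (ISP)
#'
#' The unit the atlas builder consumes: one modality's image together with
#' the manual contours drawn on it.
#'
#' @slot intensity a \code{ScalarVolume}.
#' @slot seg a \code{ProbSegVolume} on the same grid.
#' @export
setClass("ImageSegPair",
  representation(intensity = "ScalarVolume", seg = "ProbSegVolume"))

setValidity("ImageSegPair", function(object) {
  if (!sameGrid(imageGrid(object@intensity), imageGrid(object@seg)))
    return("intensity and segmentation must share one grid")
  TRUE
})

#' Spatial transform: global affine followed by a dense displacement
#'
#' Pull-back convention: a point \code{x} (mm, target space) reads the
#' moving image at \code{affine \%*\% x + disp(x)}.  The displacement field
#' is stored densely in mm on \code{dispGrid} (usually the target grid);
#' \code{disp = NULL} means a purely affine transform.
#'
#' @slot affine 4x4 homogeneous matrix (mm space).
#' @slot disp 4-D array (x, y, z, 3) of mm displacements, or NULL.
#' @slot dispGrid the grid the displacement is sampled on.
#' @export
setClass("SpatialTransform",
  representation(affine = "matrix", disp = "arrayOrNULL",
                 dispGrid = "ANY"))

setValidity("SpatialTransform", function(object) {
  if (!all(dim(object@affine) == c(4L, 4L)))
    return("affine must be a 4x4 matrix")
  if (!is.null(object@disp)) {
    if (!is(object@dispGrid, "ImageGrid"))
      return("dispGrid required when a displacement field is present")
    d <- dim(object@disp)
    if (length(d) != 4L || d[4] != 3L ||
        !identical(d[1:3], gridShape(object@dispGrid)))
      return("disp must be (nx, ny, nz, 3) on dispGrid")
    if (any(!is.finite(object@disp)))
      return("displacements must be finite")
  }
  TRUE
})

#' Per-voxel similarity score field with a validity mask
#'
#' Scores are finite where the measure is defined and \code{-Inf} outside
#' the joint field of view; the explicit \code{valid} mask keeps downstream
#' arithmetic NaN-free.
#'
#' @slot grid an \code{ImageGrid}.
#' @slot score 3-D array, \code{-Inf} at invalid voxels.
#' @slot valid 3-D logical array.
#' @export
setClass("SimilarityVolume",
  representation(grid = "ImageGrid", score = "array", valid = "array"))

setValidity("SimilarityVolume", function(object) {
  if (!identical(dim(object@score), gridShape(object@grid)) ||
      !identical(dim(object@valid), gridShape(object@grid)))
    return("score/valid dimensions do not match the grid shape")
  if (any(!is.finite(object@score[object@valid])))
    return("scores must be finite where valid")
  if (any(object@score[!object@valid] != -Inf))
    return("scores must be -Inf where invalid")
  TRUE
})

#' Per-voxel atlas ranks
#'
#' Rank 0 marks the locally most similar atlas; atlases with \code{-Inf}
#' similarity at a voxel carry NA there.  Voxels where no atlas is valid
#' are flagged unfusable.
#'
#' @slot grid an \code{ImageGrid}.
#' @slot ranks 4-D integer array (x, y, z, nAtlas); NA = excluded.
#' @slot fusable 3-D logical array.
#' @export
setClass("RankField",
  representation(grid = "ImageGrid", ranks = "array", fusable = "array"))

#' Per-voxel, per-atlas fusion weights
#'
#' @slot grid an \code{ImageGrid}.
#' @slot weights 4-D array (x, y, z, nAtlas) in [0, 1]; excluded atlases 0.
#' @slot fusable 3-D logical array.
#' @slot beta the decay parameter used.
#' @export
setClass("WeightField",
  representation(grid = "ImageGrid", weights = "array", fusable = "array",
                 beta = "numeric"))

#' An atlas propagated (resampled) onto the target grid
#'
#' @slot id source record id.
#' @slot jT2,jT1,jCt propagated intensity channels on the target grid.
#' @slot jSeg propagated segmentation (nearest-neighbour, one-hot by
#'   default).
#' @slot votes the per-label vote field used by label fusion (equals
#'   \code{jSeg} in one-hot mode).
#' @export
setClass("PropagatedAtlas",
  representation(id = "character", jT2 = "ScalarVolume", jT1 = "ScalarVolume",
                 jCt = "ScalarVolume", jSeg = "ProbSegVolume",
                 votes = "ProbSegVolume"))

#' The evolving target dataset across pipeline iterations
#'
#' Before the first iteration only the target's two MR channels exist; from
#' iteration 1 onwards the previous iteration's pseudo-CT and probabilistic
#' segmentation join them.
#'
#' @slot t completed iterations (0 before the first).
#' @slot t2,t1 target MR channels.
#' @slot pct pseudo-CT from the last iteration, or NULL.
#' @slot seg probabilistic segmentation from the last iteration, or NULL.
#' @export
setClass("TargetState",
  representation(t = "integer", t2 = "ScalarVolume", t1 = "ScalarVolume",
                 pct = "ANY", seg = "ANY"))

setValidity("TargetState", function(object) {
  if (object@t < 0L) return("t must be >= 0")
  if (!sameGrid(imageGrid(object@t2), imageGrid(object@t1)))
    return("target T2 and T1 must share one grid (co-register first)")
  if (object@t >= 1L) {
    if (is.null(object@pct) || is.null(object@seg))
      return("pct and seg must be present for t >= 1")
    if (!sameGrid(imageGrid(object@t2), imageGrid(object@pct)) ||
        !sameGrid(imageGrid(object@t2), imageGrid(object@seg)))
      return("pct/seg must live on the target grid")
  }
  TRUE
})
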