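#' Construct a scalar intensity volume
#'
#' @param values 3-D numeric array.
#' @param grid an \code{ImageGrid}; defaults to unit spacing.
#' @param fov binary 3-D array marking the field of view (default: all 1).
#' @param modality one of \code{"T1"}, \code{"T2"}, \code{"CT"},
#'   \code{"pCT"}, \code{"other"}.
#' @return a \code{ScalarVolume}.
#' @export
scalarVolume <- function(values, grid = NULL, fov = NULL,
                         modality = "other") {
  values <- as.array(values)
  if (is.null(grid)) grid <- imageGrid3(dim(values))
  if (is.null(fov)) fov <- array(1, dim(values))
  storage.mode(values) <- "double"
  fov <- array(as.numeric(fov > 0.5), dim(values))
  new("ScalarVolume", grid = grid, values = values, fov = fov,
      modality = modality)
}

#' @export
setMethod("imageGrid", "ScalarVolume", function(x) x@grid)
#' @export
setMethod("voxelData", "ScalarVolume", function(x) x@values)
#' @export
setMethod("fovMask", "ScalarVolume", function(x) x@fov)
#' @export
setMethod("modality", "ScalarVolume", function(x) x@modality)

setMethod("show", "ScalarVolume", function(object) {
  v <- object@values[object@fov > 0.5]
  cat(sprintf("ScalarVolume [%s] %s, FOV %.0f%%, range [%.4g, %.4g]\n",
              object@modality, paste(dim(object@values), collapse = "x"),
              100 * mean(object@fov),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  show(object@grid)
})

# Internal copy-with-new-values helper preserving geometry and fov.
withValues <- function(vol, values, fov = NULL, modality = NULL) {
  scalarVolume(values, grid = vol@grid,
               fov = if (is.null(fov)) vol@fov else fov,
               modality = if (is.null(modality)) vol@modality else modality)
}

#' Construct a probabilistic segmentation volume
#'
#' @param probs 4-D array (x, y, z, L) of per-voxel label probabilities
#'   summing to 1; label slice 1 is background.
#' @param grid an \code{ImageGrid}.
#' @return a \code{ProbSegVolume}.
#' @export
probSegVolume <- function(probs, grid = NULL) {
  probs <- as.array(probs)
  if (is.null(grid)) grid <- imageGrid3(dim(probs)[1:3])
  storage.mode(probs) <- "double"
  new("ProbSegVolume", grid = grid, probs = probs)
}

#' One-hot probabilistic encoding of a categorical label array
#'
#' @param labels 3-D array of 0-based label indices.
#' @param nLabels total label count L (including background).
#' @param grid an \code{ImageGrid}.
#' @return a one-hot \code{ProbSegVolume}.
#' @export
oneHotSeg <- function(labels, nLabels, grid = NULL) {
  labels <- as.array(labels)
  d <- dim(labels)
  p <- array(0, c(d, nLabels))
  idx <- cbind(seq_len(prod(d)), as.integer(labels) + 1L)
  pm <- matrix(p, ncol = nLabels)
  pm[idx] <- 1
  probSegVolume(array(pm, c(d, nLabels)), grid)
}

#' @export
setMethod("imageGrid", "ProbSegVolume", function(x) x@grid)
#' @export
setMethod("nLabels", "ProbSegVolume", function(x) dim(x@probs)[4])
#' @export
setMethod("probArray", "ProbSegVolume", function(x) x@probs)

setMethod("show", "ProbSegVolume", function(object) {
  d <- dim(object@probs)
  cat(sprintf("ProbSegVolume %s, L = %d labels\n",
              paste(d[1:3], collapse = "x"), d[4]))
})

#' Construct a categorical segmentation volume
#'
#' @param labels 3-D array of 0-based label indices.
#' @param nLabels total label count L.
#' @param grid an \code{ImageGrid}.
#' @return a \code{CategoricalSegVolume}.
#' @export
categoricalSegVolume <- function(labels, nLabels, grid = NULL) {
  labels <- as.array(labels)
  if (is.null(grid)) grid <- imageGrid3(dim(labels))
  storage.mode(labels) <- "integer"
  new("CategoricalSegVolume", grid = grid, labels = labels,
      nLabels = as.integer(nLabels))
}

#' @export
setMethod("imageGrid", "CategoricalSegVolume", function(x) x@grid)
#' @export
setMethod("labelArray", "CategoricalSegVolume", function(x) x@labels)
#' @export
setMethod("nLabels", "CategoricalSegVolume", function(x) x@nLabels)

setMethod("show", "CategoricalSegVolume", function(object) {
  cat(sprintf("CategoricalSegVolume %s, L = %d, foreground %.1f%%\n",
              paste(dim(object@labels), collapse = "x"), object@nLabels,
              100 * mean(object@labels > 0L)))
})

#' Construct an atlas record
#'
#' @param id unique identifier.
#' @param t2,t1,ct co-registered \code{ScalarVolume}s.
#' @param seg a \code{ProbSegVolume} on the same grid.
#' @param flipped logical flip-augmentation flag.
#' @return an \code{AtlasRecord}.
#' @export
atlasRecord <- function(id, t2, t1, ct, seg, flipped = FALSE) {
  new("AtlasRecord", id = as.character(id), t2 = t2, t1 = t1, ct = ct,
      seg = seg, flipped = isTRUE(flipped))
}

#' @export
setMethod("recordId", "AtlasRecord", function(x) x@id)
#' @export
setMethod("t2Volume", "AtlasRecord", function(x) x@t2)
#' @export
setMethod("t1Volume", "AtlasRecord", function(x) x@t1)
#' @export
setMethod("ctVolume", "AtlasRecord", function(x) x@ct)
#' @export
setMethod("segVolume", "AtlasRecord", function(x) x@seg)
#' @export
setMethod("isFlipped", "AtlasRecord", function(x) x@flipped)
#' @export
setMethod("imageGrid", "AtlasRecord", function(x) imageGrid(x@t2))

setMethod("show", "AtlasRecord", function(object) {
  cat(sprintf("AtlasRecord '%s'%s, %s, L = %d\n", object@id,
              if (object@flipped) " (flipped)" else "",
              paste(gridShape(imageGrid(object@t2)), collapse = "x"),
              nLabels(object@seg)))
})

#' Label dictionary
#'
#' Maps organ names to 0-based label indices and declares left/right
#' homologue pairs (needed by flip augmentation).  The default follows the
#' pelvic organ set: background, prostate, bladder, rectum, left and right
#' femur head, and the body outline.
#'
#' @param names character vector of label names in index order
#'   (index 0 = first element = background).
#' @param lateralPairs list of length-2 character vectors naming
#'   left/right homologous labels.
#' @return a list with elements \code{names}, \code{index} (named
#'   integer vector of 0-based indices) and \code{lateralPairs}.
#' @export
labelDictionary <- function(names = c("background", "prostate", "bladder",
                                      "rectum", "LFemurHead", "RFemurHead",
                                      "body"),
                            lateralPairs = list(c("LFemurHead",
                                                  "RFemurHead"))) {
  idx <- seq_along(names) - 1L
  names(idx) <- names
  for (p in lateralPairs)
    if (!all(p %in% names))
      stop("lateral pair refers to unknown labels: ", paste(p, collapse = "/"))
  list(names = names, index = idx, lateralPairs = lateralPairs)
}

#' Construct an atlas database
#'
#' @param records list of \code{AtlasRecord}s.
#' @param labelDict a \code{\link{labelDictionary}}.
#' @return an \code{AtlasDatabase}.
#' @export
atlasDatabase <- function(records, labelDict = labelDictionary()) {
  new("AtlasDatabase", records = records, labelDict = labelDict)
}

#' @export
setMethod("atlasRecords", "AtlasDatabase", function(x) x@records)
#' @export
setMethod("labelDict", "AtlasDatabase", function(x) x@labelDict)
#' @export
setMethod("length", "AtlasDatabase", function(x) length(x@records))

#' @export
setMethod("[[", "AtlasDatabase", function(x, i) {
  if (is.character(i)) {
    ids <- vapply(x@records, recordId, character(1))
    i <- match(i, ids)
    if (is.na(i)) stop("no record with that id")
  }
  x@records[[i]]
})

setMethod("show", "AtlasDatabase", function(object) {
  nf <- sum(vapply(object@records, isFlipped, logical(1)))
  cat(sprintf("AtlasDatabase: %d records (%d flipped), labels: %s\n",
              length(object@records), nf,
              paste(object@labelDict$names, collapse = ", ")))
})

#' Construct an image-segmentation pair (ISP)
#'
#' @param intensity a \code{ScalarVolume}.
#' @param seg a \code{ProbSegVolume} on the same grid.
#' @return an \code{ImageSegPair}.
#' @export
imageSegPair <- function(intensity, seg) {
  new("ImageSegPair", intensity = intensity, seg = seg)
}

#' Construct a similarity volume
#'
#' @param score 3-D array of scores (entries at invalid voxels ignored).
#' @param valid 3-D logical array.
#' @param grid an \code{ImageGrid}.
#' @return a \code{SimilarityVolume} with \code{-Inf} outside the valid set.
#' @export
similarityVolume <- function(score, valid, grid = NULL) {
  score <- as.array(score)
  if (is.null(grid)) grid <- imageGrid3(dim(score))
  valid <- array(as.logical(valid) & is.finite(score), dim(score))
  score[!valid] <- -Inf
  new("SimilarityVolume", grid = grid, score = score, valid = valid)
}

#' @export
setMethod("imageGrid", "SimilarityVolume", function(x) x@grid)
#' @export
setMethod("similarityScores", "SimilarityVolume", function(x) x@score)
#' @export
setMethod("validMask", "SimilarityVolume", function(x) x@valid)

setMethod("show", "SimilarityVolume", function(object) {
  v <- object@score[object@valid]
  cat(sprintf("SimilarityVolume %s, valid %.0f%%, range [%.4g, %.4g]\n",
              paste(dim(object@score), collapse = "x"),
              100 * mean(object@valid),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

#' @export
setMethod("imageGrid", "RankField", function(x) x@grid)
#' @export
setMethod("atlasRanks", "RankField", function(x) x@ranks)
#' @export
setMethod("fusableMask", "RankField", function(x) x@fusable)

#' @export
setMethod("imageGrid", "WeightField", function(x) x@grid)
#' @export
setMethod("fusionWeights", "WeightField", function(x) x@weights)
#' @export
setMethod("fusableMask", "WeightField", function(x) x@fusable)

#' @export
setMethod("transformAffine", "SpatialTransform", function(x) x@affine)
#' @export
setMethod("displacementField", "SpatialTransform", function(x) x@disp)

setMethod("show", "SpatialTransform", function(object) {
  t <- object@affine[1:3, 4]
  cat(sprintf("SpatialTransform: affine translation (%s) mm, %s\n",
              paste(format(t, digits = 3), collapse = ", "),
              if (is.null(object@disp)) "no displacement field"
              else sprintf("dense displacement max |u| = %.2f mm",
                           sqrt(max(rowSums(matrix(object@disp, ncol = 3)^2))))))
})

#' Construct the evolving target state
#'
#' @param t2,t1 target MR channels on one grid.
#' @param pct pseudo-CT \code{ScalarVolume} (or NULL before iteration 1).
#' @param seg probabilistic segmentation (or NULL before iteration 1).
#' @param t completed iteration count.
#' @return a \code{TargetState}.
#' @export
targetState <- function(t2, t1, pct = NULL, seg = NULL, t = 0L) {
  new("TargetState", t = as.integer(t), t2 = t2, t1 = t1, pct = pct,
      seg = seg)
}

#' @export
setMethod("imageGrid", "TargetState", function(x) imageGrid(x@t2))

setMethod("show", "TargetState", function(object) {
  cat(sprintf("TargetState after %d iteration(s)%s\n", object@t,
              if (is.null(object@pct)) " (MR only)" else ""))
})
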