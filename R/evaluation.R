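#' Fuzzy Dice score between two probabilistic segmentations
#'
#' Zadeh fuzzy-set Dice for one label:
#' \eqn{2 \sum_x \min(p, q) / \sum_x (p + q)}.  Reduces exactly to the
#' hard Dice \eqn{2|A \cap B|/(|A|+|B|)} on one-hot inputs.  Returns NA
#' when the label is absent from both segmentations.
#'
#' @param manual,auto \code{ProbSegVolume}s on one grid.
#' @param label 0-based label index.
#' @return scalar in [0, 1], or NA.
#' @export
fuzzyDice <- function(manual, auto, label) {
  stopIfGridMismatch(manual, auto, "segmentations")
  p <- manual@probs[, , , label + 1L]
  q <- auto@probs[, , , label + 1L]
  den <- sum(p) + sum(q)
  if (den == 0) return(NA_real_)
  2 * sum(pmin(p, q)) / den
}

#' Extract the boundary point set of a binary mask
#'
#' Boundary voxels are mask voxels with at least one face-adjacent
#' (6-connectivity) background neighbour; voxels on the volume edge count
#' as boundary.  Coordinates are voxel centres in mm.
#'
#' @param mask 3-D logical array.
#' @param grid the \code{ImageGrid} the mask lives on.
#' @return n x 3 matrix of mm coordinates.
#' @export
extractBoundary <- function(mask, grid = imageGrid3(dim(mask))) {
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("empty mask has no boundary")
  neighbours <- shiftSum(array(as.numeric(mask), dim(mask)))
  interiorCount <- shiftSum(array(1, dim(mask)))  # < 6 at volume edges
  boundary <- mask & (neighbours < 6 | interiorCount < 6)
  idx <- which(boundary) - 1L
  d <- dim(mask)
  vox <- cbind(idx %% d[1],
               (idx %/% d[1]) %% d[2],
               idx %/% (d[1] * d[2]))
  voxelToWorld(grid, vox)
}

#' Modified Hausdorff distance between two boundary point sets
#'
#' \eqn{\max( \mathrm{mean}_a \min_b \|a-b\|, \mathrm{mean}_b \min_a
#' \|a-b\| )} in mm; symmetric, zero iff the sets coincide.
#'
#' @param A,B n x 3 matrices of mm coordinates (both non-empty).
#' @return distance in mm.
#' @export
modifiedHausdorff <- function(A, B) {
  A <- matrix(A, ncol = 3L); B <- matrix(B, ncol = 3L)
  if (nrow(A) == 0L || nrow(B) == 0L) stop("empty point set")
  max(mean(minDistances(A, B)), mean(minDistances(B, A)))
}

# chunked nearest-neighbour distances from each row of A to the set B
minDistances <- function(A, B, chunk = 512L) {
  b2 <- rowSums(B^2)
  out <- numeric(nrow(A))
  for (s in seq(1L, nrow(A), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(A))
    Ac <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ac^2), b2, "+") - 2 * Ac %*% t(B)
    m <- pmax(0, apply(d2, 1L, min))
    m[m < 1e-12] <- 0          # cancellation noise on coincident points
    out[s:e] <- sqrt(m)
  }
  out
}

#' Mean absolute error and mean error between CT volumes in a ROI
#'
#' \eqn{MAE = \frac{1}{V}\sum |pCT - R^{CT}|},
#' \eqn{ME = \frac{1}{V}\sum (pCT - R^{CT})} over the V voxels of the ROI,
#' in HU.  \eqn{MAE \ge |ME|} always.
#'
#' @param pct,ref \code{ScalarVolume}s on one grid.
#' @param roi 3-D logical array (non-empty).
#' @return named numeric vector \code{c(mae = , me = )}.
#' @export
maeMe <- function(pct, ref, roi) {
  stopIfGridMismatch(pct, ref)
  roi <- array(as.logical(roi), dim(pct@values))
  if (!any(roi)) stop("empty ROI")
  diff <- pct@values[roi] - ref@values[roi]
  c(mae = mean(abs(diff)), me = mean(diff))
}

#' Normalised mutual information between two volumes
#'
#' \eqn{NMI = (H(I) + H(J)) / H(I, J)} from a joint histogram over the
#' joint FOV; ranges upward from 1 (independence) to 2 (deterministic
#' monotone relation, e.g. an image with itself).  Returns NA for
#' degenerate (single-occupied-bin) images.
#'
#' @param volI,volJ \code{ScalarVolume}s on one grid.
#' @param bins histogram bins per axis (default 64).
#' @return scalar NMI, or NA.
#' @export
nmi <- function(volI, volJ, bins = 64L) {
  stopIfGridMismatch(volI, volJ)
  joint <- volI@fov > 0.5 & volJ@fov > 0.5
  if (!any(joint)) stop("empty joint FOV")
  x <- volI@values[joint]
  y <- volJ@values[joint]
  bi <- binIndices(x, bins)
  bj <- binIndices(y, bins)
  if (is.null(bi) || is.null(bj)) return(NA_real_)
  tab <- tabulate((bj - 1L) * bins + bi, nbins = bins * bins)
  p <- tab / sum(tab)
  hIJ <- entropy(p)
  hI <- entropy(tabulate(bi, bins) / length(bi))
  hJ <- entropy(tabulate(bj, bins) / length(bj))
  if (hIJ == 0) return(NA_real_)
  (hI + hJ) / hIJ
}

binIndices <- function(x, bins) {
  r <- range(x)
  if (r[2] <= r[1]) return(NULL)
  idx <- pmin(bins, 1L + floor((x - r[1]) / (r[2] - r[1]) * bins))
  if (length(unique(idx)) < 2L) return(NULL)
  as.integer(idx)
}

entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Water-only pseudo-CT baseline
#'
#' Segments the body by thresholding the reference CT, fills internal
#' cavities in 3-D, and assigns 0 HU inside the body and -1000 HU (air)
#' outside — the standard bulk-density baseline that synthesis methods
#' are compared against.  On calibrated HU (air -1000) the default
#' threshold is -500; a literal +500 HU threshold (offset-intensity CT
#' conventions) is available via \code{threshold}.
#'
#' @param refCt reference CT \code{ScalarVolume}.
#' @param threshold body threshold in HU (default -500).
#' @param fill HU value assigned inside the body (default 0).
#' @return a \code{ScalarVolume} tagged \code{"pCT"}; attribute
#'   \code{"bodyMask"} carries the filled body mask.
#' @export
waterOnlyPct <- function(refCt, threshold = -500, fill = 0) {
  body <- refCt@values > threshold & refCt@fov > 0.5
  if (!any(body)) stop("empty body mask at this threshold")
  body <- fillHoles3D(body)
  out <- array(-1000, dim(body))
  out[body] <- fill
  vol <- scalarVolume(out, refCt@grid, fov = refCt@fov, modality = "pCT")
  attr(vol, "bodyMask") <- body
  vol
}

# Fill internal cavities: background connected to the volume border stays
# background; everything else becomes foreground.  Iterative 6-neighbour
# flood from the border.
fillHoles3D <- function(mask) {
  bg <- !mask
  d <- dim(mask)
  outside <- array(FALSE, d)
  outside[1, , ] <- bg[1, , ]; outside[d[1], , ] <- bg[d[1], , ]
  outside[, 1, ] <- outside[, 1, ] | bg[, 1, ]
  outside[, d[2], ] <- outside[, d[2], ] | bg[, d[2], ]
  outside[, , 1] <- outside[, , 1] | bg[, , 1]
  outside[, , d[3]] <- outside[, , d[3]] | bg[, , d[3]]
  repeat {
    grown <- (shiftSum(array(as.numeric(outside), d)) > 0) & bg
    grown <- grown | outside
    if (identical(grown, outside)) break
    outside <- grown
  }
  !outside
}

#' Per-organ and per-ROI metric report for one result set
#'
#' Convenience wrapper producing a tidy table of fuzzy Dice and modified
#' Hausdorff per organ, plus MAE/ME in the body and bone ROIs.
#'
#' @param manualSeg,autoSeg \code{ProbSegVolume}s (manual vs automatic).
#' @param refCt,pct reference and pseudo CT.
#' @param dict label dictionary; organs = all labels except background and
#'   body.
#' @param bodyMask,boneMask ROI masks (logical arrays).
#' @param subject,iteration identifiers copied into the table.
#' @return data.frame with columns subject, iteration, target, metric,
#'   value.
#' @export
metricReport <- function(manualSeg, autoSeg, refCt, pct, dict,
                         bodyMask, boneMask, subject = "", iteration = NA) {
  organs <- setdiff(dict$names, c("background", "body"))
  rows <- list()
  g <- imageGrid(manualSeg)
  autoCat <- categoricalFromProb(autoSeg)
  manCat <- categoricalFromProb(manualSeg)
  for (org in organs) {
    l <- dict$index[[org]]
    dsc <- fuzzyDice(manualSeg, autoSeg, l)
    mhd <- NA_real_
    mA <- manCat@labels == l
    mB <- autoCat@labels == l
    if (any(mA) && any(mB))
      mhd <- modifiedHausdorff(extractBoundary(mA, g), extractBoundary(mB, g))
    rows[[length(rows) + 1L]] <-
      data.frame(subject = subject, iteration = iteration, target = org,
                 metric = c("DSC", "MHD"), value = c(dsc, mhd))
  }
  for (roi in c("body", "bone")) {
    msk <- if (roi == "body") bodyMask else boneMask
    if (!is.null(msk) && any(msk)) {
      mm <- maeMe(pct, refCt, msk)
      rows[[length(rows) + 1L]] <-
        data.frame(subject = subject, iteration = iteration, target = roi,
                   metric = c("MAE", "ME"), value = unname(mm))
    }
  }
  do.call(rbind, rows)
}
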