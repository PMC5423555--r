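#' SSIM stabilising constants from a dynamic-range policy
#'
#' The standard SSIM stabilisers are \eqn{C_1 = (0.01 D)^2} and
#' \eqn{C_2 = (0.03 D)^2} with \eqn{D} the dynamic range.  For CT-like
#' modalities D is fixed at 2000 HU; for MR the robust (1st-99th
#' percentile) range inside the FOV is used.  When constants are derived
#' for a pair, the larger of the two ranges is taken so the measure stays
#' symmetric in its arguments.
#'
#' @param volI,volJ the image pair.
#' @return list with \code{C1} and \code{C2}.
#' @export
ssimConstants <- function(volI, volJ = NULL) {
  D <- dynamicRange(volI)
  if (!is.null(volJ)) D <- max(D, dynamicRange(volJ))
  list(C1 = (0.01 * D)^2, C2 = (0.03 * D)^2)
}

dynamicRange <- function(vol) {
  if (vol@modality %in% c("CT", "pCT")) return(2000)
  v <- vol@values[vol@fov > 0.5]
  q <- stats::quantile(v, c(0.01, 0.99), names = FALSE)
  D <- q[2] - q[1]
  if (!is.finite(D) || D <= 0) D <- max(abs(v), 1)
  D
}

#' Structural similarity over irregular regions of interest (ROI-SSIM)
#'
#' Voxelwise SSIM with local statistics computed by density-normalised
#' Gaussian convolution over the joint field of view, so FOV borders do
#' not bias means and variances.  The score is the product of the
#' luminance term \eqn{(2\mu_I\mu_J + C_1)/(\mu_I^2 + \mu_J^2 + C_1)} and
#' the structure term
#' \eqn{(2\sigma_{IJ} + C_2)/(\sigma_I^2 + \sigma_J^2 + C_2)}, bounded in
#' [-1, 1].  Voxels outside the joint FOV are set to \code{-Inf}.
#'
#' @param volI,volJ \code{ScalarVolume}s on one grid.
#' @param sigmaG Gaussian window standard deviation in voxels (default 3).
#' @param C1,C2 stabilising constants (> 0); defaults follow
#'   \code{\link{ssimConstants}}.
#' @param truncate kernel truncation in units of sigma.
#' @return a \code{SimilarityVolume}.
#' @export
roiSSIM <- function(volI, volJ, sigmaG = 3, C1 = NULL, C2 = NULL,
                    truncate = 3) {
  stopIfGridMismatch(volI, volJ)
  if (is.null(C1) || is.null(C2)) {
    cc <- ssimConstants(volI, volJ)
    if (is.null(C1)) C1 <- cc$C1
    if (is.null(C2)) C2 <- cc$C2
  }
  if (C1 <= 0 || C2 <= 0) stop("C1 and C2 must be > 0")
  nc <- normalizedCovariance(volI, volJ, sigmaG, truncate)
  muI <- nc$momI$mean; muJ <- nc$momJ$mean
  lum <- (2 * muI * muJ + C1) / (muI^2 + muJ^2 + C1)
  str <- (2 * nc$cov + C2) / (nc$momI$variance + nc$momJ$variance + C2)
  s <- pmax(pmin(lum * str, 1), -1)
  similarityVolume(s, nc$valid, imageGrid(volI))
}

#' Local fuzzy Dice between probabilistic segmentations (LDSC)
#'
#' Per voxel, each label's probability map is smoothed with the Gaussian
#' kernel and the fuzzy Dice term
#' \eqn{2\min(\mu_I, \mu_J)/(\mu_I + \mu_J)} is summed over labels.  A
#' label with zero smoothed mass in both images contributes 0 (absent
#' labels must not inflate similarity).  The background label is excluded
#' by default so that background agreement does not swamp organ overlap.
#' Scores lie in [0, L'] where L' is the number of labels summed.
#'
#' @param segI,segJ \code{ProbSegVolume}s on one grid with equal L.
#' @param sigmaG Gaussian kernel standard deviation in voxels.
#' @param includeBackground sum over the background label too
#'   (default FALSE).
#' @param truncate kernel truncation in units of sigma.
#' @return a \code{SimilarityVolume} (valid everywhere on the grid).
#' @export
localFuzzyDice <- function(segI, segJ, sigmaG = 3,
                           includeBackground = FALSE, truncate = 3) {
  stopIfGridMismatch(segI, segJ, "segmentations")
  if (nLabels(segI) != nLabels(segJ))
    stop("label count mismatch: ", nLabels(segI), " vs ", nLabels(segJ))
  L <- nLabels(segI)
  lab <- if (includeBackground) seq_len(L) else seq_len(L)[-1]
  acc <- array(0, gridShape(segI@grid))
  for (l in lab) {
    mi <- convGaussian(segI@probs[, , , l], sigmaG, truncate)
    mj <- convGaussian(segJ@probs[, , , l], sigmaG, truncate)
    den <- mi + mj
    term <- ifelse(den > 1e-12, 2 * pmin(mi, mj) / pmax(den, 1e-300), 0)
    acc <- acc + term
  }
  similarityVolume(acc, array(TRUE, dim(acc)), imageGrid(segI))
}

#' Combined local similarity (LSIM) between target state and an atlas
#'
#' Sums ROI-SSIM on the MR channels and, from the second iteration
#' onwards, ROI-SSIM between the previous pseudo-CT and the propagated
#' atlas CT plus the local fuzzy Dice between the previous segmentation
#' and the propagated atlas segmentation.  At the first iteration only the
#' MR channels are used (mapping and fusion are MR-driven before a
#' pseudo-CT exists).  A voxel is \code{-Inf} wherever any used channel is
#' \code{-Inf}.
#'
#' @param state a \code{TargetState}.
#' @param prop a \code{PropagatedAtlas} on the target grid.
#' @param t current iteration (>= 1).
#' @param sigmaG Gaussian window standard deviation in voxels.
#' @param channelWeights length-4 weights for (T2, T1, CT, seg) terms;
#'   the plain sum (all 1) is the default.
#' @param includeBackground passed to \code{\link{localFuzzyDice}}.
#' @param truncate kernel truncation in units of sigma.
#' @return a \code{SimilarityVolume}.
#' @export
lsim <- function(state, prop, t, sigmaG = 3,
                 channelWeights = c(1, 1, 1, 1),
                 includeBackground = FALSE, truncate = 3) {
  if (t < 1L) stop("iteration t must be >= 1")
  sT2 <- roiSSIM(state@t2, prop@jT2, sigmaG, truncate = truncate)
  sT1 <- roiSSIM(state@t1, prop@jT1, sigmaG, truncate = truncate)
  sc <- channelWeights[1] * sT2@score + channelWeights[2] * sT1@score
  valid <- sT2@valid & sT1@valid
  if (t >= 2L) {
    if (is.null(state@pct) || is.null(state@seg))
      stop("pseudo-CT / segmentation channels required at t >= 2")
    sCT <- roiSSIM(state@pct, prop@jCt, sigmaG, truncate = truncate)
    sSeg <- localFuzzyDice(state@seg, prop@jSeg, sigmaG,
                           includeBackground, truncate)
    sc <- sc + channelWeights[3] * sCT@score + channelWeights[4] * sSeg@score
    valid <- valid & sCT@valid & sSeg@valid
  }
  sc[!valid] <- -Inf
  similarityVolume(sc, valid, imageGrid(state))
}
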