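# Separable truncated-Gaussian convolution, implemented as banded-matrix
# products along each axis (BLAS-backed; no explicit voxel loops).
# Zero padding outside the grid, which is exactly what the density
# normalisation term G * Omega expects.

gaussianKernel1D <- function(sigma, truncate = 3) {
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

convMatrix1D <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (off in seq(-r, r)) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1L & j <= n
    K[cbind(i[ok], j[ok])] <- kernel[off + r + 1L]
  }
  K
}

applyAlongAxis <- function(a, K, axis) {
  d <- dim(a)
  if (axis == 1L) {
    array(K %*% matrix(a, nrow = d[1]), d)
  } else if (axis == 3L) {
    array(matrix(a, ncol = d[3]) %*% t(K), d)
  } else {
    out <- a
    tK <- t(K)
    for (k in seq_len(d[3])) out[, , k] <- a[, , k] %*% tK
    out
  }
}

# per-session cache of banded convolution matrices
.convCache <- new.env(parent = emptyenv())

cachedConvMatrix <- function(n, sigma, truncate) {
  key <- paste(n, sigma, truncate, sep = "_")
  K <- .convCache[[key]]
  if (is.null(K)) {
    K <- convMatrix1D(n, gaussianKernel1D(sigma, truncate))
    .convCache[[key]] <- K
  }
  K
}

# 3-D separable convolution of a (3-D) array with a truncated Gaussian of
# standard deviation sigma (voxels), truncation radius ceil(truncate*sigma).
convGaussian <- function(a, sigma, truncate = 3) {
  cpp_conv_sep(a, gaussianKernel1D(sigma, truncate))
}

#' Density-normalised local moments
#'
#' Local mean, second moment and variance of an image under a Gaussian
#' window, normalised by the smoothed FOV density so that irregular fields
#' of view do not bias the statistics: \eqn{\mu_I = G*(I\Omega) / G*\Omega}.
#' Voxels where the smoothed density falls below 1e-12 are marked outside
#' the usable field.  Negative variances from floating-point cancellation
#' are clamped to zero (tolerance 1e-9).
#'
#' @param vol a \code{ScalarVolume} (its own FOV is used).
#' @param sigmaG Gaussian kernel standard deviation in voxels (default 3).
#' @param truncate kernel truncation radius in units of sigma (default 3).
#' @param fov optional override FOV (e.g. a joint FOV with a second image).
#' @return list with 3-D arrays \code{mean}, \code{secondMoment},
#'   \code{variance}, \code{density}, logical \code{valid}, and
#'   \code{sigmaG}.
#' @export
normalizedMoments <- function(vol, sigmaG = 3, truncate = 3, fov = NULL) {
  if (sigmaG <= 0) stop("sigmaG must be > 0")
  om <- if (is.null(fov)) vol@fov else array(as.numeric(fov > 0.5),
                                             dim(vol@values))
  if (all(om < 0.5)) stop("empty FOV: no voxel carries data")
  v <- vol@values
  v[om < 0.5] <- 0
  d <- convGaussian(om, sigmaG, truncate)
  valid <- d > 1e-12
  dSafe <- ifelse(valid, d, 1)
  mu <- convGaussian(v * om, sigmaG, truncate) / dSafe
  mu2 <- convGaussian(v * v * om, sigmaG, truncate) / dSafe
  va <- mu2 - mu^2
  va[va < 0 & va > -1e-9] <- 0
  va[va < 0] <- 0   # larger negatives only arise from cancellation too
  mu[!valid] <- 0; mu2[!valid] <- 0; va[!valid] <- 0
  list(mean = mu, secondMoment = mu2, variance = va, density = d,
       valid = valid, sigmaG = sigmaG)
}

# Local covariance of two images over a joint FOV (density normalised).
normalizedCovariance <- function(volI, volJ, sigmaG = 3, truncate = 3) {
  stopIfGridMismatch(volI, volJ)
  om <- volI@fov * volJ@fov
  if (all(om < 0.5)) stop("empty joint FOV")
  mi <- normalizedMoments(volI, sigmaG, truncate, fov = om)
  mj <- normalizedMoments(volJ, sigmaG, truncate, fov = om)
  vi <- volI@values; vi[om < 0.5] <- 0
  vj <- volJ@values; vj[om < 0.5] <- 0
  dSafe <- ifelse(mi$valid, mi$density, 1)
  muIJ <- convGaussian(vi * vj * om, sigmaG, truncate) / dSafe
  cov <- muIJ - mi$mean * mj$mean
  cov[!mi$valid] <- 0
  list(momI = mi, momJ = mj, cov = cov, valid = mi$valid, jointFov = om)
}
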