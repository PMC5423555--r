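# Independent brute-force oracles: direct windowed sums per voxel, no
# separable convolution, no shared code with the implementation under test.

# Gaussian-weighted windowed local statistics with FOV density
# normalisation, truncated at ceil(truncate*sigma) per axis (box support,
# matching the separable truncation of the implementation).
oracleMoments <- function(vals, fov, sigma, truncate = 3) {
  d <- dim(vals)
  r <- max(1, ceiling(truncate * sigma))
  off <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  gw <- function(o) exp(-(o^2) / (2 * sigma^2))
  wsep <- gw(off[, 1]) * gw(off[, 2]) * gw(off[, 3])
  mu <- array(NA_real_, d); va <- mu; den <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    pi <- off[, 1] + i; pj <- off[, 2] + j; pk <- off[, 3] + k
    ok <- pi >= 1 & pi <= d[1] & pj >= 1 & pj <= d[2] & pk >= 1 & pk <= d[3]
    idx <- cbind(pi, pj, pk)[ok, , drop = FALSE]
    w <- wsep[ok] * fov[idx]
    s <- sum(w)
    den[i, j, k] <- s
    if (s > 0) {
      v <- vals[idx]
      m <- sum(w * v) / s
      mu[i, j, k] <- m
      va[i, j, k] <- sum(w * v^2) / s - m^2
    }
  }
  list(mean = mu, variance = va, density = den)
}

oracleCovariance <- function(valsI, valsJ, fov, sigma, truncate = 3) {
  d <- dim(valsI)
  r <- max(1, ceiling(truncate * sigma))
  off <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  gw <- function(o) exp(-(o^2) / (2 * sigma^2))
  wsep <- gw(off[, 1]) * gw(off[, 2]) * gw(off[, 3])
  cv <- array(NA_real_, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    pi <- off[, 1] + i; pj <- off[, 2] + j; pk <- off[, 3] + k
    ok <- pi >= 1 & pi <= d[1] & pj >= 1 & pj <= d[2] & pk >= 1 & pk <= d[3]
    idx <- cbind(pi, pj, pk)[ok, , drop = FALSE]
    w <- wsep[ok] * fov[idx]
    s <- sum(w)
    if (s > 0) {
      a <- valsI[idx]; b <- valsJ[idx]
      cv[i, j, k] <- sum(w * a * b) / s - (sum(w * a) / s) * (sum(w * b) / s)
    }
  }
  cv
}

oracleSSIM <- function(valsI, valsJ, fovI, fovJ, sigma, C1, C2,
                       truncate = 3) {
  fov <- fovI * fovJ
  mi <- oracleMoments(valsI, fov, sigma, truncate)
  mj <- oracleMoments(valsJ, fov, sigma, truncate)
  cv <- oracleCovariance(valsI, valsJ, fov, sigma, truncate)
  vi <- pmax(mi$variance, 0); vj <- pmax(mj$variance, 0)
  lum <- (2 * mi$mean * mj$mean + C1) / (mi$mean^2 + mj$mean^2 + C1)
  str <- (2 * cv + C2) / (vi + vj + C2)
  s <- lum * str
  s[mi$density <= 1e-12] <- -Inf
  s
}

# plain (unnormalised-domain) Gaussian smoothing of one label map with a
# kernel normalised to sum 1 over the truncated support, by direct sums
oracleSmooth <- function(vals, sigma, truncate = 3) {
  d <- dim(vals)
  r <- max(1, ceiling(truncate * sigma))
  off <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  gw <- function(o) {
    k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
    (k / sum(k))[o + r + 1]
  }
  wsep <- gw(off[, 1]) * gw(off[, 2]) * gw(off[, 3])
  out <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    pi <- off[, 1] + i; pj <- off[, 2] + j; pk <- off[, 3] + k
    ok <- pi >= 1 & pi <= d[1] & pj >= 1 & pj <= d[2] & pk >= 1 & pk <= d[3]
    idx <- cbind(pi, pj, pk)[ok, , drop = FALSE]
    out[i, j, k] <- sum(wsep[ok] * vals[idx])
  }
  out
}

oracleLDSC <- function(probsI, probsJ, sigma, includeBackground = FALSE,
                       truncate = 3) {
  L <- dim(probsI)[4]
  lab <- if (includeBackground) seq_len(L) else 2:L
  acc <- array(0, dim(probsI)[1:3])
  for (l in lab) {
    mi <- oracleSmooth(probsI[, , , l], sigma, truncate)
    mj <- oracleSmooth(probsJ[, , , l], sigma, truncate)
    den <- mi + mj
    term <- ifelse(den > 1e-12, 2 * pmin(mi, mj) / ifelse(den > 0, den, 1), 0)
    acc <- acc + term
  }
  acc
}

# O(N^2) modified Hausdorff
oracleMHD <- function(A, B) {
  dAB <- apply(A, 1, function(a) min(sqrt(colSums((t(B) - a)^2))))
  dBA <- apply(B, 1, function(b) min(sqrt(colSums((t(A) - b)^2))))
  max(mean(dAB), mean(dBA))
}

# direct-histogram NMI
oracleNMI <- function(x, y, bins) {
  bx <- cut(x, breaks = seq(min(x), max(x), length.out = bins + 1),
            include.lowest = TRUE, labels = FALSE)
  by <- cut(y, breaks = seq(min(y), max(y), length.out = bins + 1),
            include.lowest = TRUE, labels = FALSE)
  pj <- table(bx, by) / length(bx)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  (H(rowSums(pj)) + H(colSums(pj))) / H(pj)
}
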