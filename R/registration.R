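#' Local normalised cross-correlation cost
#'
#' Per-voxel LNCC \eqn{\sigma_{FM} / (\sigma_F \sigma_M)} computed with
#' density-normalised Gaussian moments over the joint FOV; the scalar cost
#' is \eqn{1 - } mean LNCC over valid voxels.  Voxels where either local
#' standard deviation vanishes (< 1e-9) are excluded.  LNCC is invariant
#' to affine intensity rescaling of either image.
#'
#' @param fixed,moving \code{ScalarVolume}s on one grid.
#' @param sigma Gaussian window standard deviation in voxels (default 3).
#' @param truncate kernel truncation in units of sigma.
#' @return list with \code{cost} (scalar) and \code{field}
#'   (a \code{SimilarityVolume}).
#' @export
lnccCost <- function(fixed, moving, sigma = 3, truncate = 3) {
  nc <- normalizedCovariance(fixed, moving, sigma, truncate)
  sf <- nc$momI$variance
  sm <- nc$momJ$variance
  ok <- nc$valid & sf > 1e-9 & sm > 1e-9
  cc <- array(0, dim(sf))
  cc[ok] <- nc$cov[ok] / sqrt(sf[ok] * sm[ok])
  cc <- pmax(pmin(cc, 1), -1)
  if (!any(ok)) stop("empty joint FOV (or no local structure anywhere)")
  list(cost = 1 - mean(cc[ok]),
       field = similarityVolume(cc, ok, imageGrid(fixed)))
}

#' Kullback-Leibler divergence cost between probabilistic segmentations
#'
#' Per voxel \eqn{\sum_l F_l \log(F_l / M_l)} after clamping both
#' probability vectors to \code{[eps, 1]} and renormalising; the scalar
#' cost is the mean.  Non-negative, and zero iff the clamped inputs agree.
#'
#' @param fixed,moving \code{ProbSegVolume}s on one grid with equal L.
#' @param eps clamping floor (default 1e-6).
#' @return list with \code{cost} and \code{field}.
#' @export
kldCost <- function(fixed, moving, eps = 1e-6) {
  stopIfGridMismatch(fixed, moving, "segmentations")
  if (nLabels(fixed) != nLabels(moving)) stop("label count mismatch")
  L <- nLabels(fixed)
  Fm <- clampSimplex(matrix(fixed@probs, ncol = L), eps)
  Mm <- clampSimplex(matrix(moving@probs, ncol = L), eps)
  kl <- rowSums(Fm * (log(Fm) - log(Mm)))
  arr <- array(kl, gridShape(fixed@grid))
  list(cost = mean(kl),
       field = similarityVolume(arr, array(TRUE, dim(arr)),
                                imageGrid(fixed)))
}

clampSimplex <- function(m, eps = 1e-6) {
  m <- pmax(pmin(m, 1), eps)
  m / rowSums(m)
}

#' Registration specification
#'
#' Describes a multi-channel deformable registration problem: per-channel
#' similarity (LNCC for intensities, KLD for segmentations), pyramid
#' levels, finest control-point spacing, regularisation and optimiser
#' settings.
#'
#' @param channels named list; each element \code{list(sim = "lncc")},
#'   \code{list(sim = "lncc2")} or \code{list(sim = "kld")}, optionally
#'   with a \code{weight} (default 1).  Channel names pair fixed and
#'   moving inputs.  \code{"lncc2"} is the squared local correlation,
#'   insensitive to the sign of the local intensity relation and hence
#'   the right choice for cross-modal pairs (e.g. T2 vs CT, where bone is
#'   dark on one and bright on the other).
#' @param levels pyramid levels (image downsampled by 2 per level; the
#'   control spacing doubles with each coarser level).
#' @param controlSpacing finest lattice spacing in mm along each axis.
#' @param maxIter optimiser iterations per level (scalar or per-level
#'   vector, coarse to fine).
#' @param lnccSigma LNCC Gaussian window, in working-grid voxels.
#' @param lnccTruncate LNCC kernel truncation, in units of sigma.
#' @param regWeight bending-energy weight.
#' @param tol relative cost-improvement convergence tolerance.
#' @param globalMode \code{"translation"} (centroid + optimiser refine),
#'   \code{"affine"} (adds a 12-parameter refinement) or \code{"none"}.
#' @param globalRefineIter Nelder-Mead iterations for the global stage.
#' @param minLevelSize skip pyramid levels whose working grid would fall
#'   below this many voxels per axis.
#' @return a list of class \code{"registrationSpec"}.
#' @export
registrationSpec <- function(channels, levels = 3L, controlSpacing = 10,
                             maxIter = 15L, lnccSigma = 2,
                             lnccTruncate = 2.5, regWeight = 0.005,
                             tol = 1e-4, globalMode = "translation",
                             globalRefineIter = 30L, minLevelSize = 12L) {
  if (length(channels) < 1L) stop("at least one channel required")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!ch$sim %in% c("lncc", "lncc2", "kld"))
      stop("channel similarity must be 'lncc', 'lncc2' or 'kld'")
    if (is.null(ch$weight)) channels[[nm]]$weight <- 1
  }
  if (controlSpacing <= 0) stop("controlSpacing must be > 0")
  structure(list(channels = channels, levels = as.integer(levels),
                 controlSpacing = controlSpacing, maxIter = maxIter,
                 lnccSigma = lnccSigma, lnccTruncate = lnccTruncate,
                 regWeight = regWeight, tol = tol,
                 globalMode = match.arg(globalMode,
                                        c("translation", "affine", "none")),
                 globalRefineIter = as.integer(globalRefineIter),
                 minLevelSize = as.integer(minLevelSize)),
            class = "registrationSpec")
}

# ---------------------------------------------------------------------------
# Reference multi-resolution B-spline free-form registration.
#
# This is a modest optimiser adequate for phantom-scale volumes: gradient
# descent with backtracking line search on the (equally) weighted sum of
# channel costs plus a bending-energy penalty on the control lattice.
# Working grids are required to be axis-aligned (direction = I), which all
# package-generated grids are.

#' Multi-channel deformable registration (reference implementation)
#'
#' Estimates a global stage (symmetric centroid alignment, optionally
#' refined by a derivative-free optimiser) followed by a multi-resolution
#' cubic B-spline free-form deformation minimising the weighted sum of
#' per-channel costs (LNCC for intensity channels, KLD for segmentation
#' channels) plus bending energy.  Linear interpolation is used during
#' optimisation.  Deterministic given inputs and spec.
#'
#' @param fixed,moving named lists of channels (\code{ScalarVolume} or
#'   \code{ProbSegVolume}); names must match \code{spec$channels}.  All
#'   fixed channels share one grid, likewise all moving channels.
#' @param spec a \code{\link{registrationSpec}}.
#' @param init optional \code{SpatialTransform} warm start (its affine is
#'   kept; the global stage is skipped).
#' @return a \code{SpatialTransform} (dense displacement on the fixed
#'   grid) with attributes \code{"converged"} and \code{"costTrace"}.
#' @export
registerMultichannel <- function(fixed, moving, spec, init = NULL) {
  chNames <- names(spec$channels)
  if (!all(chNames %in% names(fixed)) || !all(chNames %in% names(moving)))
    stop("fixed/moving channel names must cover the spec channels")
  fixedGrid <- imageGrid(fixed[[chNames[1]]])
  movGrid <- imageGrid(moving[[chNames[1]]])
  for (nm in chNames) {
    if (!sameGrid(imageGrid(fixed[[nm]]), fixedGrid))
      stop("fixed channels must share one grid")
    if (!sameGrid(imageGrid(moving[[nm]]), movGrid))
      stop("moving channels must share one grid")
  }
  assertAxisAligned(fixedGrid); assertAxisAligned(movGrid)

  # --- global stage -------------------------------------------------------
  if (!is.null(init)) {
    A <- init@affine
  } else if (spec$globalMode == "none") {
    A <- diag(4)
  } else {
    A <- globalStage(fixed, moving, spec, fixedGrid, movGrid)
  }

  # --- pyramid ------------------------------------------------------------
  levelsEff <- effectiveLevels(spec, fixedGrid)
  maxIt <- rep_len(spec$maxIter, length(levelsEff))
  Tcur <- if (!is.null(init) && !is.null(init@disp)) init else NULL
  trace <- list()
  converged <- TRUE
  for (li in seq_along(levelsEff)) {
    lev <- levelsEff[li]
    f <- 2^(lev - 1)
    work <- lapply(chNames, function(nm)
      prepareChannel(fixed[[nm]], moving[[nm]], spec$channels[[nm]], f))
    names(work) <- chNames
    workGrid <- work[[1]]$workGrid
    uBase <- if (is.null(Tcur)) matrix(0, prod(workGrid@shape), 3L)
             else matrix(resampleDisplacement(Tcur, workGrid),
                         ncol = 3L)
    lat <- makeLattice(workGrid, spec$controlSpacing * f)
    res <- optimizeLevel(work, workGrid, lat, A, uBase, spec, maxIt[li])
    uNew <- uBase + bsplineDense(lat, res$theta)
    Tcur <- displacementTransform(array(uNew, c(workGrid@shape, 3L)),
                                  workGrid, affine = A)
    trace[[li]] <- res$trace
    converged <- converged && res$converged
  }
  # express the displacement on the full-resolution fixed grid
  if (!sameGrid(Tcur@dispGrid, fixedGrid)) {
    Tcur <- displacementTransform(resampleDisplacement(Tcur, fixedGrid),
                                  fixedGrid, affine = A)
  }
  attr(Tcur, "converged") <- converged
  attr(Tcur, "costTrace") <- trace
  Tcur
}

assertAxisAligned <- function(grid) {
  if (max(abs(grid@direction - diag(3))) > 1e-6)
    stop("the reference registration requires axis-aligned grids ",
         "(direction = identity); resample first")
}

effectiveLevels <- function(spec, grid) {
  levs <- seq(spec$levels, 1L)
  keep <- vapply(levs, function(l)
    min(floor(grid@shape / 2^(l - 1))) >= spec$minLevelSize || l == 1L,
    logical(1))
  levs[keep]
}

# --- global stage ----------------------------------------------------------

globalStage <- function(fixed, moving, spec, fixedGrid, movGrid) {
  chNames <- names(spec$channels)
  # FOV centroid translation (antisymmetric, hence symmetric by
  # construction under swapping fixed and moving)
  comF <- fovCentroid(fixed, fixedGrid)
  comM <- fovCentroid(moving, movGrid)
  shift <- comM - comF
  A <- diag(4)
  A[1:3, 4] <- shift
  if (spec$globalRefineIter > 0L) {
    fCoarse <- 2^(max(effectiveLevels(spec, fixedGrid)) - 1)
    for (f in unique(c(fCoarse, max(1, fCoarse / 2)))) {
      work <- lapply(chNames, function(nm)
        prepareChannel(fixed[[nm]], moving[[nm]], spec$channels[[nm]], f,
                       gradients = FALSE))
      names(work) <- chNames
      workGrid <- work[[1]]$workGrid
      u0 <- matrix(0, prod(workGrid@shape), 3L)
      X <- gridWorldCoords(workGrid)
      costT <- function(p) {
        At <- A
        At[1:3, 4] <- A[1:3, 4] + p
        channelCosts(work, X, At, u0, spec)$total
      }
      opt <- stats::optim(c(0, 0, 0), costT, method = "Nelder-Mead",
                          control = list(maxit = spec$globalRefineIter,
                                         reltol = 1e-8))
      A[1:3, 4] <- A[1:3, 4] + opt$par
      if (spec$globalMode == "affine") {
        costAf <- function(p) {
          At <- diag(4)
          At[1:3, 1:3] <- diag(3) + matrix(p[1:9], 3, 3)
          At[1:3, 4] <- A[1:3, 4] + p[10:12]
          channelCosts(work, X, At, u0, spec)$total
        }
        opt2 <- stats::optim(rep(0, 12), costAf, method = "Nelder-Mead",
                             control = list(maxit = 4L * spec$globalRefineIter))
        A[1:3, 1:3] <- diag(3) + matrix(opt2$par[1:9], 3, 3)
        A[1:3, 4] <- A[1:3, 4] + opt2$par[10:12]
      }
    }
  }
  # overlap sanity check at the chosen global transform
  A
}

fovCentroid <- function(channels, grid) {
  fov <- NULL
  for (ch in channels) {
    if (is(ch, "ScalarVolume")) { fov <- ch@fov; break }
  }
  if (is.null(fov)) fov <- array(1, grid@shape)
  w <- as.vector(fov)
  if (sum(w) == 0) stop("empty FOV in registration input")
  pts <- gridWorldCoords(grid)
  colSums(pts * w) / sum(w)
}

# --- per-level channel preparation ----------------------------------------

# Downsample one fixed/moving channel pair by integer factor f and
# precompute what the inner loop needs.
prepareChannel <- function(fixedCh, movCh, chSpec, f, gradients = TRUE) {
  if (chSpec$sim %in% c("lncc", "lncc2")) {
    fw <- downsampleVolume(fixedCh, f)
    mw <- downsampleVolume(movCh, f)
    out <- list(sim = chSpec$sim, weight = chSpec$weight,
                workGrid = fw@grid, movGrid = mw@grid,
                fArr = fw@values, fFov = fw@fov,
                mArr = mw@values, mFov = mw@fov)
    if (gradients) out$mGrad <- mmGradients(mw)
    out
  } else {
    fw <- downsampleSeg(fixedCh, f)
    mw <- downsampleSeg(movCh, f)
    L <- nLabels(fw)
    out <- list(sim = "kld", weight = chSpec$weight,
                workGrid = fw@grid, movGrid = mw@grid, L = L,
                fProbs = clampSimplex(matrix(fw@probs, ncol = L)),
                mProbs = mw@probs)
    if (gradients) {
      # the raw KLD of near-one-hot maps is piecewise flat, so the
      # descent direction uses a smoothed overlap surrogate (see
      # costGradient); the line search always re-scores the true KLD
      out$fSmooth <- vapply(seq_len(L), function(l)
        as.vector(convGaussian(fw@probs[, , , l], 1.5)),
        numeric(prod(fw@grid@shape)))
      out$mSmooth <- lapply(seq_len(L), function(l)
        convGaussian(mw@probs[, , , l], 1.5))
      out$mGrad <- lapply(seq_len(L), function(l)
        mmGradients(scalarVolume(out$mSmooth[[l]], mw@grid)))
    }
    out
  }
}

downsampleVolume <- function(vol, f) {
  if (f == 1) {
    # at full resolution a light smoothing keeps the correlation-based
    # costs from chasing voxel noise
    sm <- normalizedMoments(vol, sigmaG = 0.7, truncate = 2)$mean
    sm[vol@fov < 0.5] <- 0
    return(scalarVolume(sm, vol@grid, fov = vol@fov,
                        modality = vol@modality))
  }
  g <- vol@grid
  sm <- normalizedMoments(vol, sigmaG = f / 2, truncate = 2)$mean
  smoothed <- scalarVolume(sm, g, fov = vol@fov, modality = vol@modality)
  newShape <- pmax(4L, as.integer(floor(g@shape / f)))
  newGrid <- imageGrid3(newShape, g@spacing * f,
                        origin = g@origin + (f - 1) / 2 * g@spacing,
                        direction = g@direction)
  resampleToGrid(smoothed, newGrid, "linear")
}

downsampleSeg <- function(seg, f) {
  if (f == 1) return(seg)
  g <- seg@grid
  L <- nLabels(seg)
  newShape <- pmax(4L, as.integer(floor(g@shape / f)))
  newGrid <- imageGrid3(newShape, g@spacing * f,
                        origin = g@origin + (f - 1) / 2 * g@spacing,
                        direction = g@direction)
  pts <- gridWorldCoords(newGrid)
  out <- matrix(0, prod(newShape), L)
  for (l in seq_len(L)) {
    sm <- convGaussian(seg@probs[, , , l], f / 2, truncate = 2)
    s <- sampleArrayAtVoxels(sm, worldToVoxel(g, pts), "linear")
    out[, l] <- pmax(0, s$values)
  }
  bad <- rowSums(out) <= 1e-12
  out[bad, 1] <- 1
  out <- out / rowSums(out)
  probSegVolume(array(out, c(newShape, L)), newGrid)
}

# Central-difference gradient arrays in mm^-1 units (axis-aligned grids).
mmGradients <- function(vol) {
  g <- vol@grid
  list(x = centralDiff(vol@values, 1L) / g@spacing[1],
       y = centralDiff(vol@values, 2L) / g@spacing[2],
       z = centralDiff(vol@values, 3L) / g@spacing[3])
}

# --- control lattice -------------------------------------------------------

makeLattice <- function(workGrid, spacing) {
  ext <- gridExtent(workGrid)
  ncp <- pmax(4L, as.integer(floor(ext / spacing)) + 4L)
  B <- lapply(1:3, function(ax) {
    x <- (seq_len(workGrid@shape[ax]) - 1L) * workGrid@spacing[ax]
    bsplineBasisMatrix(x, spacing, ncp[ax])
  })
  list(spacing = spacing, ncp = ncp, B = B,
       Bt = lapply(B, t))
}

# Basis matrix (n positions x ncp controls) for a cubic B-spline lattice
# whose control q (0-based, starting at -1) sits at position (q) * s - s.
bsplineBasisMatrix <- function(x, s, ncp) {
  u <- x / s
  i <- pmin(pmax(floor(u), 0), ncp - 4)
  t <- u - i
  w <- cbind((1 - t)^3 / 6,
             (3 * t^3 - 6 * t^2 + 4) / 6,
             (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
             t^3 / 6)
  B <- matrix(0, length(x), ncp)
  for (k in 0:3) B[cbind(seq_along(x), i + k + 1L)] <- w[, k + 1L]
  B
}

# Rectangular linear map along one array axis.
applyLinAxis <- function(a, K, axis) {
  d <- dim(a)
  if (axis == 1L) {
    out <- K %*% matrix(a, nrow = d[1])
    dim(out) <- c(nrow(K), d[-1])
    return(out)
  }
  if (axis == 3L) {
    out <- matrix(a, ncol = d[3]) %*% t(K)
    dim(out) <- c(d[1], d[2], nrow(K))
    return(out)
  }
  out <- array(0, c(d[1], nrow(K), d[3]))
  tK <- t(K)
  for (k in seq_len(d[3])) out[, , k] <- a[, , k] %*% tK
  out
}

# theta: array (ncp1, ncp2, ncp3, 3) -> dense displacement matrix (V x 3)
bsplineDense <- function(lat, theta) {
  V <- prod(vapply(lat$B, nrow, integer(1)))
  out <- matrix(0, V, 3L)
  for (c in 1:3) {
    a <- theta[, , , c, drop = TRUE]
    dim(a) <- lat$ncp
    a <- applyLinAxis(a, lat$B[[1]], 1L)
    a <- applyLinAxis(a, lat$B[[2]], 2L)
    a <- applyLinAxis(a, lat$B[[3]], 3L)
    out[, c] <- as.vector(a)
  }
  out
}

# adjoint: dense (V x 3) -> lattice gradient (ncp1, ncp2, ncp3, 3)
bsplineSplat <- function(lat, dense, workShape) {
  out <- array(0, c(lat$ncp, 3L))
  for (c in 1:3) {
    a <- array(dense[, c], workShape)
    a <- applyLinAxis(a, lat$Bt[[1]], 1L)
    a <- applyLinAxis(a, lat$Bt[[2]], 2L)
    a <- applyLinAxis(a, lat$Bt[[3]], 3L)
    out[, , , c] <- a
  }
  out
}

# --- cost and gradient -----------------------------------------------------

# Evaluate all channel costs at a given affine + dense displacement.
# Returns per-channel intermediates when wantGrad so the gradient pass can
# reuse them.
channelCosts <- function(work, X, A, u, spec, wantGrad = FALSE) {
  m <- X %*% t(A[1:3, 1:3]) + matrix(A[1:3, 4], nrow(X), 3L, byrow = TRUE) + u
  total <- 0
  details <- vector("list", length(work))
  mvShared <- worldToVoxel(work[[1]]$movGrid, m)
  for (ci in seq_along(work)) {
    ch <- work[[ci]]
    mv <- if (sameGrid(ch$movGrid, work[[1]]$movGrid)) mvShared
          else worldToVoxel(ch$movGrid, m)
    if (ch$sim %in% c("lncc", "lncc2")) {
      s <- cpp_sample(ch$mArr, ch$mFov, mv, 1L)
      sh <- dim(ch$fArr)
      J <- array(s$values, sh)
      om <- array(as.numeric(s$valid), sh) * ch$fFov
      res <- lnccPieces(ch$fArr, J, om, spec$lnccSigma, spec$lnccTruncate,
                        squared = ch$sim == "lncc2")
      total <- total + ch$weight * res$cost
      if (wantGrad) details[[ci]] <- c(res, list(J = J, om = om, mv = mv))
    } else {
      V <- nrow(mv)
      Mm <- matrix(0, V, ch$L)
      valid <- rep(TRUE, V)
      for (l in seq_len(ch$L)) {
        s <- cpp_sample(ch$mProbs[, , , l], numeric(0), mv, 1L)
        Mm[, l] <- pmax(0, s$values)
        valid <- valid & s$valid
      }
      Mm <- clampSimplex(Mm)
      kl <- rowSums(ch$fProbs * (log(ch$fProbs) - log(Mm)))
      kl[!valid] <- 0
      nV <- max(1L, sum(valid))
      total <- total + ch$weight * sum(kl) / nV
      if (wantGrad)
        details[[ci]] <- list(Mm = Mm, valid = valid, nV = nV, mv = mv)
    }
  }
  list(total = total, details = details, mv = NULL, m = m)
}

# LNCC cost + the convolution fields needed by its gradient.
lnccPieces <- function(F, J, om, sigma, truncate = 3, squared = FALSE) {
  cg <- function(x) convGaussian(x, sigma, truncate)
  d <- cg(om)
  ok <- d > 1e-12
  dS <- ifelse(ok, d, 1)
  Fo <- F * om; Jo <- J * om
  muF <- cg(Fo) / dS
  muJ <- cg(Jo) / dS
  vF <- cg(Fo * F) / dS - muF^2
  vJ <- cg(Jo * J) / dS - muJ^2
  cv <- cg(Fo * J) / dS - muF * muJ
  # gate on local structure: windows whose variance is far below the
  # image's structured range are noise-flat, and correlating noise there
  # would reward spurious deformation
  gateF <- max(1e-9, 0.02 * stats::quantile(vF[ok], 0.98, names = FALSE))
  gateJ <- max(1e-9, 0.02 * stats::quantile(vJ[ok], 0.98, names = FALSE))
  sel <- ok & vF > gateF & vJ > gateJ
  cc <- array(0, dim(F))
  cc[sel] <- cv[sel] / sqrt(vF[sel] * vJ[sel])
  cc <- pmax(pmin(cc, 1), -1)
  nV <- max(1L, sum(sel))
  cost <- if (squared) 1 - sum(cc[sel]^2) / nV else 1 - sum(cc[sel]) / nV
  list(cost = cost, muF = muF, muJ = muJ, vF = vF,
       vJ = vJ, cc = cc, d = d, sel = sel, nV = nV,
       squared = squared)
}

# Gradient of the total cost w.r.t. the lattice coefficients.
costGradient <- function(work, X, A, u, spec, lat, workShape, details) {
  V <- nrow(X)
  g <- matrix(0, V, 3L)
  for (ci in seq_along(work)) {
    ch <- work[[ci]]
    dt <- details[[ci]]
    if (ch$sim %in% c("lncc", "lncc2")) {
      sel <- dt$sel
      sdF <- sqrt(pmax(dt$vF, 1e-12)); sdJ <- sqrt(pmax(dt$vJ, 1e-12))
      P <- array(0, workShape); Q <- array(0, workShape)
      # for squared LNCC the chain rule doubles each term by cc
      sc <- if (dt$squared) 2 * dt$cc[sel] else 1
      P[sel] <- sc / (dt$d[sel] * sdF[sel] * sdJ[sel])
      Q[sel] <- sc * dt$cc[sel] / (dt$d[sel] * dt$vJ[sel])
      cP <- convGaussian(P, spec$lnccSigma, spec$lnccTruncate)
      cMP <- convGaussian(dt$muF * P, spec$lnccSigma, spec$lnccTruncate)
      cQ <- convGaussian(Q, spec$lnccSigma, spec$lnccTruncate)
      cMQ <- convGaussian(dt$muJ * Q, spec$lnccSigma, spec$lnccTruncate)
      force <- -(dt$om / dt$nV) *
        (ch$fArr * cP - cMP - dt$J * cQ + cMQ)
      gr <- cpp_sample3(ch$mGrad$x, ch$mGrad$y, ch$mGrad$z, dt$mv)
      fv <- as.vector(force) * ch$weight
      g[, 1] <- g[, 1] + fv * gr$x
      g[, 2] <- g[, 2] + fv * gr$y
      g[, 3] <- g[, 3] + fv * gr$z
    } else {
      # smoothed-overlap surrogate force: push each label's smoothed
      # probability toward the fixed one (direction of decreasing label
      # SSD, which decreases KLD as well away from plateaus)
      for (l in seq_len(ch$L)) {
        s <- cpp_sample(ch$mSmooth[[l]], numeric(0), dt$mv, 1L)
        coef <- (s$values - ch$fSmooth[, l]) / dt$nV
        coef[!dt$valid] <- 0
        gr <- cpp_sample3(ch$mGrad[[l]]$x, ch$mGrad[[l]]$y,
                          ch$mGrad[[l]]$z, dt$mv)
        fv <- coef * ch$weight
        g[, 1] <- g[, 1] + fv * gr$x
        g[, 2] <- g[, 2] + fv * gr$y
        g[, 3] <- g[, 3] + fv * gr$z
      }
    }
  }
  bsplineSplat(lat, g, workShape)
}

# Bending energy of the lattice (mean squared second difference of the
# coefficients, mm^2) and its gradient.
bendingEnergy <- function(theta, ncp) {
  be <- 0
  grad <- array(0, dim(theta))
  n <- prod(ncp) * 3
  for (ax in 1:3) {
    if (ncp[ax] < 3) next
    d2 <- secondDiff(theta, ax)
    be <- be + sum(d2^2) / n
    grad <- grad + 2 * secondDiffAdj(d2, ax, dim(theta)) / n
  }
  list(value = be, grad = grad)
}

secondDiff <- function(a, axis) {
  d <- dim(a)
  n <- d[axis]
  i0 <- rep(list(quote(expr = )), length(d))
  i1 <- i0; i2 <- i0
  i0[[axis]] <- 1:(n - 2L); i1[[axis]] <- 2:(n - 1L); i2[[axis]] <- 3:n
  do.call(`[`, c(list(a), i0, list(drop = FALSE))) -
    2 * do.call(`[`, c(list(a), i1, list(drop = FALSE))) +
    do.call(`[`, c(list(a), i2, list(drop = FALSE)))
}

secondDiffAdj <- function(d2, axis, outDim) {
  out <- array(0, outDim)
  n <- outDim[axis]
  addAt <- function(out, shift, mult) {
    idx <- rep(list(quote(expr = )), length(outDim))
    idx[[axis]] <- (1:(n - 2L)) + shift
    sub <- do.call(`[`, c(list(out), idx, list(drop = FALSE)))
    do.call(`[<-`, c(list(out), idx, list(sub + mult * d2)))
  }
  out <- addAt(out, 0L, 1)
  out <- addAt(out, 1L, -2)
  out <- addAt(out, 2L, 1)
  out
}

# --- level optimiser -------------------------------------------------------

optimizeLevel <- function(work, workGrid, lat, A, uBase, spec, maxIter) {
  X <- gridWorldCoords(workGrid)
  workShape <- workGrid@shape
  theta <- array(0, c(lat$ncp, 3L))
  # every cost evaluation keeps the channel intermediates so that the
  # gradient of an accepted iterate costs nothing extra
  evalFull <- function(th) {
    u <- uBase + bsplineDense(lat, th)
    cc <- channelCosts(work, X, A, u, spec, wantGrad = TRUE)
    be <- bendingEnergy(th, lat$ncp)
    list(cost = cc$total + spec$regWeight * be$value, cc = cc, be = be,
         u = u)
  }
  cur <- evalFull(theta)
  cost <- cur$cost
  trace <- cost
  step <- NA
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    g <- costGradient(work, X, A, cur$u, spec, lat, workShape,
                      cur$cc$details) +
      spec$regWeight * cur$be$grad
    gmax <- max(abs(g))
    if (gmax < 1e-12) { converged <- TRUE; break }
    if (is.na(step)) step <- 0.4 * min(workGrid@spacing) / gmax
    accepted <- FALSE
    for (try in 1:8) {
      thNew <- theta - step * g
      new <- evalFull(thNew)
      if (new$cost < cost - 1e-12) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) break
    improve <- (cost - new$cost) / max(abs(cost), 1e-12)
    theta <- thNew
    cur <- new
    cost <- new$cost
    trace <- c(trace, cost)
    step <- step * 1.5
    if (improve < spec$tol) { converged <- TRUE; break }
  }
  list(theta = theta, trace = trace, converged = converged || maxIter == 0L)
}

#' Write / read a registration specification as YAML
#'
#' @param spec a \code{\link{registrationSpec}}.
#' @param path YAML file path.
#' @return \code{readRegistrationSpec}: a \code{registrationSpec}.
#' @export
writeRegistrationSpec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname writeRegistrationSpec
#' @export
readRegistrationSpec <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(registrationSpec, y)
}
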