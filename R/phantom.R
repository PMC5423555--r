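# Synthetic pelvic-like phantom cohort: ground-truth co-registered
# {T2, T1, CT, labels} subjects with controlled inter-subject deformation,
# so the whole pipeline is testable without clinical data.

#' Phantom cohort specification
#'
#' Geometry (ellipsoidal organs, a pelvic bone shell, a bent rectal tube),
#' per-tissue intensity tables, noise and bias-field settings, and
#' deformation statistics for a synthetic pelvic cohort.  The template is
#' left-right symmetric (paired femur heads), the rectum's filling radius
#' varies across subjects, and the MR field of view is deliberately
#' cropped relative to the CT to exercise FOV handling.
#'
#' @param size voxels per axis (default 64).
#' @param spacing isotropic voxel size in mm (default 2.5).
#' @param noiseSigmaMR,noiseSigmaCT additive Gaussian noise sd (MR a.u.,
#'   CT HU).
#' @param biasAmplitude MR multiplicative bias-field amplitude
#'   (fractional).
#' @param deformAmplitude inter-subject B-spline coefficient sd in mm.
#' @param deformSpacing control spacing of the random warps in mm.
#' @param rectumRadiusSd per-subject sd of the rectal filling scale.
#' @param intensityJitter per-subject, per-tissue multiplicative jitter sd.
#' @param mrCrop voxels cropped from the MR FOV on each side in (x, z).
#' @return a list of class \code{"phantomSpec"}.
#' @export
phantomSpec <- function(size = 64L, spacing = 2.5, noiseSigmaMR = 3,
                        noiseSigmaCT = 15, biasAmplitude = 0.1,
                        deformAmplitude = 3, deformSpacing = 32,
                        rectumRadiusSd = 0.12, intensityJitter = 0.03,
                        mrCrop = c(3L, 5L)) {
  ext <- size * spacing
  sc <- ext / 160       # geometry below is laid out for a 160 mm cube
  structure(list(
    shape = rep(as.integer(size), 3L), spacing = rep(spacing, 3L),
    geom = list(
      bodySemi = sc * c(72, 58, 76),
      boneCenter = sc * c(0, -4, 0),
      boneOuter = sc * c(56, 44, 38), boneInner = sc * c(46, 34, 28),
      bladderCenter = sc * c(0, 12, 16), bladderSemi = sc * c(16, 12, 13),
      prostateCenter = sc * c(0, -6, -8), prostateR = sc * 8,
      rectumY = sc * -27, rectumBendAmp = sc * 5, rectumRadius = sc * 5.5,
      rectumZ = sc * c(-40, 25),
      femurCenter = sc * c(38, -6, -8), femurR = sc * 11),
    # per-tissue intensity means: CT in HU, MR in arbitrary units
    ct = c(air = -1000, soft = 30, bone = 1000, femur = 700,
           bladder = 0, prostate = 40, rectum = -30),
    t2 = c(air = 2, soft = 45, bone = 15, femur = 28,
           bladder = 180, prostate = 75, rectum = 60),
    t1 = c(air = 2, soft = 90, bone = 20, femur = 120,
           bladder = 35, prostate = 65, rectum = 55),
    noiseSigmaMR = noiseSigmaMR, noiseSigmaCT = noiseSigmaCT,
    biasAmplitude = biasAmplitude, deformAmplitude = deformAmplitude,
    deformSpacing = deformSpacing, rectumRadiusSd = rectumRadiusSd,
    intensityJitter = intensityJitter, mrCrop = as.integer(mrCrop)),
    class = "phantomSpec")
}

phantomGrid <- function(spec) {
  # centre the world origin so geometry coordinates are symmetric
  imageGrid3(spec$shape, spec$spacing,
             origin = -(spec$shape - 1L) * spec$spacing / 2)
}

# Tissue masks from the analytic geometry on a grid, optionally with a
# rectal radius scale.  Returns masks as logical vectors over voxels.
phantomMasks <- function(spec, grid, rectumScale = 1) {
  P <- gridWorldCoords(grid)
  gm <- spec$geom
  ell <- function(center, semi)
    rowSums(sweep(sweep(P, 2L, center), 2L, semi, "/")^2) <= 1
  body <- ell(c(0, 0, 0), gm$bodySemi)
  boneShell <- ell(gm$boneCenter, gm$boneOuter) &
    !ell(gm$boneCenter, gm$boneInner)
  femurL <- ell(gm$femurCenter * c(-1, 1, 1), rep(gm$femurR, 3))
  femurR <- ell(gm$femurCenter, rep(gm$femurR, 3))
  bladder <- ell(gm$bladderCenter, gm$bladderSemi)
  prostate <- ell(gm$prostateCenter, rep(gm$prostateR, 3))
  # rectum: tube along z with a sinusoidal anterior-posterior bend
  inZ <- P[, 3] >= gm$rectumZ[1] & P[, 3] <= gm$rectumZ[2]
  yc <- gm$rectumY + gm$rectumBendAmp * sin(P[, 3] / (0.25 * max(abs(gm$rectumZ))))
  r2 <- P[, 1]^2 + (P[, 2] - yc)^2
  rectum <- inZ & r2 <= (rectumScale * gm$rectumRadius)^2
  organs <- list(prostate = prostate & body, bladder = bladder & body,
                 rectum = rectum & body, LFemurHead = femurL & body,
                 RFemurHead = femurR & body)
  nms <- names(organs)
  for (i in seq_along(organs)) {
    for (j in seq_len(i - 1L)) {
      if (any(organs[[i]] & organs[[j]]))
        stop("phantom organs overlap: ", nms[j], " and ", nms[i])
    }
  }
  c(organs, list(body = body, boneShell = boneShell & body))
}

phantomLabelArray <- function(spec, grid, rectumScale = 1,
                              dict = labelDictionary()) {
  m <- phantomMasks(spec, grid, rectumScale)
  lab <- integer(prod(grid@shape))
  lab[m$body] <- dict$index[["body"]]
  for (nm in c("prostate", "bladder", "rectum", "LFemurHead", "RFemurHead"))
    lab[m[[nm]]] <- dict$index[[nm]]
  list(labels = array(lab, grid@shape),
       bone = array(m$boneShell | m$LFemurHead | m$RFemurHead, grid@shape))
}

# Render the three modalities from a label array + bone mask.
# jitter: named multiplicative factors per tissue (or NULL).
renderModalities <- function(labArr, boneArr, spec, grid,
                             dict = labelDictionary(), jitter = NULL,
                             noise = TRUE, bias = TRUE) {
  tissue <- character(length(labArr))
  nm <- dict$names[as.integer(labArr) + 1L]
  tissue[nm == "background"] <- "air"
  tissue[nm == "body"] <- "soft"
  tissue[nm == "prostate"] <- "prostate"
  tissue[nm == "bladder"] <- "bladder"
  tissue[nm == "rectum"] <- "rectum"
  tissue[nm %in% c("LFemurHead", "RFemurHead")] <- "femur"
  tissue[as.vector(boneArr) & nm == "body"] <- "bone"
  jf <- function(tab) {
    if (is.null(jitter)) return(tab)
    tab * jitter[names(tab)]
  }
  mk <- function(tab, sigma, isMR, modality) {
    v <- jf(tab)[tissue]
    v <- array(v, grid@shape)
    if (isMR && bias && spec$biasAmplitude > 0)
      v <- v * biasField(grid, spec$biasAmplitude)
    if (noise && sigma > 0) v <- v + array(stats::rnorm(length(v), 0, sigma),
                                           grid@shape)
    fov <- array(1, grid@shape)
    if (isMR) {
      cx <- spec$mrCrop[1]; cz <- spec$mrCrop[2]
      if (cx > 0) fov[c(seq_len(cx), grid@shape[1] + 1L - seq_len(cx)), , ] <- 0
      if (cz > 0) fov[, , c(seq_len(cz), grid@shape[3] + 1L - seq_len(cz))] <- 0
      v[fov < 0.5] <- 0
    }
    scalarVolume(v, grid, fov = fov, modality = modality)
  }
  list(t2 = mk(spec$t2, spec$noiseSigmaMR, TRUE, "T2"),
       t1 = mk(spec$t1, spec$noiseSigmaMR, TRUE, "T1"),
       ct = mk(spec$ct, spec$noiseSigmaCT, FALSE, "CT"))
}

# Smooth multiplicative bias field: low-frequency random field in
# [1 - a, 1 + a], from upsampled coarse noise.
biasField <- function(grid, amplitude) {
  coarse <- array(stats::rnorm(4^3), c(4, 4, 4))
  vox <- sweep(gridVoxelIndices(grid), 2L, (grid@shape - 1L) / 3, "/")
  s <- sampleArrayAtVoxels(coarse, vox, "linear")
  f <- array(s$values, grid@shape)
  f <- f / max(abs(f), 1e-9)
  1 + amplitude * f
}

gridVoxelIndices <- function(grid) {
  s <- grid@shape
  cbind(rep.int(seq_len(s[1]) - 1L, s[2] * s[3]),
        rep.int(rep(seq_len(s[2]) - 1L, each = s[1]), s[3]),
        rep(seq_len(s[3]) - 1L, each = s[1] * s[2]))
}

#' Generate the phantom template subject
#'
#' Renders the symmetric template anatomy: CT, T1 and T2 volumes from the
#' per-tissue intensity tables (plus MR bias field and Gaussian noise), a
#' one-hot organ segmentation, and the true bone mask.  Deterministic
#' given the seed.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @param seed RNG seed.
#' @param dict label dictionary (default pelvic set).
#' @return list with \code{record} (an \code{AtlasRecord}),
#'   \code{labels} (a \code{CategoricalSegVolume}) and \code{boneMask}
#'   (3-D logical array).
#' @export
generateTemplate <- function(spec = phantomSpec(), seed = 1,
                             dict = labelDictionary()) {
  set.seed(seed)
  grid <- phantomGrid(spec)
  la <- phantomLabelArray(spec, grid, dict = dict)
  mods <- renderModalities(la$labels, la$bone, spec, grid, dict)
  L <- length(dict$names)
  rec <- atlasRecord("template", mods$t2, mods$t1, mods$ct,
                     oneHotSeg(la$labels, L, grid))
  list(record = rec, labels = categoricalSegVolume(la$labels, L, grid),
       boneMask = la$bone)
}

# Random smooth displacement (B-spline coefficients ~ N(0, amplitude)) on
# the grid, with a folding guard that halves the amplitude if needed.
randomSmoothWarp <- function(grid, amplitude, spacing, rectumScaleShift = 0,
                             spec = NULL) {
  lat <- makeLattice(grid, spacing)
  theta <- array(stats::rnorm(prod(lat$ncp) * 3, 0, amplitude),
                 c(lat$ncp, 3L))
  for (guard in 1:8) {
    disp <- array(bsplineDense(lat, theta), c(grid@shape, 3L))
    Tw <- displacementTransform(disp, grid)
    if (min(jacobianDeterminant(Tw)) > 0.05) return(Tw)
    message("phantom warp caused folding; halving amplitude")
    theta <- theta / 2
  }
  displacementTransform(array(0, c(grid@shape, 3L)), grid)
}

#' Generate a phantom cohort with ground truth
#'
#' Each subject is the template warped by an independent random smooth
#' B-spline deformation (positive Jacobian guaranteed by a folding guard)
#' plus a per-subject rectal filling change, re-rendered with per-subject
#' intensity jitter, bias and noise.  The true warps are retained so that
#' registration accuracy can be scored against ground truth.  One extra
#' subject is generated as the held-out target.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @param N number of atlas subjects (>= 2).
#' @param seed RNG seed (full determinism under (spec, N, seed)).
#' @param dict label dictionary.
#' @return list with \code{db} (an \code{AtlasDatabase}), \code{target}
#'   (list: record, labels, boneMask, trueWarp) and \code{trueWarps}
#'   (per-subject \code{SpatialTransform}s).
#' @export
generateCohort <- function(spec = phantomSpec(), N = 8L, seed = 1,
                           dict = labelDictionary()) {
  if (N < 2L) stop("N must be >= 2")
  set.seed(seed)
  grid <- phantomGrid(spec)
  L <- length(dict$names)
  subjects <- vector("list", N + 1L)
  warps <- vector("list", N + 1L)
  for (i in seq_len(N + 1L)) {
    rectumScale <- max(0.5, 1 + stats::rnorm(1, 0, spec$rectumRadiusSd))
    warp <- randomSmoothWarp(grid, spec$deformAmplitude,
                             spec$deformSpacing)
    la <- phantomLabelArray(spec, grid, rectumScale, dict)
    labWarp <- applyTransform(
      categoricalSegVolume(la$labels, L, grid), warp, grid, "nearest")
    boneWarp <- applyTransform(
      categoricalSegVolume(array(as.integer(la$bone), grid@shape), 2L, grid),
      warp, grid, "nearest")
    jitter <- NULL
    if (spec$intensityJitter > 0) {
      nm <- names(spec$ct)
      jitter <- stats::setNames(
        pmax(0.5, 1 + stats::rnorm(length(nm), 0, spec$intensityJitter)), nm)
    }
    mods <- renderModalities(labWarp@labels, boneWarp@labels > 0L,
                             spec, grid, dict, jitter = jitter)
    id <- if (i <= N) sprintf("subj%02d", i) else "target"
    subjects[[i]] <- list(
      record = atlasRecord(id, mods$t2, mods$t1, mods$ct,
                           oneHotSeg(labWarp@labels, L, grid)),
      labels = labWarp, boneMask = boneWarp@labels > 0L)
    warps[[i]] <- warp
  }
  db <- atlasDatabase(lapply(subjects[seq_len(N)], `[[`, "record"), dict)
  target <- subjects[[N + 1L]]
  target$trueWarp <- warps[[N + 1L]]
  list(db = db, target = target, trueWarps = warps[seq_len(N)])
}

#' Introduce a known CT misalignment into a record
#'
#' Warps the record's CT (and a CT-side copy of the segmentation, for
#' scoring) by a known random smooth field, returning the corrupted
#' record together with the ground-truth warp — the fixture for the atlas
#' database refinement experiments.
#'
#' @param record an \code{AtlasRecord}.
#' @param amplitude B-spline coefficient sd in mm (> 0).
#' @param spacing control spacing of the warp in mm.
#' @param seed RNG seed.
#' @return list with \code{record} (CT replaced by its misaligned
#'   version), \code{ctSeg} (segmentation misaligned identically) and
#'   \code{trueWarp} (the \code{SpatialTransform} that maps the record
#'   grid onto the original CT).
#' @export
misalignRecord <- function(record, amplitude, spacing = 40, seed = 1) {
  if (amplitude <= 0) stop("amplitude must be > 0")
  set.seed(seed)
  grid <- imageGrid(record)
  warp <- randomSmoothWarp(grid, amplitude, spacing)
  ctMis <- applyTransform(record@ct, warp, grid, "linear")
  segMis <- applyTransform(record@seg, warp, grid, "nearest")
  rec <- atlasRecord(record@id, record@t2, record@t1, ctMis, record@seg,
                     flipped = record@flipped)
  list(record = rec, ctSeg = segMis, trueWarp = warp)
}
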