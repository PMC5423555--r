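test_that("LNCC cost: self-correlation, affine invariance, oracle", {
  vol <- randomVolume(10, seed = 61)
  lc <- lnccCost(vol, vol, 2)
  expect_lt(lc$cost, 1e-9)
  expect_true(all(abs(similarityScores(lc$field)[validMask(lc$field)] - 1)
                  < 1e-9))
  aff <- scalarVolume(3 * voxelData(vol) - 40, imageGrid(vol),
                      fovMask(vol))
  expect_lt(lnccCost(vol, aff, 2)$cost, 1e-9)
  volJ <- randomVolume(10, seed = 62)
  lr <- lnccCost(vol, volJ, 2)
  cv <- oracleCovariance(voxelData(vol), voxelData(volJ),
                         fovMask(vol) * fovMask(volJ), 2)
  mi <- oracleMoments(voxelData(vol), fovMask(vol) * fovMask(volJ), 2)
  mj <- oracleMoments(voxelData(volJ), fovMask(vol) * fovMask(volJ), 2)
  cc <- cv / sqrt(pmax(mi$variance, 1e-300) * pmax(mj$variance, 1e-300))
  sel <- validMask(lr$field)
  expect_lt(max(abs(similarityScores(lr$field)[sel] - cc[sel])), 1e-6)
  expect_equal(lr$cost, 1 - mean(cc[sel]), tolerance = 1e-9)
})

test_that("KLD cost: identity zero, clamp-dominated disjoint case, oracle", {
  segF <- randomSeg(6, L = 4, seed = 63, oneHot = FALSE)
  expect_equal(kldCost(segF, segF)$cost, 0, tolerance = 1e-12)
  g1 <- imageGrid3(c(1, 1, 1))
  a <- oneHotSeg(array(1L, c(1, 1, 1)), 3, g1)
  b <- oneHotSeg(array(2L, c(1, 1, 1)), 3, g1)
  kl <- kldCost(a, b)$cost
  # one-hot a vs one-hot b: dominated by log(1/eps)
  expect_equal(kl, log(1 / 1e-6), tolerance = 0.05 * kl)
  segM <- randomSeg(6, L = 4, seed = 64, oneHot = FALSE)
  got <- kldCost(segF, segM)
  clamp <- function(m) { m <- pmax(pmin(m, 1), 1e-6); m / rowSums(m) }
  Fm <- clamp(matrix(probArray(segF), ncol = 4))
  Mm <- clamp(matrix(probArray(segM), ncol = 4))
  expect_equal(got$cost, mean(rowSums(Fm * log(Fm / Mm))),
               tolerance = 1e-9)
  expect_gte(got$cost, 0)
  expect_error(kldCost(segF, randomSeg(6, L = 3)), "label")
})

test_that("applyTransform: identity, integer shift, ramp through warp", {
  vol <- randomVolume(8, seed = 65)
  idOut <- applyTransform(vol, identityTransform(), imageGrid(vol),
                          "nearest")
  expect_identical(voxelData(idOut), voxelData(vol))
  expect_identical(fovMask(idOut), fovMask(vol))
  # 1-voxel integer translation with nearest: shifted copy, FOV trimmed
  sh <- applyTransform(vol, translationTransform(c(1, 0, 0)),
                       imageGrid(vol), "nearest")
  expect_equal(voxelData(sh)[1:7, , ], voxelData(vol)[2:8, , ])
  expect_true(all(fovMask(sh)[8, , ] == 0))
  # analytic ramp through a smooth random warp (linear interpolation)
  g <- imageGrid3(c(12, 12, 12), 2)
  pts <- atlasfusion:::gridWorldCoords(g)
  ramp <- scalarVolume(array(1.5 * pts[, 1] - 0.5 * pts[, 2] + pts[, 3],
                             c(12, 12, 12)), g)
  set.seed(66)
  warp <- atlasfusion:::randomSmoothWarp(g, 1.5, 20)
  out <- applyTransform(ramp, warp, g, "linear")
  mpts <- transformPoints(warp, pts)
  expected <- 1.5 * mpts[, 1] - 0.5 * mpts[, 2] + mpts[, 3]
  ok <- as.vector(fovMask(out) > 0.5)
  expect_lt(max(abs(as.vector(voxelData(out))[ok] - expected[ok])), 1e-4)
  # output FOV never exceeds the pullback of the input FOV
  holed <- randomVolume(8, seed = 67)
  outH <- applyTransform(holed, translationTransform(c(0.6, 0, 0)),
                         imageGrid(holed), "linear")
  pulled <- applyTransform(
    scalarVolume(fovMask(holed), imageGrid(holed)),
    translationTransform(c(0.6, 0, 0)), imageGrid(holed), "nearest")
  expect_true(all(fovMask(outH) <= voxelData(pulled) + 1e-12 +
                    (fovMask(pulled) < 0.5)))
  expect_error(applyTransform(vol, identityTransform(), imageGrid(vol),
                              "quintic"), "arg")
})

test_that("multichannel cost is the weighted sum of single-channel costs", {
  tm <- cleanTemplate()
  rec <- tm$record
  g <- imageGrid(rec)
  set.seed(68)
  warp <- atlasfusion:::randomSmoothWarp(g, 1.5, 60)
  u <- matrix(displacementField(warp), ncol = 3)
  spec <- registrationSpec(list(t2 = list(sim = "lncc"),
                                seg = list(sim = "kld")),
                          lnccSigma = 2)
  work <- list(
    t2 = atlasfusion:::prepareChannel(rec@t2, rec@t2,
                                      list(sim = "lncc", weight = 1), 1,
                                      gradients = FALSE),
    seg = atlasfusion:::prepareChannel(rec@seg, rec@seg,
                                       list(sim = "kld", weight = 1), 1,
                                       gradients = FALSE))
  X <- atlasfusion:::gridWorldCoords(g)
  both <- atlasfusion:::channelCosts(work, X, diag(4), u, spec)$total
  only1 <- atlasfusion:::channelCosts(work["t2"], X, diag(4), u, spec)$total
  only2 <- atlasfusion:::channelCosts(work["seg"], X, diag(4), u, spec)$total
  expect_equal(both, only1 + only2, tolerance = 1e-12)
})

test_that("registration recovers identity and known transforms", {
  tm <- smallTemplate()
  t2 <- t2Volume(tm$record)
  g <- imageGrid(tm$record)
  spec <- registrationSpec(list(img = list(sim = "lncc")), levels = 2,
                           controlSpacing = 20, maxIter = 4,
                           globalRefineIter = 8)
  # fixed = moving: near-zero displacement
  Tid <- registerMultichannel(list(img = t2), list(img = t2), spec)
  u <- matrix(displacementField(Tid), ncol = 3)
  expect_lt(max(sqrt(rowSums(u^2))), 0.1 * min(gridSpacing(g)))
  expect_lt(max(abs(transformAffine(Tid)[1:3, 4])), 0.3)
  # known translation (applied to the fixed side: recovered directly)
  moved <- applyTransform(t2, translationTransform(c(4, 0, 0)), g,
                          "linear")
  Ttr <- registerMultichannel(list(img = moved), list(img = t2),
                              registrationSpec(list(img = list(sim = "lncc")),
                                               levels = 2, maxIter = 0,
                                               controlSpacing = 20,
                                               globalRefineIter = 40))
  expect_lt(max(abs(transformAffine(Ttr)[1:3, 4] - c(4, 0, 0))), 0.5)
  # displacement fields are folding-free on this easy problem
  expect_gt(mean(jacobianDeterminant(Tid) > 0), 0.99)
})

test_that("nearest propagation keeps segmentations one-hot under warps", {
  seg <- segVolume(smallTemplate()$record)
  g <- imageGrid(seg)
  set.seed(69)
  warp <- atlasfusion:::randomSmoothWarp(g, 2, 40)
  out <- applyTransform(seg, warp, g, "nearest")
  expect_true(all(probArray(out) %in% c(0, 1)))
  expect_true(all(abs(apply(probArray(out), 1:3, sum) - 1) < 1e-12))
})

test_that("transforms and registration specs round-trip through disk", {
  set.seed(70)
  g <- imageGrid3(c(6, 6, 6), 2.5, origin = c(-5, 0, 3))
  disp <- array(rnorm(6^3 * 3), c(6, 6, 6, 3))
  A <- diag(4); A[1:3, 4] <- c(1, -2, 0.5)
  tr <- displacementTransform(disp, g, affine = A)
  prefix <- file.path(tempdir(), "tr")
  writeTransform(tr, prefix)
  back <- readTransform(prefix)
  expect_equal(transformAffine(back), A)
  expect_equal(displacementField(back), disp, tolerance = 1e-12)
  expect_true(sameGrid(back@dispGrid, g))
  file.remove(paste0(prefix, "_affine.txt"), paste0(prefix, "_disp.nii.gz"))
  # affine-only transforms need no displacement file
  writeTransform(translationTransform(c(3, 0, 0)), prefix)
  backA <- readTransform(prefix)
  expect_equal(transformAffine(backA)[1:3, 4], c(3, 0, 0))
  file.remove(paste0(prefix, "_affine.txt"))
  # registration spec YAML round trip
  spec <- registrationSpec(list(a = list(sim = "lncc2", weight = 0.5),
                                b = list(sim = "kld")),
                           levels = 2, controlSpacing = 12.5, maxIter = 7)
  yml <- file.path(tempdir(), "spec.yaml")
  writeRegistrationSpec(spec, yml)
  spec2 <- readRegistrationSpec(yml)
  expect_equal(spec2$channels$a$weight, 0.5)
  expect_equal(spec2$controlSpacing, 12.5)
  expect_equal(spec2$levels, 2L)
  file.remove(yml)
})
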