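test_that("normalised moments match the brute-force windowed oracle", {
  vol <- randomVolume(10, seed = 11)
  mo <- normalizedMoments(vol, sigmaG = 2)
  br <- oracleMoments(voxelData(vol), fovMask(vol), 2)
  sel <- mo$valid & !is.na(br$mean)
  expect_lt(max(abs(mo$mean[sel] - br$mean[sel])), 1e-6)
  expect_lt(max(abs(mo$variance[sel] - pmax(br$variance[sel], 0))), 1e-6)
  # constant volume: mean c, zero variance wherever density is positive
  const <- scalarVolume(array(3.5, c(8, 8, 8)))
  mc <- normalizedMoments(const, 3)
  expect_lt(max(abs(mc$mean - 3.5)), 1e-9)
  expect_lt(max(mc$variance), 1e-9)
  # half-masked constant: density normalisation cancels the mask
  fov <- array(1, c(8, 8, 8)); fov[, 1:4, ] <- 0
  mh <- normalizedMoments(scalarVolume(array(2, c(8, 8, 8)), fov = fov), 2)
  expect_lt(max(abs(mh$mean[mh$valid] - 2)), 1e-9)
  expect_error(normalizedMoments(
    scalarVolume(array(1, c(4, 4, 4)), fov = array(0, c(4, 4, 4))), 2),
    "empty")
})

test_that("ROI-SSIM: self-similarity, closed forms, oracle, FOV sentinel", {
  volI <- randomVolume(10, seed = 12)
  s <- roiSSIM(volI, volI, 2, C1 = 1e-4, C2 = 1e-4)
  expect_lt(max(abs(similarityScores(s)[validMask(s)] - 1)), 1e-9)
  # constants I=1, J=0: structure term 1, luminance C1/(1+C1)
  g8 <- imageGrid3(c(8, 8, 8))
  one <- scalarVolume(array(1, c(8, 8, 8)), g8)
  zero <- scalarVolume(array(0, c(8, 8, 8)), g8)
  sc <- roiSSIM(one, zero, 2, C1 = 0.02, C2 = 0.03)
  expect_lt(max(abs(similarityScores(sc)[validMask(sc)] -
                      0.02 / 1.02)), 1e-9)
  # random pair vs brute-force windowed oracle
  volJ <- randomVolume(10, seed = 13)
  sr <- roiSSIM(volI, volJ, 2, C1 = 0.01, C2 = 0.05)
  br <- oracleSSIM(voxelData(volI), voxelData(volJ), fovMask(volI),
                   fovMask(volJ), 2, C1 = 0.01, C2 = 0.05)
  expect_lt(max(abs(similarityScores(sr)[validMask(sr)] -
                      br[validMask(sr)])), 1e-6)
  # voxels farther than the truncated kernel support from any FOV voxel
  # carry the -Inf sentinel
  fovDeep <- array(1, c(10, 10, 10)); fovDeep[1:9, , ] <- 0
  volDeep <- scalarVolume(voxelData(volJ), imageGrid(volJ), fov = fovDeep)
  sd <- roiSSIM(volI, volDeep, 1, C1 = 0.01, C2 = 0.05)
  expect_true(any(!validMask(sd)))
  expect_true(all(similarityScores(sd)[!validMask(sd)] == -Inf))
  # symmetry in the arguments
  sji <- roiSSIM(volJ, volI, 2, C1 = 0.01, C2 = 0.05)
  expect_identical(similarityScores(sr), similarityScores(sji))
  expect_error(roiSSIM(volI, volJ, 2, C1 = -1, C2 = 1), "C1")
})

test_that("ROI-SSIM is insensitive to voxels beyond the kernel support", {
  volI <- randomVolume(12, seed = 14, fovHole = FALSE)
  volJ <- randomVolume(12, seed = 15, fovHole = FALSE)
  s1 <- roiSSIM(volI, volJ, 1.5, C1 = 0.01, C2 = 0.05)
  vals <- voxelData(volI)
  vals[12, 12, 12] <- vals[12, 12, 12] + 100   # far corner
  s2 <- roiSSIM(scalarVolume(vals, imageGrid(volI), fovMask(volI)), volJ,
                1.5, C1 = 0.01, C2 = 0.05)
  # at the opposite corner, far outside the truncated kernel support
  expect_lt(abs(similarityScores(s1)[1, 1, 1] -
                  similarityScores(s2)[1, 1, 1]), 1e-9)
})

test_that("local fuzzy Dice matches its oracle and conventions", {
  segI <- randomSeg(8, L = 4, seed = 16)
  segJ <- randomSeg(8, L = 4, seed = 17)
  ld <- localFuzzyDice(segI, segJ, 2)
  br <- oracleLDSC(probArray(segI), probArray(segJ), 2)
  expect_lt(max(abs(similarityScores(ld) - br)), 1e-6)
  # identical segmentations: score = number of labels with smoothed mass
  ldi <- localFuzzyDice(segI, segI, 2)
  smoothedMass <- sapply(2:4, function(l)
    oracleSmooth(probArray(segI)[, , , l], 2) > 1e-12)
  k <- array(rowSums(smoothedMass), c(8, 8, 8))
  expect_lt(max(abs(similarityScores(ldi) - k)), 1e-6)
  # disjoint support within the kernel: zero score
  labA <- array(0L, c(12, 12, 12)); labA[1:3, , ] <- 1L
  labB <- array(0L, c(12, 12, 12)); labB[10:12, , ] <- 1L
  ld0 <- localFuzzyDice(oneHotSeg(labA, 2), oneHotSeg(labB, 2), 1)
  expect_equal(similarityScores(ld0)[1, 6, 6], 0)
  # range [0, L'] and symmetry
  expect_true(all(similarityScores(ld) >= 0 &
                    similarityScores(ld) <= 3 + 1e-9))
  ldj <- localFuzzyDice(segJ, segI, 2)
  expect_equal(similarityScores(ld), similarityScores(ldj))
  expect_error(localFuzzyDice(segI, randomSeg(8, L = 3)), "label count")
})

test_that("LSIM composes channel scores and obeys the first-iteration rule", {
  n <- 10
  t2 <- randomVolume(n, seed = 18); t1 <- randomVolume(n, seed = 19)
  pct <- scalarVolume(voxelData(randomVolume(n, seed = 20)) * 100,
                      imageGrid(t2), modality = "pCT")
  seg <- randomSeg(n, L = 3, seed = 21)
  state <- targetState(t2, t1, pct, seg, t = 1L)
  prop <- new("PropagatedAtlas", id = "a",
              jT2 = randomVolume(n, seed = 22),
              jT1 = randomVolume(n, seed = 23),
              jCt = scalarVolume(voxelData(randomVolume(n, seed = 24)) * 100,
                                 imageGrid(t2), modality = "CT"),
              jSeg = randomSeg(n, L = 3, seed = 25),
              votes = randomSeg(n, L = 3, seed = 25))
  s2 <- lsim(state, prop, t = 2, sigmaG = 2)
  parts <- list(roiSSIM(t2, prop@jT2, 2), roiSSIM(t1, prop@jT1, 2),
                roiSSIM(pct, prop@jCt, 2),
                localFuzzyDice(seg, prop@jSeg, 2))
  manual <- Reduce(`+`, lapply(parts, similarityScores))
  valid <- Reduce(`&`, lapply(parts, validMask))
  expect_lt(max(abs(similarityScores(s2)[valid] - manual[valid])), 1e-9)
  expect_true(all(similarityScores(s2)[!valid] == -Inf))
  # t = 1: result must not depend on the pCT / segmentation channels
  s1 <- lsim(state, prop, t = 1, sigmaG = 2)
  stateNoPct <- targetState(t2, t1)
  s1b <- lsim(stateNoPct, prop, t = 1, sigmaG = 2)
  expect_identical(similarityScores(s1), similarityScores(s1b))
  expect_error(lsim(stateNoPct, prop, t = 2, sigmaG = 2), "t >= 2")
})

test_that("atlas identical to a perfectly aligned target maxes out LSIM", {
  tm <- cleanTemplate()
  rec <- tm$record
  state <- targetState(rec@t2, rec@t1,
                       scalarVolume(voxelData(rec@ct), imageGrid(rec),
                                    fovMask(rec@ct), "pCT"),
                       rec@seg, t = 1L)
  prop <- new("PropagatedAtlas", id = "self", jT2 = rec@t2, jT1 = rec@t1,
              jCt = rec@ct, jSeg = rec@seg, votes = rec@seg)
  s <- lsim(state, prop, t = 2, sigmaG = 2)
  ld <- localFuzzyDice(rec@seg, rec@seg, 2)
  expected <- 3 + similarityScores(ld)
  ok <- validMask(s)
  expect_lt(max(abs(similarityScores(s)[ok] - expected[ok])), 1e-6)
})
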