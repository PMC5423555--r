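test_that("fuzzy Dice: identity, disjoint, sphere counting oracle", {
  segA <- randomSeg(8, L = 3, seed = 51)
  expect_equal(fuzzyDice(segA, segA, 1), 1)
  labA <- array(0L, c(8, 8, 8)); labA[1:3, , ] <- 1L
  labB <- array(0L, c(8, 8, 8)); labB[6:8, , ] <- 1L
  expect_equal(fuzzyDice(oneHotSeg(labA, 2), oneHotSeg(labB, 2), 1), 0)
  # two overlapping digital spheres vs the voxel-count formula
  g <- imageGrid3(c(16, 16, 16))
  pts <- atlasfusion:::gridWorldCoords(g)
  sphere <- function(c0, r) array(rowSums(sweep(pts, 2, c0)^2) <= r^2,
                                  c(16, 16, 16))
  A <- sphere(c(7, 7, 7), 4); B <- sphere(c(9, 7, 7), 4)
  d <- fuzzyDice(oneHotSeg(array(as.integer(A), dim(A)), 2, g),
                 oneHotSeg(array(as.integer(B), dim(B)), 2, g), 1)
  expect_equal(d, 2 * sum(A & B) / (sum(A) + sum(B)), tolerance = 1e-12)
  # label absent from both: NA
  expect_true(is.na(fuzzyDice(oneHotSeg(labA * 0L, 3),
                              oneHotSeg(labA * 0L, 3), 2)))
})

test_that("boundary extraction: cube, single voxel, erosion oracle", {
  m <- array(FALSE, c(7, 7, 7)); m[3:5, 3:5, 3:5] <- TRUE
  b <- extractBoundary(m)
  expect_equal(nrow(b), 26)   # all cube voxels except the centre
  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  expect_equal(extractBoundary(single), matrix(c(2, 2, 2), 1))
  # random blob vs morphological erosion-difference oracle
  set.seed(52)
  blob <- array(runif(12^3) > 0.5, c(12, 12, 12))
  b2 <- extractBoundary(blob)
  erode <- blob
  for (ax in 1:3) for (s in c(-1, 1)) {
    shifted <- array(FALSE, dim(blob))
    n <- dim(blob)[ax]
    idxT <- idxF <- rep(list(quote(expr = )), 3)
    idxT[[ax]] <- if (s == 1) 2:n else 1:(n - 1)
    idxF[[ax]] <- if (s == 1) 1:(n - 1) else 2:n
    shifted <- do.call(`[<-`, c(list(shifted), idxF,
                                list(do.call(`[`, c(list(blob), idxT)))))
    erode <- erode & shifted
  }
  oracle <- which(blob & !erode, arr.ind = TRUE) - 1L
  expect_equal(nrow(b2), nrow(oracle))
  expect_equal(b2[order(b2[,3], b2[,2], b2[,1]), ],
               unname(oracle[order(oracle[,3], oracle[,2], oracle[,1]), ]))
  expect_error(extractBoundary(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("modified Hausdorff: 3-4-5 case, symmetry, pairwise oracle", {
  expect_equal(modifiedHausdorff(matrix(c(0, 0, 0), 1),
                                 matrix(c(3, 4, 0), 1)), 5)
  set.seed(53)
  A <- matrix(rnorm(300 * 3, 0, 10), ncol = 3)
  B <- matrix(rnorm(200 * 3, 2, 12), ncol = 3)
  expect_equal(modifiedHausdorff(A, B), oracleMHD(A, B), tolerance = 1e-9)
  expect_equal(modifiedHausdorff(A, B), modifiedHausdorff(B, A))
  expect_equal(modifiedHausdorff(A, A), 0)
  # bounded by the maximum pairwise distance
  maxPair <- sqrt(max(outer(rowSums(A^2), rowSums(B^2), "+") -
                        2 * A %*% t(B)))
  expect_lte(modifiedHausdorff(A, B), maxPair)
  expect_error(modifiedHausdorff(A[0, , drop = FALSE], B), "empty")
})

test_that("MAE/ME: closed forms, oracle, MAE >= |ME|", {
  g <- imageGrid3(c(8, 8, 8))
  set.seed(54)
  ref <- scalarVolume(array(rnorm(512, 0, 300), c(8, 8, 8)), g,
                      modality = "CT")
  expect_equal(unname(maeMe(ref, ref, array(TRUE, c(8, 8, 8)))), c(0, 0))
  plus10 <- scalarVolume(voxelData(ref) + 10, g, modality = "pCT")
  expect_equal(unname(maeMe(plus10, ref, array(TRUE, c(8, 8, 8)))),
               c(10, 10))
  pct <- scalarVolume(array(rnorm(512, 0, 300), c(8, 8, 8)), g,
                      modality = "pCT")
  roi <- array(runif(512) > 0.4, c(8, 8, 8))
  mm <- maeMe(pct, ref, roi)
  diff <- voxelData(pct)[roi] - voxelData(ref)[roi]
  expect_equal(unname(mm), c(mean(abs(diff)), mean(diff)),
               tolerance = 1e-9)
  expect_gte(mm["mae"], abs(mm["me"]))
  expect_error(maeMe(pct, ref, array(FALSE, c(8, 8, 8))), "empty")
})

test_that("NMI: self-information 2, independence limit, histogram oracle", {
  set.seed(55)
  g <- imageGrid3(c(12, 12, 12))
  x <- array(rnorm(12^3), c(12, 12, 12))
  vx <- scalarVolume(x, g)
  expect_equal(nmi(vx, vx, 32), 2, tolerance = 1e-9)
  # independent uniform noise: NMI -> 1 at large sample
  g2 <- imageGrid3(c(24, 24, 24))
  a <- scalarVolume(array(runif(24^3), c(24, 24, 24)), g2)
  b <- scalarVolume(array(runif(24^3), c(24, 24, 24)), g2)
  expect_equal(nmi(a, b, 16), 1, tolerance = 0.02)
  y <- scalarVolume(array(rnorm(12^3), c(12, 12, 12)), g)
  expect_equal(nmi(vx, y, 24),
               oracleNMI(as.vector(x), as.vector(voxelData(y)), 24),
               tolerance = 1e-9)
  # degenerate single-bin image: NA
  expect_true(is.na(nmi(scalarVolume(array(1, c(4, 4, 4))),
                        scalarVolume(array(rnorm(64), c(4, 4, 4))))))
})

test_that("water-only pseudo-CT thresholds, fills cavities and is air outside", {
  tm <- cleanTemplate()
  ct <- ctVolume(tm$record)
  w <- waterOnlyPct(ct)
  body <- attr(w, "bodyMask")
  expect_true(all(voxelData(w)[body] == 0))
  expect_true(all(voxelData(w)[!body] == -1000))
  # phantom body (CT > -500 everywhere inside incl. rectum contents)
  trueBody <- labelArray(tm$labels) > 0
  expect_gt(mean(body == trueBody), 0.995)
  # internal air cavity is filled
  vals <- voxelData(ct)
  vals[15:17, 15:17, 15:17] <- -1000
  w2 <- waterOnlyPct(scalarVolume(vals, imageGrid(ct), modality = "CT"))
  expect_true(all(voxelData(w2)[15:17, 15:17, 15:17] == 0))
  expect_error(waterOnlyPct(ct, threshold = 5000), "empty body")
})
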