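test_that("the rank-decay schedule follows beta_1 = 1 minus 0.125 per step", {
  expect_equal(betaSchedule(1), 1)
  expect_equal(betaSchedule(4), 0.625)
  expect_equal(betaSchedule(7), 0.25)
  expect_equal(betaSchedule(10), 0.125)  # floored
  expect_error(betaSchedule(0), "integer")
})

test_that("per-voxel ranking matches an argsort oracle and excludes -Inf", {
  g <- imageGrid3(c(10, 10, 10))
  mkSim <- function(seed) {
    set.seed(seed)
    sc <- array(rnorm(1000), c(10, 10, 10))
    valid <- array(runif(1000) > 0.2, c(10, 10, 10))
    similarityVolume(sc, valid, g)
  }
  sims <- lapply(1:8, mkSim)
  rf <- rankAtlases(sims)
  mat <- sapply(sims, function(s) as.vector(similarityScores(s)))
  ranks <- matrix(atlasRanks(rf), ncol = 8)
  for (v in sample(1000, 50)) {
    fin <- which(is.finite(mat[v, ]))
    if (length(fin) == 0) {
      expect_false(fusableMask(rf)[arrayInd(v, c(10, 10, 10))])
      next
    }
    ord <- fin[order(-mat[v, fin], fin)]
    expect_equal(ranks[v, ord], seq_along(ord) - 1L)
    expect_true(all(is.na(ranks[v, setdiff(1:8, fin)])))
  }
  # stated example: (0.9, 0.2, 0.5) -> ranks (0, 2, 1)
  one <- function(x) similarityVolume(array(x, c(1, 1, 1)),
                                      array(is.finite(x), c(1, 1, 1)),
                                      imageGrid3(c(1, 1, 1)))
  r <- rankAtlases(list(one(0.9), one(0.2), one(0.5)))
  expect_equal(as.vector(atlasRanks(r)), c(0L, 2L, 1L))
  # all -Inf: flagged unfusable
  rAll <- rankAtlases(list(one(-Inf), one(-Inf)))
  expect_false(any(fusableMask(rAll)))
})

test_that("exponential weights: closed form, monotone, zero for excluded", {
  g <- imageGrid3(c(4, 4, 4))
  set.seed(31)
  sims <- lapply(1:8, function(i)
    similarityVolume(array(rnorm(64), c(4, 4, 4)),
                     array(TRUE, c(4, 4, 4)), g))
  rf <- rankAtlases(sims)
  w <- weightsFromRanks(rf, 0.625)
  expect_lt(max(abs(fusionWeights(w) - exp(-0.625 * atlasRanks(rf))),
                na.rm = TRUE), 1e-12)
  expect_equal(max(fusionWeights(w)), 1)   # rank 0 -> weight 1
  expect_equal(exp(-1), weightsFromRanks(rf, 1)@weights[
    which(atlasRanks(rf) == 1L)[1]])
  expect_error(weightsFromRanks(rf, 0), "beta")
})

test_that("intensity fusion equals the brute-force weighted average", {
  n <- 8; N <- 8
  g <- imageGrid3(rep(n, 3))
  set.seed(32)
  sims <- lapply(seq_len(N), function(i)
    similarityVolume(array(rnorm(n^3), rep(n, 3)),
                     array(runif(n^3) > 0.1, rep(n, 3)), g))
  cts <- lapply(seq_len(N), function(i)
    scalarVolume(array(rnorm(n^3, 0, 200), rep(n, 3)), g, modality = "CT"))
  w <- weightsFromRanks(rankAtlases(sims), 0.7)
  fused <- fuseIntensity(w, cts)
  wm <- matrix(fusionWeights(w), ncol = N)
  cm <- sapply(cts, function(v) as.vector(voxelData(v)))
  expected <- rowSums(wm * cm) / rowSums(wm)
  ok <- rowSums(wm) > 0
  expect_lt(max(abs(as.vector(voxelData(fused))[ok] - expected[ok])), 1e-9)
  # convex combination: fused value within the per-voxel atlas range
  lo <- apply(ifelse(wm > 0, cm, Inf), 1, min)
  hi <- apply(ifelse(wm > 0, cm, -Inf), 1, max)
  expect_true(all(voxelData(fused)[ok] >= lo[ok] - 1e-9 &
                    voxelData(fused)[ok] <= hi[ok] + 1e-9))
  # single atlas: bit-exact copy
  w1 <- weightsFromRanks(rankAtlases(sims[1]), 1)
  f1 <- fuseIntensity(w1, cts[1])
  sel <- fusableMask(w1)
  expect_identical(voxelData(f1)[sel], voxelData(cts[[1]])[sel])
  expect_error(fuseIntensity(w, cts[1:3]), "atlases")
})

test_that("label fusion is a normalised weighted vote on a simplex", {
  n <- 8; N <- 6; L <- 4
  g <- imageGrid3(rep(n, 3))
  set.seed(33)
  sims <- lapply(seq_len(N), function(i)
    similarityVolume(array(rnorm(n^3), rep(n, 3)),
                     array(runif(n^3) > 0.1, rep(n, 3)), g))
  votes <- lapply(seq_len(N), function(i) randomSeg(n, L, seed = 40 + i))
  w <- weightsFromRanks(rankAtlases(sims), 0.5)
  fused <- fuseLabels(w, votes)
  p <- matrix(probArray(fused), ncol = L)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  wm <- matrix(fusionWeights(w), ncol = N)
  for (v in sample(n^3, 40)) {
    num <- numeric(L)
    for (a in seq_len(N))
      num <- num + wm[v, a] * matrix(probArray(votes[[a]]), ncol = L)[v, ]
    if (sum(num) > 0) expect_lt(max(abs(p[v, ] - num / sum(num))), 1e-9)
    else expect_equal(p[v, ], c(1, rep(0, L - 1)))  # unfusable: background
  }
  # two equal-weight atlases voting different labels -> 0.5 / 0.5
  g1 <- imageGrid3(c(1, 1, 1))
  s1 <- similarityVolume(array(0.5, c(1, 1, 1)), array(TRUE, c(1, 1, 1)), g1)
  vA <- oneHotSeg(array(1L, c(1, 1, 1)), 3, g1)
  vB <- oneHotSeg(array(2L, c(1, 1, 1)), 3, g1)
  wEq <- weightsFromRanks(rankAtlases(list(s1, s1)), 1e-9)
  pf <- probArray(fuseLabels(wEq, list(vA, vB)))
  expect_equal(as.vector(pf), c(0, 0.5, 0.5), tolerance = 1e-6)
  # single-atlas identity
  w1 <- weightsFromRanks(rankAtlases(sims[1]), 1)
  f1 <- fuseLabels(w1, votes[1])
  sel <- as.vector(fusableMask(w1))
  expect_equal(matrix(probArray(f1), ncol = L)[sel, ],
               matrix(probArray(votes[[1]]), ncol = L)[sel, ])
  expect_error(fuseLabels(w, votes, oneHot = FALSE), NA)
})

test_that("fusion respects atlas-order permutation and the beta limits", {
  n <- 6; N <- 5
  g <- imageGrid3(rep(n, 3))
  set.seed(34)
  # distinct scores so that ties cannot occur
  sims <- lapply(seq_len(N), function(i)
    similarityVolume(array(rnorm(n^3) + i * 1e-3, rep(n, 3)),
                     array(TRUE, rep(n, 3)), g))
  # O(0.1) intensities keep the first-order beta*r deviation of the
  # beta -> 0 limit below the 1e-6 check tolerance
  cts <- lapply(seq_len(N), function(i)
    scalarVolume(array(rnorm(n^3, 0, 0.1), rep(n, 3)), g, modality = "CT"))
  w <- weightsFromRanks(rankAtlases(sims), 0.8)
  fused <- fuseIntensity(w, cts)
  perm <- c(3, 1, 5, 2, 4)
  wP <- weightsFromRanks(rankAtlases(sims[perm]), 0.8)
  fusedP <- fuseIntensity(wP, cts[perm])
  expect_lt(max(abs(voxelData(fused) - voxelData(fusedP))), 1e-12)
  # beta -> infinity: rank-0 (best) atlas copy
  wBig <- weightsFromRanks(rankAtlases(sims), 50)
  fBig <- fuseIntensity(wBig, cts)
  mat <- sapply(sims, function(s) as.vector(similarityScores(s)))
  bestIdx <- max.col(mat, ties.method = "first")
  cm <- sapply(cts, function(v) as.vector(voxelData(v)))
  bestVals <- cm[cbind(seq_len(n^3), bestIdx)]
  expect_lt(max(abs(as.vector(voxelData(fBig)) - bestVals)), 1e-6)
  # beta -> 0: unweighted mean of all valid atlases
  wTiny <- weightsFromRanks(rankAtlases(sims), 1e-6)
  fTiny <- fuseIntensity(wTiny, cts)
  expect_lt(max(abs(as.vector(voxelData(fTiny)) - rowMeans(cm))), 1e-6)
})

test_that("categorical view takes the argmax with lowest-index ties", {
  seg <- randomSeg(6, L = 5, seed = 35, oneHot = FALSE)
  cat <- categoricalFromProb(seg)
  m <- matrix(probArray(seg), ncol = 5)
  expect_equal(as.vector(labelArray(cat)),
               max.col(m, ties.method = "first") - 1L)
  tie <- probSegVolume(array(c(0, 0.5, 0.5), c(1, 1, 1, 3)),
                       imageGrid3(c(1, 1, 1)))
  expect_equal(as.vector(labelArray(categoricalFromProb(tie))), 1L)
  oh <- randomSeg(5, L = 3, seed = 36)
  expect_equal(probArray(oneHotSeg(labelArray(categoricalFromProb(oh)), 3,
                                   imageGrid(oh))), probArray(oh))
})
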