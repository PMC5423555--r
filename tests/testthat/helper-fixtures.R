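# Shared fixtures, built in code.  Expensive ones are computed lazily and
# cached for the session.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, builder) {
  if (is.null(.fixtureCache[[name]])) .fixtureCache[[name]] <- builder()
  .fixtureCache[[name]]
}

randomVolume <- function(n = 10, seed = 1, fovHole = TRUE, spacing = 1) {
  set.seed(seed)
  vals <- array(rnorm(n^3), rep(n, 3))
  fov <- array(1, rep(n, 3))
  if (fovHole) fov[seq_len(max(1, n %/% 3)), , ] <- 0
  scalarVolume(vals, imageGrid3(rep(n, 3), spacing), fov = fov)
}

randomSeg <- function(n = 8, L = 4, seed = 1, oneHot = TRUE) {
  set.seed(seed)
  if (oneHot) {
    oneHotSeg(array(sample(0:(L - 1), n^3, TRUE), rep(n, 3)), L,
              imageGrid3(rep(n, 3)))
  } else {
    p <- array(stats::rgamma(n^3 * L, 1), c(rep(n, 3), L))
    p <- p / array(rep(apply(p, 1:3, sum), L), dim(p))
    probSegVolume(p, imageGrid3(rep(n, 3)))
  }
}

# small quiet phantom template (32^3), cached
smallTemplate <- function() {
  cachedFixture("smallTemplate", function()
    generateTemplate(phantomSpec(size = 32L, spacing = 5), seed = 4))
}

# noise-free symmetric template for exact rendering checks
cleanTemplate <- function() {
  cachedFixture("cleanTemplate", function()
    generateTemplate(phantomSpec(size = 32L, spacing = 5, noiseSigmaMR = 0,
                                 noiseSigmaCT = 0, biasAmplitude = 0),
                     seed = 4))
}

# tiny cohort for pipeline tests (32^3, N = 3), cached
smallCohort <- function() {
  cachedFixture("smallCohort", function()
    generateCohort(phantomSpec(size = 32L, spacing = 5, deformAmplitude = 2,
                               deformSpacing = 50),
                   N = 3, seed = 6))
}

fastConfig <- function(nIterations = 1L, ...) {
  runConfig(nIterations = nIterations, maxIter = c(4, 3, 2), maxIterWarm = 3,
            globalRefineIter = 6, levels = 2L, ...)
}
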