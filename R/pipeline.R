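#' Pipeline run configuration
#'
#' Settings for the iterative joint segmentation + synthesis driver.  The
#' defaults follow the published operating point: four iterations, a
#' rank-decay schedule starting at \eqn{\beta_1 = 1} decreasing by 0.125,
#' Gaussian similarity window \eqn{\sigma_G = 3} voxels, 10 mm finest
#' control-point spacing for the inter-subject registrations, and
#' MR-only mapping and fusion at the first iteration.
#'
#' @param nIterations iterations to run (>= 1; default 4).
#' @param sigmaG similarity Gaussian window, in voxels.
#' @param beta1,betaDecrement,betaFloor rank-decay schedule parameters.
#' @param channelWeights weights of the (T2, T1, CT, seg) LSIM terms.
#' @param includeBackground include background in the LDSC label sum.
#' @param voteMode \code{"onehot"} (nearest-propagated categorical votes)
#'   or \code{"fuzzy"} (linearly interpolated probabilistic votes).
#' @param warmStart initialise each atlas's registration at iteration t+1
#'   from its iteration-t transform.
#' @param levels,controlSpacing,maxIter,maxIterWarm,lnccSigma,regWeight,
#'   globalRefineIter inter-subject registration controls (see
#'   \code{\link{registrationSpec}}); \code{maxIterWarm} applies to
#'   warm-started iterations.
#' @param keepStates retain all intermediate target states.
#' @param verbose print per-iteration progress.
#' @param seed RNG seed recorded with the run (the reference pipeline is
#'   deterministic; the seed namespaces any future stochastic backend).
#' @return a list of class \code{"runConfig"}.
#' @export
runConfig <- function(nIterations = 4L, sigmaG = 3, beta1 = 1,
                      betaDecrement = 0.125, betaFloor = 0.125,
                      channelWeights = c(1, 1, 1, 1),
                      includeBackground = FALSE,
                      voteMode = c("onehot", "fuzzy"), warmStart = TRUE,
                      levels = 3L, controlSpacing = 10,
                      maxIter = c(8L, 6L, 4L),
                      maxIterWarm = 6L, lnccSigma = 2, regWeight = 0.005,
                      globalRefineIter = 8L, keepStates = FALSE,
                      verbose = FALSE, seed = 1L) {
  if (nIterations < 1L) stop("nIterations must be >= 1")
  structure(list(nIterations = as.integer(nIterations), sigmaG = sigmaG,
                 beta1 = beta1, betaDecrement = betaDecrement,
                 betaFloor = betaFloor, channelWeights = channelWeights,
                 includeBackground = includeBackground,
                 voteMode = match.arg(voteMode), warmStart = warmStart,
                 levels = as.integer(levels),
                 controlSpacing = controlSpacing,
                 maxIter = as.integer(maxIter),
                 maxIterWarm = as.integer(maxIterWarm),
                 lnccSigma = lnccSigma, regWeight = regWeight,
                 globalRefineIter = as.integer(globalRefineIter),
                 keepStates = keepStates, verbose = verbose,
                 seed = as.integer(seed)),
            class = "runConfig")
}

interSubjectSpec <- function(config, t, warm) {
  channels <- list(t2 = list(sim = "lncc"), t1 = list(sim = "lncc"))
  if (t >= 2L) {
    channels$ct <- list(sim = "lncc")
    channels$seg <- list(sim = "kld")
  }
  # warm-started iterations resume from the previous transform, so only
  # the finest pyramid level is revisited
  registrationSpec(channels,
                   levels = if (warm) 1L else config$levels,
                   controlSpacing = config$controlSpacing,
                   maxIter = if (warm) config$maxIterWarm else config$maxIter,
                   lnccSigma = config$lnccSigma,
                   regWeight = config$regWeight,
                   globalRefineIter = config$globalRefineIter)
}

#' Run one iteration of the joint segmentation + synthesis pipeline
#'
#' Registers every atlas to the current target state (MR channels only at
#' the first iteration; MR + previous pseudo-CT + previous segmentation
#' with LNCC/LNCC/LNCC/KLD afterwards), propagates the atlas volumes
#' (intensities linearly, labels nearest-neighbour), computes the local
#' similarity (LSIM) per atlas, converts per-voxel similarity ranks into
#' exponential-decay weights with \eqn{\beta_t}, and fuses intensities and
#' labels with the one shared weight field — which is what guarantees that
#' the pseudo-CT and the segmentation are consistent.
#'
#' @param state a \code{TargetState} (t = completed iterations).
#' @param db an \code{AtlasDatabase}.
#' @param config a \code{\link{runConfig}}.
#' @param prevTransforms optional list of per-atlas
#'   \code{SpatialTransform}s from the previous iteration (warm start).
#' @return list with the advanced \code{state}, \code{transforms},
#'   \code{weights} (the shared \code{WeightField}), \code{props}
#'   (propagated atlases), \code{dropped} (ids of atlases whose
#'   registration failed) and a one-row \code{log} data.frame.
#' @export
runIteration <- function(state, db, config = runConfig(),
                         prevTransforms = NULL) {
  if (length(db) < 1L) stop("empty atlas database")
  t <- state@t + 1L
  beta <- betaSchedule(t, config$beta1, config$betaDecrement,
                       config$betaFloor)
  grid <- imageGrid(state)
  t0 <- proc.time()[["elapsed"]]
  fixed <- list(t2 = state@t2, t1 = state@t1)
  if (t >= 2L) {
    fixed$ct <- state@pct
    fixed$seg <- state@seg
  }
  warm <- config$warmStart && !is.null(prevTransforms)
  spec <- interSubjectSpec(config, t, warm)

  props <- list(); lsims <- list(); transforms <- list(); dropped <- character()
  for (n in seq_len(length(db))) {
    rec <- db[[n]]
    moving <- list(t2 = rec@t2, t1 = rec@t1)
    if (t >= 2L) {
      moving$ct <- rec@ct
      moving$seg <- rec@seg
    }
    init <- if (warm) prevTransforms[[rec@id]] else NULL
    Tn <- tryCatch(
      registerMultichannel(fixed, moving, spec, init = init),
      error = function(e) e)
    if (inherits(Tn, "error")) {
      warning("atlas '", rec@id, "' dropped at iteration ", t, ": ",
              conditionMessage(Tn))
      dropped <- c(dropped, rec@id)
      next
    }
    jT2 <- applyTransform(rec@t2, Tn, grid, "linear")
    jT1 <- applyTransform(rec@t1, Tn, grid, "linear")
    jCt <- applyTransform(rec@ct, Tn, grid, "linear")
    jSeg <- applyTransform(rec@seg, Tn, grid, "nearest")
    votes <- if (config$voteMode == "onehot") jSeg
             else applyTransform(rec@seg, Tn, grid, "linear")
    prop <- new("PropagatedAtlas", id = rec@id, jT2 = jT2, jT1 = jT1,
                jCt = jCt, jSeg = jSeg, votes = votes)
    props[[rec@id]] <- prop
    transforms[[rec@id]] <- Tn
    lsims[[rec@id]] <- lsim(state, prop, t, config$sigmaG,
                            config$channelWeights,
                            config$includeBackground)
    if (config$verbose)
      message(sprintf("  iter %d: atlas %s registered (%s)", t, rec@id,
                      if (isTRUE(attr(Tn, "converged"))) "converged"
                      else "max-iter"))
  }
  if (length(props) == 0L)
    stop("all atlases failed to register at iteration ", t)

  ranks <- rankAtlases(unname(lsims))
  weights <- weightsFromRanks(ranks, beta)
  bodyMask <- targetBodyMask(state, db)
  pct <- fuseIntensity(weights, lapply(props, function(p) p@jCt), bodyMask)
  seg <- fuseLabels(weights, lapply(props, function(p) p@votes),
                    oneHot = config$voteMode == "onehot")
  # mean similarity of the locally best atlas (monitoring hook)
  best <- do.call(pmax, lapply(lsims, function(s) s@score))
  meanBest <- mean(best[is.finite(best)])
  log <- data.frame(iteration = t, beta = beta, nAtlases = length(props),
                    nDropped = length(dropped), meanBestLsim = meanBest,
                    elapsed = proc.time()[["elapsed"]] - t0)
  list(state = targetState(state@t2, state@t1, pct, seg, t),
       transforms = transforms, weights = weights, props = props,
       dropped = dropped, log = log)
}

# Crude target body mask for the unfusable-fill policy: voxels any atlas
# could map tissue to; from the target MR foreground when available.
targetBodyMask <- function(state, db) {
  v <- state@t2@values
  thr <- stats::quantile(v[state@t2@fov > 0.5], 0.5)
  m <- v > max(thr * 0.25, 1e-6) & state@t2@fov > 0.5
  if (!any(m)) return(NULL)
  array(m, dim(v))
}

#' Run the full iterative pipeline on a target subject
#'
#' @param t2,t1 the target subject's co-registered MR channels (one
#'   grid; checked).
#' @param db an \code{AtlasDatabase}.
#' @param config a \code{\link{runConfig}}.
#' @return list with \code{pct} (pseudo-CT \code{ScalarVolume}),
#'   \code{segProb}, \code{segCat}, \code{log} (per-iteration
#'   data.frame), \code{weights} (final shared weight field),
#'   \code{transforms}, and \code{states} when
#'   \code{config$keepStates}.
#' @export
runPipeline <- function(t2, t1, db, config = runConfig()) {
  stopIfGridMismatch(t2, t1, "target MR channels")
  set.seed(config$seed)
  state <- targetState(t2, t1)
  transforms <- NULL
  logs <- list(); states <- list()
  weights <- NULL
  for (t in seq_len(config$nIterations)) {
    it <- runIteration(state, db, config, prevTransforms = transforms)
    state <- it$state
    transforms <- it$transforms
    weights <- it$weights
    logs[[t]] <- it$log
    if (config$keepStates) states[[t]] <- state
    if (config$verbose)
      message(sprintf("iteration %d done: beta=%.3f, meanBestLSIM=%.3f",
                      t, it$log$beta, it$log$meanBestLsim))
  }
  out <- list(pct = state@pct, segProb = state@seg,
              segCat = categoricalFromProb(state@seg),
              log = do.call(rbind, logs), weights = weights,
              transforms = transforms)
  if (config$keepStates) out$states <- states
  out
}

#' Leave-one-out cross-validation over an atlas database
#'
#' For each (non-flipped) subject: remove it and its flipped twin from
#' the database, run the pipeline on its MR channels, and score every
#' iteration against the subject's own CT and manual segmentation.  The
#' body ROI is the manual foreground; a bone ROI may be supplied per
#' subject.
#'
#' @param db an \code{AtlasDatabase} (N >= 2 base subjects).
#' @param config a \code{\link{runConfig}}.
#' @param boneMasks optional named list (by record id) of bone ROI masks.
#' @return list with \code{metrics} (tidy data.frame: subject, iteration,
#'   target, metric, value) and \code{runs} (per-subject pipeline
#'   outputs).
#' @export
leaveOneOut <- function(db, config = runConfig(), boneMasks = NULL) {
  recs <- atlasRecords(db)
  baseIds <- vapply(recs[!vapply(recs, isFlipped, logical(1))],
                    recordId, character(1))
  if (length(baseIds) < 2L) stop("leave-one-out needs at least 2 subjects")
  config$keepStates <- TRUE
  dict <- labelDict(db)
  metrics <- list(); runs <- list()
  for (id in baseIds) {
    keep <- vapply(recs, function(r)
      !(recordId(r) %in% c(id, paste0(id, "_flip"))), logical(1))
    dbMinus <- atlasDatabase(recs[keep], dict)
    target <- db[[id]]
    res <- runPipeline(target@t2, target@t1, dbMinus, config)
    runs[[id]] <- res
    manCat <- categoricalFromProb(target@seg)
    bodyMask <- manCat@labels > 0L
    for (t in seq_along(res$states)) {
      st <- res$states[[t]]
      metrics[[length(metrics) + 1L]] <-
        metricReport(target@seg, st@seg, target@ct, st@pct, dict,
                     bodyMask, boneMasks[[id]], subject = id,
                     iteration = t)
    }
  }
  list(metrics = do.call(rbind, metrics), runs = runs)
}
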