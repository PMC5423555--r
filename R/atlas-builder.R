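# Atlas database construction: structure-guided intra-subject alignment,
# pseudo-modality refinement of the CT-to-T2 mapping, flip augmentation.

#' Registration settings for intra-subject (database building) alignments
#'
#' Three pyramid levels; finest control spacing 2.5 mm for the T1-to-T2
#' and 7.5 mm for the CT-to-T2 registrations, with a floor of three
#' working-grid voxels so coarse phantom grids keep a meaningful lattice.
#'
#' @param kind \code{"t1"}, \code{"ct"} or \code{"refine"}.
#' @param voxelMm working voxel size in mm (for the spacing floor).
#' @param maxIter optimiser iterations per level.
#' @return a \code{\link{registrationSpec}} without channels set (filled
#'   by the builder).
#' @export
intraSubjectSpacing <- function(kind, voxelMm) {
  nominal <- switch(kind, t1 = 2.5, ct = 7.5, refine = 7.5,
                    stop("unknown registration kind"))
  max(nominal, 3 * voxelMm)
}

#' Build one atlas record by structure-guided intra-subject registration
#'
#' The T1 and CT image-segmentation pairs are registered to the T2 pair
#' with an affine stage followed by a multi-channel non-rigid
#' registration: LNCC over the intensities and KLD over the manual
#' segmentations (the segmentations guide and constrain the alignment).
#' All volumes end up on the T2 grid; the record keeps the T2-based
#' manual segmentation.
#'
#' @param t2Isp,t1Isp,ctIsp \code{ImageSegPair}s of one subject.
#' @param id record identifier.
#' @param maxIter optimiser iterations per level.
#' @param globalRefineIter global-stage refinement iterations.
#' @return list with \code{record} (an \code{AtlasRecord}) and
#'   \code{transforms} (list with \code{t1}, \code{ct}
#'   \code{SpatialTransform}s).
#' @export
buildInitialRecord <- function(t2Isp, t1Isp, ctIsp, id = "subject",
                               maxIter = 20L, globalRefineIter = 20L) {
  g <- imageGrid(t2Isp@intensity)
  vox <- min(gridSpacing(g))
  # intensity channels pair different modalities (T1 or CT against T2),
  # where the local intensity relation flips sign across tissues: the
  # squared local correlation is the sign-blind variant, and the
  # segmentation channel carries most of the weight (the structure
  # guidance is what keeps multi-modal non-rigid registration honest)
  specT1 <- registrationSpec(
    list(img = list(sim = "lncc2", weight = 0.1),
         seg = list(sim = "kld", weight = 3)),
    levels = 3L, controlSpacing = intraSubjectSpacing("t1", vox),
    maxIter = maxIter, regWeight = 0.02,
    globalRefineIter = globalRefineIter)
  specCT <- registrationSpec(
    list(img = list(sim = "lncc2", weight = 0.1),
         seg = list(sim = "kld", weight = 3)),
    levels = 3L, controlSpacing = intraSubjectSpacing("ct", vox),
    maxIter = maxIter, regWeight = 0.02,
    globalRefineIter = globalRefineIter)
  fixedCh <- list(img = t2Isp@intensity, seg = t2Isp@seg)
  tT1 <- registerMultichannel(fixedCh,
                              list(img = t1Isp@intensity, seg = t1Isp@seg),
                              specT1)
  tCT <- registerMultichannel(fixedCh,
                              list(img = ctIsp@intensity, seg = ctIsp@seg),
                              specCT)
  rec <- atlasRecord(id,
                     t2 = t2Isp@intensity,
                     t1 = applyTransform(t1Isp@intensity, tT1, g, "linear"),
                     ct = applyTransform(ctIsp@intensity, tCT, g, "linear"),
                     seg = t2Isp@seg)
  list(record = rec, transforms = list(t1 = tT1, ct = tCT))
}

#' Single-pass cross-modality synthesis from an aligned-pair database
#'
#' The non-iterative multi-atlas synthesis used inside database
#' refinement: atlas source-modality images are registered to the target
#' source-modality image, the paired other-modality images are
#' propagated, atlases are ranked per voxel by ROI-SSIM on the source
#' modality, and the propagated images are fused with exponential-decay
#' rank weights.  Direction \code{"mr2ct"} yields a pseudo-CT from a T2;
#' \code{"ct2mr"} a pseudo-T2 from a CT.
#'
#' @param target source-modality \code{ScalarVolume} of the subject.
#' @param pairs list of \code{list(source = , paired = )}
#'   \code{ScalarVolume} pairs, aligned within each atlas.
#' @param sigmaG similarity window (voxels).
#' @param beta rank-decay parameter (default 1, single-pass operating
#'   point).
#' @param maxIter,levels,controlSpacing,globalRefineIter registration
#'   controls.
#' @return the synthesised \code{ScalarVolume} (modality of the paired
#'   images).
#' @export
synthesizeCrossModality <- function(target, pairs, sigmaG = 3, beta = 1,
                                    maxIter = 10L, levels = 3L,
                                    controlSpacing = 10,
                                    globalRefineIter = 20L) {
  if (length(pairs) < 1L) stop("empty synthesis database")
  g <- imageGrid(target)
  spec <- registrationSpec(list(img = list(sim = "lncc")), levels = levels,
                           controlSpacing = controlSpacing,
                           maxIter = maxIter,
                           globalRefineIter = globalRefineIter)
  props <- list(); sims <- list()
  for (i in seq_along(pairs)) {
    Tn <- registerMultichannel(list(img = target),
                               list(img = pairs[[i]]$source), spec)
    jSrc <- applyTransform(pairs[[i]]$source, Tn, g, "linear")
    jPar <- applyTransform(pairs[[i]]$paired, Tn, g, "linear")
    props[[i]] <- jPar
    sims[[i]] <- roiSSIM(target, jSrc, sigmaG)
  }
  weights <- weightsFromRanks(rankAtlases(sims), beta)
  out <- fuseIntensity(weights, props)
  out@modality <- if (pairs[[1]]$paired@modality %in% c("CT", "pCT"))
    "pCT" else pairs[[1]]$paired@modality
  out
}

#' Refine a record's CT-to-T2 alignment with pseudo-modality channels
#'
#' Registers the fixed set \{T2, T2-based segmentation, pseudo-CT\}
#' against the moving set \{pseudo-T2, CT-based segmentation, CT\}:
#' monomodal LNCC between T2 and pseudo-T2 and between pseudo-CT and CT,
#' KLD between the segmentations, and a preserved cross-modal LNCC term
#' between the original T2 and CT channels.  The registration is
#' initialised from the record's current CT transform, so the update
#' composes with (rather than replaces) the global stage.
#'
#' @param t2,t2Seg the record's T2 image and T2-based segmentation.
#' @param pct pseudo-CT synthesised from the T2 (on the T2 grid).
#' @param ct,ctSeg the subject's CT and CT-based segmentation, in the
#'   CT's own space.
#' @param pt2 pseudo-T2 synthesised from the CT (on the CT grid).
#' @param init the current CT-to-T2 \code{SpatialTransform}.
#' @param maxIter optimiser iterations per level.
#' @return the refined \code{SpatialTransform} (CT space to T2 space).
#' @export
refineRecord <- function(t2, t2Seg, pct, ct, ctSeg, pt2, init = NULL,
                         maxIter = 20L) {
  vox <- min(gridSpacing(imageGrid(t2)))
  spec <- registrationSpec(
    list(t2pt2 = list(sim = "lncc"), seg = list(sim = "kld", weight = 3),
         pctct = list(sim = "lncc"), cross = list(sim = "lncc2", weight = 0.1)),
    levels = 3L, controlSpacing = intraSubjectSpacing("refine", vox),
    maxIter = maxIter, regWeight = 0.02)
  fixed <- list(t2pt2 = t2, seg = t2Seg, pctct = pct, cross = t2)
  moving <- list(t2pt2 = pt2, seg = ctSeg, pctct = ct, cross = ct)
  registerMultichannel(fixed, moving, spec, init = init)
}

#' Build a complete atlas database from subject image-segmentation pairs
#'
#' Runs the structure-guided initial alignment per subject; optionally
#' refines each CT-to-T2 mapping via leave-one-out pseudo-CT / pseudo-T2
#' synthesis (the synthesis atlas set is the initial records — the
#' refined set does not exist yet); optionally appends left-right flipped
#' twins.  A provenance manifest accompanies the records.
#'
#' @param subjects list; each element a list with \code{id} and
#'   \code{t2}, \code{t1}, \code{ct} \code{ImageSegPair}s.
#' @param dict the \code{\link{labelDictionary}}.
#' @param refine run the pseudo-modality refinement stage.
#' @param augmentFlip append flipped twins.
#' @param maxIter registration iterations per level.
#' @param synthBeta rank-decay parameter of the internal synthesis.
#' @return list with \code{db} (an \code{AtlasDatabase}) and
#'   \code{manifest} (data.frame: id, flipped, refined).
#' @export
buildDatabase <- function(subjects, dict = labelDictionary(),
                          refine = TRUE, augmentFlip = TRUE,
                          maxIter = 10L, synthBeta = 1) {
  if (length(subjects) < 1L) stop("at least one subject required")
  initial <- lapply(subjects, function(s)
    buildInitialRecord(s$t2, s$t1, s$ct, id = s$id, maxIter = maxIter))
  records <- lapply(initial, `[[`, "record")
  refined <- rep(FALSE, length(records))
  if (refine && length(subjects) >= 2L) {
    for (i in seq_along(subjects)) {
      others <- setdiff(seq_along(subjects), i)
      mrPairs <- lapply(others, function(j)
        list(source = records[[j]]@t2, paired = records[[j]]@ct))
      ctPairs <- lapply(others, function(j)
        list(source = records[[j]]@ct, paired = records[[j]]@t2))
      pct <- synthesizeCrossModality(records[[i]]@t2, mrPairs,
                                     beta = synthBeta, maxIter = maxIter)
      pt2 <- synthesizeCrossModality(subjects[[i]]$ct@intensity, ctPairs,
                                     beta = synthBeta, maxIter = maxIter)
      Tref <- refineRecord(records[[i]]@t2, records[[i]]@seg, pct,
                           subjects[[i]]$ct@intensity,
                           subjects[[i]]$ct@seg, pt2,
                           init = initial[[i]]$transforms$ct,
                           maxIter = maxIter)
      g <- imageGrid(records[[i]])
      newCt <- applyTransform(subjects[[i]]$ct@intensity, Tref, g, "linear")
      records[[i]] <- atlasRecord(records[[i]]@id, records[[i]]@t2,
                                  records[[i]]@t1, newCt,
                                  records[[i]]@seg)
      refined[i] <- TRUE
    }
  }
  if (augmentFlip) {
    flips <- lapply(records, leftRightFlip, dict = dict)
    records <- c(records, flips)
    refined <- c(refined, refined)
  }
  manifest <- data.frame(
    id = vapply(records, recordId, character(1)),
    flipped = vapply(records, isFlipped, logical(1)),
    refined = refined)
  list(db = atlasDatabase(records, dict), manifest = manifest)
}

#' Write / read an atlas database directory
#'
#' One sub-directory per record holding the four volumes as NIfTI (the
#' segmentation as a categorical label image) plus a top-level YAML
#' manifest with ids, flip flags and the label dictionary.
#'
#' @param db an \code{AtlasDatabase}.
#' @param dir target directory.
#' @param manifest optional provenance data.frame (from
#'   \code{\link{buildDatabase}}).
#' @return \code{dir}, invisibly.
#' @export
writeDatabase <- function(db, dir, manifest = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dict <- labelDict(db)
  ids <- character()
  for (rec in atlasRecords(db)) {
    rd <- file.path(dir, rec@id)
    dir.create(rd, showWarnings = FALSE)
    writeVolume(rec@t2, file.path(rd, "t2.nii.gz"))
    writeVolume(rec@t1, file.path(rd, "t1.nii.gz"))
    writeVolume(rec@ct, file.path(rd, "ct.nii.gz"))
    cat <- categoricalFromProb(rec@seg)
    writeVolume(scalarVolume(cat@labels + 0.0, cat@grid),
                file.path(rd, "seg.nii.gz"))
    ids <- c(ids, rec@id)
  }
  man <- list(records = lapply(atlasRecords(db), function(r)
                list(id = r@id, flipped = r@flipped)),
              labels = as.list(dict$index),
              lateral_pairs = dict$lateralPairs)
  if (!is.null(manifest)) man$provenance <- lapply(
    seq_len(nrow(manifest)), function(i) as.list(manifest[i, ]))
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname writeDatabase
#' @export
readDatabase <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  idx <- unlist(man$labels)
  dict <- labelDictionary(names = names(sort(idx)),
                          lateralPairs = lapply(man$lateral_pairs, unlist))
  L <- length(dict$names)
  records <- lapply(man$records, function(m) {
    rd <- file.path(dir, m$id)
    segVol <- readVolume(file.path(rd, "seg.nii.gz"))
    atlasRecord(m$id,
                t2 = readVolume(file.path(rd, "t2.nii.gz"), "T2"),
                t1 = readVolume(file.path(rd, "t1.nii.gz"), "T1"),
                ct = readVolume(file.path(rd, "ct.nii.gz"), "CT"),
                seg = oneHotSeg(array(as.integer(round(segVol@values)),
                                      dim(segVol@values)),
                                L, segVol@grid),
                flipped = isTRUE(m$flipped))
  })
  atlasDatabase(records, dict)
}
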