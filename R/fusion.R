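#' Iteration-dependent rank-decay parameter
#'
#' The decay starts at \eqn{\beta_1 = 1} and decreases by 0.125 per
#' iteration, so that later iterations (with better registrations) let
#' more atlases contribute to the average.  A configurable floor keeps
#' \eqn{\beta} positive if the pipeline is run past iteration 7.
#'
#' @param t iteration index (integer >= 1).
#' @param beta1 starting value (default 1).
#' @param decrement per-iteration decrease (default 0.125).
#' @param floor minimum value (default 0.125).
#' @return the scalar \eqn{\beta_t}.
#' @examples
#' betaSchedule(1)  # 1
#' betaSchedule(4)  # 0.625
#' @export
betaSchedule <- function(t, beta1 = 1, decrement = 0.125, floor = 0.125) {
  if (length(t) != 1L || !is.finite(t) || t < 1 || t != round(t))
    stop("t must be a single integer >= 1")
  max(floor, beta1 - decrement * (t - 1))
}

#' Rank atlases per voxel by local similarity
#'
#' At each voxel the atlases are sorted by descending similarity; the most
#' similar atlas gets rank 0.  Atlases with \code{-Inf} similarity at a
#' voxel are excluded there (NA rank, later weight 0); ties are broken by
#' ascending atlas index, which makes the ranking deterministic.  Voxels
#' where no atlas has a finite similarity are flagged unfusable.
#'
#' @param lsims list of \code{SimilarityVolume}s, one per atlas, on one
#'   grid.
#' @return a \code{RankField}.
#' @export
rankAtlases <- function(lsims) {
  if (length(lsims) < 1L) stop("at least one atlas required")
  g <- imageGrid(lsims[[1]])
  for (s in lsims) stopIfGridMismatch(lsims[[1]], s, "similarity volumes")
  N <- length(lsims)
  V <- prod(gridShape(g))
  mat <- vapply(lsims, function(s) as.vector(s@score), numeric(V))
  mat <- matrix(mat, nrow = V)
  ranks <- matrix(NA_integer_, V, N)
  work <- mat
  remaining <- rowSums(is.finite(mat))
  for (r in seq_len(N) - 1L) {
    todo <- remaining > r
    if (!any(todo)) break
    pick <- max.col(work[todo, , drop = FALSE], ties.method = "first")
    ranks[cbind(which(todo), pick)] <- r
    work[cbind(which(todo), pick)] <- -Inf
  }
  fusable <- array(remaining > 0L, gridShape(g))
  new("RankField", grid = g,
      ranks = array(ranks, c(gridShape(g), N)), fusable = fusable)
}

#' Exponential-decay weights from ranks
#'
#' \eqn{w = e^{-\beta r}}: the locally best atlas (rank 0) always has
#' weight 1; excluded atlases get weight 0.  Large \eqn{\beta} approaches
#' best-atlas selection, small \eqn{\beta} the unweighted mean.
#'
#' @param ranks a \code{RankField}.
#' @param beta decay parameter (> 0).
#' @return a \code{WeightField}.
#' @export
weightsFromRanks <- function(ranks, beta) {
  if (!is.finite(beta) || beta <= 0) stop("beta must be > 0")
  w <- exp(-beta * ranks@ranks)
  w[is.na(w)] <- 0
  new("WeightField", grid = ranks@grid, weights = w,
      fusable = ranks@fusable, beta = beta)
}

#' Fuse propagated CT intensities into a pseudo-CT
#'
#' Weighted average \eqn{pCT(x) = \sum_n w_n(x) J^{CT}_n(x) / \sum_n
#' w_n(x)} over the propagated atlas CTs.  Unfusable voxels (no atlas with
#' finite similarity) are filled by policy: air (-1000 HU) outside the
#' body mask, the nearest fusable value inside it; without a body mask all
#' unfusable voxels become air.
#'
#' @param weights a \code{WeightField}.
#' @param cts list of propagated CT \code{ScalarVolume}s, one per atlas,
#'   aligned with the weight field's atlas order.
#' @param bodyMask optional 3-D logical array (target body).
#' @return a \code{ScalarVolume} tagged \code{"pCT"} (HU); attribute
#'   \code{"unfusable"} carries the QA mask.
#' @export
fuseIntensity <- function(weights, cts, bodyMask = NULL) {
  N <- dim(weights@weights)[4]
  if (length(cts) != N)
    stop("weight field covers ", N, " atlases but ", length(cts),
         " CT volumes were given")
  num <- array(0, gridShape(weights@grid))
  den <- num
  for (n in seq_len(N)) {
    stopIfGridMismatch(weights, cts[[n]], "weights and propagated CTs")
    w <- weights@weights[, , , n]
    v <- cts[[n]]@values
    v[cts[[n]]@fov < 0.5] <- 0
    num <- num + w * v
    den <- den + w
  }
  ok <- den > 0
  pct <- num
  pct[ok] <- num[ok] / den[ok]
  pct <- fillUnfusable(pct, ok, bodyMask, fillValue = -1000)
  out <- scalarVolume(pct, grid = weights@grid, modality = "pCT")
  attr(out, "unfusable") <- !ok
  out
}

#' Fuse propagated label votes into a probabilistic segmentation
#'
#' \eqn{I^S(x,l) = \sum_n w_n V_n(x,l) / \sum_k \sum_n w_n V_n(x,k)}:
#' weighted voting normalised over labels, yielding a probability simplex
#' per fusable voxel.  Votes are one-hot fields from nearest-neighbour
#' propagated labels by default; a fuzzy mode accepts probabilistic votes.
#' Unfusable voxels become pure background.
#'
#' @param weights a \code{WeightField}.
#' @param votes list of \code{ProbSegVolume} vote fields, one per atlas.
#' @param oneHot require votes to be one-hot (default TRUE).
#' @return a \code{ProbSegVolume}.
#' @export
fuseLabels <- function(weights, votes, oneHot = TRUE) {
  N <- dim(weights@weights)[4]
  if (length(votes) != N)
    stop("weight field covers ", N, " atlases but ", length(votes),
         " vote fields were given")
  L <- nLabels(votes[[1]])
  sh <- gridShape(weights@grid)
  V <- prod(sh)
  num <- matrix(0, V, L)
  for (n in seq_len(N)) {
    stopIfGridMismatch(weights, votes[[n]], "weights and votes")
    if (nLabels(votes[[n]]) != L) stop("vote fields disagree on L")
    pv <- matrix(votes[[n]]@probs, ncol = L)
    if (oneHot && any(pv != 0 & pv != 1))
      stop("votes are not one-hot; use oneHot = FALSE for fuzzy votes")
    num <- num + as.vector(weights@weights[, , , n]) * pv
  }
  den <- rowSums(num)
  ok <- den > 0
  num[ok, ] <- num[ok, , drop = FALSE] / den[ok]
  num[!ok, ] <- 0
  num[!ok, 1] <- 1       # unfusable -> background
  probSegVolume(array(num, c(sh, L)), weights@grid)
}

#' Categorical view of a probabilistic segmentation
#'
#' Per voxel the argmax label; ties are broken towards the lowest label
#' index (deterministic).
#'
#' @param seg a \code{ProbSegVolume}.
#' @return a \code{CategoricalSegVolume}.
#' @export
categoricalFromProb <- function(seg) {
  L <- nLabels(seg)
  m <- matrix(seg@probs, ncol = L)
  lab <- max.col(m, ties.method = "first") - 1L
  categoricalSegVolume(array(lab, gridShape(seg@grid)), L, seg@grid)
}

# Fill unfusable voxels: air outside the body, nearest fusable value
# inside (propagated by iterative 6-neighbour averaging).
fillUnfusable <- function(vals, fusable, bodyMask, fillValue = -1000) {
  if (all(fusable)) return(vals)
  vals[!fusable] <- fillValue
  if (is.null(bodyMask)) return(vals)
  todo <- !fusable & bodyMask
  if (!any(todo)) return(vals)
  known <- fusable
  vals[!known] <- 0
  for (iter in seq_len(sum(dim(vals)))) {
    if (!any(todo)) break
    numN <- shiftSum(vals * known)
    cntN <- shiftSum(known * 1)
    fill <- todo & cntN > 0
    vals[fill] <- numN[fill] / cntN[fill]
    known[fill] <- TRUE
    todo <- todo & !fill
  }
  vals[todo] <- fillValue   # isolated pockets never reached
  vals
}

# Sum of the six face-neighbours (zero outside the grid).
shiftSum <- function(a) {
  d <- dim(a)
  out <- array(0, d)
  n <- length(d)
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      idxFrom <- rep(list(quote(expr = )), n)
      idxTo <- rep(list(quote(expr = )), n)
      if (s == 1L) {
        idxFrom[[ax]] <- seq_len(d[ax] - 1L)
        idxTo[[ax]] <- seq_len(d[ax] - 1L) + 1L
      } else {
        idxFrom[[ax]] <- seq_len(d[ax] - 1L) + 1L
        idxTo[[ax]] <- seq_len(d[ax] - 1L)
      }
      part <- do.call(`[`, c(list(a), idxFrom, list(drop = FALSE)))
      sub <- do.call(`[`, c(list(out), idxTo, list(drop = FALSE)))
      out <- do.call(`[<-`, c(list(out), idxTo, list(sub + part)))
    }
  }
  out
}
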