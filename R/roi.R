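## Participant ROI construction: localizer-selective voxels inside a group
## mask, plus nested sub-ROIs of graded size built from the most target- and
## anchor-selective voxels.

new_roi_mask <- function(roi_name, hemisphere, voxel_ids, selectivity,
                         source_alpha = NA_real_) {
  structure(list(roi_name = roi_name, hemisphere = hemisphere,
                 voxel_ids = voxel_ids, selectivity = selectivity,
                 source_alpha = source_alpha),
            class = "roi_mask")
}

#' Select localizer-active voxels within a group mask
#'
#' Keeps every group-mask voxel whose target contrast OR anchor contrast is
#' significant at `alpha` (uncorrected): the union of the two selective
#' sets, mirroring ROI construction by intersecting group-level masks with
#' participant localizer F contrasts and combining the per-contrast masks.
#'
#' @param group_mask Integer vector of candidate voxel ids.
#' @param f_target,f_anchor Lists with per-voxel `F` and `p` vectors (as
#'   from [f_contrast()]), covering (at least) the group-mask voxels; voxel
#'   id `i` indexes element `i`.
#' @param alpha Uncorrected selection threshold.
#' @param roi_name,hemisphere Labels carried on the mask.
#' @return An `roi_mask`; empty selection gives a warning and an empty mask.
#' @export
select_roi_voxels <- function(group_mask, f_target, f_anchor, alpha = 0.05,
                              roi_name = "ROI", hemisphere = "left") {
  stopifnot(is.numeric(group_mask), is_prob(alpha))
  if (max(group_mask) > length(f_target$p) ||
      max(group_mask) > length(f_anchor$p)) {
    stopf("selectivity maps do not cover the group mask")
  }
  keep <- if (alpha >= 1) rep(TRUE, length(group_mask)) else
    f_target$p[group_mask] < alpha | f_anchor$p[group_mask] < alpha
  ids <- sort(group_mask[keep])
  if (length(ids) == 0) warnf("no voxels selected at alpha = %g", alpha)
  sel <- data.frame(voxel_id = ids,
                    F_target = f_target$F[ids], p_target = f_target$p[ids],
                    F_anchor = f_anchor$F[ids], p_anchor = f_anchor$p[ids])
  new_roi_mask(roi_name, hemisphere, ids, sel, alpha)
}

#' Build nested sub-ROIs of graded size
#'
#' Sub-ROI `k` (of `n_steps`) has `round(k * max_voxels / n_steps)` voxels,
#' drawn in equal parts from the most target-selective and most
#' anchor-selective voxels of the mask (ranked by F, ties broken by voxel
#' id). Voxels appearing in both rankings are counted once and the deficit
#' backfilled alternately from each list's next-ranked voxels, implemented
#' as a deterministic alternating merge of the two rankings (target list
#' first, so odd sizes give the target list the extra voxel). Sub-ROIs are
#' nested by construction.
#'
#' @param mask An `roi_mask` with selectivity scores.
#' @param n_steps Number of sub-ROIs (>= 1).
#' @param max_voxels Largest sub-ROI size; clipped to the mask size with a
#'   warning if necessary.
#' @return List of `n_steps` nested `roi_mask` objects (smallest first).
#' @export
make_sub_rois <- function(mask, n_steps = 5, max_voxels) {
  stopifnot(inherits(mask, "roi_mask"))
  if (!is_count(n_steps)) stopf("n_steps must be a positive integer")
  n_avail <- length(mask$voxel_ids)
  if (n_avail == 0) stopf("cannot build sub-ROIs from an empty mask")
  if (max_voxels > n_avail) {
    warnf("max_voxels (%d) clipped to mask size (%d)", max_voxels, n_avail)
    max_voxels <- n_avail
  }
  sel <- mask$selectivity
  rank_t <- sel$voxel_id[order(-sel$F_target, sel$voxel_id)]
  rank_a <- sel$voxel_id[order(-sel$F_anchor, sel$voxel_id)]
  ## alternating merge, duplicates skipped, target first
  merged <- integer(0)
  it <- 1L; ia <- 1L
  next_from <- function(rank, i) { # first index not already merged
    while (i <= n_avail && rank[i] %in% merged) i <- i + 1L
    i
  }
  while (length(merged) < max_voxels) {
    prefer_t <- (length(merged) %% 2L) == 0L
    it <- next_from(rank_t, it)
    ia <- next_from(rank_a, ia)
    if (prefer_t && it <= n_avail) {
      merged <- c(merged, rank_t[it]); it <- it + 1L
    } else if (ia <= n_avail) {
      merged <- c(merged, rank_a[ia]); ia <- ia + 1L
    } else if (it <= n_avail) {
      merged <- c(merged, rank_t[it]); it <- it + 1L
    } else break # both rankings exhausted
  }
  sizes <- round(seq_len(n_steps) * max_voxels / n_steps)
  lapply(seq_len(n_steps), function(k) {
    ids <- sort(merged[seq_len(sizes[k])])
    new_roi_mask(sprintf("%s_sub%d", mask$roi_name, k), mask$hemisphere,
                 ids, sel[match(ids, sel$voxel_id), , drop = FALSE],
                 mask$source_alpha)
  })
}

#' Restrict beta patterns to an ROI mask
#'
#' @param betas A `beta_patterns` object.
#' @param mask An `roi_mask` whose `voxel_ids` index `betas$voxel_ids`.
#' @return A `beta_patterns` restricted to the mask's voxels.
#' @export
apply_roi_mask <- function(betas, mask) {
  stopifnot(inherits(betas, "beta_patterns"), inherits(mask, "roi_mask"))
  idx <- match(mask$voxel_ids, betas$voxel_ids)
  if (anyNA(idx)) stopf("mask voxels missing from beta patterns")
  new_beta_patterns(betas$values[, , idx, drop = FALSE],
                    betas$condition_labels, betas$hemisphere,
                    mask$roi_name, mask$voxel_ids)
}
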