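## Sphere-based searchlight decoding: repeat the decoding scheme in a small
## sphere centered on every in-mask voxel, write the information score at
## the center, then test the participant map stack with sign-flip TFCE and
## max-statistic correction.

#' Integer sphere offsets
#'
#' All integer 3-vectors within `radius` of the origin, under an inclusive
#' (`euclidean_le`, squared norm <= radius^2) or strict (`euclidean_lt`)
#' membership rule. Radius 5 gives 515 offsets under the inclusive rule.
#'
#' @param radius Sphere radius in voxels (>= 0).
#' @param inclusion_rule `"euclidean_le"` (default) or `"euclidean_lt"`.
#' @return List of class `sphere_neighborhood`: `offsets` (n x 3 integer
#'   matrix including the origin), `radius`, `inclusion_rule`, `n_voxels`.
#' @export
sphere_offsets <- function(radius,
                           inclusion_rule = c("euclidean_le",
                                              "euclidean_lt")) {
  inclusion_rule <- match.arg(inclusion_rule)
  if (!is.numeric(radius) || length(radius) != 1 || radius < 0) {
    stopf("radius must be a non-negative scalar")
  }
  r <- floor(radius)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  nn <- rowSums(g^2)
  keep <- if (inclusion_rule == "euclidean_le") nn <= radius^2 else
    nn < radius^2
  offsets <- g[keep, , drop = FALSE]
  structure(list(offsets = offsets, radius = radius,
                 inclusion_rule = inclusion_rule,
                 n_voxels = nrow(offsets)),
            class = "sphere_neighborhood")
}

#' Volumetric beta container
#'
#' Run x condition beta values over the voxels of a 3-D volume, the
#' searchlight-side analogue of `beta_patterns`.
#'
#' @param values Array (run x condition x voxel), voxels in column-major
#'   volume order.
#' @param dim Length-3 volume dimensions (`prod(dim)` voxels).
#' @param condition_labels Data frame as in `beta_patterns`.
#' @param affine 4x4 voxel-to-world matrix (default 2 mm isotropic).
#' @return List of class `volume_betas`.
#' @export
volume_betas <- function(values, dim, condition_labels = condition_table(),
                         affine = diag(c(2, 2, 2, 1))) {
  stopifnot(length(dim) == 3, dim(values)[3] == prod(dim))
  structure(list(values = values, dim = as.integer(dim),
                 condition_labels = condition_labels, affine = affine),
            class = "volume_betas")
}

#' Group feature mask from localizer searchlight maps
#'
#' Per voxel, a one-sample t test across participants against chance
#' (one-sided, above) for each of the two localizer decoding maps; the
#' mask is the union of voxels passing either test at `alpha`
#' (uncorrected), intersected with the cortex mask.
#'
#' @param target_maps,anchor_maps Participant x voxel matrices of decoding
#'   scores (aligned columns).
#' @param cortex_mask Logical vector over voxels.
#' @param alpha Uncorrected threshold.
#' @param chance Chance level of the score (0 for information scores).
#' @return Logical voxel mask; error if empty.
#' @export
make_feature_mask <- function(target_maps, anchor_maps, cortex_mask,
                              alpha = 0.05, chance = 0) {
  one_sided_p <- function(m) {
    tv <- group_t_map(m - chance)
    stats::pt(tv, df = nrow(m) - 1, lower.tail = FALSE)
  }
  p_t <- one_sided_p(as.matrix(target_maps))
  p_a <- one_sided_p(as.matrix(anchor_maps))
  mask <- (p_t < alpha | p_a < alpha) & as.logical(cortex_mask)
  if (!any(mask)) stopf("feature mask is empty")
  mask
}

#' Run a searchlight over a volume
#'
#' For every in-mask voxel, gathers the in-mask voxels within the sphere,
#' runs the decoding scheme on that sub-pattern, and writes the information
#' score at the center. Spheres are clipped at volume borders and to the
#' mask; centers with fewer than 2 usable voxels get `NA` (counted in the
#' `n_skipped` attribute).
#'
#' @param vb A [volume_betas()] for one participant.
#' @param mask Logical array (volume dims): analysis/feature mask.
#' @param neighborhood A [sphere_offsets()].
#' @param map The participant's association map.
#' @param scheme Decoding scheme name (default `anchor_cross_scene`).
#' @param cost SVM regularisation constant.
#' @return 3-D array of information scores (`NA` outside the mask), with
#'   attribute `n_skipped`.
#' @export
run_searchlight <- function(vb, mask, neighborhood, map,
                            scheme = "anchor_cross_scene", cost = 1) {
  stopifnot(inherits(vb, "volume_betas"),
            inherits(neighborhood, "sphere_neighborhood"))
  dims <- vb$dim
  stopifnot(all(dim(mask) == dims))
  out <- array(NA_real_, dims)
  centers <- which(mask)
  cc <- arrayInd(centers, dims)
  off <- neighborhood$offsets
  n_skipped <- 0L
  for (i in seq_along(centers)) {
    pts <- sweep(off, 2, cc[i, ], "+")
    ok <- pts[, 1] >= 1 & pts[, 1] <= dims[1] &
      pts[, 2] >= 1 & pts[, 2] <= dims[2] &
      pts[, 3] >= 1 & pts[, 3] <= dims[3]
    lin <- pts[ok, 1] + dims[1] * (pts[ok, 2] - 1) +
      dims[1] * dims[2] * (pts[ok, 3] - 1)
    lin <- lin[mask[lin]]
    if (length(lin) < 2) {
      n_skipped <- n_skipped + 1L
      next
    }
    out[centers[i]] <- scheme_core(vb$values[, , lin, drop = FALSE],
                                   vb$condition_labels, map, scheme,
                                   cost)[["info"]]
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Group-level searchlight inference
#'
#' Stacks per-participant searchlight maps, runs the sign-flip TFCE null
#' with max-statistic correction over the in-mask voxels, and reports a
#' corrected z/p volume plus a cluster table of suprathreshold voxels
#' (connected components at `alpha`), with peak world coordinates via the
#' affine and extent in voxels and mm^3.
#'
#' @param maps List of per-participant 3-D score arrays (as from
#'   [run_searchlight()]).
#' @param mask Logical array: voxels to test (must be scored in every map).
#' @param params [tfce_params()].
#' @param affine 4x4 voxel-to-world matrix (2 mm isotropic default).
#' @param alpha Corrected significance threshold for the cluster table.
#' @return List: `z` and `p` (3-D arrays, `NA` outside mask), `clusters`
#'   (data frame: `cluster_id`, `peak_x_mm`, `peak_y_mm`, `peak_z_mm`,
#'   `n_voxels`, `volume_mm3`, `peak_z`), `null_max`.
#' @export
group_searchlight <- function(maps, mask, params = tfce_params(
                                tail = "one_sided_positive"),
                              affine = diag(c(2, 2, 2, 1)), alpha = 0.05) {
  stopifnot(length(maps) >= 2)
  dims <- dim(maps[[1]])
  idx <- which(mask)
  data <- do.call(rbind, lapply(maps, function(m) m[idx]))
  if (anyNA(data)) stopf("maps contain unscored voxels inside the mask")
  adj <- lattice_adjacency(dims, mask)
  nl <- signflip_null(data, adj, params)
  mc <- maxstat_correct(nl$tfce_observed, nl$null_max)
  zmap <- array(NA_real_, dims); zmap[idx] <- mc$z
  pmap <- array(NA_real_, dims); pmap[idx] <- mc$p
  sig <- mc$p <= alpha
  clusters <- data.frame(cluster_id = integer(0), peak_x_mm = numeric(0),
                         peak_y_mm = numeric(0), peak_z_mm = numeric(0),
                         n_voxels = integer(0), volume_mm3 = numeric(0),
                         peak_z = numeric(0))
  if (any(sig)) {
    cc <- component_sizes_at(sig, adj)
    vox_vol <- abs(det(affine[1:3, 1:3]))
    for (id in seq_along(cc$sizes)) {
      members <- idx[cc$comp == id]
      peak <- members[which.max(zmap[members])]
      ijk <- arrayInd(peak, dims) - 1L # 0-based voxel indices
      world <- affine %*% c(ijk, 1)
      clusters <- rbind(clusters, data.frame(
        cluster_id = id, peak_x_mm = world[1], peak_y_mm = world[2],
        peak_z_mm = world[3], n_voxels = cc$sizes[id],
        volume_mm3 = cc$sizes[id] * vox_vol, peak_z = max(zmap[members])))
    }
  }
  list(z = zmap, p = pmap, clusters = clusters, null_max = nl$null_max)
}
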