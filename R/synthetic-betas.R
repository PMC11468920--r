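## Synthetic voxel-pattern generator. Condition betas are an additive mix of
## three multivariate codes -- anchor identity (keyed by the ASSOCIATED
## anchor under the association map, hence shared across scene contexts),
## target category and scene context -- carried by fixed random voxel
## patterns of unit per-voxel RMS amplitude, plus i.i.d. Gaussian noise per
## (run, condition, voxel). Amplitudes are therefore per-voxel effect sizes
## in units of the beta noise SD.

#' Ground-truth parameters for the synthetic generator
#'
#' Bundles every generating parameter of the synthetic experiment: voxel
#' code amplitudes (beta units), beta noise, localizer effect sizes, gaze
#' structure (fixation dropout rates, anchor guidance probabilities, first
#' fixation latency) and the guidance-to-d' link used for responses.
#'
#' Defaults encode the qualitative regime the analyses probe: a reliable
#' anchor code with no target code, first fixations mostly anchor-directed
#' and biased toward the associated anchor, and per-participant sensitivity
#' (d') increasing with guidance.
#'
#' @param anchor_amp,target_amp,context_amp Amplitudes of the anchor,
#'   target-category and scene-context codes (beta units, >= 0).
#' @param noise_sd Beta noise standard deviation (> 0).
#' @param loc_effect,loc_noise_sd Localizer selective mean difference and
#'   noise SD.
#' @param p_fix_recorded Probability a search trial has any recorded
#'   fixation.
#' @param p_center_onset Probability the scene-onset fixation lies in the
#'   center AOI (given a fixation was recorded).
#' @param anchor_fix_prob Probability the first post-onset fixation is
#'   anchor-directed (rather than staying central).
#' @param guidance_prob_present,guidance_prob_absent Population mean
#'   probability that an anchor-directed first fixation lands on the
#'   associated anchor, on target-present / target-absent trials.
#' @param guidance_sd Between-participant SD of that probability.
#' @param latency_mean_ms,latency_sd_ms First-fixation latency distribution
#'   (truncated normal, ms).
#' @param dprime_mean Population mean d'.
#' @param dprime_slope Increase in d' per percentage point of guidance
#'   delta; default calibrated with [guidance_dprime_slope()] so the latent
#'   guidance-d' correlation is 0.55.
#' @param dprime_noise_sd SD of the guidance-independent d' component.
#' @param seed Integer seed.
#' @return A list of class `ground_truth`.
#' @export
ground_truth <- function(anchor_amp = 0.5, target_amp = 0, context_amp = 0.2,
                         noise_sd = 1, loc_effect = 1, loc_noise_sd = 1,
                         p_fix_recorded = 0.94, p_center_onset = 0.83,
                         anchor_fix_prob = 0.805,
                         guidance_prob_present = 0.657,
                         guidance_prob_absent = 0.619,
                         guidance_sd = 0.10,
                         latency_mean_ms = 229.53, latency_sd_ms = 29.20,
                         dprime_mean = 1.19,
                         dprime_slope = guidance_dprime_slope(
                           0.55, 100 * 2 * anchor_fix_prob * guidance_sd,
                           dprime_noise_sd),
                         dprime_noise_sd = 0.5,
                         seed = 1L) {
  gt <- list(anchor_amp = anchor_amp, target_amp = target_amp,
             context_amp = context_amp, noise_sd = noise_sd,
             loc_effect = loc_effect, loc_noise_sd = loc_noise_sd,
             p_fix_recorded = p_fix_recorded,
             p_center_onset = p_center_onset,
             anchor_fix_prob = anchor_fix_prob,
             guidance_prob_present = guidance_prob_present,
             guidance_prob_absent = guidance_prob_absent,
             guidance_sd = guidance_sd,
             latency_mean_ms = latency_mean_ms,
             latency_sd_ms = latency_sd_ms,
             dprime_mean = dprime_mean, dprime_slope = dprime_slope,
             dprime_noise_sd = dprime_noise_sd, seed = as.integer(seed))
  for (f in c("anchor_amp", "target_amp", "context_amp")) {
    if (!is.numeric(gt[[f]]) || gt[[f]] < 0) stopf("%s must be >= 0", f)
  }
  if (!is.numeric(gt$noise_sd) || gt$noise_sd <= 0) {
    stopf("noise_sd must be > 0")
  }
  for (f in c("p_fix_recorded", "p_center_onset", "anchor_fix_prob",
              "guidance_prob_present", "guidance_prob_absent")) {
    if (!is_prob(gt[[f]])) stopf("%s must be a probability in [0, 1]", f)
  }
  class(gt) <- "ground_truth"
  gt
}

#' Calibrate the guidance-to-d' slope for a target latent correlation
#'
#' With participant guidance delta distributed with standard deviation
#' `sd_delta` (percentage points) and a guidance-independent d' component
#' with standard deviation `noise_sd`, the slope
#' `r * noise_sd / (sd_delta * sqrt(1 - r^2))` yields a latent
#' guidance-d' correlation of exactly `r`.
#'
#' @param r Target population correlation in (-1, 1).
#' @param sd_delta SD of the guidance delta (percentage points).
#' @param noise_sd SD of the residual d' component.
#' @return The slope (d' units per percentage point).
#' @export
guidance_dprime_slope <- function(r, sd_delta, noise_sd) {
  stopifnot(abs(r) < 1, sd_delta >= 0, noise_sd >= 0)
  if (sd_delta == 0) return(0) # no guidance spread: slope is irrelevant
  r * noise_sd / (sd_delta * sqrt(1 - r^2))
}

## The four (target x context) conditions of interest, in fixed order.
condition_table <- function() {
  expand.grid(target = TARGETS, context = CONTEXTS,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

new_beta_patterns <- function(values, condition_labels, hemisphere,
                              roi_name, voxel_ids) {
  structure(list(values = values, condition_labels = condition_labels,
                 hemisphere = hemisphere, roi_name = roi_name,
                 voxel_ids = voxel_ids),
            class = "beta_patterns")
}

## Random voxel pattern with unit root-mean-square amplitude (one per code
## level), so code amplitudes are per-voxel effect sizes in units of the
## beta noise standard deviation.
unit_pattern <- function(n_voxels) {
  v <- rnorm(n_voxels)
  v / sqrt(mean(v^2))
}

#' Simulate run-wise condition beta patterns for one participant
#'
#' Generates `beta_patterns` per hemisphere: arrays indexed
#' (run, condition, voxel) over the four (target x context) conditions of
#' interest. The anchor code is keyed by the associated anchor under `map`,
#' so the same anchor pattern recurs in both contexts wherever that anchor
#' is the associated one; this is what cross-scene decoding exploits.
#'
#' @param gt A [ground_truth()] object.
#' @param map An [make_association_map()] object.
#' @param n_runs Number of runs (>= 2 so cross-validation has folds).
#' @param n_voxels Voxels per hemisphere (> 0).
#' @param hemispheres Character vector of hemisphere names.
#' @param roi_name Label carried through to results.
#' @param seed Seed; defaults to `gt$seed`. Code patterns and noise both
#'   derive from it, so identical seeds give bit-identical patterns.
#' @param baseline Scalar added to every beta.
#' @return Named list of `beta_patterns`, one per hemisphere.
#' @export
simulate_participant_betas <- function(gt, map, n_runs = 8, n_voxels = 264,
                                       hemispheres = c("left", "right"),
                                       roi_name = "LOC", seed = gt$seed,
                                       baseline = 0) {
  stopifnot(inherits(gt, "ground_truth"), inherits(map, "association_map"))
  if (!is_count(n_voxels)) stopf("n_voxels must be a positive integer")
  if (!is_count(n_runs, 2L)) stopf("n_runs must be >= 2")
  conds <- condition_table()
  n_cond <- nrow(conds)
  cond_anchor <- anchor_for(map, conds$context, conds$target)
  out <- list()
  for (h in seq_along(hemispheres)) {
    hemi <- hemispheres[h]
    vals <- with_seed(derive_seed(seed, 1000L + h), {
      pat <- list(
        anchor = vapply(ANCHORS, function(a) unit_pattern(n_voxels),
                        numeric(n_voxels)),
        target = vapply(TARGETS, function(t) unit_pattern(n_voxels),
                        numeric(n_voxels)),
        context = vapply(CONTEXTS, function(cx) unit_pattern(n_voxels),
                         numeric(n_voxels)))
      a <- array(rnorm(n_runs * n_cond * n_voxels, sd = gt$noise_sd),
                 dim = c(n_runs, n_cond, n_voxels))
      for (ci in seq_len(n_cond)) {
        mu <- baseline +
          gt$anchor_amp * pat$anchor[, cond_anchor[ci]] +
          gt$target_amp * pat$target[, conds$target[ci]] +
          gt$context_amp * pat$context[, conds$context[ci]]
        a[, ci, ] <- sweep(a[, ci, , drop = FALSE], 3, mu, "+")
      }
      a
    })
    out[[hemi]] <- new_beta_patterns(vals, conds, hemi, roi_name,
                                     seq_len(n_voxels))
  }
  out
}

#' Simulate localizer run betas with selective voxels
#'
#' Emulates the visual localizer: 8 conditions (two target categories and
#' two anchor tables, each shown centrally or peripherally) x `n_runs` runs.
#' A seeded random subset of voxels carries a target-discriminating mean
#' difference and an independently drawn (possibly overlapping) subset an
#' anchor-discriminating difference; localizer patterns are independent of
#' the task code patterns.
#'
#' @param gt A [ground_truth()] object (`loc_effect`, `loc_noise_sd` used).
#' @param n_runs Localizer runs (default 4).
#' @param n_voxels Voxel count.
#' @param selective_fraction Fraction of voxels in each selective subset,
#'   in (0, 1] (0 allowed: no selective voxels).
#' @param seed Seed; defaults to `gt$seed`.
#' @return List with `values` (run x 8 conditions x voxel array),
#'   `condition_labels` (object x location data frame), and `selective`
#'   (logical data frame: per-voxel ground-truth target/anchor selectivity).
#' @export
simulate_localizer_betas <- function(gt, n_runs = 4, n_voxels = 264,
                                     selective_fraction = 0.3,
                                     seed = gt$seed) {
  stopifnot(inherits(gt, "ground_truth"))
  if (!is_prob(selective_fraction)) {
    stopf("selective_fraction must be in [0, 1]")
  }
  conds <- expand.grid(object = c(TARGETS, ANCHORS),
                       location = c("central", "peripheral"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_cond <- nrow(conds) # 8
  n_sel <- round(selective_fraction * n_voxels)
  with_seed(derive_seed(seed, 2000L), {
    target_sel <- seq_len(n_voxels) %in% sample.int(n_voxels, n_sel)
    anchor_sel <- seq_len(n_voxels) %in% sample.int(n_voxels, n_sel)
    ## random per-voxel preference sign keeps group means balanced
    tsign <- sample(c(-1, 1), n_voxels, replace = TRUE)
    asign <- sample(c(-1, 1), n_voxels, replace = TRUE)
    vals <- array(rnorm(n_runs * n_cond * n_voxels, sd = gt$loc_noise_sd),
                  dim = c(n_runs, n_cond, n_voxels))
    half <- gt$loc_effect / 2
    t_dir <- ifelse(conds$object == "target_1", 1,
                    ifelse(conds$object == "target_2", -1, 0))
    a_dir <- ifelse(conds$object == "anchor_1", 1,
                    ifelse(conds$object == "anchor_2", -1, 0))
    for (ci in seq_len(n_cond)) {
      mu <- half * t_dir[ci] * tsign * target_sel +
        half * a_dir[ci] * asign * anchor_sel
      vals[, ci, ] <- sweep(vals[, ci, , drop = FALSE], 3, mu, "+")
    }
    list(values = vals, condition_labels = conds,
         selective = data.frame(voxel_id = seq_len(n_voxels),
                                target_selective = target_sel,
                                anchor_selective = anchor_sel))
  })
}

#' Simulate a BOLD time series from condition betas
#'
#' Builds the run's convolved design matrix and returns
#' `Y = X %*% B + noise` for one run, letting the GLM stage be exercised
#' end-to-end. Interest betas come from `betas$values[run, , ]`; nuisance
#' betas are zero.
#'
#' @param betas A `beta_patterns` object.
#' @param trials Trial table (one experiment); the run's preview-only trials
#'   define the interest boxcars.
#' @param run Run index to simulate.
#' @param tr Repetition time (s).
#' @param n_scans Scans in the run; must cover the last preview offset.
#' @param noise_model List with `sd` (innovation SD; 0 = noiseless) and `ar`
#'   (AR(1) coefficient, 0 = white).
#' @param hrf [hrf_params()] for the design.
#' @param seed Seed for the noise draw.
#' @return List with `Y` (n_scans x voxel matrix) and `design` (the
#'   [build_design_matrix()] output used).
#' @export
simulate_timeseries <- function(betas, trials, run = 1, tr = 1.5,
                                n_scans = 198,
                                noise_model = list(sd = 0, ar = 0),
                                hrf = hrf_params(tr = tr), seed = 1L) {
  stopifnot(inherits(betas, "beta_patterns"))
  run_trials <- trials[trials$run == run, , drop = FALSE]
  if (nrow(run_trials) == 0) stopf("no trials for run %d", run)
  if (max(run_trials$preview_offset) > n_scans * tr) {
    stopf("n_scans * tr (%.1f s) does not cover the last preview offset (%.1f s)",
          n_scans * tr, max(run_trials$preview_offset))
  }
  X <- build_design_matrix(run_trials, tr = tr, n_scans = n_scans, hrf = hrf)
  n_vox <- dim(betas$values)[3]
  B <- matrix(0, ncol(X$values), n_vox)
  B[X$interest_columns, ] <- betas$values[run, , ]
  Y <- X$values %*% B
  if (noise_model$sd > 0) {
    eps <- with_seed(seed, {
      e <- matrix(rnorm(n_scans * n_vox, sd = noise_model$sd), n_scans, n_vox)
      if (!is.null(noise_model$ar) && noise_model$ar != 0) {
        e <- apply(e, 2, function(col) {
          as.numeric(stats::filter(col, noise_model$ar, method = "recursive"))
        })
      }
      e
    })
    Y <- Y + eps
  }
  list(Y = Y, design = X)
}
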