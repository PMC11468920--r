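## Orchestration: a validated configuration drives simulation, decoding,
## group statistics and the behavioral analysis end-to-end, writing tabular
## results and a machine-readable summary.

default_config <- function() {
  list(
    seed = 1L,
    n_participants = 34L,
    n_runs = 8L,
    trials_per_run = 32L,
    output_dir = NULL,
    ground_truth = list(), # overrides for ground_truth()
    decode = list(schemes = DECODING_SCHEMES,
                  n_voxels = 264L,
                  hemispheres = c("left", "right"),
                  roi_name = "LOC", cost = 1),
    subroi = list(enabled = TRUE, n_steps = 5L, max_voxels = 264L,
                  group_mask_voxels = 600L, selective_fraction = 0.5,
                  alpha = 0.05, localizer_runs = 4L),
    stats = list(n_boot = 10000L, tfce_extent_exponent = 0.5,
                 tfce_height_exponent = 2, tfce_permutations = 1000L),
    gaze = list(enabled = TRUE, onset_tolerance_ms = 0)
  )
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stopf("unknown config key%s: %s", if (length(unknown) > 1) "s" else "",
          paste0(path, unknown, collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
        !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Reads YAML (a path or literal text) or takes a list, fills defaults,
#' rejects unknown keys and checks cross-field constraints. An empty input
#' yields the all-defaults configuration.
#'
#' @param config A YAML file path, YAML text, a list, or `NULL`.
#' @return A validated config list of class `pipeline_config`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    config <- if (file.exists(config)) yaml::read_yaml(config) else
      yaml::yaml.load(config)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) stopf("config must be a YAML mapping or a list")
  cfg <- merge_config(default_config(), config)
  errors <- character(0)
  if (!is_count(cfg$n_participants, 2L)) {
    errors <- c(errors, "n_participants must be an integer >= 2")
  }
  if (!is_count(cfg$n_runs, 2L)) {
    errors <- c(errors, "n_runs must be an integer >= 2")
  }
  if (!is_count(cfg$trials_per_run) || cfg$trials_per_run %% 32 != 0 ||
      cfg$trials_per_run != 32) {
    errors <- c(errors,
                "trials_per_run must be a multiple of 32 (one full factorial crossing; only 32 supported)")
  }
  gt <- try(do.call(ground_truth, cfg$ground_truth), silent = TRUE)
  if (inherits(gt, "try-error")) {
    errors <- c(errors, paste("ground_truth:",
                              trimws(attr(gt, "condition")$message)))
  }
  bad_schemes <- setdiff(cfg$decode$schemes, DECODING_SCHEMES)
  if (length(bad_schemes)) {
    errors <- c(errors, paste("unknown decoding scheme:",
                              paste(bad_schemes, collapse = ", ")))
  }
  if (length(errors)) {
    stopf("invalid configuration:\n  - %s", paste(errors, collapse = "\n  - "))
  }
  cfg$ground_truth_obj <- gt
  class(cfg) <- "pipeline_config"
  cfg
}

#' Simulate and decode a group of participants
#'
#' For each participant: derive a seed, assign a counterbalance variant
#' (cycling through the four), simulate beta patterns and run the decoding
#' schemes. The workhorse behind [run_pipeline()] and the group-level
#' evaluations.
#'
#' @param gt A [ground_truth()].
#' @param n_participants Group size.
#' @param schemes Decoding scheme names.
#' @param n_runs,n_voxels,hemispheres,roi_name,cost Decoding configuration.
#' @param seed Master seed.
#' @return Long data frame: `participant`, `scheme`, `roi`, `roi_size`,
#'   `info`, `accuracy`.
#' @export
simulate_group_decoding <- function(gt, n_participants = 34,
                                    schemes = "anchor_cross_scene",
                                    n_runs = 8, n_voxels = 264,
                                    hemispheres = c("left", "right"),
                                    roi_name = "LOC", cost = 1,
                                    seed = gt$seed) {
  rows <- vector("list", n_participants * length(schemes))
  k <- 0L
  for (p in seq_len(n_participants)) {
    p_seed <- derive_seed(seed, 7L * p)
    map <- make_association_map((p - 1) %% 4)
    betas <- simulate_participant_betas(gt, map, n_runs = n_runs,
                                        n_voxels = n_voxels,
                                        hemispheres = hemispheres,
                                        roi_name = roi_name, seed = p_seed)
    for (sc in schemes) {
      res <- run_scheme(betas, sc, map, cost = cost)
      k <- k + 1L
      rows[[k]] <- data.frame(participant = p, scheme = sc,
                              roi = roi_name, roi_size = res$roi_size,
                              info = res$info, accuracy = res$accuracy)
    }
  }
  do.call(rbind, rows)
}

## Gaze + responses for one group; returns per-participant summaries.
simulate_group_behavior <- function(gt, n_participants, n_runs, seed,
                                    aois = aoi_set(),
                                    onset_tolerance_ms = 0) {
  rows <- lapply(seq_len(n_participants), function(p) {
    p_seed <- derive_seed(seed, 7L * p)
    trials <- generate_experiment(n_runs, seed = p_seed)
    beh <- simulate_participant_behavior(trials, gt, aois, seed = p_seed)
    labs <- first_fixation_labels(beh$fixations, aois, onset_tolerance_ms)
    gd <- guidance_delta(labs, trials)
    bs <- behavioral_summary(beh$responses, trials)
    data.frame(participant = p,
               delta_present = gd$delta[gd$target_present],
               delta_absent = gd$delta[!gd$target_present],
               hit_rate = bs$hit_rate, fa_rate = bs$fa_rate,
               dprime = bs$dprime, accuracy = bs$accuracy,
               delta_latent = beh$latent$delta_latent,
               dprime_true = beh$latent$dprime)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Executes, per the configuration: behavioral simulation and analysis
#' (guidance deltas, d', guidance-performance correlation, paired
#' condition test), unrestricted-ROI decoding with participant bootstrap
#' tests per scheme, and optionally the localizer-driven sub-ROI sweep with
#' TFCE inference over the size curves. With `output_dir` set, writes the
#' result tables as TSV and a JSON summary carrying the package version,
#' seed and configuration.
#'
#' @param config Anything accepted by [validate_config()].
#' @return List of class `pipeline_result`: `behavior`, `behavior_tests`,
#'   `decoding`, `group_tests`, `subroi` (curves and TFCE p-values, if
#'   enabled), `config`.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  gt <- cfg$ground_truth_obj
  seed <- cfg$seed
  out <- list(config = cfg)

  if (isTRUE(cfg$gaze$enabled)) {
    beh <- simulate_group_behavior(gt, cfg$n_participants, cfg$n_runs, seed,
                                   onset_tolerance_ms =
                                     cfg$gaze$onset_tolerance_ms)
    corr <- guidance_performance_correlation(beh)
    cond_diff <- condition_difference_test(beh$delta_present,
                                           beh$delta_absent,
                                           n_boot = cfg$stats$n_boot,
                                           seed = derive_seed(seed, 11L))
    delta_absent_test <- bootstrap_test(beh$delta_absent,
                                        n_boot = cfg$stats$n_boot,
                                        seed = derive_seed(seed, 12L))
    delta_present_test <- bootstrap_test(beh$delta_present,
                                         n_boot = cfg$stats$n_boot,
                                         seed = derive_seed(seed, 13L))
    out$behavior <- beh
    out$behavior_tests <- list(correlation = corr,
                               present_vs_absent = cond_diff,
                               delta_absent = delta_absent_test,
                               delta_present = delta_present_test)
  }

  dec <- simulate_group_decoding(gt, cfg$n_participants,
                                 schemes = cfg$decode$schemes,
                                 n_runs = cfg$n_runs,
                                 n_voxels = cfg$decode$n_voxels,
                                 hemispheres = cfg$decode$hemispheres,
                                 roi_name = cfg$decode$roi_name,
                                 cost = cfg$decode$cost, seed = seed)
  out$decoding <- dec
  out$group_tests <- lapply(split(dec, dec$scheme), function(d) {
    bootstrap_test(d$info, n_boot = cfg$stats$n_boot,
                   seed = derive_seed(seed, 14L))
  })

  if (isTRUE(cfg$subroi$enabled)) {
    out$subroi <- run_subroi_sweep(cfg, gt, seed)
  }

  if (!is.null(cfg$output_dir)) {
    write_pipeline_results(out, cfg$output_dir)
  }
  class(out) <- "pipeline_result"
  out
}

## Localizer-driven sub-ROI sweep: selection, nested sub-ROIs, decoding per
## size, TFCE over the 1-D size curves per scheme.
run_subroi_sweep <- function(cfg, gt, seed) {
  sr <- cfg$subroi
  n_sizes <- sr$n_steps
  curves <- list()
  for (p in seq_len(cfg$n_participants)) {
    p_seed <- derive_seed(seed, 7L * p)
    map <- make_association_map((p - 1) %% 4)
    betas <- simulate_participant_betas(gt, map, n_runs = cfg$n_runs,
                                        n_voxels = sr$group_mask_voxels,
                                        hemispheres = cfg$decode$hemispheres,
                                        roi_name = cfg$decode$roi_name,
                                        seed = p_seed)
    for (sc in cfg$decode$schemes) {
      infos <- matrix(NA_real_, length(betas), n_sizes)
      for (h in seq_along(betas)) {
        loc <- simulate_localizer_betas(gt, n_runs = sr$localizer_runs,
                                        n_voxels = sr$group_mask_voxels,
                                        selective_fraction =
                                          sr$selective_fraction,
                                        seed = derive_seed(p_seed, 90L + h))
        f_t <- f_contrast(loc$values,
                          list(t1 = which(loc$condition_labels$object ==
                                            "target_1"),
                               t2 = which(loc$condition_labels$object ==
                                            "target_2")))
        f_a <- f_contrast(loc$values,
                          list(a1 = which(loc$condition_labels$object ==
                                            "anchor_1"),
                               a2 = which(loc$condition_labels$object ==
                                            "anchor_2")))
        mask <- select_roi_voxels(seq_len(sr$group_mask_voxels), f_t, f_a,
                                  alpha = sr$alpha,
                                  roi_name = cfg$decode$roi_name,
                                  hemisphere = names(betas)[h])
        subs <- make_sub_rois(mask, n_steps = n_sizes,
                              max_voxels = min(sr$max_voxels,
                                               length(mask$voxel_ids)))
        for (k in seq_len(n_sizes)) {
          bb <- apply_roi_mask(betas[[h]], subs[[k]])
          infos[h, k] <- scheme_core(bb$values, bb$condition_labels, map,
                                     sc, cfg$decode$cost)[["info"]]
        }
      }
      curves[[sc]] <- rbind(curves[[sc]], colMeans(infos))
    }
  }
  tp <- tfce_params(extent_exponent = cfg$stats$tfce_extent_exponent,
                    height_exponent = cfg$stats$tfce_height_exponent,
                    n_permutations = cfg$stats$tfce_permutations,
                    seed = derive_seed(seed, 15L), tail = "two_sided")
  adj <- chain_adjacency(n_sizes)
  lapply(curves, function(cv) {
    nl <- signflip_null(cv, adj, tp)
    mc <- maxstat_correct(nl$tfce_observed, nl$null_max)
    list(curve_mean = colMeans(cv), curves = cv, p_corrected = mc$p,
         z = mc$z)
  })
}

write_pipeline_results <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(package = "anchorsearch",
                version = as.character(utils::packageVersion("anchorsearch")),
                seed = out$config$seed,
                config_hash = digest_config(out$config))
  if (!is.null(out$behavior)) {
    write_tsv_table(out$behavior, file.path(dir, "behavior.tsv"))
  }
  write_tsv_table(out$decoding, file.path(dir, "decoding.tsv"))
  gt_tests <- data.frame(
    scheme = names(out$group_tests),
    mean_info = vapply(out$group_tests, `[[`, 0, "observed_mean"),
    ci_low = vapply(out$group_tests, `[[`, 0, "ci_low"),
    ci_high = vapply(out$group_tests, `[[`, 0, "ci_high"),
    p = vapply(out$group_tests, `[[`, 0, "p_two_tailed"), row.names = NULL)
  write_tsv_table(gt_tests, file.path(dir, "group_tests.tsv"))
  if (!is.null(out$subroi)) {
    sub_tab <- do.call(rbind, lapply(names(out$subroi), function(sc) {
      s <- out$subroi[[sc]]
      data.frame(scheme = sc, size_step = seq_along(s$curve_mean),
                 mean_info = s$curve_mean, p_tfce = s$p_corrected)
    }))
    write_tsv_table(sub_tab, file.path(dir, "subroi_curves.tsv"))
  }
  summary <- c(stamp, list(
    group_tests = lapply(out$group_tests, function(g) {
      list(mean = g$observed_mean, ci = c(g$ci_low, g$ci_high),
           p = g$p_two_tailed)
    }),
    behavior_tests = if (!is.null(out$behavior_tests)) list(
      r_absent = out$behavior_tests$correlation$r[
        out$behavior_tests$correlation$condition == "absent"],
      r_present = out$behavior_tests$correlation$r[
        out$behavior_tests$correlation$condition == "present"],
      present_vs_absent_p = out$behavior_tests$present_vs_absent$p_two_tailed)))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

## Stable short hash of the configuration (no extra dependencies): sum of
## a rolling polynomial over the serialized text.
digest_config <- function(cfg) {
  cfg$ground_truth_obj <- unclass(cfg$ground_truth_obj)
  txt <- paste(deparse(unclass(cfg)), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
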