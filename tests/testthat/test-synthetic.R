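test_that("ground truth validates its parameters", {
  expect_s3_class(ground_truth(), "ground_truth")
  expect_error(ground_truth(noise_sd = 0), "noise_sd")
  expect_error(ground_truth(anchor_amp = -1), "anchor_amp")
  expect_error(ground_truth(guidance_prob_absent = 1.2), "probability")
})

test_that("anchor code is shared across contexts in noiseless betas", {
  gt <- test_gt(anchor_amp = 1, target_amp = 0, context_amp = 0,
                noise_sd = 1e-9)
  map <- make_association_map(0)
  b <- simulate_participant_betas(gt, map, n_runs = 2, n_voxels = 40,
                                  hemispheres = "left")$left
  conds <- b$condition_labels
  anchors <- anchor_for(map, conds$context, conds$target)
  for (a in unique(anchors)) {
    ix <- which(anchors == a)
    # same associated anchor -> identical betas across contexts and runs
    for (i in ix[-1]) {
      expect_equal(b$values[1, ix[1], ], b$values[2, i, ], tolerance = 1e-6)
    }
  }
  # different associated anchors -> different patterns
  expect_gt(max(abs(b$values[1, 1, ] - b$values[1, 2, ])), 0.5)
})

test_that("beta generation is seed-deterministic and error-checked", {
  gt <- test_gt()
  map <- make_association_map(1)
  b1 <- simulate_participant_betas(gt, map, n_runs = 3, n_voxels = 20)
  b2 <- simulate_participant_betas(gt, map, n_runs = 3, n_voxels = 20)
  expect_identical(b1$left$values, b2$left$values)
  expect_false(identical(b1$left$values, b1$right$values))
  expect_error(simulate_participant_betas(gt, map, n_voxels = 0), "n_voxels")
  expect_error(simulate_participant_betas(gt, map, n_runs = 1), "n_runs")
})

test_that("amplitude-zero betas decode at chance on average", {
  gt <- test_gt(anchor_amp = 0, target_amp = 0, context_amp = 0)
  infos <- sapply(1:30, function(r) {
    map <- make_association_map(r %% 4)
    b <- simulate_participant_betas(gt, map, n_runs = 4, n_voxels = 24,
                                    hemispheres = "left",
                                    seed = 100 + r)
    run_scheme(b, "anchor_cross_scene", map)$info
  })
  expect_lt(abs(mean(infos)), 3 * sd(infos) / sqrt(length(infos)))
})

test_that("localizer selectivity labels match the planted structure", {
  gt <- test_gt(loc_effect = 4, loc_noise_sd = 1)
  loc <- simulate_localizer_betas(gt, n_runs = 4, n_voxels = 100,
                                  selective_fraction = 0.2)
  expect_equal(dim(loc$values), c(4, 8, 100))
  expect_equal(sum(loc$selective$target_selective), 20)
  labs <- loc$condition_labels
  f_t <- f_contrast(loc$values, list(which(labs$object == "target_1"),
                                     which(labs$object == "target_2")))
  # strongly selective voxels dominate the F ranking
  top20 <- order(-f_t$F)[1:20]
  expect_gt(mean(loc$selective$target_selective[top20]), 0.8)
  # zero selective fraction: significant rate stays near alpha
  loc0 <- simulate_localizer_betas(gt, n_voxels = 400,
                                   selective_fraction = 0)
  f0 <- f_contrast(loc0$values, list(which(labs$object == "target_1"),
                                     which(labs$object == "target_2")))
  expect_lt(mean(f0$p < 0.05), 0.12)
})

test_that("beta patterns round-trip through the tabular format", {
  gt <- test_gt()
  map <- make_association_map(0)
  b <- simulate_participant_betas(gt, map, n_runs = 2, n_voxels = 6,
                                  hemispheres = "right")$right
  path <- withr::local_tempfile(fileext = ".tsv")
  write_beta_table(b, path)
  back <- read_beta_table(path)
  expect_equal(back$values, b$values, tolerance = 1e-9)
  expect_equal(back$condition_labels, b$condition_labels)
  expect_equal(back$hemisphere, "right")
})

test_that("ground truth round-trips through the JSON sidecar", {
  gt <- test_gt(anchor_amp = 0.25, guidance_sd = 0.05)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(gt, path)
  back <- read_ground_truth(path)
  expect_equal(unclass(back), unclass(gt), tolerance = 1e-12)
})

test_that("fixation generator respects guidance extremes", {
  gt <- test_gt(p_fix_recorded = 1, p_center_onset = 1, anchor_fix_prob = 1,
                guidance_sd = 0)
  trials <- generate_experiment(2, seed = 9)
  # guidance 1: every anchor-directed first fixation on the associated side
  fix <- simulate_fixations(trials, gt,
                            guidance_probs = c(present = 1, absent = 1),
                            seed = 1)
  labs <- first_fixation_labels(fix)
  gd <- guidance_delta(labs, trials)
  expect_equal(gd$delta, c(100, 100))
  # guidance 0: all on the other side
  fix0 <- simulate_fixations(trials, gt,
                             guidance_probs = c(present = 0, absent = 0),
                             seed = 1)
  gd0 <- guidance_delta(first_fixation_labels(fix0), trials)
  expect_equal(gd0$delta, c(-100, -100))
})

test_that("response generator tracks d-prime limits", {
  trials <- generate_experiment(4, seed = 2)
  gt0 <- test_gt(dprime_mean = 0, dprime_slope = 0, dprime_noise_sd = 0)
  r0 <- simulate_responses(trials, gt0, participant_guidance = 0, seed = 3)
  expect_equal(r0$dprime_true, 0)
  expect_lt(abs(mean(r0$responses$correct) - 0.5), 0.15)
  gt_inf <- test_gt(dprime_mean = 20, dprime_slope = 0, dprime_noise_sd = 0)
  r_inf <- simulate_responses(trials, gt_inf, participant_guidance = 0)
  expect_equal(mean(r_inf$responses$correct), 1)
})
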