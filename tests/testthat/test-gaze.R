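test_that("fixations classify into AOIs with anchor precedence", {
  aois <- aoi_set()
  expect_equal(classify_fixation(0, 0, aois), "center")
  expect_equal(classify_fixation(-7.5, -1.5, aois), "left_anchor")
  expect_equal(classify_fixation(7.5, -1.5, aois), "right_anchor")
  expect_equal(classify_fixation(0, 20, aois), "none")
  expect_equal(classify_fixation(2.25, 0, aois), "center") # inclusive edge
  # overlapping center/anchor geometry: anchor label wins
  tight <- aoi_set(anchor_offset_x = 5, center_wh = c(4.5, 10.5),
                   anchor_wh = c(7.5, 10.5))
  expect_equal(classify_fixation(2, 0, tight), "right_anchor")
  expect_error(aoi_set(anchor_offset_x = 1), "overlap")
})

test_that("first-fixation inclusion follows the onset-fixation rule", {
  fx <- function(trial, onset, dur, x, y) {
    data.frame(run = 1, trial_index = trial, x_deg = x, y_deg = y,
               onset_ms = onset, duration_ms = dur)
  }
  fixes <- rbind(
    fx(1, -150, 300, 0, 0), fx(1, 230, 180, -7.5, -1.5), # valid -> left
    fx(2, -150, 300, 8, 0), fx(2, 230, 180, -7.5, -1.5), # off-center onset
    fx(3, -150, 300, 0, 0),                              # no next fixation
    fx(4, 100, 200, 7.5, -1.5))                          # nothing at onset
  labs <- first_fixation_labels(fixes)
  expect_equal(labs$label[labs$trial_index == 1], "left_anchor")
  expect_equal(labs$label[labs$trial_index == 2], "excluded")
  expect_equal(labs$label[labs$trial_index == 3], "excluded")
  expect_equal(labs$label[labs$trial_index == 4], "excluded")
  # AOI label counts conserve the included-trial count
  expect_equal(sum(labs$label != "excluded"), 1L)
})

test_that("guidance delta computes the signed first-fixation difference", {
  trials <- generate_experiment(1, seed = 1)
  search <- trials[trials$trial_type == "search", ]
  # all first fixations to the associated side
  labs <- data.frame(run = search$run, trial_index = search$trial_index,
                     label = ifelse(search$anchor_side == "left",
                                    "left_anchor", "right_anchor"))
  gd <- guidance_delta(labs, trials)
  expect_equal(gd$delta, c(100, 100))
  # equal split: zero
  labs2 <- labs
  flip <- rep(c(TRUE, FALSE), length.out = nrow(labs2))
  labs2$label[flip] <- ifelse(labs2$label[flip] == "left_anchor",
                              "right_anchor", "left_anchor")
  gd2 <- guidance_delta(labs2, trials)
  expect_equal(gd2$delta, c(0, 0))
  # antisymmetric under swapping which anchor is associated
  trials_swapped <- trials
  trials_swapped$anchor_side <- ifelse(trials$anchor_side == "left",
                                       "right", "left")
  gd3 <- guidance_delta(labs, trials_swapped)
  expect_equal(gd3$delta, -gd$delta)
  # center/none fixations dilute the denominator
  labs4 <- labs
  labs4$label[1:8] <- "center"
  gd4 <- guidance_delta(labs4, trials)
  expect_true(all(gd4$delta < 100))
  expect_equal(gd4$n_included, gd$n_included) # center trials still included
})

test_that("d-prime matches the inverse-normal arithmetic", {
  expect_equal(dprime(8, 16, 8, 16), 0)            # h = f
  expect_equal(dprime(0.8 * 20, 20, 0.2 * 20, 20), 2 * qnorm(0.8),
               tolerance = 1e-9)
  # extreme rates corrected by 1/(2N)
  expect_equal(dprime(16, 16, 4, 16),
               qnorm(31 / 32) - qnorm(0.25), tolerance = 1e-12)
  expect_equal(dprime(0, 16, 4, 16),
               qnorm(1 / 32) - qnorm(0.25), tolerance = 1e-12)
  # monotone in hit rate, antitone in false-alarm rate
  expect_true(dprime(12, 16, 4, 16) > dprime(10, 16, 4, 16))
  expect_true(dprime(12, 16, 6, 16) < dprime(12, 16, 4, 16))
})

test_that("behavioral summary and correlation integrate the pieces", {
  set.seed(8)
  n <- 34
  delta <- rnorm(n, 20, 15)
  dp <- 1 + 0.03 * delta + rnorm(n, 0, 0.1)
  summaries <- data.frame(participant = 1:n, delta_present = delta,
                          delta_absent = delta + rnorm(n, 0, 5),
                          dprime = dp)
  gc <- guidance_performance_correlation(summaries)
  expect_setequal(gc$condition, c("present", "absent"))
  expect_gt(gc$r[gc$condition == "present"], 0.8)
  expect_lt(gc$p[gc$condition == "present"], 0.001)
  # perfectly monotone noise-free relation: r = 1
  s2 <- summaries
  s2$dprime <- 0.5 + 0.01 * s2$delta_present
  expect_equal(guidance_performance_correlation(
    s2)$r[gc$condition == "present"], 1, tolerance = 1e-12)
  # paired condition test: constant positive difference is maximally sure
  ct <- condition_difference_test(delta + 5, delta, n_boot = 500, seed = 2)
  expect_equal(ct$p_two_tailed, 2 / 501)
  expect_error(condition_difference_test(1:3, 1:4), "paired")
})

test_that("simulated guidance recovers the generating probability", {
  gt <- test_gt(p_fix_recorded = 1, p_center_onset = 1, anchor_fix_prob = 1,
                guidance_sd = 0, guidance_prob_present = 0.6,
                guidance_prob_absent = 0.6)
  deltas <- sapply(1:12, function(p) {
    trials <- generate_experiment(4, seed = 50 + p)
    fix <- simulate_fixations(trials, gt, seed = 50 + p)
    gd <- guidance_delta(first_fixation_labels(fix), trials)
    mean(gd$delta)
  })
  n_trials <- 12 * 64 # participants x search trials
  se <- 100 * 2 * sqrt(0.6 * 0.4 / n_trials)
  expect_lt(abs(mean(deltas) - 20), 1.96 * se + 1e-9)
})
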