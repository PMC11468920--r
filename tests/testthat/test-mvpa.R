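test_that("linear SVM separates simple geometries with the right sign", {
  m <- train_linear(rbind(c(1, 0), c(-1, 0)), c(1, -1))
  # perpendicular bisector of +/- e1: margin 1, correct sides
  expect_equal(decision_values(m, rbind(c(1, 0), c(-1, 0))), c(1, -1),
               tolerance = 1e-6)
  expect_equal(decision_values(m, c(0, 0)), 0, tolerance = 1e-9)
  expect_error(train_linear(rbind(c(1, 0), c(2, 0)), c(1, 1)),
               "single class")
  expect_error(decision_values(m, c(1, 2, 3)), "dimension mismatch")
})

test_that("duplicating separable training patterns leaves the model unchanged", {
  set.seed(3)
  X <- rbind(matrix(rnorm(10 * 3, mean = 2), 10), matrix(rnorm(10 * 3, -2), 10))
  y <- rep(c(1, -1), each = 10)
  m1 <- train_linear(X, y)
  m2 <- train_linear(rbind(X, X), c(y, y))
  expect_equal(m1$w, m2$w, tolerance = 1e-6)
  expect_equal(m1$b, m2$b, tolerance = 1e-6)
})

test_that("hard-margin solution matches the QP oracle", {
  skip_if_not_installed("kernlab")
  set.seed(11)
  X <- rbind(matrix(rnorm(10 * 5, mean = 1.5), 10),
             matrix(rnorm(10 * 5, mean = -1.5), 10))
  y <- rep(c(1, -1), each = 10)
  m <- train_linear(X, y, cost = 1e6, tolerance = 1e-9)
  d <- decision_values(m, X)
  expect_true(all(sign(d) == y)) # zero training errors
  margin_qp <- svm_margin_qp_oracle(X, y)
  expect_lt(abs(m$margin - margin_qp), 1e-6)
})

test_that("fixed weight vectors give hand-computed distances", {
  m <- structure(list(w = c(3, 4), b = 0, w_norm = 5, margin = 0.2,
                      cost = 1), class = "linear_svm")
  expect_equal(decision_values(m, c(1, 1)), 1.4)
})

test_that("classifier information matches its worked examples and symmetries", {
  expect_equal(classifier_information(c(1, -1), c(1, -1)), 1.0)
  expect_equal(classifier_information(c(2, 0.5, -1, -0.5), c(1, 1, -1, -1)),
               0.8729, tolerance = 1e-4)
  d <- c(2, 0.5, -1, -0.5); l <- c(1, 1, -1, -1)
  # label flip negates; balanced-label shift invariance; positive rescale
  expect_equal(classifier_information(d, -l),
               -classifier_information(d, l))
  expect_equal(classifier_information(d + 7, l),
               classifier_information(d, l), tolerance = 1e-12)
  expect_equal(classifier_information(3.7 * d, l),
               classifier_information(d, l), tolerance = 1e-12)
  expect_equal(classifier_information(c(5, 5, 5, 5), l), 0) # degenerate sd
  expect_error(classifier_information(1, 1), "n >= 2")
  expect_error(classifier_information(d, c(1, 1, -1, 0)), "labels")
})

test_that("accuracy counts correct signs with half-credit ties", {
  expect_equal(accuracy_score(c(2, 0.5, -1, -0.5), c(1, 1, -1, -1)), 1.0)
  expect_equal(accuracy_score(c(2, -0.5, -1, 0.5), c(1, 1, -1, -1)), 0.5)
  expect_equal(accuracy_score(c(0, 1), c(1, 1)), 0.75)
  set.seed(5)
  d <- rnorm(4000)
  l <- sample(c(-1, 1), 4000, replace = TRUE)
  expect_lt(abs(accuracy_score(d, l) - 0.5), 0.03)
})

test_that("decoding schemes recover their own planted codes", {
  map <- make_association_map(0)
  gt_a <- test_gt(anchor_amp = 0.6, target_amp = 0, context_amp = 0.1)
  gt_t <- test_gt(anchor_amp = 0, target_amp = 0.6, context_amp = 0.1)
  ba <- simulate_participant_betas(gt_a, map, n_voxels = 40)
  bt <- simulate_participant_betas(gt_t, map, n_voxels = 40)
  expect_gt(run_scheme(ba, "anchor_loro", map)$info, 0.3)
  expect_gt(run_scheme(bt, "target_loro", map)$info, 0.3)
  # cross-scene sign logic: anchor code positive, target code negative
  expect_gt(run_scheme(ba, "anchor_cross_scene", map)$info, 0.3)
  expect_lt(run_scheme(bt, "anchor_cross_scene", map)$info, -0.3)
  # information grows with amplitude/noise ratio
  weak <- simulate_participant_betas(test_gt(anchor_amp = 0.1,
                                             target_amp = 0,
                                             context_amp = 0),
                                     map, n_voxels = 40)
  expect_gt(run_scheme(ba, "anchor_loro", map)$info,
            run_scheme(weak, "anchor_loro", map)$info)
})

test_that("hemisphere and direction averaging behave as specified", {
  map <- make_association_map(1)
  gt <- test_gt(anchor_amp = 0.5)
  b <- simulate_participant_betas(gt, map, n_voxels = 30)
  res <- run_scheme(b, "anchor_cross_scene", map)
  expect_equal(res$info, mean(res$per_hemisphere$info))
  expect_equal(nrow(res$per_hemisphere), 2L)
  # swapping context roles (relabeling the contexts) keeps the score
  b_swap <- lapply(b, function(x) {
    x$condition_labels$context <- ifelse(
      x$condition_labels$context == "context_A", "context_B", "context_A")
    x
  })
  # identical up to the solver's termination tolerance
  res_swap <- run_scheme(b_swap, "anchor_cross_scene", map)
  expect_equal(res_swap$info, res$info, tolerance = 1e-4)
})

test_that("permuted labels decode at chance on average", {
  map <- make_association_map(0)
  gt <- test_gt(anchor_amp = 0.8, target_amp = 0, context_amp = 0)
  infos <- sapply(1:25, function(r) {
    b <- simulate_participant_betas(gt, map, n_runs = 4, n_voxels = 20,
                                    hemispheres = "left", seed = 300 + r)$left
    # permute condition labels independently within each run
    perm <- b$values
    set.seed(400 + r)
    for (run in 1:4) perm[run, , ] <- perm[run, sample(4), ]
    b$values <- perm
    run_scheme(list(left = b), "anchor_loro", map)$info
  })
  expect_lt(abs(mean(infos)), 3 * sd(infos) / sqrt(length(infos)))
})

test_that("degenerate inputs are rejected", {
  map <- make_association_map(0)
  gt <- test_gt()
  b <- simulate_participant_betas(gt, map, n_voxels = 10)
  empty <- b
  empty$left$values <- b$left$values[, , integer(0), drop = FALSE]
  expect_error(run_scheme(empty["left"], "anchor_loro", map), "empty ROI")
})
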