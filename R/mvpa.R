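## Linear decoding of condition beta patterns. Classification is scored by
## "classifier information": the mean over test patterns of the z-scored
## signed distance to the decision boundary multiplied by the true label, a
## continuous analogue of decoding accuracy (0 at chance, positive when the
## classifier ranks the classes correctly).

DECODING_SCHEMES <- c("target_loro", "anchor_loro", "anchor_cross_scene")

#' Train a linear support-vector classifier
#'
#' Thin wrapper around a linear soft-margin SVM (libsvm via e1071) that
#' extracts the primal weight vector and offset. Training rows are stably
#' reordered so a +1 example comes first, fixing libsvm's internal label
#' order and hence the sign convention of decision values (positive = class
#' +1). No feature scaling is applied.
#'
#' @param train_patterns Pattern x voxel numeric matrix.
#' @param train_labels Vector in `{-1, +1}` (or coercible factor).
#' @param cost Soft-margin regularisation constant C (default 1).
#' @param tolerance libsvm termination tolerance (default 0.001; tighten
#'   for high-precision solutions).
#' @return List of class `linear_svm`: `w` (voxel weights), `b` (offset),
#'   `w_norm`, `margin` (`1/||w||`), `cost`.
#' @export
train_linear <- function(train_patterns, train_labels, cost = 1,
                         tolerance = 0.001) {
  X <- as.matrix(train_patterns)
  y <- as.numeric(as.character(train_labels))
  if (!all(y %in% c(-1, 1))) stopf("labels must be -1 or +1")
  if (length(unique(y)) < 2) stopf("training set contains a single class")
  if (ncol(X) < 1 || nrow(X) != length(y)) {
    stopf("train_patterns must be a pattern x voxel matrix matching labels")
  }
  ord <- order(-y) # stable: +1 rows first
  fit <- e1071::svm(X[ord, , drop = FALSE],
                    factor(y[ord], levels = c(-1, 1)),
                    kernel = "linear", cost = cost, scale = FALSE,
                    tolerance = tolerance)
  w <- drop(crossprod(fit$SV, fit$coefs))
  b <- -fit$rho
  wn <- sqrt(sum(w^2))
  structure(list(w = w, b = b, w_norm = wn, margin = 1 / wn, cost = cost),
            class = "linear_svm")
}

#' Signed distances from the decision boundary
#'
#' Returns `(w . x + b) / ||w||` per test pattern: geometric distance in
#' input-space units, positive on the +1 side.
#'
#' @param model A [train_linear()] model.
#' @param test_patterns Pattern x voxel matrix (voxel dimension must match
#'   training).
#' @return Numeric vector of signed distances.
#' @export
decision_values <- function(model, test_patterns) {
  stopifnot(inherits(model, "linear_svm"))
  X <- test_patterns
  if (is.null(dim(X))) X <- matrix(X, nrow = 1) # single pattern
  X <- as.matrix(X)
  if (ncol(X) != length(model$w)) {
    stopf("voxel dimension mismatch: model has %d, test has %d",
          length(model$w), ncol(X))
  }
  drop(X %*% model$w + model$b) / model$w_norm
}

#' Distance-to-bound classifier information
#'
#' `(1/n) * sum(z(d_i) * l_i)`: distances are z-scored over the n test
#' patterns (mean subtracted, divided by the population standard deviation)
#' and multiplied by their true labels. Zero in expectation at chance;
#' positive when the classifier separates the classes in the labeled
#' direction. If the distances have zero spread the score is defined as 0.
#'
#' @param distances Signed distances `d_i` (length n >= 2).
#' @param labels True labels `l_i` in `{-1, +1}`.
#' @return Scalar information score (dimensionless).
#' @export
classifier_information <- function(distances, labels) {
  d <- as.numeric(distances)
  l <- as.numeric(labels)
  n <- length(d)
  if (n < 2) stopf("classifier_information needs n >= 2 test patterns")
  if (length(l) != n) stopf("labels and distances differ in length")
  if (!all(l %in% c(-1, 1))) stopf("labels must be -1 or +1")
  sd_pop <- sqrt(mean((d - mean(d))^2))
  if (sd_pop == 0) return(0)
  mean(((d - mean(d)) / sd_pop) * l)
}

#' Sign-based decoding accuracy
#'
#' Fraction of test patterns whose distance sign matches the label; exact
#' zeros count 0.5 (unbiased under the null).
#'
#' @inheritParams classifier_information
#' @return Fraction in `[0, 1]`.
#' @export
accuracy_score <- function(distances, labels) {
  d <- as.numeric(distances)
  l <- as.numeric(labels)
  if (length(d) != length(l)) stopf("labels and distances differ in length")
  if (!all(l %in% c(-1, 1))) stopf("labels must be -1 or +1")
  mean(ifelse(d == 0, 0.5, (sign(d) == l) * 1))
}

## Scheme label functions: map the 4 (target, context) conditions to +/-1.
scheme_labels <- function(scheme, conds, map) {
  switch(scheme,
         target_loro = ifelse(conds$target == "target_1", -1, 1),
         anchor_loro = ,
         anchor_cross_scene = ifelse(
           anchor_for(map, conds$context, conds$target) == "anchor_1", -1, 1),
         stopf("unknown decoding scheme '%s'", scheme))
}

## Core decoder on one (run x condition x voxel) array. Returns info and
## accuracy for one hemisphere.
scheme_core <- function(values, conds, map, scheme, cost = 1,
                        per_fold_z = FALSE) {
  n_runs <- dim(values)[1]
  n_cond <- dim(values)[2]
  n_vox <- dim(values)[3]
  if (is.na(n_vox) || n_vox < 1) stopf("empty ROI: no voxels to decode")
  pat <- matrix(aperm(values, c(2, 1, 3)), n_runs * n_cond, n_vox)
  row_run <- rep(seq_len(n_runs), each = n_cond)
  row_cond <- rep(seq_len(n_cond), n_runs)
  labels <- scheme_labels(scheme, conds, map)[row_cond]
  if (scheme %in% c("target_loro", "anchor_loro")) {
    if (n_runs < 2) stopf("leave-one-run-out needs >= 2 runs")
    d <- numeric(nrow(pat))
    info_parts <- numeric(0)
    for (r in seq_len(n_runs)) {
      tr_i <- row_run != r
      te_i <- !tr_i
      if (length(unique(labels[tr_i])) < 2) {
        warnf("fold %d skipped: single-class training set", r)
        d[te_i] <- NA
        next
      }
      m <- train_linear(pat[tr_i, , drop = FALSE], labels[tr_i], cost = cost)
      d[te_i] <- decision_values(m, pat[te_i, , drop = FALSE])
      if (per_fold_z) {
        info_parts <- c(info_parts,
                        classifier_information(d[te_i], labels[te_i]))
      }
    }
    ok <- !is.na(d)
    info <- if (per_fold_z) mean(info_parts) else
      classifier_information(d[ok], labels[ok])
    acc <- accuracy_score(d[ok], labels[ok])
  } else { # anchor_cross_scene
    ctx <- conds$context[row_cond]
    if (length(unique(ctx)) < 2) stopf("cross-scene needs both contexts")
    one_dir <- function(train_ctx, test_ctx) {
      tr_i <- ctx == train_ctx
      te_i <- ctx == test_ctx
      m <- train_linear(pat[tr_i, , drop = FALSE], labels[tr_i], cost = cost)
      d <- decision_values(m, pat[te_i, , drop = FALSE])
      c(info = classifier_information(d, labels[te_i]),
        acc = accuracy_score(d, labels[te_i]))
    }
    ab <- one_dir("context_A", "context_B")
    ba <- one_dir("context_B", "context_A")
    info <- mean(c(ab["info"], ba["info"])) # directions averaged
    acc <- mean(c(ab["acc"], ba["acc"]))
  }
  c(info = unname(info), accuracy = unname(acc))
}

#' Run a decoding scheme on per-hemisphere beta patterns
#'
#' Supported schemes: `target_loro` (decode target category,
#' leave-one-run-out), `anchor_loro` (decode the associated anchor,
#' leave-one-run-out) and `anchor_cross_scene` (train on one scene
#' context's patterns labeled by associated anchor, test on the other, both
#' directions averaged). Under the reversed associations, a positive
#' cross-scene score indicates an anchor code generalising across contexts;
#' a negative score indicates a target code.
#'
#' Leave-one-run-out pools test distances across folds and computes the
#' information score once on the pooled set per hemisphere (per-fold
#' z-scoring available via `per_fold_z`); hemispheres are decoded
#' separately and their scores averaged.
#'
#' @param betas Named list of `beta_patterns` (one per hemisphere), as from
#'   [simulate_participant_betas()].
#' @param scheme One of the scheme names above.
#' @param map The participant's [make_association_map()].
#' @param cost SVM regularisation constant.
#' @param per_fold_z Z-score distances within fold instead of pooled.
#' @return List of class `decoding_result`: `scheme`, `info`, `accuracy`
#'   (hemisphere averages), `per_hemisphere` data frame, `roi_name`,
#'   `roi_size`.
#' @export
run_scheme <- function(betas, scheme = DECODING_SCHEMES, map, cost = 1,
                       per_fold_z = FALSE) {
  scheme <- match.arg(scheme)
  if (inherits(betas, "beta_patterns")) betas <- list(betas)
  stopifnot(length(betas) >= 1, inherits(map, "association_map"))
  per_h <- lapply(betas, function(b) {
    stopifnot(inherits(b, "beta_patterns"))
    if (dim(b$values)[3] < 1) stopf("empty ROI '%s'", b$roi_name)
    scheme_core(b$values, b$condition_labels, map, scheme, cost, per_fold_z)
  })
  ph <- data.frame(hemisphere = vapply(betas, `[[`, "", "hemisphere"),
                   info = vapply(per_h, `[[`, 0, "info"),
                   accuracy = vapply(per_h, `[[`, 0, "accuracy"),
                   row.names = NULL)
  structure(list(scheme = scheme, info = mean(ph$info),
                 accuracy = mean(ph$accuracy), per_hemisphere = ph,
                 roi_name = betas[[1]]$roi_name,
                 roi_size = dim(betas[[1]]$values)[3]),
            class = "decoding_result")
}
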