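## Run-wise GLM estimation: boxcar regressors convolved with the canonical
## double-gamma HRF at a microtime resolution of tr/16, sampled at scan
## acquisition times, estimated by ordinary least squares.

#' Canonical HRF parameters
#'
#' Double-gamma parameterisation: the response is the difference of two
#' gamma densities (peak minus undershoot), the undershoot scaled by
#' `1/peak_undershoot_ratio`. Defaults are the widely used canonical values
#' (peak delay 6 s, undershoot delay 16 s, unit dispersions, ratio 6,
#' 32 s kernel).
#'
#' @param tr Repetition time in seconds.
#' @param peak_delay,undershoot_delay Delays (s).
#' @param peak_dispersion,undershoot_dispersion Dispersions (s).
#' @param peak_undershoot_ratio Peak:undershoot amplitude ratio.
#' @param kernel_length Kernel support (s).
#' @return A list of class `hrf_params`.
#' @export
hrf_params <- function(tr = 1.5, peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       peak_undershoot_ratio = 6, kernel_length = 32) {
  p <- list(tr = tr, peak_delay = peak_delay,
            undershoot_delay = undershoot_delay,
            peak_dispersion = peak_dispersion,
            undershoot_dispersion = undershoot_dispersion,
            peak_undershoot_ratio = peak_undershoot_ratio,
            kernel_length = kernel_length)
  if (any(unlist(p) <= 0)) stopf("all HRF parameters must be positive")
  if (p$kernel_length < p$peak_delay) {
    stopf("kernel_length must be >= peak_delay")
  }
  class(p) <- "hrf_params"
  p
}

#' Sample the canonical double-gamma HRF
#'
#' Evaluates the kernel on a grid of resolution `tr/16` over
#' `[0, kernel_length]` and normalises it to unit peak. Gamma shapes are
#' `delay/dispersion` with rate `1/dispersion`, so the peak-gamma mode sits
#' near `peak_delay - peak_dispersion` (about 5 s with defaults).
#'
#' @param params An [hrf_params()] object.
#' @return Numeric vector with attribute `times` (seconds).
#' @export
canonical_hrf <- function(params = hrf_params()) {
  stopifnot(inherits(params, "hrf_params"))
  dt <- params$tr / 16
  t <- seq(0, params$kernel_length, by = dt)
  h <- stats::dgamma(t, shape = params$peak_delay / params$peak_dispersion,
                     rate = 1 / params$peak_dispersion) -
    stats::dgamma(t, shape = params$undershoot_delay /
                    params$undershoot_dispersion,
                  rate = 1 / params$undershoot_dispersion) /
    params$peak_undershoot_ratio
  h <- h / max(h)
  attr(h, "times") <- t
  h
}

#' Build a run's design matrix
#'
#' Four regressors of interest -- the (target x context) combinations,
#' modeled from preview-only trials only, as boxcars spanning preview onset
#' to offset convolved with the canonical HRF and sampled at scan times --
#' plus six motion regressors (zeros if none supplied) and a constant.
#' Overlapping boxcars within one condition are summed. Conditions with no
#' preview-only trial in the run yield an all-zero column, flagged in
#' `empty_interest`.
#'
#' @param trials Trial table rows for one run.
#' @param tr Repetition time (s).
#' @param n_scans Number of scans (> 0).
#' @param hrf [hrf_params()] object.
#' @param motion Optional n_scans x 6 motion parameter matrix.
#' @return List of class `design_matrix`: `values` (n_scans x regressors),
#'   `column_names`, `interest_columns`, `nuisance_columns`,
#'   `empty_interest` (names of all-zero interest columns).
#' @export
build_design_matrix <- function(trials, tr = 1.5, n_scans = 198,
                                hrf = hrf_params(tr = tr), motion = NULL) {
  if (!is_count(n_scans)) stopf("n_scans must be a positive integer")
  conds <- condition_table()
  prev <- trials[trials$trial_type == "preview_only", , drop = FALSE]
  if (nrow(prev) > 0 && max(prev$preview_onset) > n_scans * tr) {
    stopf("trial onsets fall outside the scan window")
  }
  dt <- tr / 16
  n_fine <- n_scans * 16L
  kern <- canonical_hrf(hrf)
  scan_idx <- 1L + (seq_len(n_scans) - 1L) * 16L # acquisition times (0, tr, ...)
  interest <- matrix(0, n_scans, nrow(conds))
  colnames(interest) <- paste(conds$target, conds$context, sep = ".")
  for (ci in seq_len(nrow(conds))) {
    rows <- prev$target == conds$target[ci] & prev$context == conds$context[ci]
    box <- numeric(n_fine)
    if (any(rows)) {
      t_fine <- (seq_len(n_fine) - 1L) * dt
      on <- prev$preview_onset[rows]
      off <- prev$preview_offset[rows]
      for (k in seq_along(on)) {
        # half-open [on, off): boxcar area tracks the true duration
        box <- box + (t_fine >= on[k] & t_fine < off[k]) # overlaps sum
      }
    }
    conv <- stats::convolve(box, rev(kern), type = "open")[seq_len(n_fine)]
    interest[, ci] <- conv[scan_idx] * dt # dt-scaled: invariant to microtime
  }
  if (is.null(motion)) {
    motion <- matrix(0, n_scans, 6)
  } else {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_scans || ncol(motion) != 6) {
      stopf("motion must be an n_scans x 6 matrix")
    }
  }
  colnames(motion) <- paste0("motion_", 1:6)
  X <- cbind(interest, motion, constant = 1)
  structure(list(values = X, column_names = colnames(X),
                 interest_columns = seq_len(nrow(conds)),
                 nuisance_columns = nrow(conds) + seq_len(7L),
                 empty_interest = colnames(interest)[colSums(abs(interest)) == 0],
                 tr = tr),
            class = "design_matrix")
}

#' Ordinary least-squares GLM fit
#'
#' @param Y n_scans x voxel data matrix.
#' @param X A [build_design_matrix()] object (or plain matrix).
#' @return List: `betas` (regressor x voxel), `residuals`, `df` (residual
#'   degrees of freedom, `n_scans - rank(X)`), `column_names`.
#' @export
fit_ols <- function(Y, X) {
  Xm <- if (inherits(X, "design_matrix")) X$values else as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(Xm)) stopf("Y and design have different scan counts")
  qrX <- qr(Xm)
  rank <- qrX$rank
  if (inherits(X, "design_matrix") && rank < ncol(Xm)) {
    ## identify which columns are linearly dependent
    dep <- qrX$pivot[-seq_len(rank)]
    bad <- intersect(dep, X$interest_columns)
    if (length(bad)) {
      stopf("confounded interest regressors: %s",
            paste(X$column_names[bad], collapse = ", "))
    }
    ## all-zero columns (e.g. placeholder motion regressors) drop silently
    dep_nz <- dep[colSums(abs(Xm[, dep, drop = FALSE])) > 0]
    if (length(dep_nz)) {
      warnf("rank-deficient nuisance columns dropped: %s",
            paste(X$column_names[dep_nz], collapse = ", "))
    }
  }
  betas <- qr.coef(qrX, Y)
  betas[is.na(betas)] <- 0
  res <- Y - Xm %*% betas
  cn <- if (inherits(X, "design_matrix")) X$column_names else colnames(Xm)
  rownames(betas) <- cn
  list(betas = betas, residuals = res, df = nrow(Y) - rank,
       column_names = cn)
}

#' One-way F contrast over run-wise condition betas
#'
#' Treats run betas as replicates and computes, per voxel, a one-way ANOVA
#' F statistic across the supplied condition groups, with degrees of
#' freedom `(k - 1, N - k)` where `N` is the total number of replicate
#' values and `k` the number of groups. Voxels with zero within-group
#' variance but distinct group means report `F = Inf`, `p = 0`.
#'
#' @param run_betas Array (run x condition x voxel) or matrix
#'   (replicate x voxel) with a `groups` assignment per row.
#' @param groups List of condition index vectors (>= 2 groups), e.g.
#'   `list(target_1 = c(1, 3), target_2 = c(2, 4))`; for a matrix input, a
#'   vector of group labels per row.
#' @return List: `F`, `p` (per voxel), `df` (length-2 vector).
#' @export
f_contrast <- function(run_betas, groups) {
  if (is.array(run_betas) && length(dim(run_betas)) == 3) {
    stopifnot(is.list(groups), length(groups) >= 2)
    n_runs <- dim(run_betas)[1]
    if (n_runs < 2) stopf("f_contrast needs >= 2 runs")
    mats <- lapply(groups, function(g) {
      m <- run_betas[, g, , drop = FALSE]
      matrix(m, nrow = n_runs * length(g),
             ncol = dim(run_betas)[3]) # replicates x voxel
    })
    values <- do.call(rbind, mats)
    lab <- rep(seq_along(groups), vapply(mats, nrow, 1L))
  } else {
    values <- as.matrix(run_betas)
    lab <- as.integer(factor(groups))
    if (length(lab) != nrow(values)) stopf("groups must label every row")
    if (length(unique(lab)) < 2) stopf("need >= 2 condition groups")
  }
  k <- length(unique(lab))
  N <- nrow(values)
  n_g <- tabulate(lab, k)
  gmeans <- rowsum(values, lab) / n_g
  grand <- colMeans(values)
  ss_b <- colSums(n_g * (gmeans - rep(grand, each = k))^2)
  ss_w <- colSums((values - gmeans[lab, , drop = FALSE])^2)
  df <- c(k - 1, N - k)
  Fv <- (ss_b / df[1]) / (ss_w / df[2])
  Fv[ss_w == 0 & ss_b > 0] <- Inf
  Fv[ss_w == 0 & ss_b == 0] <- 0
  p <- stats::pf(Fv, df[1], df[2], lower.tail = FALSE)
  p[is.infinite(Fv)] <- 0
  list(F = Fv, p = p, df = df)
}
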