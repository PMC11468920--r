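## Eye-movement and behavioral analysis: rectangular AOI classification of
## fixations, the first-fixation guidance statistic (percentage-point
## advantage of the associated anchor over the other anchor), d' from
## present/absent reports, and the guidance-performance correlation.

#' Rectangular areas of interest for fixation analysis
#'
#' Coordinates are degrees of visual angle, origin at fixation, x positive
#' rightward, y positive upward. Defaults: a 4.5 x 10.5 degree center AOI at
#' the origin, and 7.5 x 10.5 degree anchor AOIs centered at x = -7.5 and
#' +7.5, slightly below fixation.
#'
#' @param center_xy,center_wh Center AOI center and (width, height).
#' @param anchor_offset_x Horizontal distance of each anchor AOI center.
#' @param anchor_y Vertical position of the anchor AOI centers.
#' @param anchor_wh Anchor AOI (width, height).
#' @return List of class `aoi_set` with `center`, `left_anchor`,
#'   `right_anchor` rectangles (`cx, cy, w, h`).
#' @export
aoi_set <- function(center_xy = c(0, 0), center_wh = c(4.5, 10.5),
                    anchor_offset_x = 7.5, anchor_y = -1.5,
                    anchor_wh = c(7.5, 10.5)) {
  rect <- function(cx, cy, wh) list(cx = cx, cy = cy, w = wh[1], h = wh[2])
  aois <- structure(list(
    center = rect(center_xy[1], center_xy[2], center_wh),
    left_anchor = rect(-anchor_offset_x, anchor_y, anchor_wh),
    right_anchor = rect(anchor_offset_x, anchor_y, anchor_wh)),
    class = "aoi_set")
  if (aois$left_anchor$cx + aois$left_anchor$w / 2 >
      aois$right_anchor$cx - aois$right_anchor$w / 2) {
    stopf("anchor AOIs must not overlap")
  }
  aois
}

in_rect <- function(x, y, r) {
  x >= r$cx - r$w / 2 & x <= r$cx + r$w / 2 &
    y >= r$cy - r$h / 2 & y <= r$cy + r$h / 2
}

#' Classify fixation positions into AOIs
#'
#' Point-in-rectangle test with inclusive boundaries; a point inside both
#' the center and an anchor rectangle takes the anchor label (anchors have
#' precedence).
#'
#' @param x,y Fixation coordinates (degrees, vectorised).
#' @param aois An [aoi_set()].
#' @return Character vector in `{"center", "left_anchor", "right_anchor",
#'   "none"}`.
#' @export
classify_fixation <- function(x, y, aois = aoi_set()) {
  stopifnot(inherits(aois, "aoi_set"), all(is.finite(x)), all(is.finite(y)))
  lab <- rep("none", length(x))
  lab[in_rect(x, y, aois$center)] <- "center"
  lab[in_rect(x, y, aois$left_anchor)] <- "left_anchor"
  lab[in_rect(x, y, aois$right_anchor)] <- "right_anchor"
  lab
}

#' First-fixation AOI label per trial
#'
#' A trial is included iff some fixation overlaps scene onset (onset <=
#' tolerance and offset > 0) and lies in the center AOI; its label is then
#' the AOI of the first fixation starting after scene onset. Trials with no
#' recorded fixation, an off-center onset fixation, or no subsequent
#' fixation are `"excluded"`.
#'
#' @param fixations Data frame with columns `run`, `trial_index`, `x_deg`,
#'   `y_deg`, `onset_ms`, `duration_ms` (onsets relative to scene onset),
#'   sorted by onset within trial.
#' @param aois An [aoi_set()].
#' @param onset_tolerance_ms Slack allowed for the onset fixation's start.
#' @return Data frame (`run`, `trial_index`, `label`), one row per trial
#'   present in `fixations`.
#' @export
first_fixation_labels <- function(fixations, aois = aoi_set(),
                                  onset_tolerance_ms = 0) {
  key <- paste(fixations$run, fixations$trial_index, sep = "_")
  lab <- vapply(split(seq_len(nrow(fixations)), key), function(ix) {
    f <- fixations[ix, , drop = FALSE]
    at_onset <- f$onset_ms <= onset_tolerance_ms &
      f$onset_ms + f$duration_ms > 0
    if (!any(at_onset)) return("excluded")
    f0 <- f[which(at_onset)[1], ]
    if (classify_fixation(f0$x_deg, f0$y_deg, aois) != "center") {
      return("excluded")
    }
    after <- f$onset_ms > 0
    if (!any(after)) return("excluded")
    f1 <- f[which(after)[1], ]
    classify_fixation(f1$x_deg, f1$y_deg, aois)
  }, character(1))
  first <- !duplicated(key)
  out <- data.frame(run = fixations$run[first],
                    trial_index = fixations$trial_index[first])
  out$label <- unname(lab[key[first]])
  out
}

#' First-fixation guidance delta
#'
#' Percentage-point difference between first fixations on the associated
#' anchor and on the nonassociated anchor, relative to all included trials,
#' split by target presence:
#' `delta = 100 * (n_associated - n_other) / n_included`.
#'
#' @param labels Output of [first_fixation_labels()].
#' @param trials Trial table (search trials are matched by run and
#'   trial_index; `anchor_side` gives the associated anchor's side).
#' @return Data frame with columns `target_present`, `delta`, `n_included`;
#'   conditions with zero included trials get `NA` with a warning.
#' @export
guidance_delta <- function(labels, trials) {
  m <- merge(labels, trials[, c("run", "trial_index", "trial_type",
                                "present", "anchor_side")],
             by = c("run", "trial_index"))
  m <- m[m$trial_type == "search", , drop = FALSE]
  res <- lapply(c(TRUE, FALSE), function(p) {
    mm <- m[m$present == p & m$label != "excluded", , drop = FALSE]
    n <- nrow(mm)
    if (n == 0) {
      warnf("no included trials for target_present = %s", p)
      return(data.frame(target_present = p, delta = NA_real_,
                        n_included = 0L))
    }
    assoc <- ifelse(mm$anchor_side == "left", "left_anchor", "right_anchor")
    other <- ifelse(mm$anchor_side == "left", "right_anchor", "left_anchor")
    data.frame(target_present = p,
               delta = 100 * (sum(mm$label == assoc) -
                                sum(mm$label == other)) / n,
               n_included = n)
  })
  do.call(rbind, res)
}

#' Signal-detection sensitivity d'
#'
#' `d' = qnorm(hit_rate) - qnorm(fa_rate)`, with extreme rates (0 or 1)
#' corrected by the 1/(2N) rule before the transform.
#'
#' @param n_hits,n_target_present Hits and target-present trial count.
#' @param n_fa,n_target_absent False alarms and target-absent trial count.
#' @return d' (finite by construction).
#' @export
dprime <- function(n_hits, n_target_present, n_fa, n_target_absent) {
  stopifnot(n_target_present > 0, n_target_absent > 0)
  correct_rate <- function(k, n) {
    r <- k / n
    r[r == 0] <- 1 / (2 * n)
    r[r == 1] <- 1 - 1 / (2 * n)
    r
  }
  h <- correct_rate(n_hits, n_target_present)
  f <- correct_rate(n_fa, n_target_absent)
  stats::qnorm(h) - stats::qnorm(f)
}

#' Per-participant behavioral summary from responses
#'
#' @param responses Data frame with `run`, `trial_index`, `reported_present`.
#' @param trials Trial table (search trials with `present`).
#' @return List with `hit_rate`, `fa_rate`, `dprime`, `accuracy`, counts.
#' @export
behavioral_summary <- function(responses, trials) {
  m <- merge(responses, trials[, c("run", "trial_index", "present")],
             by = c("run", "trial_index"))
  np <- sum(m$present)
  na_ <- sum(!m$present)
  hits <- sum(m$present & m$reported_present)
  fas <- sum(!m$present & m$reported_present)
  list(hit_rate = hits / np, fa_rate = fas / na_,
       dprime = dprime(hits, np, fas, na_),
       accuracy = mean(m$reported_present == m$present),
       n_present = np, n_absent = na_)
}

#' Correlation between guidance and search sensitivity
#'
#' Pearson correlation of first-fixation guidance deltas with d' across
#' participants, separately for guidance measured on target-present and
#' target-absent trials.
#'
#' @param summaries Data frame with per-participant columns `dprime`,
#'   `delta_present`, `delta_absent`.
#' @return Data frame with columns `condition`, `r`, `p`, `n`.
#' @export
guidance_performance_correlation <- function(summaries) {
  rows <- lapply(c(present = "delta_present", absent = "delta_absent"),
                 function(col) {
                   ok <- is.finite(summaries[[col]]) &
                     is.finite(summaries$dprime)
                   if (sum(ok) < 3) stopf("need >= 3 participants with defined values")
                   pearson_correlation(summaries[[col]][ok],
                                       summaries$dprime[ok])
                 })
  data.frame(condition = names(rows),
             r = vapply(rows, `[[`, 0, "r"),
             p = vapply(rows, `[[`, 0, "p"),
             n = vapply(rows, `[[`, 0L, "n"), row.names = NULL)
}

#' Paired bootstrap test of a condition difference
#'
#' Bootstrap test on paired per-participant differences (e.g. guidance on
#' target-present minus target-absent trials).
#'
#' @param deltas_a,deltas_b Paired per-participant values.
#' @inheritParams bootstrap_test
#' @return A `group_stat` for the mean difference.
#' @export
condition_difference_test <- function(deltas_a, deltas_b, n_boot = 10000,
                                      seed = 1L) {
  if (length(deltas_a) != length(deltas_b)) {
    stopf("conditions must be paired per participant")
  }
  bootstrap_test(deltas_a - deltas_b, n_boot = n_boot, seed = seed)
}
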