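## Synthetic eye-movement and response generator. Search trials get an
## onset fixation in the center AOI (with dropout), then an anchor-directed
## first fixation that lands on the associated anchor with the participant's
## guidance probability; present/absent reports follow an equal-variance
## signal-detection model with criterion 0 and d' tied to guidance.

runif_rect <- function(n, r, shrink = 0.8) {
  data.frame(x = runif(n, r$cx - shrink * r$w / 2, r$cx + shrink * r$w / 2),
             y = runif(n, r$cy - shrink * r$h / 2, r$cy + shrink * r$h / 2))
}

#' Simulate fixation sequences for the search trials
#'
#' Per search trial: with probability `gt$p_fix_recorded` at least one
#' fixation is recorded; the scene-onset fixation lies in the center AOI
#' with probability `gt$p_center_onset` (otherwise offset, so the trial is
#' later excluded); with probability `gt$anchor_fix_prob` the next fixation
#' is anchor-directed and lands on the associated anchor with the guidance
#' probability of the trial's condition (else on the other anchor), with
#' latency drawn from a truncated normal; otherwise the gaze stays central.
#'
#' @param trials Trial table from [generate_experiment()].
#' @param gt A [ground_truth()].
#' @param aois An [aoi_set()].
#' @param guidance_probs Named vector `c(present = , absent = )` of the
#'   participant's guidance probabilities; defaults to the population
#'   values in `gt`.
#' @param seed Integer seed.
#' @return Data frame of fixations: `run`, `trial_index`, `ordinal` (from
#'   0), `x_deg`, `y_deg`, `onset_ms` (from scene onset), `duration_ms`.
#' @export
simulate_fixations <- function(trials, gt, aois = aoi_set(),
                               guidance_probs = c(
                                 present = gt$guidance_prob_present,
                                 absent = gt$guidance_prob_absent),
                               seed = gt$seed) {
  stopifnot(inherits(gt, "ground_truth"), inherits(aois, "aoi_set"))
  s <- trials[trials$trial_type == "search", , drop = FALSE]
  n <- nrow(s)
  with_seed(derive_seed(seed, 3000L), {
    recorded <- runif(n) < gt$p_fix_recorded
    centered <- runif(n) < gt$p_center_onset
    anchor_dir <- runif(n) < gt$anchor_fix_prob
    q <- ifelse(s$present, guidance_probs[["present"]],
                guidance_probs[["absent"]])
    on_assoc <- runif(n) < q
    latency <- pmax(1, rnorm(n, gt$latency_mean_ms, gt$latency_sd_ms))
    ## onset fixation: center AOI or offset (beyond its right edge)
    p0 <- runif_rect(n, aois$center)
    off <- !centered
    p0$x[off] <- aois$center$cx + aois$center$w / 2 + 0.5 + runif(sum(off))
    ## first post-onset fixation
    side <- ifelse(anchor_dir,
                   ifelse(on_assoc == (s$anchor_side == "left"),
                          "left", "right"),
                   "center")
    p1 <- runif_rect(n, aois$center)
    for (sd_ in c("left", "right")) {
      i <- side == sd_
      p1[i, ] <- runif_rect(sum(i), aois[[paste0(sd_, "_anchor")]])
    }
    fix0 <- data.frame(run = s$run, trial_index = s$trial_index,
                       ordinal = 0L, x_deg = p0$x, y_deg = p0$y,
                       onset_ms = -200, duration_ms = 200 + latency)
    fix1 <- data.frame(run = s$run, trial_index = s$trial_index,
                       ordinal = 1L, x_deg = p1$x, y_deg = p1$y,
                       onset_ms = latency,
                       duration_ms = 180 + 40 * runif(n))
    out <- rbind(fix0[recorded, ], fix1[recorded, ])
    out <- out[order(out$run, out$trial_index, out$onset_ms), ]
    rownames(out) <- NULL
    out
  })
}

#' Simulate present/absent responses under a signal-detection model
#'
#' The participant's sensitivity is
#' `d' = dprime_mean + dprime_slope * (guidance - mean_guidance) + noise`
#' with criterion 0, so hits occur with probability `pnorm(d'/2)` on
#' target-present search trials and false alarms with `pnorm(-d'/2)` on
#' target-absent ones.
#'
#' @param trials Trial table.
#' @param gt A [ground_truth()].
#' @param participant_guidance The participant's guidance delta
#'   (percentage points, target-absent trials).
#' @param mean_guidance Population mean guidance delta used for centering;
#'   defaults to the value implied by `gt`.
#' @param seed Integer seed.
#' @return List: `responses` (data frame `run`, `trial_index`,
#'   `reported_present`, `correct`) and `dprime_true`.
#' @export
simulate_responses <- function(trials, gt, participant_guidance,
                               mean_guidance = 100 * gt$anchor_fix_prob *
                                 (2 * gt$guidance_prob_absent - 1),
                               seed = gt$seed) {
  stopifnot(inherits(gt, "ground_truth"))
  s <- trials[trials$trial_type == "search", , drop = FALSE]
  with_seed(derive_seed(seed, 4000L), {
    dp <- gt$dprime_mean +
      gt$dprime_slope * (participant_guidance - mean_guidance) +
      rnorm(1, 0, gt$dprime_noise_sd)
    p_yes <- ifelse(s$present, stats::pnorm(dp / 2), stats::pnorm(-dp / 2))
    rep_p <- runif(nrow(s)) < p_yes
    list(responses = data.frame(run = s$run, trial_index = s$trial_index,
                                reported_present = rep_p,
                                correct = rep_p == s$present),
         dprime_true = dp)
  })
}

#' Simulate one participant's gaze and responses with latent traits
#'
#' Draws the participant's guidance probabilities around the population
#' values (shared normal deviation with SD `gt$guidance_sd`, clamped to
#' [0, 1]), simulates fixations and responses, and returns the latent
#' ground truth for recovery tests.
#'
#' @param trials Trial table.
#' @param gt A [ground_truth()].
#' @param aois An [aoi_set()].
#' @param seed Integer participant seed.
#' @return List: `fixations`, `responses`, `latent` (guidance
#'   probabilities, latent delta, true d').
#' @export
simulate_participant_behavior <- function(trials, gt, aois = aoi_set(),
                                          seed = gt$seed) {
  u <- with_seed(derive_seed(seed, 5000L), rnorm(1, 0, gt$guidance_sd))
  clamp <- function(p) pmin(1, pmax(0, p))
  qp <- clamp(gt$guidance_prob_present + u)
  qa <- clamp(gt$guidance_prob_absent + u)
  delta_latent <- 100 * gt$anchor_fix_prob * (2 * qa - 1)
  fix <- simulate_fixations(trials, gt, aois,
                            guidance_probs = c(present = qp, absent = qa),
                            seed = seed)
  resp <- simulate_responses(trials, gt, delta_latent, seed = seed)
  list(fixations = fix, responses = resp$responses,
       latent = list(guidance_prob_present = qp, guidance_prob_absent = qa,
                     delta_latent = delta_latent,
                     dprime = resp$dprime_true))
}
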