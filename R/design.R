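## Factorial design of the context-guided search experiment: two target
## categories (book, bowl) are each associated with one of two anchor tables,
## and the pairing reverses between the two scene contexts (blue vs yellow
## living room). Every run fully crosses five binary factors.

TARGETS <- c("target_1", "target_2")
CONTEXTS <- c("context_A", "context_B")
ANCHORS <- c("anchor_1", "anchor_2")

#' Build a target-anchor association map
#'
#' Constructs the context-dependent mapping from (scene context, target
#' category) to the associated anchor object. Within each context the two
#' targets map to distinct anchors, and the mapping in one context is the
#' anchor-swap of the mapping in the other (association reversal). Four
#' counterbalance variants exist: two possible pairings in the reference
#' context, crossed with which scene context plays the reference role.
#'
#' @param counterbalance_id Integer in `0:3`. Bit 0 selects the pairing in
#'   the reference context (`0`: target_1 with anchor_1); bit 1 selects which
#'   scene context is the reference ("context A") role.
#' @return An object of class `association_map` with elements `mapping` (a
#'   2x2 character matrix, rows = contexts, columns = targets, entries =
#'   anchors), `context_a` (which context holds the reference pairing) and
#'   `counterbalance_id`.
#' @examples
#' m <- make_association_map(0)
#' anchor_for(m, "context_A", "target_1")
#' @export
make_association_map <- function(counterbalance_id) {
  if (!is_count(counterbalance_id, min = 0L) || counterbalance_id > 3) {
    stopf("counterbalance_id must be an integer in 0:3, got %s",
          deparse(substitute(counterbalance_id)))
  }
  id <- as.integer(counterbalance_id)
  swap <- id %% 2L == 1L
  context_a <- CONTEXTS[(id %/% 2L) + 1L]
  base <- if (swap) c("anchor_2", "anchor_1") else c("anchor_1", "anchor_2")
  mapping <- matrix(NA_character_, 2, 2,
                    dimnames = list(context = CONTEXTS, target = TARGETS))
  mapping[context_a, ] <- base
  mapping[setdiff(CONTEXTS, context_a), ] <- rev(base)
  structure(list(mapping = mapping, context_a = context_a,
                 counterbalance_id = id),
            class = "association_map")
}

#' Look up the associated anchor
#'
#' @param map An `association_map`.
#' @param context,target Character vectors of scene contexts and target
#'   categories (recycled to common length).
#' @return Character vector of anchor labels.
#' @export
anchor_for <- function(map, context, target) {
  stopifnot(inherits(map, "association_map"))
  n <- max(length(context), length(target))
  context <- rep_len(as.character(context), n)
  target <- rep_len(as.character(target), n)
  if (!all(context %in% CONTEXTS)) stopf("unknown scene context")
  if (!all(target %in% TARGETS)) stopf("unknown target category")
  map$mapping[cbind(context, target)]
}

#' Default trial timing parameters
#'
#' Cue duration is 1 s; the scene preview is jittered uniformly between
#' `preview_min` and `preview_max` on search trials and lasts a fixed
#' `preview_only_duration` on preview-only trials; the brief search display
#' (search trials only) lasts `scene_duration`; the inter-trial interval is
#' uniform on `[iti_min, iti_max]` (response and feedback fall inside it).
#' All values in seconds.
#'
#' @param cue_duration,preview_min,preview_max,preview_only_duration
#'   Cue and preview epochs.
#' @param scene_duration Search display duration.
#' @param iti_min,iti_max Inter-trial interval bounds.
#' @return A list of timing parameters.
#' @export
timing_params <- function(cue_duration = 1, preview_min = 3.1,
                          preview_max = 4.0, preview_only_duration = 4.4,
                          scene_duration = 0.4, iti_min = 2, iti_max = 4) {
  p <- list(cue_duration = cue_duration, preview_min = preview_min,
            preview_max = preview_max,
            preview_only_duration = preview_only_duration,
            scene_duration = scene_duration,
            iti_min = iti_min, iti_max = iti_max)
  if (any(vapply(p, function(x) !is.numeric(x) || length(x) != 1 || x < 0,
                 logical(1)))) {
    stopf("all timing parameters must be non-negative scalars")
  }
  if (p$preview_max < p$preview_min || p$iti_max < p$iti_min) {
    stopf("interval upper bounds must be >= lower bounds")
  }
  p
}

#' Generate one fully counterbalanced run of 32 trials
#'
#' Each run contains every combination of the five binary factors (trial
#' type, target presence, target category, scene context, associated-anchor
#' side) exactly once, in a seeded random order, with onsets laid out
#' sequentially from the timing parameters.
#'
#' @param run_index 1-based run number.
#' @param timing Output of [timing_params()].
#' @param seed Integer seed controlling trial order and jitter.
#' @return A data frame of 32 trials with columns `run`, `trial_index`
#'   (1-based), `trial_type`, `target`, `context`, `present`, `anchor_side`,
#'   `cue_onset`, `preview_onset`, `preview_offset` (seconds from run start).
#' @export
generate_run <- function(run_index, timing = timing_params(), seed = 1L) {
  stopifnot(is_count(run_index))
  cells <- expand.grid(trial_type = c("search", "preview_only"),
                       target = TARGETS, context = CONTEXTS,
                       present = c(TRUE, FALSE),
                       anchor_side = c("left", "right"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(cells) # 32
  with_seed(seed, {
    ord <- sample.int(n)
    trials <- cells[ord, , drop = FALSE]
    rownames(trials) <- NULL
    preview_dur <- ifelse(
      trials$trial_type == "preview_only",
      timing$preview_only_duration,
      runif(n, timing$preview_min, timing$preview_max))
    iti <- runif(n, timing$iti_min, timing$iti_max)
    post <- ifelse(trials$trial_type == "search", timing$scene_duration, 0)
    trial_len <- timing$cue_duration + preview_dur + post + iti
    cue_onset <- cumsum(c(0, trial_len[-n]))
    data.frame(run = run_index, trial_index = seq_len(n),
               trials,
               cue_onset = cue_onset,
               preview_onset = cue_onset + timing$cue_duration,
               preview_offset = cue_onset + timing$cue_duration + preview_dur,
               stringsAsFactors = FALSE)
  })
}

#' Generate a full experiment of counterbalanced runs
#'
#' Concatenates [generate_run()] outputs with per-run seeds derived from
#' `seed`; the default 8 runs of 32 trials give the experiment's 256 trials
#' (128 of them preview-only).
#'
#' @param n_runs Number of runs (>= 1).
#' @param timing Output of [timing_params()].
#' @param seed Integer master seed.
#' @return A data frame of `32 * n_runs` trials (see [generate_run()]).
#' @export
generate_experiment <- function(n_runs = 8, timing = timing_params(),
                                seed = 1L) {
  stopifnot(is_count(n_runs))
  runs <- lapply(seq_len(n_runs), function(r) {
    generate_run(r, timing, seed = derive_seed(seed, r))
  })
  do.call(rbind, runs)
}

#' Write / read a trial events table
#'
#' Tab-separated events file with 0-based `run` and `trial_index` columns and
#' onset times in seconds; the in-memory representation uses 1-based indices.
#'
#' @param trials Trial data frame from [generate_experiment()].
#' @param path File path.
#' @return `read_trials` returns the trial data frame.
#' @export
write_trials <- function(trials, path) {
  out <- trials[, c("run", "trial_index", "trial_type", "target", "context",
                    "present", "anchor_side", "cue_onset", "preview_onset",
                    "preview_offset")]
  out$run <- out$run - 1L
  out$trial_index <- out$trial_index - 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  out$run <- out$run + 1L
  out$trial_index <- out$trial_index + 1L
  out
}
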