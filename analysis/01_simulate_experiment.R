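#!/usr/bin/env Rscript

# Simulate one example participant of the context-guided search experiment
# and write the raw-data artifacts: the counterbalanced trial table, the
# fixation and response tables, run-wise beta patterns for both hemispheres
# and the generator's ground truth. Later drivers re-simulate whole groups
# in memory; this script exists to show (and version) the data formats.

suppressPackageStartupMessages(library(anchorsearch))

out <- "results/example_participant"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

gt <- ground_truth(seed = seed)
map <- make_association_map(0)
trials <- generate_experiment(n_runs = 8, seed = seed)
write_trials(trials, file.path(out, "events.tsv"))
write_ground_truth(gt, file.path(out, "ground_truth.json"))

beh <- simulate_participant_behavior(trials, gt, seed = seed)
write_tsv_table(beh$fixations, file.path(out, "fixations.tsv"))
write_tsv_table(beh$responses, file.path(out, "responses.tsv"))

betas <- simulate_participant_betas(gt, map, n_runs = 8, n_voxels = 264,
                                    seed = seed)
for (h in names(betas)) {
  write_beta_table(betas[[h]], file.path(out, sprintf("betas_%s.tsv", h)))
}

cat("Trials:", nrow(trials), "(",
    sum(trials$trial_type == "preview_only"), "preview-only )\n")
cat("Fixations:", nrow(beh$fixations), "rows;",
    "responses:", nrow(beh$responses), "rows\n")
cat("Latent guidance delta (absent trials):",
    round(beh$latent$delta_latent, 2), "pp; true d':",
    round(beh$latent$dprime, 2), "\n")
cat("Wrote", out, "\n")
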