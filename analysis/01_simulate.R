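#!/usr/bin/env Rscript

# Stage 1: generate the synthetic survey used by the downstream stages.
#
# The generator emulates a national HIV survey with a three-level design
# (adults in households in clusters), three correlated binary outcomes
# (HIV blood test, awareness of HIV/AIDS, awareness of an HIV/AIDS
# campaign), cluster/household random intercepts at published survey
# magnitudes, and covariates for age, education, sex, wealth quintile and
# electricity.  Writes the dataset, the true random-effect draws, and the
# generative configuration under results/.

suppressPackageStartupMessages(library(triglmm))

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
dir.create("results", showWarnings = FALSE)

cfg <- default_emulation_config(seed = seed)
sim <- simulate_survey(cfg)

write_survey_csv(sim$dataset, "results/survey.csv", effects = sim$effects,
                 effects_path = "results/survey_true_effects.csv")
write_simulation_config(cfg, "results/simulation_config.yaml")

cat(sprintf("simulated %d adults in %d households in %d clusters (seed %d)\n",
            nrow(sim$dataset$df),
            length(unique(sim$dataset$df$household_id)),
            length(unique(sim$dataset$df$cluster_id)), seed))
cat(sprintf("%d records (%.1f%%) have their outcome triple missing\n",
            sum(!sim$dataset$complete),
            100 * mean(!sim$dataset$complete)))
for (q in 1:3) {
  ic <- latent_icc_of_config(cfg, q)
  cat(sprintf("outcome %d: theoretical cluster ICC %.4f, household (cum.) %.4f\n",
              q, ic$icc_cluster, ic$icc_household_cumulative))
}
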