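#!/usr/bin/env Rscript
# Stage 1: generate the synthetic UV time-course dataset.
#
# The design mirrors the photoaging mouse study: 3 control mice at week 1
# (reference), 3 at week 8 (intrinsic-aging control), and 3 UV-irradiated
# mice at each of weeks 1, 2, 4, 6, 8. A "collagen-regulatory" module of
# 11 seed genes + 50 true neighbors shares one repression kinetic
# (archetype 6); 450 background genes cycle through the 8 kinetic
# archetypes and flat noise; 20 intrinsic-drift genes shift their week-8
# control mean two-fold.

suppressPackageStartupMessages(library(uvkinet))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- synthetic_spec(
  n_background = 450L,
  n_module_true_neighbors = 50L,
  n_seeds = 11L,
  n_drift = 20L,
  # background kinetics: all eight archetypes plus flat genes, recycled
  archetype_assignments = c(as.character(1:8), rep("flat", 4)),
  module_noise_sd_log2 = 0.10,
  noise_sd_log2 = 0.25,
  drift_fold = 2.0,
  rng_seed = 20230901L
)
sim <- simulate_timecourse(spec)
write_simulation(sim, out)

cat("Simulated", nrow(sim$expression$values), "genes x",
    ncol(sim$expression$values), "samples\n")
print(table(sim$truth$role))
cat("Files written under", out, "\n")
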