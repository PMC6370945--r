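#!/usr/bin/env Rscript
# Stage 1 — simulate the study's raw material: a cohort of mosaic pupal-wing
# images (polarized membrane stacks with a reduced-intensity clone), matched
# sub-junctional puncta fields, an antibody-internalization time course and
# FRAP traces for two genotypes. Image rasters go to scratch/ (bulky);
# ground-truth tables go to results/.

suppressPackageStartupMessages(library(wingpol))
seed <- 20260924L
n_wings <- 10

dir.create("results", showWarnings = FALSE)
dir.create("scratch/sim", showWarnings = FALSE, recursive = TRUE)

cat("Simulating", n_wings, "mosaic wings (Snx27-like clone, membrane x0.7)\n")
truth <- NULL
for (i in seq_len(n_wings)) {
  sp <- wing_spec(n_cell_rows = 6, n_cell_cols = 6, mutant_scale = 0.7,
                  mutant_fraction = 0.25, noise_sd = 5,
                  z_profile = c(0.6, 1, 0.8), seed = seed + i)
  lat <- make_lattice(sp)
  st <- render_membrane_stack(lat, sp)
  stem <- sprintf("scratch/sim/wing%02d", i)
  write_stack(st, paste0(stem, "_membrane.tif"))
  write_mask(lat$label, paste0(stem, "_labels.tif"))
  write_mask(lat$clone, paste0(stem, "_clone.tif"))
  truth <- rbind(truth, data.frame(
    wing_id = sprintf("wing%02d", i), mutant_scale = sp$mutant_scale,
    polarity_axis_deg = sp$polarity_axis_deg,
    polarity_amplitude = sp$polarity_amplitude,
    n_cells = length(cell_ids(lat$label))))
}
utils::write.csv(truth, "results/sim_wing_truth.csv", row.names = FALSE)
cat("  wrote scratch/sim/wingNN_{membrane,labels,clone}.tif",
    "and results/sim_wing_truth.csv\n")

cat("Simulating internalization time course (0/10/30 min, two genotypes)\n")
rec <- simulate_internalization(
  n_wings = n_wings, genotypes = c("wildtype", "mutant"),
  retention = list(wildtype = c(1, 0.55, 0.30), mutant = c(1, 0.55, 0.30)),
  noise_sd = 30, background = 60, seed = seed + 100L)
utils::write.csv(rec, "results/sim_internalization_raw.csv", row.names = FALSE)

cat("Simulating FRAP traces (10 wings per genotype; mutant slow phase halved)\n")
frap_rows <- NULL
for (g in c("wildtype", "mutant")) {
  A2 <- if (g == "wildtype") 0.25 else 0.125
  for (w in seq_len(n_wings)) {
    sp <- frap_sim_spec(Y0 = 0.3, A1 = 0.25, k1 = 0.15, A2 = A2, k2 = 0.008,
                        acq_bleach_rate = 0.002, background = 0.05,
                        noise_sd = 0.02,
                        seed = seed + 200L + w + 1000L * (g == "mutant"))
    tr <- simulate_frap_trace(sp)
    frap_rows <- rbind(frap_rows, data.frame(
      genotype = g, wing = w, frame = seq_along(tr$raw),
      raw = tr$raw, reference = tr$reference, background = tr$background))
  }
}
utils::write.csv(frap_rows, "results/sim_frap_traces.csv", row.names = FALSE)
cat("Done. Ground truth: membrane ratio 0.7; FRAP A2 wildtype 0.25, mutant 0.125.\n")
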