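#!/usr/bin/env Rscript
# Stage 4 — FRAP kinetics: preprocess each wing's trace (background, bleach
# correction, prebleach normalization), fit one- and two-phase exponential
# association models, prefer by extra-sum-of-squares F, then compare
# genotypes on the fast and slow recovery components.

suppressPackageStartupMessages(library(wingpol))
rows <- utils::read.csv("results/sim_frap_traces.csv")

traces <- list(wildtype = list(), mutant = list())
fits <- NULL
for (g in c("wildtype", "mutant")) {
  for (w in unique(rows$wing[rows$genotype == g])) {
    tr <- rows[rows$genotype == g & rows$wing == w, ]
    ft <- preprocess_trace(tr$raw, tr$reference, tr$background[1])
    traces[[g]][[length(traces[[g]]) + 1L]] <- ft
    f1 <- fit_recovery(ft, 1); f2 <- fit_recovery(ft, 2)
    cmp <- compare_nested_fits(f1, f2)
    fits <- rbind(fits, data.frame(
      genotype = g, wing = w, t(f2$par), ss1 = f1$ss, ss2 = f2$ss,
      F = cmp$statistic, p_two_phase = cmp$p,
      preferred = ifelse(cmp$p <= 0.05, "two-phase", "one-phase")))
  }
}
utils::write.csv(fits, "results/frap_fits.csv", row.names = FALSE)

cat("Per-wing model preference (extra-sum-of-squares F, alpha 0.05):\n")
print(table(fits$genotype, fits$preferred))
cat("\nMean two-phase parameters per genotype:\n")
agg <- stats::aggregate(cbind(Y0, A1, k1, A2, k2) ~ genotype, fits, mean)
print(format(agg, digits = 3), row.names = FALSE)

for (comp in c("fast", "slow")) {
  gc <- compare_genotypes(traces$wildtype, traces$mutant, comp)
  cat(sprintf("\n%s-component comparison (shared vs genotype-specific):\n",
              comp))
  cat(sprintf("  F(%d,%d) = %.2f, p = %.4g %s\n", gc$test$df[1],
              gc$test$df[2], gc$test$statistic, gc$test$p, gc$test$stars))
}
cat("\n(The generator halves the mutant slow amplitude: the slow comparison\n",
    "should reject while the fast comparison should not.)\n", sep = "")
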