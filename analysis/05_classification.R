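#!/usr/bin/env Rscript
# Stage 4: B/vB classification with organism-specific thresholds.
#
# Fish-derived depuration thresholds (UK EA: 0.0059 / 0.0027 h^-1) would
# miss fast-eliminating invertebrates entirely, so species-specific
# thresholds are derived by inverting the published log BCF_L5% vs log k2
# regressions at the REACH criteria (2000 / 5000 L/kg). A synthetic
# literature scatter regenerated around the Daphnia line demonstrates the
# full derivation path; the shipped constants are used for the actual
# classification.

suppressPackageStartupMessages(library(daphtk))

# derivation demo: regenerate a Daphnia-like literature set, refit, invert
synth <- gen_bcf_k2(bcf_k2_lines$daphnia, sigma = 0.41, n = 14,
                    seed = 20260928)
refit <- fit_loglinear(synth)
cat("refit of synthetic literature scatter: ")
print(refit)
cat(sprintf("  inverted: B %.2g, vB %.2g h^-1 (published-line values: %.2g, %.2g)\n\n",
            k2_threshold(refit, 2000), k2_threshold(refit, 5000),
            k2_threshold(bcf_k2_lines$daphnia, 2000),
            k2_threshold(bcf_k2_lines$daphnia, 5000)))

rows <- list()
for (sp in c("daphnia", "hyalella", "fish")) {
  th <- b_thresholds(sp)
  print(th)
  rows[[sp]] <- data.frame(species_group = sp, k2_b = th$k2_b,
                           k2_vb = th$k2_vb, t50_b = th$t50_b,
                           t50_vb = th$t50_vb)
}
write.csv(do.call(rbind, rows), "results/k2_thresholds.csv", row.names = FALSE)

# classify the study chemicals with daphnid thresholds
tk <- read.csv("results/tk_fits.csv")
th <- b_thresholds("daphnia")
tk$category <- classify_k2(ifelse(!is.na(tk$k2g) & tk$k2g > 0, tk$k2g, tk$k2), th)
cat("\nclassification (daphnia thresholds):\n")
print(tk[c("chemical_id", "k2g", "category")])
write.csv(tk[c("chemical_id", "k2", "k2g", "category")],
          "results/classification.csv", row.names = FALSE)

# fish-invertebrate concordance on a synthetic paired set: shared chemicals,
# per-species BCF from each species line plus noise (fish offset keeps a mix
# of quadrants around the log BCF 3.3 criterion)
set.seed(20260928)
x <- runif(20, -2.5, 0.5)
pairs <- data.frame(
  chemical = sprintf("pair_%02d", 1:20),
  log_bcf_fish = bcf_k2_lines$fish$slope * x + bcf_k2_lines$fish$intercept +
    rnorm(20, 0, 0.4) + 3,
  log_bcf_invert = bcf_k2_lines$daphnia$slope * x +
    bcf_k2_lines$daphnia$intercept + rnorm(20, 0, 0.4)
)
cc <- concordance(pairs)
cat(sprintf("\nconcordance on synthetic pairs: %s; agreement %.0f%%\n",
            paste(names(cc$counts), cc$counts, collapse = ", "),
            cc$agreement_pct))
cat("wrote results/k2_thresholds.csv, results/classification.csv\n")
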