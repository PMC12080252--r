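#!/usr/bin/env Rscript
# Stage 0: build the synthetic study.
#
# No raw measurements ship with this repository, so the whole workflow runs
# on seeded synthetic data emulating the study design: two chemicals
# bracketing the observed elimination range (a fast eliminator at k2 = 0.1
# h^-1 and a slow one at k2 = 0.011 h^-1), 21-day reproduction tests with
# OECD-211-valid controls, 5x24 h uptake / 4-point depuration body-burden
# sampling with 2 replicate pools, and passive-dosing exposure series over 6
# media-change cycles.

suppressPackageStartupMessages(library(daphtk))

seed <- 20260928L
dir.create("results/inputs", showWarnings = FALSE, recursive = TRUE)

writeLines(c(
  "id,name,mw,sw_ug_per_L,log_kow,tm_K,pka",
  "fast,synthetic fast eliminator,217.3,300,5.2,381,",
  "slow,synthetic slow eliminator,268.3,15,6.9,455,"
), "results/inputs/chemicals.csv")

expo <- rbind(
  gen_exposure(c(L1 = 2, L2 = 6.3, L3 = 20), cv = 0.06,
               chemical_id = "fast", seed = seed),
  gen_exposure(c(L1 = 0.1, L2 = 0.32, L3 = 1), cv = 0.15,
               chemical_id = "slow", seed = seed + 1)
)
write.csv(expo, "results/inputs/exposure.csv", row.names = FALSE)

repro <- rbind(
  gen_reproduction(true_params = c(bottom = 0, top = 100,
                                   log10_ec50 = log10(6), hill = 1.3),
                   conc = 6 * 10^seq(-1.2, 1.2, length.out = 6),
                   chemical_id = "fast", seed = seed + 2),
  gen_reproduction(true_params = c(bottom = 0, top = 100,
                                   log10_ec50 = log10(0.4), hill = 1.1),
                   conc = 0.4 * 10^seq(-1.2, 1.2, length.out = 6),
                   chemical_id = "slow", seed = seed + 3)
)
write.csv(repro, "results/inputs/reproduction.csv", row.names = FALSE)

bb <- rbind(
  gen_tk_series(k1 = 400, k2 = 0.1, kg = 0.005, cw = 6.3, noise_cv = 0.15,
                chemical_id = "fast", seed = seed + 4),
  gen_tk_series(k1 = 300, k2 = 0.011, kg = 0.005, cw = 0.32, noise_cv = 0.15,
                chemical_id = "slow", seed = seed + 5)
)
write.csv(bb, "results/inputs/body_burden.csv", row.names = FALSE)

cat("wrote synthetic study under results/inputs/:\n")
cat(sprintf("  %d exposure measurements, %d reproduction records, %d body burdens\n",
            nrow(expo), nrow(repro), nrow(bb)))
cat("  true parameters: fast (k2 0.1, kg 0.005, EC50 6 ug/L),",
    "slow (k2 0.011, kg 0.005, EC50 0.4 ug/L)\n")
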