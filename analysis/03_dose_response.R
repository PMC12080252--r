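#!/usr/bin/env Rscript
# Stage 2: reproduction dose-response analysis.
#
# For each chemical: OECD-211 validity check, per-replicate inhibition
# relative to the control mean, variable-slope 4PL fit on log10
# concentration, bootstrap 95% CIs for EC10/EC20/EC50, effective chemical
# activity of the EC50, and the critical target lipid body burden from EC10.

suppressPackageStartupMessages(library(daphtk))

chems <- read_chemicals("results/inputs/chemicals.csv")
records <- read_reproduction("results/inputs/reproduction.csv")

rows <- list()
for (id in unique(records$chemical_id)) {
  r <- records[records$chemical_id == id, ]
  v <- validity_check(r)
  cat(sprintf("== %s: test %s\n", id, if (v$valid) "valid" else "INVALID"))
  fit <- fit_4pl(percent_inhibition(r))
  print(fit)
  ch <- chems[chems$id == id, ]
  for (x in c(10, 20, 50)) {
    ci <- ecx_ci(fit, x, n_boot = 500, seed = 20260928, records = r)
    cat(sprintf("  EC%d = %.3g [%.3g, %.3g] ug/L\n",
                x, ci$estimate_ug_per_L, ci$ci_low, ci$ci_high))
    rows[[length(rows) + 1]] <- data.frame(
      chemical_id = id, x = x,
      estimate_ug_per_L = ci$estimate_ug_per_L,
      estimate_nmol_per_L = to_molar(ci$estimate_ug_per_L, ch$mw),
      ci_low = ci$ci_low, ci_high = ci$ci_high)
  }
  s_l <- subcooled_solubility(ch$sw, ch$tm)
  ec50_nmol <- to_molar(rows[[length(rows)]]$estimate_ug_per_L, ch$mw)
  print(effective_activity(ec50_nmol, s_l, "chronic", chemical_id = id))
  ec10_mmol <- to_molar(rows[[length(rows) - 2]]$estimate_ug_per_L, ch$mw) * 1e-6
  cat(sprintf("  CTLBB = %.3g umol/g octanol\n\n", ctlbb(ec10_mmol, ch$log_kow)))
}

ecx <- do.call(rbind, rows)
write.csv(ecx, "results/ecx.csv", row.names = FALSE)
cat("wrote results/ecx.csv\n")
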