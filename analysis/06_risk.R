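#!/usr/bin/env Rscript
# Stage 5: PNEC derivation and risk-quotient screening.
#
# PNEC = chronic EC10 / AF (default 100); RQ compares an environmental
# concentration against the PNEC; the REACH chronic-toxicity flag applies a
# strict EC10 < 10 ug/L cutoff.

suppressPackageStartupMessages(library(daphtk))

chems <- read_chemicals("results/inputs/chemicals.csv")
ecx <- read.csv("results/ecx.csv")
mec <- c(fast = 0.8, slow = 0.8)  # screening-level environmental concentration

rows <- list()
for (id in unique(ecx$chemical_id)) {
  ec10 <- ecx$estimate_ug_per_L[ecx$chemical_id == id & ecx$x == 10]
  ch <- chems[chems$id == id, ]
  rs <- risk_screen(ec10, af = 100, mec = mec[[id]], mw = ch$mw,
                    chemical_id = id)
  print(rs)
  rows[[id]] <- data.frame(chemical_id = id, ec10_ug_per_L = ec10,
                           pnec_ug_per_L = rs$pnec_ug_per_L,
                           pnec_pmol_per_L = rs$pnec_pmol_per_L,
                           rq = rs$rq, rq_exceeds = rs$rq_exceeds,
                           reach_toxic = rs$reach_toxic)
}
write.csv(do.call(rbind, rows), "results/risk.csv", row.names = FALSE)
cat("wrote results/risk.csv\n")
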