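# Build a complete synthetic study (two chemicals bracketing the fast/slow
# eliminator range) as CSV inputs plus a run_all() config, rooted at `dir`.
make_study <- function(dir, seed = 1, n_boot = 50) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)

  writeLines(c(
    "id,name,mw,sw_ug_per_L,log_kow,tm_K,pka",
    "fast,synthetic fast eliminator,217.3,300,5.2,381,",
    "slow,synthetic slow eliminator,268.3,15,6.9,455,"
  ), p("chemicals.csv"))

  expo <- rbind(
    gen_exposure(c(L1 = 2, L2 = 6.3, L3 = 20), cv = 0.06,
                 chemical_id = "fast", seed = seed),
    gen_exposure(c(L1 = 0.1, L2 = 0.32, L3 = 1), cv = 0.15,
                 chemical_id = "slow", seed = seed + 1)
  )
  write.csv(expo, p("exposure.csv"), row.names = FALSE)

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
  write.csv(repro, p("reproduction.csv"), row.names = FALSE)

  bb <- rbind(
    gen_tk_series(k1 = 400, k2 = 0.1, kg = 0.005, cw = 6.3, noise_cv = 0.15,
                  chemical_id = "fast", seed = seed + 4),
    gen_tk_series(k1 = 300, k2 = 0.011, kg = 0.005, cw = 0.32, noise_cv = 0.15,
                  chemical_id = "slow", seed = seed + 5)
  )
  write.csv(bb, p("body_burden.csv"), row.names = FALSE)

  list(
    schema_version = 1,
    paths = list(chemicals = p("chemicals.csv"), exposure = p("exposure.csv"),
                 reproduction = p("reproduction.csv"),
                 body_burden = p("body_burden.csv")),
    out_dir = p("out"),
    options = list(seed = seed, n_boot = n_boot,
                   threshold_source = "daphnia",
                   cw = list(fast = 6.3, slow = 0.32),
                   mec = list(fast = 0.8))
  )
}
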