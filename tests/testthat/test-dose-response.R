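make_records <- function(control = rep(70, 10), dead_controls = 0,
                         conc = numeric(0), offspring = integer(0)) {
  ctrl <- data.frame(chemical_id = "x", conc_ug_per_L = 0,
                     replicate = seq_along(control),
                     offspring = control,
                     parent_dead = seq_along(control) <= dead_controls)
  if (!length(conc)) return(ctrl)
  trt <- data.frame(chemical_id = "x", conc_ug_per_L = conc,
                    replicate = seq_along(conc), offspring = offspring,
                    parent_dead = FALSE)
  rbind(ctrl, trt)
}

test_that("validity check applies the three OECD-211 criteria strictly", {
  r <- make_records(control = round(rnorm(10, 68, 6.8)))
  set.seed(1)
  v <- validity_check(make_records(control = c(66, 70, 64, 72, 68, 75, 61, 69, 67, 68)))
  expect_true(v$valid)
  expect_length(v$reasons, 0)

  v2 <- validity_check(make_records(control = rep(70, 10), dead_controls = 2))
  expect_false(v2$valid)
  expect_true("parent mortality" %in% v2$reasons)

  # exactly 60 offspring fails the strict > 60
  v3 <- validity_check(make_records(control = rep(60, 10)))
  expect_false(v3$valid)
  expect_true("control mean offspring" %in% v3$reasons)

  # exactly 10% mortality fails the strict < 10
  v4 <- validity_check(make_records(control = rep(70, 10), dead_controls = 1))
  expect_false(v4$valid)

  expect_error(validity_check(make_records(conc = 5, offspring = 10L)[-(1:10), ]),
               "control")
})

test_that("percent inhibition is 100*(1 - offspring/control mean), unclipped", {
  r <- make_records(control = rep(70, 10),
                    conc = c(1, 2, 4), offspring = c(70, 35, 84))
  inh <- percent_inhibition(r)
  expect_equal(inh$inhibition_pct, c(0, 50, -20))
  r0 <- make_records(control = rep(70, 10), conc = 1, offspring = 0L)
  expect_equal(percent_inhibition(r0)$inhibition_pct, 100)
})

test_that("4PL fit recovers exact model data and orders ECx", {
  true <- c(bottom = 0, top = 100, log10_ec50 = log10(5), hill = 1.2)
  conc <- 10^seq(-1, 2, length.out = 7)
  y <- true[["bottom"]] + (true[["top"]] - true[["bottom"]]) /
    (1 + 10^((true[["log10_ec50"]] - log10(conc)) * true[["hill"]]))
  fit <- fit_4pl(data.frame(conc_ug_per_L = conc, inhibition_pct = y))
  expect_true(fit$converged)
  expect_equal(unname(fit$params["log10_ec50"]), log10(5), tolerance = 1e-6)
  expect_equal(unname(fit$params["hill"]), 1.2, tolerance = 1e-6)
  expect_equal(fit$ecx$estimate_ug_per_L[fit$ecx$x == 50], 5, tolerance = 1e-6)
  # with bottom 0 / top 100 the EC50 is the inflection concentration,
  # and ECx are ordered for positive hill
  e <- fit$ecx$estimate_ug_per_L
  expect_true(e[1] < e[2] && e[2] < e[3])
})

test_that("4PL fit is invariant to replicate order and rescales with units", {
  d <- percent_inhibition(gen_reproduction(seed = 42))
  f1 <- fit_4pl(d)
  f2 <- fit_4pl(d[rev(seq_len(nrow(d))), ])
  expect_equal(f1$params, f2$params, tolerance = 1e-8)

  d_ng <- d; d_ng$conc_ug_per_L <- d$conc_ug_per_L * 1000
  f3 <- fit_4pl(d_ng)
  expect_equal(f3$ecx$estimate_ug_per_L, f1$ecx$estimate_ug_per_L * 1000,
               tolerance = 1e-6)
})

test_that("4PL fit enforces the minimum number of concentrations", {
  d <- data.frame(conc_ug_per_L = c(1, 2, 4, 8), inhibition_pct = c(10, 30, 60, 90))
  expect_error(fit_4pl(d), "distinct non-zero concentrations")
})

test_that("ECx outside the tested range are flagged extrapolated", {
  true <- c(bottom = 0, top = 100, log10_ec50 = log10(50), hill = 1)
  conc <- c(0.1, 0.3, 1, 3, 10)  # all below EC50
  y <- 100 / (1 + 10^((log10(50) - log10(conc)) * 1))
  fit <- fit_4pl(data.frame(conc_ug_per_L = conc, inhibition_pct = y))
  expect_true(fit$ecx$extrapolated[fit$ecx$x == 50])
  expect_false(fit$ecx$extrapolated[fit$ecx$x == 10])
})

test_that("bootstrap CI is degenerate on noise-free data and seed-deterministic", {
  conc <- 10^seq(-1, 2, length.out = 7)
  y <- 100 / (1 + 10^((log10(5) - log10(conc)) * 1.2))
  d <- data.frame(conc_ug_per_L = rep(conc, each = 3),
                  inhibition_pct = rep(y, each = 3))
  fit <- fit_4pl(d)
  ci <- ecx_ci(fit, 50, n_boot = 50, seed = 9)
  expect_lt(ci$ci_high - ci$ci_low, 1e-6 * ci$estimate_ug_per_L)

  rec <- gen_reproduction(seed = 5)
  f <- fit_4pl(percent_inhibition(rec))
  c1 <- ecx_ci(f, 50, n_boot = 100, seed = 7, records = rec)
  c2 <- ecx_ci(f, 50, n_boot = 100, seed = 7, records = rec)
  expect_identical(c1[c("ci_low", "ci_high")], c2[c("ci_low", "ci_high")])
  expect_true(c1$ci_low <= c1$estimate_ug_per_L)
  expect_true(c1$estimate_ug_per_L <= c1$ci_high)
  expect_false(c1$unstable)
})

test_that("CTLBB evaluates the chronic target lipid model", {
  # null-slope, no class correction: identity on EC10
  expect_equal(ctlbb(2.5, log_kow = 6, m = 0, delta_c = 0), 2.5)
  # transcribed-formula hand evaluation: EC10 * 10^(0.94*logKow - 0.352)
  expect_equal(ctlbb(1e-4, 5.9), 1e-4 * 10^(0.94 * 5.9 - 0.352))
  expect_error(ctlbb(0, 5), "ec10")
})

test_that("CTLBB magnitudes for study-like chemicals sit in the chronic narcosis range", {
  # EC10 0.1-15 ug/L at MW ~200-270 g/mol and log Kow 5.2-6.9
  ec10_ug <- c(15, 1.5, 0.6, 0.1)
  mw <- c(217, 218, 234, 268)
  log_kow <- c(5.2, 5.9, 6.2, 6.9)
  ec10_mmol <- to_molar(ec10_ug, mw) * 1e-6
  vals <- ctlbb(ec10_mmol, log_kow)
  expect_true(all(vals >= 0.36 & vals <= 137))
})
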