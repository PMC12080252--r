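test_that("depuration fit is exact on noiseless exponentials", {
  t <- c(0, 24, 48, 72)
  s <- data.frame(time_h = t, cd_ug_per_kg = 100 * exp(-0.1 * t))
  fit <- suppressWarnings(fit_depuration(s))
  expect_equal(fit$k2, 0.1, tolerance = 1e-12)
  expect_true(fit$valid)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  # three collinear points in log space: (0,100), (10,100/e) and a midpoint
  s2 <- data.frame(time_h = c(0, 5, 10),
                   cd_ug_per_kg = c(100, 100 * exp(-0.5), 100 / exp(1)))
  expect_equal(suppressWarnings(fit_depuration(s2))$k2, 0.1, tolerance = 1e-12)
})

test_that("depuration fit matches the two-point analytic slope", {
  # OLS through two points is the analytic secant; checked via a midpoint set
  t <- c(0, 30, 60)
  cd <- c(80, 80 * exp(-0.02 * 30), 80 * exp(-0.02 * 60))
  k_analytic <- (log(cd[1]) - log(cd[3])) / (t[3] - t[1])
  expect_equal(suppressWarnings(fit_depuration(
    data.frame(time_h = t, cd_ug_per_kg = cd)))$k2, k_analytic,
    tolerance = 1e-12)
})

test_that("depuration fit enforces preconditions and records exclusions", {
  s <- data.frame(time_h = c(0, 24), cd_ug_per_kg = c(10, 5))
  expect_error(fit_depuration(s), ">= 3")
  s2 <- data.frame(time_h = c(0, 24, 48), cd_ug_per_kg = c(10, 5, -1))
  expect_error(fit_depuration(s2), "> 0")

  t <- c(0, 24, 48, 72, 96)
  s3 <- data.frame(time_h = t, cd_ug_per_kg = 100 * exp(-0.05 * t))
  fit <- fit_depuration(s3, exclusions = list(time_h = 96))
  expect_equal(fit$n, 4)
  expect_equal(fit$excluded_points$time_h, 96)

  # rising series yields an invalid (non-positive) k2 flag
  s4 <- data.frame(time_h = t, cd_ug_per_kg = 100 * exp(0.02 * t))
  expect_false(suppressWarnings(fit_depuration(s4))$valid)
})

test_that("plateau detection flags an elimination-resistant tail, not clean decay", {
  t <- c(0, 24, 48, 72, 96, 120)
  clean <- data.frame(time_h = t, cd_ug_per_kg = 100 * exp(-0.05 * t))
  expect_equal(nrow(detect_plateau(clean)), 0)

  # exponential decay onto a constant floor at 10% of C0
  floor_series <- data.frame(time_h = t,
                             cd_ug_per_kg = 90 * exp(-0.08 * t) + 10)
  flags <- detect_plateau(floor_series)
  expect_gt(nrow(flags), 0)
  expect_true(all(flags$time_h >= 96))

  short <- clean[1:3, ]
  expect_equal(nrow(detect_plateau(short)), 0)
})

test_that("plateau exclusion restores the fitted k2 on a floored series", {
  t <- c(0, 24, 48, 72, 96, 120, 192)
  s <- data.frame(time_h = t, cd_ug_per_kg = 1000 * exp(-0.06 * t) + 12)
  biased <- fit_depuration(s)
  flags <- detect_plateau(s, tail_window = 3)
  cleaned <- fit_depuration(s, exclusions = flags)
  expect_gt(nrow(flags), 0)
  expect_gt(cleaned$k2, biased$k2)
  expect_lt(abs(cleaned$k2 - 0.06) / 0.06, abs(biased$k2 - 0.06) / 0.06)
})

test_that("growth rate is the log-linear slope of weight vs time", {
  t <- c(0, 48, 96, 144)
  expect_equal(suppressWarnings(growth_rate(
    data.frame(time_h = t, wet_weight_mg = rep(3, 4))))$kg, 0,
    tolerance = 1e-12)
  expect_equal(suppressWarnings(growth_rate(
    data.frame(time_h = t, wet_weight_mg = 3 * exp(0.01 * t))))$kg, 0.01,
    tolerance = 1e-12)
  expect_error(growth_rate(data.frame(time_h = 1:2, wet_weight_mg = c(1, 2))),
               ">= 3")
})

test_that("growth correction subtracts kg and flags negative results", {
  expect_equal(growth_correct(0.05, 0)$k2g, 0.05)
  expect_equal(growth_correct(0.05, 0.01)$k2g, 0.04)
  neg <- growth_correct(0.01, 0.02)
  expect_equal(neg$k2g, -0.01)
  expect_false(neg$valid)
})

test_that("time to steady state follows -ln(1-f)/k", {
  expect_equal(time_to_ss(0.0059, 0.5), 117, tolerance = 0.005)
  expect_equal(time_to_ss(0.25, 0.5), 2.8, tolerance = 0.02)
  expect_equal(time_to_ss(0.1, 0.95), log(20) / 0.1, tolerance = 1e-12)
  # t95/t50 is ln20/ln2 for any rate
  for (k in c(0.001, 0.05, 2)) {
    expect_equal(time_to_ss(k, 0.95) / time_to_ss(k, 0.5), log(20) / log(2),
                 tolerance = 1e-12)
  }
  # higher k means shorter t95
  ks <- c(0.01, 0.05, 0.2, 1)
  expect_true(all(diff(time_to_ss(ks, 0.95)) < 0))
  expect_error(time_to_ss(0.1, 1), "fraction")
  expect_error(time_to_ss(0, 0.5), "k")
})

test_that("BAF computes CD/CW with 5% lipid normalization", {
  b <- baf(150000, 12, f_lipid = 0.015)
  expect_equal(b$baf, 12500)
  expect_equal(b$baf_l5, 12500 * 0.05 / 0.015)
  expect_equal(b$log_baf_l5, log10(12500 * 0.05 / 0.015))
  # at the reference lipid content the normalization is the identity
  expect_equal(baf(1000, 10, f_lipid = 0.05)$baf_l5, 100)
  expect_equal(baf(0, 10)$baf, 0)
  expect_error(baf(100, 0), "cw")
})

test_that("mean log BAF*_L5% across two exposure levels matches the hand value", {
  vals <- c(baf(150000, 12)$log_baf_l5, baf(50000, 4.7)$log_baf_l5)
  expect_equal(round(mean(vals), 2), 4.58)
})

test_that("tk_summary chains depuration, growth and steady-state times", {
  s <- gen_tk_series(k1 = 50, k2 = 0.05, kg = 0.01, cw = 10, noise_cv = 0,
                     seed = 1)
  tk <- suppressWarnings(tk_summary(s))
  expect_equal(tk$k2, 0.05, tolerance = 1e-10)
  expect_equal(tk$kg, 0.01, tolerance = 1e-6)
  expect_equal(tk$k2g, 0.04, tolerance = 1e-6)
  expect_equal(tk$ss_basis_used, "k2g")
  expect_equal(tk$t50_h, log(2) / tk$k2g, tolerance = 1e-10)
  tk2 <- suppressWarnings(tk_summary(s, ss_basis = "k2"))
  expect_equal(tk2$t50_h, log(2) / 0.05, tolerance = 1e-8)
})
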