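test_that("noiseless TK series lies exactly on the one-compartment curve", {
  s <- gen_tk_series(k1 = 40, k2 = 0.05, kg = 0.01, cw = 10, noise_cv = 0,
                     seed = 1)
  up <- s[s$phase == "uptake" & s$replicate == 1, ]
  ktot <- 0.06
  expect_equal(up$cd_ug_per_kg, 40 / ktot * 10 * (1 - exp(-ktot * up$time_h)),
               tolerance = 1e-12)
  dep <- s[s$phase == "depuration" & s$replicate == 1, ]
  cd_end <- 40 / ktot * 10 * (1 - exp(-ktot * 120))
  expect_equal(dep$cd_ug_per_kg, cd_end * exp(-0.05 * dep$time_h),
               tolerance = 1e-12)
  # wet weights grow at kg
  expect_equal(suppressWarnings(growth_rate(s))$kg, 0.01, tolerance = 1e-9)
})

test_that("generators are pure functions of (params, seed)", {
  a <- gen_tk_series(k1 = 40, k2 = 0.05, cw = 10, seed = 7)
  b <- gen_tk_series(k1 = 40, k2 = 0.05, cw = 10, seed = 7)
  c <- gen_tk_series(k1 = 40, k2 = 0.05, cw = 10, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a, c))

  r1 <- gen_reproduction(seed = 3)
  r2 <- gen_reproduction(seed = 3)
  expect_identical(r1, r2)

  s1 <- gen_bcf_k2(bcf_k2_lines$daphnia, 0.3, 14, seed = 4)
  expect_identical(s1, gen_bcf_k2(bcf_k2_lines$daphnia, 0.3, 14, seed = 4))
  expect_false(identical(s1, gen_bcf_k2(bcf_k2_lines$daphnia, 0.3, 14, seed = 5)))
})

test_that("generators do not perturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(gen_tk_series(k1 = 40, k2 = 0.05, cw = 10, seed = 1))
  invisible(gen_reproduction(seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("TK round trip recovers the growth-corrected depuration rate", {
  s <- gen_tk_series(k1 = 40, k2 = 0.05, kg = 0.01, cw = 10, noise_cv = 0,
                     seed = 2)
  dep <- suppressWarnings(fit_depuration(s))
  kg <- suppressWarnings(growth_rate(s))$kg
  expect_equal(growth_correct(dep$k2, kg)$k2g, 0.04, tolerance = 1e-8)
})

test_that("default reproduction data pass OECD-211 validity and span the curve", {
  d <- gen_reproduction(seed = 21)
  expect_true(validity_check(d)$valid)
  expect_gte(length(unique(d$conc_ug_per_L[d$conc_ug_per_L > 0])), 5)
  # a flat true curve makes treated and control distributions alike
  flat <- gen_reproduction(true_params = c(bottom = 0, top = 0,
                                           log10_ec50 = 0, hill = 1),
                           conc = c(1, 2, 4, 8, 16), seed = 21)
  ctrl <- flat$offspring[flat$conc_ug_per_L == 0]
  trt <- flat$offspring[flat$conc_ug_per_L > 0]
  expect_gt(t.test(ctrl, trt)$p.value, 0.05)
})

test_that("zero-sigma BCF scatter reproduces the target line exactly", {
  d <- gen_bcf_k2(regression_line(-1.2, 2.1), sigma = 0, n = 10, seed = 6)
  line <- fit_loglinear(d)
  expect_equal(line$slope, -1.2, tolerance = 1e-10)
  expect_equal(line$intercept, 2.1, tolerance = 1e-10)
  expect_equal(line$r2, 1, tolerance = 1e-10)
})

test_that("sigma tuned for R2 ~ 0.9 yields fitted R2 in a plausible band", {
  # with slope -1.41 over x-range width 3, sd(yhat) ~ 1.22; R2 0.9 needs
  # sigma ~ sd(yhat)/3 ~ 0.41
  r2s <- vapply(1:100, function(i) {
    fit_loglinear(gen_bcf_k2(regression_line(-1.41, 2.85), sigma = 0.41,
                             n = 14, seed = i))$r2
  }, numeric(1))
  expect_gt(median(r2s), 0.8)
  expect_lt(median(r2s), 0.97)
  expect_gt(mean(r2s >= 0.75 & r2s <= 0.99), 0.9)
})

test_that("generator rejects invalid parameters", {
  expect_error(gen_tk_series(k1 = 0, k2 = 0.05, cw = 10), "rates")
  expect_error(gen_tk_series(k1 = 1, k2 = 0.05, cw = 10,
                             uptake_times = c(48, 24)), "increasing")
  expect_error(gen_reproduction(conc = c(1, 2, 3), seed = 1), ">= 5")
  expect_error(gen_bcf_k2(bcf_k2_lines$daphnia, 0.3, 2, seed = 1), "n >= 3")
})
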