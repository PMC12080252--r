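test_that("log-linear fit matches closed-form normal equations", {
  # exact line
  r <- data.frame(chemical = letters[1:3], log_k2 = c(-2, -1, 0),
                  log_bcf_l5 = c(-3, -1, 1))
  line <- fit_loglinear(r)
  expect_equal(line$slope, 2, tolerance = 1e-12)
  expect_equal(line$intercept, 1, tolerance = 1e-12)
  expect_equal(line$r2, 1, tolerance = 1e-12)

  # arbitrary data: closed-form normal-equation oracle
  set.seed(12)
  x <- rnorm(20); y <- 1.7 * x - 0.4 + rnorm(20, 0, 0.5)
  d <- data.frame(chemical = paste0("c", 1:20), log_k2 = x, log_bcf_l5 = y)
  line2 <- fit_loglinear(d)
  slope_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept_hat <- mean(y) - slope_hat * mean(x)
  expect_equal(line2$slope, slope_hat, tolerance = 1e-10)
  expect_equal(line2$intercept, intercept_hat, tolerance = 1e-10)
})

test_that("log-linear fit validates input and honours exclusions", {
  r <- data.frame(chemical = c("a", "b"), log_k2 = c(1, 2),
                  log_bcf_l5 = c(1, 2))
  expect_error(fit_loglinear(r), ">= 3")
  r2 <- data.frame(chemical = letters[1:4], log_k2 = rep(1, 4),
                   log_bcf_l5 = 1:4)
  expect_error(fit_loglinear(r2), "degenerate")

  d <- gen_bcf_k2(regression_line(-1.4, 2.8), sigma = 0.2, n = 16, seed = 2)
  d$log_bcf_l5[1:2] <- d$log_bcf_l5[1:2] - 3  # two underestimated records
  line <- fit_loglinear(d, exclude = d$chemical[1:2])
  expect_equal(line$n, 14)
  expect_equal(attr(line, "excluded"), d$chemical[1:2])
})

test_that("generator round-trip recovers the target regression", {
  slopes <- vapply(1:100, function(i) {
    d <- gen_bcf_k2(regression_line(-1.41, 2.85), sigma = 0.45, n = 14,
                    seed = i)
    fit_loglinear(d)$slope
  }, numeric(1))
  expect_lt(abs(median(slopes) - (-1.41)), 0.15)

  exact <- gen_bcf_k2(regression_line(-1.41, 2.85), sigma = 0, n = 14, seed = 1)
  line <- fit_loglinear(exact)
  expect_equal(line$slope, -1.41, tolerance = 1e-10)
  expect_equal(line$r2, 1, tolerance = 1e-10)
})

test_that("k2 threshold inversion reproduces the published species thresholds", {
  expect_equal(round(k2_threshold(bcf_k2_lines$daphnia, 2000), 2), 0.48)
  expect_equal(round(k2_threshold(bcf_k2_lines$daphnia, 5000), 2), 0.25)
  expect_equal(round(k2_threshold(bcf_k2_lines$hyalella, 2000), 3), 0.037)
  expect_equal(round(k2_threshold(bcf_k2_lines$hyalella, 5000), 3), 0.017)
})

test_that("threshold inversion round-trips through the line", {
  line <- bcf_k2_lines$daphnia
  for (x0 in c(-2, -0.5, 0.3)) {
    bcf <- 10^(line$intercept + line$slope * x0)
    expect_equal(k2_threshold(line, bcf), 10^x0, tolerance = 1e-9)
  }
  expect_error(k2_threshold(regression_line(0.5, 1, n = 3), 2000), "negative slope")
})

test_that("b_thresholds orders k2_vb < k2_b and carries half-lives", {
  for (sp in c("daphnia", "hyalella", "fish")) {
    th <- b_thresholds(sp)
    expect_lt(th$k2_vb, th$k2_b)
    expect_equal(th$t50_b, log(2) / th$k2_b)
  }
  # fish default uses the UK-EA literature values
  expect_equal(b_thresholds("fish")$k2_b, 0.0059)
  expect_equal(b_thresholds("fish")$k2_vb, 0.0027)
  # regression-derived fish thresholds nearly coincide
  reg <- b_thresholds("fish", fish_source = "regression")
  expect_equal(reg$k2_b, 0.0059, tolerance = 0.25)
})

test_that("classify_k2 uses inclusive bounds and is monotone", {
  th <- b_thresholds("daphnia")
  expect_equal(classify_k2(0.011, th), "vB")
  expect_equal(classify_k2(th$k2_b, th), "B")       # exactly at bound
  expect_equal(classify_k2(th$k2_vb, th), "vB")
  expect_equal(classify_k2(10 * th$k2_b, th), "not_B")

  ranks <- c(not_B = 0, B = 1, vB = 2)
  ks <- sort(10^runif(50, -4, 1), decreasing = TRUE)
  cats <- ranks[classify_k2(ks, th)]
  expect_true(all(diff(cats) >= 0))  # decreasing k2 never lowers the category
})

test_that("concordance counts quadrants with inclusive thresholds", {
  same <- data.frame(chemical = letters[1:4],
                     log_bcf_fish = c(4, 2, 3.5, 1),
                     log_bcf_invert = c(4, 2, 3.5, 1))
  expect_equal(concordance(same)$agreement_pct, 100)

  quad <- data.frame(chemical = letters[1:4],
                     log_bcf_fish = c(4, 4, 2, 2),
                     log_bcf_invert = c(4, 2, 4, 2))
  cc <- concordance(quad)
  expect_equal(unname(cc$counts), c(1, 1, 1, 1))
  expect_equal(cc$agreement_pct, 50)

  edge <- data.frame(chemical = "x", log_bcf_fish = 3.3, log_bcf_invert = 3.3)
  expect_equal(unname(concordance(edge)$counts["both"]), 1)
})

test_that("species BCF reader validates the controlled vocabulary", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(gen_bcf_k2(bcf_k2_lines$daphnia, 0.3, 10, seed = 1), path,
            row.names = FALSE)
  expect_equal(nrow(read_species_bcf(path)), 10)
  bad <- gen_bcf_k2(bcf_k2_lines$daphnia, 0.3, 5, seed = 1)
  bad$species_group <- "copepod"
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_species_bcf(path), "species_group")
})
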