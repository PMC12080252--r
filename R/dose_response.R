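#' OECD-211 validity check for a reproduction test
#'
#' A 21-day Daphnia magna reproduction test is valid when, in the controls,
#' parent mortality is below 10%, the average number of live offspring per
#' mother exceeds 60, and the coefficient of variation of live offspring is
#' below 15%. All three inequalities are strict.
#'
#' @param records A data.frame with columns `chemical_id`, `conc_ug_per_L`
#'   (0 marks controls), `replicate`, `offspring` (cumulative live offspring,
#'   integer >= 0) and `parent_dead` (logical).
#' @return A list of class `validity_report` with `parent_mortality_pct`,
#'   `control_mean_offspring`, `control_cv_pct`, `valid` and `reasons`
#'   (character vector of failed criteria, empty when valid).
#' @export
validity_check <- function(records) {
  r <- .check_repro(records)
  ctrl <- r[r$conc_ug_per_L == 0, ]
  if (nrow(ctrl) == 0) stop("no control (conc = 0) records", call. = FALSE)
  mort <- 100 * mean(ctrl$parent_dead)
  surv <- ctrl[!ctrl$parent_dead, ]
  mu <- mean(surv$offspring)
  cv <- if (nrow(surv) >= 2 && mu > 0) 100 * stats::sd(surv$offspring) / mu else NA_real_
  reasons <- character()
  if (!(mort < 10)) reasons <- c(reasons, "parent mortality")
  if (!(isTRUE(mu > 60))) reasons <- c(reasons, "control mean offspring")
  if (!(isTRUE(cv < 15))) reasons <- c(reasons, "control offspring CV")
  structure(
    list(parent_mortality_pct = mort, control_mean_offspring = mu,
         control_cv_pct = cv, valid = length(reasons) == 0, reasons = reasons),
    class = "validity_report"
  )
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf(
    "OECD-211 validity: %s\n  parent mortality: %.1f%% (< 10)\n  control mean offspring: %.1f (> 60)\n  control CV: %.1f%% (< 15)\n",
    if (x$valid) "VALID" else paste("INVALID:", paste(x$reasons, collapse = ", ")),
    x$parent_mortality_pct, x$control_mean_offspring, x$control_cv_pct
  ))
  invisible(x)
}

#' Per-replicate reproduction inhibition relative to the control mean
#'
#' Inhibition is `100 * (1 - offspring / control_mean)`, where the control
#' mean is taken over surviving control mothers. Negative values
#' (stimulation) are reported as-is, never clipped. Records from dead parents
#' are excluded.
#'
#' @inheritParams validity_check
#' @return A data.frame with columns `chemical_id`, `conc_ug_per_L`,
#'   `replicate`, `offspring` and `inhibition_pct`, containing the treated
#'   (conc > 0) surviving replicates.
#' @export
percent_inhibition <- function(records) {
  r <- .check_repro(records)
  ctrl <- r[r$conc_ug_per_L == 0 & !r$parent_dead, ]
  if (nrow(ctrl) == 0) stop("no surviving control records", call. = FALSE)
  cm <- mean(ctrl$offspring)
  if (cm == 0) stop("control mean offspring is zero", call. = FALSE)
  trt <- r[r$conc_ug_per_L > 0 & !r$parent_dead, ]
  data.frame(
    chemical_id = trt$chemical_id,
    conc_ug_per_L = trt$conc_ug_per_L,
    replicate = trt$replicate,
    offspring = trt$offspring,
    inhibition_pct = 100 * (1 - trt$offspring / cm),
    stringsAsFactors = FALSE
  )
}

#' Fit a four-parameter logistic concentration-response curve
#'
#' Least-squares fit of
#' \deqn{y = bottom + \frac{top - bottom}{1 + 10^{(\log_{10}EC_{50} - x)\,h}}}
#' on `x = log10(concentration)` with variable Hill slope `h`, mirroring the
#' standard variable-slope 4PL used for chronic ECx estimation.
#' Controls (conc = 0) never enter the fit (log undefined); they act only
#' through the control mean used to compute inhibition. ECx for the requested
#' effect levels are solved analytically from the fitted parameters.
#'
#' @param data A data.frame with columns `conc_ug_per_L` (> 0) and
#'   `inhibition_pct`, e.g. from [percent_inhibition()].
#' @param ecx_levels Effect levels (percent) to solve for; default
#'   `c(10, 20, 50)`.
#' @param bottom_range,top_range Box constraints for the asymptotes, in
#'   percent; defaults `[-20, 20]` and `[80, 120]`. Use `c(0, 0)` /
#'   `c(100, 100)` to fix them.
#' @param min_levels Minimum number of distinct non-zero concentrations
#'   required; default 5.
#' @return An object of class `dr_fit`: a list with `params`
#'   (`bottom`, `top`, `log10_ec50`, `hill`), `ecx` (data.frame `x`,
#'   `estimate_ug_per_L`, `extrapolated`), `converged`, `r2`, `data`,
#'   `conc_range`.
#' @export
fit_4pl <- function(data, ecx_levels = c(10, 20, 50),
                    bottom_range = c(-20, 20), top_range = c(80, 120),
                    min_levels = 5) {
  if (!all(c("conc_ug_per_L", "inhibition_pct") %in% names(data))) {
    stop("`data` needs columns conc_ug_per_L and inhibition_pct", call. = FALSE)
  }
  data <- data[data$conc_ug_per_L > 0, ]
  nconc <- length(unique(data$conc_ug_per_L))
  if (nconc < min_levels) {
    stop(sprintf("need >= %d distinct non-zero concentrations, got %d",
                 min_levels, nconc), call. = FALSE)
  }
  x <- log10(data$conc_ug_per_L)
  y <- data$inhibition_pct

  start <- list(bottom = max(bottom_range[1], min(0, min(y))),
                top = min(top_range[2], max(100, max(y))),
                e = stats::median(x), h = 1)
  # clamp starts inside the box
  start$bottom <- min(max(start$bottom, bottom_range[1]), bottom_range[2])
  start$top <- min(max(start$top, top_range[1]), top_range[2])
  lower <- c(bottom_range[1], top_range[1], min(x) - 3, 1e-3)
  upper <- c(bottom_range[2], top_range[2], max(x) + 3, 20)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^((e - x) * h)),
      data = data.frame(x = x, y = y),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )

  if (is.null(fit)) {
    return(structure(
      list(params = c(bottom = NA_real_, top = NA_real_,
                      log10_ec50 = NA_real_, hill = NA_real_),
           ecx = NULL, converged = FALSE, r2 = NA_real_,
           data = data, conc_range = range(data$conc_ug_per_L)),
      class = "dr_fit"
    ))
  }

  p <- stats::coef(fit)
  params <- c(bottom = unname(p["bottom"]), top = unname(p["top"]),
              log10_ec50 = unname(p["e"]), hill = unname(p["h"]))
  resid <- stats::resid(fit)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_

  ecx <- .solve_ecx(params, ecx_levels, range(data$conc_ug_per_L))
  structure(
    list(params = params, ecx = ecx, converged = TRUE, r2 = r2,
         data = data, conc_range = range(data$conc_ug_per_L)),
    class = "dr_fit"
  )
}

# Analytic ECx from 4PL parameters; NA when the effect level lies outside the
# open interval (bottom, top).
.solve_ecx <- function(params, levels, conc_range) {
  bottom <- params[["bottom"]]; top <- params[["top"]]
  e <- params[["log10_ec50"]]; h <- params[["hill"]]
  est <- vapply(levels, function(yx) {
    if (!(bottom < yx && yx < top)) return(NA_real_)
    10^(e - log10((top - yx) / (yx - bottom)) / h)
  }, numeric(1))
  data.frame(
    x = levels,
    estimate_ug_per_L = est,
    extrapolated = !is.na(est) & (est < conc_range[1] | est > conc_range[2])
  )
}

#' @export
print.dr_fit <- function(x, ...) {
  if (!x$converged) {
    cat("4PL fit: did not converge\n")
    return(invisible(x))
  }
  cat(sprintf(
    "4PL fit: bottom %.2f%%, top %.2f%%, log10 EC50 %.4f, hill %.3f (R2 %.3f)\n",
    x$params["bottom"], x$params["top"], x$params["log10_ec50"],
    x$params["hill"], x$r2
  ))
  if (!is.null(x$ecx)) {
    for (i in seq_len(nrow(x$ecx))) {
      cat(sprintf("  EC%d = %.4g ug/L%s\n", x$ecx$x[i],
                  x$ecx$estimate_ug_per_L[i],
                  if (isTRUE(x$ecx$extrapolated[i])) " (extrapolated)" else ""))
    }
  }
  invisible(x)
}

#' Bootstrap confidence interval for an ECx estimate
#'
#' Case-resampling bootstrap: replicates are resampled with replacement
#' within each concentration, the 4PL is refit, and the 2.5/97.5 percentiles
#' of the resampled ECx form the interval. Deterministic under a fixed seed.
#'
#' When the raw reproduction `records` are supplied, the controls (conc 0)
#' are resampled like any other concentration group and the control mean —
#' hence every inhibition value — is recomputed per resample, so the
#' uncertainty of the control mean propagates into the interval. Without
#' `records` only the treated inhibition values are resampled, which
#' understates the interval when the control mean is itself noisy.
#'
#' @param fit A converged [fit_4pl()] result.
#' @param x Effect level (percent), e.g. 50.
#' @param n_boot Number of bootstrap resamples; default 1000.
#' @param seed Integer seed.
#' @param records Optional raw reproduction records (as for
#'   [percent_inhibition()]) including the controls.
#' @return A list with `x`, `estimate_ug_per_L`, `ci_low`, `ci_high`,
#'   `n_boot`, `n_failed` and `unstable` (TRUE when more than 20% of the
#'   refits failed to yield an ECx).
#' @export
ecx_ci <- function(fit, x = 50, n_boot = 1000, seed = 1, records = NULL) {
  stopifnot(inherits(fit, "dr_fit"))
  if (!fit$converged) stop("cannot bootstrap a non-converged fit", call. = FALSE)
  est <- fit$ecx$estimate_ug_per_L[match(x, fit$ecx$x)]
  if (length(est) == 0 || is.na(est)) {
    est <- .solve_ecx(fit$params, x, fit$conc_range)$estimate_ug_per_L
  }
  # m = n-1 resampling per group: drawing n-1 with replacement makes the
  # bootstrap variance of a group mean unbiased (plain n-from-n deflates it
  # by (n-1)/n), which matters at OECD-211 replicate counts (~10 per level).
  draw <- function(g) {
    m <- max(2L, length(g) - 1L)
    g[sample.int(length(g), size = m, replace = TRUE)]
  }
  if (!is.null(records)) {
    r <- .check_repro(records)
    r <- r[!r$parent_dead, ]
    groups <- split(seq_len(nrow(r)), r$conc_ug_per_L)
    one_resample <- function() {
      percent_inhibition(r[unlist(lapply(groups, draw), use.names = FALSE), ])
    }
  } else {
    data <- fit$data
    groups <- split(seq_len(nrow(data)), data$conc_ug_per_L)
    one_resample <- function() {
      data[unlist(lapply(groups, draw), use.names = FALSE), ]
    }
  }
  boot_ecx <- numeric(n_boot)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    bf <- tryCatch(
      suppressWarnings(fit_4pl(one_resample(), ecx_levels = x,
                               min_levels = 1)),
      error = function(e) NULL
    )
    boot_ecx[b] <- if (!is.null(bf) && bf$converged) {
      bf$ecx$estimate_ug_per_L[1]
    } else NA_real_
  }
  n_failed <- sum(is.na(boot_ecx))
  ci <- stats::quantile(boot_ecx, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(x = x, estimate_ug_per_L = unname(est),
       ci_low = ci[1], ci_high = ci[2],
       n_boot = n_boot, n_failed = n_failed, seed = seed,
       unstable = n_failed > 0.2 * n_boot)
}

# save/restore the global RNG state so seeded helpers do not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Critical target lipid body burden from a chronic EC10
#'
#' The target lipid model posits that baseline (narcosis) toxicity occurs at
#' a fixed chemical concentration in organism lipid. With the chronic-endpoint
#' calibration, \eqn{\log_{10} EC_{10} = m \log_{10} K_{OW} + \log_{10} CTLBB
#' + \Delta c}, with universal slope `m = -0.94` and a PAH class correction
#' `delta_c = 0.352`, so
#' \deqn{CTLBB = EC_{10} \cdot 10^{-m \log_{10}K_{OW} - \Delta c}}
#'
#' @param ec10 Chronic EC10 in mmol/L (strictly positive).
#' @param log_kow log10 octanol-water partition coefficient.
#' @param m Universal slope; default -0.94.
#' @param delta_c Chemical-class correction; default 0.352 (PAHs).
#' @return CTLBB in µmol/g octanol.
#' @export
ctlbb <- function(ec10, log_kow, m = -0.94, delta_c = 0.352) {
  if (any(!is.finite(ec10)) || any(ec10 <= 0)) {
    stop("`ec10` must be positive (mmol/L)", call. = FALSE)
  }
  ec10 * 10^(-m * log_kow - delta_c)
}

#' Read a reproduction record table
#'
#' CSV with header `chemical_id,conc_ug_per_L,replicate,offspring,parent_dead`.
#'
#' @param path Path to the CSV file.
#' @return A validated data.frame of reproduction records.
#' @export
read_reproduction <- function(path) {
  .check_repro(utils::read.csv(path, stringsAsFactors = FALSE))
}

.check_repro <- function(r) {
  need <- c("chemical_id", "conc_ug_per_L", "replicate", "offspring",
            "parent_dead")
  miss <- setdiff(need, names(r))
  if (length(miss)) {
    stop("reproduction table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(r$offspring < 0)) stop("`offspring` must be >= 0", call. = FALSE)
  if (any(r$conc_ug_per_L < 0)) stop("`conc_ug_per_L` must be >= 0", call. = FALSE)
  r$parent_dead <- as.logical(r$parent_dead)
  r
}
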