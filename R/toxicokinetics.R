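#' Fit a first-order depuration model to a body-burden time series
#'
#' One-compartment elimination: the natural log of the body burden declines
#' linearly in time, ln C_D(t) = ln C_D(0) - k2 t. Ordinary least squares of
#' ln(cd) on time over all retained points (replicates pooled) gives the
#' depuration rate constant k2 as minus the slope.
#'
#' @param series A data.frame with at least `time_h` (hours from the start of
#'   depuration, >= 0) and `cd_ug_per_kg` (> 0). Additional columns
#'   (`replicate`, `phase`) pass through untouched; when a `phase` column is
#'   present only `phase == "depuration"` rows are used.
#' @param exclusions Optional data.frame or list with a `time_h` element
#'   naming time points to drop (e.g. a plateau tail confirmed from
#'   [detect_plateau()] suggestions); each exclusion is recorded with its
#'   reason.
#' @return An object of class `tk_fit`: a list with `k2` (h^-1), `k2_se`,
#'   `r2`, `n`, `intercept_ln` (ln µg/kg at t = 0), `valid` (FALSE when the
#'   slope is non-negative), and `excluded_points`.
#' @export
fit_depuration <- function(series, exclusions = NULL) {
  s <- series
  if ("phase" %in% names(s)) s <- s[s$phase == "depuration", ]
  if (!all(c("time_h", "cd_ug_per_kg") %in% names(s))) {
    stop("`series` needs columns time_h and cd_ug_per_kg", call. = FALSE)
  }
  excluded <- data.frame(time_h = numeric(), reason = character())
  if (!is.null(exclusions) && length(exclusions$time_h)) {
    drop <- s$time_h %in% exclusions$time_h
    excluded <- data.frame(
      time_h = s$time_h[drop],
      reason = rep("user-confirmed exclusion", sum(drop))
    )
    s <- s[!drop, ]
  }
  if (any(s$cd_ug_per_kg <= 0)) {
    stop("all body burdens must be > 0 for the log-space fit", call. = FALSE)
  }
  if (nrow(s) < 3) {
    stop("need >= 3 retained depuration points", call. = FALSE)
  }
  fit <- stats::lm(log(cd_ug_per_kg) ~ time_h, data = s)
  sm <- suppressWarnings(summary(fit))  # exact exponentials are legitimate
  slope <- unname(stats::coef(fit)["time_h"])
  structure(
    list(
      k2 = -slope,
      k2_se = sm$coefficients["time_h", "Std. Error"],
      r2 = sm$r.squared,
      n = nrow(s),
      intercept_ln = unname(stats::coef(fit)["(Intercept)"]),
      valid = slope < 0,
      excluded_points = excluded
    ),
    class = "tk_fit"
  )
}

#' @export
print.tk_fit <- function(x, ...) {
  cat(sprintf("Depuration fit: k2 = %.4g h^-1 (SE %.3g, R2 %.3f, n = %d)%s\n",
              x$k2, x$k2_se, x$r2, x$n,
              if (!x$valid) " [INVALID: non-negative slope]" else ""))
  if (nrow(x$excluded_points)) {
    cat(sprintf("  excluded: t = %s h (%s)\n",
                paste(x$excluded_points$time_h, collapse = ", "),
                x$excluded_points$reason[1]))
  }
  invisible(x)
}

#' Suggest trailing plateau points for exclusion from a depuration fit
#'
#' Elimination-resistant residues show up as a plateau at the tail of a
#' depuration series; leaving such points in biases k2 low. This flags
#' trailing points whose removal changes the fitted k2 by more than `tol`
#' (relative) and whose local tail slope is shallower than `tol_slope`.
#' Suggestions only — exclusion requires the caller to pass them explicitly
#' to [fit_depuration()], so fits stay auditable.
#'
#' @param series As in [fit_depuration()]; needs >= 4 points.
#' @param tail_window Maximum number of trailing points considered; default 2.
#' @param tol Relative change in k2 that triggers a flag; default 0.2.
#' @param tol_slope Local slope threshold in h^-1 (a tail flatter than this,
#'   i.e. slope >= -tol_slope, supports a plateau); default 0.005.
#' @return A data.frame of suggested exclusions (`time_h`, `reason`); empty
#'   on clean decay or when fewer than 4 points are available.
#' @export
detect_plateau <- function(series, tail_window = 2, tol = 0.2,
                           tol_slope = 0.005) {
  s <- series
  if ("phase" %in% names(s)) s <- s[s$phase == "depuration", ]
  none <- data.frame(time_h = numeric(), reason = character())
  # pool replicates: mean cd per time point, fit behaviour judged on pooled fit
  agg <- stats::aggregate(cd_ug_per_kg ~ time_h, data = s, FUN = mean)
  agg <- agg[order(agg$time_h), ]
  n <- nrow(agg)
  if (n < 4) return(none)
  k2_full <- fit_depuration(data.frame(time_h = agg$time_h,
                                       cd_ug_per_kg = agg$cd_ug_per_kg))$k2
  for (j in seq_len(min(tail_window, n - 3))) {
    keep <- agg[seq_len(n - j), ]
    k2_trim <- fit_depuration(keep)$k2
    tail_pts <- agg[(n - j):n, ]
    local_slope <- unname(stats::coef(
      stats::lm(log(cd_ug_per_kg) ~ time_h, data = tail_pts))["time_h"])
    if (abs(k2_trim - k2_full) > tol * abs(k2_full) &&
        local_slope >= -tol_slope) {
      flagged <- agg$time_h[(n - j + 1):n]
      return(data.frame(
        time_h = flagged,
        reason = sprintf(
          "apparent plateau: removing tail changes k2 by %.0f%% and local slope %.4g h^-1 >= %.4g",
          100 * abs(k2_trim - k2_full) / abs(k2_full), local_slope, -tol_slope)
      ))
    }
  }
  none
}

#' Growth rate constant from wet-weight measurements
#'
#' Growth dilutes body burdens; the growth rate constant kg is the slope of
#' ln(wet weight) against time.
#'
#' @param weights A data.frame with columns `time_h` and `wet_weight_mg`
#'   (> 0); >= 3 points required. When a `phase` column is present,
#'   depuration times (phase-relative by convention) are shifted onto the
#'   absolute experiment clock by adding the last uptake time, so weights
#'   from both phases fit on one line.
#' @return A list with `kg` (h^-1), `kg_se`, `r2`, `n`.
#' @export
growth_rate <- function(weights) {
  if (!all(c("time_h", "wet_weight_mg") %in% names(weights))) {
    stop("`weights` needs columns time_h and wet_weight_mg", call. = FALSE)
  }
  if ("phase" %in% names(weights) && any(weights$phase == "depuration") &&
      any(weights$phase == "uptake")) {
    t_end <- max(weights$time_h[weights$phase == "uptake"])
    weights$time_h[weights$phase == "depuration"] <-
      weights$time_h[weights$phase == "depuration"] + t_end
  }
  w <- weights[!is.na(weights$wet_weight_mg), ]
  if (nrow(w) < 3) stop("need >= 3 weight measurements", call. = FALSE)
  if (any(w$wet_weight_mg <= 0)) stop("weights must be > 0", call. = FALSE)
  fit <- stats::lm(log(wet_weight_mg) ~ time_h, data = w)
  sm <- suppressWarnings(summary(fit))
  list(kg = unname(stats::coef(fit)["time_h"]),
       kg_se = sm$coefficients["time_h", "Std. Error"],
       r2 = sm$r.squared, n = nrow(w))
}

#' Growth-corrected depuration rate constant
#'
#' Apparent depuration includes growth dilution; the growth-corrected rate is
#' `k2g = k2 - kg`. A negative result (growth faster than elimination) is
#' returned but flagged invalid.
#'
#' @param k2 Depuration rate constant, h^-1 (> 0).
#' @param kg Growth rate constant, h^-1.
#' @return A list with `k2g` and `valid`.
#' @export
growth_correct <- function(k2, kg) {
  if (!is.finite(k2) || k2 <= 0) stop("`k2` must be > 0", call. = FALSE)
  k2g <- k2 - kg
  list(k2g = k2g, valid = k2g > 0)
}

#' Time to reach a given fraction of steady state
#'
#' In a first-order one-compartment model the body burden approaches steady
#' state as `1 - exp(-k t)`, so the time to a fraction `f` of steady state is
#' `t = -ln(1 - f)/k`; `t50 = ln(2)/k`, `t95 = ln(20)/k`.
#'
#' @param k Rate constant in h^-1 (> 0) — conventionally the growth-corrected
#'   depuration constant k2g when available, else k2.
#' @param fraction Fraction of steady state in (0, 1); default 0.5.
#' @return Time in hours.
#' @export
#' @examples
#' time_to_ss(0.0059, 0.5)   # ~117 h
#' time_to_ss(0.25, 0.5)     # ~2.8 h
time_to_ss <- function(k, fraction = 0.5) {
  if (any(!is.finite(k)) || any(k <= 0)) stop("`k` must be > 0", call. = FALSE)
  if (any(fraction <= 0) || any(fraction >= 1)) {
    stop("`fraction` must lie in (0, 1)", call. = FALSE)
  }
  -log(1 - fraction) / k
}

#' Kinetic bioaccumulation factor with lipid normalization
#'
#' BAF* = C_D / C_W, with C_D the body burden at the end of the uptake phase
#' (µg/kg wet weight) and C_W the water concentration (µg/L). To compare
#' across organisms the BAF is normalized to a reference 5% lipid content:
#' `BAF*_L5% = BAF* x 0.05 / f_lipid`. The D. magna default lipid fraction is
#' 1.5%. When uptake has not reached steady state (the default assumption
#' here), BAF* is a best-case approximation and the true BAF is likely
#' higher.
#'
#' @param cd_end Body burden at the end of uptake, µg/kg wet weight (>= 0).
#' @param cw Water concentration, µg/L (> 0).
#' @param f_lipid Actual lipid fraction of the organism; default 0.015.
#' @param steady_state_reached Caller-supplied flag; default FALSE.
#' @return A list of class `baf_result` with `baf` (L/kg), `baf_l5` (L/kg),
#'   `log_baf_l5`, `f_lipid`, `steady_state_reached`.
#' @export
#' @examples
#' baf(150000, 12)  # log BAF*_L5% ~ 4.62
baf <- function(cd_end, cw, f_lipid = 0.015, steady_state_reached = FALSE) {
  if (!is.finite(cw) || cw <= 0) stop("`cw` must be > 0 (ug/L)", call. = FALSE)
  if (!is.finite(cd_end) || cd_end < 0) stop("`cd_end` must be >= 0", call. = FALSE)
  if (!is.finite(f_lipid) || f_lipid <= 0 || f_lipid > 1) {
    stop("`f_lipid` must lie in (0, 1]", call. = FALSE)
  }
  b <- cd_end / cw
  bl5 <- b * 0.05 / f_lipid
  structure(
    list(baf = b, baf_l5 = bl5,
         log_baf_l5 = if (bl5 > 0) log10(bl5) else -Inf,
         f_lipid = f_lipid, steady_state_reached = steady_state_reached),
    class = "baf_result"
  )
}

#' @export
print.baf_result <- function(x, ...) {
  cat(sprintf(
    "BAF* = %.4g L/kg; BAF*_L5%% = %.4g L/kg (log10 %.2f; f_lipid %.3f)%s\n",
    x$baf, x$baf_l5, x$log_baf_l5, x$f_lipid,
    if (!x$steady_state_reached) " [steady state not reached: best-case approximation]" else ""
  ))
  invisible(x)
}

#' Full toxicokinetic summary for one chemical
#'
#' Convenience wrapper chaining [fit_depuration()], [growth_rate()],
#' [growth_correct()] and [time_to_ss()] for a body-burden series that
#' carries wet weights.
#'
#' @param series A data.frame with `phase`, `time_h`, `cd_ug_per_kg`,
#'   `replicate`, and optionally `wet_weight_mg`.
#' @param exclusions Passed to [fit_depuration()].
#' @param ss_basis Which rate feeds t50/t95: `"k2g"` (default, falls back to
#'   k2 when weights are absent or the correction is invalid) or `"k2"`.
#' @return A list with `k2`, `k2_se`, `r2`, `kg`, `k2g`, `t50_h`, `t95_h`,
#'   `ss_basis_used`, `excluded_points`, `valid`.
#' @export
tk_summary <- function(series, exclusions = NULL, ss_basis = c("k2g", "k2")) {
  ss_basis <- match.arg(ss_basis)
  dep <- fit_depuration(series, exclusions)
  kg <- NA_real_
  if ("wet_weight_mg" %in% names(series) &&
      sum(!is.na(series$wet_weight_mg)) >= 3) {
    kg <- growth_rate(series)$kg
  }
  k2g <- if (is.na(kg)) NA_real_ else growth_correct(dep$k2, kg)$k2g
  k_ss <- if (ss_basis == "k2g" && !is.na(k2g) && k2g > 0) k2g else dep$k2
  basis_used <- if (ss_basis == "k2g" && !is.na(k2g) && k2g > 0) "k2g" else "k2"
  list(
    k2 = dep$k2, k2_se = dep$k2_se, r2 = dep$r2,
    kg = kg, k2g = k2g,
    t50_h = if (dep$valid) time_to_ss(k_ss, 0.5) else NA_real_,
    t95_h = if (dep$valid) time_to_ss(k_ss, 0.95) else NA_real_,
    ss_basis_used = basis_used,
    excluded_points = dep$excluded_points,
    valid = dep$valid
  )
}

#' Read a body-burden time series table
#'
#' CSV with header
#' `chemical_id,phase,time_h,cd_ug_per_kg,replicate,wet_weight_mg`
#' (`wet_weight_mg` may be empty).
#'
#' @param path Path to the CSV file.
#' @return A validated data.frame.
#' @export
read_body_burden <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chemical_id", "phase", "time_h", "cd_ug_per_kg", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("body-burden table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"wet_weight_mg" %in% names(d)) d$wet_weight_mg <- NA_real_
  if (!all(d$phase %in% c("uptake", "depuration"))) {
    stop('`phase` must be "uptake" or "depuration"', call. = FALSE)
  }
  if (any(d$time_h < 0) || any(d$cd_ug_per_kg <= 0)) {
    stop("need time_h >= 0 and cd_ug_per_kg > 0", call. = FALSE)
  }
  d
}
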