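# Deterministic substream seeds: one global integer seed, per-stream offsets.
# Kept below 2^31 - 1 so set.seed() always accepts them.
.substream <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + offset
}

# Lognormal multiplicative noise with a target coefficient of variation and
# unit mean: E[noise] = 1, CV = noise_cv.
.ln_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic body-burden time series
#'
#' One-compartment bioaccumulation under constant exposure: during uptake the
#' mean body burden follows
#' \deqn{C_D(t) = \frac{k_1}{k_2 + k_g} C_W (1 - e^{-(k_2+k_g)t})}
#' (growth dilution enters uptake through the combined constant `k2 + kg`),
#' and during depuration it decays from the end-of-uptake burden at the
#' apparent rate `k2` — the rate a log-linear depuration fit recovers, so the
#' growth-corrected elimination is `k2 - kg`. Wet weights grow exponentially
#' at `kg`. Measurements carry multiplicative lognormal noise with the given
#' CV. Deterministic under `seed`; the uptake-rate constant `k1` exists only
#' here, as a generation parameter — it is never estimated by the analysis.
#'
#' @param k1 Uptake rate constant, L/(kg h) (> 0).
#' @param k2 Apparent depuration rate constant, h^-1 (> 0).
#' @param kg Growth rate constant, h^-1 (>= 0); default 0.
#' @param cw Water concentration, µg/L (> 0).
#' @param noise_cv Measurement CV as a fraction; default 0.15.
#' @param uptake_times Sampling times (h) for the uptake phase; default
#'   24 h intervals over 120 h.
#' @param depuration_times Sampling times (h from depuration start); default
#'   4 points over 96 h.
#' @param n_replicates Replicates (pools of animals) per time point; default 2.
#' @param w0_mg Initial wet weight per pooled sample, mg; default 3.
#' @param chemical_id Identifier; default `"synth"`.
#' @param seed Integer seed.
#' @return A data.frame with columns `chemical_id`, `phase`, `time_h`,
#'   `cd_ug_per_kg`, `replicate`, `wet_weight_mg`. Depuration `time_h` is
#'   relative to the start of depuration.
#' @export
gen_tk_series <- function(k1, k2, kg = 0, cw, noise_cv = 0.15,
                          uptake_times = c(24, 48, 72, 96, 120),
                          depuration_times = c(24, 48, 72, 96),
                          n_replicates = 2, w0_mg = 3,
                          chemical_id = "synth", seed = 1) {
  if (k1 <= 0 || k2 <= 0 || kg < 0 || cw <= 0) {
    stop("rates must be positive (kg >= 0) and cw > 0", call. = FALSE)
  }
  if (is.unsorted(uptake_times, strictly = TRUE) ||
      is.unsorted(depuration_times, strictly = TRUE)) {
    stop("sampling schedules must be strictly increasing", call. = FALSE)
  }
  ktot <- k2 + kg
  up_mean <- k1 / ktot * cw * (1 - exp(-ktot * uptake_times))
  cd_end <- k1 / ktot * cw * (1 - exp(-ktot * max(uptake_times)))
  dep_mean <- cd_end * exp(-k2 * depuration_times)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.substream(seed, 101L))

  mk <- function(phase, times, means, t_offset) {
    do.call(rbind, lapply(seq_len(n_replicates), function(rep_i) {
      data.frame(
        chemical_id = chemical_id,
        phase = phase,
        time_h = times,
        cd_ug_per_kg = means * .ln_noise(length(times), noise_cv),
        replicate = rep_i,
        wet_weight_mg = w0_mg * exp(kg * (times + t_offset)) *
          .ln_noise(length(times), noise_cv / 2)
      )
    }))
  }
  out <- rbind(
    mk("uptake", uptake_times, up_mean, 0),
    mk("depuration", depuration_times, dep_mean, max(uptake_times))
  )
  rownames(out) <- NULL
  out
}

#' Generate synthetic reproduction-test records
#'
#' Controls draw rounded lognormal offspring counts at the configured mean
#' and CV (defaults chosen so generated controls pass the OECD-211 validity
#' criteria: mean 75 > 60, CV 10% < 15%). Treated replicates scale the
#' control mean by `1 - inhibition(conc)/100` from a true 4PL inhibition
#' curve, with the same multiplicative noise, floored at zero and rounded.
#' Parent deaths are Bernoulli in the treated levels only (emulating
#' exposure-related mortality); control mothers always survive, so default
#' parameters always satisfy the validity criteria.
#'
#' @param control_mean Mean cumulative live offspring per control mother;
#'   default 75.
#' @param control_cv Control CV as a fraction; default 0.10.
#' @param true_params Named vector/list with `bottom`, `top`, `log10_ec50`,
#'   `hill` of the true inhibition curve (percent scale).
#' @param conc Concentration grid, µg/L (>= 5 non-zero levels); default a
#'   7-level geometric series spanning 1.5 decades either side of the true
#'   EC50.
#' @param n_replicates Mothers per level (controls included); default 10.
#' @param mortality_p Per-mother death probability in treated levels;
#'   default 0.02.
#' @param chemical_id Identifier; default `"synth"`.
#' @param seed Integer seed.
#' @return A data.frame with columns `chemical_id`, `conc_ug_per_L`,
#'   `replicate`, `offspring`, `parent_dead` (controls at conc 0).
#' @export
gen_reproduction <- function(control_mean = 75, control_cv = 0.10,
                             true_params = c(bottom = 0, top = 100,
                                             log10_ec50 = log10(5), hill = 1.2),
                             conc = NULL, n_replicates = 10,
                             mortality_p = 0.02,
                             chemical_id = "synth", seed = 1) {
  p <- as.list(true_params)
  if (is.null(conc)) {
    conc <- 10^(p$log10_ec50 + seq(-1.5, 1.5, length.out = 7))
  }
  conc <- sort(unique(conc[conc > 0]))
  if (length(conc) < 5) stop("need >= 5 non-zero concentrations", call. = FALSE)

  inhibition <- function(cc) {
    p$bottom + (p$top - p$bottom) /
      (1 + 10^((p$log10_ec50 - log10(cc)) * p$hill))
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.substream(seed, 202L))

  all_conc <- c(0, conc)
  out <- do.call(rbind, lapply(all_conc, function(cc) {
    mu <- if (cc == 0) control_mean else {
      control_mean * (1 - inhibition(cc) / 100)
    }
    counts <- if (mu <= 0) rep(0, n_replicates) else {
      round(pmax(0, mu * .ln_noise(n_replicates, control_cv)))
    }
    data.frame(
      chemical_id = chemical_id,
      conc_ug_per_L = cc,
      replicate = seq_len(n_replicates),
      offspring = as.integer(counts),
      parent_dead = cc > 0 & stats::runif(n_replicates) < mortality_p
    )
  }))
  rownames(out) <- NULL
  out
}

#' Generate synthetic cross-species BCF-k2 scatter
#'
#' Draws `log_k2` uniformly over `x_range` and sets
#' `log_bcf_l5 = slope * log_k2 + intercept + N(0, sigma)`, emulating a
#' literature compilation around a known regression line.
#'
#' @param line A `regression_line` (or list with `slope`, `intercept`).
#' @param sigma Residual SD on the log BCF scale.
#' @param n Number of records (>= 3).
#' @param x_range Range of log10 k2; default `c(-3, 0)`.
#' @param species_group Label; default `"daphnia"`.
#' @param log_kow_range Range for an accompanying log K_OW column; default
#'   `c(4, 7)`.
#' @param seed Integer seed.
#' @return A data.frame with columns `species_group`, `chemical`, `log_kow`,
#'   `log_bcf_l5`, `log_k2`, `bcf_type`.
#' @export
gen_bcf_k2 <- function(line, sigma, n, x_range = c(-3, 0),
                       species_group = "daphnia", log_kow_range = c(4, 7),
                       seed = 1) {
  if (n < 3) stop("need n >= 3", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.substream(seed, 303L))
  x <- stats::runif(n, x_range[1], x_range[2])
  y <- line$slope * x + line$intercept + stats::rnorm(n, 0, sigma)
  data.frame(
    species_group = species_group,
    chemical = sprintf("synth_%02d", seq_len(n)),
    log_kow = stats::runif(n, log_kow_range[1], log_kow_range[2]),
    log_bcf_l5 = y,
    log_k2 = x,
    bcf_type = "kinetic",
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic exposure-water measurements
#'
#' Initial and final water concentrations over media-change cycles, lognormal
#' around the nominal level with the given CV; an optional `decline` factor
#' multiplies final concentrations to emulate dosing failure.
#'
#' @param levels Named numeric vector of nominal concentrations µg/L (names
#'   become `level_id`).
#' @param n_cycles Media-change cycles; default 6 (12 measurements per level,
#'   matching a 21-day test with 2-3 day renewals).
#' @param cv Measurement CV as a fraction; default 0.07.
#' @param decline Multiplier on final-stage means; default 1 (stable dosing).
#' @param chemical_id Identifier; default `"synth"`.
#' @param seed Integer seed.
#' @return A data.frame with columns `chemical_id`, `level_id`, `cycle`,
#'   `stage`, `cw_ug_per_L`.
#' @export
gen_exposure <- function(levels, n_cycles = 6, cv = 0.07, decline = 1,
                         chemical_id = "synth", seed = 1) {
  if (is.null(names(levels))) names(levels) <- paste0("L", seq_along(levels))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.substream(seed, 404L))
  out <- do.call(rbind, lapply(names(levels), function(lv) {
    nom <- levels[[lv]]
    do.call(rbind, lapply(seq_len(n_cycles), function(cy) {
      data.frame(
        chemical_id = chemical_id,
        level_id = lv,
        cycle = cy,
        stage = c("initial", "final"),
        cw_ug_per_L = c(nom * .ln_noise(1, cv),
                        nom * decline * .ln_noise(1, cv))
      )
    }))
  }))
  rownames(out) <- NULL
  out
}
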