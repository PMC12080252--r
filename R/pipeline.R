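#' Run the full assessment pipeline from a single configuration
#'
#' Executes the stages in order — exposure QC, dose-response, toxicokinetics,
#' B/vB classification, risk screening — each stage writing its outputs
#' before the next runs. Outputs are pure functions of the inputs and the
#' configuration (the seed is recorded in the report), so a rerun with the
#' same config produces identical report bodies.
#'
#' @param config Either a path to a YAML file or a list, with elements:
#'   \describe{
#'     \item{schema_version}{Config schema tag (currently 1).}
#'     \item{paths}{Named list: `chemicals`, `exposure`, `reproduction`,
#'       `body_burden` — CSV paths (see the `read_*` functions for dialects);
#'       `exposure` is optional.}
#'     \item{out_dir}{Directory for stage outputs.}
#'     \item{options}{`f_lipid` (default 0.015), `af` (100), `n_boot` (1000),
#'       `seed` (1), `temperature_K` (293.15), `threshold_source` (`"daphnia"`,
#'       `"hyalella"` or `"fish"`), `ss_basis` (`"k2g"`), `exclusions` (named
#'       list: chemical_id -> vector of depuration `time_h` to drop),
#'       `mec` (named list: chemical_id -> environmental concentration µg/L).}
#'   }
#' @param quiet Suppress per-stage log lines; default FALSE.
#' @return Invisibly, the consolidated report (a list; also written as
#'   `report.json` and `report.md` under `out_dir`).
#' @export
run_all <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .normalize_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  report <- list(schema_version = cfg$schema_version,
                 seed = cfg$options$seed, options = cfg$options)

  chems <- stage("chemicals", read_chemicals(cfg$paths$chemicals))
  log_line("chemicals: %d entries", nrow(chems))

  # --- stage 1: exposure QC ------------------------------------------------
  if (!is.null(cfg$paths$exposure)) {
    report$exposure <- stage("exposure_qc", {
      meas <- read_exposure(cfg$paths$exposure)
      summ <- summarize_exposure(meas)
      keys <- unique(meas[c("chemical_id", "level_id")])
      stab <- lapply(seq_len(nrow(keys)), function(i) {
        stability_test(meas, keys$level_id[i], keys$chemical_id[i])
      })
      summ$stability <- vapply(stab, `[[`, character(1), "status")
      utils::write.csv(summ, file.path(cfg$out_dir, "exposure_summary.csv"),
                       row.names = FALSE)
      log_line("exposure_qc: %d measurements, %d levels, CV %.1f-%.1f%%",
               nrow(meas), nrow(summ),
               min(summ$cv_pct, na.rm = TRUE), max(summ$cv_pct, na.rm = TRUE))
      summ
    })
  }

  # --- stage 2: dose-response ---------------------------------------------
  report$dose_response <- stage("dose_response", {
    rec <- read_reproduction(cfg$paths$reproduction)
    out <- lapply(split(rec, rec$chemical_id), function(r) {
      vr <- validity_check(r)
      inh <- percent_inhibition(r)
      fit <- fit_4pl(inh)
      res <- list(chemical_id = r$chemical_id[1],
                  validity = unclass(vr),
                  params = as.list(fit$params), r2 = fit$r2,
                  converged = fit$converged)
      if (fit$converged) {
        cis <- lapply(c(10, 20, 50), function(xx) {
          ecx_ci(fit, xx, n_boot = cfg$options$n_boot, seed = cfg$options$seed)
        })
        res$ecx <- data.frame(
          x = vapply(cis, `[[`, numeric(1), "x"),
          estimate_ug_per_L = vapply(cis, `[[`, numeric(1), "estimate_ug_per_L"),
          ci_low = vapply(cis, `[[`, numeric(1), "ci_low"),
          ci_high = vapply(cis, `[[`, numeric(1), "ci_high"),
          extrapolated = fit$ecx$extrapolated[match(c(10, 20, 50), fit$ecx$x)]
        )
        ch <- chems[chems$id == r$chemical_id[1], ]
        if (nrow(ch) == 1) {
          s_l <- subcooled_solubility(ch$sw, ch$tm, cfg$options$temperature_K)
          ec50_nmol <- to_molar(res$ecx$estimate_ug_per_L[res$ecx$x == 50], ch$mw)
          res$activity <- unclass(effective_activity(ec50_nmol, s_l, "chronic",
                                                     chemical_id = ch$id))
          ec10_mmol <- to_molar(res$ecx$estimate_ug_per_L[res$ecx$x == 10], ch$mw) * 1e-6
          res$ctlbb_umol_per_g <- ctlbb(ec10_mmol, ch$log_kow)
          res$ecx$estimate_nmol_per_L <- to_molar(res$ecx$estimate_ug_per_L, ch$mw)
        }
      }
      res
    })
    ecx_tab <- do.call(rbind, lapply(out, function(o) {
      if (is.null(o$ecx)) return(NULL)
      cbind(chemical_id = o$chemical_id, o$ecx)
    }))
    if (!is.null(ecx_tab)) {
      utils::write.csv(ecx_tab, file.path(cfg$out_dir, "ecx.csv"),
                       row.names = FALSE)
    }
    log_line("dose_response: %d chemicals fit", length(out))
    out
  })

  # --- stage 3: toxicokinetics --------------------------------------------
  report$toxicokinetics <- stage("toxicokinetics", {
    bb <- read_body_burden(cfg$paths$body_burden)
    out <- lapply(split(bb, bb$chemical_id), function(s) {
      id <- s$chemical_id[1]
      excl <- cfg$options$exclusions[[id]]
      tk <- tk_summary(s, exclusions = if (!is.null(excl)) list(time_h = excl),
                       ss_basis = cfg$options$ss_basis)
      up <- s[s$phase == "uptake", ]
      t_end <- max(up$time_h)
      cd_end <- mean(up$cd_ug_per_kg[up$time_h == t_end])
      cw <- cfg$options$cw[[id]]
      bafres <- if (!is.null(cw)) {
        unclass(baf(cd_end, cw, f_lipid = cfg$options$f_lipid,
                    steady_state_reached = isTRUE(tk$t95_h <= t_end)))
      }
      c(list(chemical_id = id), tk, list(baf = bafres))
    })
    tk_tab <- do.call(rbind, lapply(out, function(o) {
      data.frame(chemical_id = o$chemical_id, k2 = o$k2, kg = o$kg,
                 k2g = o$k2g, t50_h = o$t50_h, t95_h = o$t95_h, r2 = o$r2,
                 log_baf_l5 = if (!is.null(o$baf)) o$baf$log_baf_l5 else NA_real_)
    }))
    utils::write.csv(tk_tab, file.path(cfg$out_dir, "tk_fits.csv"),
                     row.names = FALSE)
    log_line("toxicokinetics: %d chemicals, k2 %.3g-%.3g h^-1",
             nrow(tk_tab), min(tk_tab$k2), max(tk_tab$k2))
    out
  })

  # --- stage 4: classification --------------------------------------------
  report$classification <- stage("classification", {
    thr <- b_thresholds(cfg$options$threshold_source)
    cls <- lapply(report$toxicokinetics, function(o) {
      k <- if (!is.na(o$k2g) && o$k2g > 0) o$k2g else o$k2
      list(chemical_id = o$chemical_id, k2_used = k,
           category = classify_k2(k, thr))
    })
    log_line("classification (%s thresholds): %s", thr$species_group,
             paste(vapply(cls, function(x)
             sprintf("%s=%s", x$chemical_id, x$category), character(1)),
             collapse = ", "))
    list(thresholds = unclass(thr), chemicals = cls)
  })

  # --- stage 5: risk -------------------------------------------------------
  report$risk <- stage("risk", {
    out <- lapply(report$dose_response, function(o) {
      if (is.null(o$ecx)) return(NULL)
      ec10 <- o$ecx$estimate_ug_per_L[o$ecx$x == 10]
      if (!length(ec10) || is.na(ec10)) return(NULL)
      ch <- chems[chems$id == o$chemical_id, ]
      unclass(risk_screen(
        ec10, af = cfg$options$af,
        mec = cfg$options$mec[[o$chemical_id]],
        mw = if (nrow(ch) == 1) ch$mw,
        chemical_id = o$chemical_id
      ))
    })
    out <- Filter(Negate(is.null), out)
    log_line("risk: %d chemicals screened (AF %g)", length(out),
             cfg$options$af)
    out
  })

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  writeLines(.report_md(report), file.path(cfg$out_dir, "report.md"))
  invisible(report)
}

.normalize_config <- function(config) {
  if (is.null(config$paths)) stop("config needs a `paths` block", call. = FALSE)
  for (p in c("chemicals", "reproduction", "body_burden")) {
    if (is.null(config$paths[[p]])) {
      stop(sprintf("config paths must include `%s`", p), call. = FALSE)
    }
    if (!file.exists(config$paths[[p]])) {
      stop(sprintf("input file for `%s` not found: %s", p, config$paths[[p]]),
           call. = FALSE)
    }
  }
  if (!is.null(config$paths$exposure) && !file.exists(config$paths$exposure)) {
    stop("exposure file not found: ", config$paths$exposure, call. = FALSE)
  }
  opts <- config$options
  defaults <- list(f_lipid = 0.015, af = 100, n_boot = 1000, seed = 1,
                   temperature_K = 293.15, threshold_source = "daphnia",
                   ss_basis = "k2g", exclusions = list(), mec = list(),
                   cw = list())
  for (nm in names(defaults)) {
    if (is.null(opts[[nm]])) opts[[nm]] <- defaults[[nm]]
  }
  list(schema_version = if (is.null(config$schema_version)) 1L else config$schema_version,
       paths = config$paths,
       out_dir = if (is.null(config$out_dir)) "daphtk_out" else config$out_dir,
       options = opts)
}

.report_md <- function(report) {
  lines <- c("# Assessment report", "",
             sprintf("Seed: %d; thresholds: %s; AF: %g; f_lipid: %.3f",
                     report$seed, report$options$threshold_source,
                     report$options$af, report$options$f_lipid), "")
  if (!is.null(report$dose_response)) {
    lines <- c(lines, "## Dose-response", "")
    for (o in report$dose_response) {
      if (is.null(o$ecx)) next
      lines <- c(lines, sprintf(
        "- %s: EC10 %.3g, EC20 %.3g, EC50 %.3g ug/L (valid test: %s)",
        o$chemical_id,
        o$ecx$estimate_ug_per_L[o$ecx$x == 10],
        o$ecx$estimate_ug_per_L[o$ecx$x == 20],
        o$ecx$estimate_ug_per_L[o$ecx$x == 50],
        o$validity$valid))
    }
  }
  if (!is.null(report$toxicokinetics)) {
    lines <- c(lines, "", "## Toxicokinetics", "")
    for (o in report$toxicokinetics) {
      lines <- c(lines, sprintf(
        "- %s: k2 %.3g h^-1, k2g %.3g h^-1, t50 %.3g h%s",
        o$chemical_id, o$k2, o$k2g, o$t50_h,
        if (!is.null(o$baf)) sprintf(", log BAF*_L5%% %.2f", o$baf$log_baf_l5)
        else ""))
    }
  }
  if (!is.null(report$classification)) {
    lines <- c(lines, "", "## B/vB classification", "")
    for (o in report$classification$chemicals) {
      lines <- c(lines, sprintf("- %s: %s (k2 %.3g h^-1)",
                                o$chemical_id, o$category, o$k2_used))
    }
  }
  if (!is.null(report$risk)) {
    lines <- c(lines, "", "## Risk screen", "")
    for (o in report$risk) {
      lines <- c(lines, sprintf(
        "- %s: PNEC %.3g ug/L%s; REACH toxic: %s",
        o$chemical_id, o$pnec_ug_per_L,
        if (!is.na(o$rq)) sprintf(", RQ %.3g", o$rq) else "",
        o$reach_toxic))
    }
  }
  lines
}
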