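#' Summarize measured water concentrations per exposure level
#'
#' Passive dosing is meant to hold the freely dissolved water concentration
#' constant across media-change cycles; this summarizes all measurements
#' (initial and final pooled) per exposure level as mean, SD and coefficient
#' of variation.
#'
#' @param measurements A data.frame with columns `chemical_id`, `level_id`,
#'   `cycle` (integer >= 1), `stage` (`"initial"` or `"final"`) and
#'   `cw_ug_per_L` (>= 0).
#' @return A data.frame with one row per (`chemical_id`, `level_id`):
#'   `n`, `mean_ug_per_L`, `sd_ug_per_L`, `cv_pct`, and `flagged`
#'   (TRUE when fewer than 2 measurements were available, in which case the
#'   summary statistics are NA).
#' @export
summarize_exposure <- function(measurements) {
  m <- .check_exposure(measurements)
  keys <- unique(m[c("chemical_id", "level_id")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- m[m$chemical_id == keys$chemical_id[i] & m$level_id == keys$level_id[i], ]
    n <- nrow(sub)
    if (n < 2) {
      data.frame(chemical_id = keys$chemical_id[i], level_id = keys$level_id[i],
                 n = n, mean_ug_per_L = NA_real_, sd_ug_per_L = NA_real_,
                 cv_pct = NA_real_, flagged = TRUE)
    } else {
      mu <- mean(sub$cw_ug_per_L)
      s <- stats::sd(sub$cw_ug_per_L)
      data.frame(chemical_id = keys$chemical_id[i], level_id = keys$level_id[i],
                 n = n, mean_ug_per_L = mu, sd_ug_per_L = s,
                 cv_pct = if (mu > 0) 100 * s / mu else NA_real_,
                 flagged = FALSE)
    }
  }))
  rownames(out) <- NULL
  out
}

#' Test an exposure level for a systematic concentration decline
#'
#' Compares final (end of a media-change cycle, just before renewal) against
#' initial (freshly dosed) water concentrations with a one-sided Welch
#' two-sample t-test. Only losses threaten the dosing system, so the
#' alternative is "final < initial"; a decline is flagged when the final mean
#' is lower and p < 0.05.
#'
#' @param measurements As in [summarize_exposure()].
#' @param level_id The exposure level to test.
#' @param chemical_id Optional chemical filter (required when `measurements`
#'   holds several chemicals sharing level tokens).
#' @param alpha Significance level; default 0.05.
#' @return A list with `status` (`"ok"`, `"decline"` or `"inconclusive"`),
#'   `p_value`, `statistic`, `mean_initial`, `mean_final`, `n_initial`,
#'   `n_final`.
#' @export
stability_test <- function(measurements, level_id, chemical_id = NULL,
                           alpha = 0.05) {
  m <- .check_exposure(measurements)
  m <- m[m$level_id == level_id, ]
  if (!is.null(chemical_id)) m <- m[m$chemical_id == chemical_id, ]
  ini <- m$cw_ug_per_L[m$stage == "initial"]
  fin <- m$cw_ug_per_L[m$stage == "final"]
  base <- list(
    level_id = level_id,
    mean_initial = if (length(ini)) mean(ini) else NA_real_,
    mean_final = if (length(fin)) mean(fin) else NA_real_,
    n_initial = length(ini), n_final = length(fin)
  )
  if (length(ini) < 2 || length(fin) < 2) {
    return(c(list(status = "inconclusive", p_value = NA_real_,
                  statistic = NA_real_), base))
  }
  if (stats::sd(ini) == 0 && stats::sd(fin) == 0) {
    # degenerate: no variance; compare means directly
    declined <- mean(fin) < mean(ini)
    return(c(list(status = if (declined) "decline" else "ok",
                  p_value = if (declined) 0 else 1, statistic = NA_real_),
             base))
  }
  tt <- stats::t.test(fin, ini, alternative = "less", var.equal = FALSE)
  declined <- mean(fin) < mean(ini) && tt$p.value < alpha
  c(list(status = if (declined) "decline" else "ok",
         p_value = tt$p.value, statistic = unname(tt$statistic)), base)
}

#' Read an exposure measurement table
#'
#' CSV with header `chemical_id,level_id,cycle,stage,cw_ug_per_L`.
#'
#' @param path Path to the CSV file.
#' @return A validated data.frame of exposure measurements.
#' @export
read_exposure <- function(path) {
  .check_exposure(utils::read.csv(path, stringsAsFactors = FALSE))
}

.check_exposure <- function(m) {
  need <- c("chemical_id", "level_id", "cycle", "stage", "cw_ug_per_L")
  miss <- setdiff(need, names(m))
  if (length(miss)) {
    stop("exposure table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(m$stage %in% c("initial", "final"))) {
    stop('`stage` must be "initial" or "final"', call. = FALSE)
  }
  if (any(m$cw_ug_per_L < 0)) stop("`cw_ug_per_L` must be >= 0", call. = FALSE)
  if (any(m$cycle < 1)) stop("`cycle` must be >= 1", call. = FALSE)
  m
}
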