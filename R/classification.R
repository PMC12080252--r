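#' Published log-linear regression lines for bioaccumulation screening
#'
#' Regression coefficients relating lipid-normalized log BCF (5% lipid) to
#' either log K_OW or log k2 (log10 of the depuration rate constant, h^-1)
#' in fish, Daphnia sp. and Hyalella azteca, as reported from literature
#' compilations. Shipped as named constants so threshold arithmetic is
#' reproducible without the underlying literature table (the packaged species
#' dataset generator is synthetic).
#'
#' `bcf_k2_lines`: log BCF_L5% vs log k2 — daphnia (slope -1.41, intercept
#' 2.85, R2 0.90, n 14), hyalella (-1.16, 1.64, R2 0.49, n 25), fish (-1.19,
#' 0.66, R2 0.78, n 169).
#'
#' `kow_bcf_lines`: log BCF_L5% vs log K_OW — fish (0.58, -0.15, R2 0.67,
#' n 169), hyalella (0.72, -0.33, R2 0.78, n 25), daphnia (0.86, -0.80,
#' R2 0.90, n 45).
#'
#' `fish_k2_thresholds_uk_ea`: fish depuration-rate thresholds derived by the
#' UK Environment Agency: k2 <= 0.0059 h^-1 for B, <= 0.0027 h^-1 for vB.
#'
#' @format Lists of `regression_line` objects / named numeric vectors.
#' @name reference_lines
NULL

#' Construct a regression line object
#'
#' @param slope,intercept Coefficients of `y = slope * x + intercept`.
#' @param r2 Coefficient of determination in `[0, 1]`.
#' @param n Number of observations (>= 3).
#' @return An object of class `regression_line`.
#' @export
regression_line <- function(slope, intercept, r2 = NA_real_, n = NA_integer_) {
  if (!is.na(r2) && (r2 < 0 || r2 > 1)) stop("`r2` must lie in [0, 1]", call. = FALSE)
  if (!is.na(n) && n < 3) stop("`n` must be >= 3", call. = FALSE)
  structure(list(slope = slope, intercept = intercept, r2 = r2, n = n),
            class = "regression_line")
}

#' @export
print.regression_line <- function(x, ...) {
  cat(sprintf("y = %.4g x + %.4g (R2 = %.3g, n = %s)\n",
              x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' @rdname reference_lines
#' @export
bcf_k2_lines <- list(
  daphnia  = regression_line(-1.41, 2.85, r2 = 0.90, n = 14),
  hyalella = regression_line(-1.16, 1.64, r2 = 0.49, n = 25),
  fish     = regression_line(-1.19, 0.66, r2 = 0.78, n = 169)
)

#' @rdname reference_lines
#' @export
kow_bcf_lines <- list(
  fish     = regression_line(0.58, -0.15, r2 = 0.67, n = 169),
  hyalella = regression_line(0.72, -0.33, r2 = 0.78, n = 25),
  daphnia  = regression_line(0.86, -0.80, r2 = 0.90, n = 45)
)

#' @rdname reference_lines
#' @export
fish_k2_thresholds_uk_ea <- c(k2_b = 0.0059, k2_vb = 0.0027)

#' Ordinary least-squares log-linear regression over species BCF records
#'
#' @param records A data.frame of literature-style observations, e.g. with
#'   columns `species_group`, `chemical`, `log_kow`, `log_bcf_l5`, `log_k2`,
#'   `bcf_type`.
#' @param x_field,y_field Column names for predictor and response (already on
#'   log scales).
#' @param exclude Optional logical vector or chemical names to drop before
#'   fitting (e.g. records whose t95 exceeded the uptake duration); exclusions
#'   are recorded in the result.
#' @return A `regression_line` with an extra `excluded` attribute listing the
#'   dropped chemicals.
#' @export
fit_loglinear <- function(records, x_field = "log_k2", y_field = "log_bcf_l5",
                          exclude = NULL) {
  r <- records
  dropped <- character()
  if (!is.null(exclude)) {
    if (is.logical(exclude)) {
      dropped <- as.character(r$chemical[exclude])
      r <- r[!exclude, ]
    } else {
      dropped <- as.character(exclude)
      r <- r[!(r$chemical %in% exclude), ]
    }
  }
  x <- r[[x_field]]; y <- r[[y_field]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 records with both fields", call. = FALSE)
  if (stats::var(x) == 0) stop("degenerate predictor: zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  line <- regression_line(
    slope = unname(stats::coef(fit)["x"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    r2 = suppressWarnings(summary(fit))$r.squared,
    n = length(x)
  )
  attr(line, "excluded") <- dropped
  line
}

#' Invert a BCF-k2 regression into a depuration-rate threshold
#'
#' Given a fitted line `log10 BCF_L5% = slope * log10 k2 + intercept` with
#' negative slope (slower depuration means higher accumulation), the
#' depuration rate corresponding to a regulatory BCF criterion is
#' \deqn{k_2 = 10^{(\log_{10} BCF_{crit} - intercept)/slope}}
#' A chemical depurating no faster than this threshold meets the criterion.
#'
#' @param line A `regression_line` (or list with `slope`, `intercept`).
#' @param bcf_crit BCF criterion in L/kg (> 0); REACH uses 2000 (B) and
#'   5000 (vB).
#' @return k2 threshold in h^-1.
#' @export
#' @examples
#' k2_threshold(bcf_k2_lines$daphnia, 2000)  # ~0.48 h^-1
#' k2_threshold(bcf_k2_lines$daphnia, 5000)  # ~0.25 h^-1
k2_threshold <- function(line, bcf_crit) {
  if (!is.finite(line$slope) || line$slope >= 0) {
    stop("inversion requires a negative slope", call. = FALSE)
  }
  if (any(!is.finite(bcf_crit)) || any(bcf_crit <= 0)) {
    stop("`bcf_crit` must be > 0 (L/kg)", call. = FALSE)
  }
  10^((log10(bcf_crit) - line$intercept) / line$slope)
}

#' Organism-specific B/vB depuration-rate thresholds
#'
#' @param species_group `"daphnia"`, `"hyalella"` or `"fish"`. For fish the
#'   default source is the UK Environment Agency literature values; the
#'   regression inversion is available via `fish_source = "regression"`.
#' @param bcf_b,bcf_vb BCF criteria in L/kg; REACH defaults 2000 and 5000.
#' @param line Optional `regression_line` overriding the shipped one.
#' @param fish_source `"uk_ea"` (default) or `"regression"`.
#' @return A list of class `b_thresholds` with `species_group`, `k2_b`,
#'   `k2_vb` (h^-1) and `t50_b`, `t50_vb` (h).
#' @export
b_thresholds <- function(species_group = c("daphnia", "hyalella", "fish"),
                         bcf_b = 2000, bcf_vb = 5000, line = NULL,
                         fish_source = c("uk_ea", "regression")) {
  species_group <- match.arg(species_group)
  fish_source <- match.arg(fish_source)
  if (bcf_vb <= bcf_b) stop("`bcf_vb` must exceed `bcf_b`", call. = FALSE)
  if (species_group == "fish" && is.null(line) && fish_source == "uk_ea") {
    k2_b <- fish_k2_thresholds_uk_ea[["k2_b"]]
    k2_vb <- fish_k2_thresholds_uk_ea[["k2_vb"]]
  } else {
    if (is.null(line)) line <- bcf_k2_lines[[species_group]]
    k2_b <- k2_threshold(line, bcf_b)
    k2_vb <- k2_threshold(line, bcf_vb)
  }
  structure(
    list(species_group = species_group, k2_b = k2_b, k2_vb = k2_vb,
         t50_b = log(2) / k2_b, t50_vb = log(2) / k2_vb),
    class = "b_thresholds"
  )
}

#' @export
print.b_thresholds <- function(x, ...) {
  cat(sprintf(
    "%s: B at k2 <= %.3g h^-1 (t50 %.3g h); vB at k2 <= %.3g h^-1 (t50 %.3g h)\n",
    x$species_group, x$k2_b, x$t50_b, x$k2_vb, x$t50_vb
  ))
  invisible(x)
}

#' Classify a depuration rate against B/vB thresholds
#'
#' Inclusive bounds: `vB` when `k2 <= k2_vb`, else `B` when `k2 <= k2_b`,
#' else `not_B`. Slower depuration can only raise the category.
#'
#' @param k2 Depuration rate constant, h^-1 (> 0). Vectorized.
#' @param thresholds A [b_thresholds()] result (or list with `k2_b`, `k2_vb`).
#' @return Character vector of labels `"not_B"`, `"B"` or `"vB"`.
#' @export
classify_k2 <- function(k2, thresholds) {
  if (any(!is.finite(k2)) || any(k2 <= 0)) stop("`k2` must be > 0", call. = FALSE)
  if (thresholds$k2_vb >= thresholds$k2_b) {
    stop("thresholds must satisfy k2_vb < k2_b", call. = FALSE)
  }
  ifelse(k2 <= thresholds$k2_vb, "vB",
         ifelse(k2 <= thresholds$k2_b, "B", "not_B"))
}

#' Fish-invertebrate bioaccumulation concordance
#'
#' Counts chemicals by accumulation quadrant, pairing fish and invertebrate
#' lipid-normalized log BCF values, using an inclusive threshold (default
#' log10 BCF 3.3, i.e. BCF ~2000 L/kg) on both axes.
#'
#' @param pairs A data.frame with columns `chemical`, `log_bcf_fish` and
#'   `log_bcf_invert`.
#' @param crit log10 BCF threshold; default 3.3, inclusive (>=) on both axes.
#' @return A list with `counts` (named: `both`, `fish_only`, `invert_only`,
#'   `neither`), `agreement_pct` and `n`.
#' @export
concordance <- function(pairs, crit = 3.3) {
  need <- c("log_bcf_fish", "log_bcf_invert")
  if (!all(need %in% names(pairs))) {
    stop("`pairs` needs columns log_bcf_fish and log_bcf_invert", call. = FALSE)
  }
  if (nrow(pairs) < 1) stop("need >= 1 pair", call. = FALSE)
  f <- pairs$log_bcf_fish >= crit
  i <- pairs$log_bcf_invert >= crit
  counts <- c(both = sum(f & i), fish_only = sum(f & !i),
              invert_only = sum(!f & i), neither = sum(!f & !i))
  list(counts = counts,
       agreement_pct = 100 * (counts[["both"]] + counts[["neither"]]) / nrow(pairs),
       n = nrow(pairs))
}

#' Read a cross-species BCF literature table
#'
#' CSV with header `species_group,chemical,log_kow,log_bcf_l5,log_k2,bcf_type`
#' (`log_k2` may be empty).
#'
#' @param path Path to the CSV file.
#' @return A validated data.frame.
#' @export
read_species_bcf <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_group", "chemical", "log_kow", "log_bcf_l5", "bcf_type")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("species table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"log_k2" %in% names(d)) d$log_k2 <- NA_real_
  if (!all(d$species_group %in% c("fish", "daphnia", "hyalella", "other"))) {
    stop("`species_group` must be fish/daphnia/hyalella/other", call. = FALSE)
  }
  if (any(!is.finite(d$log_bcf_l5))) {
    stop("`log_bcf_l5` must be finite", call. = FALSE)
  }
  d
}
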