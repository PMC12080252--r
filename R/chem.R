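#' Convert a mass concentration to a molar concentration
#'
#' Internal calculations are molar (nmol/L); mass units (µg/L) appear only at
#' the I/O boundary.
#'
#' @param conc Mass concentration in µg/L (non-negative).
#' @param mw Molar mass in g/mol (strictly positive).
#' @return Molar concentration in nmol/L.
#' @seealso [to_mass()] for the inverse.
#' @export
#' @examples
#' to_molar(1, 1000)  # 1 nmol/L
to_molar <- function(conc, mw) {
  if (any(!is.finite(mw)) || any(mw <= 0)) {
    stop("`mw` must be a positive molar mass in g/mol", call. = FALSE)
  }
  if (any(conc < 0, na.rm = TRUE)) {
    stop("`conc` must be non-negative", call. = FALSE)
  }
  conc / mw * 1000
}

#' Convert a molar concentration to a mass concentration
#'
#' @param conc Molar concentration in nmol/L (non-negative).
#' @param mw Molar mass in g/mol (strictly positive).
#' @return Mass concentration in µg/L.
#' @export
to_mass <- function(conc, mw) {
  if (any(!is.finite(mw)) || any(mw <= 0)) {
    stop("`mw` must be a positive molar mass in g/mol", call. = FALSE)
  }
  if (any(conc < 0, na.rm = TRUE)) {
    stop("`conc` must be non-negative", call. = FALSE)
  }
  conc * mw / 1000
}

#' Subcooled liquid solubility
#'
#' Solids below their melting point have an aqueous solubility lower than
#' their hypothetical liquid state would; chemical activities are referenced
#' to the liquid state, so the solid solubility is corrected upward using the
#' Walden-rule entropy-of-fusion approximation:
#' \deqn{S_L = S_W \exp\{6.79\,(T_M/T - 1)\}}{S_L = S_W * exp(6.79 * (Tm/T - 1))}
#' For chemicals that are liquid at the test temperature (\code{tm <= t}) the
#' correction is the identity.
#'
#' @param sw Water solubility in nmol/L (non-negative).
#' @param tm Melting point in K.
#' @param t Test temperature in K; default 293.15 K.
#' @return Subcooled liquid solubility in nmol/L; always \code{>= sw}.
#' @export
subcooled_solubility <- function(sw, tm, t = 293.15) {
  if (any(!is.finite(tm)) || any(tm <= 0) || any(!is.finite(t)) || any(t <= 0)) {
    stop("temperatures must be positive and finite (K)", call. = FALSE)
  }
  if (any(sw < 0, na.rm = TRUE)) {
    stop("`sw` must be non-negative", call. = FALSE)
  }
  ifelse(tm <= t, sw, sw * exp(6.79 * (tm / t - 1)))
}

# Baseline-toxicity activity bands (dimensionless chemical activity); chronic
# narcosis occupies 0.001-0.01, acute 0.01-0.1. Bounds inclusive.
.activity_bands <- list(
  chronic = c(low = 0.001, high = 0.01),
  acute   = c(low = 0.01,  high = 0.1)
)

#' Effective chemical activity of an effect concentration
#'
#' The effective activity EA is the effect concentration divided by the
#' subcooled liquid solubility, a thermodynamic measure on which baseline
#' (narcosis) toxicity occupies a characteristic band: 0.001–0.01 for chronic
#' endpoints and 0.01–0.1 for acute endpoints. Band bounds are inclusive;
#' a value lying exactly on a bound is reported with a tie note.
#'
#' @param ecx Effect concentration in nmol/L (non-negative).
#' @param s_l Subcooled liquid solubility in nmol/L (strictly positive).
#' @param endpoint `"chronic"` (default) or `"acute"`; selects the baseline
#'   band used to interpret the activity.
#' @param chemical_id Optional identifier carried into the result.
#' @return An object of class `activity_result`: a list with `chemical_id`,
#'   `s_l`, `ea`, `endpoint`, `band` (`"below"`, `"baseline"` or `"above"`)
#'   and `tie` (TRUE when `ea` sits exactly on a band bound).
#' @export
#' @examples
#' effective_activity(ecx = 5, s_l = 1000)  # ea 0.005, chronic baseline
effective_activity <- function(ecx, s_l, endpoint = c("chronic", "acute"),
                               chemical_id = NA_character_) {
  endpoint <- match.arg(endpoint)
  if (!is.finite(s_l) || s_l <= 0) {
    stop("`s_l` must be a positive solubility (nmol/L)", call. = FALSE)
  }
  if (!is.finite(ecx) || ecx < 0) {
    stop("`ecx` must be non-negative (nmol/L)", call. = FALSE)
  }
  ea <- ecx / s_l
  b <- .activity_bands[[endpoint]]
  band <- if (ea < b[["low"]]) "below" else if (ea > b[["high"]]) "above" else "baseline"
  structure(
    list(
      chemical_id = chemical_id,
      s_l = s_l,
      ea = ea,
      endpoint = endpoint,
      band = band,
      tie = isTRUE(ea == b[["low"]] || ea == b[["high"]])
    ),
    class = "activity_result"
  )
}

#' @export
print.activity_result <- function(x, ...) {
  cat(sprintf(
    "Effective activity (%s endpoint): EA = %.4g -> %s%s\n",
    x$endpoint, x$ea, x$band,
    if (x$tie) " (exactly at a band bound)" else ""
  ))
  invisible(x)
}

#' Read a chemical property table
#'
#' Expects a CSV with header
#' `id,name,mw,sw_ug_per_L,log_kow,tm_K,pka` (empty `pka` allowed). Water
#' solubility is converted to the internal molar unit (nmol/L) on read.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with columns `id`, `name`, `mw` (g/mol),
#'   `sw` (nmol/L), `log_kow`, `tm` (K) and `pka`.
#' @export
read_chemicals <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "name", "mw", "sw_ug_per_L", "log_kow", "tm_K")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("chemical table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"pka" %in% names(d)) d$pka <- NA_real_
  if (any(d$mw <= 0) || any(d$tm_K <= 0) || any(d$sw_ug_per_L < 0)) {
    stop("chemical table violates mw > 0, tm_K > 0, sw_ug_per_L >= 0",
         call. = FALSE)
  }
  data.frame(
    id = as.character(d$id),
    name = as.character(d$name),
    mw = as.numeric(d$mw),
    sw = to_molar(as.numeric(d$sw_ug_per_L), as.numeric(d$mw)),
    log_kow = as.numeric(d$log_kow),
    tm = as.numeric(d$tm_K),
    pka = suppressWarnings(as.numeric(d$pka)),
    stringsAsFactors = FALSE
  )
}
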