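#' Predicted no-effect concentration from a chronic EC10
#'
#' PNEC = EC10 / AF, with the default assessment factor of 100 covering
#' interspecies variability and lab-to-field extrapolation; AF = 10 is
#' sometimes used for baseline toxicants.
#'
#' @param ec10 Chronic EC10 in µg/L (> 0). Vectorized.
#' @param af Assessment factor (>= 1); default 100.
#' @return PNEC in µg/L.
#' @export
#' @examples
#' pnec(15, 100)  # 0.15 ug/L = 150 ng/L
pnec <- function(ec10, af = 100) {
  if (any(!is.finite(ec10)) || any(ec10 <= 0)) {
    stop("`ec10` must be > 0 (ug/L)", call. = FALSE)
  }
  if (any(!is.finite(af)) || any(af < 1)) {
    stop("`af` must be >= 1", call. = FALSE)
  }
  ec10 / af
}

#' Risk quotient
#'
#' RQ = environmental concentration / PNEC; an RQ strictly above 1 indicates
#' potential risk.
#'
#' @param mec Measured/modelled environmental concentration, µg/L (>= 0).
#' @param pnec PNEC in µg/L (> 0).
#' @return A list with `rq` and `exceeds` (strict `rq > 1`).
#' @export
risk_quotient <- function(mec, pnec) {
  if (any(!is.finite(pnec)) || any(pnec <= 0)) {
    stop("`pnec` must be > 0 (ug/L)", call. = FALSE)
  }
  if (any(!is.finite(mec)) || any(mec < 0)) {
    stop("`mec` must be >= 0 (ug/L)", call. = FALSE)
  }
  rq <- mec / pnec
  list(rq = rq, exceeds = rq > 1)
}

#' REACH chronic-toxicity flag
#'
#' A substance is classified "toxic to aquatic life" under REACH Annex XIII
#' when its chronic EC10 is strictly below 10 µg/L.
#'
#' @param ec10 Chronic EC10 in µg/L (> 0). Vectorized.
#' @return Logical.
#' @export
reach_toxic_flag <- function(ec10) {
  if (any(!is.finite(ec10)) || any(ec10 <= 0)) {
    stop("`ec10` must be > 0 (ug/L)", call. = FALSE)
  }
  ec10 < 10
}

#' Full risk screen for one chemical
#'
#' Chains [pnec()], [risk_quotient()] and [reach_toxic_flag()]; when a molar
#' mass is supplied the PNEC is also reported in pmol/L.
#'
#' @param ec10 Chronic EC10 in µg/L.
#' @param af Assessment factor; default 100.
#' @param mec Optional environmental concentration, µg/L.
#' @param mw Optional molar mass (g/mol) for molar PNEC reporting.
#' @param chemical_id Optional identifier carried into the result.
#' @return A list of class `risk_assessment` with `chemical_id`, `ec10`,
#'   `af`, `pnec_ug_per_L`, `pnec_pmol_per_L` (NA without `mw`), `mec`, `rq`,
#'   `rq_exceeds`, `reach_toxic`.
#' @export
risk_screen <- function(ec10, af = 100, mec = NULL, mw = NULL,
                        chemical_id = NA_character_) {
  p <- pnec(ec10, af)
  rq <- if (!is.null(mec)) risk_quotient(mec, p) else list(rq = NA_real_, exceeds = NA)
  structure(
    list(chemical_id = chemical_id, ec10 = ec10, af = af,
         pnec_ug_per_L = p,
         pnec_pmol_per_L = if (!is.null(mw)) to_molar(p, mw) * 1000 else NA_real_,
         mec = if (is.null(mec)) NA_real_ else mec,
         rq = rq$rq, rq_exceeds = rq$exceeds,
         reach_toxic = reach_toxic_flag(ec10)),
    class = "risk_assessment"
  )
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat(sprintf(
    "Risk screen%s: PNEC = %.4g ug/L (EC10 %.4g / AF %g)%s; REACH toxic: %s\n",
    if (is.na(x$chemical_id)) "" else paste0(" [", x$chemical_id, "]"),
    x$pnec_ug_per_L, x$ec10, x$af,
    if (!is.na(x$rq)) sprintf("; RQ = %.3g (%s)", x$rq,
                              if (x$rq_exceeds) "exceeds 1" else "below 1") else "",
    x$reach_toxic
  ))
  invisible(x)
}
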