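---
title: "Models and methods behind daphtk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind daphtk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daphtk)
```

`daphtk` chains the computations needed to assess chronic toxicity and
bioaccumulation of hydrophobic chemicals in *Daphnia magna* when exposure is
held constant by passive dosing. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## Exposure stability

Passive dosing buffers losses of hydrophobic chemicals so that the freely
dissolved water concentration stays constant across media-change cycles.
`summarize_exposure()` reports per-level mean, SD and CV over all
measurements, pooling initial (freshly dosed) and final (pre-renewal)
samples — the convention we adopt for reporting exposure concentrations,
since a stable system makes the two stages exchangeable. `stability_test()`
is a one-sided Welch two-sample comparison of final versus initial
concentrations. The one-sided alternative ("final < initial") reflects that
only losses threaten the dosing system; the unequal-variance form is the
safer default when each stage contributes a handful of pooled measurements.
A decline is flagged at p < 0.05 only when the final mean is actually lower.
With many levels tested at the 5% level, occasional false flags are
expected; the flag is a prompt to inspect, not an automatic rejection.

## Reproduction dose–response

A 21-day *D. magna* reproduction test is accepted when, in the controls,
parent mortality is below 10%, mean live offspring per mother exceeds 60,
and the offspring CV is below 15% (`validity_check()`). All three
inequalities are strict, matching the printed criteria; a control mean of
exactly 60 fails. Dead mothers are excluded from the control mean and from
inhibition records.

Per-replicate inhibition is `100·(1 − offspring/control mean)` — negative
values (stimulation) are kept, never clipped, because clipping would bias
the lower asymptote of the curve fit. The concentration–response model is
the variable-slope four-parameter logistic on x = log10(concentration):

$$y = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
      {1 + 10^{(\log_{10}EC_{50} - x)\,h}}$$

fit by bounded Levenberg–Marquardt least squares (`minpack.lm::nlsLM`).
Controls (conc = 0) cannot enter a log10 fit and act only through the
control mean. Default box constraints keep the asymptotes interpretable on
the percent-inhibition scale — bottom in [−20, 20]%, top in [80, 120]% —
while leaving room for stimulation and overshoot; passing `c(0, 0)` /
`c(100, 100)` fixes them. The Hill slope is bounded to (0.001, 20]: the
endpoint is inhibition, so the curve must rise with concentration, and the
upper bound only excludes step-function degeneracies. Fits require at least
five distinct non-zero concentrations.

ECx is defined on the absolute inhibition scale (EC10 = concentration at 10%
inhibition) and solved analytically from the fitted parameters; it exists
only when bottom < x < top. Estimates outside the tested concentration range
are flagged `extrapolated` rather than suppressed.

### Bootstrap confidence intervals

`ecx_ci()` uses a case-resampling bootstrap: replicates are resampled with
replacement within each concentration, the model is refit, and the 2.5/97.5
percentiles of the resampled ECx form the interval. Two details matter for
its calibration at realistic replicate counts (ten mothers per level):

- When the raw records are supplied, the controls are resampled like any
  other concentration group and the control mean — hence every inhibition
  value — is recomputed per resample. The control mean is a shared,
  noisy divisor; ignoring its uncertainty produces intervals that are
  visibly too narrow.
- Each group is resampled with m = n − 1 draws. The plain n-from-n bootstrap
  estimates the variance of a group mean with divisor n instead of n − 1,
  deflating it by (n − 1)/n; drawing n − 1 removes that bias exactly. At
  n = 10 per level this is a ~5% standard-error correction.

Intervals are deterministic under a fixed seed, and an interval is flagged
`unstable` when more than 20% of refits fail.

## Chemical activity and target lipid body burden

Effective activity EA = ECx / S_L places an effect concentration on a
thermodynamic scale where baseline (narcosis) toxicity occupies a
characteristic band: 0.001–0.01 for chronic endpoints, 0.01–0.1 for acute.
Band bounds are treated as inclusive — the source ranges give no boundary
semantics — and a value exactly on a bound carries a tie note.
The subcooled-liquid solubility converts the solid's water solubility to the
liquid reference state via the Walden-rule entropy-of-fusion approximation
S_L = S_W·exp(6.79(T_M/T − 1)), the identity for chemicals liquid at the
test temperature (default 293.15 K, configurable). All internal
concentrations are molar (nmol/L); mass units are converted at the I/O
boundary because the activity and target-lipid equations are molar.

The critical target lipid body burden uses the chronic-endpoint calibration
of the target lipid model, with universal slope m = −0.94 and PAH class
correction Δc = 0.352 (both configurable):
CTLBB = EC10[mmol/L]·10^(−m·log K_OW − Δc), in µmol/g octanol. We adopt the
standard arrangement of the model, log EC = m·log K_OW + log CTLBB + Δc; its
outputs for study-scale inputs (EC10 0.1–15 µg/L, log K_OW 5.2–6.9) fall
inside the 0.36–137 µmol/g range reported for chronic narcosis across
species, which is the plausibility check the test suite applies.

## Toxicokinetics

The one-compartment model drives all kinetics. Depuration: ln C_D declines
linearly in time; `fit_depuration()` estimates k2 = −slope by OLS over all
retained points with replicates pooled (the sampling design pools 2
replicates of 5 animals per time point — too few per-replicate points for
separate fits). A non-negative slope is returned but flagged invalid. Growth
dilution: k_g is the slope of ln(wet weight) vs time; when a series carries
both phases, depuration times (phase-relative by convention) are shifted
onto the absolute clock before the weight regression. The growth-corrected
rate is k2g = k2 − k_g, flagged when growth exceeds elimination. Times to
steady state follow t = −ln(1 − f)/k, so t50 = ln 2/k and t95 = ln 20/k with
the exact invariant t95/t50 = ln 20/ln 2 ≈ 4.32. Which rate feeds t50/t95 is
genuinely ambiguous in practice; we default to k2g when available (growth
dilution is not elimination) and record the basis used, with `ss_basis =
"k2"` available.

The uptake rate constant k1 is never estimated: with simultaneous aqueous
and dietary exposure the uptake routes are confounded, and depuration-based
metrics are the reliable ones. k1 exists only as a synthetic-generation
parameter.

`detect_plateau()` screens the depuration tail for elimination-resistant
residues: trailing points are flagged when their removal changes k2 by more
than 20% (relative) and the local tail slope is shallower than −0.005 h⁻¹.
Both tolerances are configurable; the defaults mark a tail that is both
influential and visibly flat. Flags are suggestions only — exclusion
happens only when the caller passes them to `fit_depuration()` explicitly,
keeping every exclusion auditable in the fit record.

The kinetic bioaccumulation factor BAF* = C_D/C_W uses the body burden at
the end of uptake; without steady state it is a best-case (low-biased)
approximation, and results carry a `steady_state_reached` flag (default
FALSE). Lipid normalization to the 5% reference uses
BAF*_L5% = BAF*·0.05/f_lipid with f_lipid = 0.015 for *D. magna* by
default. Averaging across exposure levels is done on log10 BAF*_L5% values
(mean of logs), the convention consistent with reported summary values.

## B/vB classification

Cross-species regressions of lipid-normalized log BCF_L5% on log k2 ship as
named constants (`bcf_k2_lines`: *Daphnia sp.* slope −1.41, intercept 2.85;
*H. azteca* −1.16, 1.64; fish −1.19, 0.66), so the threshold arithmetic is
reproducible without the underlying literature compilation, which this
package does not redistribute — `gen_bcf_k2()` generates synthetic
stand-ins around any target line instead. Inverting a line at a BCF
criterion gives the depuration-rate threshold
k2 = 10^((log10 BCF_crit − intercept)/slope); at the REACH criteria
(B: 2000, vB: 5000 L/kg) this yields 0.48/0.25 h⁻¹ for *Daphnia* and
0.037/0.017 h⁻¹ for *H. azteca*. For fish, the default thresholds are the
UK Environment Agency literature values (0.0059/0.0027 h⁻¹) rather than the
fish-line inversion — they nearly coincide, but the UK-EA values are the
ones in regulatory use; `fish_source = "regression"` exposes the other
choice. Classification uses inclusive bounds (vB when k2 ≤ k2_vb, B when
k2 ≤ k2_b), following the printed "≤", and is monotone: slower depuration
never lowers the category. Records whose t95 reaches the uptake duration
underestimate BCF and can be excluded from regression fitting via the
explicit, logged `exclude` argument.

Fish–invertebrate concordance counts chemicals by quadrant at an inclusive
log10 BCF threshold of 3.3 on both axes and reports percent agreement
(both + neither)/total.

## Risk screening

PNEC = EC10/AF with AF = 100 by default (interspecies variability plus
lab-to-field extrapolation); AF = 10 is exposed for baseline toxicants.
RQ = MEC/PNEC with a strict RQ > 1 exceedance flag, and the REACH
"toxic to aquatic life" flag applies a strict chronic EC10 < 10 µg/L. Molar
PNECs (pmol/L) are reported when a molar mass is available.

## Synthetic data: what it emulates, what it does not

The generators reproduce the study design so every stage is testable
without raw data. `gen_tk_series()` follows the one-compartment model —
uptake C_D(t) = (k1/(k2+k_g))·C_W·(1 − e^{−(k2+k_g)t}) on the default
5-point/24-h schedule with 2 replicate pools, depuration decaying at the
apparent rate k2 over 4 points — with multiplicative lognormal noise
(default CV 15%, the scale of body-burden variability in such tests) and
exponentially growing wet weights. Growth dilution enters uptake through the
combined constant (k2 + k_g) while the analysis corrects only depuration;
the asymmetry is deliberate and documented here. `gen_reproduction()` draws
rounded lognormal brood counts (control mean 75, CV 10% — values chosen so
default controls satisfy the validity criteria, as real control broods of
68–86 do) and scales treated means by the true 4PL curve; parent deaths are
Bernoulli in treated levels only, so default data always pass validity.
`gen_exposure()` draws lognormal measurements around nominal levels
(default CV 7%, the stability of a working passive-dosing system) with an
optional decline factor for failure scenarios. All generators are pure
functions of (parameters, seed), with per-stream substreams derived from one
global seed, and never perturb the caller's RNG state.

What they do not emulate: the non-monotone 24–72 h dip in uptake body
burdens seen in real daphnids (offspring delivery, possible metabolism),
biotransformation, dietary-vs-aqueous route structure, polymer–water
partitioning kinetics, or time-resolved brood structure. Tests passing on
synthetic data therefore validate the estimators under the stated
one-compartment and 4PL assumptions — they do not certify those assumptions
for real data, where plateau screening and the validity checks do that work.

## Problem sizes and numerical choices

The recovery and calibration simulations in the test suite use the study's
own scale: 200 seeded series for k2 recovery (median relative error well
under the 15% acceptance bound at CV 15% noise) and 200 for EC50 recovery
(median error under 10%); bootstrap coverage is assessed over 500
replications with 200 resamples each, sizes at which the whole suite runs in
a few minutes on one core. Optimizer starts for the 4PL are data-driven
(median log10 concentration, Hill 1) and clamped inside the box; bootstrap
refits that fail are counted, not silently dropped below the 20% instability
bound. Ties at activity-band bounds and at classification thresholds are
resolved inclusively and annotated. Degenerate inputs (zero variance,
all-identical exposure measurements, rising depuration series) return
explicit flags or errors rather than numerical surprises.

## Known limitations

- Depuration fits assume first-order elimination throughout; plateau
  handling is exclusion, not a two-compartment model.
- BAF* without steady state is a lower bound; no extrapolation to
  steady-state BAF is attempted.
- The shipped regression constants are point estimates; threshold
  uncertainty from the regression fit is not propagated.
- Bootstrap intervals are percentile intervals; at very small replicate
  counts they remain slightly anti-conservative even with the m = n − 1
  correction.
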