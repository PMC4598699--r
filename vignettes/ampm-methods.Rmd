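---
title: "Estimating 24-h milk and fatty-acid yields from a single milking: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating 24-h milk and fatty-acid yields from a single milking: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampmyield)
```

## 1. Setting

Twice-daily-milked cows are recorded on periodic test days. Three
observation schemes coexist:

* **S-scheme (50/50 composite)**: one laboratory sample per cow mixing equal
  volumes of morning (AM) and evening (PM) milk, so every content analysis
  observes the midpoint `0.5·AM + 0.5·PM`; AM, PM and 24-h milk *weights*
  are still recorded individually.
* **T-scheme (alternate)**: one sample per cow per visit, from one milking
  only, alternating between visits.
* **Validation scheme**: both consecutive milkings sampled — expensive, so
  available only for modest campaigns.

The goal is a prediction equation for the 24-h yield of milk, fat, and seven
fatty-acid (FA) groups (SFA, MUFA, UFA, SCFA, MCFA, LCFA, C18:1 cis-9) from
one milking's data, *without* a milking-interval (MI) covariate. Throughout,
contents are g/dL of milk, and `yield (g) = content (g/dL) × milk (kg) × 10`
(1 kg of milk taken as 1 L = 10 dL; this convention reproduces the magnitude
relationships among the published per-milking means, e.g. 4.11 g/dL ×
12.79 kg × 10 ≈ 515 g of fat).

## 2. Selection-index decomposition of composite records

Large S-scheme archives observe composite contents only. To turn them into a
calibration set with per-milking phenotypes, the composite is combined with
session-specific regression information, in the spirit of selection-index
theory: a linear blend of an observed aggregate and regression-predicted
components.

From T-scheme records, for each trait and session, a **through-origin**
least-squares regression of per-milking trait yield `y = content × milk ×
10` (g) on per-milking milk yield `m` (kg) gives the slope

`b = Σ m·y / Σ m²` (g trait per kg milk),

so that the expected session yield is `b × milk`. No intercept is fitted:
the construction downstream uses expected values of the exact form
`b × milk`, which an intercept would break. (Whether the original analysts
included one is not documented; the through-origin choice keeps the stated
form exact.)

The published account references a combination matrix it never prints, so
the concrete rule here is a documented reconstruction. Writing implied
session contents `q_s = b_s / 10` (g/dL) and `d = q_AM − q_PM`, the default
(`method = "offset"`) rule is

`content_AM = content_50/50 + d/2`, `content_PM = content_50/50 − d/2`.

It is the unique *linear* rule that (i) uses only the observed composite and
the `b × milk` expectations, (ii) satisfies the 50/50 identity exactly for
every record, and (iii) reproduces the predicted between-session contrast
`d`. An alternative allocation that preserves the implied content *ratio*
instead of the difference (`content_AM = 2·c·q_AM/(q_AM + q_PM)`) is
available as `method = "ratio"`; both preserve the identity exactly, and on
data with an additive session offset the offset rule is unbiased while the
ratio rule compresses low-content records, which is why offset is the
default. Expected contents below `content_floor = 0.001` g/dL (a
non-physical negative can arise on extreme records) are clipped with the
partner session re-adjusted so the identity still holds to 1e-12; more than
1% of records clipping any trait raises a warning, as that signals
misestimated b-coefficients rather than trimming noise.

Records are screened *before* decomposition with the classical mean ± 3 SD
filter, means and SDs computed once on the unfiltered table; a zero-SD
column triggers no removals (the rule is vacuous without variance).

## 3. Prediction models: covariate products nested in class crosses

A model term is a product of zero or more session covariates (session milk
yield; session trait content `q`) nested in a cross of zero or more class
factors:

* **DIM classes**: 30-day classes to day 300 plus one open class (11
  levels). The source material uses unspecified "classes of days in milk";
  30-day classes are standard milk-recording practice and keep every class
  populated at desk scale.
* **Parity classes**: {1, 2, 3+}, the conventional grouping when levels are
  not listed.
* **Month of test**: 12 calendar levels, a proxy for season and feeding.

A term with classes contributes one coefficient per *occupied* subclass cell
(the covariate product inside the cell, zero outside; plain indicators when
the covariate set is empty); unoccupied cells contribute no column. Fitting
is ordinary least squares through a rank-revealing pivoted QR; linearly
dependent columns are dropped deterministically (earlier columns kept,
coefficients reported `NA`) and the parameter count `p` counts estimated
coefficients including the intercept. Columns are laid out in sorted-cell
order, so the fit is invariant to row order.

Eighteen selected model forms — nine traits × two sessions, each four to six
terms — ship as presets (`preset_models()`), expressed in a human-readable
grammar such as `a + b*(qFAT_AM*milk_AM*DIM) + c*(parity) +
d*(milk_AM*parity) + e*(qFAT_AM*milk_AM*parity)` that `parse_model()` reads
back.

**Stepwise selection.** The selection procedure behind the shipped forms
(a stepwise general-linear-model search supplied with separate TEST and VAL
datasets) left its entry criterion undocumented, so the package defines
one: forward selection, at each step adding the candidate that minimises the
TEST-set RMSE `√(SSE_TEST/(n_TEST − p))`, stopping when the best addition
improves it by ≤ 1e-3 (relative; an absolute floor guards the degenerate
zero-RMSE case). The VAL set never influences selection and is only reported
on. TEST-RMSE already penalises complexity out-of-sample, which is why no
additional information criterion is layered on top. Candidates adding no
estimable parameter (rank collapse) are skipped and logged. The default
candidate pool is every preset term for that trait/session plus all single-
and two-way covariate-in-class terms.

## 4. Accuracy statistics

`RMSE = √(SSE/(n−p))`; `R²` is the squared Pearson correlation of observed
and predicted daily yields (also on validation sets — the correlation
definition, not `1 − SSE/SST`, because the reported quantity `R_y,ŷ =
100·√R²` is a correlation; for a least-squares training fit with intercept
both definitions coincide). `R_y,ŷ` is reported as `100·|r|` with the sign
carried separately, since the square root would silently lose it. The
spread criterion requires `σ_ŷ ≤ SD(observed)`, which training-set least
squares satisfies by the variance decomposition; on external data it is a
genuine check.

## 5. The synthetic test-day generator

No usable real data accompany the methodology, so the generator defines the
study conditions for every test:

* **Scale**: 40 herds × 30 cows × 8 monthly test days (9,600 cow-days) — a
  desk-scale stand-in for the ~80,000-record calibration archives.
* **Lactation curve**: Wood form `a·DIM^b·exp(−c·DIM)` per parity, with
  parity-1 scale 14.8 rising to 18.2 for parity 3+ (peak yields ~24–31
  kg/day, daily mean ~26 kg — the published calibration mean is 26.36
  kg/day), plus a cow effect (SD 2.2 kg) and day noise.
* **Milking split**: milk at a milking = daily yield × (preceding
  interval)/24 h + noise (SD 0.9 kg/milking), the simplest mechanism that
  produces the observed AM<PM asymmetry. The AM-preceding interval is
  N(11.5, 1.0²) h, clipped to [4, 20]; intervals sum to 24 h exactly. The
  11.5-h mean gives an AM share of ~0.48, matching the published AM/PM
  yield ratio of roughly 12.8/13.6.
* **Dilution**: each milking's fat content is the cow-day base (mean 4.3
  g/dL, cow SD 0.35, mild late-lactation rise) minus 0.15 g/dL per kg of
  that milking's excess over the half-day mean, plus noise (SD 0.15 g/dL).
  The 0.15 slope yields between-session content gaps of ~0.2 g/dL at the
  default interval asymmetry, the order seen in real AM/PM campaigns. Note
  the direction this implies: the higher-yield milking has the *lower* fat
  content. Published expected contents show the opposite sign for their
  population; the decomposition modules are therefore tested on planted
  offsets of both signs, and nothing downstream assumes a direction.
* **FA composition**: group contents are fixed mean fractions of fat (SFA
  0.66, UFA 0.34, MUFA 0.29, SCFA 0.09, MCFA 0.51, LCFA 0.40, C18:1 0.19 —
  the ratios of the published daily means), with a seasonal sinusoid
  (amplitude 0.05 g/dL, peak in July) moving fat from the
  saturated/medium-chain side to the unsaturated/long-chain side, emulating
  summer pasture feeding. By construction SFA+UFA and SCFA+MCFA+LCFA sum
  exactly to fat, and MUFA ⊆ UFA, C18:1 ⊆ MUFA.
* **Positivity**: milking yields and contents are redrawn (noise only) up to
  20 times if they fall below small floors, then error — a misconfigured
  generator should fail loudly rather than emit non-physical records.

Everything is driven by one integer seed; identical configurations produce
bit-identical tables.

**What it does not emulate** — and hence what passing tests cannot show
about real data: no genetic or pedigree structure, no herd-level feeding or
management effects beyond the start month, no missing data, no recording
error in the class variables, no MIR spectral prediction error structure
(contents are taken as given), and the MI drives the milking split far more
deterministically than in reality, so the MI nested-R² jump (~70% here) is
much larger than the published ~17%. Comparisons against the published
accuracy tables are therefore directional only; the package's tests assert
structural properties (conservation, unbiasedness, monotonicity,
consistency) rather than the proprietary-data numbers.

## 6. Numerical choices and degenerate inputs

* 50/50 conservation is enforced algebraically and tested to 1e-12,
  including after clipping.
* Aliasing: reference handling is "first column wins", via the pivoted QR's
  deterministic drop order; duplicate information changes `p`, never the
  fit.
* Degenerate statistics: `correlation_stats()` refuses zero-variance input
  (<3 pairs likewise); `fit_stats()` and `validation_report()` tolerate
  degenerate *predictions* (intercept-only models keep their RMSE, with
  `NA` correlations).
* Prediction refuses unseen class levels by name — no silent extrapolation;
  a seen-level combination whose cell was unoccupied in training contributes
  zero for that term.
* The MI analysis requires ≥2 distinct interval values; partial F-tests
  flag each added block at α = 0.05 (the original work reports significance
  without naming the test; the partial F is the natural choice for nested
  least squares).

## 7. Problem sizes used by the tests and acceptance script

Unit tests run small populations (typically 6 herds × 8 cows × 4 test days)
chosen so each suite exercises every code path in seconds. The structural
acceptance checks use: 10,080 cow-days for 50/50 conservation; n = 10,000
records for decomposition recovery (planted ±0.2 g/dL session offset;
acceptance band: mean bias within 2 Monte-Carlo SEs); 20 replicates at
n = 1,000 for b-estimator consistency (3 SE band); 50×4 systems for the
normal-equations cross-check (1e-8); 20 replicates of a planted-signal
selection experiment (the planted covariate product must enter first in at
least 19; its class-nested refinement counts, as it contains the signal);
and the default 9,600-cow-day pipeline for calibration correlations, the
σ_ŷ criterion and the MI sequence. The full default pipeline completes in
well under a minute on one CPU.

## 8. Known limitations

* The reconstruction of the combination rule is one of several linear rules
  consistent with the published description; the original coefficients are
  unavailable. The strategy switch documents the sensitivity.
* b-coefficients are estimated globally per trait × session; heterogeneous
  herds would motivate subclass-specific slopes, which is exactly the
  classical MI-adjustment-factor family (parity × stage × season
  subclasses) this methodology intends to replace, so it is deliberately
  out of scope.
* The stepwise criterion is a reasoned stand-in for an undocumented
  procedure; selected forms can differ from the shipped presets on data
  with different signal structure — the presets exist precisely so the
  published forms can be fitted without reselection.
* Validation-set accuracy on synthetic data can exceed calibration accuracy
  for fatty traits: the calibration responses carry decomposition
  approximation error while validation responses are exact. On held-out
  data of the *same* (decomposed) kind, calibration accuracy dominates on
  average, which is what the package's tests assert.
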