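---
title: "Harmonizing heterogeneous PROMs in MCID units: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing heterogeneous PROMs in MCID units: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcidmeta)
```

## The problem

Hip arthroscopy trials report functional outcome on many different
patient-reported outcome measures (PROMs) — mHHS, iHOT-12, iHOT-33, HOS-SSS,
HOS-ADL, NAHS and others — with no accepted gold standard. Raw means on
different instruments cannot be pooled, which fragments the evidence base.
`mcidmeta` harmonizes such study-level summaries by expressing every score in
**MCID units**: the observed value divided by the instrument's minimal
clinically important difference. On that scale, 1.0 corresponds to one
clinically meaningful improvement regardless of which questionnaire produced
it, so pooled results read directly as "numbers of clinically important
differences".

## The procedure

Four stages, each a standalone function and chained by `mcid_pipeline()`:

1. **Registry.** Instrument metadata (scale bounds, orientation, MCID) live
   in a CSV registry, not in code. The shipped registry covers the ten most
   frequently reported hip PROMs; only the six leading instruments carry an
   adopted MCID (mHHS 9.5, iHOT-12 13.0, HOS-SSS 12.1, NAHS 8.5, HOS-ADL 9.8,
   iHOT-33 10.7 points). Instruments without one (HOOS, WOMAC, HAGOS, HHS)
   are deliberately *non-normalizable*: asking to normalize them is an error,
   never a silent skip, because a silently dropped cohort biases a review.
   Name matching is canonical (case, punctuation and unicode-hyphen
   insensitive) with synonyms carried in the registry file.

2. **Normalization.** Means and SDs are divided by the instrument's MCID.
   Missing SDs are resolved in a fixed order: reported value, then the
   quarter-range rule `SD = (max − min)/4`, then conservative borrowing of
   the *largest* SD among arms reporting the same instrument at the same
   timepoint. Each resolution is tagged with its provenance
   (`reported` / `from_range` / `imputed`) and logged. For change scores,
   improvement is `(post − pre)/MCID`, sign-flipped for inversely scaled
   instruments so positive always means improvement, and the change-score SD
   uses the paired formula
   `sqrt(sd_pre^2 + sd_post^2 − 2 r sd_pre sd_post)`.

3. **Prioritization.** A study reporting several PROMs would otherwise
   contribute several statistically dependent effect sizes. One instrument
   per study is retained — the one ranked highest in a literature
   reporting-frequency ranking — and the rest are recorded as discarded.

4. **Pooling.** Per-study mean differences in MCID units, with sampling
   variance `sd1²/n1 + sd2²/n2`, enter an inverse-variance random-effects
   meta-analysis (`mcid_meta()`) with a self-contained REML estimator of the
   between-study variance. Heterogeneity is reported as Cochran's Q and
   Higgins' I².

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `r` (pre/post correlation) | 0.5 | — | Rarely reported; 0.5 is the conventional midpoint. `change_outcomes()` accepts a vector (we recommend `c(0.2, 0.5, 0.8)`) so the sensitivity sweep is one call. |
| `impute_rule` | `"max"` | — | Borrowing the largest donor SD inflates rather than shrinks uncertainty; `"mean"` is available. |
| `method` | `"REML"` | — | Approximately unbiased for the between-study variance; `"DL"` and `"FE"` for comparison. |
| `level` | 0.95 | — | Wald CI `mu ± 1.959964·se`. `knapp_hartung = TRUE` switches to the small-sample t-based adjustment. |
| reporting precision | 1 decimal | MCID units | Summary tables round half-up (`round_half_up()`), matching clinical reporting convention; internal arithmetic keeps full precision. |

## Design choices where the design was open

**Tie in the frequency ranking.** In the shipped 100-study survey NAHS and
HOS-ADL tie at 27 mentions. `rank_proms()` breaks ties lexicographically by
default (deterministic and order-independent), and records the rule it
applied. Prioritization, however, takes its ranking as an *explicit input*
rather than recomputing it, precisely so the governing order is a recorded,
reviewable artifact. The packaged default ranking places NAHS ahead of
HOS-ADL, the order in which the two instruments are used operationally in
hip-arthroscopy outcome harmonization work; pass `tie_break = ` an explicit
priority vector, or your own ranking file, to override.

**Retention needs both arms.** An effect size requires the same instrument
in both arms, so retention is decided on the intersection of the two arms'
instrument sets; an instrument reported by a single arm is ineligible and the
audit log says so. Arms with entirely disjoint instrument sets are an error,
not a guess.

**Levels vs change scores.** Both postoperative levels and pre/post change
scores are implemented (`normalize_measurements()` vs `change_outcomes()`).
Which one a synthesis should pool depends on the available data and the
review question; the package does not adjudicate, it makes both paths
explicit and auditable.

**Effect direction is never inferred.** Effects are `arm1 − arm2` with arm
order taken from the data, or controlled by `reference_arm=`; the direction
used is recorded on the result. Narrative directions ("favours X") are the
analyst's responsibility.

## Numerical choices

* REML is solved by Fisher scoring on the restricted log-likelihood,
  started at the DerSimonian–Laird estimate, clamped to `tau2 ≥ 0` after each
  step, converged when the change in `tau2` falls below `1e-10` (at most 100
  iterations; non-convergence is an error carrying the last iterate).
  The estimate agrees with a brute-force grid maximizer of the restricted
  log-likelihood to better than `1e-5` and with an independent REML
  implementation to `1e-4` on random instances (see the test suite).
* `I² = max(0, (Q − df)/Q)·100` with fixed-effect weights in Q; values are
  clamped at 0 when Q falls below its degrees of freedom. Banding: low below
  25%, high above 75%, *both boundaries* moderate.
* Zero-dispersion inputs give `tau2 = 0` exactly; a study pair with zero SD
  in both arms is a degenerate-effect error.
* `sd_change()` clamps tiny negative radicands (possible at `r = 1` in
  floating point) to zero.
* Scale values outside an instrument's bounds warn and are flagged in the
  audit log but are not dropped — source typos should be visible, not fatal.

## What the synthetic generator emulates — and what it does not

`simulate_mcid_studies()` emulates the multi-study two-arm design used to
demonstrate the framework: `k` studies, each with a true effect
`theta_i = delta + tau·z_i` in MCID units, reporting 1–3 instruments drawn
with probability proportional to the reporting-frequency survey, per-arm
sizes 20–180, raw-scale SDs 9–19 points, and arm-2 means placed in the upper
half of each instrument's scale — all reflecting the ranges seen in the hip
arthroscopy literature. Arms are summarized analytically (observed mean from
its normal sampling distribution, observed SD from a scaled chi
distribution) because the pipeline consumes summaries only. Truncation at
scale bounds is flagged, and a configuration truncating more than 1% of arms
fails fast, since silent truncation would bias recovery experiments. One
global seed drives a separate stream per study, so enlarging `k` leaves
earlier studies unchanged.

It does **not** simulate responder proportions, dropout, floor/ceiling
non-normality, or construct differences between instruments. Passing
recovery tests on this generator therefore shows the *pipeline arithmetic*
is sound under the stated model; it does not show that MCID normalization
removes construct-level heterogeneity in real data — it cannot, and residual
differences in what the instruments measure persist after harmonization.

## Validation problem sizes

The test suite validates the pipeline at the following scales, chosen to
give tight Monte-Carlo error while staying quick to run: REML vs grid-search
oracle on 100 random instances with `k ≤ 10`; estimator recovery at
`k = 100, tau² = 0.09` over 200 replicates; end-to-end recovery of
`delta = 0.4, tau = 0.2` at `k = 15` over 200 simulated pipelines; and a
500-replicate bias/coverage study of the pooled estimate
(`|bias| < 0.02` MCID units, 95% CI coverage within [90%, 98%]).

## Known limitations

* Published MCIDs vary with population, indication and follow-up; a single
  registry value per instrument is a pragmatic choice, and conservative
  (most frequently reported) MCIDs may understate improvements.
* MCID normalization aligns *scales*, not *constructs*.
* The quarter-range SD rule and donor imputation are coarse; their
  provenance tags exist so a sensitivity analysis can exclude them.
* Wald CIs are anti-conservative for very small `k`; use
  `knapp_hartung = TRUE` there.

## A worked run

```{r}
res <- mcid_pipeline(demo_hip_studies())
res
summary(res$fit)
```
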