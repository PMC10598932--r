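---
title: "Chemogram scoring: model, quality control, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemogram scoring: model, quality control, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemogram)
```

This vignette is the package's account of the science it implements: the
measurement model behind an ex vivo organoid drug screen, the scoring
procedure and its assumptions, the parameters a user may want to touch, and
the choices we made where the procedure was genuinely open.

## The measurement

A patient-derived organoid (PDO) line is dissociated, seeded in basement
membrane extract droplets in the 60 center wells of 96-well plates, and
exposed to a panel of drugs — by default the packaged 25-drug library, each
drug at three concentrations chosen to be physiologically plausible and to
straddle typical IC50s. The three concentrations per drug are uniformly
spaced in log10 molar units. Each drug×concentration condition occupies
three wells; solvent-only control wells sit on every plate. The readout is
end-point ATP bioluminescence, a proxy for the number of viable cells.

Two facts about this design drive the whole pipeline. First, raw
luminescence has no absolute meaning — only the ratio to the solvent
controls on the same plate does, which is why every quantity downstream is
a *relative viability* in percent of control. Second, with 25 drugs × 3
concentrations × 3 replicates = 225 condition wells and only 60 usable
wells per plate, a screen necessarily spans several plates, so plate-level
gain differences are a real nuisance factor; controls are therefore pooled
*per plate* by default (`qc_config(control_scope = "per_screen")` pools
globally instead — appropriate when a reader session is known to be
homogeneous).

## Quality control

For each condition the triplicate is collapsed to its mean relative
viability and the standard error of the three normalized wells (sample SD /
√3, in percent points). A condition whose SE exceeds 12 points is excluded;
the comparison is strict, so an SE of exactly 12.0 is retained — the rule
says "over" the threshold and we read that verbatim; the threshold itself
is configurable (`qc_config(se_threshold = )`). Exclusion is the only
remedy the pipeline applies: a PDO×drug pair missing any of its three
levels is reported as unavailable ("not tested"), never interpolated or
imputed. Re-running a failed test is an experimental act, not an analytic
one; re-runs enter the pipeline as new raw rows.

Normalized viabilities below zero (possible when background subtraction
happens upstream of this package) are clamped to 0 so that areas cannot go
negative; values above 100% are kept as-is, because growth stimulation is
real signal and feeds the score with the correct sign.

## The score

Let $v$ be a profile's viability triple in percent and $\mathrm{AUC}(v)$
the trapezoidal area under the curve divided by the full-response
rectangle (100% × x-range). The final score is

$$\text{final} \;=\; \underbrace{\frac{\mathrm{AUC}(\bar v)}{\mathrm{AUC}(v)}}_{\text{AUC score}} \;+\; \underbrace{1 - \mathrm{AUC}(v)}_{\text{sensitivity score}},$$

where $\bar v$ is the per-level mean curve over all PDOs with an available
profile for the drug. The two parts answer different questions. The AUC
score is *relative*: it calibrates each drug against the cohort, which
matters because drugs differ wildly in how much killing their chosen
concentrations produce — a kinase inhibitor can have a high AUC ratio with
only modest absolute kill. The sensitivity score is *absolute*: it rewards
profiles that actually lose viability at the tested concentrations. Summing
them lets neither artifact dominate: a drug scores high only if the PDO is
both more sensitive than the collection and substantially affected.

A drug is a **hit** when the final score strictly exceeds the threshold.
The default threshold 1.9 is the third quartile of the pooled score
distribution of the calibrating 25-PDO × 25-drug cohort (pooled median
≈ 1.46); `scoring_config(threshold_mode = "cohort_q3")` re-derives it from
the matrix being scored, using the linear-interpolation quantile rule
between order statistics (`stats::quantile` type 7, the common
spreadsheet-style inclusive method) so a derived threshold is reproducible
from a published matrix. The default stays *fixed* so that one new PDO can
be scored against a frozen reference without shifting everyone's hit calls.

### Numerical choices

- **x-axis of the AUC: concentration index (0, 1, 2).** Every triple of the
  packaged panel is uniformly spaced in log10 M, so index spacing equals
  log-spacing up to a per-drug constant that cancels in both the AUC ratio
  and the normalized sensitivity score; the `spacing = "log10M"` switch is
  provided and gives bit-identical scores on the default panel (asserted in
  the tests). Index spacing additionally tolerates custom panels with
  non-uniform triples.
- **Trapezoid rule.** The standard discrete-AUC choice for three points;
  crucially it is *linear* in the viabilities, so the AUC of the cohort
  mean curve equals the mean of individual AUCs — an identity the test
  suite exploits as an independent oracle.
- **Division guard.** A total-kill profile has AUC 0; the PDO AUC is
  floored at `auc_floor_fraction` (default 0.01) before dividing, keeping
  scores finite and preserving monotonicity. The floor caps the AUC score
  at 100 × the cohort AUC.
- **Reference includes the scored PDO.** The reference is "the average
  response of the collection", and cohort members are part of that
  collection. `leave_one_out = TRUE` is available for scoring against a
  reference that must not contain the new sample; by trapezoid linearity it
  is computed exactly from the pooled mean without re-averaging curves.
- **Ties are not hits.** The hit rule is a strict `>`, matching the
  verbatim "score > 1.9" phrasing; the same strictness governs the QC rule
  in the other direction (SE exactly at threshold is kept).

Two useful consequences, both asserted as properties in the tests: for any
fully observed drug the mean AUC score over PDOs is ≥ 1 (arithmetic–harmonic
mean inequality, equality iff all AUCs are equal), and a PDO identical to
the cohort average scores exactly 1 + its own sensitivity score. Scores are
invariant to expressing viability as fractions instead of percent.

## Cohort analytics

`heterogeneity_score()` is the sample SD (n − 1) of a drug's present
scores — a plain dispersion summary used to ask which drugs discriminate
between patients at all. `drug_correlation()` computes pairwise Pearson
correlations between drugs over the PDOs present for both (pairwise
complete, with the complete-pair count reported so thin pairs can be
discounted; pairs with fewer than 3 complete observations are masked), and
clusters drugs on the distance 1 − r with average linkage — the linkage is
configurable since only the correlation, not the linkage, is canonical.
Drugs sharing a mechanism of action are expected to cluster, which doubles
as an internal quality control of the whole assay. Group comparisons of
per-PDO hit counts use Welch's unpaired two-tailed t-test, implemented from
the closed-form statistic and Welch–Satterthwaite degrees of freedom and
verified against `stats::t.test` to 10⁻¹⁰; no multiple-testing correction
is applied because the intended use is single planned comparisons.

## Clinical concordance

For a patient who received a panel drug, the PDO call is *sensitive* iff
its final score for that drug exceeds the threshold, and the clinical call
is *responder* iff the best response shows clinical benefit (PR or SD,
versus PD). The three-level outcome is collapsed to two because the
decision the chemogram informs is binary; the strict alternative
(`responder_def = "strict"`, responder = PR only) is provided since SD is
arguably ambiguous. Sensitivity, specificity, PPV and NPV come from the
2×2 table; a metric with an empty denominator is reported as undefined
(NA with a flag), never as 0. When a regimen contains one panel drug
(e.g. an oxaliplatin-based combination), the record should name the panel
drug; combination effects are out of scope.

## The synthetic screen generator

`simulate_screen()` emulates the statistical structure the pipeline
assumes, not the biology of any particular tumor:

- each PDO×drug pair draws a latent log10 IC50 from a per-drug normal
  distribution centered by default on the drug's *medium* test
  concentration (the panel was calibrated so the three concentrations
  straddle typical IC50s) with SD 0.5 log units — a realistic spread of
  inter-patient sensitivity of roughly ±1 concentration step;
- expected viability follows the three-parameter log-logistic (Hill) curve
  $v(c) = 100\,(e_\infty + (1 - e_\infty)/(1 + 10^{h(c - \mathrm{IC50})}))$
  with slope $h = 1$ and residual viability $e_\infty = 0.1$ — organoid
  cultures rarely reach zero ATP signal;
- wells get multiplicative Gaussian noise with CV 8% (truncated so signal
  stays non-negative; a lognormal alternative is available), matching
  typical plate-reader replicate scatter; each plate carries its own scale
  factor (lognormal, 5%) around 10,000 RLU to exercise per-plate
  normalization;
- 2% of conditions are deliberately degraded with a structured replicate
  spread whose injected SEM is 2 × the QC threshold in expectation, and 2%
  of pairs are never tested, mimicking sporadic technical failures and
  panel gaps; spiked pairs (ground-truth sensitive, IC50 shifted down) are
  never made missing so recovery can be measured.

What the generator does *not* emulate: spatial plate effects (edge
evaporation, gradients), drug cross-contamination, passage effects,
between-run batch drift, correlated drug responses within a mechanism
class, or any genotype–response association. Passing the recovery tests
therefore shows that the pipeline correctly extracts what its own model
assumes is there — it says nothing about whether the assay itself predicts
clinical response; that question is exactly what the concordance module
quantifies on real matched data.

With the default conditions (24 PDOs, noise as above) the scored synthetic
cohort lands, without any tuning, near the operating regime the scoring
system was designed around: pooled median final score ≈ 1.47, third
quartile ≈ 1.9, and about 6 hits per PDO at the fixed threshold — an
unsurprising consequence of centering IC50s on the medium concentration
(which puts typical sensitivity scores near 0.5 and AUC scores near 1)
but a useful sanity check that the default generator exercises the
pipeline where it is meant to operate. The acceptance script computes
these numbers at run time; nothing in the package hard-codes them.

## Problem sizes and determinism

The test suite and acceptance script run everything at desk scale: oracle
checks use 100–1000 random small cohorts; parameter-recovery uses 20
seeds × 24 PDOs × the full 25-drug panel (≈ 6,000 wells per screen), sizes
at which the whole suite completes in well under a minute while leaving the
recovery rates with comfortable margins. Every stochastic path — the
generator, the clinical sampler, the acceptance script — is a pure function
of an explicit integer seed; identical seeds give bit-identical outputs.

## Known limitations

- Three concentration points bound how much curve shape the AUC can see;
  profiles that cross the cohort average can receive middling scores that a
  full dose–response fit would separate.
- The cohort reference changes as the cohort grows; scores are comparable
  only within a fixed reference (use `leave_one_out` or a frozen fit via
  `predict()` for prospective use).
- The hit threshold is a quantile of a particular cohort, not a biological
  constant; transferring it to a different tumor type or panel deserves
  re-derivation (`threshold_mode = "cohort_q3"`).
- Correlation clustering treats missing correlations as maximally distant,
  which can distort trees on very sparse matrices; `pair_n` is exposed so
  users can prune first.
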