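---
title: "Inferring drug-induced death rates from viability kinetics and pooled screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring drug-induced death rates from viability kinetics and pooled screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lethaldyn)
```

## The problem

Most drug-response readouts measure the *net* size of a live population.
Relative viability (RV: treated live cells over untreated live cells) and its
screen analogue, the treated-versus-untreated log2 fold change (L2FC) of
sgRNA abundance, confound two different biologies: how fast cells divide and
how fast they die. When a perturbation changes the proliferation rate — as
knockouts of essential or DNA-repair genes do — net-size metrics misreport
its effect on death, up to and including a full sign inversion (a knockout
that dies *faster* under drug scoring as "resistant" because it grew slower
in the untreated arm). `lethaldyn` implements death-specific metrics for
plate-reader kinetics, a population forward model that makes the confound
explicit, and an inversion of that model that recovers per-gene death rates
from standard pooled-screen count data.

## Death-specific metrics from plate kinetics

The supported assay measures dead-cell fluorescence per well over time,
plus total-cell fluorescence from lysed duplicate plates at the start and
end of the assay. Intermediate totals are interpolated with a single
exponential between the two lysed measurements
(`infer_total_timecourse()`). From dead and total signal:

* fractional viability `FV = live / (live + dead)` and lethal fraction
  `LF = 1 - FV` (death-specific, bounded in [0, 1]);
* relative viability `RV = live_treated / live_untreated` (kept for
  comparison precisely because it is confounded);
* the growth-rate-normalized response
  `GR = 2^(log2(live_tx / live_T0) / log2(live_unt / live_T0)) - 1`,
  which is 1 for unperturbed growth, 0 at complete arrest, and negative for
  net population shrinkage. GR is reported as `NA` with a flag when the
  untreated reference has not grown past its baseline, since the
  normalization is undefined there.

All fluorescence-to-cell conversions assume a constant per-cell signal
within one plate and gain setting; every metric is a ratio, so the constant
cancels and the results are invariant to the gain (this is tested).

Dose-response curves are fit with a four-parameter logistic on log10 dose
(`fit_dose_response()`), with the vehicle wells anchoring the zero-dose
plateau but excluded from the log-dose regression. Death kinetics are fit
with the lag-exponential death model (`fit_led()`),

\[ LF(t) = LF_0 + (LF_p - LF_0)\,(1 - e^{-DR\,(t - D_0)}) \quad (t \ge D_0), \]

flat at `LF0` before the onset time `D0`. The optimizer is bounded
nonlinear least squares with four deterministic starts placing `D0` at the
quartiles of the time window; ties are broken by lowest residual sum of
squares, then lowest `D0`. A flat series is returned as degenerate
(`DR = 0`, `D0` unidentifiable) rather than fit; a monotone-decreasing
series is refused because death is irreversible under the model.

### GRADE

GRADE quantifies how tightly death is coupled to growth inhibition across
doses. Fractional viability is first normalized for the basal death rate of
the line: `LF_norm = max(0, (LF - basal_LF) / (1 - basal_LF))`,
`FV_norm = 1 - LF_norm`, which removes background death and pins untreated
wells to `FV_norm = 1`. Doses with `GR >= 0` are fit to a line of `FV_norm`
on GR (slope `m_drug`), and the steepest coupling representable on the
observed GR range is the line from `(GR = 1, FV_norm = 1)` down to
`(GR_min, FV_norm = 0)`, i.e. `m_max = 1 / (1 - GR_min)`. GRADE is the
angle ratio `atan(m_drug) / atan(m_max)`. The basal-death normalization and
the `m_max` construction are this package's explicit formulations of a
coordination score usually described operationally; both are documented
here because other conventions exist.

## The biphasic population model

Under high, lethal drug exposure the response is biphasic: cells keep
proliferating at their intrinsic rate until arrest at `t_arrest`, after
which the killable fraction `LFp` of the arrested cohort decays
exponentially. In units of doublings and halvings per hour (all log ratios
base 2, which makes fold changes linear in the rates when `LFp = 1`):

\[ \mathrm{live}(t) = N_0\, 2^{g\,\min(t, t_\mathrm{arrest})}\, S(t), \qquad
   S(t) = (1 - LF_p) + LF_p\, 2^{-d\,(t - t_\mathrm{arrest})_+} . \]

Dead cells are the cohort complement, so `live + dead` is conserved after
arrest. The published description of the treated-arm dynamics is ambiguous
about whether a distinct treated-arm doubling time exists; we implement a
single clone growth rate plus arrest, which matches the constraint that
death occurs only in growth-arrested cells and reproduces the stated
wild-type behavior. The treated arm's pre-arrest growth uses the clone's
*own* rate (knockouts alter intrinsic proliferation regardless of drug).

`simulate_rv_scenarios()` reproduces the key diagnosis: with realistic
rates (24 h doubling, arrest at 24 h, one halving per 72 h), the
sensitivity of RV to the death rate peaks a day or two after onset and
decays toward zero as untreated proliferation dominates the scale — by
168 h it is under 10% of its peak (`rv_death_sensitivity()`), which is why
endpoint RV, and by extension endpoint screen L2FC, is nearly blind to
death.

## Screen analysis

Counts enter as a MAGeCK-style tab-delimited table plus a sample sheet
labeling T0, untreated, and treated replicates. The pipeline
(`analyze_screen()`):

1. **Trim**: the bottom 5% of guides by total raw count across all samples
   (library-wide, ties broken lexicographically) and all miRNA-flagged
   guides are removed. If whole genes would vanish for more than 20% of the
   library, the run aborts — that pattern indicates a population
   bottleneck, not a filtering problem.
2. **Normalize**: median-of-ratios size factors computed on non-targeting
   guides only (guides with a zero anywhere are excluded from estimation
   only). Anchoring to non-targeting guides means "abundance relative to
   wild type" is the natural scale of every downstream fold change.
3. **Fold changes**: per guide,
   `L2FC = log2((mean_num + pc) / (mean_den + pc))` with pseudocount 1 on
   the normalized scale, for treated/untreated and untreated/T0. This is a
   deliberate, documented substitute for a shrinkage-based differential
   abundance fit: the empirical non-targeting null used for significance
   absorbs the slightly wider spread that results. Guide values are
   collapsed to genes by the mean.
4. **Empirical null**: non-targeting guides are shuffled (seeded) into
   6-guide pseudo-genes — 1,000 guides yield 166 — which travel through the
   entire pipeline, including rate inference. Gene values are z-scored
   against the pseudo-gene distribution; two-sided empirical p-values come
   from bootstrap resamples of the null (floored at `1/n_boot`) and are
   Benjamini-Hochberg adjusted.
5. **Rate inference**: the untreated/T0 contrast gives each clone's growth
   rate directly, `g_hat = g_wt + l2fc_unt_t0 / T_unt0` (floored at a small
   positive value with a flag when dropout is implausibly strong). The
   treated/untreated contrast is then inverted for the death rate by
   bisection on `[0, 10 d_wt]` (absolute tolerance 1e-8): because death
   engages only after arrest, the forward map is strictly decreasing in `d`
   at fixed `g`, so the solution is unique. `build_phase_diagram()` asserts
   this monotonicity at build time. Observations outside the achievable
   range are clipped to the boundary with `on_manifold = FALSE` rather than
   dropped, so FDR accounting keeps the full gene set; clipping can only
   shrink `|L2DR|`, never inflate it.
6. **Scoring**: genes are scored on `L2DR = log2(d_hat / d_wt)` rather than
   on `d_hat`, so the null is symmetric. A death rate clipped to zero would
   give `-Inf`; L2DR is floored at -10 (a 1024-fold reduction, far below
   any resolvable effect) to keep the shared scoring machinery finite.
7. **Error taxonomy**: each gene's conventional call (`sign(-l2fc)` past a
   0.25 threshold) is compared with its rate-based call (`sign(l2dr)` past
   0.25): Type I (spurious call), Type II (missed effect), Type III
   (inverted sign). A clone with half the wild-type growth rate and an
   unchanged death rate has `l2fc_unt_t0 = -2` and `l2fc_tx_unt = +1.5`
   under the default design — called "resistant" by L2FC, correctly null by
   L2DR.

### Design defaults

The wild-type reference (`assay_design()`) defaults to
`g_wt = 1/24` doublings/h, `t_arrest = 24` h, `d_wt = 1/72` halvings/h,
`LFp_wt = 1`, over 96 h contrasts. These are chosen so the treated
wild-type arm reaches a lethal fraction of exactly 0.5 at assay end,
matching a screen dosed for half-lethal response; all of them can be
overridden from fitted kinetic parameters (`t_arrest` from a fitted `D0`,
`d_wt` from a fitted `DR`). Untreated-arm passaging preserves relative
abundance and is therefore ignored in ratio space.

## The synthetic-data generator

`generate_truth()` and `simulate_screen_counts()` produce fully
ground-truthed screens: a GeCKO-like library (6 guides per gene plus 1,000
non-targeting guides; 19,050 genes supported, 1,000 used routinely),
clone-specific growth/death multipliers in five classes (neutral,
essential, repair-like with both a growth defect and excess death, death
sensitizers, death suppressors), 400x coverage, three replicates per
condition, and gamma-Poisson counts with dispersion 0.01 (a conventional
value for replicate screen scatter; the true dispersion is not printed
anywhere and is a config knob). Effect magnitudes default to one log2 unit
with 0.25 log2 spread.

Guide-level effects model sgRNA-efficacy variation as a *relative* jitter
on the log2 effect (10% by default): a guide against a gene with no effect
stays exactly neutral. An additive jitter would instead make
targeting-neutral genes systematically noisier than the non-targeting
pseudo-gene null and silently break FDR calibration — the null must be
exchangeable with true negatives for the empirical-p machinery to mean
anything.

The generator runs the *forward* model only; the inference owns the
inverse. What the generator does not emulate: PCR/sequencing error
profiles, guide cross-mapping, copy-number effects, clone-to-clone
variation in arrest timing or `LFp`, and cell-to-cell stochasticity (the
dynamics are deterministic closed forms). Passing recovery tests on this
synthetic data therefore demonstrates correctness of the analysis under
its stated model, not robustness to every failure mode of real screens.

## Numerical choices and degenerate inputs

* Bisection tolerance 1e-8 absolute in `d`; the phase-diagram monotonicity
  assertion makes a bracketing failure impossible rather than unlikely.
* The LED and 4PL fits use Levenberg-Marquardt least squares directly on
  the residual function, which is robust to the zero-residual (exact-fit)
  case that breaks the usual model-object construction.
* Flat responses are flagged degenerate, not fit; negative live signals are
  clipped to zero with a logged count; a non-growing untreated reference
  flags GR as undefined instead of dropping the point.
* All randomness (truth sampling, count sampling, pseudo-gene shuffle,
  bootstrap) is seeded through one function that restores the caller's RNG
  state; two runs with the same seed are byte-identical.
* Test-scale defaults (1,000 genes, 50-replicate noise studies, 20x20
  inversion grids) keep the full validation suite at a few seconds while
  leaving every rate estimate's Monte-Carlo error far below the effect
  sizes of interest.

## Known limitations

* Exponential interpolation of lysed-plate totals is exact for steadily
  growing or static populations but distorts mid-assay lethal fractions
  when growth arrests partway through; fitted plateaus from plate data are
  correspondingly approximate even though endpoint values are exact. This
  is a property of the assay design, not of the fit.
* With a single treated contrast, `d` and `LFp` are not jointly
  identifiable per clone; `LFp` is a design-level parameter shared across
  the library.
* The inversion inherits the model's central assumption — death only in
  arrested cells. Perturbations that decouple arrest from death (e.g. a
  knockout that dies while still cycling) will be projected onto the
  nearest point of the model manifold and flagged only if they leave the
  achievable range.
* Empirical p-values are floored at `1/n_boot`; ranking below that floor
  relies on the z-score.
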