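# lethaldyn

Death-rate inference for drug-response assays and pooled CRISPR screens.

## The problem

Standard drug-response readouts — relative viability in plates, the
treated-vs-untreated log2 fold change (L2FC) of sgRNA abundance in pooled
screens — measure the *net* size of the live population. Net size conflates
proliferation and death: a knockout that dies faster under drug but grows
slower without it can score as "resistant", and endpoint measurements become
almost completely insensitive to the death rate once exponential growth
dominates the scale. `lethaldyn` is for cell-death biologists and
functional-genomics analysts who need death-specific answers from these
standard data types.

## What it computes

**Plate kinetics** (dead-cell dye signal plus lysed-plate totals):

- lethal fraction `LF`, fractional viability `FV = 1 − LF`, relative
  viability `RV`, and the growth-rate–normalized response
  `GR = 2^(log2(live_tx/live_T0) / log2(live_unt/live_T0)) − 1`;
- four-parameter logistic dose–response fits
  (`ECmax + (FV0 − ECmax)/(1 + 10^((x − EC50)·h))` on log10 dose);
- lag-exponential death kinetics
  `LF(t) = LF0 + (LFp − LF0)(1 − e^(−DR(t − D0)))` with onset time `D0`,
  rate `DR`, plateau `LFp`;
- GRADE, the angle ratio `atan(m_drug)/atan(m_max)` measuring how tightly
  death is coupled to growth inhibition across doses.

**Population model**: biphasic growth-then-death,
`live(t) = N0·2^(g·min(t, t_arrest))·[(1 − LFp) + LFp·2^(−d(t − t_arrest)+)]`,
with growth in doublings/h and death in halvings/h, shared between the
relative-viability simulations and the screen inference.

**Screens**: non-targeting-anchored normalization, guide→gene L2FC for both
screen contrasts, randomized non-targeting pseudo-genes as the empirical
null (z, bootstrap p, Benjamini–Hochberg FDR), and the central inversion:
because death occurs only after proliferation arrest, the forward map from
(growth rate, death rate) to L2FC is monotone in the death rate, so each
gene's death rate is uniquely determined by its two fold changes. Results
are reported as `L2DR = log2(d_hat/d_wt)` with an error-type classification
(Type I/II/III) of what a conventional L2FC analysis would have concluded.

**Synthetic data**: a ground-truthed screen generator (GeCKO-like library
structure, clone-specific growth/death multipliers, overdispersed counts)
and a recovery benchmark, used throughout the test suite.

## Worked example

```r
library(lethaldyn)

design <- assay_design()                       # g_wt = 1/24, d_wt = 1/72, arrest 24 h
cfg    <- synthetic_screen_config(n_genes = 1000, seed = 11)
truth  <- generate_truth(cfg)
screen <- simulate_screen_counts(truth, design)

analysis <- analyze_screen(screen$cm, design, seed = 7)
analysis
#> Screen death-rate analysis: 991 genes, 166 pseudo-genes
#>   genes at FDR < 0.1: 153
#>   error classes vs conventional L2FC: I=99 II=8 III=32 none=852

benchmark_recovery(truth, analysis)
#> Synthetic-screen recovery benchmark
#>   Spearman rho (true vs inferred death multiplier): 0.982
#>   death_down   sign concordance: L2DR 1.00, conventional L2FC 1.00
#>   death_up     sign concordance: L2DR 1.00, conventional L2FC 1.00
#>   repair_like  sign concordance: L2DR 1.00, conventional L2FC 0.12
#>   direction-call OR: L2DR 1.83e+04, conventional 163
#>   conventional-analysis error census: I=99 II=8 III=32 none=852
```

Reading this: of 1,000 genes (991 survive guide trimming), the inferred
death-rate multipliers track the simulated truth at Spearman ρ = 0.98. For
the repair-like class — knockouts that both grow slower and die faster, the
signature of DNA-repair genes under a DNA-damaging drug — the conventional
L2FC calls the correct death direction for only 12% of genes (they look
"enriched", hence resistant), while the death-rate analysis calls 100%
correctly. The error census counts the conventional analysis's 99 spurious
calls (Type I, mostly essential genes), 8 missed effects (Type II, the
growth defect exactly canceling the death excess in the fold change), and
32 sign inversions (Type III).

A Type II gene looks like this — L2FC indistinguishable from zero, yet a
confidently doubled death rate:

```r
subset(analysis$results, error_class == "II")[1, c("gene", "l2fc_tx_unt", "l2dr", "fdr")]
#>          gene l2fc_tx_unt l2dr      fdr
#> 244 GENE00247      0.0743 1.03 0.000648
```

A command-line front end over the same functions is installed at
`exec/lethaldyn` (subcommands `fit-kinetics`, `simulate-rv`, `synth-screen`,
`screen-analyze`, `benchmark`).

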