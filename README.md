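# ddabpp

Quantitative analysis of **depletion-dependent activity-based protein
profiling (dd-ABPP)** experiments measured by DIA/SWATH mass spectrometry.

## The problem

Protein and transcript abundances say nothing about whether an enzyme is
catalytically *active* — activity is set by active-site mutations,
post-translational modification, inhibitor binding. In dd-ABPP a tissue
lysate is split into two aliquots: one is left untreated (the **total**
extract), the other is reacted with an activity-based probe (for serine
hydrolases, a fluorophosphonate that covalently binds the active-site
serine) and the tagged enzymes are pulled out on beads (the **depleted**
extract). Both aliquots are quantified by DIA-MS over the same peptide
transitions. Whatever signal an enzyme *loses* in the depleted extract is
the part of it that was active.

The package turns paired total/depleted transition tables into per-enzyme
active fractions and everything downstream of them: differential activity
statistics, co-depletion interactomes, discriminant signatures, and
spectral-library error rates. A fully seeded synthetic cohort generator
provides ground truth, so every stage has a recovery test without any raw
MS data.

## The estimator

For enzyme *E* in one sample, over the *k* confident peptides whose
transitions are observed in **both** extracts:

```
log2ΔInt = log2( Σ depleted intensities ) − log2( Σ total intensities )
RADDi    = 1 − 2^(log2ΔInt)          (clamped to [0, 1])
```

RADDi estimates the catalytically active fraction of the enzyme. Because
stable proteins also fluctuate between paired runs, an enzyme's per-sample
ratios within a condition are gated against the pooled depletion ratios of
**internal standard peptides** (ISPs — endogenous housekeeping/cytoskeletal
peptides selected by a five-fold filter) with a one-sided two-sample
Kolmogorov–Smirnov test (`D⁺ = sup [F_enzyme − F_ISP]`,
`p = exp(−2mnD⁺²/(m+n))`, the orientation of R's
`ks.test(..., alternative = "greater")`). Where the depletion signal stays
inside the technical-noise range, the activity is set to 0.

Around the core sit the standard stages: ISP-anchored normalization,
left-censored imputation, median-polish protein summarization,
layer-appropriate GLMs (Gaussian for log2 abundance,
quasibinomial-probit for RADDi, Poisson for counts) with
Benjamini–Hochberg correction, two-sided-KS co-depletion calls with
random-interactome and physical-evidence permutation nulls, single- and
multi-block sparse PLS-DA with five-fold cross-validated tuning, and a
permutation estimate of the FDR of a filtered spectral sub-library.

## Worked example

```r
library(ddabpp)

sim <- simulate_cohort(sim_params(seed = 7))   # 12 patients, T/N pairs
isp <- select_isp(sim$quant, isp_criteria(sim$isp_candidates))
qn  <- normalize_by_isp(sim$quant, isp)
fit <- ddabpp(qn, sim$design, isp, sim$catalog)
fit
#> dd-ABPP activity profile
#>   enzymes:    50
#>   samples:    24
#>   conditions: N_long, N_short, T_long, T_short
#>   enzymes passing the KS gate (p <= 0.05) in >= 1 condition: 31

s <- summary(fit)
head(s[s$gated, ], 5)
#>     enzyme_id condition m statistic     ks_p gated mean_raddi
#> 1       SH001    N_long 6     1.000 1.09e-05  TRUE      0.770
#> 51      SH001   N_short 6     1.000 1.09e-05  TRUE      0.585
#> 101     SH001    T_long 6     0.833 3.57e-04  TRUE      0.198
#> 151     SH001   T_short 6     1.000 1.09e-05  TRUE      0.542
#> 2       SH002    N_long 6     1.000 1.09e-05  TRUE      0.432
```

`m` is the number of condition samples entering the KS gate, `statistic`
the one-sided D⁺ against the ISP reference, and `mean_raddi` the average
active fraction across the condition's samples. On this simulated cohort
(noise sd 0.2 log2 units) the gated estimates recover the planted active
fractions with a mean absolute error of 0.018; with the noise switched off
the recovery is exact to machine precision — the identity
`1 − 2^(log2(1−α)) = α` holds by construction.

`coef(fit)` returns the enzyme × sample RADDi matrix, `plot(fit)` the
per-condition dot display. `run_pipeline(default_config())` chains all
eight stages (simulate → select-isp → normalize → impute → raddi →
differential → interactome → classify) into an artifact directory with a
seed-recording manifest; the same subcommands are available from the shell
via `exec/ddabpp`.

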