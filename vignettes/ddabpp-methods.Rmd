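---
title: "Models and methods behind ddabpp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ddabpp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddabpp)
```

## The measurement model

dd-ABPP splits one tissue lysate into two aliquots. The *total* aliquot is
quantified as is; the *depleted* aliquot first has its catalytically
active enzymes removed by covalent probe capture on beads. Both aliquots
are acquired by DIA-MS over identical peptide transitions, so for any
protein the two extracts are two measurements of the same molecules, the
second scaled by whatever fraction survived the capture.

Writing the active fraction of enzyme $E$ in a specimen as $\alpha$, the
depleted-extract signal is $(1-\alpha)$ times the total-extract signal.
The package estimates $\alpha$ through the depletion ratio of the summed
matched transitions,

$$\log_2\Delta \mathrm{Int} \;=\;
  \log_2\!\Big(\sum_{i=1}^{k} \mathrm{dep}_i\Big) -
  \log_2\!\Big(\sum_{i=1}^{k} \mathrm{tot}_i\Big),
  \qquad
  \mathrm{RADDi} = 1 - 2^{\log_2\Delta \mathrm{Int}},$$

where the $k$ confident peptides contribute only transitions observed in
*both* extracts of that sample. Only the ratio of sums is used, so any
per-sample rescaling common to both extracts — protein loading, specimen
size — cancels; the package's tests assert this scale invariance
explicitly.

Assumptions worth keeping in mind: capture efficiency is treated as
complete (a partially efficient probe biases $\alpha$ downward for all
enzymes alike); transitions are assumed comparable between the paired
runs, which is why the matched-transition restriction is enforced
structurally; and apparent *enrichment* in the depleted extract
($\log_2\Delta\mathrm{Int} > 0$) is treated as noise and clamped to
RADDi $= 0$ rather than reported as negative activity.

## The technical-noise reference and the KS gate

An undepleted protein still shows a nonzero ratio between paired runs —
chemical noise, sampling error, drift. The reference for "how large is
that" is built from **internal standard peptides (ISPs)**: endogenous
housekeeping/cytoskeletal peptides passing five filters
(`isp_criteria()`):

* membership of the user-supplied candidate list;
* missing fraction below 5% of runs;
* variance equality between the peptide's depleted-run and total-run log2
  values (two-sided F-test with the larger variance in the numerator,
  $p > 0.2$ — the test is directionless because "stable" means neither
  extract is noisier);
* paired Pearson correlation between extracts $r > 0.6$, $p < 0.05$;
* sequence length of at least 8 residues ("more than 7" read strictly).

The variance and correlation screens run on quantile-normalized log2
peptide intensities; quantile normalization is internal to this
pre-screen and deliberately not offered as a user-facing normalization
mode, since the pipeline's normalization is ISP-anchored instead.

Per condition, the pooled ISP-protein-by-sample ratios form the reference
distribution, and each enzyme's per-sample ratios are compared with it by
a one-sided two-sample Kolmogorov–Smirnov statistic
$D^+=\sup_t[\hat F_{\mathrm{enzyme}}(t)-\hat F_{\mathrm{ISP}}(t)]$, large
when the enzyme's ratios sit below (more depleted than) the reference.
This is exactly the orientation of R's
`ks.test(x, y, alternative = "greater")`, which the implementation
cross-checks in its tests. The default p-value is the one-sided
asymptotic bound $\exp(-2mnD^{+2}/(m+n))$, conservative at the
per-condition sample sizes involved (six or so); the exact Smirnov null
is available via `ks_gate(..., exact = TRUE)`. Where the gate stays shut
the activity is reported as 0, which makes RADDi matrices zero-inflated —
the reason the differential layer uses a quasibinomial model rather than
a Gaussian one.

Two granularities are defensible for the KS input: one ratio per enzyme
per sample (default, matching the reference's protein-by-sample
granularity) or the pooled per-peptide ratios (`pool = "peptide"`, more
values but pseudo-replicated). The default was chosen so both sides of
the test carry one value per protein per sample; the flag exposes the
alternative rather than deciding it silently.

## Normalization, imputation, summarization

**Normalization** subtracts, per MS run, the deviation of the run's ISP
median log2 intensity from the global ISP median — one multiplicative
constant per run, so within-run ranks and log-ratios are untouched and
per-run ISP medians become exactly equal. Runs without any ISP feature
are an error by design: silently skipping them would leave their ratios
on a different scale.

**Imputation** replaces each missing value with a draw from
$\mathcal N(0.9\cdot\min(\text{observed}),\, 0.5\cdot\mathrm{sd}(\text{observed}))$
over the protein's observed intensities in the same extract, floored at
zero — the model being that DIA missingness is mostly left-censored, so
plausible values sit just under the protein's detection floor. The rule
is applied on the linear intensity scale, where a protein with minimum
1000 and sd 100 yields draws from $\mathcal N(900, 50)$; the scale is
genuinely underdetermined, so `scale = "log2"` applies the same rule on
the log2 scale instead. A protein with no observed value at all falls
back to the global minimum with a warning. Depletion ratios themselves
are computed on observed, matched transitions only — imputation feeds the
abundance and classification layers, never the ratio numerator or
denominator.

**Protein summarization** of the total-extract proteome is Tukey median
polish over each protein's transition-by-sample log2 matrix (the protein
abundance is the overall plus the column effect). Median polish is the
robust summary conventionally used for exactly this job; a single outlier
transition among five moves the summary by less than 0.1 log2 units in
the package's robustness test. A full linear mixed-effects summarization
would add run-level inference the rest of the pipeline does not consume.

## Differential statistics

`fit_glm()` maps each data layer to its family: Gaussian/identity for
log2 abundances, quasibinomial/probit for RADDi (a proportion, typically
zero-inflated; dispersion by Pearson $\chi^2/\mathrm{df}$), and
Poisson/log for spectral counts. Covariates (age, 0/1 sex, 0/1 smoking,
tumor-cell percentage) enter additively; Wald contrasts are reported per
condition pair with raw p-values always alongside any adjustment. RADDi
values of exactly 0 or 1 are nudged by $10^{-6}$ before the probit fit to
avoid infinite working responses; degenerate fits (no residual variance,
separation) surface as flagged `NA` p-values, while covariate–condition
collinearity is a hard rank-deficiency error. When more than one contrast
is tested within a feature, the default post-hoc adjustment is
single-step max-t via `multcomp`; Bonferroni is available behind the
`posthoc` flag, and neither is asserted to be "the" correct choice —
the underlying convention is genuinely unspecified in this field's
practice. Across features, BH step-up is used (`adjust_bh()`, with
missing p-values excluded from the family size), verified in the tests
against a brute-force step-up oracle.

## Interactome layer

Co-depletion of a non-enzyme protein — its ratios shifted *or* reshaped
relative to the ISP reference — is evidence of physical association with
captured enzymes, so `call_codepleted()` uses the **two-sided** KS test,
at the nested 0.05 and 0.01 strata. Two permutation null models judge
enrichment, both reporting one-tailed normal (z-score) p-values:
`random_interactome_null()` redraws the enzyme set uniformly from the
quantified universe (without replacement, 200 iterations by default) and
recounts first-degree-neighborhood overlap with the depleted set;
`physical_overlap_null()` keeps the retained enzyme–protein pairs but
replaces the protein side with random quantified proteins (100
iterations) and recounts experimental-evidence edges. A degenerate null
(sd 0) yields a boundary p with a warning instead of a division by zero.
Enzyme–protein pairing itself uses plain Pearson correlation across
samples with the significance rule $t = r\sqrt{n-2}/\sqrt{1-r^2}$,
retaining $|r|>0.4$, $p<0.05$; the latent-variable variant of the same
selection consumes `pairwise_association()` from the multi-block fit.

## Discriminant signatures

`fit_plsda()` is NIPALS PLS2 against the centered one-hot class matrix,
with the component count defaulting to one fewer than the number of
classes. Sparsity is per-component hard truncation: after convergence
only the top-k largest-magnitude weights survive and the weight vector is
renormalized. Deflation is classic PLS2 regression deflation, giving
mutually orthogonal scores (asserted to $10^{-8}$); weight-vector signs
are fixed by making the largest-magnitude entry positive, so fits are
deterministic and comparable. VIP scores use per-component explained
class variance as weights, which fixes $\mathrm{mean(VIP^2)}=1$ as an
identity the tests assert on every fit.

The multi-block extension is sGCCA-style alternating optimization:
block weights maximize the design-weighted sum of covariances between
block scores and the class-block score; each block is deflated by its own
score and the class block by the consensus (average) score. With one
block the updates collapse to the NIPALS fixed point, and the test suite
requires score equality with `fit_plsda()` to $10^{-6}$. The block design
defaults to full connectivity with weight 1 — with two feature blocks and
a class block there is little room for anything subtler, and the weight
is exposed as `design_connectivity`. Prediction is nearest class centroid
in consensus score space (Euclidean; Mahalanobis behind a flag), and
`tune_cv()` grids per-block keep values and component counts under
stratified k-fold cross-validation, breaking error ties toward fewer
features and fewer components. Features are autoscaled by default;
activity (RADDi) blocks are conventionally fit unscaled since they
already live on $[0,1]$, and the pipeline does so.

## Spectral-library FDR

`estimate_fdr_permutation()` pools two virtual library matrices (defaults
139,449 and 30,000 entries — the first is the printed size of the
pan-human assay resource, the second a round figure for a project-scale
DDA library, configurable because the true value is not printed
anywhere), flags $\lfloor 0.01\cdot\text{size}\rfloor$ of each as false
targets, draws 100 random sub-libraries of 3,593 entries uniformly
without replacement, and summarizes the per-draw empirical FDR (mean, sd,
quantiles including the 95th percentile, and the probability of exceeding
a stated bound). The direction of "random data samplings" is ambiguous
between subsampling entries and permuting labels; uniform subsampling is
the default and `mode = "label_permutation"` provides the (here
distributionally equivalent) alternative. Library assembly itself gives
project-specific assays precedence on peptide overlap, drops
non-proteotypic peptides, and keeps the six most intense transitions per
peptide with ties broken by ascending product m/z — a deterministic rule
so assembly is idempotent.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates the paired-aliquot structure directly:

* log-normal transition baselines (log2 mean 14, sd 2, spanning a DIA
  dynamic range without overflow);
* a per-protein, per-specimen biological effect (log2 sd 1) shared by
  both aliquots of a lysate — it cancels exactly in ratios but gives
  paired extracts the strong total-vs-depleted correlation on which the
  ISP Pearson filter depends;
* additive per-run log2 shifts (sd 0.3) emulating LC-MS drift, which the
  ISP normalization must remove;
* independent per-transition multiplicative noise in each extract (log2
  sd 0.2 by default), so a protein's depletion-ratio noise follows the
  pairing model with sd $\approx \sigma\sqrt2$ — exact at one transition
  per protein, which is where the tests assert it;
* depletion of enzymes by planted $\alpha$, of coupled partner proteins
  by $1-\mathrm{strength}\cdot\alpha$, and of housekeeping proteins never
  (they also carry half the noise, making them selectable as standards);
* missingness, completely at random by default, with a left-censored
  option that drops the lowest-intensity records.

The default layout (12 patients, each a tumor and an adjacent-tissue
sample, survival halves, hence four conditions of six samples) mirrors a
discovery-cohort design. With the noise switched off, RADDi recovery is
exact to machine precision — the pipeline's strongest end-to-end
invariant.

Deliberately not simulated: chromatography, spectra, identification
error, interference between co-eluting peptides, intensity-dependent
(heteroscedastic) noise, batch structure beyond a single run effect, and
survival times. Passing tests therefore demonstrate the correctness of
the estimators under the stated model, not robustness to every artifact
of real acquisitions.

## Numerical choices and desk-scale test sizes

Tolerances and degenerate-input rules collected in one place: positive
ratios clamp to RADDi 0; a zero total-extract sum is a flagged undefined
ratio, and an enzyme with no matched transitions propagates `NA`, never
0; the KS gate needs at least 3 enzyme ratios (configurable) and warns
below 20 reference values; NIPALS converges at $10^{-10}$ on the squared
weight change with a 500-iteration cap; constant features are skipped in
correlation screens with a note; fold assignment in `tune_cv()` is
stratified and fully determined by its seed.

The verification suite runs at sizes chosen for completeness per CPU
minute, stated here as the package's own choices: exact recovery on a
4-condition × 6-sample cohort with 50 enzymes over the planted grid
$\alpha \in \{0, 0.1, \ldots, 0.9\}$; gate calibration on 10,000 null
enzyme–reference comparisons at the depletion-ratio level (the scale on
which the gate operates); interactome-null calibration on 200 replicate
experiments over 400-protein universes with 1,500-edge random graphs, 30
pseudo-targets and 120-protein depleted sets — sized so the null overlap
count has a standard deviation well above 1 and the normal p-grid is much
finer than the 0.1 uniformity tolerance; and a planted 4-class, 2-block
cohort (6 samples per class, four informative features per class per
block at 2.5 sd) for the cross-validated consensus classifier.

## Known limitations

RADDi is a *relative* index: it does not recover absolute active-site
stoichiometry, and probe-binding kinetics are outside the model. The
asymptotic KS p-value is conservative at small per-condition sample
sizes, so gates err toward reporting inactivity. The ISP reference is
assumed exchangeable with enzyme noise; if standards are systematically
quieter than enzymes (as selection for stability encourages), the
two-sided co-depletion test can read the extra spread of a noisy-but-
undepleted protein as signal — one reason calls carry two strata and the
permutation nulls judge set-level enrichment rather than single calls.
Identification-level FDR is accepted as upstream metadata; the package
does not re-score peptide identifications.
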