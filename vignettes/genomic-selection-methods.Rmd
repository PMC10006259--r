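---
title: "Genomic selection for forage grass breeding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection for forage grass breeding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

forageGS implements the genomic-selection workflow used for
obligate-outbreeding forage grasses such as perennial ryegrass, where
candidates are individual plants or poly-cross synthetic varieties, traits
range from seasonal nutritive value to ordinal 1–9 morphological scores, and
genotypes come from sequencing with substantial missingness. This vignette
explains the models, the defaults, and the reasoning behind the numerical
choices; the README shows the workflow end to end.

## The prediction model

The core is BayesA whole-genome regression,

$$ y = u\,1_n + K v + e, \qquad
   v_j \sim N(0, \sigma^2_{v_j}), \qquad e \sim N(0, \sigma^2_e I), $$

where $K$ is the $n \times m$ matrix of alternative-allele dosages (0/1/2
for individuals; continuous $[0,2]$ rows for pooled variety genotypes) and
every marker effect has its own variance with a scaled-inverse-chi-squared
prior — marginally a scaled-t prior on effects, which accommodates traits
controlled by few large-effect loci (typical of morphological scores) as
well as highly polygenic ones (nutritive value). Dosages enter the model as
coded; no centring or standardisation is applied by default (`center =
FALSE`), because the model is stated on raw allele counts and the intercept
absorbs the resulting location shift. Centring is available as an option
and changes GEBVs only by a constant.

Fitting is single-site Gibbs sampling (`fit_bayesa()`), with the inner loop
in compiled code. Updates per iteration: the intercept from its normal full
conditional; each effect $v_j$ from its normal full conditional; each
$\sigma^2_{v_j}$ from scaled-inv-$\chi^2(\nu_v + 1,\, S_v + v_j^2)$; the
residual variance from scaled-inv-$\chi^2(\nu_e + n,\, S_e + e'e)$. We use
the sum-of-squares convention throughout: a draw from
scaled-inv-$\chi^2(\nu, S)$ is $S/\chi^2_\nu$, so prior scales enter full
conditionals additively. This is stated explicitly because the other
convention (scale multiplied by $\nu$) silently changes the strength of the
prior.

### Prior calibration and the adaptive marker scale

Hyper-scales follow the standard calibration rule of Bayesian
whole-genome-regression software, anchored on a prior heritability $h^2_0$
(`h2_prior`): with $V = \mathrm{Var}(y)$ and $\mathrm{MSx}$ the sum of the
genotype columns' sample variances,

$$ S_e = V (1 - h^2_0)(\nu_e + 2), \qquad
   S_v = \frac{V h^2_0 (\nu_v + 2)}{\mathrm{MSx}}. $$

Degrees of freedom default to 5 for both, so each marker variance has a
strong prior relative to its single observation. If $S_v$ stayed fixed,
markers with no real effect would keep drawing effects of prior-scale
magnitude; with hundreds of such markers their summed contribution inflates
the sampled genomic values and hence the heritability estimate — in our
recovery experiments (400 individuals, 600 loci, true $h^2 \approx 0.37$) a
fixed scale produced estimates of 0.43–0.56 depending on the prior. The
default (`update_scale = TRUE`) therefore treats $S_v$ as unknown with a
Gamma prior (shape 1.1, prior mode at the rule's value) and samples it from
its Gamma full conditional each iteration — the default behaviour of the
reference software this workflow emulates. With the adaptive scale the same
experiments give 0.370–0.378 for priors 0.2–0.8, i.e. the estimate is
driven by the data, not the prior. `update_scale = FALSE` restores the
fixed-scale variant.

### Heritability and the two-stage protocol

Narrow-sense heritability is tracked per iteration as

$$ h^2_t = \frac{\mathrm{Var}_s(g_t)}{\mathrm{Var}_s(g_t) + \sigma^2_{e,t}},
   \qquad g_t = K v_t, $$

with $\mathrm{Var}_s$ the sample variance over individuals; `h2_mean`
averages the post-burn-in values. Analyses follow a two-stage protocol
(`genomic_prediction()`): a pre-pass with a neutral prior ($h^2_0 = 0.5$)
estimates heritability, and that estimate seeds the prior of the prediction
run. When an external heritability expectation exists — e.g. 0.85 for
heading date predicted from a large synthetic-variety reference — it can be
passed directly. Chains default to 12,000 iterations with 2,000 burn-in;
traces of the intercept, residual variance and heritability are kept for
convergence inspection. The pre-pass uses the same chain settings as the
prediction run.

## Evaluation schemes

Accuracy is always *predictive ability*: the Pearson correlation between
GEBVs and observed phenotypes in the validation samples. It is not divided
by $\sqrt{h^2}$, so the heritability ceiling applies: expected accuracy
cannot meaningfully exceed $\sqrt{h^2}$.

* **k-fold** (`kfold_accuracy()`): one random partition into five disjoint
  folds of ~20%, each fold predicted from the remaining 80%; mean and sd
  over folds. Disjoint folds (every sample tested exactly once) are the
  default reading of "masking 20% at a time, averaged over 5 rounds"; five
  independent 20% masks are available via `disjoint = FALSE`. The MAF
  filter (default 0.05) is re-applied within every training subset, since
  a fold's allele frequencies differ from the full set's.
* **Forward prediction** (`forward_prediction()`): fit on pooled earlier
  years, predict the next year. Besides accuracy it reports the *inflation
  slope*, the regression coefficient of observed phenotype on GEBV: slope
  < 1 means the GEBV spread overstates the realised phenotype spread. The
  orientation matters — regressing GEBV on phenotype would put inflated
  predictions above 1 — and is chosen so that inflation reads as < 1.
* **Pooled reference** (`pooled_reference_prediction()`): train on
  synthetic-variety rows (per-locus mean parent dosage, continuous in
  $[0,2]$) with pool-mean phenotypes, predict individuals. Pools of size 1
  reduce exactly to individual-reference prediction, which the tests
  exploit.

A caution from our null-calibration experiments: for a trait with zero
heritability the five fold accuracies are *not* independent — they share
the trait's chance association with the marker panel — so a single trait's
fold-mean accuracy has a standard deviation near 0.1 and either sign.
Accuracy estimates near zero should be read with that noise floor in mind;
the package's own calibration checks average over replicate simulated
traits for this reason.

## Genotype quality control

The QC cascade mirrors standard practice for sequencing-derived SNP
matrices and is order-dependent by design:

1. `filter_allowed_alleles()` — drop loci whose observed alternative allele
   is not the designed one, and loci absent from the SNP list.
2. `missingness_filter()` — per-locus missingness computed over
   *informative* samples only (overall missingness < 50%), loci above 25%
   dropped; then per-sample missingness recomputed on the retained loci and
   samples above 90% dropped. All thresholds are strict inequalities
   ("more than", "greater than"); a locus at exactly 25% survives.
3. `maf_filter()` — minor-allele frequency $\min(p, 1-p)$ with $p$ the mean
   dosage over non-missing entries divided by 2; default minimum 0.05.
4. `ld_knn_impute()` — LD-informed k-nearest-neighbour imputation.

For each missing call at locus $j$, imputation ranks the other loci by
squared Pearson correlation with $j$ (the standard composite-LD surrogate
when phase is unknown), takes the top `n_ld_snps` (default 30), measures
the distance between the target sample and every sample observed at $j$ as
the mean absolute dosage difference over those loci (missing pairs skipped,
the sum rescaled by the count used, plus $10^{-6}$ so inverse-distance
weights stay finite), and imputes the 1/distance-weighted mean of the
`n_neighbors` (default 5) nearest samples' dosages, rounded to the nearest
integer in $\{0,1,2\}$ — downstream models code genotypes as integers. The
`l` and `k` defaults are the published defaults of the method. Ties in LD
rank and in distance break by column/row order, making results
deterministic. Loci with fewer observed calls than neighbours fall back to
the rounded mean dosage and are flagged. `imputation_accuracy()` estimates
accuracy by masking observed entries and scoring exact dosage agreement.

## Synthetic populations

`simulate_genotypes()` generates diploid dosages in consecutive LD blocks:
each block draws an allele frequency uniformly from `maf_range` and a pair
of latent gametes per individual; each locus in the block copies the latent
alleles, independently redrawing each with probability `ld_decay` (default
0.1, giving within-block $r^2 \approx 0.8$). This gives tunable LD with the
marginal allele frequency preserved, without coalescent machinery —
deliberately simple, and sufficient for the imputation and prediction
properties the tests exercise. What it does *not* emulate: realistic
allele-frequency spectra, LD decay with distance, inbreeding, or
self-incompatibility structure; conclusions about real panels should not be
drawn from the generator beyond the tested properties.

`simulate_phenotypes()` draws `n_qtl` causal loci, samples their additive
effects across measurement occasions from a multivariate normal with the
configured genetic correlation matrix, and adds environmental noise with
variance $\mathrm{Var}(g)(1-h^2)/h^2$, so the expected narrow-sense
heritability equals the target analytically rather than by post-hoc
rescaling — phenotype units stay stable across replicates. True breeding
values are centred per occasion and returned with the realized
heritability, supporting parameter-recovery tests. Ordinal 1–9 traits are
produced by rounding the latent trait into the configured range (clamped at
the bounds); cohort year shifts are additive offsets. With a zero target
heritability the genetic term is omitted from the phenotype (the noise
formula is undefined at $h^2 = 0$) while the breeding values are still
reported, making phenotype and breeding value independent by construction.
Missingness (`inject_missingness()`) is completely at random; real
missingness mechanisms (coverage-, frequency- or batch-dependent) are out
of scope.

Desk-scale defaults (hundreds of individuals, hundreds of loci) are used
throughout the tests and the acceptance script; the recovery experiments
run at 400 individuals × 600 loci with the full 12,000-iteration chain,
the calibration and imputation experiments at 300 × 200.

## Parental grouping under GEBV windows

`simulate_parent_groups()` emulates assembling a poly-cross from a clonal
nursery under a distinctness/uniformity restriction: the first parent is
drawn uniformly; every later parent is drawn uniformly from the plants
whose GEBV is within the selection window of *all* previously chosen
parents (the joint reading of the restriction), inclusive bounds, without
replacement within a replicate. The recorded outcome is the observed
phenotype range of the group, averaged over successful replicates (default
10,000); replicates that exhaust the candidate pool are counted as failed
and excluded — with a window of zero and continuous GEBVs every replicate
fails and the mean is reported missing rather than zero. Inclusive bounds
were chosen for determinism at integer windows. The characteristic
attenuation — narrowing the window by one unit reduces the phenotype range
by less than one unit whenever GEBV–phenotype correlation is below 1 — is
reproduced on simulation and verified against an exact path-enumeration
oracle on small fixtures. Group sizes 5 and 6 are supported for breeders
who over-select and cull visually.

## Phenotype statistics

Outlier removal delegates to `grDevices::boxplot.stats()` — points outside
$[Q_1 - 1.5\,\mathrm{IQR},\ Q_3 + 1.5\,\mathrm{IQR}]$ with Tukey hinge
quartiles — applied once per trait × occasion, not iterated (re-application
can cascade). Groups with fewer than four values are left untouched with a
warning. Correlation matrices (`correlation_matrix()`) use pairwise-complete
Pearson correlations with two-sided t-test p-values and star flags at
0.05/0.01/0.001, uncorrected for multiple testing, matching the standard
presentation of seasonal trait-correlation panels. Distribution summaries
use Tukey hinges for consistency with the outlier rule.

## Reference tables

`nv_reference()`, `pbr_reference()` and `selection_window_reference()` ship
per-trait heritabilities, prediction accuracies and grouping-simulation
ranges reported by a published perennial-ryegrass genomic-selection study
(plain CSV under `inst/extdata`). The underlying breeding-program data are
not publicly deposited, so these summary tables are the only real-data
anchor: the package's table-level statistics (e.g.
`heritability_accuracy_correlation()`, seasonal means) are computed from
them, while all data-level validation runs on synthetic populations with
known ground truth. Passing those synthetic checks demonstrates the
machinery is correct at desk scale; it does not certify accuracy levels on
any particular real panel.

## Known limitations

* Single-trait, additive model: no multi-trait fits, no
  genotype-by-environment terms, no dominance/epistasis.
* The generator's LD is block-wise with a constant level, not
  distance-decaying; imputation accuracies on it are optimistic relative to
  panels with weaker local LD.
* Pooled-variety prediction assumes pool phenotype = mean parent phenotype,
  ignoring non-additive variety effects.
* `correlation_matrix()` materialises the trait × occasion wide matrix;
  with tens of thousands of samples × cells memory grows accordingly.
* LD ranking inside `ld_knn_impute()` computes an $m \times m$ correlation
  matrix; for panels much beyond $10^4$ loci a windowed strategy would be
  needed.
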