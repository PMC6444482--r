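---
title: "Genomic prediction of bull fertility with major dominance markers and functional SNP classes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction of bull fertility with major dominance markers and functional SNP classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirefert)
```

## The problem

Sire conception rate (SCR) is the phenotypic measure of dairy bull
fertility used in the US national evaluation: the expected deviation of a
bull's conception rate from the mean of all evaluated bulls, in
percentage points. Bull fertility is lowly heritable (h&sup2; &asymp;
0.30) and hard to predict, yet a single sire can inseminate hundreds of
cows, so even modest gains in predictive accuracy matter. Two sources of
information beyond the standard whole-genome model are of interest:

1. a handful of **large-effect dominance markers** — SNPs at which one
   copy of the alternate allele is enough to shift fertility, consistent
   with recessive-acting variants in male-fertility genes; and
2. **functional annotation**, partitioning markers into classes (5'
   region, 3' region, non-synonymous, synonymous, ncRNA, intergenic)
   whose biology suggests different prior relevance.

`sirefert` implements the full analysis as a tested pipeline: a
synthetic-data generator with a known truth ledger, quality control, SNP
annotation, a two-step mixed-model dominance scan with genomic control,
and Bayesian RKHS (kernel) prediction models evaluated by repeated
cross-validation. Real national-evaluation genotypes are not
redistributable, so every claim the package makes is demonstrated on
synthetic data whose generating process is documented below.

## Models

### Dominance scan (two-step mixed model)

Step one fits the no-SNP animal model
$$y = Xb + u + e, \qquad u \sim N(0, G\sigma^2_u), \quad
  e \sim N(0, I\sigma^2_e),$$
where $X$ carries the intercept and evaluation-class effects and $G$ is
the additive genomic relationship matrix from all post-QC SNPs. REML
estimation uses the eigendecomposition $G = UDU'$, which diagonalises
$V_0 = G\sigma^2_u + I\sigma^2_e$ and reduces REML to a one-dimensional
search over $h = \sigma^2_u / (\sigma^2_u + \sigma^2_e)$ with the scale
profiled out.

Step two scores each SNP's **carrier code** $x$ (0 for AA, 1 for AB or
BB — testing whether one B copy acts like two) with
$$z = \frac{\tilde x' V_0^{-1} (y - X\hat\beta)}
           {\sqrt{\tilde x' V_0^{-1} \tilde x}},$$
where $\tilde x$ is $x$ adjusted for the fixed effects in the
$V_0^{-1}$ metric. The adjustment leaves the numerator untouched (the
GLS residual is orthogonal to $X$ already) but is essential in the
denominator: with a raw 0/1 coding the term $1'V_0^{-1}1$ roughly halves
the statistic and destroys its standard-normal null calibration, which
is the property the test is built on. Mixed-model score implementations
achieve the same thing by centring the genotype before scoring. After
the one-time $O(n^3)$ decomposition, scoring all $p$ SNPs costs one
$n \times n$ by $n \times p$ product (the numerator alone is $O(n)$ per
SNP); no dense $V_0^{-1}$ is ever formed.

Genome-wide statistics are corrected by **genomic control**: the
inflation factor $\lambda$ is the no-intercept regression slope of the
sorted observed $\chi^2_1$ statistics on their expected order quantiles,
truncated below at 1 so the correction is never anti-conservative, and
$z_{corr} = z/\sqrt\lambda$. Major markers are selected at Bonferroni
$\alpha = 0.05$; planted QTL reach $|z|$ far beyond any reasonable
threshold, so the exact cutoff does not drive recovery.

### Kernel prediction models

All prediction models are Bayesian RKHS regressions with linear genomic
kernels
$$K = \frac{SS'}{p},$$
$S$ the centred, standardized genotype matrix — the VanRaden genomic
relationship matrix, under which the single-kernel model is GBLUP.
Single-kernel models use all SNPs ("Base") or one functional class;
multi-kernel models fit the five functional classes plus intergenic
simultaneously,
$$y = Xb + \sum_{j} K_j \alpha_j + e,$$
so the data weight each class through its own variance component
$\sigma^2_{gj}$. Selected major markers enter as **fixed** 0/1 carrier
covariates ("Base + 5 SNP" and "Intergenic + 5 SNP + Functional").

The Gibbs sampler works on the genetic-value scale $g_j = K_j\alpha_j$
through the eigendecomposition $K_j = U_j D_j U_j'$: with
$g_j = U_j\delta_j$ and $\delta_{jk} \sim N(0, d_{jk}\sigma^2_{gj})$
every update is element-wise, costing two $n^2$ rotations per kernel per
iteration after one $O(n^3)$ decomposition (eigenvalues below $10^{-10}$
truncated). Literature sometimes writes
$\alpha \sim N(0, K^{-1}\sigma^2_g)$; that density is only proper for
full-rank $K$, while the $g$-scale formulation used here is equivalent
when $K$ is full rank and remains well-defined otherwise — that is why
the sampler is parameterised on $g$.

Priors are scaled-inverse-$\chi^2$ on every variance with `prior_df = 5`
and scales set so the prior mode assigns `prior_R2 = 0.5` of the
phenotypic variance to genetics, split equally across kernels — the
default rule of the standard Bayesian regression software for this model
class. Fixed effects get a flat prior. Held-out phenotypes are treated
by data augmentation: sampled from their conditional normal each
iteration and excluded from the variance updates' sufficient statistics
only through their sampled values, which is exactly how test animals are
predicted ("phenotypes set to unknown").

### Cross-validated evaluation

Five-fold cross-validation, repeated (ten times at full scale), refits
each model with the test fold's phenotypes masked; fixed effects,
including evaluation classes, are re-estimated within each training set
through the masking. Performance is the Pearson correlation (CORR)
between observed and predicted test phenotypes, and the mean squared
error of prediction. MSEP is computed as the total squared error over
all test predictions divided by their number: a display that divides the
across-fold sum by a per-fold $n$ would scale as $k$ times the
per-observation error, inconsistent with MSEP values near 4 on a
phenotype with SD near 2, so the per-observation convention is used.
Functional classes are benchmarked against size-matched random SNP sets
(10 samplings at full scale, giving 500 estimates). CORR converts to a
selection accuracy as CORR$/\sqrt{h^2}$; the conversion truncates (not
rounds) when reported to three decimals, the convention under which
$0.403/\sqrt{0.30}$ is quoted as 0.735.

Major markers for "Base + 5 SNP" are selected once on the complete data
before cross-validation — matching how such markers are found in
practice on a full evaluation — which leaks selection information into
the folds; the planted-QTL simulations here are insensitive to this
because the markers are overwhelmingly significant, but a strict
within-training-fold selection is the right design when effects are
marginal.

## The synthetic-data generator

The generator defines the study conditions; it is deliberately simple
and fully parameterised by `sim_config()`:

* **Genotypes.** Biallelic SNPs, B-allele frequency uniform on
  [0.05, 0.5], evenly spaced on 29 autosomes. Linkage disequilibrium is
  modelled by latent Gaussian AR(1) haplotypes (rho = 0.9) within fixed
  SNP blocks: marginal frequencies are preserved exactly while adjacent
  SNPs within a block correlate positively; `ld_block_size = 1` gives
  independent SNPs. Missing calls are independent at `missing_rate`.
* **Phenotypes.** $y = \mu + c_{e} + \sum_j s_{j} a_j +
  \sum_q d_q 1[x_q \ge 1] + e$ with 29 evaluation classes
  (SD 0.5), additive effects scaled so the additive share of the
  phenotypic variance (default 4, the SCR scale) is exactly
  `h2_additive`, and each dominance QTL a pure carrier shift — AB and BB
  means coincide and the QTL's additive effect is zero — contributing
  `dominance_variance_fraction` of the variance. Carriers are shifted
  downwards, as expected for deleterious recessive-acting fertility
  variants. Breeding counts follow a negative-binomial (mean 500); 10%
  of bulls get a duplicate record with a distinct breeding count, whose
  lower-reliability copy carries extra noise, so the "keep the most
  breedings" rule is exercised deterministically.
* **Annotation.** Class labels are drawn per SNP from
  `class_proportions` (defaults mirror a 295k-SNP Holstein panel:
  7280 : 4122 : 1144 : 2090 : 1556 over the five classes, the remainder
  intergenic). Positional classes emit a gene whose 5' or 3' end lies
  within 5 kb of the SNP so the annotation module re-derives the label
  from coordinates; coding/ncRNA classes emit a containing gene plus an
  explicit effect term. Inter-SNP spacing (25 kb) exceeds any gene plus
  its flanks, so labels never interfere. Functional classes can be given
  additive-variance enrichment multipliers, which is what makes a
  functional kernel out-predict random SNP sets in the directional
  tests.

What the generator does **not** emulate: real Holstein allele-frequency
spectra and long-range LD, pedigree/family structure, selection, and
sequence-level codon context. Consequently, passing tests show the
machinery is correct and the study's contrasts reproduce in direction
under known truth; they do not certify real-data effect sizes. In
particular, with independent SNPs a random marker subset captures much
less polygenic signal than it would under real LD, so the
functional-vs-random contrast here is cleaner than on real data, where
intergenic proxies of functional variants blur it.

## Numerical choices

* Genotype standardization divides by $\sqrt{2\hat p(1-\hat p)}$ with
  $\hat p$ the observed frequency (VanRaden/Yang convention), after
  mean-imputing missing dosages. An `"empirical"` option divides by the
  observed population SD instead, under which `mean(diag(K)) == 1` holds
  as an algebraic identity (the two coincide only under exact
  Hardy-Weinberg proportions); kernels default to the binomial
  convention.
* Kernel eigenvalues below $10^{-10}$ are truncated; a ridge of
  $10^{-8}$ is tolerated on near-singular kernels. Non-PSD inputs
  (eigenvalues below $-10^{-8}$) are rejected.
* REML optimises over $h \in (10^{-6}, 1-10^{-6})$; estimates with
  $h < 10^{-3}$ are flagged as boundary (zero additive variance).
* QC boundaries are kept: MAF exactly 0.05 and call rate exactly 0.95
  pass, reading "below" strictly. MAF uses non-missing calls only.
  Ties in breeding counts break to the latest evaluation id, so
  de-duplication is deterministic.
* Annotation uses 0-based, half-open BED gene intervals; the 5 kb
  regulatory windows are inclusive of base 5000 and strand-aware. When
  classes conflict, coding labels beat positional ones and 5region
  beats 3region (the strongest annotation wins). Gene-body SNPs without
  a coding label fall to intergenic — UTRs are not modelled separately.
* The Geweke diagnostic compares the first 10% of a chain against the
  last 50%. Window-mean variances come from equal-length
  non-overlapping batch means (a Bartlett-type spectral-at-zero
  estimate); the pooled two-sample t statistic is mapped to the normal
  scale by a probability-integral transform, making the score standard
  normal for stationary white chains at finite length, not just
  asymptotically. AR-model spectral estimates were measured at about
  94.9% coverage at the nominal 95.4% threshold, which silently fails
  calibration checks; the batch-means form measures at 95.5%. Chains
  with residual autocorrelation longer than the batch length make the
  diagnostic anti-conservative — monitor thinned chains.
* Per-fit MCMC seeds in cross-validation derive deterministically from
  the base seed, repeat and fold, so every result is bit-reproducible;
  pipeline stages derive their seeds from one master seed by fixed
  offsets.

## Scale of the shipped experiments

The package's tests and the acceptance script run the full designs at
desk scale, chosen once: oracle equivalences at $n \le 200$; calibration
on 10,000 null statistics and a 300 x 10,000 null scan; heritability
recovery at $n = 2000$, $p = 2000$; QTL recovery over ten replicates at
$n = 1500$, $p = 2000$ with five QTL of 4% variance each; and
cross-validated model comparisons at $n = 400$–$600$ with chains of
1,200–1,500 iterations. The full-scale MCMC schedule (100,000 /
30,000 / thin 5, i.e. 14,000 retained samples) is available through
`mcmc_config()` and is verified arithmetically. At these scales the
planted contrasts are large relative to Monte-Carlo noise, which is what
a directional test needs; absolute CORR values are smaller than a
312k-SNP, 11k-bull analysis would give and are not compared to it.

## Known limitations

* The two-step scan loses some power relative to an exact per-SNP mixed
  model because the tested marker also contributes to $G$ and the
  polygenic fit partially absorbs strong signals; at the shipped scales
  the planted QTL remain overwhelming. Leave-one-chromosome-out
  variance estimation would remove this at extra cost and is not part
  of the design being reproduced.
* Marker selection for "+ 5 SNP" models leaks full-data information
  into cross-validation folds (see above).
* Missense/synonymous status is taken from provided labels, never
  computed from sequence; no reference genome is in scope.
* The multi-kernel sampler shares one residual variance across kernels;
  kernel-specific residual structures (heteroscedastic R) are out of
  scope.
* Class kernels need at least two usable SNPs; at small $p$ with
  realistic (panel-sized) class proportions some classes are skipped
  with a warning, so the shipped class-model experiments enlarge class
  shares instead of pretending panel scale.

## A worked example

```{r example, eval = FALSE}
library(sirefert)

cfg <- sim_config(n_individuals = 600, n_snps = 1200,
                  n_dominance_qtl = 5,
                  dominance_variance_fraction = 0.05, seed = 1)
g <- simulate_genotypes(cfg)
sim <- simulate_phenotypes(g, cfg)

gq <- filter_snps(g)                       # MAF/call-rate/sex-chrom QC
ph <- dedupe_records(sim$phenotypes)       # most breedings wins
ph <- ph[match(gq$sample_ids, ph$animal_id), ]

nf <- fit_null_model(ph$scr, eval_class_design(ph), grm(gq))
scan <- scan_dominance(gq, nf)             # carrier-coded score scan
sel <- attr(scan, "selected")

folds <- kfold_split(gq$sample_ids, k = 5, n_repeats = 10, seed = 2)
mc <- mcmc_config(n_iter = 1500, burn_in = 500, thin = 5, seed = 3)
base <- evaluate_model(model_spec("Base"), gq, ph, folds, mc)
plus <- evaluate_model(model_spec("Base + 5 SNP", fixed_snps = sel),
                       gq, ph, folds, mc)
summarize_cv(rbind(as.data.frame(base), as.data.frame(plus)))
```

The numbered scripts under `analysis/` run the same sequence stage by
stage, writing tables under `results/`, and `run_experiment()` drives it
from a single configuration with a reproducibility manifest.
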