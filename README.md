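# sirefert

Genomic prediction of dairy bull fertility (sire conception rate, SCR)
with large-effect dominance markers and functional SNP classes.

SCR is the US national phenotypic evaluation of bull fertility: the
expected deviation, in percentage points, of a bull's conception rate
from the mean of all evaluated bulls. It is lowly heritable
(h² ≈ 0.30), which caps what a standard whole-genome model can do. This
package implements, as a tested R pipeline, an analysis strategy that
augments genomic prediction with two extra sources of signal:

* a **two-step mixed-model genome scan for dominance**: a no-SNP animal
  model `y = Xb + u + e` with `u ~ N(0, G σ²ᵤ)` is fitted by REML on the
  genomic relationship matrix, then every SNP's 0/1 carrier code
  (AA vs {AB, BB}) is scored with the V₀-weighted statistic
  `z = x̃'V₀⁻¹(y − Xβ̂) / √(x̃'V₀⁻¹x̃)`, corrected by genomic control
  (regression-based λ, truncated at 1), with Bonferroni selection of
  major markers;
* **Bayesian RKHS / GBLUP prediction** with linear kernels `K = SS'/p`
  over all SNPs, single functional classes (5′region, 3′region,
  non-synonymous, synonymous, ncRNA, intergenic), or all six classes as
  separate kernels fitted jointly — with the selected major markers
  entering as fixed 0/1 effects — estimated by Gibbs sampling with an
  eigendecomposition reparameterization and scaled-inv-χ² variance
  priors;
* **repeated k-fold cross-validation** with predictive correlation
  (CORR) and mean squared error of prediction (MSEP), size-matched
  random-SNP baselines for each functional class, and the accuracy
  conversion CORR/√h².

Because national-evaluation genotypes are not redistributable, the
package ships a first-class synthetic-data generator (`sim_config()`,
`simulate_genotypes()`, `simulate_gene_models()`,
`simulate_phenotypes()`) that emulates the study structure — 29
evaluation classes, additive background at h² = 0.30, carrier-coded
dominance QTLs, functional-class labels with panel-like proportions,
duplicate phenotype records — and records the generating truth, so
every stage is testable end to end.

## Worked example

The numbered drivers under `analysis/` run the whole analysis on a
synthetic population of 600 bulls × 1,200 SNPs with five planted
dominance QTL (5% of variance each) and functionally enriched
annotation classes:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_annotate.R
Rscript analysis/04_dominance_scan.R
Rscript analysis/05_prediction_cv.R
Rscript analysis/06_report.R
```

which prints (abridged):

```
QC: 1200 -> 1195 SNPs (removed: excluded_chrom=0, low_maf=5, low_call_rate=0)
records: 660 -> 600 after keeping the most-bred record per bull
null_model_fit: sigma2_u = 1.5689, sigma2_e = 2.4566 (h2 = 0.390)
lambda_gc = 1.248
major markers (Bonferroni 0.05): snp00851, snp00796, snp00706
Base model:                 CORR 0.255, MSEP 3.958
Base + 5 SNP:               CORR 0.436, MSEP 3.432
CORR gain from major markers: +70.8%; MSEP change: -13.3%
multi-kernel vs Base CORR difference: -0.038
5region kernel CORR 0.169 vs size-matched random sets 0.133
```

Reading these numbers: the scan recovers the strongest planted markers
genome-wide (λ is mildly inflated because real signal is present);
adding them as fixed effects raises the cross-validated predictive
correlation and lowers MSEP, the multi-kernel model matches the
single-kernel whole-genome model within noise, and an additively
enriched functional class out-predicts random SNP sets of the same
size — the qualitative pattern the method is designed to show. At this
desk scale the null-model h² (0.39) exceeds the additive 0.30 because
the polygenic term absorbs part of the planted dominance variance.

The same sequence is available as one call,
`run_experiment(default_experiment_config(seed), out_dir)`, which also
writes a manifest (config snapshot, derived per-stage seeds, input
digests, timings) so a rerun reproduces identical outputs.

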