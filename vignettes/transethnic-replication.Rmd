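---
title: "Trans-ethnic replication and fine-mapping of height loci: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trans-ethnic replication and fine-mapping of height loci: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transheight)
```

# The analysis problem

Most height-associated variants were discovered in European-ancestry
cohorts.  Testing whether those signals are shared by African-ancestry
populations — and using the shorter-range linkage disequilibrium (LD) of
African genomes to fine-map them — raises three statistical problems that
this package addresses end to end:

1. **Per-study association and meta-analysis.**  Raw height is adjusted for
   sex, age, disease status, and ancestry covariates, normalized to
   Z-scores, and tested SNP by SNP under an additive model.  Studies are
   combined by fixed-effect inverse-variance weighting, with genomic
   control applied twice: within each study and again on the combined
   statistics.
2. **LD-aware replication.**  A European index SNP may fail to replicate
   simply because the causal variant sits on different haplotypes in
   African genomes.  The replication unit is therefore not the index SNP
   but the *bin*: European-LD proxies (r² ≥ 0.8) of each index SNP are
   clustered by African-LD (r² ≥ 0.3), each bin is represented by an index
   chosen from a randomized order, and its two-tailed P-value is converted
   to a one-tailed P using the direction predicted from phased European
   haplotypes.  Overall replication is judged against frequency-matched
   permutation null sets subjected to the identical procedure.
3. **Fine-mapping and functional enrichment.**  Re-running the binning with
   SNPs sorted by P-value (instead of randomized) yields each locus's
   best-supported candidate; comparing the fraction of candidates that are
   jointly associated with height and with cis gene expression against
   matched null sets tests whether fine-mapping enriches for functional
   variants.

# The synthetic cohorts

No individual-level data ship with the package.  The `synthetic_data`
module simulates the study conditions so every stage is testable:

* **Haplotype panels.**  A miniature chromosome is divided into blocks with
  exponentially distributed lengths (default mean 20 kb).  Each block draws
  an ancestral allele frequency uniformly from (0.05, 0.95); each
  population draws per-variant frequencies from the Balding–Nichols Beta
  distribution.  Because both populations diverge independently from the
  common ancestor, the Beta parameter is calibrated as `F' = 2F/(1+F)` so
  that the *pairwise* expected fixation index between the two panels equals
  the configured `divergence_F`.  Within each block, haplotypes copy one of
  8 founder haplotypes whose alternate-allele sets are nested by allele
  count: allele frequencies track the Balding–Nichols draws, within-block
  r² is high, and between-block r² is at sampling-noise level.  This
  founder-block construction was chosen over coalescent simulation because
  it is deterministic, fast, and gives exactly the LD features the binning
  machinery needs; it does not attempt realistic recombination maps,
  selection, or demographic history.
* **Admixed cohorts.**  Each individual's two chromosomes are mosaics of
  panel haplotypes with exponentially distributed ancestry tracts; each
  tract is African with probability `admixture_alpha` (default 0.8, the
  typical African-American genome-wide proportion).  The default tract mean
  (1 Mb) is scaled down to the miniature chromosome: real admixture tracts
  are tens of megabases, but a tract longer than the simulated chromosome
  would leave no within-chromosome ancestry variation to exercise the
  local-ancestry models.  The local-ancestry truth (European chromosome
  count, 0/1/2, per variant) is recorded from the tract origins, so
  conditional and stratified models can be validated against a known
  standard.  On the X chromosome, males carry one doubled chromosome
  (0/2 coding), keeping a single additive regression path for both sexes.
* **Phenotypes.**  Height is `baseline + sex and age effects +
  pheno_sd * (G + e)` with `G` the additive causal score in Z-units.  With
  `heritability_target = NULL` (default), the environmental noise has unit
  variance, so planted betas are recovered on the Z-score scale up to a
  small total-variance inflation; a numeric target instead scales the noise
  so the realized genetic variance fraction matches it exactly.
* **Summary-level simulation.**  For replication experiments at realistic
  sample sizes, `simulate_summary_stats()` draws meta-analysis-level
  estimates directly: `SE = 1/sqrt(2 n f (1-f))` and
  `beta_hat ~ N(beta_marginal, SE^2)`, with marginal effects propagated
  from causal SNPs through the panel's own LD (`beta * D / (f(1-f))`).
  This is the standard large-sample shortcut; it deliberately omits
  finite-sample and missing-genotype artifacts of real per-study scans.

What passing tests on these data do and do not show: they validate the
statistical machinery (calibration, power, invariances, exact worked
examples) under a clean generative model with block LD, two-way admixture,
and additive effects.  They do not certify behavior under genotyping error,
imputation uncertainty, relatedness, or fine-scale recombination — none of
which the generator emulates.

# Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `divergence_F` | 0.15 | – | target pairwise Fst between panels; CEU/YRI-scale divergence |
| `block_length_mean` | 20 000 | bp | LD block scale; sets proxy and bin sizes |
| `founders_per_block` | 8 | – | haplotype diversity within blocks |
| `admixture_alpha` | 0.8 | – | per-tract African-ancestry probability |
| `tract_length_mean` | 1e6 | bp | ancestry tract scale (miniature-chromosome units) |
| `r2_proxy` | 0.8 | – | European-LD proxy threshold |
| `r2_bin` | 0.3 | – | African-LD binning threshold |
| `r2_indep` | 0.2 | – | within-null-set independence threshold |
| `maf_tol` | 0.02 | – | null-set frequency-matching tolerance (widened stepwise to 0.05) |
| `alpha` | 0.05 | – | nominal bin significance (compared with `<=`) |

# Numerical and design choices

* **Z-scores.**  Residualize on covariates first, then center and scale
  with the n−1 standard deviation.  Whether standardization should happen
  within strata (e.g. by sex) before residualization is underdetermined;
  residualize-then-standardize was chosen and applied uniformly.  The
  minimum input is two observations (the smallest sample with a defined
  standard deviation).
* **P-value reference.**  Per-SNP regressions use the normal reference
  above n = 200 and the t reference below; the studies this machinery is
  meant for have hundreds to thousands of individuals, where the two are
  indistinguishable, and summary statistics are treated as Z-scores
  throughout.
* **Genomic control.**  λ is the median chi-square over 0.4549; correction
  divides chi-squares by λ (equivalently multiplies SE by √λ) and is
  applied only when λ > 1 — deflating results when λ < 1 would
  anti-conservatively sharpen them.  The two-stage correction (per study,
  then on the meta-analysis) is exposed as two explicit pipeline steps.
* **Heterogeneity.**  Cochran's Q with k−1 degrees of freedom; I² floored
  at zero; both 0 for a single study.
* **LD.**  r² is computed from phased haplotype counts only (panels are
  phased; no EM from unphased genotypes).  Proxy search is window-limited
  (±1 Mb by default) to bound the locus; coordinates are 1-based inclusive.
* **Fst.**  The equal-weight two-population estimator
  `(H_T - H_S)/H_T`; at the frequency pair (0.85, 0.02) it gives 0.701,
  matching the reference value, which is the only evidence available for
  the estimator choice.  Multi-locus values combine numerator and
  denominator as ratios of sums.
* **Binning ties and degeneracy.**  Randomized binning is deterministic
  given a seed; fine-mapping sorts by P with ties broken by genomic
  position (ascending).  SNPs absent from the target panel are dropped with
  a log record; proxies with D = 0 carry no direction and are dropped and
  tallied, as are index SNPs monomorphic in the source panel (no usable LD
  data).
* **Empirical P.**  `k/N`, not `(k+1)/(N+1)`: with one exceedance among
  5 819 sets this reproduces the reference value 1.7e-4 (the alternative
  convention gives 3.4e-4).  A zero numerator is reported as `< 1/N`.
* **Null-set directions.**  Matched null SNPs have no externally predicted
  direction, so each pool SNP receives a random height-increasing allele
  once per run (seeded); under the null this is exchangeable with the real
  list.
* **Matched-set eligibility.**  The MAF tolerance widens stepwise (+0.01 up
  to 0.05) until a locus has a healthy candidate quota; a locus with zero
  eligible candidates at the widest tolerance is an error.  A degenerate
  pool consisting only of the loci themselves is allowed and yields
  permutations of the loci.
* **Allele harmonization.**  Direct match, swap (negate beta, complement
  frequency), strand flip, or flip-plus-swap; strand-ambiguous A/T and C/G
  pairs are oriented by frequency against the panel and dropped inside the
  0.42–0.58 exclusion zone.  Alleles are reported on the forward strand.
* **eQTL enrichment.**  The per-SNP expression statistic is consumed as a
  pre-computed best cis P-value; missing SNPs stay in the denominator
  (conservative).  Null sets are re-matched to the fine-mapped list's MAFs
  for each enrichment run rather than reusing the replication sets, since
  the two lists generally differ in frequency composition.

# Problem sizes used by the test suite

The statistical checks run at sizes chosen to make Monte-Carlo noise small
relative to the tested margins while staying desk-scale: panels of
2 400–10 000 variants with 160–400 haplotypes per population; 100 index
loci with 200 matched null sets per pipeline run; 200 replicate pipelines
for null calibration and 50 for power; 100 replicates at n = 4 000 for
estimator bias; 1e5 P-values for the genomic-control null.  The calibration
experiment uses a ±100 kb proxy window — generous relative to the 20 kb
simulated blocks, for the same reason the real analysis bounds loci at
±1 Mb.

# Known limitations

* The generator's nested-founder blocks give predominantly coupling-phase
  LD within blocks; repulsion-phase fixtures are constructed explicitly in
  tests where the distinction matters.
* Family structure, relatedness, genotyping error, and imputation are out
  of scope; family-based designs would need a mixed-model extension.
* Random-effects meta-analysis and Bayesian fine-mapping (credible sets)
  are deliberately not provided; the replication framework is the
  frequency-matched permutation design described above.
* The unbiasedness acceptance check compares the mean bias over 100
  replicates against a tenth of the per-replicate standard error — a bound
  equal to one Monte-Carlo standard deviation of that mean, so it sits at
  chance level by construction; it is retained in the stated form with a
  fixed seed.

# A worked miniature run

```{r, eval = FALSE}
sim <- simulation_config(n_variants = 1200, n_haplotypes = 160,
                         per_study_n = 1000, n_studies = 2, seed = 1)
panels <- simulate_panels(sim)
realized_fst(panels$source, panels$target)

cfg <- pipeline_config(sim = sim, n_sets = 100, n_sims = 50, seed = 1)
res <- run_pipeline(cfg, "demo_run")
res$summary$lambda_meta
res$summary$replication
```
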