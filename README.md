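# transheight

Trans-ethnic meta-analysis, replication, and fine-mapping of adult-height
loci, for statistical geneticists working with admixed cohorts.

Height is a classic polygenic trait whose associated variants were mostly
discovered in European-ancestry samples.  Testing whether those signals
replicate in African-ancestry populations — and exploiting the
shorter-range linkage disequilibrium (LD) of African genomes to narrow the
implicated intervals — requires machinery beyond per-SNP lookups, because a
European index SNP can tag a causal variant through haplotypes that do not
exist on African chromosomes.  `transheight` implements that machinery end
to end, together with a synthetic-data module that simulates two-population
haplotype panels and admixed cohorts so the full pipeline runs and is
tested without any external data.

## What it computes

* **Per-study association** — heights residualized on sex, age, disease
  status, and ancestry covariates, normalized to Z-scores
  (`zscore_transform`), then additive linear regression per SNP
  (`snp_regression`, vectorized in `assoc_scan`), plus local-ancestry
  conditional (`conditional_model`) and stratified
  (`stratified_by_ancestry`) models.
* **Meta-analysis** — fixed-effect inverse-variance combination with
  Cochran Q and I² heterogeneity (`inverse_variance_meta`,
  `meta_analyze`), genomic control (`genomic_control_lambda`,
  `gc_correct`; applied per study and again on the combined statistics),
  and QQ data with empirical confidence bands (`qq_with_bands`):

  β = Σwᵢβᵢ / Σwᵢ,  SE = (Σwᵢ)^(−1/2),  wᵢ = 1/SEᵢ²,  λ = median(χ²)/0.4549.

* **LD from phased haplotypes** — D and r² by direct haplotype counting
  (`r2_from_haplotypes`), proxy expansion at r² ≥ 0.8 with phase-predicted
  height-increasing alleles (`expand_proxies`, `predict_direction`),
  LD-interval narrowing (`ld_interval`), and the two-population fixation
  index (`fst_two_pop`).
* **Replication framework** — randomized LD binning of each locus's
  proxies in the target population at r² ≥ 0.3 (`build_bins`), one-tailed
  conversion against the predicted direction (`one_tailed`: P/2 or
  1 − P/2), significant-bin counting (`count_significant_bins`),
  frequency-matched mutually independent null SNP sets
  (`generate_matched_sets`), and the empirical replication P
  (`empirical_p`, orchestrated by `run_replication`).
* **Fine-mapping** — the binning procedure re-run in ascending P order
  picks each locus's best-supported SNP (`fine_map_best`), flagged against
  the Bonferroni threshold 0.05/`n_loci`.
* **cis-eQTL enrichment** — the fraction of a SNP list jointly associated
  with height (P < 0.05) and cis expression (P < 0.01), compared between
  index and fine-mapped lists against matched null sets
  (`joint_fraction`, `enrichment_test`).

Formats: phased VCF and IMPUTE hap/legend panels, tab-separated summary
statistics (with allele harmonization, `harmonize_summary_stats`), YAML
pipeline configs, JSON run summaries.  A thin CLI lives in
`exec/transheight`.

## A worked example

Simulate two studies of 1,000 admixed individuals over a 1,200-variant
chromosome with ten planted height loci (|β| = 0.2 Z-units), then run every
stage:

```r
library(transheight)

sim <- simulation_config(n_variants = 1200, n_haplotypes = 160,
                         per_study_n = 1000, n_studies = 2, seed = 1)
panels <- simulate_panels(sim)
round(realized_fst(panels$source, panels$target), 3)
#> [1] 0.155

maf <- panel_maf(panels$source)
ok  <- names(maf)[maf >= 0.1 & panel_maf(panels$target) >= 0.1]
blk <- setNames(panels$source$variants$block, panels$source$variants$id)
set.seed(1)
causal <- sample(ok[!duplicated(blk[ok])], 10)
sim$causal_effects <- data.frame(snp = causal, beta = rep(c(0.2, -0.2), 5))

cfg <- pipeline_config(sim = sim, n_sets = 100, n_sims = 50,
                       proxy_window = 1e5, seed = 1)
res <- run_pipeline(cfg, "demo_run")
res$summary$replication
#> $observed_significant_bins
#> [1] 6
#> $null_median
#> [1] 0
#> $null_range
#> [1] 0 3
#> $empirical_p
#> [1] 0
#> $empirical_label
#> [1] "< 0.01"
```

Reading the output: the two panels realize a fixation index of 0.155
(CEU/YRI-scale divergence, target 0.15).  Of the ten planted loci, six
produce a significant one-tailed bin in the target-population
meta-analysis, while none of 100 frequency-matched null SNP sets reaches
that count — the overall replication P is below 1/100.  The run directory
also holds per-study association TSVs, the meta-analysis
(`meta.tsv`), fine-mapping results (`finemap.tsv`; here 4 of 10 loci pass
the Bonferroni threshold 0.05/10), the eQTL enrichment summary, and a
`run.log` recording every stage seed.  On this miniature, densely causal
chromosome the per-study genomic-control factors (1.71 and 1.11 here) are
dominated by the planted polygenic and admixture signal rather than by
artifacts; the second genomic-control pass makes the combined statistics
deliberately conservative.

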