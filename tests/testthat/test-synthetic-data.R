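# Synthetic-data generator: panels, admixed cohorts, phenotypes.

test_that("panel simulation is reproducible and validates its config", {
  cfg <- simulation_config(n_variants = 300, n_haplotypes = 60, seed = 11)
  p1 <- simulate_panels(cfg)
  p2 <- simulate_panels(cfg)
  expect_identical(p1$source$haplotypes, p2$source$haplotypes)
  expect_identical(p1$target$haplotypes, p2$target$haplotypes)
  expect_identical(p1$source$variants, p2$source$variants)
  expect_true(all(p1$source$haplotypes %in% 0:1))
  expect_false(is.unsorted(p1$source$variants$pos, strictly = TRUE))

  expect_error(simulation_config(n_variants = 0), "n_variants")
  expect_error(simulation_config(n_variants = 10, chrom_length = 5000,
                                 block_length_mean = 20000), "exceeds")
  expect_error(simulation_config(heritability_target = 1), "heritability")
  expect_error(simulation_config(divergence_F = 0), "divergence_F")
})

test_that("realized Fst tracks the divergence parameter", {
  # Target F = 0.15 at genome scale.
  cfg <- simulation_config(n_variants = 10000, n_haplotypes = 400,
                           divergence_F = 0.15, seed = 21)
  panels <- simulate_panels(cfg)
  fst <- realized_fst(panels$source, panels$target)
  expect_lt(abs(fst - 0.15), 0.03)

  # No-divergence limit.
  cfg0 <- simulation_config(n_variants = 4000, n_haplotypes = 400,
                            divergence_F = 1e-4, seed = 22)
  panels0 <- simulate_panels(cfg0)
  expect_lt(realized_fst(panels0$source, panels0$target), 0.02)

  # Monotonicity across a grid of divergence values.
  grid <- c(0.01, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3)
  realized <- vapply(grid, function(f) {
    cfg_f <- simulation_config(n_variants = 3000, n_haplotypes = 200,
                               divergence_F = f, seed = 23)
    p <- simulate_panels(cfg_f)
    realized_fst(p$source, p$target)
  }, numeric(1))
  expect_gt(cor(grid, realized, method = "spearman"), 0.9)
})

test_that("LD is block-structured: within-block r2 exceeds between-block r2", {
  cfg <- simulation_config(n_variants = 800, n_haplotypes = 200, seed = 31)
  panels <- simulate_panels(cfg)
  for (panel in panels) {
    f <- alt_freq(panel)
    keep <- which(f > 0 & f < 1)
    s <- sample(keep, min(150, length(keep)))
    r2 <- suppressWarnings(cor(t(panel$haplotypes[s, ])))^2
    same <- outer(panel$variants$block[s], panel$variants$block[s], "==")
    ut <- upper.tri(r2)
    expect_gt(mean(r2[same & ut], na.rm = TRUE),
              mean(r2[!same & ut], na.rm = TRUE))
  }
})

test_that("admixture proportion controls local-ancestry dosage", {
  cfg <- simulation_config(n_variants = 200, n_haplotypes = 40,
                           admixture_alpha = 1, seed = 41, per_study_n = 50)
  panels <- simulate_panels(cfg)
  coh <- simulate_admixed_cohort(panels, cfg, seed = 42)
  expect_true(all(coh$local_ancestry == 0L))  # fully African

  cfg2 <- simulation_config(n_variants = 200, n_haplotypes = 40,
                            admixture_alpha = 0.8, tract_length_mean = 5e4,
                            seed = 43, per_study_n = 5000)
  coh2 <- simulate_admixed_cohort(panels, cfg2, seed = 44)
  expect_lt(abs(mean(coh2$local_ancestry) - 0.4), 0.02)  # 2 * (1 - 0.8)

  # Determinism and genotype bounds.
  coh2b <- simulate_admixed_cohort(panels, cfg2, seed = 44)
  expect_identical(coh2$genotypes, coh2b$genotypes)
  expect_true(all(coh2$genotypes %in% 0:2))
  expect_true(all(coh2$local_ancestry %in% 0:2))
})

test_that("admixed allele frequencies follow the ancestry-weighted mixture", {
  expect_equal(expected_admixed_freq(0.54, 1.00, 0.08), 0.9632)

  # Generator consistency at a strongly differentiated variant:
  # alt fixed in the European panel, 54% in the African panel, 8% African
  # ancestry.
  n_hap <- 100
  eur <- matrix(1L, 3, n_hap)
  afr <- rbind(rep(c(1L, 0L), c(54, 46)), rep(c(1L, 0L), c(54, 46)),
               rep(c(1L, 0L), c(54, 46)))
  panels <- list(source = make_panel(eur, population = "EUR"),
                 target = make_panel(afr, population = "AFR"))
  cfg <- simulation_config(n_variants = 3, n_haplotypes = n_hap,
                           chrom_length = 4000, block_length_mean = 4000,
                           admixture_alpha = 0.08, tract_length_mean = 4000,
                           per_study_n = 4000, seed = 5)
  coh <- simulate_admixed_cohort(panels, cfg, seed = 51)
  realized <- mean(coh$genotypes) / 2
  expect_lt(abs(realized - 0.9632), 0.015)
})

test_that("local-ancestry truth and genotype agree at fixed divergent variants", {
  # Variant fixed ref (0) in Europeans and fixed alt (1) in Africans:
  # genotype must equal the African dosage = 2 - European dosage.
  eur <- matrix(0L, 4, 60)
  afr <- matrix(1L, 4, 60)
  panels <- list(source = make_panel(eur, population = "EUR"),
                 target = make_panel(afr, population = "AFR"))
  cfg <- simulation_config(n_variants = 4, n_haplotypes = 60,
                           chrom_length = 5000, block_length_mean = 2000,
                           admixture_alpha = 0.6, tract_length_mean = 1500,
                           per_study_n = 200, seed = 6)
  coh <- simulate_admixed_cohort(panels, cfg, seed = 61)
  expect_identical(coh$genotypes, 2L - coh$local_ancestry)
})

test_that("male X genotypes use doubled haploid coding", {
  cfg <- simulation_config(n_variants = 50, n_haplotypes = 40, chrom = "X",
                           per_study_n = 80, seed = 71)
  panels <- simulate_panels(cfg)
  coh <- simulate_admixed_cohort(panels, cfg, seed = 72)
  males <- coh$covariates$sex == 1
  expect_true(all(coh$genotypes[, males] %in% c(0L, 2L)))
  expect_true(all(coh$local_ancestry[, males] %in% c(0L, 2L)))
})

test_that("null phenotypes give uniform association P-values", {
  # Single-variant blocks so the 2000 per-SNP tests are independent and the
  # Kolmogorov-Smirnov reference distribution applies.
  cfg <- simulation_config(n_variants = 2000, n_haplotypes = 100,
                           block_length_mean = 500, variant_spacing = 2000,
                           per_study_n = 500, seed = 81)
  panels <- simulate_panels(cfg)
  coh <- simulate_admixed_cohort(panels, cfg, seed = 82)
  coh <- simulate_phenotype(coh, cfg, seed = 83)  # no causal effects
  z <- zscore_transform(coh$phenotype,
                        coh$covariates[, c("sex", "age", "disease")])
  scan <- suppressMessages(
    assoc_scan(z, coh$genotypes,
               covariates = coh$covariates[, "global_eur", drop = FALSE],
               variants = coh$variants)
  )
  ks <- suppressWarnings(ks.test(scan$P, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("phenotype simulation recovers a planted effect and is reproducible", {
  cfg <- simulation_config(n_variants = 400, n_haplotypes = 200,
                           per_study_n = 1500, seed = 91)
  panels <- simulate_panels(cfg)
  coh <- simulate_admixed_cohort(panels, cfg, seed = 92)
  maf <- pmin(rowMeans(coh$genotypes) / 2, 1 - rowMeans(coh$genotypes) / 2)
  causal <- names(which.min(abs(maf - 0.3)))
  cfg_c <- simulation_config(n_variants = 400, n_haplotypes = 200,
                             per_study_n = 1500, seed = 91,
                             causal_effects = data.frame(snp = causal, beta = 0.3))
  coh <- simulate_phenotype(coh, cfg_c, seed = 93)
  coh_b <- simulate_phenotype(coh, cfg_c, seed = 93)
  expect_identical(coh$phenotype, coh_b$phenotype)

  # Coverage: the regression recovers the planted 0.3 within 2 SE in most
  # noise replicates (nominal coverage 95%).
  covered <- vapply(1:30, function(r) {
    ch <- simulate_phenotype(coh, cfg_c, seed = 1000 + r)
    z <- zscore_transform(ch$phenotype, ch$covariates[, c("sex", "age", "disease")])
    res <- snp_regression(z, ch$genotypes[causal, ], snp = causal)
    abs(res$BETA - 0.3) <= 2 * res$SE
  }, logical(1))
  expect_gte(mean(covered), 0.85)

  # Heritability targeting: realized genetic variance fraction.
  cfg_h <- simulation_config(n_variants = 400, n_haplotypes = 200,
                             per_study_n = 1500, seed = 91,
                             causal_effects = data.frame(snp = causal, beta = 0.3),
                             heritability_target = 0.4)
  coh_h <- simulate_phenotype(coh, cfg_h, seed = 94)
  cv <- coh_h$covariates
  g_plus_e <- (coh_h$phenotype - cfg_h$baseline_height -
                 cfg_h$sex_effect * cv$sex -
                 cfg_h$age_effect * (cv$age - 50)) / cfg_h$pheno_sd
  expect_lt(abs(var(coh_h$genetic_value) / var(g_plus_e) - 0.4), 0.05)

  expect_error(simulate_phenotype(coh, simulation_config(
    n_variants = 400, causal_effects = data.frame(snp = "nope", beta = 1))),
    "not in cohort")
})
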