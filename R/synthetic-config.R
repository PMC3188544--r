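#' Configuration for the synthetic admixed-cohort generator
#'
#' Collects every knob of the synthetic-data module in one validated list:
#' the two-population haplotype panels (divergence, block structure), the
#' admixture process (ancestry proportion, tract lengths), and the phenotype
#' model (additive causal effects, heritability, covariate effects).
#'
#' Populations are labelled `source` (the European-ancestry reference whose
#' LD defines proxies, by analogy with CEU) and `target` (the
#' African-ancestry reference used for binning, by analogy with YRI).
#' `admixture_alpha` is the per-tract probability of AFRICAN (target) origin,
#' so admixed individuals carry `2 * (1 - admixture_alpha)` European-derived
#' chromosomes per locus in expectation.
#'
#' @param n_variants number of variants on the simulated chromosome.
#' @param n_haplotypes phased haplotypes per population panel (must be even).
#' @param chrom chromosome label; `"X"` activates male 0/2 dosage coding in
#'   cohort simulation.
#' @param chrom_length chromosome span in bp; defaults to
#'   `n_variants * variant_spacing`.
#' @param variant_spacing mean inter-variant spacing in bp used for the
#'   default chromosome span.
#' @param block_length_mean mean haplotype-block length in bp (blocks have
#'   exponentially distributed lengths); within-block LD is high and
#'   between-block LD is negligible by construction.
#' @param founders_per_block number of founder haplotypes per block from which
#'   panel haplotypes are copied (default 8).
#' @param ancestral_freq_range interval from which each block's ancestral
#'   allele frequency is drawn uniformly.
#' @param divergence_F target pairwise fixation index (Fst) between the two
#'   population panels, in (0, 1).  Population frequencies are drawn from a
#'   Balding-Nichols Beta distribution calibrated so the expected realized
#'   two-population Fst equals this value.
#' @param admixture_alpha African (target-panel) ancestry proportion per
#'   tract, in \[0, 1\].
#' @param tract_length_mean mean ancestry-tract length in bp (exponential).
#' @param causal_effects `NULL` or data.frame with columns `snp` and `beta`
#'   (additive effect per alternate allele, Z-score units).
#' @param heritability_target `NULL` or a value in \[0, 1): realized fraction
#'   of phenotypic variance explained by the causal genotypes.  `NULL` keeps
#'   unit environmental variance so causal betas stay on the Z-score scale.
#' @param n_studies,per_study_n number of studies and individuals per study
#'   for cohort simulation.
#' @param baseline_height,sex_effect,age_effect,pheno_sd raw-height model:
#'   mean height (cm), additive male effect (cm), per-year age slope (cm),
#'   and the scale (cm) of the standardized genetic-plus-environmental
#'   component.
#' @param seed default seed threaded to the generator operations.
#'
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_variants = 2400,
                              n_haplotypes = 200,
                              chrom = "1",
                              chrom_length = NULL,
                              variant_spacing = 2000,
                              block_length_mean = 20000,
                              founders_per_block = 8,
                              ancestral_freq_range = c(0.05, 0.95),
                              divergence_F = 0.15,
                              admixture_alpha = 0.8,
                              tract_length_mean = 1e6,
                              causal_effects = NULL,
                              heritability_target = NULL,
                              n_studies = 2,
                              per_study_n = 2000,
                              baseline_height = 170,
                              sex_effect = 13,
                              age_effect = -0.05,
                              pheno_sd = 7,
                              seed = NULL) {
  config <- list(
    n_variants = as.integer(n_variants),
    n_haplotypes = as.integer(n_haplotypes),
    chrom = as.character(chrom),
    chrom_length = chrom_length %||% (as.integer(n_variants) * variant_spacing),
    variant_spacing = variant_spacing,
    block_length_mean = block_length_mean,
    founders_per_block = as.integer(founders_per_block),
    ancestral_freq_range = ancestral_freq_range,
    divergence_F = divergence_F,
    admixture_alpha = admixture_alpha,
    tract_length_mean = tract_length_mean,
    causal_effects = causal_effects,
    heritability_target = heritability_target,
    n_studies = as.integer(n_studies),
    per_study_n = as.integer(per_study_n),
    baseline_height = baseline_height,
    sex_effect = sex_effect,
    age_effect = age_effect,
    pheno_sd = pheno_sd,
    seed = seed
  )
  validate_simulation_config(config)
  class(config) <- "simulation_config"
  config
}

validate_simulation_config <- function(config) {
  if (config$n_variants < 1L) {
    stop_invalid("invalid config: n_variants must be >= 1")
  }
  if (config$n_haplotypes < 2L || config$n_haplotypes %% 2L != 0L) {
    stop_invalid("invalid config: n_haplotypes must be a positive even number")
  }
  if (!(config$divergence_F > 0 && config$divergence_F < 1)) {
    stop_invalid("invalid config: divergence_F must be in (0, 1)")
  }
  if (config$admixture_alpha < 0 || config$admixture_alpha > 1) {
    stop_invalid("invalid config: admixture_alpha must be in [0, 1]")
  }
  if (config$block_length_mean > config$chrom_length) {
    stop_invalid("invalid config: block_length_mean (%g bp) exceeds the chromosome span (%g bp)",
                 config$block_length_mean, config$chrom_length)
  }
  h <- config$heritability_target
  if (!is.null(h) && (h < 0 || h >= 1)) {
    stop_invalid("invalid config: heritability_target must be in [0, 1)")
  }
  rng <- config$ancestral_freq_range
  if (length(rng) != 2 || rng[1] <= 0 || rng[2] >= 1 || rng[1] > rng[2]) {
    stop_invalid("invalid config: ancestral_freq_range must be an interval inside (0, 1)")
  }
  if (!is.null(config$causal_effects)) {
    ce <- config$causal_effects
    if (!is.data.frame(ce) || !all(c("snp", "beta") %in% names(ce))) {
      stop_invalid("invalid config: causal_effects must be a data.frame with columns snp, beta")
    }
  }
  invisible(config)
}
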