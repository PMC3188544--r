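#' Simulate an admixed diploid cohort with known local-ancestry tracts
#'
#' Each individual's two chromosomes are mosaics of haplotypes copied from
#' the source (European-like) and target (African-like) panels.  Tract
#' lengths are exponentially distributed with mean `tract_length_mean`; each
#' tract's origin is African with probability `admixture_alpha` and a fresh
#' panel haplotype is drawn per tract.  The genotype is the sum of the two
#' chromosome alleles, and the local-ancestry truth records, per variant,
#' the number of EUROPEAN-derived chromosomes (0, 1, or 2) - the dosage used
#' by the conditional and stratified association models.
#'
#' On the X chromosome (`config$chrom == "X"`), males carry a single
#' simulated chromosome whose allele and ancestry contributions are doubled,
#' giving the conventional 0/2 additive coding.
#'
#' @param panels list with `source` and `target` [haplotype_panel()]s sharing
#'   one variant list (as returned by [simulate_panels()]).
#' @param config a [simulation_config()].
#' @param n number of individuals (defaults to `config$per_study_n`).
#' @param study study label stored in the covariate table.
#' @param seed integer seed.
#'
#' @return An object of class `admixed_cohort`: list with `genotypes`
#'   (variants x individuals, 0/1/2), `local_ancestry` (variants x
#'   individuals European-chromosome counts), `covariates` (data.frame with
#'   `id`, `sex` (1 = male), `age`, `disease`, `study`, `global_eur` = mean
#'   genome-wide European dosage / 2), `phenotype` (NULL until
#'   [simulate_phenotype()]), and the shared `variants` table.
#' @export
simulate_admixed_cohort <- function(panels, config, n = config$per_study_n,
                                    study = "study1", seed = config$seed) {
  validate_simulation_config(config)
  src <- panels$source
  tgt <- panels$target
  stopifnot(inherits(src, "haplotype_panel"), inherits(tgt, "haplotype_panel"))
  if (nrow(src$haplotypes) == 0 || nrow(tgt$haplotypes) == 0) {
    stop_invalid("empty haplotype panel")
  }
  if (!identical(src$variants$id, tgt$variants$id) ||
      !identical(src$variants$pos, tgt$variants$pos)) {
    stop_invalid("source and target panels must share the variant list")
  }
  n <- as.integer(n)
  stopifnot(n >= 1L)

  pos <- src$variants$pos
  n_var <- length(pos)
  span <- max(config$chrom_length, pos[n_var])
  alpha <- config$admixture_alpha
  rate <- 1 / config$tract_length_mean
  x_linked <- identical(config$chrom, "X")

  with_seed(seed, {
    sex <- stats::rbinom(n, 1L, 0.5)          # 1 = male
    age <- round(stats::runif(n, 30, 75))
    disease <- stats::rbinom(n, 1L, 0.3)

    geno <- matrix(0L, n_var, n)
    eur <- matrix(0L, n_var, n)

    draw_chromosome <- function() {
      # Tract boundaries over (0, span], origins, and donor haplotypes.
      cuts <- numeric(0)
      total <- 0
      while (total <= span) {
        len <- stats::rexp(1, rate)
        total <- total + len
        cuts <- c(cuts, total)
      }
      tract_of <- findInterval(pos, cuts) + 1L
      n_tracts <- max(tract_of)
      origin_afr <- stats::rbinom(n_tracts, 1L, alpha)
      hap_allele <- integer(n_var)
      for (t in seq_len(n_tracts)) {
        idx <- which(tract_of == t)
        if (length(idx) == 0) next
        donor_panel <- if (origin_afr[t] == 1L) tgt else src
        donor <- sample.int(ncol(donor_panel$haplotypes), 1L)
        hap_allele[idx] <- donor_panel$haplotypes[idx, donor]
      }
      list(allele = hap_allele, eur = as.integer(origin_afr == 0L)[tract_of])
    }

    for (i in seq_len(n)) {
      if (x_linked && sex[i] == 1L) {
        chr <- draw_chromosome()
        geno[, i] <- 2L * chr$allele
        eur[, i] <- 2L * chr$eur
      } else {
        c1 <- draw_chromosome()
        c2 <- draw_chromosome()
        geno[, i] <- c1$allele + c2$allele
        eur[, i] <- c1$eur + c2$eur
      }
    }

    rownames(geno) <- src$variants$id
    rownames(eur) <- src$variants$id
    covariates <- data.frame(
      id = sprintf("%s_ind%04d", study, seq_len(n)),
      sex = sex, age = age, disease = disease, study = study,
      global_eur = colMeans(eur) / 2,
      stringsAsFactors = FALSE
    )
    structure(
      list(genotypes = geno, local_ancestry = eur, covariates = covariates,
           phenotype = NULL, variants = src$variants,
           populations = c(source = src$population, target = tgt$population)),
      class = "admixed_cohort"
    )
  })
}

#' @export
print.admixed_cohort <- function(x, ...) {
  cat(sprintf("<admixed_cohort> %d individuals x %d variants (study %s)\n",
              ncol(x$genotypes), nrow(x$genotypes), x$covariates$study[1]))
  invisible(x)
}

#' Expected allele frequency in an admixed population
#'
#' The ancestry-weighted mixture `alpha_afr * f_afr + (1 - alpha_afr) * f_eur`,
#' the first-order expectation for a variant's frequency in a two-way admixed
#' cohort.
#'
#' @param f_afr,f_eur allele frequencies in the African and European ancestral
#'   populations.
#' @param alpha_afr African ancestry proportion in \[0, 1\].
#' @return Expected admixed allele frequency.
#' @export
expected_admixed_freq <- function(f_afr, f_eur, alpha_afr) {
  stopifnot(all(alpha_afr >= 0 & alpha_afr <= 1))
  alpha_afr * f_afr + (1 - alpha_afr) * f_eur
}

#' Fill in additive height phenotypes for a cohort
#'
#' Height is generated as
#' `baseline + sex_effect * sex + age_effect * (age - 50) + pheno_sd * (G + e)`
#' where `G = sum_j beta_j * genotype_j` over the configured causal variants
#' and `e` is Gaussian noise.  With `heritability_target = NULL` the noise
#' has unit variance, so causal betas are on the standardized (Z-score)
#' phenotype scale up to the small total-variance inflation `var(G)`.  With
#' a numeric `heritability_target` in (0, 1), the noise is scaled so the
#' realized genetic variance fraction of `G + e` matches the target.
#'
#' @param cohort an `admixed_cohort`.
#' @param config a [simulation_config()]; `config$causal_effects` names the
#'   causal variants and their per-allele effects.
#' @param seed integer seed.
#' @return The cohort with `phenotype` (raw height) and `genetic_value`
#'   filled in.
#' @export
simulate_phenotype <- function(cohort, config, seed = config$seed) {
  stopifnot(inherits(cohort, "admixed_cohort"))
  validate_simulation_config(config)
  n <- ncol(cohort$genotypes)

  ce <- config$causal_effects
  if (is.null(ce) || nrow(ce) == 0) {
    g_value <- rep(0, n)
  } else {
    idx <- match(ce$snp, rownames(cohort$genotypes))
    if (anyNA(idx)) {
      stop_invalid("causal variant(s) not in cohort: %s",
                   paste(ce$snp[is.na(idx)], collapse = ", "))
    }
    g_value <- as.numeric(crossprod(cohort$genotypes[idx, , drop = FALSE], ce$beta))
  }

  h2 <- config$heritability_target
  var_g <- stats::var(g_value)
  sigma <- if (is.null(h2) || var_g == 0 || h2 == 0) {
    1
  } else {
    sqrt(var_g * (1 - h2) / h2)
  }

  with_seed(seed, {
    e <- stats::rnorm(n, 0, sigma)
    z_part <- g_value + e
    cov <- cohort$covariates
    cohort$phenotype <- config$baseline_height +
      config$sex_effect * cov$sex +
      config$age_effect * (cov$age - 50) +
      config$pheno_sd * z_part
    cohort$genetic_value <- g_value
    cohort
  })
}
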