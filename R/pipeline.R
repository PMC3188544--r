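#' Pipeline configuration
#'
#' Bundles the stage thresholds and sizes of the end-to-end synthetic
#' experiment.  The analysis thresholds default to the conventional values:
#' proxy r-squared 0.8, bin r-squared 0.3, null-set independence r-squared
#' 0.2, nominal alpha 0.05, genome-wide significance 5e-8, follow-up
#' threshold 1e-5, and cis-eQTL threshold 0.01.
#'
#' @param sim a [simulation_config()] describing panels, cohorts, and
#'   phenotypes.
#' @param r2_proxy,r2_bin,r2_indep,alpha,p_genomewide,p_followup,p_eqtl
#'   analysis thresholds, all in (0, 1\].
#' @param n_sets matched null sets for replication (0 skips that stage).
#' @param n_sims simulated sets for the eQTL enrichment stage.
#' @param proxy_window proxy search window in bp.
#' @param write_panels whether `run_pipeline()` writes the panels as VCF.
#' @param seed master seed; every stage derives its own stream from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            r2_proxy = 0.8, r2_bin = 0.3, r2_indep = 0.2,
                            alpha = 0.05, p_genomewide = 5e-8,
                            p_followup = 1e-5, p_eqtl = 0.01,
                            n_sets = 200, n_sims = 100,
                            proxy_window = 1e6,
                            write_panels = TRUE, seed = 1) {
  config <- list(sim = sim, r2_proxy = r2_proxy, r2_bin = r2_bin,
                 r2_indep = r2_indep, alpha = alpha,
                 p_genomewide = p_genomewide, p_followup = p_followup,
                 p_eqtl = p_eqtl, n_sets = as.integer(n_sets),
                 n_sims = as.integer(n_sims), proxy_window = proxy_window,
                 write_panels = isTRUE(write_panels), seed = seed)
  thr <- c(config$r2_proxy, config$r2_bin, config$r2_indep, config$alpha,
           config$p_genomewide, config$p_followup, config$p_eqtl)
  if (any(thr <= 0 | thr > 1)) stop_invalid("thresholds must lie in (0, 1]")
  class(config) <- "pipeline_config"
  config
}

#' Write a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path output path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  if (!is.null(x$sim$causal_effects)) {
    x$sim$causal_effects <- as.list(as.data.frame(x$sim$causal_effects))
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML path written by [write_pipeline_config()] (or edited by
#'   hand; missing fields fall back to defaults).
#' @return A validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim_args <- x$sim %||% list()
  if (!is.null(sim_args$causal_effects)) {
    sim_args$causal_effects <- as.data.frame(sim_args$causal_effects,
                                             stringsAsFactors = FALSE)
  }
  if (!is.null(sim_args$ancestral_freq_range)) {
    sim_args$ancestral_freq_range <- as.numeric(sim_args$ancestral_freq_range)
  }
  sim <- do.call(simulation_config, sim_args)
  args <- x[setdiff(names(x), "sim")]
  do.call(pipeline_config, c(list(sim = sim), args))
}

#' Run the full synthetic trans-ethnic analysis pipeline
#'
#' Executes every stage on freshly simulated data: panel simulation,
#' per-study cohort + phenotype simulation, Z-score association scans,
#' per-study genomic control, inverse-variance meta-analysis with a second
#' genomic-control pass, the LD-aware replication framework with matched
#' null sets, per-locus fine-mapping, and the cis-eQTL enrichment test.
#' Every stage records its derived seed in the run log, and rerunning with
#' the same config and seed reproduces the JSON summary byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created if needed); receives per-stage TSV
#'   outputs, `summary.json`, and `run.log`.
#' @param eqtl_table optional data.frame (`SNP`, `P`) of best cis
#'   association P-values; when NULL a uniform null table is simulated.
#' @return Invisible list with the per-stage results.
#' @export
run_pipeline <- function(config, out_dir, eqtl_table = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  log_msg <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  seed <- config$seed
  sim <- config$sim
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(log_lines, log_path)
      stop_invalid("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }

  log_msg("master seed: %s", format(seed))
  panels <- run_stage("simulate", {
    s <- derive_seed(seed, 1L)
    log_msg("stage simulate: seed %d", s)
    simulate_panels(sim, seed = s)
  })
  if (config$write_panels) {
    write_phased_vcf(panels$source, file.path(out_dir, "panel_source.vcf"))
    write_phased_vcf(panels$target, file.path(out_dir, "panel_target.vcf"))
  }

  studies <- run_stage("association", {
    lapply(seq_len(sim$n_studies), function(s_idx) {
      s_cohort <- derive_seed(seed, 10L + s_idx)
      s_pheno <- derive_seed(seed, 40L + s_idx)
      log_msg("stage association study %d: cohort seed %d, phenotype seed %d",
              s_idx, s_cohort, s_pheno)
      cohort <- simulate_admixed_cohort(panels, sim, study = sprintf("study%d", s_idx),
                                        seed = s_cohort)
      cohort <- simulate_phenotype(cohort, sim, seed = s_pheno)
      cv <- cohort$covariates
      z <- zscore_transform(cohort$phenotype,
                            cv[, c("sex", "age", "disease"), drop = FALSE])
      scan <- suppressMessages(
        assoc_scan(z, cohort$genotypes,
                   covariates = cv[, "global_eur", drop = FALSE],
                   variants = cohort$variants)
      )
      write_summary_stats(scan, file.path(out_dir, sprintf("assoc_study%d.tsv", s_idx)))
      list(cohort = cohort, scan = scan)
    })
  })

  gc_stage <- run_stage("genomic_control", {
    lapply(seq_along(studies), function(s_idx) {
      lam <- genomic_control_lambda(studies[[s_idx]]$scan$P)
      log_msg("stage genomic_control study %d: lambda = %.4f", s_idx, lam)
      list(lambda = lam, scan = gc_correct(studies[[s_idx]]$scan, lam))
    })
  })

  meta <- run_stage("meta", {
    m <- meta_analyze(lapply(gc_stage, `[[`, "scan"))
    lam <- genomic_control_lambda(m$P)
    log_msg("stage meta: %d SNPs, lambda = %.4f (second GC pass)", nrow(m), lam)
    m <- gc_correct(m, lam)
    write_summary_stats(m, file.path(out_dir, "meta.tsv"))
    attr(m, "lambda") <- lam
    m
  })
  n_gw <- sum(meta$P < config$p_genomewide)
  log_msg("genome-wide significant SNPs (P < %g): %d", config$p_genomewide, n_gw)

  causal <- sim$causal_effects
  index_snps <- if (is.null(causal) || nrow(causal) == 0) {
    data.frame(snp = character(0), increasing_allele = character(0))
  } else {
    data.frame(snp = causal$snp,
               increasing_allele = ifelse(causal$beta > 0, "alt", "ref"),
               stringsAsFactors = FALSE)
  }

  replication <- NULL
  if (config$n_sets > 0 && nrow(index_snps) > 0) {
    replication <- run_stage("replication", {
      s <- derive_seed(seed, 100L)
      log_msg("stage replication: seed %d, %d loci, %d null sets",
              s, nrow(index_snps), config$n_sets)
      suppressMessages(
        run_replication(index_snps, panels$source, panels$target, meta,
                        n_sets = config$n_sets, r2_proxy = config$r2_proxy,
                        r2_bin = config$r2_bin, r2_indep = config$r2_indep,
                        alpha = config$alpha, window = config$proxy_window,
                        seed = s)
      )
    })
    rep_df <- replication$per_locus
    data.table::fwrite(rep_df, file.path(out_dir, "replication.tsv"),
                       sep = "\t", quote = FALSE)
  } else {
    log_msg("stage replication: skipped (n_sets = %d, loci = %d)",
            config$n_sets, nrow(index_snps))
  }

  finemap <- NULL
  if (nrow(index_snps) > 0) {
    finemap <- run_stage("finemap", {
      s <- derive_seed(seed, 200L)
      log_msg("stage finemap: seed %d", s)
      p_lookup <- stats::setNames(meta$P, meta$SNP)
      res <- lapply(seq_len(nrow(index_snps)), function(k) {
        ps <- proxy_set_one(index_snps$snp[k], index_snps$increasing_allele[k],
                            panels$source, r2_min = config$r2_proxy,
                            window = config$proxy_window)
        if (ps$unresolvable) return(NULL)
        mem <- ps$members$snp[ps$members$snp %in% names(p_lookup)]
        if (length(mem) == 0) return(NULL)
        fm <- fine_map_best(mem, p_lookup, panels$target, r2_bin = config$r2_bin,
                            bonferroni_n = nrow(index_snps))
        data.frame(locus = index_snps$snp[k], best_snp = fm$best_snp,
                   best_p = fm$best_p, passes_bonferroni = fm$passes_bonferroni,
                   stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, Filter(Negate(is.null), res))
      data.table::fwrite(df, file.path(out_dir, "finemap.tsv"), sep = "\t", quote = FALSE)
      df
    })
  }

  enrichment <- NULL
  if (!is.null(finemap) && nrow(finemap) > 0 && config$n_sims > 0) {
    enrichment <- run_stage("eqtl", {
      s <- derive_seed(seed, 300L)
      log_msg("stage eqtl: seed %d, %d simulated sets", s, config$n_sims)
      height_p <- stats::setNames(meta$P, meta$SNP)
      if (is.null(eqtl_table)) {
        eqtl_p <- with_seed(derive_seed(s, 1L),
                            stats::setNames(stats::runif(nrow(meta)), meta$SNP))
      } else {
        eqtl_p <- stats::setNames(eqtl_table$P, eqtl_table$SNP)
      }
      maf_src <- panel_maf(panels$source)
      pool_keep <- maf_src >= 0.02 & !(names(maf_src) %in% finemap$best_snp)
      pool <- data.frame(snp = names(maf_src)[pool_keep],
                         maf = unname(maf_src[pool_keep]), stringsAsFactors = FALSE)
      suppressMessages(
        enrichment_test(index_snps$snp, finemap$best_snp, height_p, eqtl_p,
                        pool = pool, ld = panels$source,
                        p_height = config$alpha, p_eqtl = config$p_eqtl,
                        n_sims = config$n_sims, seed = s)
      )
    })
  }

  summary <- list(
    seed = seed,
    n_variants = sim$n_variants,
    n_studies = sim$n_studies,
    per_study_n = sim$per_study_n,
    lambda_per_study = vapply(gc_stage, `[[`, numeric(1), "lambda"),
    lambda_meta = attr(meta, "lambda"),
    n_genomewide = n_gw,
    replication = if (is.null(replication)) NULL else list(
      observed_significant_bins = replication$observed_total,
      null_median = stats::median(replication$null_counts),
      null_range = range(replication$null_counts),
      empirical_p = replication$empirical$p,
      empirical_label = replication$empirical$label
    ),
    finemap_n_bonferroni = if (is.null(finemap)) NULL else sum(finemap$passes_bonferroni),
    eqtl = if (is.null(enrichment)) NULL else list(
      fraction_index = enrichment$fraction_a,
      fraction_finemapped = enrichment$fraction_b,
      empirical_p = enrichment$empirical$p,
      empirical_label = enrichment$empirical$label
    )
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  writeLines(log_lines, log_path)
  invisible(list(panels = panels, studies = studies, gc = gc_stage, meta = meta,
                 replication = replication, finemap = finemap,
                 enrichment = enrichment, summary = summary))
}
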