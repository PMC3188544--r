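#' Run the trans-ethnic replication framework end to end
#'
#' Orchestrates, for a list of index SNPs with known height-increasing
#' alleles: proxy expansion in the source (discovery-LD) panel, randomized
#' LD binning in the target panel, one-tailed conversion of the
#' meta-analysis P-values against the phase-predicted directions, and
#' significant-bin counting — then repeats the identical procedure on
#' `n_sets` frequency-matched null SNP sets to obtain an empirical
#' replication P-value.
#'
#' Null index SNPs carry no externally predicted direction, so each pool SNP
#' is assigned a random height-increasing allele once per run (seeded),
#' which is exchangeable with the real list under the null.  Index SNPs
#' monomorphic in the source panel are dropped as lacking LD data and
#' tallied, mirroring the treatment of untestable loci.
#'
#' @param index_snps data.frame with columns `snp` and `increasing_allele`
#'   (`"ref"`/`"alt"`).  Zero rows yield an empty report.
#' @param source_panel,target_panel phased [haplotype_panel()]s sharing a
#'   variant list: proxies and directions from `source_panel`, bins from
#'   `target_panel`.
#' @param meta association summary statistics (data.frame with `SNP, EA,
#'   BETA, P`), harmonized so `EA` is the panel alternate allele.
#' @param pool candidate pool for matched sets: data.frame with `snp`,
#'   `maf`; defaults to all source-panel SNPs with MAF at least
#'   `pool_min_maf`, excluding the index SNPs.
#' @param n_sets number of matched null sets (0 skips the null stage).
#' @param r2_proxy,r2_bin,r2_indep proxy, binning, and independence
#'   r-squared thresholds.
#' @param maf_tol MAF matching tolerance for the null sets.
#' @param alpha nominal significance threshold for bins.
#' @param window proxy search window (bp).
#' @param pool_min_maf minimum source MAF for default pool membership.
#' @param seed integer seed governing binning shuffles, null-set sampling,
#'   and null direction assignment.
#' @return object of class `replication_report`: list with `observed_total`,
#'   `per_locus` (data.frame), `null_counts`, `empirical`
#'   (see [empirical_p()]), `n_loci_dropped`, and the parameters used.
#' @export
run_replication <- function(index_snps, source_panel, target_panel, meta,
                            pool = NULL, n_sets = 200,
                            r2_proxy = 0.8, r2_bin = 0.3, r2_indep = 0.2,
                            maf_tol = 0.02, alpha = 0.05, window = 1e6,
                            pool_min_maf = 0.02, seed = NULL) {
  stopifnot(is.data.frame(index_snps))
  if (nrow(index_snps) == 0) {
    return(structure(list(observed_total = 0,
                          per_locus = data.frame(), null_counts = numeric(0),
                          empirical = NULL, n_loci_dropped = 0L),
                     class = "replication_report"))
  }
  stopifnot(all(c("snp", "increasing_allele") %in% names(index_snps)))
  stopifnot(all(c("SNP", "BETA", "P") %in% names(meta)))

  p_two <- stats::setNames(meta$P, meta$SNP)
  b_sign <- stats::setNames(sign(meta$BETA), meta$SNP)

  maf_src <- panel_maf(source_panel)
  if (is.null(pool)) {
    keep <- maf_src >= pool_min_maf & !(names(maf_src) %in% index_snps$snp)
    pool <- data.frame(snp = names(maf_src)[keep], maf = unname(maf_src[keep]),
                       stringsAsFactors = FALSE)
  }

  all_loci <- c(index_snps$snp, setdiff(pool$snp, index_snps$snp))
  locus_seed <- function(snp) derive_seed(seed, 1000L + match(snp, all_loci))

  count_cache <- new.env(parent = emptyenv())
  locus_count <- function(snp, inc_allele) {
    if (!is.null(count_cache[[snp]])) return(count_cache[[snp]])
    ps <- proxy_set_one(snp, inc_allele, source_panel,
                        r2_min = r2_proxy, window = window)
    res <- if (ps$unresolvable) {
      list(count = NA_real_, n_proxies = 0L, n_bins = 0L, dropped = "no LD data")
    } else {
      mem <- ps$members
      usable <- mem$snp %in% names(p_two) & ld_has_snp(target_panel, mem$snp)
      mem <- mem[usable, , drop = FALSE]
      if (nrow(mem) == 0) {
        list(count = 0, n_proxies = 0L, n_bins = 0L, dropped = "no testable proxies")
      } else {
        bins <- build_bins(mem$snp, target_panel, r2_bin = r2_bin,
                           seed = locus_seed(snp))
        idx <- vapply(bins, function(b) b$index, character(1))
        pred_sign <- ifelse(mem$predicted_allele[match(idx, mem$snp)] == "alt", 1, -1)
        ot <- one_tailed(p_two[idx], b_sign[idx], pred_sign)
        list(count = sum(ot <= alpha), n_proxies = nrow(mem),
             n_bins = length(bins), dropped = "")
      }
    }
    count_cache[[snp]] <- res
    res
  }

  # Observed list.
  obs <- lapply(seq_len(nrow(index_snps)), function(k) {
    locus_count(index_snps$snp[k], index_snps$increasing_allele[k])
  })
  per_locus <- data.frame(
    snp = index_snps$snp,
    n_proxies = vapply(obs, `[[`, integer(1), "n_proxies"),
    n_bins = vapply(obs, `[[`, integer(1), "n_bins"),
    count = vapply(obs, `[[`, numeric(1), "count"),
    dropped = vapply(obs, `[[`, character(1), "dropped"),
    stringsAsFactors = FALSE
  )
  n_dropped <- sum(is.na(per_locus$count))
  if (n_dropped > 0) {
    message(sprintf("%d index locus/loci dropped for lack of LD data", n_dropped))
  }
  observed_total <- sum(per_locus$count, na.rm = TRUE)

  null_counts <- numeric(0)
  empirical <- NULL
  if (n_sets > 0) {
    idx_maf <- maf_src[index_snps$snp[!is.na(per_locus$count)]]
    null_allele <- with_seed(derive_seed(seed, 2L), {
      stats::setNames(sample(c("ref", "alt"), nrow(pool), replace = TRUE), pool$snp)
    })
    sets <- generate_matched_sets(idx_maf, pool, source_panel,
                                  n_sets = n_sets, maf_tol = maf_tol,
                                  r2_indep = r2_indep,
                                  seed = derive_seed(seed, 3L))
    null_counts <- vapply(sets$sets, function(members) {
      counts <- vapply(members, function(s) locus_count(s, null_allele[[s]])$count,
                       numeric(1))
      sum(counts, na.rm = TRUE)
    }, numeric(1))
    empirical <- empirical_p(observed_total, null_counts)
  }

  structure(list(observed_total = observed_total, per_locus = per_locus,
                 null_counts = null_counts, empirical = empirical,
                 n_loci_dropped = n_dropped,
                 params = list(n_sets = n_sets, r2_proxy = r2_proxy,
                               r2_bin = r2_bin, r2_indep = r2_indep,
                               maf_tol = maf_tol, alpha = alpha,
                               window = window, seed = seed)),
            class = "replication_report")
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf("<replication_report> %d loci (%d dropped), observed significant bins: %g\n",
              nrow(x$per_locus), x$n_loci_dropped, x$observed_total))
  if (!is.null(x$empirical)) {
    cat(sprintf("  null sets: %d (median %g, range %g-%g); empirical P %s\n",
                length(x$null_counts), stats::median(x$null_counts),
                min(x$null_counts), max(x$null_counts), x$empirical$label))
  }
  invisible(x)
}
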