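#' Simulate meta-analysis-level summary statistics from a panel
#'
#' Draws per-SNP association estimates directly on the summary-statistic
#' scale, the standard large-sample shortcut for replication-framework
#' experiments: the standard error at a SNP with alternate-allele frequency
#' `f` and effective sample size `n_eff` is `1 / sqrt(2 n f (1 - f))`
#' (standardized phenotype, additive coding), and the estimate is
#' `beta_marginal + N(0, SE^2)`.
#'
#' Marginal effects are induced by the supplied causal effects through the
#' panel's own LD: for SNP j and causal SNP c,
#' `beta_marginal_j += beta_c * D_jc / (f_j (1 - f_j))`, where `D_jc` is the
#' haplotype coupling disequilibrium between the alternate alleles.  Only
#' SNPs within `window` bp of a causal SNP receive a marginal contribution.
#'
#' Effect alleles are reported as the panel alternate allele, so the output
#' is already harmonized to the panel.
#'
#' @param panel [haplotype_panel()] of the association population.
#' @param n_eff effective sample size.
#' @param effects `NULL` (global null) or data.frame with columns `snp`,
#'   `beta` giving causal effects in Z-score units per alternate allele.
#' @param window bp window around each causal SNP within which marginal
#'   effects are propagated.
#' @param seed integer seed.
#'
#' @return data.frame with columns `SNP, CHR, POS, EA, OA, EAF, BETA, SE, P,
#'   N` (monomorphic panel variants are excluded).
#' @export
simulate_summary_stats <- function(panel, n_eff, effects = NULL,
                                   window = 1e6, seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"), n_eff > 0)
  f <- alt_freq(panel)
  poly <- f > 0 & f < 1
  v <- panel$variants[poly, , drop = FALSE]
  f <- f[poly]
  hap <- panel$haplotypes[poly, , drop = FALSE]
  n_hap <- ncol(hap)

  beta_marg <- rep(0, nrow(v))
  if (!is.null(effects) && nrow(effects) > 0) {
    idx <- match(effects$snp, v$id)
    if (anyNA(idx)) {
      stop_invalid("causal SNP(s) absent or monomorphic in panel: %s",
                   paste(effects$snp[is.na(idx)], collapse = ", "))
    }
    for (k in seq_along(idx)) {
      c_row <- idx[k]
      near <- which(v$chrom == v$chrom[c_row] & abs(v$pos - v$pos[c_row]) <= window)
      p_ab <- as.numeric(hap[near, , drop = FALSE] %*% hap[c_row, ]) / n_hap
      d <- p_ab - f[near] * f[c_row]
      beta_marg[near] <- beta_marg[near] + effects$beta[k] * d / (f[near] * (1 - f[near]))
    }
  }

  se <- 1 / sqrt(2 * n_eff * f * (1 - f))
  with_seed(seed, {
    beta_hat <- beta_marg + stats::rnorm(length(se), 0, se)
    data.frame(
      SNP = v$id, CHR = v$chrom, POS = v$pos,
      EA = v$alt, OA = v$ref, EAF = unname(f),
      BETA = beta_hat, SE = se,
      P = 2 * stats::pnorm(-abs(beta_hat / se)),
      N = n_eff,
      stringsAsFactors = FALSE
    )
  })
}
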