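#' Fraction of SNPs jointly significant for height and cis-expression
#'
#' The joint-significance statistic of the cis-eQTL enrichment comparison:
#' the fraction of a SNP list nominally associated with height
#' (`P < p_height`) and with a cis expression phenotype (`P < p_eqtl`).
#' SNPs missing from either lookup stay in the denominator (a conservative
#' choice) and are logged.
#'
#' @param snps character vector of SNP ids (nonempty).
#' @param height_p named numeric vector of height association P-values
#'   (one- or two-tailed, whichever the caller's convention is).
#' @param eqtl_p named numeric vector: best cis association P per SNP.
#' @param p_height,p_eqtl thresholds (defaults 0.05 and 0.01).
#' @return Fraction in \[0, 1\].
#' @export
joint_fraction <- function(snps, height_p, eqtl_p,
                           p_height = 0.05, p_eqtl = 0.01) {
  snps <- as.character(snps)
  if (length(snps) == 0) stop_invalid("empty SNP list")
  hp <- height_p[snps]
  ep <- eqtl_p[snps]
  n_miss <- sum(is.na(hp) | is.na(ep))
  if (n_miss > 0) {
    message(sprintf("%d SNP(s) missing from a lookup kept in the denominator", n_miss))
  }
  pass <- !is.na(hp) & !is.na(ep) & hp < p_height & ep < p_eqtl
  sum(pass) / length(snps)
}

#' cis-eQTL enrichment of a fine-mapped SNP list
#'
#' Compares the joint height/eQTL significance fraction of a fine-mapped
#' candidate list (`list_b`) with that of the original index list
#' (`list_a`), and assesses the observed fraction of `list_b` against
#' `n_sims` frequency-matched null SNP sets (re-matched to `list_b`'s minor
#' allele frequencies) via [empirical_p()].  When no null set reaches the
#' observed enrichment the P is reported as `"< 1/n_sims"`.
#'
#' @param list_a,list_b SNP id vectors: the original index list and the
#'   fine-mapped list.
#' @param height_p,eqtl_p,p_height,p_eqtl as in [joint_fraction()].
#' @param pool candidate pool data.frame (`snp`, `maf`) for the matched
#'   sets.
#' @param ld LD source for the independence screen (see
#'   [generate_matched_sets()]); also supplies `list_b` MAFs when it is a
#'   panel and `list_maf` is NULL.
#' @param list_maf optional named MAF vector for `list_b`.
#' @param n_sims number of simulated matched sets (default 100).
#' @param seed integer seed.
#' @return list with `fraction_a`, `fraction_b`, `null_fractions`, and
#'   `empirical` (see [empirical_p()]).
#' @export
enrichment_test <- function(list_a, list_b, height_p, eqtl_p,
                            pool, ld, list_maf = NULL,
                            p_height = 0.05, p_eqtl = 0.01,
                            n_sims = 100, seed = NULL) {
  fraction_a <- joint_fraction(list_a, height_p, eqtl_p, p_height, p_eqtl)
  fraction_b <- joint_fraction(list_b, height_p, eqtl_p, p_height, p_eqtl)
  if (is.null(list_maf)) {
    if (!inherits(ld, "haplotype_panel")) {
      stop_invalid("supply list_maf when ld is not a haplotype_panel")
    }
    list_maf <- panel_maf(ld)[list_b]
  } else {
    list_maf <- list_maf[list_b]
  }
  if (anyNA(list_maf)) stop_invalid("missing MAF for fine-mapped SNP(s)")
  names(list_maf) <- list_b
  sets <- generate_matched_sets(list_maf, pool, ld, n_sets = n_sims,
                                seed = derive_seed(seed, 1L))
  null_fractions <- vapply(sets$sets, function(s) {
    suppressMessages(joint_fraction(s, height_p, eqtl_p, p_height, p_eqtl))
  }, numeric(1))
  list(fraction_a = fraction_a, fraction_b = fraction_b,
       null_fractions = null_fractions,
       empirical = empirical_p(fraction_b, null_fractions))
}
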