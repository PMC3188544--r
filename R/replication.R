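#' One-tailed conversion of a two-tailed P-value
#'
#' When a replication direction is predicted in advance (the proxy allele in
#' coupling phase with the discovery height-increasing allele), the
#' two-tailed P is converted to `P/2` if the observed effect direction
#' matches the prediction and `1 - P/2` otherwise.  A zero effect estimate
#' carries no direction and maps to 0.5.
#'
#' @param p_two two-tailed P-value(s) in (0, 1\].
#' @param observed_sign sign of the observed effect: numeric (e.g.
#'   `sign(beta)`, or beta itself) or `"+"`/`"-"`.
#' @param predicted_sign predicted sign, same conventions.
#' @return One-tailed P-value(s).
#' @export
one_tailed <- function(p_two, observed_sign, predicted_sign) {
  p_two <- as.numeric(p_two)
  if (any(p_two <= 0 | p_two > 1)) stop_invalid("two-tailed P must be in (0, 1]")
  so <- parse_sign(observed_sign)
  sp <- parse_sign(predicted_sign)
  out <- ifelse(so == 0, 0.5, ifelse(so == sp, p_two / 2, 1 - p_two / 2))
  unname(out)
}

parse_sign <- function(s) {
  if (is.character(s)) {
    s <- match(s, c("-", "+")) * 2 - 3
    if (anyNA(s)) stop_invalid("character signs must be \"+\" or \"-\"")
    s
  } else {
    sign(as.numeric(s))
  }
}

# r^2 provider: a haplotype_panel or a named square r^2 matrix.
ld_r2_of <- function(ld, snp, others) {
  if (length(others) == 0) return(numeric(0))
  if (inherits(ld, "haplotype_panel")) {
    r2_vector(ld, variant_row(ld, snp), variant_row(ld, others))
  } else if (is.matrix(ld)) {
    ld[snp, others]
  } else {
    stop_invalid("ld must be a haplotype_panel or a named r^2 matrix")
  }
}

ld_has_snp <- function(ld, snps) {
  if (inherits(ld, "haplotype_panel")) panel_has(ld, snps) else snps %in% rownames(ld)
}

#' Randomized LD binning of a proxy list
#'
#' The replication bin structure: the proxy list is shuffled (to remove any
#' bias towards significance in which SNP represents a bin), the first
#' unbinned SNP becomes an index, and every remaining SNP with r-squared at
#' least `r2_bin` to that index joins its bin; the procedure repeats until
#' all SNPs are binned.  Deterministic given `seed`.
#'
#' @param snps character vector of SNP ids (one locus's proxies).  SNPs
#'   missing from `ld` are dropped with a message.
#' @param ld target-population LD source: a [haplotype_panel()] or a named
#'   square r-squared matrix.
#' @param r2_bin binning threshold (default 0.3).
#' @param seed integer seed for the shuffle.
#' @param order_by optional numeric vector parallel to `snps`; when given,
#'   SNPs are processed in ascending order of this key instead of being
#'   randomized (the fine-mapping variant of the procedure).
#' @return list of bins, each `list(index = <snp>, members = <character>)`;
#'   bins partition the (retained) input list.
#' @export
build_bins <- function(snps, ld, r2_bin = 0.3, seed = NULL, order_by = NULL) {
  snps <- as.character(snps)
  if (length(snps) == 0) return(list())
  if (anyDuplicated(snps)) stop_invalid("duplicate SNP ids in proxy list")
  present <- ld_has_snp(ld, snps)
  if (any(!present)) {
    message(sprintf("%d SNP(s) absent from the LD panel dropped before binning: %s",
                    sum(!present), paste(snps[!present], collapse = ", ")))
    if (!is.null(order_by)) order_by <- order_by[present]
    snps <- snps[present]
  }
  if (length(snps) == 0) return(list())
  queue <- if (is.null(order_by)) {
    with_seed(seed, sample(snps))
  } else {
    stopifnot(length(order_by) == length(snps))
    snps[order(order_by)]
  }
  bins <- list()
  while (length(queue) > 0) {
    index <- queue[1]
    rest <- queue[-1]
    r2 <- ld_r2_of(ld, index, rest)
    absorb <- !is.na(r2) & r2 >= r2_bin
    bins[[length(bins) + 1]] <- list(index = index, members = c(index, rest[absorb]))
    queue <- rest[!absorb]
  }
  bins
}

#' Count nominally significant bins
#'
#' A bin is significant when its index SNP's one-tailed P-value is at most
#' `alpha`; the replication metric for a locus is its significant-bin count,
#' and for a whole SNP list the total across loci.  Bins whose index SNP has
#' no P-value are excluded with a warning.
#'
#' @param bins either a list of bins (one locus, as from [build_bins()]) or
#'   a named list of such lists (one element per locus).
#' @param p_onetailed named numeric vector of one-tailed P-values.
#' @param alpha significance threshold (default 0.05, compared with `<=`).
#' @return list with `per_locus` (named numeric) and `total`.
#' @export
count_significant_bins <- function(bins, p_onetailed, alpha = 0.05) {
  single <- length(bins) > 0 && !is.null(bins[[1]]$index)
  loci <- if (single) list(locus = bins) else bins
  per_locus <- vapply(loci, function(locus_bins) {
    idx <- vapply(locus_bins, function(b) b$index, character(1))
    p <- p_onetailed[idx]
    if (anyNA(p)) {
      warning(sprintf("bin index SNP(s) without a P-value excluded: %s",
                      paste(idx[is.na(p)], collapse = ", ")), call. = FALSE)
    }
    sum(p <= alpha, na.rm = TRUE)
  }, numeric(1))
  list(per_locus = per_locus, total = sum(per_locus))
}

#' Frequency-matched, mutually independent null SNP sets
#'
#' Generates `n_sets` lists of SNPs matched one-to-one to the index loci on
#' source-population minor allele frequency (tolerance `maf_tol`, widened
#' stepwise up to `maf_tol_max` for hard-to-match loci, with a message), in
#' which members are pairwise quasi-independent (r-squared below
#' `r2_indep`).  Members are sampled without replacement within a set;
#' candidates violating independence with an already-chosen member are
#' rejected.
#'
#' @param index_maf named numeric vector: minor allele frequency of each
#'   index locus.
#' @param pool data.frame with columns `snp` and `maf`: the candidate pool
#'   (an explicit input; typically all polymorphic panel SNPs minus the
#'   index loci).
#' @param ld LD source for the independence screen ([haplotype_panel()] or
#'   named r-squared matrix).  For panels carrying a `block` column the
#'   screen is restricted to same-block pairs (cross-block LD is nil by
#'   construction); otherwise it is restricted to pairs within
#'   `indep_window` bp.
#' @param n_sets number of sets (the reference analysis used 5,819).
#' @param maf_tol,maf_tol_max initial and maximum MAF matching tolerance.
#' @param r2_indep within-set independence threshold (default 0.2).
#' @param indep_window window for the pairwise screen when no block labels
#'   are available.
#' @param seed integer seed.
#' @return object of class `matched_null_sets`: list with `sets` (list of
#'   character vectors, each the same length as `index_maf`), `tolerance`
#'   (named, per locus), and the matching parameters.
#' @export
generate_matched_sets <- function(index_maf, pool, ld, n_sets = 5819,
                                  maf_tol = 0.02, maf_tol_max = 0.05,
                                  r2_indep = 0.2, indep_window = 1e6,
                                  seed = NULL) {
  stopifnot(is.numeric(index_maf), length(index_maf) >= 1, !is.null(names(index_maf)))
  stopifnot(is.data.frame(pool), all(c("snp", "maf") %in% names(pool)))
  m <- length(index_maf)
  quota <- max(1L, ceiling(n_sets / 10))

  # Per-locus eligibility with stepwise tolerance widening.
  eligible <- vector("list", m)
  tol_used <- numeric(m)
  for (l in seq_len(m)) {
    tol <- maf_tol
    repeat {
      el <- pool$snp[abs(pool$maf - index_maf[l]) <= tol]
      if (length(el) >= quota || tol >= maf_tol_max) break
      tol <- min(tol + 0.01, maf_tol_max)
    }
    if (length(el) == 0) {
      stop_invalid("matching impossible for locus %s (MAF %.3f) even at tolerance %.2f",
                   names(index_maf)[l], index_maf[l], maf_tol_max)
    }
    if (length(el) < quota) {
      warning(sprintf("locus %s has only %d MAF-eligible candidates (quota %d) at tolerance %.2f",
                      names(index_maf)[l], length(el), quota, tol), call. = FALSE)
    }
    if (tol > maf_tol) {
      message(sprintf("locus %s: MAF tolerance widened to %.2f", names(index_maf)[l], tol))
    }
    eligible[[l]] <- el
    tol_used[l] <- tol
  }
  names(tol_used) <- names(index_maf)

  # Location metadata for the windowed/blocked independence screen, held as
  # integer vectors parallel to the pool for speed.
  is_panel <- inherits(ld, "haplotype_panel")
  if (is_panel) {
    prow <- variant_row(ld, pool$snp)
    v <- ld$variants
    blk_pool <- if ("block" %in% names(v)) v$block[prow] else NULL
    pos_pool <- v$pos[prow]
    chrom_pool <- v$chrom[prow]
  }
  elig_idx <- lapply(eligible, function(el) match(el, pool$snp))

  sets <- with_seed(seed, {
    lapply(seq_len(n_sets), function(s) {
      chosen <- integer(0)
      for (l in seq_len(m)) {
        cands <- sample(elig_idx[[l]])
        picked <- NA_integer_
        for (cand in cands) {
          if (cand %in% chosen) next
          near <- if (length(chosen) == 0) {
            integer(0)
          } else if (!is_panel) {
            chosen  # full screen against a matrix
          } else if (!is.null(blk_pool)) {
            chosen[blk_pool[chosen] == blk_pool[cand]]
          } else {
            chosen[chrom_pool[chosen] == chrom_pool[cand] &
                     abs(pos_pool[chosen] - pos_pool[cand]) <= indep_window]
          }
          if (length(near) > 0) {
            r2 <- if (is_panel) {
              r2_vector(ld, prow[cand], prow[near])
            } else {
              ld_r2_of(ld, pool$snp[cand], pool$snp[near])
            }
            if (any(!is.na(r2) & r2 >= r2_indep)) next
          }
          picked <- cand
          break
        }
        if (is.na(picked)) {
          stop_invalid("set %d: no independent MAF-matched candidate left for locus %s",
                       s, names(index_maf)[l])
        }
        chosen <- c(chosen, picked)
      }
      pool$snp[chosen]
    })
  })
  structure(list(sets = sets, tolerance = tol_used, n_sets = n_sets,
                 maf_tol = maf_tol, r2_indep = r2_indep),
            class = "matched_null_sets")
}

#' Empirical P-value from a permutation null
#'
#' `P = (# null counts >= observed) / n_sets`.  When no null count reaches
#' the observed value the result is reported as `"< 1/n_sets"`, with the
#' stored value 0 and `less_than = TRUE`.
#'
#' @param observed observed statistic (e.g. total significant-bin count).
#' @param null_counts numeric vector of the statistic over null sets.
#' @return list with `p`, `k` (numerator), `n_sets`, `less_than`, and a
#'   display `label`.
#' @export
empirical_p <- function(observed, null_counts) {
  null_counts <- as.numeric(null_counts)
  if (length(null_counts) == 0) stop_invalid("need at least one null count")
  n <- length(null_counts)
  k <- sum(null_counts >= observed)
  p <- k / n
  list(p = p, k = k, n_sets = n, less_than = k == 0,
       label = if (k == 0) sprintf("< %.3g", 1 / n) else sprintf("%.3g", p))
}

#' Best-supported SNP of a locus (trans-ethnic fine-mapping)
#'
#' Repeats the binning of [build_bins()] but processes SNPs in ascending
#' P-value order (ties broken by genomic position) instead of randomized
#' order.  The first bin's index — the smallest-P SNP once LD redundancy is
#' removed — is the locus's best candidate.
#'
#' @param snps character vector of the locus's proxy SNPs.
#' @param p named numeric vector of (one-tailed) P-values.
#' @param pos named numeric vector of positions (bp) used for tie-breaking;
#'   taken from `ld` when it is a panel and `pos` is NULL.
#' @param ld target-population LD source.
#' @param r2_bin binning threshold.
#' @param bonferroni_n when given, the result records whether the best P
#'   passes the Bonferroni threshold `0.05 / bonferroni_n`.
#' @return list with `best_snp`, `best_p`, `bins`, and (if requested)
#'   `passes_bonferroni` and `bonferroni_threshold`.
#' @export
fine_map_best <- function(snps, p, ld, pos = NULL, r2_bin = 0.3,
                          bonferroni_n = NULL) {
  snps <- as.character(snps)
  if (length(snps) == 0) return(list(best_snp = NA_character_, best_p = NA_real_, bins = list()))
  pv <- p[snps]
  if (anyNA(pv)) {
    message(sprintf("%d SNP(s) without a P-value dropped from fine-mapping", sum(is.na(pv))))
    snps <- snps[!is.na(pv)]
    pv <- pv[!is.na(pv)]
  }
  if (length(snps) == 0) return(list(best_snp = NA_character_, best_p = NA_real_, bins = list()))
  if (is.null(pos) && inherits(ld, "haplotype_panel")) {
    pos <- stats::setNames(ld$variants$pos, ld$variants$id)
  }
  tie <- if (is.null(pos)) seq_along(snps) else pos[snps]
  key <- order(pv, tie)
  bins <- build_bins(snps[key], ld, r2_bin = r2_bin, order_by = seq_along(key))
  out <- list(best_snp = bins[[1]]$index, best_p = unname(pv[bins[[1]]$index]), bins = bins)
  if (!is.null(bonferroni_n)) {
    out$bonferroni_threshold <- 0.05 / bonferroni_n
    out$passes_bonferroni <- out$best_p < out$bonferroni_threshold
  }
  out
}
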