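#' Pairwise linkage disequilibrium from phased haplotypes
#'
#' Haplotype-count estimates between two stated alleles: with `p_ab` the
#' frequency of haplotypes carrying both alleles, the coupling
#' disequilibrium is `D = p_ab - p_a * p_b` and
#' `r2 = D^2 / (p_a (1 - p_a) p_b (1 - p_b))`.  No EM phasing is involved:
#' panels are phased, so counts are exact.
#'
#' @param panel a [haplotype_panel()].
#' @param snp_a,snp_b variant ids present in the panel; both must be
#'   polymorphic.
#' @param allele_a,allele_b which allele of each SNP `D` is stated for:
#'   `"alt"` (default) or `"ref"`.  `r2` is invariant to this choice; the
#'   sign of `D` is not.
#' @return list of class `ld_pair` with `snp_a, snp_b, allele_a, allele_b,
#'   p_a, p_b, p_ab, D, r2`.
#' @export
r2_from_haplotypes <- function(panel, snp_a, snp_b,
                               allele_a = "alt", allele_b = "alt") {
  stopifnot(inherits(panel, "haplotype_panel"))
  ia <- variant_row(panel, snp_a)
  ib <- variant_row(panel, snp_b)
  xa <- allele_indicator(panel, ia, allele_a)
  xb <- allele_indicator(panel, ib, allele_b)
  p_a <- mean(xa)
  p_b <- mean(xb)
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    stop_invalid("undefined LD: SNP %s is monomorphic in panel %s",
                 if (p_a %in% c(0, 1)) snp_a else snp_b, panel$population)
  }
  p_ab <- mean(xa & xb)
  d <- p_ab - p_a * p_b
  structure(
    list(snp_a = snp_a, snp_b = snp_b, allele_a = allele_a, allele_b = allele_b,
         p_a = p_a, p_b = p_b, p_ab = p_ab, D = d,
         r2 = d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))),
    class = "ld_pair"
  )
}

allele_indicator <- function(panel, row, allele) {
  x <- panel$haplotypes[row, ]
  switch(match.arg(allele, c("alt", "ref")), alt = x, ref = 1L - x)
}

# r^2 of one variant row against many rows, vectorized; NA where a candidate
# is monomorphic.
r2_vector <- function(panel, row, rows) {
  hap <- panel$haplotypes
  n <- ncol(hap)
  p_i <- panel$freq[row]
  if (p_i %in% c(0, 1)) return(rep(NA_real_, length(rows)))
  p_j <- panel$freq[rows]
  p_ab <- as.numeric(hap[rows, , drop = FALSE] %*% hap[row, ]) / n
  d <- p_ab - p_j * p_i
  r2 <- d^2 / (p_i * (1 - p_i) * p_j * (1 - p_j))
  r2[p_j %in% c(0, 1)] <- NA_real_
  unname(r2)
}

#' Predict a proxy SNP's height-increasing allele from phase
#'
#' Given the allele of an index SNP known (from the discovery population) to
#' increase height, the proxy allele expected to increase height is the one
#' in coupling phase with it: the proxy allele whose coupling disequilibrium
#' `D` with the index increasing allele is positive.
#'
#' @param panel phased [haplotype_panel()] (the discovery-population panel).
#' @param index_snp,proxy_snp variant ids.
#' @param increasing_allele `"ref"` or `"alt"`: the index allele that
#'   increases height.
#' @return The proxy's predicted increasing allele, `"ref"` or `"alt"`.
#'   `D = 0` (no phase information) raises a no-prediction error; callers
#'   performing bulk expansion should drop such proxies.
#' @export
predict_direction <- function(panel, index_snp, increasing_allele, proxy_snp) {
  increasing_allele <- match.arg(increasing_allele, c("ref", "alt"))
  pair <- r2_from_haplotypes(panel, index_snp, proxy_snp,
                             allele_a = increasing_allele, allele_b = "alt")
  if (pair$D == 0) {
    stop_invalid("no prediction: D = 0 between %s (%s allele) and %s",
                 index_snp, increasing_allele, proxy_snp)
  }
  if (pair$D > 0) "alt" else "ref"
}

# Single-locus proxy expansion; the workhorse behind expand_proxies().
proxy_set_one <- function(index_snp, increasing_allele, panel,
                          r2_min = 0.8, window = 1e6) {
  i <- variant_row(panel, index_snp)
  f <- panel$freq[i]
  if (f %in% c(0, 1)) {
    return(list(index = index_snp, increasing_allele = increasing_allele,
                members = data.frame(snp = character(0), pos = integer(0),
                                     r2 = numeric(0), predicted_allele = character(0),
                                     stringsAsFactors = FALSE),
                unresolvable = TRUE, n_dropped_direction = 0L))
  }
  v <- panel$variants
  cand <- which(v$chrom == v$chrom[i] & abs(v$pos - v$pos[i]) <= window & seq_len(nrow(v)) != i)
  r2 <- r2_vector(panel, i, cand)
  sel <- !is.na(r2) & r2 >= r2_min
  hit <- cand[sel]
  r2 <- r2[sel]

  # Coupling sign of each proxy's alt allele with the index increasing allele.
  x_inc <- allele_indicator(panel, i, increasing_allele)
  n_hap <- ncol(panel$haplotypes)
  dropped <- 0L
  if (length(hit) > 0) {
    d <- as.numeric(panel$haplotypes[hit, , drop = FALSE] %*% x_inc) / n_hap -
      panel$freq[hit] * mean(x_inc)
    keep <- d != 0
    dropped <- sum(!keep)
    snps <- c(index_snp, v$id[hit][keep])
    pos <- c(v$pos[i], v$pos[hit][keep])
    rr <- c(1, r2[keep])
    pred <- c(increasing_allele, ifelse(d[keep] > 0, "alt", "ref"))
  } else {
    snps <- index_snp
    pos <- v$pos[i]
    rr <- 1
    pred <- increasing_allele
  }
  o <- order(pos)
  members <- data.frame(snp = snps[o], pos = pos[o], r2 = rr[o],
                        predicted_allele = pred[o], stringsAsFactors = FALSE)
  list(index = index_snp, increasing_allele = increasing_allele,
       members = members, unresolvable = FALSE,
       n_dropped_direction = dropped)
}

#' Expand index SNPs into proxy sets
#'
#' For each index SNP, collects every panel SNP within `window` bp whose
#' r-squared with the index reaches `r2_min` (default 0.8, the conventional
#' strong-LD proxy threshold), annotating each proxy with its predicted
#' height-increasing allele via [predict_direction()].  The index SNP itself
#' is always a member with `r2 = 1`.  Proxies whose direction is
#' unpredictable (`D = 0`) are dropped and tallied; an index SNP monomorphic
#' in the panel yields a set flagged `unresolvable` (no usable LD data).
#'
#' @param index_snps data.frame with columns `snp` and `increasing_allele`
#'   (`"ref"`/`"alt"`).
#' @param panel phased [haplotype_panel()] of the discovery population.
#' @param r2_min proxy r-squared threshold.
#' @param window search window in bp on either side of the index.
#' @return list of proxy sets, one per index SNP; each has `index`,
#'   `increasing_allele`, `members` (data.frame `snp, pos, r2,
#'   predicted_allele`), `unresolvable`, `n_dropped_direction`.
#' @export
expand_proxies <- function(index_snps, panel, r2_min = 0.8, window = 1e6) {
  stopifnot(is.data.frame(index_snps),
            all(c("snp", "increasing_allele") %in% names(index_snps)))
  out <- lapply(seq_len(nrow(index_snps)), function(k) {
    proxy_set_one(index_snps$snp[k], index_snps$increasing_allele[k],
                  panel, r2_min = r2_min, window = window)
  })
  names(out) <- index_snps$snp
  out
}

#' LD-defined interval around a SNP
#'
#' The chromosomal interval flanked by the leftmost and rightmost SNPs whose
#' r-squared with the query SNP reaches `r2_min`, within `window` bp.  This
#' is the interval-narrowing statistic of trans-ethnic fine-mapping: panels
#' with shorter-range LD (e.g. African-ancestry panels) produce narrower
#' intervals over the same variants.
#'
#' @param snp variant id (must be polymorphic in the panel).
#' @inheritParams expand_proxies
#' @return list with `left`, `right` (bp, 1-based inclusive), `width`
#'   (`right - left`, so a SNP with no qualifying neighbor has width 0), and
#'   `n_snps`.
#' @export
ld_interval <- function(snp, panel, r2_min = 0.8, window = 1e6) {
  i <- variant_row(panel, snp)
  f <- panel$freq[i]
  if (f %in% c(0, 1)) {
    stop_invalid("undefined LD: SNP %s is monomorphic in panel %s", snp, panel$population)
  }
  v <- panel$variants
  cand <- which(v$chrom == v$chrom[i] & abs(v$pos - v$pos[i]) <= window & seq_len(nrow(v)) != i)
  r2 <- r2_vector(panel, i, cand)
  pos <- c(v$pos[i], v$pos[cand[!is.na(r2) & r2 >= r2_min]])
  list(left = min(pos), right = max(pos), width = max(pos) - min(pos),
       n_snps = length(pos))
}

#' Two-population fixation index
#'
#' Equal-weight Fst from a pair of allele frequencies:
#' `p_bar = (p1 + p2)/2`, total heterozygosity `H_T = 2 p_bar (1 - p_bar)`,
#' mean subpopulation heterozygosity `H_S = mean(2 p_i (1 - p_i))`, and
#' `Fst = (H_T - H_S)/H_T` (0 when `H_T = 0`).  Vectorized over frequency
#' pairs.
#'
#' @param p1,p2 allele frequencies in \[0, 1\].
#' @return Fst value(s) in \[0, 1\].
#' @export
fst_two_pop <- function(p1, p2) {
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  ifelse(ht == 0, 0, (ht - hs) / ht)
}
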