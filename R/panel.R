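#' Phased haplotype reference panel
#'
#' A `haplotype_panel` holds a binary allele matrix (variants x haplotypes,
#' entries 0 = reference allele, 1 = alternate allele) over phased reference
#' haplotypes of one population, together with variant coordinates and
#' alleles.  Panels play the role that phased CEU/YRI-style reference
#' datasets play in trans-ethnic analyses: linkage disequilibrium, proxy
#' SNPs, and allele-direction predictions are all computed from them.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based bp, strictly
#'   increasing within a chromosome), `id`, `ref`, `alt`; an optional `block`
#'   column (integer haplotype-block label) is kept when present.
#' @param haplotypes integer matrix of 0/1 allele indicators, one row per
#'   variant and one column per haplotype.  The number of columns must be even
#'   (panels represent diploid reference individuals).
#' @param population character label, e.g. `"EUR"` or `"AFR"`.
#'
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(variants, haplotypes, population = "pop") {
  stopifnot(is.data.frame(variants))
  need <- c("chrom", "pos", "id", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss) > 0) {
    stop_invalid("variant table is missing column(s): %s", paste(miss, collapse = ", "))
  }
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (nrow(variants) != nrow(haplotypes)) {
    stop_invalid("variant table (%d rows) and haplotype matrix (%d rows) disagree",
                 nrow(variants), nrow(haplotypes))
  }
  if (nrow(haplotypes) > 0 && ncol(haplotypes) %% 2L != 0L) {
    stop_invalid("number of haplotypes must be even (diploid reference individuals)")
  }
  if (nrow(haplotypes) > 0 && !all(haplotypes %in% c(0L, 1L))) {
    stop_invalid("haplotype matrix entries must be 0 or 1")
  }
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop_invalid("positions must be strictly increasing within chromosome %s", ch)
    }
  }
  if (anyDuplicated(variants$id)) {
    stop_invalid("variant ids must be unique")
  }
  rownames(haplotypes) <- variants$id
  n <- nrow(haplotypes)
  index <- new.env(hash = TRUE, parent = emptyenv(), size = max(n, 1L))
  if (n > 0) list2env(stats::setNames(as.list(seq_len(n)), variants$id), envir = index)
  structure(
    list(variants = as.data.frame(variants, stringsAsFactors = FALSE),
         haplotypes = haplotypes,
         freq = if (n > 0) rowMeans(haplotypes) else numeric(0),  # alt-allele freq cache
         index = index,
         population = population),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %s: %d variants x %d haplotypes\n",
              x$population, nrow(x$haplotypes), ncol(x$haplotypes)))
  invisible(x)
}

n_haplotypes <- function(panel) ncol(panel$haplotypes)

#' Alternate-allele frequencies of a panel
#'
#' @param panel a [haplotype_panel()].
#' @return Named numeric vector of alternate-allele frequencies.
#' @export
alt_freq <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  stats::setNames(panel$freq, panel$variants$id)
}

#' Minor-allele frequencies of a panel
#'
#' @inheritParams alt_freq
#' @return Named numeric vector of minor-allele frequencies.
#' @export
panel_maf <- function(panel) {
  f <- alt_freq(panel)
  pmin(f, 1 - f)
}

# Row index of a variant id (hashed lookup), erroring on unknown SNPs.
variant_row <- function(panel, snp) {
  i <- unlist(mget(snp, envir = panel$index, ifnotfound = NA_integer_),
              use.names = FALSE)
  if (anyNA(i)) {
    stop_invalid("SNP(s) not in panel: %s", paste(snp[is.na(i)], collapse = ", "))
  }
  i
}

# Vectorized membership test against the panel's id index.
panel_has <- function(panel, snps) {
  !is.na(unlist(mget(snps, envir = panel$index, ifnotfound = NA_integer_),
                use.names = FALSE))
}
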