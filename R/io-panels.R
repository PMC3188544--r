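#' Write a haplotype panel as phased VCF
#'
#' Plain-text VCF 4.2 with one diploid sample per haplotype pair and phased
#' `GT` fields (`"0|1"`).  Positions are 1-based inclusive.
#'
#' @param panel a [haplotype_panel()].
#' @param path output path (conventionally `.vcf`).
#' @export
write_phased_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  hap <- panel$haplotypes
  n_sample <- ncol(hap) / 2
  sample_names <- sprintf("%s_%04d", panel$population, seq_len(n_sample))
  gt <- matrix(paste(hap[, seq(1, ncol(hap), by = 2), drop = FALSE],
                     hap[, seq(2, ncol(hap), by = 2), drop = FALSE], sep = "|"),
               nrow = nrow(hap))
  v <- panel$variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=transheight",
    sprintf("##contig=<ID=%s>", unique(v$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            sample_names), collapse = "\t")
  )
  body <- do.call(paste, c(list(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT"),
                           lapply(seq_len(ncol(gt)), function(j) gt[, j]),
                           sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phased VCF into a haplotype panel
#'
#' Parses with `vcfR` and splits each sample's phased `GT` into two
#' haplotype columns.  Unphased or half-missing genotypes are rejected.
#'
#' @param path VCF path.
#' @param population population label for the panel.
#' @return A [haplotype_panel()].
#' @export
read_phased_vcf <- function(path, population = "pop") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (any(!grepl("^[01]\\|[01]$", gt))) {
    stop_invalid("VCF %s contains unphased or missing GT fields", path)
  }
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  hap <- matrix(0L, nrow = nrow(gt), ncol = 2 * ncol(gt))
  hap[, seq(1, ncol(hap), by = 2)] <- as.integer(a1)
  hap[, seq(2, ncol(hap), by = 2)] <- as.integer(a2)
  variants <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    id = fix[, "ID"], ref = fix[, "REF"], alt = fix[, "ALT"],
    stringsAsFactors = FALSE
  )
  haplotype_panel(variants, hap, population = population)
}

#' Write a panel as an IMPUTE-style hap/legend pair
#'
#' The legend file has columns `id position a0 a1`; the hap file has one
#' space-separated 0/1 row per variant, one column per haplotype.
#'
#' @param panel a [haplotype_panel()].
#' @param hap_path,legend_path output paths.
#' @export
write_hap_legend <- function(panel, hap_path, legend_path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  v <- panel$variants
  legend <- data.frame(id = v$id, position = v$pos, a0 = v$ref, a1 = v$alt)
  data.table::fwrite(legend, legend_path, sep = " ", quote = FALSE)
  data.table::fwrite(as.data.frame(panel$haplotypes), hap_path,
                     sep = " ", quote = FALSE, col.names = FALSE)
  invisible(hap_path)
}

#' Read an IMPUTE-style hap/legend pair
#'
#' @param hap_path,legend_path input paths (see [write_hap_legend()]).
#' @param chrom chromosome label to assign.
#' @param population population label.
#' @return A [haplotype_panel()].
#' @export
read_hap_legend <- function(hap_path, legend_path, chrom = "1", population = "pop") {
  legend <- as.data.frame(data.table::fread(legend_path, header = TRUE))
  hap <- as.matrix(data.table::fread(hap_path, header = FALSE))
  variants <- data.frame(
    chrom = chrom, pos = as.integer(legend$position), id = legend$id,
    ref = legend$a0, alt = legend$a1, stringsAsFactors = FALSE
  )
  haplotype_panel(variants, hap, population = population)
}

#' Write a cohort as TSV tables
#'
#' One row per individual (`id, sex, age, disease, study, global_eur,
#' height`), plus a genotype matrix file (variants x individuals,
#' tab-separated with a SNP id column) and an identically shaped
#' local-ancestry dosage file.
#'
#' @param cohort an `admixed_cohort`.
#' @param prefix output path prefix; writes `<prefix>_individuals.tsv`,
#'   `<prefix>_genotypes.tsv`, `<prefix>_ancestry.tsv`.
#' @export
write_cohort <- function(cohort, prefix) {
  stopifnot(inherits(cohort, "admixed_cohort"))
  ind <- cohort$covariates
  ind$height <- cohort$phenotype %||% NA_real_
  data.table::fwrite(ind, paste0(prefix, "_individuals.tsv"), sep = "\t", quote = FALSE)
  gm <- data.frame(SNP = rownames(cohort$genotypes), cohort$genotypes,
                   check.names = FALSE)
  data.table::fwrite(gm, paste0(prefix, "_genotypes.tsv"), sep = "\t", quote = FALSE)
  am <- data.frame(SNP = rownames(cohort$local_ancestry), cohort$local_ancestry,
                   check.names = FALSE)
  data.table::fwrite(am, paste0(prefix, "_ancestry.tsv"), sep = "\t", quote = FALSE)
  invisible(prefix)
}
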