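SUMMARY_STAT_COLUMNS <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")

#' Read per-study GWAS summary statistics
#'
#' Tab-separated with a header row; the required columns are
#' `SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N`.  Alleles are upper-cased,
#' rows with non-positive or missing SE are rejected with line-numbered
#' messages, and duplicated chromosome:position pairs (e.g. both strand
#' representations of one SNP) trigger a warning.
#'
#' @param path file path.
#' @return data.frame of typed association records.
#' @export
read_summary_stats <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  miss <- setdiff(SUMMARY_STAT_COLUMNS, names(df))
  if (length(miss) > 0) {
    stop_invalid("summary-statistic file %s is missing column(s): %s",
                 path, paste(miss, collapse = ", "))
  }
  df$EA <- toupper(df$EA)
  df$OA <- toupper(df$OA)
  df$CHR <- as.character(df$CHR)
  bad <- !is.finite(df$SE) | df$SE <= 0
  if (any(bad)) {
    message(sprintf("rejected %d row(s) with non-positive SE (line %s)",
                    sum(bad), paste(which(bad) + 1L, collapse = ", ")))
    df <- df[!bad, , drop = FALSE]
  }
  key <- paste(df$CHR, df$POS, sep = ":")
  if (anyDuplicated(key)) {
    warning(sprintf("duplicate position(s): %s",
                    paste(unique(key[duplicated(key)]), collapse = ", ")),
            call. = FALSE)
  }
  row.names(df) <- NULL
  df
}

#' Write summary statistics as TSV
#'
#' @param stats data.frame of association records.
#' @param path output path.
#' @export
write_summary_stats <- function(stats, path) {
  data.table::fwrite(stats, path, sep = "\t", quote = FALSE)
  invisible(path)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_ambiguous_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Align one association record to a panel's alternate allele
#'
#' Resolves allele-coding differences between a study record and a reference
#' panel variant: direct match, effect/other swap (beta negated, frequency
#' complemented), strand flip, or flip-plus-swap.  For strand-ambiguous
#' pairs (A/T, C/G) orientation is decided by comparing the effect-allele
#' frequency with the panel alternate-allele frequency, except inside the
#' frequency exclusion zone (`ambiguous_band`, default 0.42-0.58) where the
#' record is unresolvable and dropped.
#'
#' @param ea,oa study effect and other allele (single characters).
#' @param beta,eaf study effect estimate and effect-allele frequency.
#' @param ref,alt panel reference and alternate alleles.
#' @param alt_freq panel alternate-allele frequency (required to resolve
#'   ambiguous pairs).
#' @param ambiguous_band frequency zone within which ambiguous pairs are
#'   dropped.
#' @return list with `beta`, `eaf`, `ea = alt`, `oa = ref`, and `action`
#'   (`"keep"`, `"swap"`, `"flip"`, `"flip_swap"`, `"freq_keep"`,
#'   `"freq_swap"`), or `NULL` (with a warning) when unresolvable.
#' @export
harmonize_alleles <- function(ea, oa, beta, eaf, ref, alt, alt_freq = NULL,
                              ambiguous_band = c(0.42, 0.58)) {
  ea <- toupper(ea); oa <- toupper(oa)
  ref <- toupper(ref); alt <- toupper(alt)
  aligned <- function(beta, eaf, action) {
    list(beta = beta, eaf = eaf, ea = alt, oa = ref, action = action)
  }
  if (is_ambiguous_pair(ea, oa)) {
    if (!setequal(c(ea, oa), c(ref, alt))) {
      warning(sprintf("allele mismatch for ambiguous pair %s/%s vs %s/%s; dropped",
                      ea, oa, ref, alt), call. = FALSE)
      return(NULL)
    }
    if (eaf >= ambiguous_band[1] && eaf <= ambiguous_band[2]) {
      warning(sprintf("ambiguous %s/%s SNP with EAF %.2f in the exclusion zone; dropped",
                      ea, oa, eaf), call. = FALSE)
      return(NULL)
    }
    if (is.null(alt_freq)) {
      warning("ambiguous pair needs a panel frequency to orient; dropped", call. = FALSE)
      return(NULL)
    }
    if (abs(eaf - alt_freq) <= abs((1 - eaf) - alt_freq)) {
      return(aligned(beta, eaf, "freq_keep"))
    }
    return(aligned(-beta, 1 - eaf, "freq_swap"))
  }
  if (ea == alt && oa == ref) return(aligned(beta, eaf, "keep"))
  if (ea == ref && oa == alt) return(aligned(-beta, 1 - eaf, "swap"))
  cea <- unname(COMPLEMENT[ea]); coa <- unname(COMPLEMENT[oa])
  if (!is.na(cea) && !is.na(coa)) {
    if (cea == alt && coa == ref) return(aligned(beta, eaf, "flip"))
    if (cea == ref && coa == alt) return(aligned(-beta, 1 - eaf, "flip_swap"))
  }
  warning(sprintf("alleles %s/%s do not match panel %s/%s; dropped", ea, oa, ref, alt),
          call. = FALSE)
  NULL
}

#' Harmonize a summary-statistic table to a panel
#'
#' Applies [harmonize_alleles()] row by row against the panel's variants
#' (matched on SNP id); unresolvable rows and SNPs absent from the panel are
#' dropped.
#'
#' @param stats summary-statistic data.frame (see [read_summary_stats()]).
#' @param panel a [haplotype_panel()].
#' @return Harmonized data.frame (effect allele = panel alternate allele).
#' @export
harmonize_summary_stats <- function(stats, panel) {
  m <- match(stats$SNP, panel$variants$id)
  keep_rows <- !is.na(m)
  if (any(!keep_rows)) {
    message(sprintf("%d SNP(s) absent from the panel dropped", sum(!keep_rows)))
  }
  stats <- stats[keep_rows, , drop = FALSE]
  m <- m[keep_rows]
  fr <- alt_freq(panel)[m]
  out <- vector("list", nrow(stats))
  for (i in seq_len(nrow(stats))) {
    h <- harmonize_alleles(stats$EA[i], stats$OA[i], stats$BETA[i], stats$EAF[i],
                           panel$variants$ref[m[i]], panel$variants$alt[m[i]],
                           alt_freq = fr[i])
    if (is.null(h)) next
    row <- stats[i, , drop = FALSE]
    row$EA <- h$ea; row$OA <- h$oa; row$BETA <- h$beta; row$EAF <- h$eaf
    out[[i]] <- row
  }
  res <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(res)) res <- stats[0, , drop = FALSE]
  row.names(res) <- NULL
  res
}
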