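#' Vectorized per-SNP association scan
#'
#' Runs the additive regression of [snp_regression()] across every variant of
#' a genotype matrix at once using the Frisch-Waugh decomposition: phenotype
#' and genotypes are residualized on the covariates, after which each SNP's
#' slope, standard error, and P-value follow from simple cross-products.
#' Results are numerically identical to looping [snp_regression()] over SNPs
#' (a property the test suite checks); SNPs with any missing genotype fall
#' back to the per-SNP path.
#'
#' @param z phenotype Z-scores.
#' @param genotypes variants x individuals matrix of allele counts, with
#'   variant ids as row names.
#' @param covariates optional per-individual covariates.
#' @param variants optional variant table (`id`, `chrom`, `pos`, `ref`,
#'   `alt`) used to annotate the output.
#' @return data.frame of association results (`SNP, CHR, POS, EA, OA, EAF,
#'   BETA, SE, P, N`), monomorphic SNPs omitted.
#' @export
assoc_scan <- function(z, genotypes, covariates = NULL, variants = NULL) {
  z <- as.numeric(z)
  n <- length(z)
  stopifnot(ncol(genotypes) == n)
  x <- model_matrix_with_intercept(covariates, n)
  if (qr(x)$rank < ncol(x)) stop_invalid("degenerate input: collinear covariate matrix")

  has_na <- rowSums(is.na(genotypes)) > 0
  gv <- apply(genotypes, 1, stats::var)
  keep <- !has_na & !is.na(gv) & gv > 0
  if (any(!keep & !has_na)) {
    message(sprintf("%d monomorphic SNP(s) omitted from scan", sum(!keep & !has_na)))
  }

  qx <- qr(x)
  z_r <- stats::residuals(stats::lm.fit(x, z))
  g_r <- t(genotypes[keep, , drop = FALSE]) -
    qr.fitted(qx, t(genotypes[keep, , drop = FALSE]))  # individuals x SNPs

  den <- colSums(g_r^2)
  num <- as.numeric(crossprod(g_r, z_r))
  beta <- num / den
  df <- n - ncol(x) - 1L
  if (df < 1) stop_invalid("degenerate input: n too small for the model")
  rss <- pmax(sum(z_r^2) - beta^2 * den, 0)
  se <- sqrt(rss / df / den)
  t_stat <- abs(beta / se)
  p <- if (n > 200) 2 * stats::pnorm(-t_stat) else 2 * stats::pt(-t_stat, df)
  p[se == 0] <- 0

  ids <- rownames(genotypes)[keep]
  out <- data.frame(SNP = ids, CHR = NA, POS = NA,
                    EA = "ALT", OA = "REF",
                    EAF = rowMeans(genotypes[keep, , drop = FALSE]) / 2,
                    BETA = beta, SE = se, P = p, N = n,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(variants)) {
    m <- match(ids, variants$id)
    out$CHR <- variants$chrom[m]
    out$POS <- variants$pos[m]
    out$EA <- variants$alt[m]
    out$OA <- variants$ref[m]
  }

  if (any(has_na)) {
    extra <- lapply(which(has_na), function(i) {
      snp_regression(z, genotypes[i, ], covariates, snp = rownames(genotypes)[i])
    })
    extra <- do.call(rbind, Filter(Negate(is.null), extra))
    if (!is.null(extra) && !is.null(variants)) {
      m <- match(extra$SNP, variants$id)
      extra$CHR <- variants$chrom[m]
      extra$POS <- variants$pos[m]
      extra$EA <- variants$alt[m]
      extra$OA <- variants$ref[m]
    }
    out <- rbind(out, extra)
    out <- out[order(match(out$SNP, rownames(genotypes))), , drop = FALSE]
    row.names(out) <- NULL
  }
  out
}
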