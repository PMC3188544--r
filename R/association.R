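#' Covariate-adjusted height Z-scores
#'
#' Residualizes raw height on the supplied covariates (sex, age, disease
#' status, global-ancestry axes, ...) by ordinary least squares, then centers
#' and scales the residuals to mean 0 and sample standard deviation 1
#' (n - 1 denominator).  This is the standard normalization applied before
#' per-SNP association testing so that effect sizes are in Z-score units.
#'
#' @param height numeric vector of raw heights.
#' @param covariates `NULL`, or a data.frame / matrix of numeric covariates
#'   (one row per individual).
#' @return Numeric vector of Z-scores, same length as `height`.
#' @export
zscore_transform <- function(height, covariates = NULL) {
  height <- as.numeric(height)
  if (anyNA(height)) stop_invalid("height contains missing values")
  n <- length(height)
  if (n < 2) stop_invalid("degenerate input: need at least 2 individuals")
  if (stats::var(height) == 0) stop_invalid("degenerate input: height is constant")
  x <- model_matrix_with_intercept(covariates, n)
  if (!all(is.finite(x))) stop_invalid("covariates must be finite")
  if (qr(x)$rank < ncol(x)) {
    stop_invalid("degenerate input: collinear covariate matrix")
  }
  if (n <= ncol(x)) stop_invalid("degenerate input: more model columns than individuals")
  r <- stats::lm.fit(x, height)$residuals
  s <- stats::sd(r)
  if (s == 0) stop_invalid("degenerate input: height fully explained by covariates")
  (r - mean(r)) / s
}

model_matrix_with_intercept <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1))
  cv <- as.matrix(as.data.frame(covariates))
  storage.mode(cv) <- "double"
  if (nrow(cv) != n) stop_invalid("covariates must have one row per individual")
  cbind(`(Intercept)` = 1, cv)
}

#' Per-SNP additive linear regression
#'
#' Ordinary least squares of a standardized phenotype on an additive allele
#' count plus covariates.  The two-tailed P-value uses the normal reference
#' for n > 200 complete cases and the t reference below that.  Monomorphic
#' SNPs are flagged and omitted (the function returns `NULL` with a message
#' rather than raising an error); missing genotypes are dropped per SNP and
#' the complete-case count is reported as `N`.
#'
#' @param z numeric phenotype Z-scores (see [zscore_transform()]).
#' @param genotype additive allele counts (0/1/2; males on X may be 0/2).
#' @param covariates optional per-individual covariates.
#' @param snp,effect_allele,other_allele,chrom,pos metadata copied into the
#'   result row.
#' @return One-row data.frame with columns `SNP, CHR, POS, EA, OA, EAF,
#'   BETA, SE, P, N`, or `NULL` for a monomorphic SNP.
#' @export
snp_regression <- function(z, genotype, covariates = NULL,
                           snp = "SNP", effect_allele = "ALT",
                           other_allele = "REF", chrom = NA, pos = NA) {
  z <- as.numeric(z)
  genotype <- as.numeric(genotype)
  stopifnot(length(z) == length(genotype))
  keep <- stats::complete.cases(z, genotype,
                                if (is.null(covariates)) rep(TRUE, length(z)) else as.data.frame(covariates))
  z <- z[keep]
  genotype <- genotype[keep]
  cv <- if (is.null(covariates)) NULL else as.data.frame(covariates)[keep, , drop = FALSE]
  n <- length(z)

  if (n == 0 || stats::var(genotype) == 0) {
    message(sprintf("SNP %s is monomorphic after removing missing values; omitted", snp))
    return(NULL)
  }
  x <- cbind(model_matrix_with_intercept(cv, n), genotype = genotype)
  if (n <= ncol(x)) stop_invalid("degenerate input: n <= number of model parameters")
  fit <- stats::lm.fit(x, z)
  if (fit$rank < ncol(x) || is.na(fit$coefficients["genotype"])) {
    stop_invalid("degenerate input: genotype collinear with covariates")
  }
  beta <- unname(fit$coefficients["genotype"])
  df <- n - ncol(x)
  rss <- sum(fit$residuals^2)
  xtx_inv <- chol2inv(chol(crossprod(x)))
  se <- sqrt(max(rss / df, 0) * xtx_inv[ncol(x), ncol(x)])
  p <- regression_p(beta, se, n, df)
  data.frame(SNP = snp, CHR = chrom, POS = pos,
             EA = effect_allele, OA = other_allele,
             EAF = mean(genotype) / 2,
             BETA = beta, SE = se, P = p, N = n,
             stringsAsFactors = FALSE)
}

# Two-tailed P: normal reference for large n, t below n = 201; an exact fit
# (SE = 0) maps to P = 0.
regression_p <- function(beta, se, n, df) {
  if (se == 0) return(0)
  t_stat <- abs(beta / se)
  if (n > 200) 2 * stats::pnorm(-t_stat) else 2 * stats::pt(-t_stat, df)
}

#' Two-tailed P-value from a normal effect estimate
#'
#' `P = 2 * Phi(-|beta / SE|)`, the standard conversion used for summary
#' statistics in Z-score units.
#'
#' @param beta,se effect estimate and its standard error (SE > 0); both may
#'   be vectors.
#' @return Two-tailed P-value(s).
#' @export
two_tailed_p <- function(beta, se) {
  if (any(se <= 0)) stop_invalid("SE must be > 0")
  2 * stats::pnorm(-abs(beta / se))
}

#' Joint genotype + local-ancestry conditional model
#'
#' Fits the joint OLS model `z ~ genotype + ancestry + covariates` and
#' returns both adjusted terms, so the caller can report the SNP effect
#' conditional on local ancestry and the local-ancestry effect conditional
#' on the SNP.  When genotype and ancestry dosage are perfectly collinear
#' (given the covariates), both terms are marked not estimable and the
#' result carries `collinear = TRUE`.
#'
#' @param z phenotype Z-scores.
#' @param genotype additive allele counts.
#' @param ancestry local-ancestry dosage: number of European-derived
#'   chromosomes (0, 1, or 2) at the locus.
#' @param covariates optional covariates (e.g. global-ancestry axes).
#' @return data.frame with rows `genotype` and `ancestry` (columns `term,
#'   BETA, SE, P, estimable`) and attribute `collinear`.
#' @export
conditional_model <- function(z, genotype, ancestry, covariates = NULL) {
  z <- as.numeric(z)
  genotype <- as.numeric(genotype)
  ancestry <- as.numeric(ancestry)
  stopifnot(length(z) == length(genotype), length(z) == length(ancestry))
  if (!all(ancestry %in% 0:2)) stop_invalid("ancestry dosage must be 0, 1, or 2")
  n <- length(z)
  x <- cbind(model_matrix_with_intercept(covariates, n),
             genotype = genotype, ancestry = ancestry)
  out <- data.frame(term = c("genotype", "ancestry"),
                    BETA = NA_real_, SE = NA_real_, P = NA_real_,
                    estimable = FALSE, stringsAsFactors = FALSE)
  if (qr(x)$rank < ncol(x)) {
    attr(out, "collinear") <- TRUE
    return(out)
  }
  if (n <= ncol(x)) stop_invalid("degenerate input: n <= number of model parameters")
  fit <- stats::lm.fit(x, z)
  df <- n - ncol(x)
  rss <- sum(fit$residuals^2)
  xtx_inv <- chol2inv(chol(crossprod(x)))
  for (term in c("genotype", "ancestry")) {
    j <- match(term, colnames(x))
    beta <- unname(fit$coefficients[term])
    se <- sqrt(max(rss / df, 0) * xtx_inv[j, j])
    out[out$term == term, c("BETA", "SE", "P")] <-
      list(beta, se, regression_p(beta, se, n, df))
    out$estimable[out$term == term] <- TRUE
  }
  attr(out, "collinear") <- FALSE
  out
}

#' Association stratified by local ancestry
#'
#' Runs [snp_regression()] separately within the three local-ancestry strata
#' (0, 1, or 2 European-derived chromosomes) and combines the per-stratum
#' estimates by fixed-effect inverse-variance meta-analysis.  Strata with
#' fewer than `min_n` individuals, or monomorphic within the stratum, are
#' skipped with a log record.
#'
#' @inheritParams conditional_model
#' @param min_n minimum stratum size analyzed (default 50).
#' @param snp SNP label for the per-stratum results.
#' @return list with `strata` (data.frame: stratum, n, BETA, SE, P, skipped,
#'   reason) and `combined` (the inverse-variance combination, see
#'   [inverse_variance_meta()]).
#' @export
stratified_by_ancestry <- function(z, genotype, ancestry, covariates = NULL,
                                   min_n = 50, snp = "SNP") {
  z <- as.numeric(z)
  genotype <- as.numeric(genotype)
  ancestry <- as.numeric(ancestry)
  if (!all(ancestry %in% 0:2)) stop_invalid("ancestry dosage must be 0, 1, or 2")
  strata <- data.frame(stratum = 0:2, n = NA_integer_,
                       BETA = NA_real_, SE = NA_real_, P = NA_real_,
                       skipped = TRUE, reason = "", stringsAsFactors = FALSE)
  for (s in 0:2) {
    idx <- which(ancestry == s)
    strata$n[s + 1] <- length(idx)
    if (length(idx) < min_n) {
      strata$reason[s + 1] <- sprintf("n = %d below minimum %d", length(idx), min_n)
      message(sprintf("stratum %d skipped: %s", s, strata$reason[s + 1]))
      next
    }
    cv <- if (is.null(covariates)) NULL else as.data.frame(covariates)[idx, , drop = FALSE]
    res <- snp_regression(z[idx], genotype[idx], cv, snp = snp)
    if (is.null(res)) {
      strata$reason[s + 1] <- "monomorphic within stratum"
      next
    }
    strata[s + 1, c("BETA", "SE", "P")] <- res[, c("BETA", "SE", "P")]
    strata$skipped[s + 1] <- FALSE
  }
  used <- !strata$skipped
  if (!any(used)) stop_invalid("all ancestry strata were skipped")
  combined <- inverse_variance_meta(strata$BETA[used], strata$SE[used])
  list(strata = strata, combined = combined)
}
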