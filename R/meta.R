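#' Genomic-control inflation factor
#'
#' Converts two-tailed P-values to 1-df chi-square statistics and estimates
#' the median-based inflation factor
#' `lambda = median(chi^2) / qchisq(0.5, 1)` (denominator 0.45494).  Under
#' the null, lambda is 1; polygenicity or stratification inflate it.
#'
#' @param p_values vector of two-tailed P-values in (0, 1\].  Exact zeros are
#'   clipped to the smallest representable positive double, with a message.
#' @return The inflation factor lambda (a positive scalar).
#' @export
genomic_control_lambda <- function(p_values) {
  p <- as.numeric(p_values)
  p <- p[!is.na(p)]
  if (length(p) == 0) stop_invalid("no P-values supplied")
  if (any(p < 0 | p > 1)) stop_invalid("P-values must lie in (0, 1]")
  if (any(p == 0)) {
    message(sprintf("%d P-value(s) equal to 0 clipped to the smallest positive double",
                    sum(p == 0)))
    p[p == 0] <- .Machine$double.xmin
  }
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Apply genomic control to association results
#'
#' Divides each SNP's chi-square statistic by `lambda` - equivalently,
#' multiplies the standard error by `sqrt(lambda)` - and recomputes the
#' two-tailed P on the normal scale.  Effect estimates are unchanged.
#' Following the usual convention (genomic control is a conservative
#' correction, not a sharpening), `lambda <= 1` leaves the results untouched.
#'
#' @param assoc data.frame with columns `BETA`, `SE`, `P` (e.g. from
#'   [assoc_scan()] or [meta_analyze()]).
#' @param lambda inflation factor from [genomic_control_lambda()].
#' @return `assoc` with corrected `SE` and `P`.
#' @export
gc_correct <- function(assoc, lambda) {
  stopifnot(is.data.frame(assoc), all(c("BETA", "SE", "P") %in% names(assoc)))
  stopifnot(is.numeric(lambda), length(lambda) == 1, lambda > 0)
  if (lambda <= 1) return(assoc)
  assoc$SE <- assoc$SE * sqrt(lambda)
  assoc$P <- two_tailed_p(assoc$BETA, assoc$SE)
  assoc
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Combines k study estimates with weights `w_i = 1/SE_i^2`:
#' `beta = sum(w b) / sum(w)`, `SE = sum(w)^(-1/2)`, two-tailed normal P.
#' Heterogeneity is summarized by Cochran's `Q = sum(w (b_i - beta)^2)` with
#' `P_het` from the chi-square distribution on k - 1 df, and
#' `I2 = max(0, (Q - (k-1))/Q) * 100` percent (0 when k = 1).
#'
#' @param beta,se numeric vectors of study estimates and standard errors
#'   (all SE > 0).
#' @return One-row data.frame with `BETA, SE, P, K, Q, P_HET, I2`.
#' @export
inverse_variance_meta <- function(beta, se) {
  beta <- as.numeric(beta)
  se <- as.numeric(se)
  stopifnot(length(beta) == length(se))
  if (length(beta) == 0) stop_invalid("need at least one estimate")
  if (any(is.na(beta) | is.na(se))) stop_invalid("estimates must be non-missing")
  if (any(se <= 0)) stop_invalid("all SE must be > 0")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- sqrt(1 / sum(w))
  k <- length(beta)
  q <- sum(w * (beta - b)^2)
  p_het <- if (k >= 2) stats::pchisq(q, df = k - 1, lower.tail = FALSE) else NA_real_
  i2 <- if (k == 1 || q == 0) 0 else max(0, (q - (k - 1)) / q) * 100
  data.frame(BETA = b, SE = s, P = two_tailed_p(b, s),
             K = k, Q = q, P_HET = p_het, I2 = i2)
}

#' Meta-analyze per-study association tables
#'
#' Inverse-variance combination SNP by SNP across studies.  Input tables are
#' assumed allele-harmonized (same effect allele per SNP across studies; see
#' [harmonize_summary_stats()]).  SNPs present in a single study are passed
#' through with `K = 1`.
#'
#' @param studies list of association data.frames (`SNP, CHR, POS, EA, OA,
#'   EAF, BETA, SE, P, N`).
#' @return data.frame with the combined `BETA, SE, P`, heterogeneity columns
#'   `Q, P_HET, I2`, the number of studies `K`, and `N_TOTAL`.
#' @export
meta_analyze <- function(studies) {
  stopifnot(is.list(studies), length(studies) >= 1)
  all_df <- data.table::rbindlist(lapply(studies, data.table::as.data.table),
                                  use.names = TRUE, fill = TRUE)
  if (any(all_df$SE <= 0, na.rm = TRUE)) stop_invalid("all SE must be > 0")
  SNP <- BETA <- SE <- EAF <- N <- NULL  # data.table NSE
  res <- all_df[, {
    w <- 1 / SE^2
    b <- sum(w * BETA) / sum(w)
    s <- sqrt(1 / sum(w))
    k <- .N
    q <- sum(w * (BETA - b)^2)
    list(CHR = .SD$CHR[1], POS = .SD$POS[1], EA = .SD$EA[1], OA = .SD$OA[1],
         EAF = sum(EAF * N) / sum(N),
         BETA = b, SE = s, P = 2 * stats::pnorm(-abs(b / s)),
         K = k, Q = q,
         P_HET = if (k >= 2) stats::pchisq(q, df = k - 1, lower.tail = FALSE) else NA_real_,
         I2 = if (k == 1 || q == 0) 0 else max(0, (q - (k - 1)) / q) * 100,
         N = sum(N),        # total, repeated as N_TOTAL for clarity
         N_TOTAL = sum(N))
  }, by = SNP]
  out <- as.data.frame(res)
  out[order(match(out$SNP, unique(all_df$SNP))), , drop = FALSE]
}

#' Quantile-quantile data with empirical confidence bands
#'
#' Expected quantiles are `-log10` of uniform order-statistic plotting
#' positions `(i - 0.5)/n`; the band is the pointwise 5th/95th percentile
#' envelope (for `band = 0.9`) of each order statistic across
#' `n_permutations` simulated uniform P-value sets of the same size.
#'
#' @param p_values observed two-tailed P-values (at least 10).
#' @param n_permutations number of simulated uniform sets (at least 20; the
#'   band is unreliable below that).
#' @param band central band mass (default 0.90).
#' @param seed integer seed for the permutation draws.
#' @return data.frame with one row per order statistic (largest `-log10 P`
#'   first): `expected`, `observed`, `lower`, `upper`.
#' @export
qq_with_bands <- function(p_values, n_permutations = 200, band = 0.9, seed = NULL) {
  p <- as.numeric(p_values)
  p <- p[!is.na(p)]
  n <- length(p)
  if (n < 10) stop_invalid("need at least 10 P-values")
  if (n_permutations < 20) stop_invalid("n_permutations must be at least 20")
  stopifnot(band > 0, band < 1)
  obs <- -log10(sort(p))
  expd <- -log10((seq_len(n) - 0.5) / n)
  sims <- with_seed(seed, {
    m <- matrix(stats::runif(n * n_permutations), nrow = n_permutations)
    t(apply(m, 1, function(r) -log10(sort(r))))
  })
  alpha <- (1 - band) / 2
  lower <- apply(sims, 2, stats::quantile, probs = alpha)
  upper <- apply(sims, 2, stats::quantile, probs = 1 - alpha)
  data.frame(expected = expd, observed = obs, lower = lower, upper = upper,
             row.names = NULL)
}
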