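#' Simulate a pair of diverged phased haplotype panels
#'
#' Generates two reference panels (`source` = European-like, `target` =
#' African-like) over a shared variant list, emulating the salient features
#' of HapMap-style phased data: divergent allele frequencies between the two
#' populations and block-structured linkage disequilibrium.
#'
#' The chromosome is partitioned into blocks with exponentially distributed
#' lengths (mean `block_length_mean`).  Each block draws an ancestral allele
#' frequency uniformly from `ancestral_freq_range`; each population then
#' draws per-variant frequencies from the Balding-Nichols Beta distribution
#' `Beta(p(1-F')/F', (1-p)(1-F')/F')`.  Because both populations diverge
#' independently from the shared ancestor, the Beta parameter is calibrated
#' as `F' = 2F/(1+F)` so that the *pairwise* expected Fst between the two
#' panels equals `divergence_F`.
#'
#' Within each block, every population builds a small set of founder
#' haplotypes (default 8) nested by allele count, and panel haplotypes copy
#' a uniformly chosen founder per block: allele frequencies track the
#' Balding-Nichols draws while within-block r-squared is high and
#' between-block r-squared is at sampling-noise level.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed (defaults to `config$seed`); the same seed
#'   reproduces the panels exactly.
#'
#' @return A list with elements `source` and `target`, each a
#'   [haplotype_panel()] sharing the same variant table (including a `block`
#'   column with the true block labels).
#' @export
simulate_panels <- function(config, seed = config$seed) {
  validate_simulation_config(config)
  with_seed(seed, {
    n_var <- config$n_variants
    span <- config$chrom_length
    pos <- sort(sample.int(span, n_var, replace = FALSE))

    # Block boundaries: exponential lengths along the chromosome.
    n_guess <- ceiling(span / config$block_length_mean * 3) + 10L
    bounds <- cumsum(stats::rexp(n_guess, rate = 1 / config$block_length_mean))
    while (bounds[length(bounds)] <= span) {
      bounds <- c(bounds, bounds[length(bounds)] +
                    cumsum(stats::rexp(10L, rate = 1 / config$block_length_mean)))
    }
    block <- findInterval(pos, bounds) + 1L
    block <- match(block, sort(unique(block)))  # compact labels 1..n_blocks
    n_blocks <- max(block)

    p_anc_block <- stats::runif(n_blocks, config$ancestral_freq_range[1],
                                config$ancestral_freq_range[2])
    p_anc <- p_anc_block[block]

    # Pairwise-Fst calibration (see Details).
    f_bn <- 2 * config$divergence_F / (1 + config$divergence_F)
    shape_scale <- (1 - f_bn) / f_bn

    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_var, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    variants <- data.frame(
      chrom = config$chrom, pos = pos,
      id = sprintf("snp%05d", seq_len(n_var)),
      ref = ref, alt = unname(alt), block = block,
      stringsAsFactors = FALSE
    )

    m <- config$founders_per_block
    n_hap <- config$n_haplotypes
    draw_population <- function(pop_label) {
      q <- stats::rbeta(n_var, p_anc * shape_scale, (1 - p_anc) * shape_scale)
      k <- pmin(pmax(round(m * q), 0L), m)  # founders 1..k carry the alt allele
      founder_of_hap <- matrix(sample.int(m, n_blocks * n_hap, replace = TRUE),
                               nrow = n_blocks, ncol = n_hap)
      hap <- founder_of_hap[block, , drop = FALSE] <= k
      storage.mode(hap) <- "integer"
      haplotype_panel(variants, hap, population = pop_label)
    }

    list(source = draw_population("EUR"), target = draw_population("AFR"))
  })
}

#' Multi-locus realized Fst between two panels
#'
#' Combines per-variant heterozygosity components as a ratio of sums (the
#' standard multi-locus estimator): `sum(H_T - H_S) / sum(H_T)` over all
#' variants with `H_T > 0`, using equal population weights as in
#' [fst_two_pop()].
#'
#' @param panel_a,panel_b two [haplotype_panel()]s over the same variants.
#' @return A single realized Fst value.
#' @export
realized_fst <- function(panel_a, panel_b) {
  stopifnot(inherits(panel_a, "haplotype_panel"), inherits(panel_b, "haplotype_panel"))
  if (!identical(panel_a$variants$id, panel_b$variants$id)) {
    stop_invalid("panels must share the same variant list")
  }
  p1 <- alt_freq(panel_a)
  p2 <- alt_freq(panel_b)
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  keep <- ht > 0
  sum(ht[keep] - hs[keep]) / sum(ht[keep])
}
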