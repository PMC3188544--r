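# Fixture builders and independent oracles shared across test files.

# Build a haplotype_panel from a variants x haplotypes 0/1 matrix.
make_panel <- function(mat, pos = NULL, chrom = "1", population = "pop",
                       ids = NULL, block = NULL) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  ids <- ids %||% sprintf("s%03d", seq_len(n))
  pos <- pos %||% (seq_len(n) * 1000L)
  v <- data.frame(chrom = chrom, pos = as.integer(pos), id = ids,
                  ref = rep("A", n), alt = rep("G", n),
                  stringsAsFactors = FALSE)
  if (!is.null(block)) v$block <- block
  haplotype_panel(v, mat, population = population)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Random polymorphic panel for property tests: independent Bernoulli columns.
random_panel <- function(n_var, n_hap, seed, population = "pop") {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    repeat {
      mat <- matrix(rbinom(n_var * n_hap, 1L, runif(n_var, 0.2, 0.8)), n_var, n_hap)
      f <- rowMeans(mat)
      if (all(f > 0 & f < 1)) break
    }
    make_panel(mat, population = population)
  })
}

# Brute-force LD oracle: direct haplotype counting, no shared code with the
# implementation.
bf_ld <- function(xa, xb) {
  n <- length(xa)
  p_a <- sum(xa == 1) / n
  p_b <- sum(xb == 1) / n
  p_ab <- sum(xa == 1 & xb == 1) / n
  D <- p_ab - p_a * p_b
  list(D = D, r2 = D^2 / (p_a * (1 - p_a) * p_b * (1 - p_b)))
}

# Brute-force greedy binning for a given processing order (independent
# re-implementation used as the order-enumeration oracle).
bf_bins <- function(order_snps, r2mat, r2_bin) {
  queue <- order_snps
  bins <- list()
  while (length(queue) > 0) {
    idx <- queue[1]
    rest <- queue[-1]
    absorb <- rest[r2mat[idx, rest] >= r2_bin]
    bins[[length(bins) + 1]] <- list(index = idx, members = c(idx, absorb))
    queue <- setdiff(rest, absorb)
  }
  bins
}

# All permutations of a small vector (for exhaustive order enumeration).
all_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in all_perms(x[-i])) out[[length(out) + 1]] <- c(x[i], p)
  }
  out
}
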