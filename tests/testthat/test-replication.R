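# One-tailed conversion, binning, matched null sets, empirical P,
# fine-mapping, and the orchestrated replication run.

test_that("one_tailed halves or complements the two-tailed P", {
  expect_equal(one_tailed(0.05, "+", "+"), 0.025)
  expect_equal(one_tailed(0.05, "-", "+"), 0.975)
  expect_equal(one_tailed(1.0, "+", "-"), 0.5)
  expect_equal(one_tailed(1.0, "-", "-"), 0.5)
  expect_equal(one_tailed(0.2, 0, "+"), 0.5)        # zero effect
  expect_equal(one_tailed(0.05, -0.02, -1), 0.025)  # numeric signs
  expect_equal(one_tailed(c(0.05, 0.2), c(1, -1), c(1, 1)), c(0.025, 0.9))
  expect_error(one_tailed(0, "+", "+"), "0, 1")
})

test_that("build_bins partitions the proxy list deterministically", {
  # Fully unlinked: every SNP its own bin; fully linked: one bin.
  snps <- c("a", "b", "c", "d")
  low <- matrix(0.1, 4, 4, dimnames = list(snps, snps)); diag(low) <- 1
  high <- matrix(0.9, 4, 4, dimnames = list(snps, snps)); diag(high) <- 1
  expect_length(build_bins(snps, low, seed = 1), 4)
  expect_length(build_bins(snps, high, seed = 1), 1)

  # Determinism under a fixed seed.
  set.seed(42)
  r <- matrix(runif(64), 8, 8)
  r <- (r + t(r)) / 2; diag(r) <- 1
  ids <- letters[1:8]
  dimnames(r) <- list(ids, ids)
  b1 <- build_bins(ids, r, seed = 9)
  b2 <- build_bins(ids, r, seed = 9)
  expect_identical(b1, b2)

  # Partition property across seeds.
  for (s in 1:20) {
    bins <- build_bins(ids, r, seed = s)
    members <- unlist(lapply(bins, `[[`, "members"))
    expect_setequal(members, ids)
    expect_equal(anyDuplicated(members), 0L)
  }
})

test_that("bin counts on the LD chain match exhaustive order enumeration", {
  # Chain: A-B r2 = 0.5, B-C r2 = 0.5, A-C r2 = 0.1.
  snps <- c("A", "B", "C")
  r <- matrix(c(1, 0.5, 0.1,
                0.5, 1, 0.5,
                0.1, 0.5, 1), 3, 3, dimnames = list(snps, snps))
  for (perm in all_perms(snps)) {
    got <- build_bins(perm, r, r2_bin = 0.3, order_by = seq_along(perm))
    want <- bf_bins(perm, r, 0.3)
    expect_equal(length(got), length(want))
    expect_equal(lapply(got, `[[`, "index"), lapply(want, `[[`, "index"))
    # B drawn first absorbs both ends; otherwise two bins.
    expect_equal(length(got), if (perm[1] == "B") 1L else 2L)
  }

  # Random fixtures: implementation equals the independent oracle for every
  # processing order.
  set.seed(7)
  ids <- letters[1:5]
  for (rep in 1:5) {
    r <- matrix(runif(25), 5, 5); r <- (r + t(r)) / 2; diag(r) <- 1
    dimnames(r) <- list(ids, ids)
    for (perm in all_perms(ids)) {
      got <- build_bins(perm, r, r2_bin = 0.4, order_by = seq_along(perm))
      want <- bf_bins(perm, r, 0.4)
      expect_equal(lapply(got, `[[`, "members"), lapply(want, `[[`, "members"))
    }
  }
})

test_that("count_significant_bins counts index-SNP one-tailed P <= alpha", {
  mk_bin <- function(index, members = index) list(index = index, members = members)
  p <- c(a = 1.0, b = 1.0, c = 0.04, d = 0.05, e = 0.2, f = 0.001)

  # All index P = 1: nothing significant.
  bins0 <- list(mk_bin("a"), mk_bin("b"))
  expect_equal(count_significant_bins(bins0, p)$total, 0)

  # Hand-enumerated multi-locus fixture (alpha = 0.05, <= comparison).
  loci <- list(l1 = list(mk_bin("c"), mk_bin("a")),
               l2 = list(mk_bin("d")),
               l3 = list(mk_bin("e"), mk_bin("f"), mk_bin("b")))
  got <- count_significant_bins(loci, p)
  expect_equal(unname(got$per_locus), c(1, 1, 1))
  expect_equal(got$total, 3)

  # Bin order and locus order do not change the total.
  loci_perm <- rev(lapply(loci, rev))
  expect_equal(count_significant_bins(loci_perm, p)$total, 3)

  # Missing index P: excluded with a warning.
  expect_warning(got2 <- count_significant_bins(list(mk_bin("zz"), mk_bin("c")), p),
                 "without a P-value")
  expect_equal(got2$total, 1)
})

test_that("matched null sets honor MAF tolerance and mutual independence", {
  cfg <- simulation_config(n_variants = 600, n_haplotypes = 120, seed = 17)
  panels <- simulate_panels(cfg)
  src <- panels$source
  maf <- panel_maf(src)
  usable <- names(maf)[maf >= 0.05]
  idx <- usable[seq(1, length(usable), length.out = 20)]
  pool <- data.frame(snp = setdiff(usable, idx),
                     maf = unname(maf[setdiff(usable, idx)]))
  sets <- generate_matched_sets(maf[idx], pool, src, n_sets = 30,
                                maf_tol = 0.02, seed = 3)
  expect_length(sets$sets, 30)
  hap <- src$haplotypes
  for (s in sets$sets) {
    expect_length(s, 20)
    expect_equal(anyDuplicated(s), 0L)
    # MAF tolerance, per locus, at the (possibly widened) tolerance used.
    expect_true(all(abs(pool$maf[match(s, pool$snp)] - maf[idx]) <=
                      sets$tolerance + 1e-12))
  }
  # Full pairwise independence audit on a subsample of sets.
  for (s in sets$sets[1:5]) {
    r2 <- suppressWarnings(cor(t(hap[s, ])))^2
    diag(r2) <- 0
    expect_true(all(r2 < 0.2, na.rm = TRUE))
  }
  # Matching quality: pooled member MAFs are indistinguishable from the
  # index MAF distribution.
  pooled <- pool$maf[match(unlist(sets$sets), pool$snp)]
  ks <- suppressWarnings(ks.test(pooled, rep(unname(maf[idx]), 30)))
  expect_gt(ks$p.value, 0.01)

  # Determinism.
  sets2 <- generate_matched_sets(maf[idx], pool, src, n_sets = 30,
                                 maf_tol = 0.02, seed = 3)
  expect_identical(sets$sets, sets2$sets)
})

test_that("a pool made of the loci themselves returns permutations of the loci", {
  idx_maf <- c(a = 0.10, b = 0.20, c = 0.30, d = 0.45)
  pool <- data.frame(snp = names(idx_maf), maf = unname(idx_maf))
  r2 <- diag(4) * 0  # no LD among them
  dimnames(r2) <- list(names(idx_maf), names(idx_maf))
  sets <- suppressWarnings(generate_matched_sets(idx_maf, pool, r2, n_sets = 10,
                                                 maf_tol = 0.02, seed = 5))
  for (s in sets$sets) expect_setequal(s, names(idx_maf))

  # Impossible matching errors out, naming the locus.
  pool_far <- data.frame(snp = c("x", "y"), maf = c(0.45, 0.5))
  expect_error(
    suppressWarnings(generate_matched_sets(c(q = 0.05), pool_far, r2[1:2, 1:2],
                                           n_sets = 5)),
    "matching impossible")
})

test_that("empirical_p reproduces the reference numerators", {
  # 1 of 5,819 null sets at or above the observed count.
  nulls <- c(rep(10, 5818), 200)
  ep <- empirical_p(171, nulls)
  expect_equal(ep$k, 1)
  expect_equal(signif(ep$p, 2), 1.7e-4)

  # Observed below every null count.
  expect_equal(empirical_p(1, rep(5, 10))$p, 1)

  # No null reaches the observed value: reported as a bound.
  ep0 <- empirical_p(50, rep(3, 100))
  expect_true(ep0$less_than)
  expect_equal(ep0$p, 0)
  expect_match(ep0$label, "< 0.01")
})

test_that("fine-mapping selects the smallest-P representative after binning", {
  p <- c(a = 0.5)
  expect_equal(fine_map_best("a", p, ld = matrix(1, 1, 1, dimnames = list("a", "a")))$best_snp,
               "a")

  # A proxy with a smaller P than the original index SNP wins.
  snps <- c("index_eur", "proxy_afr")
  r2 <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(snps, snps))
  p2 <- c(index_eur = 0.0025, proxy_afr = 2.9e-7)
  fm <- fine_map_best(snps, p2, r2, bonferroni_n = 161)
  expect_equal(fm$best_snp, "proxy_afr")
  expect_equal(fm$best_p, 2.9e-7)
  expect_true(fm$passes_bonferroni)
  expect_equal(fm$bonferroni_threshold, 0.05 / 161)

  # The best P never exceeds any bin-index P from any randomized order
  # (exhaustive enumeration on small loci).
  set.seed(8)
  ids <- letters[1:6]
  for (rep in 1:4) {
    r <- matrix(runif(36), 6, 6); r <- (r + t(r)) / 2; diag(r) <- 1
    dimnames(r) <- list(ids, ids)
    pv <- setNames(runif(6), ids)
    fm <- fine_map_best(ids, pv, r, r2_bin = 0.4)
    for (perm in all_perms(ids)) {
      bins <- build_bins(perm, r, r2_bin = 0.4, order_by = seq_along(perm))
      idx_p <- pv[vapply(bins, `[[`, character(1), "index")]
      expect_lte(fm$best_p, min(idx_p))
    }
  }

  # Ties in P break by genomic position.
  pos <- c(x = 500, y = 100)
  r2t <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("x", "y"), c("x", "y")))
  fmt <- fine_map_best(c("x", "y"), c(x = 0.01, y = 0.01), r2t, pos = pos)
  expect_equal(fmt$best_snp, "y")
})

test_that("run_replication handles the degenerate and null cases", {
  empty <- run_replication(data.frame(snp = character(0),
                                      increasing_allele = character(0)),
                           NULL, NULL, data.frame(SNP = character(0),
                                                  BETA = numeric(0), P = numeric(0)))
  expect_s3_class(empty, "replication_report")
  expect_equal(empty$observed_total, 0)
  expect_equal(nrow(empty$per_locus), 0)

  # Under the global null the observed count is exchangeable with the null
  # counts: compare their distributions across replicate pipelines.
  obs_counts <- numeric(40)
  one_null_count <- numeric(40)
  for (r in 1:40) {
    cfg <- simulation_config(n_variants = 900, n_haplotypes = 120,
                             variant_spacing = 2000, seed = 4000 + r)
    panels <- simulate_panels(cfg)
    maf <- panel_maf(panels$source)
    ok <- names(maf)[maf >= 0.05 & panel_maf(panels$target) > 0]
    blk <- setNames(panels$source$variants$block, panels$source$variants$id)
    set.seed(5000 + r)
    idx <- sample(ok[!duplicated(blk[ok])], 30)
    index_snps <- data.frame(snp = idx,
                             increasing_allele = sample(c("ref", "alt"), 30, TRUE))
    meta <- simulate_summary_stats(panels$target, n_eff = 20000, seed = 6000 + r)
    rep_out <- suppressWarnings(suppressMessages(
      run_replication(index_snps, panels$source, panels$target, meta,
                      n_sets = 15, window = 1e5, seed = 7000 + r)))
    obs_counts[r] <- rep_out$observed_total
    one_null_count[r] <- rep_out$null_counts[1]
    expect_true(all(rep_out$null_counts >= 0))
    expect_gte(rep_out$empirical$p, 0)
    expect_lte(rep_out$empirical$p, 1)
  }
  ks <- suppressWarnings(ks.test(obs_counts, one_null_count))
  expect_gt(ks$p.value, 0.01)
})
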