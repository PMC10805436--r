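test_that("Tajima's D handles undefined cases and matches the pairwise oracle", {
  # S = 0 windows are flagged undefined, not an error
  expect_true(is.na(tajimas_d_counts(integer(0), 10)$D))
  expect_true(is.na(tajimas_d_counts(c(0, 10), 10)$D))
  # n = 2 collapses the variance constants to zero
  cst <- tajima_constants(2)
  expect_equal(cst$c1, 0)
  expect_equal(cst$c2, 0)
  expect_true(is.na(tajimas_d_counts(c(1, 1, 1), 2)$D))

  # fixed n=10, 5-segregating-site fixture against the brute-force oracle
  set.seed(101)
  haps <- matrix(rbinom(50, 1, 0.4), nrow = 10)
  o <- oracle_tajimas_d(haps)
  f <- tajimas_d_counts(colSums(haps), 10)
  expect_equal(f$D, o$D, tolerance = 1e-12)
})

test_that("Tajima's D agrees with the brute-force oracle on 200 random panels", {
  set.seed(202)
  for (i in 1:200) {
    n <- sample(3:25, 1)
    m <- sample(1:40, 1)
    freq <- runif(m, 0.05, 0.95)
    haps <- matrix(rbinom(n * m, 1, rep(freq, each = n)), nrow = n)
    o <- oracle_tajimas_d(haps)
    f <- tajimas_d_counts(colSums(haps), n)
    expect_equal(f$S, o$S)
    if (is.na(o$D)) expect_true(is.na(f$D))
    else expect_equal(f$D, o$D, tolerance = 1e-9)
  }
})

test_that("window scan tiles the region and applies the missingness rule", {
  bn <- sim_balding_nichols(0.05, n_pops = 1, n_diploids = 20, n_sites = 30,
                            seed = 5)
  g <- bn$genotypes  # positions 100..3000
  w <- scan_tajima_windows(g, "1", 0, 3500, width = 1000)
  expect_equal(nrow(w), 4)                       # last window truncated
  expect_equal(w$end, c(1000, 2000, 3000, 3500))
  # per-window S matches a manual segregating count
  for (i in 1:4) {
    in_w <- g$sites$pos - 1 >= w$start[i] & g$sites$pos - 1 < w$end[i]
    k <- colSums(g$dosages[, in_w, drop = FALSE])
    expect_equal(w$n_snps[i], sum(k > 0 & k < 40))
  }
  # a window with all genotypes missing is excluded
  g$dosages[, g$sites$pos <= 1000] <- NA
  w2 <- scan_tajima_windows(g, "1", 0, 3500, width = 1000)
  expect_true(w2$excluded[1])
  expect_false(any(w2$excluded[-1]))
})

test_that("empirical null percentiles follow the linear-interpolation convention", {
  null <- empirical_null(1:40)
  expect_equal(null$lower, 1.975)
  expect_equal(null$upper, 39.025)
  # constant null collapses both bounds
  nc <- empirical_null(rep(3.2, 50))
  expect_equal(nc$lower, 3.2)
  expect_equal(nc$upper, 3.2)
  # undefined entries are skipped, too few values error
  expect_equal(empirical_null(c(1:40, NA, NA))$lower, 1.975)
  expect_error(empirical_null(1:39), "at least 40")
})

test_that("window classification uses strict inequalities and per-gene proportions", {
  null <- empirical_null(1:40)   # bounds 1.975 / 39.025
  w <- data.frame(chrom = "1", start = c(0, 1000, 2000, 3000),
                  end = c(1000, 2000, 3000, 4000),
                  D = c(1.0, 39.025, 39.5, NA), excluded = FALSE)
  cls <- classify_windows(w, null)
  expect_equal(cls$flag, c("low", "ns", "high", "ns"))  # exact tie -> ns
  gene <- region_table("G1", "1", 0, 4000)
  sm <- gene_window_summary(cls, gene)
  expect_equal(sm$n_windows, 4)
  expect_equal(sm$prop_low, 0.25)
  expect_equal(sm$prop_high, 0.25)
})

test_that("WC FST handles fixed differences, monomorphic sites, and matches the ANOVA oracle", {
  # two populations fixed for opposite alleles: fst = 1
  f <- wc_fst_site(c(20, 20), c(0, 40), c(0, 0))
  expect_equal(f$fst, 1)
  expect_equal(f$b, 0)
  expect_equal(f$c, 0)
  # identical monomorphic populations: undefined
  expect_true(is.na(wc_fst_site(c(20, 20), c(0, 0), c(0, 0))$fst))
  # Hardy-Weinberg 0.3 vs 0.7 fixture vs the independent ANOVA transcription
  d1 <- c(rep(0, round(20 * 0.49)), rep(1, round(20 * 0.42)), rep(2, round(20 * 0.09)))
  d2 <- 2 - d1
  o <- oracle_wc_fst(list(d1, d2))
  f2 <- wc_fst_site(c(20, 20), c(sum(d1), sum(d2)),
                    c(sum(d1 == 1), sum(d2 == 1)))
  expect_equal(f2$fst, o$fst, tolerance = 1e-12)

  # 200 random instances against the oracle
  set.seed(303)
  for (i in 1:200) {
    r <- sample(2:5, 1)
    dl <- lapply(seq_len(r), function(k)
      rbinom(sample(5:40, 1), 2, runif(1, 0.05, 0.95)))
    o <- oracle_wc_fst(dl)
    f <- wc_fst_site(vapply(dl, length, 1), vapply(dl, sum, 1),
                     vapply(dl, function(d) sum(d == 1), 1))
    for (cmp in c("a", "b", "c"))
      expect_equal(f[[cmp]], o[[cmp]], tolerance = 1e-10)
    if (is.na(o$fst)) expect_true(is.na(f$fst))
    else expect_equal(f$fst, o$fst, tolerance = 1e-10)
  }
})

test_that("FST is invariant to swapping ref/alt labels", {
  set.seed(7)
  for (i in 1:50) {
    n <- c(15, 25, 30)
    dl <- lapply(n, function(k) rbinom(k, 2, runif(1, 0.1, 0.9)))
    alt <- vapply(dl, sum, 1); het <- vapply(dl, function(d) sum(d == 1), 1)
    f1 <- wc_fst_site(n, alt, het)
    f2 <- wc_fst_site(n, 2 * n - alt, het)   # relabel: alt count complements
    expect_equal(f1$fst, f2$fst, tolerance = 1e-12)
  }
})

test_that("per-gene means are raw arithmetic means of defined values", {
  gene <- region_table("G", "1", 100, 400)
  gm <- gene_mean(c(0.1, -0.1, NA, 0.5), c(150L, 250L, 350L, 450L), gene)
  expect_equal(gm$mean, 0.0)
  expect_equal(gm$n, 2)
  expect_equal(gene_mean(0.4, 101L, gene)$mean, 0.4)
  expect_true(is.na(gene_mean(NA_real_, 150L, gene)$mean))
})
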