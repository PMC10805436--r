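make_panel <- function(haps, spacing = 100L) {
  m <- ncol(haps)
  sites <- site_table("1", seq_len(m) * spacing, rep("A", m), rep("G", m),
                      ancestral = rep("ref", m))
  haplotype_panel(sites, haps, coding = "derived")
}

flat_map <- function(max_bp, cm_per_mb = 1) {
  genetic_map("1", c(1, max_bp), c(0, (max_bp - 1) * cm_per_mb / 100 / 1e4))
}

test_that("EHH starts at 1, follows the carrier-pair definition, and is monotone", {
  # 4 derived carriers split 2/2 at the first site to the right:
  # EHH = (C(2,2)+C(2,2)) / C(4,2) = 1/3
  haps <- rbind(c(1, 0, 0), c(1, 0, 1), c(1, 1, 0), c(1, 1, 1),
                c(0, 0, 0), c(0, 0, 0))
  panel <- make_panel(haps)
  e <- ehh(panel, core = 1, allele = 1, side = "right")
  expect_equal(e$ehh[1], 1)
  expect_equal(e$ehh[2], 1 / 3)
  # all carriers identical over a side: EHH stays 1
  haps2 <- rbind(c(1, 1, 0), c(1, 1, 0), c(1, 1, 0), c(0, 0, 1), c(0, 1, 0))
  e2 <- ehh(make_panel(haps2), core = 1, allele = 1, side = "right")
  expect_equal(e2$ehh, c(1, 1, 1))
  # core at the panel edge: the curve is just the core itself
  expect_equal(nrow(ehh(make_panel(haps2), 1, allele = 1, side = "left")), 1)
  expect_error(ehh(make_panel(rbind(c(1, 0), c(0, 0), c(0, 1))), 1, 1, "right"),
               "carriers")
})

test_that("EHH curves are non-increasing and within [0,1] on random panels", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(6:20, 1); m <- sample(5:30, 1)
    haps <- matrix(rbinom(n * m, 1, 0.5), nrow = n)
    core <- sample(2:(m - 1), 1)
    for (al in 0:1) {
      if (min(sum(haps[, core] == al)) < 2) next
      for (sd in c("left", "right")) {
        e <- ehh(make_panel(haps), core, al, sd)
        expect_true(all(diff(e$ehh) <= 1e-12))
        expect_true(all(e$ehh >= 0 & e$ehh <= 1))
      }
    }
  }
})

test_that("iHS skips low-MAF and edge cores and is antisymmetric in allele labels", {
  sw <- sim_sweep_panel(n_chrom = 80, n_sites = 81, q = 0.4,
                        founder_fidelity = 0.9, seed = 21)
  sc <- ihs_core(sw$panel, sw$map, sw$core)
  expect_equal(sc$status, "ok")
  expect_lt(sc$ihs_raw, 0)   # selection on the derived allele

  # swapping ancestral/derived at every site negates ihs_raw
  flipped <- sw$panel
  flipped$haplotypes <- 1L - flipped$haplotypes
  flipped <- haplotype_panel(flipped$sites, flipped$haplotypes, "derived")
  sc2 <- ihs_core(flipped, sw$map, sw$core)
  expect_equal(sc2$ihs_raw, -sc$ihs_raw, tolerance = 1e-12)

  # MAF floor
  low <- sw$panel
  low$haplotypes[, sw$core] <- c(1L, 1L, rep(0L, 78))
  low <- haplotype_panel(low$sites, low$haplotypes, "derived")
  expect_equal(ihs_core(low, sw$map, sw$core)$status, "maf")

  # perfect founder fidelity: derived EHH never decays -> edge skip
  per <- sim_sweep_panel(n_chrom = 80, n_sites = 81, q = 0.4,
                         founder_fidelity = 1, seed = 22)
  expect_equal(ihs_core(per$panel, per$map, per$core)$status, "edge")
})

test_that("iHS standardization gives mean 0 / sd 1 within occupied bins", {
  set.seed(33)
  scores <- data.frame(
    pos = 1:600, derived_freq = runif(600, 0.05, 0.95),
    ihh_a = 1, ihh_d = 1, ihs_raw = rnorm(600, -0.2, 0.8), status = "ok")
  std <- standardize_ihs(scores, n_bins = 10, min_per_bin = 20)
  for (b in unique(std$freq_bin)) {
    v <- std$ihs_std[std$freq_bin == b]
    expect_equal(mean(v), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean((v - mean(v))^2)), 1, tolerance = 1e-9)
    expect_gte(length(v), 20)            # merged bins respect the minimum
  }
  # single-bin toy: raw {-1, 1} standardizes to itself (mean 0, sd 1)
  toy <- data.frame(pos = 1:2, derived_freq = c(0.4, 0.6), ihh_a = 1,
                    ihh_d = 1, ihs_raw = c(-1, 1), status = "ok")
  stdt <- standardize_ihs(toy, n_bins = 1, min_per_bin = 1)
  expect_equal(stdt$ihs_std, c(-1, 1), tolerance = 1e-12)
})

test_that("beta score follows the folded similarity-weight formulas", {
  # n = 10, core folded 0.4, window folded {0.4, 0.1, 0.3}: frozen oracle value
  haps <- matrix(0L, nrow = 10, ncol = 4)
  haps[1:4, 1] <- 1L   # core, f = 0.4
  haps[1:4, 2] <- 1L   # f = 0.4
  haps[1:1, 3] <- 1L   # f = 0.1
  haps[1:3, 4] <- 1L   # f = 0.3
  panel <- make_panel(haps)
  b <- beta_score(panel, core = 1, half_width = 1000, p = 2)
  o <- oracle_beta(c(0.4, 0.1, 0.3), 0.4, 10, p = 2)
  expect_equal(b$beta, o$beta, tolerance = 1e-12)
  expect_equal(b$beta, 0.3770055, tolerance = 1e-6)  # frozen from the oracle

  # a window SNP at the core's folded frequency has weight 1:
  # adding it raises theta_beta by exactly 1/denominator
  expect_equal(b$theta_beta - beta_score(subset_sites(panel, c(TRUE, FALSE, TRUE, TRUE)),
                                         1, 1000, 2)$theta_beta,
               1 / sum((1 - abs(pmin(1:9 / 10, 1 - 1:9 / 10) - 0.4) / 0.5)^2 / 1:9),
               tolerance = 1e-12)

  # empty window: all components zero
  lone <- make_panel(matrix(c(1L, 1L, 0L, 0L), ncol = 1))
  b0 <- beta_score(lone, 1)
  expect_equal(c(b0$theta_beta, b0$theta_w, b0$beta), c(0, 0, 0))

  # monomorphic core errors
  mono <- make_panel(cbind(rep(0L, 6), c(1L, rep(0L, 5))))
  expect_error(beta_score(mono, 1), "monomorphic")
})

test_that("beta score is invariant to unfolding any window site", {
  set.seed(44)
  for (i in 1:30) {
    n <- 20; m <- 9
    haps <- matrix(rbinom(n * m, 1, runif(m, 0.1, 0.9)[rep(1:m, each = n)]),
                   nrow = n)
    if (any(colMeans(haps) %in% c(0, 1))) next
    panel <- make_panel(haps)
    core <- 5
    b1 <- beta_score(panel, core)
    j <- sample(setdiff(1:m, core), 1)
    haps2 <- haps; haps2[, j] <- 1L - haps2[, j]
    b2 <- beta_score(make_panel(haps2), core)
    expect_equal(b1$beta, b2$beta, tolerance = 1e-12)
  }
})

test_that("top-fraction flagging follows the strict quantile convention", {
  top <- empirical_top_fraction(1:200, 0.01)
  expect_equal(top$threshold, 198.01)
  expect_equal(which(top$flagged), c(199, 200))
  # all-equal scores: none flagged
  expect_equal(sum(empirical_top_fraction(rep(1, 150))$flagged), 0)
  # i.i.d. continuous scores flag at most 1%
  set.seed(55)
  tf <- empirical_top_fraction(rnorm(1000), 0.01)
  expect_lte(sum(tf$flagged), 10)
  expect_error(empirical_top_fraction(1:50), "at least 100")
})

test_that("sweep panels produce negative mean iHS at swept cores vs matched neutral cores", {
  raw_sweep <- vapply(1:60, function(s) {
    sw <- sim_sweep_panel(n_chrom = 60, n_sites = 61, q = 0.4,
                          founder_fidelity = 0.9, seed = 1000 + s)
    ihs_core(sw$panel, sw$map, sw$core)$ihs_raw
  }, numeric(1))
  ok <- !is.na(raw_sweep)
  expect_gt(mean(ok), 0.5)
  expect_lt(mean(raw_sweep[ok]), 0)
})
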