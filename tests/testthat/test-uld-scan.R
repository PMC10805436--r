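test_that("geno_r2 matches direct Pearson arithmetic and handles degeneracy", {
  expect_equal(geno_r2(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1)
  expect_equal(geno_r2(c(0, 0, 2, 2), c(0, 2, 0, 2)), 0)
  g1 <- c(0, 1, 2, 0); g2 <- c(0, 1, 2, 2)
  expect_equal(geno_r2(g1, g2), oracle_r2(g1, g2), tolerance = 1e-14)
  expect_true(is.na(geno_r2(c(1, 1, 1, 1), c(0, 1, 2, 0))))  # constant vector
  expect_true(is.na(geno_r2(c(0, 1, NA, NA), c(0, 1, 2, 0)))) # < 3 complete

  # 500 random vector pairs vs the brute-force oracle
  set.seed(99)
  for (i in 1:500) {
    n <- sample(5:60, 1)
    a <- rbinom(n, 2, runif(1, 0.1, 0.9))
    b <- rbinom(n, 2, runif(1, 0.1, 0.9))
    if (var(a) == 0 || var(b) == 0) next
    expect_equal(geno_r2(a, b), oracle_r2(a, b), tolerance = 1e-12)
  }
})

test_that("cluster pairs apply the strict MAF rule and gene labels", {
  set.seed(12)
  n <- 40
  # 5 SNPs: one at MAF exactly 0.05 (excluded), one below, three clearly above
  dos <- cbind(rbinom(n, 2, 0.5), rbinom(n, 2, 0.4), rbinom(n, 2, 0.6),
               c(rep(1, 4), rep(0, n - 4)),      # MAF = 4/80 = 0.05 exactly
               c(rep(1, 2), rep(0, n - 2)))      # MAF = 0.025
  sites <- site_table("1", c(100L, 200L, 300L, 400L, 500L),
                      rep("A", 5), rep("G", 5))
  g <- genotype_matrix(sites, dos)
  genes <- region_table(c("GA", "GB"), "1", c(0, 250), c(250, 450))
  map <- genetic_map("1", c(0, 1000), c(0, 0.1))
  pr <- cluster_pairs(g, genes, map, maf_min = 0.05)
  surv <- sort(unique(c(pr$pos_i, pr$pos_j)))
  expect_equal(surv, c(100, 200, 300))           # 0.05 is excluded (strict)
  expect_equal(nrow(pr), choose(3, 2))
  # gene membership by interval lookup: 100,200 in GA; 300 in GB
  expect_equal(pr$gene_i[pr$pos_i == 100 & pr$pos_j == 300], "GA")
  expect_equal(pr$gene_j[pr$pos_i == 100 & pr$pos_j == 300], "GB")
  # distances come from the map: 100 bp apart = 0.01 cM
  expect_equal(pr$d_cm[pr$pos_i == 100 & pr$pos_j == 200], 0.01, tolerance = 1e-9)
})

test_that("matched-window search requires exact containment and exclusion", {
  genes <- region_table(paste0("g", 1:10), "1",
                        start = c(0, 100, 220, 300, 420, 2000, 2100, 2220, 2300, 2420),
                        end   = c(80, 180, 280, 380, 480, 2080, 2180, 2280, 2380, 2480))
  # L = 500, k = 5: anchors g1 and g6 contain exactly five genes
  w <- find_matched_windows(genes, L = 500, k = 5)
  expect_equal(w$anchor, c("g1", "g6"))
  expect_equal(w$end - w$start, c(500, 500))
  expect_equal(w$n_genes, c(5, 5))
  # excluding the first cluster removes the window anchored on it
  w2 <- find_matched_windows(genes, 500, 5,
                             exclude = region_table("cl", "1", 0, 480))
  expect_equal(w2$anchor, "g6")
  # a chromosome with fewer than k genes yields nothing
  expect_equal(nrow(find_matched_windows(genes[1:3, ], 500, 5)), 0)
})

test_that("the distance-binned null follows the quantile and min-pairs rules", {
  pairs <- data.frame(r2 = seq(0.01, 1, 0.01), d_cm = rep(0.005, 100))
  null <- build_binned_null(pairs, min_pairs = 100)
  expect_equal(null$bins$threshold[null$bins$bin == 0], 0.9901)
  # bins below min_pairs carry no threshold
  pairs2 <- rbind(pairs, data.frame(r2 = runif(10), d_cm = rep(0.015, 10)))
  null2 <- build_binned_null(pairs2, min_pairs = 100)
  expect_true(is.na(null2$bins$threshold[null2$bins$bin == 1]))
  expect_error(build_binned_null(pairs[1:10, ], min_pairs = 100), "enough pairs")
})

test_that("uLD flagging is strict and leaves uncovered bins unflagged", {
  null <- structure(list(bin_width = 0.01, percentile = 0.99, min_pairs = 1,
                         bins = data.frame(bin = 0, bin_start_cm = 0,
                                           n_pairs = 100, threshold = 0.5)),
                    class = "distance_binned_null")
  pairs <- data.frame(pos_i = 1:3, pos_j = 4:6,
                      gene_i = "A", gene_j = "B",
                      r2 = c(0.5, 0.51, 0.9), d_cm = c(0.005, 0.005, 0.05))
  fl <- flag_uld(pairs, null)
  expect_equal(fl$flagged, c(FALSE, TRUE, FALSE))  # tie unflagged; bin 5 uncovered
  sm <- attr(fl, "summary")
  expect_equal(sm$n_uncovered, 1)
  expect_equal(sm$n_flagged, 1)
})

test_that("pair extraction by gene honors the endpoint mode", {
  pairs <- data.frame(pos_i = c(1, 2, 3), pos_j = c(4, 5, 6),
                      gene_i = c("X", "X", "Y"), gene_j = c("X", "Y", "Z"),
                      r2 = 0.9, d_cm = 0.001, flagged = TRUE)
  genes <- region_table(c("X", "Y", "Z"), "1", c(0, 100, 200), c(50, 150, 250))
  expect_equal(nrow(extract_pairs_by_gene(pairs, "X", genes, mode = "one")), 1)
  expect_equal(nrow(extract_pairs_by_gene(pairs, "X", genes, mode = "either")), 2)
  expect_equal(nrow(extract_pairs_by_gene(pairs, "Z", genes, mode = "one")), 1)
  expect_error(extract_pairs_by_gene(pairs, "NOPE", genes), "unknown gene")
  # no flagged pairs touching the gene -> empty
  pairs$flagged <- FALSE
  expect_equal(nrow(extract_pairs_by_gene(pairs, "X", genes, mode = "either")), 0)
})

test_that("planted epistatic pairs are flagged at >= 95%", {
  profile <- data.frame(d_cm = c(0.005, 0.015, 0.025),
                        r2_target = c(0.25, 0.15, 0.1))
  nul <- sim_ld_pairs(profile, n_pairs_per_bin = 400, n_samples = 200, seed = 71)
  planted <- data.frame(d_cm = rep(c(0.005, 0.015, 0.025), each = 20),
                        r2_target = 0.9)
  tst <- sim_ld_pairs(profile, n_pairs_per_bin = 50, planted = planted,
                      n_samples = 200, seed = 72)
  null <- build_binned_null(nul$pairs, min_pairs = 100)
  fl <- flag_uld(tst$pairs, null)
  expect_gte(mean(fl$flagged[fl$planted]), 0.95)
})
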