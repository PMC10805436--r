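test_that("instrument selection applies F, p and greedy LD pruning", {
  # F for b/se = 3.15/1 is 9.9225: dropped even with tiny p
  assoc <- data.frame(snp = paste0("s", 1:5),
                      b_x = c(3.15, 0.5, 0.45, 0.4, 0.2),
                      se_x = c(1, 0.05, 0.05, 0.05, 0.05),
                      p_x = c(1e-6, 1e-6, 1e-4, 1e-5, 0.5))
  ld <- diag(5); dimnames(ld) <- list(assoc$snp, assoc$snp)
  ld["s2", "s3"] <- ld["s3", "s2"] <- 0.9
  sel <- select_instruments(assoc, ld)
  # s1 fails F, s5 fails p, s3 pruned against the stronger s2
  expect_equal(sort(sel$snp), c("s2", "s4"))
  # pruning keeps the smaller p of a correlated pair
  ld2 <- diag(2); dimnames(ld2) <- list(c("a", "b"), c("a", "b"))
  ld2["a", "b"] <- ld2["b", "a"] <- 0.9
  assoc2 <- data.frame(snp = c("a", "b"), b_x = c(0.5, 0.5),
                       se_x = 0.05, p_x = c(1e-6, 1e-4))
  expect_equal(select_instruments(assoc2, ld2)$snp, "a")
  expect_error(select_instruments(assoc2[assoc2$p_x > 1, ], ld2), "no instruments")
})

test_that("correlated IVW matches closed forms and the GLS oracle", {
  # exact proportionality with identity correlation
  inp <- mr_input(paste0("s", 1:4), c(0.2, 0.3, 0.4, 0.5), rep(0.05, 4),
                  0.5 * c(0.2, 0.3, 0.4, 0.5), rep(0.04, 4))
  expect_equal(mr_ivw(inp)$beta, 0.5, tolerance = 1e-12)
  # single instrument: Wald ratio
  one <- mr_input("s", 0.4, 0.05, 0.12, 0.03)
  expect_equal(mr_ivw(one)$beta, 0.3, tolerance = 1e-12)
  expect_equal(mr_ivw(one)$se, 0.03 / 0.4, tolerance = 1e-12)
  # with identity rho, equals the textbook fixed-effect IVW
  set.seed(20)
  bx <- runif(6, 0.1, 0.5); by <- 0.3 * bx + rnorm(6, 0, 0.02)
  sey <- runif(6, 0.02, 0.06)
  iv <- mr_ivw(mr_input(paste0("s", 1:6), bx, 0.05, by, sey))
  w <- bx^2 / sey^2
  expect_equal(iv$beta, sum(w * (by / bx)) / sum(w), tolerance = 1e-12)
  expect_equal(iv$se, sqrt(1 / sum(w)), tolerance = 1e-12)

  # 200 random correlated instances vs the Cholesky-decorrelation oracle
  set.seed(21)
  for (i in 1:200) {
    J <- sample(3:10, 1)
    r <- runif(1, 0, 0.5)
    rho <- r + (1 - r) * diag(J)
    bx <- runif(J, 0.1, 0.6)
    sey <- runif(J, 0.02, 0.08)
    by <- 0.4 * bx + rnorm(J, 0, 0.05)
    inp <- mr_input(paste0("s", 1:J), bx, 0.05, by, sey, rho)
    o <- oracle_gls(bx, by, sey, rho)
    iv <- mr_ivw(inp)
    expect_equal(iv$beta, o$coef, tolerance = 1e-10)
    expect_equal(iv$se, o$se, tolerance = 1e-10)
    # Egger on the same instance (bx > 0 so no orientation flip)
    oe <- oracle_gls(bx, by, sey, rho, intercept = TRUE)
    eg <- mr_egger(inp)
    expect_equal(eg$egger_intercept, oe$coef[1], tolerance = 1e-10)
    expect_equal(eg$beta, oe$coef[2], tolerance = 1e-10)
    expect_equal(eg$se, oe$se[2], tolerance = 1e-10)
  }
  expect_equal(mr_ivw(inp)$ci95, mr_ivw(inp)$beta + c(-1.96, 1.96) * mr_ivw(inp)$se)
})

test_that("MR-Egger recovers an exact affine relation and needs 3 instruments", {
  bx <- c(0.1, 0.25, 0.4, 0.6)
  inp <- mr_input(paste0("s", 1:4), bx, 0.05, 0.2 + 0.5 * bx, 0.04)
  eg <- mr_egger(inp)
  expect_equal(eg$egger_intercept, 0.2, tolerance = 1e-10)
  expect_equal(eg$beta, 0.5, tolerance = 1e-10)
  expect_true(eg$pleiotropy_flag)
  expect_error(mr_egger(mr_input(c("a", "b"), c(0.2, 0.3), 0.05,
                                 c(0.1, 0.2), 0.04)), "at least 3")
})

test_that("Egger intercept test is calibrated without pleiotropy and powered with it", {
  # calibration: ~5% false rejections over 50 null replicates
  rej <- vapply(1:50, function(s) {
    d <- sim_mr_dataset(10, 0.3, pleiotropy_intercept = 0, seed = 3000 + s)
    mr_egger(d$input)$intercept_p < 0.05
  }, logical(1))
  expect_lte(sum(rej), 8)
  # power: planted intercept 0.3 rejected at rate >= 0.8 (20 instruments)
  rej2 <- vapply(1:100, function(s) {
    d <- sim_mr_dataset(20, 0.3, pleiotropy_intercept = 0.3, seed = 4000 + s)
    mr_egger(d$input)$intercept_p < 0.05
  }, logical(1))
  expect_gte(mean(rej2), 0.8)
})

test_that("weighted median follows the cumulative-weight convention", {
  # equal weights, ratios {1,2,3} -> 2
  inp <- mr_input(c("a", "b", "c"), c(1, 1, 1), 0.05, c(1, 2, 3), c(1, 1, 1))
  expect_equal(mr_weighted_median(inp, n_boot = 50, seed = 1)$beta, 2)
  # a dominant instrument flanked by balanced weights returns its ratio
  w_target <- c(0.2, 0.6, 0.2)   # weights w = (b_x/se_y)^2
  sey <- 1 / sqrt(w_target)
  inp2 <- mr_input(c("a", "b", "c"), c(1, 1, 1), 0.05, c(1, 2, 3), sey)
  expect_equal(mr_weighted_median(inp2, n_boot = 50, seed = 1)$beta, 2)
  # 4 unequal weights vs the brute-force oracle
  set.seed(30)
  for (i in 1:50) {
    bx <- runif(4, 0.2, 0.8); by <- runif(4, -0.2, 0.6)
    sey <- runif(4, 0.2, 0.9)
    inp3 <- mr_input(paste0("s", 1:4), bx, 0.05, by, sey)
    expect_equal(mr_weighted_median(inp3, n_boot = 2, seed = 1)$beta,
                 oracle_weighted_median(by / bx, (bx / sey)^2),
                 tolerance = 1e-12)
  }
  # invariance: duplicating an instrument while halving its weight
  r <- c(0.1, 0.45, 0.9); w <- c(2, 3.5, 4.5)
  split_w <- c(w[1], w[2], w[3] / 2, w[3] / 2)
  expect_equal(coevscan:::weighted_median_point(r, w),
               coevscan:::weighted_median_point(r[c(1, 2, 3, 3)], split_w),
               tolerance = 1e-12)
  expect_error(mr_weighted_median(mr_input("a", 0, 0.05, 0.1, 0.04)),
               "at least 3")
})

test_that("the Bonferroni threshold arithmetic matches the phenotype categories", {
  expect_equal(signif(bonferroni_threshold(c(90, 11, 603, 62, 11)), 3), 6.44e-5)
  expect_equal(bonferroni_threshold(20), 0.0025)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_error(bonferroni_threshold(integer(0)), "empty")
})

test_that("the reporting rule foregrounds Egger under directional pleiotropy", {
  d <- sim_mr_dataset(20, 0.3, pleiotropy_intercept = 0.4, seed = 77)
  rep <- mr_report(d$input, n_boot = 100, seed = 78)
  expect_equal(rep$preferred, "Egger")
  expect_false(rep$ivw_reliable)
  d0 <- sim_mr_dataset(8, 0.3, pleiotropy_intercept = 0, seed = 79)
  rep0 <- mr_report(d0$input, n_boot = 100, seed = 80)
  expect_equal(rep0$preferred, "IVW")
})
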