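# Independent brute-force oracles. These re-derive each statistic by a
# different route than the package (explicit pair loops, ANOVA sums of
# squares, normal equations, decorrelating transforms) so agreement is a real
# cross-check, not a tautology.

# Tajima's D by explicit haplotype-pair differences and direct constant sums
oracle_tajimas_d <- function(haps) {
  n <- nrow(haps)
  seg <- apply(haps, 2, function(col) length(unique(col)) == 2)
  S <- sum(seg)
  if (S == 0 || n < 3) return(list(S = S, D = NA_real_))
  diffs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    diffs <- diffs + sum(haps[i, ] != haps[j, ])
  pi <- diffs / choose(n, 2)
  a1 <- 0; a2 <- 0
  for (i in seq_len(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  list(S = S, pi = pi, D = if (v > 0) (pi - S / a1) / sqrt(v) else NA_real_)
}

# Weir-Cockerham components by numeric two-level ANOVA on allele indicators:
# sums of squares among populations / among individuals / within individuals,
# rather than the closed-form component algebra the package uses.
oracle_wc_fst <- function(dosage_by_pop) {
  n <- vapply(dosage_by_pop, length, numeric(1))
  r <- length(n)
  p <- vapply(dosage_by_pop, function(d) mean(d) / 2, numeric(1))
  pbar <- sum(n * p) / sum(n)
  ssg <- sum(vapply(dosage_by_pop, function(d) sum(d == 1) * 0.5, numeric(1)))
  ssi <- sum(unlist(lapply(seq_len(r), function(i)
    2 * (dosage_by_pop[[i]] / 2 - p[i])^2)))
  ssp <- sum(2 * n * (p - pbar)^2)
  msg <- ssg / sum(n)
  msi <- ssi / sum(n - 1)
  msp <- ssp / (r - 1)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  a <- (msp - msi) / (2 * nc)
  b <- (msi - msg) / 2
  cc <- msg
  tot <- a + b + cc
  list(a = a, b = b, c = cc, fst = if (tot == 0) NA_real_ else a / tot)
}

# squared Pearson correlation from raw sums
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  sxy <- sum(x * y) - n * mean(x) * mean(y)
  sxx <- sum(x^2) - n * mean(x)^2
  syy <- sum(y^2) - n * mean(y)^2
  (sxy / sqrt(sxx * syy))^2
}

# OLS by the normal equations
oracle_ols <- function(y, g, C = NULL) {
  X <- cbind(1, g, C)
  XtX <- t(X) %*% X
  bhat <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% bhat
  df <- length(y) - ncol(X)
  s2 <- sum(resid^2) / df
  V <- s2 * solve(XtX)
  se <- sqrt(V[2, 2])
  t <- bhat[2] / se
  list(beta = bhat[2], se = se, t = t, p = 2 * pt(-abs(t), df))
}

# correlated IVW / Egger via the decorrelating Cholesky transform: premultiply
# by inv(t(L)) with Omega = L'L, then plain least squares with unit variance
oracle_gls <- function(bx, by, se_y, rho, intercept = FALSE) {
  omega <- outer(se_y, se_y) * rho
  L <- chol(omega)
  X <- if (intercept) cbind(1, bx) else cbind(bx)
  Xs <- backsolve(L, X, transpose = TRUE)
  ys <- backsolve(L, by, transpose = TRUE)
  XtX <- t(Xs) %*% Xs
  bhat <- solve(XtX, t(Xs) %*% ys)
  V <- solve(XtX)
  list(coef = drop(bhat), se = sqrt(diag(V)))
}

# beta score by spreadsheet-style explicit loops over the stated formulas
oracle_beta <- function(folded_window, f_core, n, p = 2) {
  stopifnot(f_core > 0, f_core <= 0.5)
  wsum <- 0
  for (f in folded_window) wsum <- wsum + (1 - abs(f - f_core) / 0.5)^p
  denom <- 0; a_n <- 0
  for (k in 1:(n - 1)) {
    fk <- min(k / n, 1 - k / n)
    denom <- denom + (1 - abs(fk - f_core) / 0.5)^p / k
    a_n <- a_n + 1 / k
  }
  tb <- if (length(folded_window)) wsum / denom else 0
  tw <- length(folded_window) / a_n
  list(theta_beta = tb, theta_w = tw, beta = tb - tw)
}

# weighted median by brute-force accumulation: walk the sorted ratios adding
# weight until half the total mass is covered; average adjacent ratios when
# the half-mass point lands exactly on a boundary
oracle_weighted_median <- function(ratios, w) {
  o <- order(ratios)
  r <- ratios[o]; w <- w[o]
  half <- sum(w) / 2
  acc <- 0
  for (j in seq_along(r)) {
    acc <- acc + w[j]
    if (acc > half + 1e-12) return(r[j])
    if (abs(acc - half) <= 1e-12)
      return(if (j < length(r)) (r[j] + r[j + 1]) / 2 else r[j])
  }
  r[length(r)]
}

# small phased toy VCF: 1 indel, 1 triallelic, 3 biallelic SNPs, 3 samples
write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\t.\tA\tG\t.\tPASS\tAA=A\tGT\t0|1\t1|1\t0|0",
    "1\t150\t.\tAT\tA\t.\tPASS\t.\tGT\t0|0\t0|1\t0|0",
    "1\t200\t.\tC\tT\t.\tPASS\tAA=T\tGT\t0|0\t0|1\t1|1",
    "1\t250\t.\tG\tA,C\t.\tPASS\t.\tGT\t0|1\t0|2\t0|0",
    "1\t300\t.\tT\tC\t.\tPASS\t.\tGT\t1|1\t1|0\t0|0"
  ), path)
  path
}
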