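## Tajima's D ----------------------------------------------------------------

#' Tajima's D normalizing constants
#'
#' @param n number of sampled chromosomes.
#' @return list with a1, a2, b1, b2, c1, c2, e1, e2. For `n = 2` the variance
#'   constants collapse to zero and D is undefined.
#' @export
tajima_constants <- function(n) {
  if (n < 2) stop("need at least 2 chromosomes")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D from per-site allele counts
#'
#' The workhorse behind [tajimas_d()]: per-site pairwise diversity
#' `pi_j = 2 k_j (n_j - k_j) / (n_j (n_j - 1))` is summed over sites, S counts
#' segregating sites, and `D = (pi - S/a1) / sqrt(e1 S + e2 S (S-1))` with the
#' constants evaluated at the median per-site chromosome count (sites may
#' differ in n when genotypes are missing).
#'
#' @param k per-site count of the alternate/derived allele.
#' @param n per-site number of observed chromosomes (recycled if scalar).
#' @return list with S, pi, n_chrom, D (`NA` when S = 0, n < 3 or the variance
#'   is not positive).
#' @export
tajimas_d_counts <- function(k, n) {
  n <- rep_len(n, length(k))
  seg <- k > 0 & k < n & n >= 2
  S <- sum(seg)
  pi <- sum(2 * k[seg] * (n[seg] - k[seg]) / (n[seg] * (n[seg] - 1)))
  n_chrom <- if (length(n) > 0) round(stats::median(n)) else 0L
  D <- NA_real_
  if (S >= 1 && n_chrom >= 3) {
    cst <- tajima_constants(n_chrom)
    v <- cst$e1 * S + cst$e2 * S * (S - 1)
    if (v > 0) D <- (pi - S / cst$a1) / sqrt(v)
  }
  list(S = S, pi = pi, n_chrom = n_chrom, D = D)
}

#' Tajima's D for a genotype window
#'
#' @param x a [genotype_matrix()] slice or [haplotype_panel()] covering one
#'   window.
#' @return as [tajimas_d_counts()].
#' @export
tajimas_d <- function(x) {
  if (inherits(x, "haplotype_panel")) {
    tajimas_d_counts(colSums(x$haplotypes), nrow(x$haplotypes))
  } else if (inherits(x, "genotype_matrix")) {
    k <- colSums(x$dosages, na.rm = TRUE)
    n <- 2 * colSums(!is.na(x$dosages))
    tajimas_d_counts(k, n)
  } else stop("x must be a genotype_matrix or haplotype_panel")
}

#' Windowed Tajima's D over a region
#'
#' Tiles `[start, end)` with non-overlapping windows of `width` bp (the last
#' window truncated) and computes D per window. Windows whose dosage entries
#' exceed `max_missing` missingness are excluded from downstream calling but
#' reported with `excluded = TRUE`.
#'
#' @param geno a [genotype_matrix()].
#' @param chrom chromosome; `start`, `end` 0-based half-open bounds.
#' @param width window width in bp (default 1000).
#' @param max_missing maximum tolerated fraction of missing dosage entries.
#' @return data.frame: chrom, start, end, n_snps, pi, n_chrom, D, excluded.
#' @export
scan_tajima_windows <- function(geno, chrom, start, end, width = 1000,
                                max_missing = 0.1) {
  stopifnot(width > 0, end > start)
  starts <- seq(start, end - 1, by = width)
  ends <- pmin(starts + width, end)
  on_chrom <- geno$sites$chrom == chrom
  p0 <- geno$sites$pos - 1L
  rows <- lapply(seq_along(starts), function(i) {
    in_win <- which(on_chrom & p0 >= starts[i] & p0 < ends[i])
    d <- geno$dosages[, in_win, drop = FALSE]
    miss <- if (length(in_win) > 0) mean(is.na(d)) else 0
    td <- tajimas_d_counts(colSums(d, na.rm = TRUE), 2 * colSums(!is.na(d)))
    data.frame(chrom = chrom, start = starts[i], end = ends[i],
               n_snps = td$S, pi = td$pi, n_chrom = td$n_chrom, D = td$D,
               excluded = miss > max_missing)
  })
  do.call(rbind, rows)
}

## Empirical null ------------------------------------------------------------

#' Build an empirical null from statistic values in neutral/reference regions
#'
#' @param values statistic values (e.g. window D on a reference chromosome);
#'   undefined (`NA`) entries are skipped.
#' @param lower,upper tail probabilities (defaults 0.025 / 0.975).
#' @param min_values minimum defined values for stable percentiles.
#' @return object of class `empirical_null` with elements values, lower, upper.
#' @export
empirical_null <- function(values, lower = 0.025, upper = 0.975,
                           min_values = 40) {
  v <- values[!is.na(values)]
  if (length(v) < min_values)
    stop("need at least ", min_values, " defined values for a stable null (got ",
         length(v), ")")
  q <- pkg_quantile(v, c(lower, upper))
  structure(list(values = v, lower = q[1], upper = q[2]),
            class = "empirical_null")
}

#' Classify test windows against an empirical null
#'
#' Strict inequalities: a window is `"low"` when D < lower bound, `"high"`
#' when D > upper bound, otherwise `"ns"` (ties and undefined D are `"ns"`).
#' Excluded windows are `"ns"`.
#'
#' @param windows data.frame from [scan_tajima_windows()] (needs a `D`
#'   column; an `excluded` column is honored if present).
#' @param null an [empirical_null()].
#' @return `windows` with a `flag` column added.
#' @export
classify_windows <- function(windows, null) {
  stopifnot(inherits(null, "empirical_null"))
  D <- windows$D
  excl <- windows$excluded %||% rep(FALSE, length(D))
  usable <- !is.na(D) & !excl
  flag <- rep("ns", length(D))
  flag[usable & D < null$lower] <- "low"
  flag[usable & D > null$upper] <- "high"
  windows$flag <- flag
  windows
}

#' Per-gene summary of window flags
#'
#' A window belongs to a gene when its interval overlaps the gene's.
#'
#' @param windows classified windows (with `flag`).
#' @param genes a [region_table()].
#' @return data.frame: gene, n_windows, prop_low, prop_high, mean_D.
#' @export
gene_window_summary <- function(windows, genes) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ov <- windows$chrom == g$chrom & windows$start < g$end & windows$end > g$start
    w <- windows[ov & !(windows$excluded %||% FALSE), , drop = FALSE]
    n <- nrow(w)
    data.frame(gene = g$name, n_windows = n,
               prop_low = if (n) mean(w$flag == "low") else NA_real_,
               prop_high = if (n) mean(w$flag == "high") else NA_real_,
               mean_D = if (any(!is.na(w$D))) mean(w$D, na.rm = TRUE) else NA_real_)
  })
  do.call(rbind, rows)
}

## Weir-Cockerham FST ---------------------------------------------------------

#' Weir-Cockerham per-site FST variance components
#'
#' Implements the diploid single-locus estimator: with r populations of n_i
#' individuals, allele frequency p_i and observed heterozygote proportion h_i,
#' the among-population (a), among-individual (b) and within-individual (c)
#' components are combined as FST = a / (a + b + c).
#'
#' @param n_ind per-population diploid sample sizes (length r >= 2, each >= 2).
#' @param alt_count per-population count of the alternate allele.
#' @param het_count per-population count of heterozygous individuals.
#' @return list with a, b, c, fst (`NA` when the site is monomorphic in every
#'   population, i.e. a + b + c = 0).
#' @export
wc_fst_site <- function(n_ind, alt_count, het_count) {
  r <- length(n_ind)
  if (r < 2) stop("need at least 2 populations")
  if (any(n_ind < 2)) stop("each population needs >= 2 individuals")
  p <- alt_count / (2 * n_ind)
  h <- het_count / n_ind
  nbar <- sum(n_ind) / r
  nc <- (r * nbar - sum(n_ind^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_ind * p) / (r * nbar)
  s2 <- sum(n_ind * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_ind * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - (2 * nbar - 1) * hbar / (4 * nbar))
  cc <- hbar / 2
  tot <- a + b + cc
  list(a = a, b = b, c = cc, fst = if (tot == 0) NA_real_ else a / tot)
}

#' Per-site Weir-Cockerham FST across populations of a genotype matrix
#'
#' Populations with fewer than 2 genotyped individuals at a site are dropped
#' for that site; sites with fewer than 2 usable populations get `NA`.
#'
#' @param geno a [genotype_matrix()].
#' @param pops optional sample -> population vector (default the matrix's own).
#' @return data.frame: chrom, pos, a, b, c, fst.
#' @export
wc_fst <- function(geno, pops = NULL) {
  pops <- pops %||% geno$populations
  pops <- pops[geno$samples]
  labs <- sort(unique(pops))
  rows <- lapply(seq_len(nrow(geno$sites)), function(j) {
    d <- geno$dosages[, j]
    n <- alt <- het <- numeric(0)
    for (pl in labs) {
      dp <- d[pops == pl]
      dp <- dp[!is.na(dp)]
      if (length(dp) >= 2) {
        n <- c(n, length(dp)); alt <- c(alt, sum(dp)); het <- c(het, sum(dp == 1))
      }
    }
    f <- if (length(n) >= 2) wc_fst_site(n, alt, het)
         else list(a = NA_real_, b = NA_real_, c = NA_real_, fst = NA_real_)
    data.frame(chrom = geno$sites$chrom[j], pos = geno$sites$pos[j],
               a = f$a, b = f$b, c = f$c, fst = f$fst)
  })
  do.call(rbind, rows)
}

#' Multi-locus Weir-Cockerham FST
#'
#' Combines per-site variance components as `sum(a) / sum(a + b + c)` -- the
#' standard multi-locus estimator, and the one to use when recovering a
#' simulation's fixation index (the mean of per-site ratios is downward-biased
#' by Jensen's inequality; it is kept only for per-gene ranking, where the
#' study averaged raw per-site values).
#'
#' @param fst_sites data.frame from [wc_fst()] (columns a, b, c).
#' @return scalar FST estimate.
#' @export
wc_fst_global <- function(fst_sites) {
  tot <- fst_sites$a + fst_sites$b + fst_sites$c
  sum(fst_sites$a[!is.na(tot)]) / sum(tot, na.rm = TRUE)
}

#' Per-gene mean of a per-site or per-window statistic
#'
#' Raw arithmetic mean of defined values falling in the gene's interval;
#' negative values are retained.
#'
#' @param values statistic values.
#' @param pos 1-based positions aligned to `values` (window midpoints work for
#'   window statistics).
#' @param gene one row of a [region_table()].
#' @param chrom optional chromosome labels aligned to `values`.
#' @return list with mean (`NA` if no defined values) and n.
#' @export
gene_mean <- function(values, pos, gene, chrom = NULL) {
  inside <- (pos - 1) >= gene$start & (pos - 1) < gene$end
  if (!is.null(chrom)) inside <- inside & chrom == gene$chrom
  v <- values[inside]
  v <- v[!is.na(v)]
  list(mean = if (length(v)) mean(v) else NA_real_, n = length(v))
}
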