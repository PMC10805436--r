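## Every generator is a pure function of its seed: it saves and restores the
## caller's RNG state, and the same seed gives identical output. Each dataset
## ships with a `synthetic_truth` record carrying the planted parameters;
## recovery tests read truth only from that record.

synthetic_truth <- function(scenario, params, seed) {
  structure(list(scenario = scenario, params = params, seed = seed),
            class = "synthetic_truth")
}

#' Balding-Nichols structured genotypes with known FST
#'
#' For each population and site, the population allele frequency is drawn from
#' a Beta distribution with mean `p0` and variance `F p0 (1 - p0)`
#' (shape parameters `p0 (1-F)/F` and `(1-p0)(1-F)/F`), and diploid genotypes
#' are Binomial(2, freq) -- Hardy-Weinberg within populations.
#'
#' @param F fixation index in (0, 1).
#' @param p0 ancestral allele frequency (scalar or per-site vector).
#' @param n_pops number of populations.
#' @param n_diploids diploid individuals per population.
#' @param n_sites number of independent SNPs.
#' @param seed RNG seed.
#' @return list: genotypes (a [genotype_matrix()]), truth.
#' @export
sim_balding_nichols <- function(F, p0 = 0.5, n_pops = 2, n_diploids = 200,
                                n_sites = 1000, seed = 1) {
  stopifnot(F > 0, F < 1, all(p0 > 0), all(p0 < 1), n_pops >= 1,
            n_diploids >= 2, n_sites >= 1)
  p0 <- rep_len(p0, n_sites)
  with_seed(seed, {
    dos <- matrix(NA_integer_, nrow = n_pops * n_diploids, ncol = n_sites)
    pops <- rep(paste0("pop", seq_len(n_pops)), each = n_diploids)
    for (k in seq_len(n_pops)) {
      pk <- stats::rbeta(n_sites, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
      rows <- (k - 1) * n_diploids + seq_len(n_diploids)
      dos[rows, ] <- stats::rbinom(n_diploids * n_sites, 2,
                                   rep(pk, each = n_diploids))
    }
    rownames(dos) <- paste0(pops, "_", rep(seq_len(n_diploids), n_pops))
    sites <- site_table(rep("1", n_sites), seq_len(n_sites) * 100L,
                        rep("A", n_sites), rep("G", n_sites))
    g <- genotype_matrix(sites, dos,
                         stats::setNames(pops, rownames(dos)))
    list(genotypes = g,
         truth = synthetic_truth("balding_nichols",
                                 list(F = F, p0 = p0[1], n_pops = n_pops,
                                      n_diploids = n_diploids,
                                      n_sites = n_sites), seed))
  })
}

## one standard (Kingman) coalescent window without recombination:
## exponential coalescence times at rate k(k-1)/2, Poisson mutations at rate
## theta/2 per unit branch length, infinite-sites 0/1 output (derived coding)
sim_one_coalescent_window <- function(n_chrom, theta, window_bp = 1000) {
  members <- lapply(seq_len(n_chrom), identity)
  blen <- numeric(n_chrom)
  branches <- list(); branch_len <- numeric(0)
  k <- n_chrom
  while (k > 1) {
    blen <- blen + stats::rexp(1, rate = k * (k - 1) / 2)
    pair <- sample.int(k, 2)
    branches <- c(branches, members[pair])
    branch_len <- c(branch_len, blen[pair])
    members <- c(members[-pair], list(sort(c(members[[pair[1]]],
                                             members[[pair[2]]]))))
    blen <- c(blen[-pair], 0)
    k <- k - 1
  }
  total <- sum(branch_len)
  n_mut <- stats::rpois(1, theta / 2 * total)
  n_mut <- min(n_mut, window_bp)     # infinite-sites within a finite window
  if (n_mut == 0) {
    return(matrix(0L, nrow = n_chrom, ncol = 0,
                  dimnames = list(NULL, NULL)))
  }
  br <- sample.int(length(branch_len), n_mut, replace = TRUE,
                   prob = branch_len)
  pos <- sort(sample.int(window_bp, n_mut))
  haps <- matrix(0L, nrow = n_chrom, ncol = n_mut)
  for (j in seq_len(n_mut)) haps[branches[[br[j]]], j] <- 1L
  colnames(haps) <- pos
  haps
}

#' Neutral coalescent windows with known theta
#'
#' Each window is an independent standard coalescent genealogy (no
#' recombination) with infinite-sites mutations at rate theta/2 per unit
#' branch length, so E\[S\] = theta * a_n. Used as the known-truth null for
#' Tajima's D calibration.
#'
#' @param n_chrom haplotypes per window (>= 3 for a defined D).
#' @param theta population-scaled mutation rate per window.
#' @param n_windows number of windows.
#' @param seed RNG seed.
#' @param window_bp physical window span for site positions (default 1000).
#' @return list: panels (list of derived-coded [haplotype_panel()], possibly
#'   with 0 sites), truth.
#' @export
sim_neutral_windows <- function(n_chrom = 50, theta = 10, n_windows = 100,
                                seed = 1, window_bp = 1000) {
  stopifnot(n_chrom >= 2)
  with_seed(seed, {
    panels <- lapply(seq_len(n_windows), function(w) {
      haps <- sim_one_coalescent_window(n_chrom, theta, window_bp)
      np <- ncol(haps)
      pos <- if (np) as.integer(colnames(haps)) else integer(0)
      sites <- site_table(rep("1", np), pos, rep("A", np), rep("G", np),
                          ancestral = rep("ref", np))
      colnames(haps) <- NULL
      haplotype_panel(sites, haps, coding = "derived")
    })
    list(panels = panels,
         truth = synthetic_truth("neutral_windows",
                                 list(n_chrom = n_chrom, theta = theta,
                                      n_windows = n_windows,
                                      window_bp = window_bp), seed))
  })
}

#' Constructed sweep panel for exercising EHH/iHS
#'
#' Derived carriers at the core copy a single founder haplotype over a
#' contiguous block around the core; each carrier's block ends independently
#' on each side after a Geometric(1 - founder_fidelity) number of sites,
#' beyond which sites are drawn from the background frequencies. Ancestral
#' carriers are drawn independently from the background throughout. By
#' construction derived haplotypes are long and mutually similar, so iHH_D
#' exceeds iHH_A and ihs_raw is negative at the core.
#'
#' @param n_chrom haplotypes.
#' @param n_sites odd number of sites; the core is the middle site.
#' @param q derived frequency at the core (needs >= 2 carriers of each class).
#' @param founder_fidelity per-site probability the founder block continues
#'   (1 = perfect copies everywhere).
#' @param spacing_bp distance between adjacent sites (default 100).
#' @param cm_per_mb uniform recombination rate for the bundled map.
#' @param seed RNG seed.
#' @return list: panel (derived-coded), map (a [genetic_map()]), core (site
#'   index), truth.
#' @export
sim_sweep_panel <- function(n_chrom = 100, n_sites = 101, q = 0.3,
                            founder_fidelity = 0.95, spacing_bp = 100,
                            cm_per_mb = 1, seed = 1) {
  n_der <- round(q * n_chrom)
  if (n_der < 2 || n_chrom - n_der < 2)
    stop("q = ", q, " leaves fewer than 2 carriers of one allele class")
  with_seed(seed, {
    core <- (n_sites + 1) %/% 2
    pos <- seq_len(n_sites) * spacing_bp
    bg <- stats::runif(n_sites, 0.2, 0.8)
    haps <- matrix(stats::rbinom(n_chrom * n_sites, 1, rep(bg, each = n_chrom)),
                   nrow = n_chrom)
    founder <- stats::rbinom(n_sites, 1, bg)
    for (h in seq_len(n_der)) {
      lb <- if (founder_fidelity >= 1) Inf else stats::rgeom(1, 1 - founder_fidelity)
      rb <- if (founder_fidelity >= 1) Inf else stats::rgeom(1, 1 - founder_fidelity)
      lo <- max(1, core - lb); hi <- min(n_sites, core + rb)
      haps[h, lo:hi] <- founder[lo:hi]
    }
    haps[, core] <- c(rep(1L, n_der), rep(0L, n_chrom - n_der))
    sites <- site_table(rep("1", n_sites), pos, rep("A", n_sites),
                        rep("G", n_sites), ancestral = rep("ref", n_sites))
    panel <- haplotype_panel(sites, haps, coding = "derived")
    map <- genetic_map("1", c(1, max(pos) + spacing_bp),
                       c(0, (max(pos) + spacing_bp - 1) * cm_per_mb / 1e6 * 100))
    list(panel = panel, map = map, core = core,
         truth = synthetic_truth("sweep",
                                 list(q = q, founder_fidelity = founder_fidelity,
                                      n_chrom = n_chrom, n_sites = n_sites),
                                 seed))
  })
}

## two-locus haplotype frequencies for allele freqs (p, q) and target r2;
## errors when the target is infeasible for those frequencies
two_locus_hap_freqs <- function(p, q, r2_target) {
  r <- sqrt(r2_target)
  D <- r * sqrt(p * (1 - p) * q * (1 - q))
  h <- c(p * q + D, p * (1 - q) - D, (1 - p) * q - D, (1 - p) * (1 - q) + D)
  if (any(h < -1e-12))
    stop("target r2 = ", r2_target, " infeasible for frequencies ", p, ", ", q)
  pmax(h, 0) / sum(pmax(h, 0))
}

#' Two-locus genotype pairs with controlled LD, plus planted high-r2 pairs
#'
#' Each pair of loci is simulated independently: two-locus haplotype
#' frequencies are solved so the expected r2 equals the pair's target, 2N
#' haplotypes are drawn multinomially and combined into diploid dosages.
#' Null pairs follow `bin_profile` (a target r2 per genetic distance);
#' planted "epistatic" pairs get their own (high) targets, chosen above the
#' null variation in their distance bin.
#'
#' @param bin_profile data.frame with columns d_cm, r2_target: the null LD
#'   level at each simulated distance; each row is replicated
#'   `n_pairs_per_bin` times.
#' @param n_pairs_per_bin null pairs to draw per profile row.
#' @param planted optional data.frame with columns d_cm, r2_target for planted
#'   pairs.
#' @param n_samples diploid sample size.
#' @param p,q allele frequencies at the two loci (default 0.5, 0.5).
#' @param seed RNG seed.
#' @return list: pairs (data.frame pair_id, d_cm, r2_target, planted, r2 with
#'   realized genotype r2), dosages (n_samples x 2*n_pairs matrix), truth.
#' @export
sim_ld_pairs <- function(bin_profile, n_pairs_per_bin = 100, planted = NULL,
                         n_samples = 200, p = 0.5, q = 0.5, seed = 1) {
  design <- data.frame(
    d_cm = rep(bin_profile$d_cm, each = n_pairs_per_bin),
    r2_target = rep(bin_profile$r2_target, each = n_pairs_per_bin),
    planted = FALSE)
  if (!is.null(planted) && nrow(planted) > 0)
    design <- rbind(design, data.frame(d_cm = planted$d_cm,
                                   r2_target = planted$r2_target,
                                   planted = TRUE))
  with_seed(seed, {
    n_pairs <- nrow(design)
    dos <- matrix(NA_integer_, nrow = n_samples, ncol = 2 * n_pairs)
    r2 <- numeric(n_pairs)
    hap_dos <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
    for (i in seq_len(n_pairs)) {
      hf <- two_locus_hap_freqs(p, q, design$r2_target[i])
      draws <- sample.int(4, 2 * n_samples, replace = TRUE, prob = hf)
      al <- hap_dos[draws, , drop = FALSE]
      g1 <- al[seq(1, 2 * n_samples, 2), 1] + al[seq(2, 2 * n_samples, 2), 1]
      g2 <- al[seq(1, 2 * n_samples, 2), 2] + al[seq(2, 2 * n_samples, 2), 2]
      dos[, 2 * i - 1] <- g1
      dos[, 2 * i] <- g2
      r2[i] <- geno_r2(g1, g2)
    }
    pairs <- data.frame(pair_id = seq_len(n_pairs), d_cm = design$d_cm,
                        r2_target = design$r2_target, planted = design$planted,
                        r2 = r2)
    list(pairs = pairs, dosages = dos,
         truth = synthetic_truth("ld_pairs",
                                 list(bin_profile = bin_profile,
                                      n_pairs_per_bin = n_pairs_per_bin,
                                      planted = planted,
                                      n_samples = n_samples, p = p, q = q),
                                 seed))
  })
}

#' Expression matrix with planted eQTL effects
#'
#' `expression(gene, sample) = sum(beta * dosage) + covariates %*% gamma +
#' N(0, noise_sd)`.
#'
#' @param geno a [genotype_matrix()].
#' @param effects data.frame with columns snp (position), gene, beta; every
#'   snp must be present in `geno`.
#' @param genes gene names for the expression matrix (effect genes are added
#'   if absent).
#' @param n_covariates standard-normal covariates to include (default 2).
#' @param covariate_beta effect of each covariate on every gene (default 0.5).
#' @param noise_sd residual standard deviation.
#' @param tissue tissue label.
#' @param seed RNG seed.
#' @return list: expr_set (list tissue/expr/covariates), truth.
#' @export
sim_expression <- function(geno, effects, genes = unique(effects$gene),
                           n_covariates = 2, covariate_beta = 0.5,
                           noise_sd = 0.5, tissue = "synthetic_tissue",
                           seed = 1) {
  idx <- match(effects$snp, geno$sites$pos)
  if (anyNA(idx)) stop("effect SNP(s) not in genotypes: ",
                       paste(effects$snp[is.na(idx)], collapse = ", "))
  genes <- union(genes, effects$gene)
  n <- length(geno$samples)
  with_seed(seed, {
    C <- if (n_covariates > 0)
      matrix(stats::rnorm(n * n_covariates), nrow = n,
             dimnames = list(geno$samples,
                             paste0("cov", seq_len(n_covariates))))
    expr <- matrix(stats::rnorm(length(genes) * n, sd = noise_sd),
                   nrow = length(genes),
                   dimnames = list(genes, geno$samples))
    if (!is.null(C))
      expr <- expr + matrix(rep(rowSums(C) * covariate_beta, each = length(genes)),
                            nrow = length(genes))
    for (e in seq_len(nrow(effects))) {
      g <- geno$dosages[, idx[e]]
      expr[effects$gene[e], ] <- expr[effects$gene[e], ] + effects$beta[e] * g
    }
    list(expr_set = list(tissue = tissue, expr = expr, covariates = C),
         truth = synthetic_truth("expression",
                                 list(effects = effects, noise_sd = noise_sd,
                                      n_covariates = n_covariates,
                                      covariate_beta = covariate_beta), seed))
  })
}

#' Synthetic MR summary statistics with a known causal effect
#'
#' Exposure effects are drawn from N(0.3, 0.1) (predominantly positive, as
#' after orientation); outcome effects are
#' `b_y = causal_beta * b_x + pleiotropy_intercept + noise_scale * e` with
#' `e ~ N(0, Omega)`, `Omega = se_y se_y' rho`. `noise_scale = 0` gives exact
#' proportionality while keeping the stated standard errors usable by the
#' estimators.
#'
#' @param n_instruments number of instruments.
#' @param causal_beta true causal effect.
#' @param pleiotropy_intercept directional pleiotropy added to every outcome
#'   effect (default 0).
#' @param rho LD correlation matrix (default identity).
#' @param se_x,se_y stated standard errors (scalar or per instrument).
#' @param noise_scale multiplier on the outcome noise (default 1).
#' @param seed RNG seed.
#' @return list: input (an [mr_input()]), truth.
#' @export
sim_mr_dataset <- function(n_instruments = 8, causal_beta = 0.3,
                           pleiotropy_intercept = 0, rho = NULL,
                           se_x = 0.05, se_y = 0.05, noise_scale = 1,
                           seed = 1) {
  J <- n_instruments
  if (is.null(rho)) rho <- diag(J)
  se_x <- rep_len(se_x, J); se_y <- rep_len(se_y, J)
  om <- outer(se_y, se_y) * rho
  with_seed(seed, {
    b_x <- stats::rnorm(J, 0.3, 0.1)
    L <- chol(om + diag(1e-12, J))
    e <- drop(t(L) %*% stats::rnorm(J))
    b_y <- causal_beta * b_x + pleiotropy_intercept + noise_scale * e
    list(input = mr_input(paste0("rs", seq_len(J)), b_x, se_x, b_y, se_y, rho),
         truth = synthetic_truth("mr",
                                 list(causal_beta = causal_beta,
                                      pleiotropy_intercept = pleiotropy_intercept,
                                      n_instruments = J,
                                      noise_scale = noise_scale), seed))
  })
}
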