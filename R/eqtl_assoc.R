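#' Single-SNP linear-model association
#'
#' Ordinary least squares of an expression vector on a dosage vector with
#' covariate adjustment: `y ~ g + C` (intercept added internally). The
#' reported effect is the genotype coefficient, per non-reference allele, with
#' its two-sided t-test p-value.
#'
#' @param y expression vector.
#' @param g dosage vector.
#' @param C optional covariate matrix (samples x covariates), no missing
#'   entries.
#' @return list: beta, se, t, p, n, df_resid.
#' @export
ols_association <- function(y, g, C = NULL) {
  stopifnot(length(y) == length(g))
  if (stats::var(g) == 0) stop("rank deficiency: genotype vector 'g' is constant")
  dat <- data.frame(y = y, g = g)
  if (!is.null(C)) {
    C <- as.matrix(C)
    if (anyNA(C)) stop("covariate matrix has missing entries")
    colnames(C) <- paste0("c", seq_len(ncol(C)))
    dat <- cbind(dat, C)
  }
  fit <- stats::lm(y ~ ., data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    bad <- names(cf)[is.na(cf)]
    stop("rank-deficient design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  if (fit$df.residual < 1) stop("no residual degrees of freedom")
  sm <- summary(fit)$coefficients
  list(beta = unname(sm["g", 1]), se = unname(sm["g", 2]),
       t = unname(sm["g", 3]), p = unname(sm["g", 4]),
       n = length(y), df_resid = fit$df.residual)
}

#' eQTL scan of selected SNPs against cluster gene expression
#'
#' One linear model per (SNP, gene, tissue): SNPs below the MAF floor are
#' excluded (strictly "above 5%"), samples are aligned by id across genotypes,
#' expression and covariates, and significance uses the fixed genome-wide
#' threshold (default 1e-8) with a strict inequality.
#'
#' @param snp_pos positions of the selected SNPs (must be in `geno`).
#' @param geno a [genotype_matrix()].
#' @param expr_sets list of expression sets, each a list with elements
#'   `tissue`, `expr` (genes x samples matrix) and `covariates` (samples x
#'   covariates matrix or NULL).
#' @param threshold significance threshold on p (default 1e-8).
#' @param maf_min MAF floor, strict (default 0.05).
#' @return data.frame: snp, gene, tissue, beta, se, t, p, significant.
#' @export
eqtl_scan <- function(snp_pos, geno, expr_sets, threshold = 1e-8,
                      maf_min = 0.05) {
  if (length(snp_pos) == 0) stop("empty SNP list")
  idx <- match(snp_pos, geno$sites$pos)
  if (anyNA(idx)) stop("SNP(s) not in genotypes: ",
                       paste(snp_pos[is.na(idx)], collapse = ", "))
  maf <- dosage_maf(geno$dosages[, idx, drop = FALSE])
  idx <- idx[maf > maf_min]
  rows <- list()
  for (es in expr_sets) {
    samples <- intersect(geno$samples, colnames(es$expr))
    if (length(samples) < 3) stop("tissue ", es$tissue,
                                  ": too few shared samples")
    C <- if (!is.null(es$covariates)) es$covariates[samples, , drop = FALSE]
    for (j in idx) {
      g <- geno$dosages[samples, j]
      for (gene in rownames(es$expr)) {
        fit <- ols_association(es$expr[gene, samples], g, C)
        rows[[length(rows) + 1]] <- data.frame(
          snp = geno$sites$pos[j], gene = gene, tissue = es$tissue,
          beta = fit$beta, se = fit$se, t = fit$t, p = fit$p,
          significant = fit$p < threshold)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
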