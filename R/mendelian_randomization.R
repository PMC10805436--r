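## MR input -----------------------------------------------------------------

#' Assemble a Mendelian-randomization input
#'
#' Per-instrument exposure and outcome effects with their standard errors and
#' an optional instrument-by-instrument LD correlation matrix. The correlation
#' matrix must be symmetric with unit diagonal and positive semi-definite (to
#' numerical tolerance).
#'
#' @param snp instrument identifiers.
#' @param b_x,se_x exposure effects and standard errors.
#' @param b_y,se_y outcome effects and standard errors.
#' @param rho LD correlation matrix (default identity = uncorrelated).
#' @return object of class `mr_input`.
#' @export
mr_input <- function(snp, b_x, se_x, b_y, se_y, rho = NULL) {
  J <- length(b_x)
  se_x <- rep_len(se_x, J); se_y <- rep_len(se_y, J)
  stopifnot(length(b_y) == J, length(snp) == J)
  if (is.null(rho)) rho <- diag(J)
  rho <- as.matrix(rho)
  if (!isTRUE(all.equal(rho, t(rho), tolerance = 1e-8)))
    stop("rho must be symmetric")
  if (any(abs(diag(rho) - 1) > 1e-8)) stop("rho must have unit diagonal")
  if (min(eigen(rho, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("rho must be positive semi-definite")
  structure(list(snp = as.character(snp), b_x = as.numeric(b_x),
                 se_x = as.numeric(se_x), b_y = as.numeric(b_y),
                 se_y = as.numeric(se_y), rho = rho),
            class = "mr_input")
}

mr_result <- function(method, beta, se, p, extra = list()) {
  structure(c(list(method = method, beta = beta, se = se,
                   ci95 = c(beta - 1.96 * se, beta + 1.96 * se), p = p),
              extra),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (se %.4f, 95%% CI %.4f..%.4f), p = %.3g\n",
              x$method, x$beta, x$se, x$ci95[1], x$ci95[2], x$p))
  if (!is.null(x$egger_intercept))
    cat(sprintf("  Egger intercept = %.4f (p = %.3g)%s\n", x$egger_intercept,
                x$intercept_p,
                if (isTRUE(x$pleiotropy_flag)) "  [directional pleiotropy]" else ""))
  invisible(x)
}

## outcome covariance Omega_ij = se_y_i se_y_j rho_ij
mr_omega <- function(input) outer(input$se_y, input$se_y) * input$rho

## Instrument selection --------------------------------------------------------

#' Select and prune MR instruments
#'
#' Keeps SNPs with instrument strength F = (b_x/se_x)^2 strictly above `f_min`
#' and exposure p-value strictly below `p_max`, then prunes for LD greedily by
#' ascending p-value: the strongest SNP is kept and any later SNP with
#' r2 > `r2_max` against an already-kept SNP is dropped.
#'
#' @param assoc data.frame with columns snp, b_x, se_x, p_x.
#' @param ld_r2 pairwise r2 matrix with dimnames matching `assoc$snp`.
#' @param f_min F-statistic floor (default 10).
#' @param p_max exposure p-value ceiling (default 0.001, i.e. 0.05/50).
#' @param r2_max pruning threshold (default 0.8).
#' @return the surviving rows of `assoc`, ordered by ascending p_x.
#' @export
select_instruments <- function(assoc, ld_r2, f_min = 10, p_max = 0.001,
                               r2_max = 0.8) {
  F <- (assoc$b_x / assoc$se_x)^2
  cand <- assoc[F > f_min & assoc$p_x < p_max, , drop = FALSE]
  cand <- cand[order(cand$p_x), , drop = FALSE]
  kept <- character(0)
  for (s in cand$snp) {
    if (length(kept) == 0 || all(ld_r2[s, kept] <= r2_max)) kept <- c(kept, s)
  }
  if (length(kept) == 0) stop("no instruments survive selection")
  out <- cand[cand$snp %in% kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Estimators ------------------------------------------------------------------

#' Inverse-variance-weighted causal estimate with correlated instruments
#'
#' Generalized weighted regression of outcome effects on exposure effects
#' through the origin with outcome covariance `Omega = se_y se_y' * rho`:
#' `beta = (b_x' W b_x)^{-1} b_x' W b_y` with `W = Omega^{-1}`, and
#' `se = sqrt((b_x' W b_x)^{-1})` (fixed-effect). With `random_effects = TRUE`
#' the se is inflated by `max(1, sqrt(Q / (J - 1)))` where Q is Cochran's
#' heterogeneity statistic.
#'
#' @param input an [mr_input()].
#' @param random_effects inflate the se under heterogeneity (default FALSE).
#' @return an `mr_result` (method "IVW").
#' @export
mr_ivw <- function(input, random_effects = FALSE) {
  stopifnot(inherits(input, "mr_input"))
  om <- mr_omega(input)
  W <- tryCatch(solve(om), error = function(e)
    stop("outcome covariance is singular; prune correlated instruments"))
  bxWbx <- drop(t(input$b_x) %*% W %*% input$b_x)
  beta <- drop(t(input$b_x) %*% W %*% input$b_y) / bxWbx
  se <- sqrt(1 / bxWbx)
  if (random_effects && length(input$b_x) > 1) {
    resid <- input$b_y - beta * input$b_x
    Q <- drop(t(resid) %*% W %*% resid)
    se <- se * max(1, sqrt(Q / (length(input$b_x) - 1)))
  }
  p <- 2 * stats::pnorm(-abs(beta / se))
  mr_result("IVW", beta, se, p)
}

#' MR-Egger regression with correlated instruments
#'
#' Generalized least squares of outcome effects on `[1, b_x]` with weight
#' `Omega^{-1}`, after orienting instruments so exposure effects are positive
#' (Egger is not invariant to allele coding). The slope is the
#' pleiotropy-corrected causal estimate; the intercept tests directional
#' pleiotropy (two-sided normal), and `pleiotropy_flag = intercept_p < 0.05`.
#'
#' @param input an [mr_input()] with at least 3 instruments.
#' @return an `mr_result` (method "Egger") with egger_intercept, intercept_se,
#'   intercept_p and pleiotropy_flag.
#' @export
mr_egger <- function(input) {
  stopifnot(inherits(input, "mr_input"))
  J <- length(input$b_x)
  if (J < 3) stop("MR-Egger needs at least 3 instruments")
  s <- ifelse(input$b_x < 0, -1, 1)
  bx <- input$b_x * s
  by <- input$b_y * s
  om <- outer(input$se_y, input$se_y) * (outer(s, s) * input$rho)
  W <- tryCatch(solve(om), error = function(e)
    stop("outcome covariance is singular; prune correlated instruments"))
  X <- cbind(1, bx)
  XtW <- t(X) %*% W
  V <- solve(XtW %*% X)
  B <- drop(V %*% XtW %*% by)
  se <- sqrt(diag(V))
  B <- unname(B); se <- unname(se)
  int_p <- 2 * stats::pnorm(-abs(B[1] / se[1]))
  slope_p <- 2 * stats::pnorm(-abs(B[2] / se[2]))
  mr_result("Egger", B[2], se[2], slope_p,
            extra = list(egger_intercept = B[1], intercept_se = se[1],
                         intercept_p = int_p,
                         pleiotropy_flag = int_p < 0.05))
}

## weighted-median point estimate: the median of the discrete ratio
## distribution with the given weights -- the ratio whose cumulative weight
## interval contains 0.5, interpolating between adjacent ratios when 0.5
## falls exactly on a boundary. Being a pure functional of the weighted CDF,
## it is invariant to splitting an instrument's weight across duplicates.
weighted_median_point <- function(ratios, w, tol = 1e-12) {
  o <- order(ratios)
  r <- ratios[o]
  cum <- cumsum(w[o] / sum(w))
  j <- which(cum >= 0.5 - tol)[1]
  if (abs(cum[j] - 0.5) < tol && j < length(r)) (r[j] + r[j + 1]) / 2 else r[j]
}

#' Weighted-median causal estimate
#'
#' Per-instrument ratio estimates `b_y / b_x` with weights proportional to
#' `(b_x / se_y)^2`; the estimate is the point where the cumulative sorted
#' weight crosses 0.5 (linear interpolation between adjacent ratios when the
#' crossing falls exactly on a boundary), i.e. the median of the weighted
#' ratio distribution. The standard error comes from a parametric bootstrap that
#' resamples `b_x` and `b_y` from their stated standard errors. The LD matrix
#' is ignored: the method is run, as a sensitivity test, on the pruned and
#' hence weakly correlated instrument set.
#'
#' @param input an [mr_input()] with at least 3 instruments.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return an `mr_result` (method "WeightedMedian").
#' @export
mr_weighted_median <- function(input, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(input, "mr_input"))
  J <- length(input$b_x)
  if (J < 3) stop("weighted median needs at least 3 instruments")
  if (any(input$b_x == 0)) stop("zero exposure effect: ratio undefined")
  w <- (input$b_x / input$se_y)^2
  beta <- weighted_median_point(input$b_y / input$b_x, w)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(J, input$b_x, input$se_x)
      by <- stats::rnorm(J, input$b_y, input$se_y)
      bx[bx == 0] <- .Machine$double.eps
      weighted_median_point(by / bx, (bx / input$se_y)^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  p <- 2 * stats::pnorm(-abs(beta / se))
  mr_result("WeightedMedian", beta, se, p)
}

#' Run all three MR estimators with the pleiotropy-aware reporting rule
#'
#' IVW is the primary analysis; if the MR-Egger intercept is significant
#' (p < 0.05, directional pleiotropy) the report marks IVW as unreliable and
#' foregrounds the Egger estimate; the weighted median is the sensitivity
#' analysis.
#'
#' @param input an [mr_input()].
#' @param n_boot,seed passed to [mr_weighted_median()].
#' @return list: ivw, egger, weighted_median, preferred ("IVW" or "Egger"),
#'   ivw_reliable.
#' @export
mr_report <- function(input, n_boot = 1000, seed = NULL) {
  ivw <- mr_ivw(input)
  egger <- if (length(input$b_x) >= 3) mr_egger(input) else NULL
  wm <- if (length(input$b_x) >= 3) mr_weighted_median(input, n_boot, seed) else NULL
  pleio <- !is.null(egger) && isTRUE(egger$pleiotropy_flag)
  list(ivw = ivw, egger = egger, weighted_median = wm,
       preferred = if (pleio) "Egger" else "IVW",
       ivw_reliable = !pleio)
}

#' Bonferroni significance threshold over phenotype categories
#'
#' @param category_counts positive integer counts of tests per category.
#' @param alpha family-wise error rate (default 0.05).
#' @return `alpha / sum(category_counts)`.
#' @export
bonferroni_threshold <- function(category_counts, alpha = 0.05) {
  if (length(category_counts) == 0) stop("empty category list")
  if (any(category_counts <= 0)) stop("counts must be positive")
  alpha / sum(category_counts)
}
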