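## EHH / iHS -------------------------------------------------------------------

#' Extended haplotype homozygosity outward from a core site
#'
#' Among the `m` haplotypes carrying `allele` at the core, EHH at a site s is
#' the probability that two randomly drawn carriers are identical over every
#' site from the core through s: `EHH(s) = sum_g C(m_g, 2) / C(m, 2)` where
#' the m_g are the sizes of the distinct extended haplotypes. EHH starts at 1
#' at the core and is non-increasing outward.
#'
#' @param panel a derived-coded [haplotype_panel()] (complete, phased).
#' @param core site index in `panel$sites`.
#' @param allele core allele class: 1 = derived, 0 = ancestral.
#' @param side `"left"` or `"right"`.
#' @param map optional [genetic_map()] for cM distances.
#' @return data.frame: site index, pos, d_cm (|cM - cM_core|, NA without a
#'   map), ehh. The first row is the core itself (d_cm 0, ehh 1).
#' @export
ehh <- function(panel, core, allele, side = c("left", "right"), map = NULL) {
  side <- match.arg(side)
  carriers <- which(panel$haplotypes[, core] == allele)
  m <- length(carriers)
  if (m < 2) stop("fewer than 2 carriers of allele ", allele, " at the core")
  idx <- if (side == "left") rev(seq_len(core - 1)) else
    seq_len(nrow(panel$sites))[-seq_len(core)]
  pos <- panel$sites$pos
  cm <- if (!is.null(map)) interpolate_cm(map, pos, panel$sites$chrom[core]) else NULL
  denom <- choose(m, 2)
  grp <- rep(1L, m)
  out_site <- c(core, idx)
  out_ehh <- numeric(length(idx) + 1)
  out_ehh[1] <- 1
  for (i in seq_along(idx)) {
    s <- idx[i]
    grp <- as.integer(factor(paste(grp, panel$haplotypes[carriers, s])))
    out_ehh[i + 1] <- sum(choose(tabulate(grp), 2)) / denom
  }
  data.frame(site = out_site, pos = pos[out_site],
             d_cm = if (is.null(cm)) NA_real_ else abs(cm[out_site] - cm[core]),
             ehh = out_ehh)
}

## integrate one EHH curve by the trapezoid rule over cM, truncating after the
## first site where EHH < cutoff (that site closes the last trapezoid);
## returns NA when the curve never reaches the cutoff before the panel edge
integrate_ehh <- function(curve, cutoff) {
  below <- which(curve$ehh < cutoff)
  if (length(below) == 0) return(NA_real_)
  last <- below[1]
  x <- curve$d_cm[seq_len(last)]
  y <- curve$ehh[seq_len(last)]
  if (last == 1) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Unstandardized iHS at one core site
#'
#' Integrates the ancestral- and derived-allele EHH curves over genetic
#' distance on both sides of the core (trapezoid rule, truncated once EHH
#' falls below `ehh_cutoff`) and returns `ihs_raw = ln(iHH_A / iHH_D)`.
#' Negative values indicate long derived-allele haplotypes, i.e. positive
#' selection acting on the derived allele. Cores are skipped (with a status
#' reason) when the derived frequency is outside `[maf_min, 1 - maf_min]`,
#' when an allele class has fewer than 2 carriers, when an EHH curve never
#' reaches the cutoff before the panel edge, or when an integral is zero.
#'
#' @param panel derived-coded [haplotype_panel()].
#' @param map [genetic_map()].
#' @param core site index.
#' @param ehh_cutoff EHH truncation level (default 0.05).
#' @param maf_min minimum minor derived frequency (default 0.05).
#' @return one-row data.frame: pos, derived_freq, ihh_a, ihh_d, ihs_raw, status.
#' @export
ihs_core <- function(panel, map, core, ehh_cutoff = 0.05, maf_min = 0.05) {
  stopifnot(panel$coding == "derived")
  f <- panel$derived_freq[core]
  res <- data.frame(pos = panel$sites$pos[core], derived_freq = f,
                    ihh_a = NA_real_, ihh_d = NA_real_, ihs_raw = NA_real_,
                    status = "ok", stringsAsFactors = FALSE)
  if (f < maf_min || f > 1 - maf_min) { res$status <- "maf"; return(res) }
  n <- nrow(panel$haplotypes)
  if (min(f, 1 - f) * n < 2) { res$status <- "carriers"; return(res) }
  ihh <- c(a = 0, d = 0)
  for (al in c(0, 1)) {
    tot <- 0
    for (sd in c("left", "right")) {
      part <- integrate_ehh(ehh(panel, core, al, sd, map), ehh_cutoff)
      if (is.na(part)) { res$status <- "edge"; return(res) }
      tot <- tot + part
    }
    ihh[if (al == 0) "a" else "d"] <- tot
  }
  if (any(ihh == 0)) { res$status <- "degenerate"; return(res) }
  res$ihh_a <- unname(ihh["a"]); res$ihh_d <- unname(ihh["d"])
  res$ihs_raw <- unname(log(ihh["a"] / ihh["d"]))
  res
}

#' iHS over all eligible cores of a panel
#'
#' @inheritParams ihs_core
#' @param cores site indices to evaluate (default all sites).
#' @return data.frame, one row per core, as [ihs_core()].
#' @export
ihs_scan <- function(panel, map, cores = seq_len(nrow(panel$sites)),
                     ehh_cutoff = 0.05, maf_min = 0.05) {
  do.call(rbind, lapply(cores, function(i)
    ihs_core(panel, map, i, ehh_cutoff, maf_min)))
}

#' Standardize raw iHS within derived-frequency bins
#'
#' Scores are binned by derived allele frequency into `n_bins` equal-width
#' bins on `[maf_min, 1 - maf_min]`; occupied bins with fewer than
#' `min_per_bin` usable scores are merged with their nearest occupied
#' neighbor; within each final bin `ihs_std = (ihs_raw - mean) / sd`.
#'
#' @param scores data.frame from [ihs_scan()].
#' @param n_bins number of frequency bins (default 50).
#' @param min_per_bin minimum usable scores per bin before merging (default 20).
#' @param maf_min frequency floor used for the bin range.
#' @return `scores` with columns `freq_bin` and `ihs_std` added (NA for
#'   non-ok rows).
#' @export
standardize_ihs <- function(scores, n_bins = 50, min_per_bin = 20,
                            maf_min = 0.05) {
  ok <- scores$status == "ok" & !is.na(scores$ihs_raw)
  if (!any(ok)) stop("no usable iHS scores to standardize")
  breaks <- seq(maf_min, 1 - maf_min, length.out = n_bins + 1)
  bin <- findInterval(scores$derived_freq, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  bin[!ok] <- NA
  # merge under-occupied bins into the nearest occupied neighbor
  repeat {
    tab <- table(bin[ok])
    small <- names(tab)[tab < min_per_bin]
    if (length(small) == 0 || length(tab) == 1) break
    b <- as.integer(small[1])
    others <- as.integer(setdiff(names(tab), small[1]))
    target <- others[which.min(abs(others - b))]
    bin[!is.na(bin) & bin == b] <- target
  }
  if (length(unique(bin[ok])) == 1 && stats::var(scores$ihs_raw[ok]) == 0)
    stop("degenerate standardization: single bin with zero variance")
  scores$freq_bin <- bin
  scores$ihs_std <- NA_real_
  for (b in unique(bin[ok])) {
    sel <- ok & !is.na(bin) & bin == b
    mu <- mean(scores$ihs_raw[sel])
    # population (n-denominator) moments, so a bin is exactly mean 0 / sd 1
    sdev <- sqrt(mean((scores$ihs_raw[sel] - mu)^2))
    if (is.na(sdev) || sdev == 0) sdev <- 1
    scores$ihs_std[sel] <- (scores$ihs_raw[sel] - mu) / sdev
  }
  scores
}

## beta score ------------------------------------------------------------------

#' Folded beta score for balancing selection at a core SNP
#'
#' Contrasts a frequency-similarity-weighted mutation estimate with
#' Watterson's estimate around the core. For window SNPs i (within
#' `half_width` bp of the core, core excluded) with folded frequencies f_i and
#' core folded frequency f_c, the similarity weight is
#' `w_i = (1 - |f_i - f_c| / 0.5)^p`. Then
#' `theta_beta = sum(w_i) / sum_{k=1..n-1} w(fold(k/n)) / k`,
#' `theta_w = S / a_n`, and `beta = theta_beta - theta_w`. An empty window
#' yields beta = 0.
#'
#' @param panel a [haplotype_panel()] (folding makes the coding irrelevant).
#' @param core site index; must be polymorphic.
#' @param half_width window half-width in bp (default 1000).
#' @param p sharpness of the similarity weight (default 2).
#' @return list: pos, folded_freq, theta_beta, theta_w, beta, n_window.
#' @export
beta_score <- function(panel, core, half_width = 1000, p = 2) {
  n <- nrow(panel$haplotypes)
  freq <- panel$derived_freq
  fc <- min(freq[core], 1 - freq[core])
  if (fc == 0) stop("core site is monomorphic")
  pos <- panel$sites$pos
  win <- which(abs(pos - pos[core]) <= half_width & seq_along(pos) != core &
                 freq > 0 & freq < 1 & panel$sites$chrom == panel$sites$chrom[core])
  k <- seq_len(n - 1)
  a_n <- sum(1 / k)
  w_of <- function(f) (1 - abs(f - fc) / 0.5)^p
  denom <- sum(w_of(pmin(k / n, 1 - k / n)) / k)
  fw <- pmin(freq[win], 1 - freq[win])
  theta_beta <- if (length(win)) sum(w_of(fw)) / denom else 0
  theta_w <- length(win) / a_n
  list(pos = pos[core], folded_freq = fc, theta_beta = theta_beta,
       theta_w = theta_w, beta = theta_beta - theta_w, n_window = length(win))
}

#' Beta score over all polymorphic cores of a panel
#'
#' @inheritParams beta_score
#' @return data.frame: pos, folded_freq, theta_beta, theta_w, beta, n_window.
#' @export
beta_scan <- function(panel, half_width = 1000, p = 2) {
  poly <- which(panel$derived_freq > 0 & panel$derived_freq < 1)
  do.call(rbind, lapply(poly, function(i)
    as.data.frame(beta_score(panel, i, half_width, p))))
}

#' Flag the empirical top fraction of a score vector
#'
#' The chromosome-wide significance rule for the beta score: the threshold is
#' the `1 - fraction` quantile (package convention) and scores strictly above
#' it are flagged, so with continuous scores at most `fraction` of them flag.
#'
#' @param scores numeric scores (NA dropped for the threshold).
#' @param fraction top fraction to flag (default 0.01).
#' @param min_scores minimum number of scores for a stable quantile.
#' @return list: threshold, flagged (logical aligned to `scores`).
#' @export
empirical_top_fraction <- function(scores, fraction = 0.01, min_scores = 100) {
  v <- scores[!is.na(scores)]
  if (length(v) < min_scores)
    stop("need at least ", min_scores, " scores (got ", length(v), ")")
  thr <- pkg_quantile(v, 1 - fraction)
  list(threshold = thr, flagged = !is.na(scores) & scores > thr)
}
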