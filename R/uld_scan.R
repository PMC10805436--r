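## Genotype r2 and cluster pair tables -----------------------------------------

#' Squared Pearson correlation of two dosage vectors
#'
#' The genotype (composite) r2, computed over samples non-missing in both
#' vectors. Undefined (NA) when fewer than 3 such samples remain or either
#' vector is constant.
#'
#' @param g1,g2 dosage vectors (0/1/2, NA missing).
#' @return r2 in \[0, 1\] or NA.
#' @export
geno_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 3) return(NA_real_)
  x <- g1[ok]; y <- g2[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

## minor allele frequency per dosage column
dosage_maf <- function(d) {
  af <- colMeans(d, na.rm = TRUE) / 2
  pmin(af, 1 - af)
}

## gene label for 1-based positions against a 0-based half-open region table
gene_label <- function(chrom, pos, genes) {
  vapply(seq_along(pos), function(i) {
    hit <- genes$chrom == chrom[i] & genes$start <= (pos[i] - 1) &
      (pos[i] - 1) < genes$end
    if (any(hit)) genes$name[which(hit)[1]] else "intergenic"
  }, character(1))
}

#' All SNP-pair r2 within a gene cluster
#'
#' Keeps SNPs with minor allele frequency strictly above `maf_min`, annotates
#' each surviving SNP with the gene containing it (or "intergenic"), computes
#' r2 for every unordered pair and the genetic distance between the pair from
#' the map, and assigns each pair its 0.01 cM distance bin. Pairs with
#' undefined r2 are dropped and counted in the `n_skipped` attribute.
#'
#' @param geno a [genotype_matrix()] restricted to the cluster.
#' @param genes a [region_table()] of the cluster's genes.
#' @param map a [genetic_map()].
#' @param maf_min MAF floor; "above 0.05" is strict (default 0.05).
#' @param bin_width distance bin width in cM (default 0.01).
#' @return data.frame: pos_i, pos_j, gene_i, gene_j, r2, d_cm, bin.
#' @export
cluster_pairs <- function(geno, genes, map, maf_min = 0.05, bin_width = 0.01) {
  keep <- which(dosage_maf(geno$dosages) > maf_min)
  if (length(keep) < 2) stop("fewer than 2 SNPs survive the MAF filter")
  d <- geno$dosages[, keep, drop = FALSE]
  sites <- geno$sites[keep, , drop = FALSE]
  cm <- interpolate_cm(map, sites$pos, sites$chrom[1])
  lab <- gene_label(sites$chrom, sites$pos, genes)
  ij <- utils::combn(length(keep), 2)
  r2 <- vapply(seq_len(ncol(ij)), function(k)
    geno_r2(d[, ij[1, k]], d[, ij[2, k]]), numeric(1))
  out <- data.frame(pos_i = sites$pos[ij[1, ]], pos_j = sites$pos[ij[2, ]],
                    gene_i = lab[ij[1, ]], gene_j = lab[ij[2, ]],
                    r2 = r2, d_cm = abs(cm[ij[1, ]] - cm[ij[2, ]]))
  skipped <- is.na(out$r2)
  out <- out[!skipped, , drop = FALSE]
  out$bin <- floor(out$d_cm / bin_width)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(skipped)
  attr(out, "bin_width") <- bin_width
  out
}

## Matched windows and the distance-binned null ---------------------------------

#' Find genome-wide windows matched to a target gene cluster
#'
#' Scans a gene annotation for candidate windows that look like the target
#' cluster: one candidate `[gene.start, gene.start + L)` is anchored at every
#' gene start, and a candidate is kept iff it fully contains exactly `k`
#' genes and does not overlap any excluded region (the target cluster itself).
#' Overlapping candidates are all retained.
#'
#' @param genes genome-wide [region_table()] of genes.
#' @param L window length in bp (e.g. 430000).
#' @param k required number of fully contained genes (e.g. 6).
#' @param exclude optional [region_table()] of regions candidates must not
#'   overlap.
#' @return data.frame: chrom, start, end, anchor (gene name), n_genes.
#' @export
find_matched_windows <- function(genes, L, k, exclude = NULL) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ws <- g$start; we <- g$start + L
    same <- genes$chrom == g$chrom
    contained <- sum(same & genes$start >= ws & genes$end <= we)
    if (contained != k) return(NULL)
    if (!is.null(exclude) && nrow(exclude) > 0) {
      ov <- exclude$chrom == g$chrom & exclude$start < we & ws < exclude$end
      if (any(ov)) return(NULL)
    }
    data.frame(chrom = g$chrom, start = ws, end = we, anchor = g$name,
               n_genes = contained)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      anchor = character(), n_genes = integer())
  out
}

#' Build the distance-binned r2 null from matched-window pairs
#'
#' Pools SNP-pair r2 values from cluster-matched windows, bins them by genetic
#' distance (`floor(d_cm / bin_width)`), and records the per-bin `percentile`
#' r2 threshold. Bins with fewer than `min_pairs` pairs get no threshold (a
#' 99th percentile from a handful of pairs is noise).
#'
#' @param pairs pair table (needs `r2` and `d_cm`), e.g. pooled
#'   [cluster_pairs()] output over matched windows.
#' @param bin_width bin width in cM (default 0.01).
#' @param percentile threshold percentile (default 0.99).
#' @param min_pairs minimum pairs per bin for a defined threshold.
#' @return object of class `distance_binned_null`: bin_width, percentile and a
#'   `bins` data.frame (bin, bin_start_cm, n_pairs, threshold).
#' @export
build_binned_null <- function(pairs, bin_width = 0.01, percentile = 0.99,
                              min_pairs = 100) {
  ok <- !is.na(pairs$r2) & !is.na(pairs$d_cm)
  bin <- floor(pairs$d_cm[ok] / bin_width)
  r2 <- pairs$r2[ok]
  ub <- sort(unique(bin))
  bins <- do.call(rbind, lapply(ub, function(b) {
    v <- r2[bin == b]
    data.frame(bin = b, bin_start_cm = b * bin_width, n_pairs = length(v),
               threshold = if (length(v) >= min_pairs) pkg_quantile(v, percentile)
                           else NA_real_)
  }))
  if (is.null(bins) || all(is.na(bins$threshold)))
    stop("no distance bin has enough pairs (min_pairs = ", min_pairs,
         ") to define a threshold")
  structure(list(bin_width = bin_width, percentile = percentile,
                 min_pairs = min_pairs, bins = bins),
            class = "distance_binned_null")
}

#' Flag unusual LD against a distance-binned null
#'
#' A pair is flagged iff its distance bin has a defined threshold and its r2
#' strictly exceeds it. Pairs in bins without a threshold (or beyond the
#' null's largest covered bin) are never flagged; they are counted as
#' uncovered.
#'
#' @param pairs pair table from [cluster_pairs()].
#' @param null a [build_binned_null()] result.
#' @return `pairs` with `threshold` and `flagged` columns, plus a `summary`
#'   attribute: n_pairs, n_flagged, fraction, n_uncovered, and per gene-pair
#'   flagged counts.
#' @export
flag_uld <- function(pairs, null) {
  stopifnot(inherits(null, "distance_binned_null"))
  bin <- floor(pairs$d_cm / null$bin_width)
  thr <- null$bins$threshold[match(bin, null$bins$bin)]
  flagged <- !is.na(thr) & !is.na(pairs$r2) & pairs$r2 > thr
  pairs$bin <- bin
  pairs$threshold <- thr
  pairs$flagged <- flagged
  gp <- if (all(c("gene_i", "gene_j") %in% names(pairs)) && any(flagged)) {
    key <- apply(cbind(pairs$gene_i, pairs$gene_j)[flagged, , drop = FALSE], 1,
                 function(x) paste(sort(x), collapse = "--"))
    as.data.frame(table(gene_pair = key), stringsAsFactors = FALSE)
  } else data.frame(gene_pair = character(), Freq = integer())
  attr(pairs, "summary") <- list(
    n_pairs = nrow(pairs), n_flagged = sum(flagged),
    fraction = if (nrow(pairs)) sum(flagged) / nrow(pairs) else NA_real_,
    n_uncovered = sum(is.na(thr)), gene_pairs = gp)
  pairs
}

#' Subset flagged pairs touching a named gene
#'
#' The replication step: keep pairs where exactly one (`mode = "one"`) or at
#' least one (`mode = "either"`) endpoint lies in `gene`.
#'
#' @param pairs flagged pair table (from [flag_uld()]); only rows with
#'   `flagged = TRUE` are considered when a `flagged` column is present.
#' @param gene gene name.
#' @param genes optional [region_table()] used to validate `gene`; when given,
#'   an unknown name is an error.
#' @param mode `"one"` or `"either"`.
#' @return the matching subset of `pairs`.
#' @export
extract_pairs_by_gene <- function(pairs, gene, genes = NULL,
                                  mode = c("one", "either")) {
  mode <- match.arg(mode)
  if (!is.null(genes) && !gene %in% genes$name)
    stop("unknown gene name: ", gene)
  if ("flagged" %in% names(pairs)) pairs <- pairs[pairs$flagged, , drop = FALSE]
  in_i <- pairs$gene_i == gene
  in_j <- pairs$gene_j == gene
  keep <- if (mode == "one") xor(in_i, in_j) else (in_i | in_j)
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
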