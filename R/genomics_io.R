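## Containers ----------------------------------------------------------------

#' Site table constructor
#'
#' A site table holds per-SNP metadata shared by all containers: chromosome,
#' 1-based physical position, REF/ALT alleles, the ancestral state relative to
#' the REF/ALT coding, and a mask flag. Sites must be sorted by (chrom, pos)
#' with no duplicate positions within a chromosome, and strictly biallelic.
#'
#' @param chrom,pos,ref,alt vectors of equal length; `pos` is 1-based bp.
#' @param ancestral one of `"ref"`, `"alt"`, `"unknown"` per site.
#' @param masked logical per site.
#' @return a `data.frame` with columns chrom, pos, ref, alt, ancestral, masked.
#' @export
site_table <- function(chrom, pos, ref, alt,
                       ancestral = rep("unknown", length(pos)),
                       masked = rep(FALSE, length(pos))) {
  pos <- as.integer(pos)
  chrom <- rep_len(chrom, length(pos))
  stopifnot(length(ref) == length(pos), length(alt) == length(pos))
  if (length(pos) > 0) {
    if (any(pos < 1)) stop("site positions must be >= 1")
    if (any(ref == alt)) stop("ref and alt alleles must differ")
    o <- order(chrom, pos)
    if (any(o != seq_along(pos))) stop("sites must be sorted by (chrom, pos)")
    if (anyDuplicated(paste(chrom, pos))) stop("duplicate site positions")
  }
  if (!all(ancestral %in% c("ref", "alt", "unknown")))
    stop("ancestral must be 'ref', 'alt' or 'unknown'")
  data.frame(chrom = as.character(chrom), pos = pos,
             ref = as.character(ref), alt = as.character(alt),
             ancestral = ancestral, masked = as.logical(masked),
             stringsAsFactors = FALSE)
}

#' Genotype matrix container
#'
#' Samples x sites dosage matrix (count of ALT alleles, 0/1/2, `NA` missing)
#' plus a site table and a sample-to-population map.
#'
#' @param sites site table (see [site_table()]).
#' @param dosages integer matrix, samples in rows, sites in columns.
#' @param populations named character vector mapping sample id to population.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, dosages, populations = NULL) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(sites))
    stop("dosage columns (", ncol(dosages), ") != sites (", nrow(sites), ")")
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("sample", seq_len(nrow(dosages)))
  samples <- rownames(dosages)
  if (is.null(populations)) {
    populations <- stats::setNames(rep("pop1", length(samples)), samples)
  }
  if (!all(samples %in% names(populations)))
    stop("every sample needs a population label")
  ok <- is.na(dosages) | dosages %in% 0:2
  if (!all(ok)) stop("dosages must be in {0,1,2} or NA")
  structure(list(sites = sites, dosages = dosages,
                 samples = samples,
                 populations = populations[samples]),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x", nrow(x$sites),
      "sites;", length(unique(x$populations)), "population(s)\n")
  invisible(x)
}

#' Haplotype panel container
#'
#' 2N x sites binary matrix of phased haplotypes with no missing entries.
#' `coding` records whether 1 means the ALT allele (as read from a VCF) or the
#' derived allele (after [polarize_ancestral()]); haplotype-based statistics
#' (EHH/iHS) require `coding = "derived"`.
#'
#' @param sites site table.
#' @param haplotypes 0/1 matrix, haplotypes in rows.
#' @param coding `"alt"` or `"derived"`.
#' @return object of class `haplotype_panel` with a `derived_freq` element
#'   equal to the per-site column mean.
#' @export
haplotype_panel <- function(sites, haplotypes, coding = c("alt", "derived")) {
  coding <- match.arg(coding)
  haplotypes <- as.matrix(haplotypes)
  if (ncol(haplotypes) != nrow(sites)) stop("haplotype columns != sites")
  if (anyNA(haplotypes)) stop("haplotype panels must be complete (no missing)")
  if (!all(haplotypes %in% 0:1)) stop("haplotypes must be 0/1")
  if (coding == "derived" && any(sites$ancestral == "unknown"))
    stop("derived-coded panels may not contain sites with unknown ancestral state")
  structure(list(sites = sites, haplotypes = haplotypes,
                 derived_freq = unname(colMeans(haplotypes)),
                 coding = coding),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", nrow(x$haplotypes), "haplotypes x", nrow(x$sites),
      "sites; coding =", x$coding, "\n")
  invisible(x)
}

#' Region table constructor
#'
#' BED-convention interval table: 0-based half-open `[start, end)`. Used for
#' gene annotations, scan regions, and repeat/mappability masks.
#'
#' @param name unique region names.
#' @param chrom,start,end interval coordinates, `start < end`.
#' @param class optional feature class (`"gene"`, `"pseudogene"`, `"mask"`).
#' @return a `data.frame` with columns name, chrom, start, end, class.
#' @export
region_table <- function(name, chrom, start, end, class = "gene") {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start >= end)) stop("regions must satisfy start < end")
  if (anyDuplicated(name)) stop("region names must be unique")
  data.frame(name = as.character(name), chrom = as.character(chrom),
             start = start, end = end,
             class = rep_len(as.character(class), length(name)),
             stringsAsFactors = FALSE)
}

## VCF -----------------------------------------------------------------------

## keep only biallelic SNP records: single-base REF and ALT, no comma ALT,
## and drop *all* records at a position that appears more than once
biallelic_snp_rows <- function(fix) {
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt, fixed = TRUE) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  key <- paste(fix[, "CHROM"], fix[, "POS"])
  snp & !(key %in% key[duplicated(key)])
}

#' Read a genotype matrix from a VCF file
#'
#' Keeps only biallelic SNPs (indels, multiallelic records and duplicated
#' positions are dropped), optionally restricted to a region and a sample
#' subset. Missing genotypes are kept as `NA` dosages. If the INFO field
#' carries `AA=` ancestral-allele annotations they populate the ancestral
#' state (case-insensitively; low-confidence lowercase calls are accepted).
#'
#' @param path VCF file (plain or gzipped).
#' @param chrom,start,end optional region restriction; `start`/`end` are
#'   0-based half-open and require `chrom`.
#' @param samples optional character vector of sample ids to keep; an unknown
#'   id is an error.
#' @param populations optional named vector sample -> population.
#' @return a [genotype_matrix()].
#' @export
read_vcf_region <- function(path, chrom = NULL, start = NULL, end = NULL,
                            samples = NULL, populations = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fix[is.na(fix[, "INFO"]), "INFO"] <- "."
  keep <- biallelic_snp_rows(fix)
  if (!is.null(chrom)) {
    if (!any(fix[, "CHROM"] == chrom))
      stop("chromosome not present in VCF: ", chrom)
    keep <- keep & fix[, "CHROM"] == chrom
    pos <- as.integer(fix[, "POS"])
    if (!is.null(start)) keep <- keep & (pos - 1L) >= start
    if (!is.null(end)) keep <- keep & (pos - 1L) < end
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, ncol = ncol(v@gt) - 1L,
                                     dimnames = list(NULL, colnames(v@gt)[-1]))
  all_samples <- colnames(gt)
  if (is.null(samples)) samples <- all_samples
  missing_samples <- setdiff(samples, all_samples)
  if (length(missing_samples) > 0)
    stop("samples not in VCF header: ", paste(missing_samples, collapse = ", "))
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, samples, drop = FALSE]

  anc <- rep("unknown", nrow(fix))
  info <- fix[, "INFO"]
  aa <- toupper(sub(".*AA=([^;,|]+).*", "\\1", info))
  has_aa <- grepl("(^|;)AA=", info)
  anc[has_aa & aa == toupper(fix[, "REF"])] <- "ref"
  anc[has_aa & aa == toupper(fix[, "ALT"])] <- "alt"

  sites <- site_table(fix[, "CHROM"], as.integer(fix[, "POS"]),
                      fix[, "REF"], fix[, "ALT"], ancestral = anc)
  alleles <- gt_to_alleles(gt)
  dos <- t(alleles$a1 + alleles$a2)
  rownames(dos) <- samples
  attr_phased <- all(alleles$phased) && !anyNA(dos)
  g <- genotype_matrix(sites, dos, populations)
  attr(g, "phased") <- attr_phased
  if (attr_phased) {
    haps <- matrix(0L, nrow = 2L * length(samples), ncol = nrow(sites))
    haps[seq(1, 2 * length(samples), 2), ] <- t(alleles$a1)
    haps[seq(2, 2 * length(samples), 2), ] <- t(alleles$a2)
    rownames(haps) <- paste0(rep(samples, each = 2), c("_1", "_2"))
    attr(g, "haplotypes") <- haplotype_panel(sites, haps, coding = "alt")
  }
  g
}

## split GT strings ("0|1", "0/1", ".") into two allele matrices + phased flag
gt_to_alleles <- function(gt) {
  a1 <- sub("[|/].*", "", gt)
  a2 <- ifelse(grepl("[|/]", gt), sub(".*[|/]", "", gt), a1)
  phased <- grepl("|", gt, fixed = TRUE)
  num <- function(x) {
    x[x == "." | is.na(x)] <- NA
    out <- suppressWarnings(as.integer(x))
    dim(out) <- dim(gt)
    out
  }
  list(a1 = num(a1), a2 = num(a2), phased = phased | !grepl("/", gt, fixed = TRUE))
}

#' Extract the phased haplotype panel attached to a genotype matrix
#'
#' @param geno a [genotype_matrix()] read from a fully phased, complete VCF.
#' @return a [haplotype_panel()] with ALT coding.
#' @export
vcf_haplotypes <- function(geno) {
  h <- attr(geno, "haplotypes")
  if (is.null(h))
    stop("genotypes are not fully phased/complete; haplotype stages need phased data")
  h
}

#' Write a genotype matrix to VCF
#'
#' Inverse of [read_vcf_region()] for round-trip use and for handing synthetic
#' data to the same I/O path real data takes. Haplotype panels are written
#' phased (`a|b`); genotype matrices unphased (`a/b`, `./.` for missing).
#'
#' @param x a [genotype_matrix()] or [haplotype_panel()].
#' @param path output file; vcfR writes gzipped VCF.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(x, path) {
  if (inherits(x, "haplotype_panel")) {
    n <- nrow(x$haplotypes) / 2
    samples <- paste0("sample", seq_len(n))
    a1 <- x$haplotypes[seq(1, 2 * n, 2), , drop = FALSE]
    a2 <- x$haplotypes[seq(2, 2 * n, 2), , drop = FALSE]
    gtm <- matrix(paste0(t(a1), "|", t(a2)), nrow = nrow(x$sites))
    sites <- x$sites
  } else {
    samples <- x$samples
    d <- t(x$dosages)
    gtm <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
    gtm[!is.na(d) & d == 0] <- "0/0"
    gtm[!is.na(d) & d == 1] <- "0/1"
    gtm[!is.na(d) & d == 2] <- "1/1"
    sites <- x$sites
  }
  colnames(gtm) <- samples
  info <- ifelse(sites$ancestral == "unknown", ".",
                 paste0("AA=", ifelse(sites$ancestral == "ref", sites$ref, sites$alt)))
  fix <- cbind(CHROM = sites$chrom, POS = as.character(sites$pos), ID = ".",
               REF = sites$ref, ALT = sites$alt, QUAL = ".", FILTER = "PASS",
               INFO = info)
  gt <- cbind(FORMAT = "GT", gtm)
  meta <- c("##fileformat=VCFv4.2",
            "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  v <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                    meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

## Polarization and masking --------------------------------------------------

#' Polarize a haplotype panel to ancestral/derived coding
#'
#' Recodes an ALT-coded panel so that 1 means the derived allele: sites whose
#' ancestral call equals REF keep their coding, sites whose ancestral call
#' equals ALT are flipped, and sites whose call matches neither allele (or is
#' missing/unknown) are dropped and counted in the `n_dropped` attribute.
#' Lowercase (low-confidence) calls are treated as valid.
#'
#' @param panel an ALT- or derived-coded [haplotype_panel()].
#' @param ancestral character vector of ancestral bases aligned to
#'   `panel$sites` (`NA`, `"."`, `"-"` or `"N"` mean unknown).
#' @return a derived-coded [haplotype_panel()].
#' @export
polarize_ancestral <- function(panel, ancestral) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (length(ancestral) != nrow(panel$sites))
    stop("ancestral calls (", length(ancestral), ") do not align to sites (",
         nrow(panel$sites), ")")
  anc <- toupper(as.character(ancestral))
  anc[is.na(anc) | anc %in% c(".", "-", "N", "")] <- "unknown"
  is_ref <- anc == toupper(panel$sites$ref)
  is_alt <- anc == toupper(panel$sites$alt)
  keep <- is_ref | is_alt
  haps <- panel$haplotypes[, keep, drop = FALSE]
  flip <- is_alt[keep]
  haps[, flip] <- 1L - haps[, flip]
  sites <- panel$sites[keep, , drop = FALSE]
  sites$ancestral <- ifelse(flip, "alt", "ref")
  rownames(sites) <- NULL
  out <- haplotype_panel(sites, haps, coding = "derived")
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Remove sites falling in masked intervals
#'
#' Intervals are 0-based half-open; a site at 1-based position `pos` is masked
#' when `pos - 1` lies in any interval on its chromosome. With an empty mask
#' this is the identity.
#'
#' @param sites a site table.
#' @param mask a [region_table()] of masked intervals.
#' @return the surviving rows of `sites`, order preserved, with an `n_masked`
#'   attribute.
#' @export
apply_mask <- function(sites, mask) {
  if (is.null(mask) || nrow(mask) == 0) {
    attr(sites, "n_masked") <- 0L
    return(sites)
  }
  hit <- vapply(seq_len(nrow(sites)), function(i) {
    p0 <- sites$pos[i] - 1L
    any(mask$chrom == sites$chrom[i] & mask$start <= p0 & p0 < mask$end)
  }, logical(1))
  out <- sites[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_masked") <- sum(hit)
  out
}

#' Subset a container to a set of site positions
#'
#' @param x [genotype_matrix()] or [haplotype_panel()].
#' @param keep logical vector over sites, or a site table (as returned by
#'   [apply_mask()]) whose (chrom, pos) rows define the survivors.
#' @return the subsetted container.
#' @export
subset_sites <- function(x, keep) {
  if (is.data.frame(keep)) {
    keep <- paste(x$sites$chrom, x$sites$pos) %in% paste(keep$chrom, keep$pos)
  }
  sites <- x$sites[keep, , drop = FALSE]
  rownames(sites) <- NULL
  if (inherits(x, "genotype_matrix")) {
    genotype_matrix(sites, x$dosages[, keep, drop = FALSE], x$populations)
  } else {
    haplotype_panel(sites, x$haplotypes[, keep, drop = FALSE], coding = x$coding)
  }
}

## Genetic maps --------------------------------------------------------------

#' Genetic map constructor
#'
#' @param chrom,pos,cm map points: physical position (bp, strictly increasing
#'   within a chromosome) and cumulative genetic position (cM, non-decreasing).
#' @return object of class `genetic_map` (a data.frame chrom/pos/cm).
#' @export
genetic_map <- function(chrom, pos, cm) {
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   cm = as.numeric(cm), stringsAsFactors = FALSE)
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (is.unsorted(sub$pos, strictly = TRUE))
      stop("map positions must be strictly increasing on chromosome ", ch)
    if (is.unsorted(sub$cm)) stop("cM must be non-decreasing on chromosome ", ch)
  }
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' Read a genetic map file
#'
#' Accepts the PLINK-style dialects: 4 columns (chrom, pos, rate, cM),
#' 3 columns (pos, rate, cM) or 2 columns (pos, cM); a non-numeric first line
#' is treated as a header.
#'
#' @param path map text file.
#' @param chrom chromosome label to assign when the file carries none.
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path, chrom = "1") {
  first <- readLines(path, n = 1)
  f1 <- strsplit(trimws(first), "[\t ]+")[[1]]
  header <- anyNA(suppressWarnings(as.numeric(f1[-1]))) ||
    (length(f1) < 4 && anyNA(suppressWarnings(as.numeric(f1))))
  tab <- utils::read.table(path, header = header, stringsAsFactors = FALSE)
  if (ncol(tab) == 4) {
    genetic_map(tab[[1]], tab[[2]], tab[[4]])
  } else if (ncol(tab) == 3) {
    genetic_map(chrom, tab[[1]], tab[[3]])
  } else if (ncol(tab) == 2) {
    genetic_map(chrom, tab[[1]], tab[[2]])
  } else stop("unrecognized genetic-map layout: ", ncol(tab), " columns")
}

#' Interpolate genetic position (cM) at physical positions
#'
#' Linear interpolation between flanking map points; positions beyond the map
#' ends are clamped to the nearest endpoint's cM (constant extrapolation, so
#' distances never become negative or extrapolate beyond observed
#' recombination).
#'
#' @param map a [genetic_map()].
#' @param pos bp positions (vectorized).
#' @param chrom chromosome label (single value).
#' @return cM positions.
#' @export
interpolate_cm <- function(map, pos, chrom = map$chrom[1]) {
  sub <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(sub) == 0) stop("no map points for chromosome ", chrom)
  if (nrow(sub) == 1) return(rep(sub$cm, length(pos)))
  stats::approx(sub$pos, sub$cm, xout = pos, rule = 2, ties = "ordered")$y
}

## Annotations and panels ----------------------------------------------------

#' Read BED intervals as a region table
#'
#' @param path BED file (3+ columns).
#' @param class feature class to assign.
#' @return a [region_table()] (BED is natively 0-based half-open).
#' @export
read_bed_regions <- function(path, class = "mask") {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- if (!is.null(gr$name) && !anyNA(gr$name)) as.character(gr$name)
        else sprintf("region%04d", seq_along(gr))
  region_table(nm, as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
               class = class)
}

#' Read gene features from a GTF annotation
#'
#' Keeps `gene` feature rows; names come from `gene_name`, falling back to
#' `gene_id`. GTF 1-based closed intervals are converted to the package's
#' 0-based half-open convention at this boundary.
#'
#' @param path GTF file (Ensembl dialect).
#' @return a [region_table()] of genes.
#' @export
read_gtf_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "GTF")
  gr <- gr[gr$type == "gene"]
  nm <- if (!is.null(gr$gene_name)) as.character(gr$gene_name) else NULL
  if (is.null(nm) || anyNA(nm)) nm <- as.character(gr$gene_id)
  region_table(make.unique(nm), as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
               class = "gene")
}

#' Read a population panel TSV (sample, pop, super_pop)
#'
#' @param path tab-separated panel with a header line.
#' @return data.frame with columns sample, pop, super_pop.
#' @export
read_population_panel <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(tab)[1:2] <- c("sample", "pop")
  if (ncol(tab) >= 3) names(tab)[3] <- "super_pop" else tab$super_pop <- tab$pop
  tab[, c("sample", "pop", "super_pop")]
}
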