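#!/usr/bin/env Rscript
# Build the synthetic study inputs every later step consumes, through the
# same file formats real cohort data would arrive in:
#   - cohort.vcf.gz  : 4-population structured genotypes (Balding-Nichols,
#                      F = 0.1) over the 6-gene target cluster -- the FST,
#                      uLD and eQTL material
#   - neutral.vcf.gz : 60 Kb of neutral coalescent windows (theta = 10/Kb),
#                      phased -- the Tajima's D material
#   - panel.tsv, map.txt, genes.tsv : population panel, 1 cM/Mb genetic map,
#                      and a gene annotation with the target cluster plus two
#                      decoy 6-gene clusters for the matched-window search

suppressMessages(library(coevscan))

seed <- 20260926L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Simulating a 4-population cohort (Balding-Nichols, F = 0.1) ...")
bn <- sim_balding_nichols(F = 0.1, n_pops = 4, n_diploids = 100,
                          n_sites = 600, seed = seed)
write_genotype_vcf(bn$genotypes, file.path(out, "cohort.vcf.gz"))
panel <- data.frame(sample = bn$genotypes$samples,
                    pop = unname(bn$genotypes$populations),
                    super_pop = unname(bn$genotypes$populations))
write.table(panel, file.path(out, "panel.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

message("Simulating 60 neutral 1 Kb coalescent windows (n = 100, theta = 10) ...")
nt <- sim_neutral_windows(n_chrom = 100, theta = 10, n_windows = 60,
                          seed = seed + 10)
offset <- 0L
parts <- lapply(nt$panels, function(p) {
  s <- p$sites
  s$pos <- s$pos + offset
  offset <<- offset + 1000L
  list(sites = s, haps = p$haplotypes)
})
sites <- do.call(rbind, lapply(parts, `[[`, "sites"))
rownames(sites) <- NULL
neutral <- haplotype_panel(sites, do.call(cbind, lapply(parts, `[[`, "haps")),
                           coding = "derived")
write_genotype_vcf(neutral, file.path(out, "neutral.vcf.gz"))

# uniform 1 cM/Mb map over the simulated region
map <- data.frame(chrom = "1", pos = c(0, 100000), rate = 1, cm = c(0, 0.1))
write.table(map, file.path(out, "map.txt"), sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)

# target cluster: 6 genes of 5 Kb every 10 Kb; two decoy clusters with the
# same geometry elsewhere, so the matched-window search has true matches
cluster_geom <- function(base) cbind(start = base + seq(0, 50000, 10000),
                                     end = base + seq(5000, 55000, 10000))
g1 <- cluster_geom(1000); g2 <- cluster_geom(200000); g3 <- cluster_geom(300000)
genes <- region_table(
  name = c(paste0("CLU", 1:6), paste0("DECA", 1:6), paste0("DECB", 1:6)),
  chrom = "1",
  start = c(g1[, 1], g2[, 1], g3[, 1]),
  end = c(g1[, 2], g2[, 2], g3[, 2]))
write.table(genes, file.path(out, "genes.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

message("Inputs written under ", out, ": cohort.vcf.gz, neutral.vcf.gz, ",
        "panel.tsv, map.txt, genes.tsv")
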