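#!/usr/bin/env Rscript
# Causal-effect estimation from summary statistics: instrument selection
# (F > 10, p < 0.001, greedy r2 > 0.8 pruning), then IVW with an LD
# correlation matrix, MR-Egger for directional pleiotropy, and the weighted
# median as sensitivity test. The PheWAS multiplicity arithmetic is also
# reproduced from the printed category counts.

suppressMessages(library(coevscan))

seed <- 20260926L
dir.create("results", showWarnings = FALSE)

# synthetic exposure associations for 15 candidate instruments
d <- sim_mr_dataset(n_instruments = 15, causal_beta = 0.3,
                    rho = 0.2 + 0.8 * diag(15), seed = seed + 7)
inp <- d$input
assoc <- data.frame(snp = inp$snp, b_x = inp$b_x, se_x = inp$se_x,
                    p_x = 2 * pnorm(-abs(inp$b_x / inp$se_x)))
ld <- inp$rho^2
dimnames(ld) <- list(inp$snp, inp$snp)
sel <- select_instruments(assoc, ld, f_min = 10, p_max = 0.001, r2_max = 0.8)
message(sprintf("Instruments: %d/%d survive F/p/LD selection", nrow(sel),
                nrow(assoc)))

keep <- match(sel$snp, inp$snp)
pruned <- mr_input(inp$snp[keep], inp$b_x[keep], inp$se_x[keep],
                   inp$b_y[keep], inp$se_y[keep], inp$rho[keep, keep])
report <- mr_report(pruned, n_boot = 1000, seed = seed + 8)

res <- data.frame(
  method = c("IVW", "Egger", "WeightedMedian"),
  beta = c(report$ivw$beta, report$egger$beta, report$weighted_median$beta),
  se = c(report$ivw$se, report$egger$se, report$weighted_median$se),
  ci_low = c(report$ivw$ci95[1], report$egger$ci95[1],
             report$weighted_median$ci95[1]),
  ci_high = c(report$ivw$ci95[2], report$egger$ci95[2],
              report$weighted_median$ci95[2]),
  p = c(report$ivw$p, report$egger$p, report$weighted_median$p))
write.table(res, "results/mr_results.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(res, row.names = FALSE)
message(sprintf("True causal effect 0.3; Egger intercept p = %.3f -> report %s",
                report$egger$intercept_p, report$preferred))
message(sprintf("PheWAS Bonferroni threshold: %.3g (777 phenotype tests)",
                bonferroni_threshold(c(90, 11, 603, 62, 11))))
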