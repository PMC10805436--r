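---
title: "Selection scans and co-evolution detection in gene clusters: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection scans and co-evolution detection in gene clusters: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevscan)
```

# What the package computes

Tandemly duplicated gene families — the cytochrome P450 clusters (CYP3A on
chromosome 7, CYP4F on chromosome 19) are the motivating case — sit at the
crossroads of several evolutionary forces: recent positive selection on
individual variants, long-term balancing selection maintaining intermediate
frequencies, and possible co-evolution between paralogs that manifests as
linkage disequilibrium far in excess of what their genetic distance predicts.
`coevscan` implements the full chain of analyses needed to interrogate such a
cluster from population genotype data:

1. windowed **Tajima's D** with an empirical null and two-sided outlier
   calling;
2. per-site **Weir–Cockerham FST** across populations with per-gene
   summaries;
3. the **EHH/iHS** haplotype scan for recent positive selection;
4. the folded **β score** for balancing selection with chromosome-wide
   empirical significance;
5. the **unusual-LD (uLD)** co-evolution detector: genotype r² between SNP
   pairs of the cluster, judged against a genetic-distance-binned 99th
   percentile null built from cluster-matched windows elsewhere in the
   genome;
6. a per-SNP **eQTL** linear-model scan with covariate adjustment;
7. **Mendelian randomization** (IVW, MR-Egger, weighted median) with
   LD-correlated instruments, plus the Bonferroni arithmetic for a
   phenome-wide association follow-up.

Every stage is exercised end to end on synthetic data with known truth; the
generators are part of the package, not test fixtures.

# Models and estimators

## Tajima's D

For a window with `S` segregating sites among `n` chromosomes, per-site
pairwise diversity is accumulated as
`pi = sum_j 2 k_j (n_j - k_j) / (n_j (n_j - 1))` with `k_j` the alternate
(or derived) allele count and `n_j` the per-site number of observed
chromosomes, and

```
D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1))
```

with the standard constants `a1 = sum 1/i`, `a2 = sum 1/i^2`,
`b1 = (n+1)/(3(n-1))`, `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
`c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`, `e2 = c2/(a1^2+a2)`.
`D` is undefined (flagged, never an exception) when `S = 0`, when `n < 3`
(at `n = 2` the variance constants collapse to zero), or when the variance
is non-positive. With missing genotypes the per-site `n_j` varies; the
window's constants use the rounded median of the per-site `n_j`, and windows
with more than 10% missing entries are excluded from calling and counted.
This missingness rule is declared rather than inherited: window-based tools
differ silently on this point.

Outlier calling is fully empirical: window values from designated null
regions (in the original design, gene-associated windows of a reference
chromosome; in the synthetic pipeline, neutral coalescent windows) give the
2.5th and 97.5th percentiles, and a test window flags `low`/`high` only if
it *strictly* exceeds a bound — ties are not significant, which keeps the
two-sided false-positive rate at or below the nominal 5%.

## Weir–Cockerham FST

Per site, with `r` populations of `n_i` diploids, allele frequency `p_i` and
observed heterozygote proportion `h_i`, the three variance components
(among-population `a`, among-individual `b`, within-individual `c`) follow
the diploid single-locus estimator, and `FST = a/(a+b+c)`, undefined when
the site is monomorphic everywhere. Two aggregations are offered and they
are *not* interchangeable:

* `gene_mean()` — the raw arithmetic mean of per-site ratios over a gene,
  negatives retained. This matches how per-gene FST rankings are built, but
  it is Jensen-biased low as an estimate of the underlying fixation index.
* `wc_fst_global()` — `sum(a) / sum(a+b+c)`, the standard multi-locus
  combination; this is what recovers a simulated `F` and what the
  calibration checks use.

On Balding–Nichols simulations with four populations of 200 diploids and
1,000 sites, `wc_fst_global()` recovers `F` in {0.01, 0.1, 0.3} within
±0.02.

## EHH and iHS

Among the `m` carriers of an allele at a core SNP, EHH at site `s` is the
probability that two random carriers are identical at every site from the
core through `s`: `EHH(s) = sum_g C(m_g,2) / C(m,2)` over the distinct
extended haplotypes. iHS integrates the EHH curve over genetic distance
(trapezoid rule on cM from the genetic map) separately for ancestral- and
derived-allele carriers and on both sides of the core, truncating once EHH
falls below 0.05 (the truncating site closes the last trapezoid):
`ihs_raw = ln(iHH_A / iHH_D)`. Negative values mean unusually long derived
haplotypes — positive selection on the derived allele; `|iHS| >= 2` after
standardization is the conventional candidate threshold.

Numerical choices, all configurable and none dictated by theory:

* EHH cutoff 0.05 and MAF floor 0.05 (common defaults in haplotype-scan
  tools);
* cores whose EHH never reaches the cutoff before the panel edge are
  **skipped** (status `edge`), not truncated — truncation biases iHH
  downward on exactly the long haplotypes the scan looks for; this is a
  deliberate divergence from tools that integrate to the edge;
* standardization within 50 equal-width derived-frequency bins on
  [0.05, 0.95]; occupied bins with fewer than 20 usable scores merge into
  their nearest occupied neighbor; bin moments use the population
  (n-denominator) convention so a standardized bin is exactly mean 0, sd 1;
* ancestral polarization is an input (ancestral calls per site); sites whose
  call matches neither allele are dropped and counted, and lowercase
  (low-confidence) calls are accepted as valid — a declared choice where
  upstream pipelines are silent.

## β score

The folded β(1) statistic contrasts a frequency-similarity-weighted mutation
estimate with Watterson's estimate around a core SNP. With folded
frequencies `f_i = min(f, 1-f)`, window sites within 1,000 bp of the core
(core excluded) get weights `w_i = (1 - |f_i - f_c|/0.5)^p` (sharpness
`p = 2` by default); then `theta_beta = sum(w_i) / sum_k w(fold(k/n))/k`,
`theta_w = S/a_n`, `beta = theta_beta - theta_w`. An empty window gives
β = 0; a monomorphic core is an error. Window half-width and `p` are
declared defaults — analyses that consume consortium-precomputed scores
never state them — and significance is chromosome-wide empirical: scores
strictly above the top-1% quantile flag, so at most 1% of neutral cores can
ever flag.

## Unusual LD

Within a cluster, all SNP pairs with MAF strictly above 0.05 get genotype
r² (squared Pearson correlation of dosages, the `geno-r2` convention,
computed over samples non-missing in both; undefined for constant vectors or
fewer than 3 complete pairs) and a genetic distance `d_cm` interpolated from
the map. The null is built from *matched windows*: the genome-wide gene
annotation is screened for windows of the cluster's length containing
exactly the cluster's gene count — candidates are anchored at every gene
start, containment (not overlap) counts, overlapping candidates are all
kept, and windows overlapping the target cluster are excluded. Pooled
matched-window pairs are binned by `floor(d_cm / 0.01)` and each bin with at
least 100 pairs records its 99th-percentile r². A cluster pair is in uLD iff
its bin has a threshold and its r² strictly exceeds it; pairs beyond the
null's covered range are never flagged, only counted. With held-out pairs
drawn from the null's own distribution the flagged fraction sits in
[0.005, 0.015], and planted pairs with r² above their bin's extreme tail are
caught at ≥95%.

The anchoring rule (gene starts) is the one genuinely open design point —
sliding or tiling would also be defensible; anchoring is deterministic,
reproducible, and its sensitivity is testable by perturbing the annotation.

## eQTL scan

One ordinary least squares fit per (SNP, gene, tissue): expression on dosage
plus the covariate matrix as given (principal components, PEER factors, age,
sex, batch covariates are upstream inputs, not computations — re-deriving
them is out of scope). The reported effect is per non-reference allele; the
genome-wide threshold 1e-8 is applied verbatim with no FDR machinery. Rank
deficiency (a constant genotype, collinear covariates) is an error naming
the offending column rather than a silent NA.

## Mendelian randomization

Instruments are selected by strength `F = (b_X/se_X)^2 > 10` and exposure
`p < 0.001` (0.05/50 tissues), then pruned greedily by ascending p-value
dropping any SNP with `r² > 0.8` against a kept one. With instrument LD
correlation ρ and outcome covariance `Omega = se_Y se_Y' ∘ ρ`:

* **IVW**: `beta = (b_X' W b_X)^{-1} b_X' W b_Y`, `W = Omega^{-1}`;
  fixed-effect `se = sqrt((b_X' W b_X)^{-1})` by default, with an optional
  multiplicative random-effects inflation `max(1, sqrt(Q/(J-1)))`. With
  ρ = I this reduces exactly to the textbook `sum(w beta_j)/sum(w)` with
  `w = b_X^2/se_Y^2`.
* **MR-Egger**: GLS of `b_Y` on `[1, b_X]` with weight `W`, after orienting
  instruments so exposure effects are positive (Egger is not invariant to
  allele coding). The intercept tests directional pleiotropy; if its p is
  below 0.05 the report marks IVW unreliable and foregrounds Egger.
* **Weighted median**: ratio estimates `b_Y/b_X` weighted by
  `(b_X/se_Y)^2`; the estimate is the median of this discrete weighted
  distribution — the ratio whose cumulative-weight interval contains 0.5,
  interpolating between adjacent ratios only when 0.5 falls exactly on a
  boundary. This convention is a pure functional of the weighted CDF, hence
  invariant to duplicating an instrument while splitting its weight; the
  midpoint-interpolation variant found elsewhere lacks that invariance,
  which is why it was not used. The standard error is a parametric
  bootstrap (default 1,000 resamples of `b_X`, `b_Y` from their stated
  errors; the bootstrap size and seed are declared defaults). The median
  deliberately ignores ρ: it runs, as a sensitivity test, on the pruned and
  therefore weakly correlated set.

Exposure and outcome are assumed standardized upstream (effects in SD
units); the estimators are scale-agnostic. The phenome-wide follow-up's
multiplicity correction is reproduced as arithmetic:
`bonferroni_threshold(c(90, 11, 603, 62, 11))` =
`r signif(bonferroni_threshold(c(90, 11, 603, 62, 11)), 3)` over 777 tests.

# One quantile convention

Every empirical percentile in the package — the 2.5/97.5 null bounds, the
top-1% β threshold, the per-bin 99th percentile r² — uses linear
interpolation between closest order statistics (`quantile` type 7), and
every outlier rule is a strict inequality. The combination is conservative:
ties never flag, and a continuous statistic can never flag more than the
nominal fraction of its own null.

# The synthetic-data module

Each generator produces exactly the structure one stage assumes, with the
truth serialized alongside (`synthetic_truth`), and is a pure function of
its seed (the caller's RNG state is saved and restored):

* `sim_balding_nichols()` — population frequencies Beta with mean `p0` and
  variance `F p0 (1-p0)` (shapes `p0(1-F)/F`, `(1-p0)(1-F)/F`), genotypes
  Binomial(2, freq). Validates the FST estimator.
* `sim_neutral_windows()` — Kingman coalescent per window (exponential
  coalescence at rate `k(k-1)/2`), Poisson mutations at θ/2 per unit branch
  length, infinite sites. Windows are independent and recombination-free,
  matching the 1 Kb analysis scale; no attempt is made to emulate
  genome-scale recombination. `E[S] = θ a_n` is verified to 5%.
* `sim_sweep_panel()` — constructive sweep: derived carriers copy one
  founder haplotype over contiguous blocks whose ends are geometric in the
  per-site fidelity (default 0.95; 1 = perfect copies), ancestral carriers
  draw independently from background frequencies. The unit under test is
  the EHH/iHS machinery, not sweep realism — no forward simulation.
* `sim_ld_pairs()` — per pair, two-locus haplotype frequencies are solved so
  expected r² hits the target (`D = r sqrt(p(1-p)q(1-q))`; infeasible
  targets error), 2N haplotypes drawn multinomially. Null profiles and
  planted high-r² pairs calibrate the uLD stage.
* `sim_expression()` — expression = planted dosage effects + covariates +
  Gaussian noise.
* `sim_mr_dataset()` — exposure effects N(0.3, 0.1) (predominantly positive,
  as after orientation), outcomes `causal_beta · b_X + intercept +
  noise` with covariance `Omega`; `noise_scale = 0` gives exact
  proportionality while keeping usable standard errors.

What passing these tests shows — and does not. The generators verify the
estimators and their calibration under the stated models. Real cohort data
add features none of them emulate: linked selection and recombination-rate
variation, genotyping and phasing error, missingness structured by
mappability, population admixture, and expression normalization artifacts.
Passing here demonstrates correctness of the statistics and their null
calibration, not robustness to those confounders; the masking, missingness
and covariate interfaces are where such structure enters in real use.

# Problem sizes

The bundled checks run at sizes chosen to keep the full suite in a few
minutes while leaving Monte-Carlo noise well inside the asserted bands:
2,000 + 2,000 coalescent windows (n = 50, θ = 10) for the Tajima null
calibration; 1,000 sites × 4 × 200 diploids per fixation index; ~5,000
neutral β cores; ~10,400 held-out LD pairs over four distance bins (150
diploids each); 200 replicates each for eQTL unbiasedness, IVW recovery and
coverage, and Egger power; 200 random instances per estimator-vs-oracle
check.

# Reproducing on real cohort data

The same workflow applies unchanged to real inputs: phased VCFs (e.g. 1000
Genomes phase 3, restricted to non-admixed populations), a gene annotation
(Ensembl GTF), population-specific genetic maps, RepeatMasker-style masks as
BED, expression matrices with covariates, and GWAS summary statistics. That
replication needs cohort downloads and hours of compute, so it is documented
here rather than run in the test suite: with the 57-gene CYP450 extraction
and the biallelic-SNP filters, the expected corpus is on the order of
61,700 SNPs across 2,157 individuals, and the uLD fractions in the CYP4F
and CYP3A clusters are expected near 8% and 5% respectively, CYP4F the more
extreme despite its four-fold larger genetic span.

# Known limitations

* π is dosage-based; haplotype-aware diversity is not computed.
* No XP-EHH/nSL; no substitution-aware β(2); no D/D′ haplotype LD.
* Genetic-map extrapolation clamps to the map ends — positions outside the
  map get the endpoint cM, a divergence risk against tools that extrapolate
  the terminal rate.
* Multi-allelic records are dropped entirely, never split.
* FST confidence intervals and uLD significance beyond the empirical
  percentile rule are out of scope.
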