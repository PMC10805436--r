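#' Default pipeline configuration
#'
#' Every analysis parameter defaults to the study's value: 1 Kb Tajima's D
#' windows with 2.5/97.5 empirical-null percentiles, |iHS| >= 2, top-1%
#' beta-score significance, 0.01 cM LD bins with a 99th-percentile threshold,
#' strict MAF > 0.05, eQTL p < 1e-8, and instrument selection at F > 10,
#' p < 0.001, r2 <= 0.8.
#'
#' @param seed run seed.
#' @param out_dir output directory.
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1, out_dir = tempfile("coevscan_run_")) {
  list(
    seed = seed,
    out_dir = out_dir,
    stages = list(diversity = TRUE, haplotype = TRUE, uld = TRUE,
                  eqtl = TRUE, mr = TRUE),
    params = list(
      window_bp = 1000, null_lower = 0.025, null_upper = 0.975,
      max_missing = 0.1,
      ihs_threshold = 2, ehh_cutoff = 0.05, ihs_bins = 50,
      beta_half_width = 1000, beta_p = 2, beta_top_fraction = 0.01,
      uld_bin_cm = 0.01, uld_percentile = 0.99, uld_min_pairs = 100,
      maf_min = 0.05, eqtl_threshold = 1e-8,
      mr_f_min = 10, mr_p_max = 0.001, mr_r2_max = 0.8, mr_boot = 1000),
    inputs = list()  # optional file paths; stages fall back to synthetic demos
  )
}

#' Load a pipeline configuration from a YAML file
#'
#' Values present in the file override the defaults of [default_run_config()].
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  merge_into <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_into(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  merge_into(cfg, user)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config[setdiff(names(config), "out_dir")], f)
  unname(tools::md5sum(f))
}

write_stage_tsv <- function(df, path, version, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# coevscan ", version), paste0("# config_hash ", hash),
               paste0("# seed ", seed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full pipeline from a configuration
#'
#' Stages run in dependency order (simulate/load -> diversity and selection
#' scans and uLD -> eQTL -> MR). With no input paths configured, each stage
#' runs on a small synthetic demo dataset seeded from the config seed, so the
#' end-to-end path is exercised deterministically. Each output TSV carries the
#' package version, config hash and seed in comment headers, and a summary
#' JSON aggregates per-stage headline numbers. Any stage failure aborts with
#' the stage name.
#'
#' @param config list from [default_run_config()] or [read_run_config()].
#' @return the summary list, invisibly; written to `summary.json` in
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  version <- as.character(utils::packageVersion("coevscan"))
  hash <- config_hash(config)
  p <- config$params
  summary <- list(package_version = version, config_hash = hash,
                  seed = config$seed, stages = list())
  log_msg <- function(...) message("[coevscan] ", ...)
  run_stage <- function(name, fn) {
    t0 <- Sys.time()
    out <- tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    log_msg(name, " done in ",
            sprintf("%.2fs", as.numeric(Sys.time() - t0, units = "secs")))
    summary$stages[[name]] <<- out
  }

  if (isTRUE(config$stages$diversity)) run_stage("diversity", function() {
    nulls <- sim_neutral_windows(50, 10, 300, seed = config$seed)
    tests <- sim_neutral_windows(50, 10, 200, seed = config$seed + 1)
    d_null <- vapply(nulls$panels, function(pn) tajimas_d(pn)$D, numeric(1))
    null <- empirical_null(d_null, p$null_lower, p$null_upper)
    d_test <- vapply(tests$panels, function(pn) tajimas_d(pn)$D, numeric(1))
    win <- data.frame(chrom = "1", start = (seq_along(d_test) - 1) * p$window_bp,
                      end = seq_along(d_test) * p$window_bp, D = d_test,
                      excluded = FALSE)
    cls <- classify_windows(win, null)
    bn <- sim_balding_nichols(0.1, n_diploids = 100, n_sites = 300,
                              seed = config$seed + 2)
    fst <- wc_fst(bn$genotypes)
    write_stage_tsv(cls, file.path(config$out_dir, "tajima_windows.tsv"),
                    version, hash, config$seed)
    write_stage_tsv(fst, file.path(config$out_dir, "fst_sites.tsv"),
                    version, hash, config$seed)
    list(n_windows = nrow(cls), null_lower = null$lower,
         null_upper = null$upper,
         flagged_fraction = mean(cls$flag != "ns"),
         mean_fst = mean(fst$fst, na.rm = TRUE))
  })

  if (isTRUE(config$stages$haplotype)) run_stage("haplotype", function() {
    sw <- sim_sweep_panel(n_chrom = 100, n_sites = 101, q = 0.3,
                          seed = config$seed)
    score <- ihs_core(sw$panel, sw$map, sw$core, p$ehh_cutoff, p$maf_min)
    nt <- sim_neutral_windows(50, 30, 60, seed = config$seed + 3,
                              window_bp = 4000)
    betas <- unlist(lapply(nt$panels, function(pn) {
      if (nrow(pn$sites) < 3) return(NULL)
      beta_scan(pn, p$beta_half_width, p$beta_p)$beta
    }))
    top <- empirical_top_fraction(betas, p$beta_top_fraction)
    write_stage_tsv(score, file.path(config$out_dir, "ihs_demo.tsv"),
                    version, hash, config$seed)
    list(sweep_ihs_raw = score$ihs_raw, sweep_status = score$status,
         n_beta_scores = length(betas),
         beta_threshold = top$threshold,
         beta_flagged_fraction = mean(top$flagged))
  })

  if (isTRUE(config$stages$uld)) run_stage("uld", function() {
    profile <- data.frame(d_cm = c(0.005, 0.015, 0.025),
                          r2_target = c(0.3, 0.2, 0.1))
    nul <- sim_ld_pairs(profile, n_pairs_per_bin = 300, n_samples = 150,
                        seed = config$seed + 4)
    tst <- sim_ld_pairs(profile, n_pairs_per_bin = 200,
                        planted = data.frame(d_cm = 0.005, r2_target = 0.9),
                        n_samples = 150, seed = config$seed + 5)
    null <- build_binned_null(nul$pairs, p$uld_bin_cm, p$uld_percentile,
                              p$uld_min_pairs)
    flg <- flag_uld(tst$pairs, null)
    sm <- attr(flg, "summary")
    write_stage_tsv(null$bins, file.path(config$out_dir, "uld_null_bins.tsv"),
                    version, hash, config$seed)
    write_stage_tsv(flg, file.path(config$out_dir, "uld_pairs.tsv"),
                    version, hash, config$seed)
    list(n_pairs = sm$n_pairs, n_flagged = sm$n_flagged,
         flagged_fraction = sm$fraction,
         planted_flagged = all(flg$flagged[flg$planted]))
  })

  if (isTRUE(config$stages$eqtl)) run_stage("eqtl", function() {
    bn <- sim_balding_nichols(0.01, n_pops = 1, n_diploids = 400,
                              n_sites = 20, seed = config$seed + 6)
    eff <- data.frame(snp = bn$genotypes$sites$pos[5], gene = "GENE1",
                      beta = 1)
    ex <- sim_expression(bn$genotypes, eff, genes = paste0("GENE", 1:3),
                         noise_sd = 0.5, seed = config$seed + 7)
    res <- eqtl_scan(bn$genotypes$sites$pos[c(5, 10)], bn$genotypes,
                     list(ex$expr_set), p$eqtl_threshold, p$maf_min)
    write_stage_tsv(res, file.path(config$out_dir, "eqtl_results.tsv"),
                    version, hash, config$seed)
    list(n_tests = nrow(res), n_significant = sum(res$significant),
         planted_recovered = any(res$significant &
                                   res$snp == eff$snp & res$gene == eff$gene))
  })

  if (isTRUE(config$stages$mr)) run_stage("mr", function() {
    mr <- sim_mr_dataset(8, causal_beta = 0.3, seed = config$seed + 8)
    rep <- mr_report(mr$input, n_boot = p$mr_boot, seed = config$seed + 9)
    res <- data.frame(method = c("IVW", "Egger", "WeightedMedian"),
                      beta = c(rep$ivw$beta, rep$egger$beta,
                               rep$weighted_median$beta),
                      se = c(rep$ivw$se, rep$egger$se,
                             rep$weighted_median$se),
                      p = c(rep$ivw$p, rep$egger$p, rep$weighted_median$p))
    write_stage_tsv(res, file.path(config$out_dir, "mr_results.tsv"),
                    version, hash, config$seed)
    list(ivw_beta = rep$ivw$beta, egger_beta = rep$egger$beta,
         weighted_median_beta = rep$weighted_median$beta,
         egger_intercept_p = rep$egger$intercept_p,
         preferred = rep$preferred,
         phewas_bonferroni = bonferroni_threshold(c(90, 11, 603, 62, 11)))
  })

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
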