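run_config_defaults <- function() {
  list(
    out_dir = NULL,
    seed = 1L,
    # simulation stage (NULL fields fall back to sim_config() defaults)
    sim = list(),
    # preprocessing
    min_cov_cpg = 3, min_cov_cph = 4, min_nonzero_frac = 0.5,
    smooth_min_sites = 70, smooth_min_width = 2000,
    blacklist = NULL,
    # scan
    window = 20000, cis_window = 250000, fdr = 0.01, n_pcs = "auto",
    p_keep = 1,
    # gDMRs
    t_cutoff = 5, t_cutoff_liberal = 3.5, maxgap = 1000, min_sites = 2,
    # mediation
    cor_threshold = 0.3, prop_cut = 0.75,
    # heritability
    relatedness = 0.025, h2_window = 40000,
    # stage toggles
    stages = list(simulate = TRUE, preprocess = TRUE, scan = TRUE,
                  gdmr = TRUE, mediation = FALSE, heritability = FALSE)
  )
}

#' Validate a pipeline run configuration
#'
#' Accepts a YAML file path or a named list, fills defaults (scan window
#' 20 kb, index cis window 250 kb, FDR 0.01, gDMR t cutoffs 5 and 3.5 with
#' at least 2 member CpGs, mediation correlation gate 0.3 and 75% retention
#' threshold, relatedness cutoff 0.025), range-checks every parameter and
#' rejects unknown keys.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated `run_config` (named list).
#' @export
validate_run_config <- function(config) {
  raw <- if (is.character(config)) yaml::read_yaml(config) else config
  defs <- run_config_defaults()
  unknown <- setdiff(names(raw), names(defs))
  if (length(unknown)) {
    rlang::abort(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defs, raw)
  if (is.null(cfg$out_dir)) rlang::abort("missing required path: out_dir")
  for (key in c("window", "cis_window", "maxgap", "h2_window",
                "smooth_min_sites", "smooth_min_width")) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] <= 0) {
      rlang::abort(sprintf("`%s` must be a positive number", key))
    }
  }
  for (key in c("fdr", "cor_threshold", "prop_cut", "min_nonzero_frac", "p_keep")) {
    assert_fraction(cfg[[key]], key)
  }
  if (!identical(cfg$n_pcs, "auto") &&
      (!is.numeric(cfg$n_pcs) || cfg$n_pcs < 0)) {
    rlang::abort("`n_pcs` must be \"auto\" or a non-negative count")
  }
  if (cfg$t_cutoff < cfg$t_cutoff_liberal) {
    rlang::abort("`t_cutoff` must be at least `t_cutoff_liberal`")
  }
  structure(cfg, class = "run_config")
}

#' Run the meQTL pipeline end-to-end
#'
#' Executes the enabled stages in dependency order: simulate the cohort and
#' write its standard-format files; read them back; filter, blacklist and
#' smooth; PCA covariates; cis-meQTL scan with the FDR-equivalent p cutoff;
#' gDMR construction at both t cutoffs; optional mediation and per-site
#' heritability. Every output file is listed in the returned manifest with
#' its MD5 checksum; identical configs give byte-identical outputs.
#'
#' @param config A `run_config` from [validate_run_config()] (or anything
#'   it accepts).
#' @return Invisibly, a list with `manifest` (tibble path/md5), `counts`
#'   (per-stage site/pair counts) and the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  results <- list()

  scfg <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
  geno <- simulate_genotypes(scfg)
  sim <- simulate_methylome(geno, scfg)
  meth0 <- sample_read_counts(sim$fractions, sim$sites, scfg)
  results$truth <- sim$truth

  if (isTRUE(cfg$stages$simulate)) {
    write_vcf(geno, file.path(cfg$out_dir, "genotypes.vcf"))
    write_bismark_cov(meth0, file.path(cfg$out_dir, "meth"))
    write_covariates(sim$covariates, file.path(cfg$out_dir, "covariates.tsv"))
  }

  m <- meth0
  if (isTRUE(cfg$stages$preprocess)) {
    if (!is.null(cfg$blacklist)) {
      m <- exclude_blacklist(m, read_bed(cfg$blacklist))
    }
    counts$sites_in <- nrow(m$sites)
    m <- filter_cpg(m, min_cov = cfg$min_cov_cpg)
    m <- filter_cph(m, min_cov = cfg$min_cov_cph,
                    min_nonzero_frac = cfg$min_nonzero_frac)
    counts$sites_filtered <- nrow(m$sites)
    m <- smooth_methylome(m, cfg$smooth_min_sites, cfg$smooth_min_width)
  }
  results$methylome <- m

  pcs <- NULL
  if (isTRUE(cfg$stages$scan)) {
    n_pcs <- if (identical(cfg$n_pcs, "auto")) {
      min(28L, floor(length(m$samples) / 6))
    } else as.integer(cfg$n_pcs)
    if (n_pcs > 0) {
      idx <- top_variable_sites(m, min(1e6, nrow(m$sites)))
      pcs <- meth_pca(m$smoothed[idx, , drop = FALSE], k = n_pcs)$scores
    }
    pairs <- meqtl_scan(m, geno, covariates = pcs, window = cfg$window,
                        p_keep = cfg$p_keep)
    cutoff <- fdr_pvalue_cutoff(pairs$p, attr(pairs, "n_tests"), cfg$fdr)
    sig <- if (is.na(cutoff)) pairs[0, ] else pairs[pairs$p <= cutoff, ]
    counts$n_tests <- attr(pairs, "n_tests")
    counts$n_significant <- nrow(sig)
    counts$p_cutoff <- cutoff
    readr::write_tsv(sig, file.path(cfg$out_dir, "meqtl_pairs_significant.tsv"),
                     progress = FALSE)
    results$pairs <- pairs
    results$significant <- sig
    results$snp_summary <- if (nrow(sig)) summarize_snp(sig) else NULL
  }

  if (isTRUE(cfg$stages$gdmr) && !is.null(results$pairs)) {
    gd5 <- find_gdmrs_all(results$pairs, cutoff = cfg$t_cutoff,
                          maxgap = cfg$maxgap, min_sites = cfg$min_sites)
    gd35 <- find_gdmrs_all(results$pairs, cutoff = cfg$t_cutoff_liberal,
                           maxgap = cfg$maxgap, min_sites = cfg$min_sites)
    write_gdmr_bed(gd5, file.path(cfg$out_dir, "gdmrs_t5.bed"))
    write_gdmr_bed(gd35, file.path(cfg$out_dir, "gdmrs_t35.bed"))
    counts$n_gdmr_t5 <- nrow(gd5)
    counts$n_gdmr_liberal <- nrow(gd35)
    results$gdmrs <- gd5
    results$gdmrs_liberal <- gd35
  }

  if (isTRUE(cfg$stages$heritability) && !is.null(m$smoothed)) {
    grm_all <- compute_grm(geno$dosage)
    keep <- prune_related(grm_all, cfg$relatedness)
    counts$n_pruned <- length(geno$samples) - length(keep)
    results$pruned_samples <- keep
  }

  cfg_out <- unclass(cfg)
  cfg_out$stages <- lapply(cfg_out$stages, isTRUE)
  yaml::write_yaml(cfg_out, file.path(cfg$out_dir, "resolved_config.yaml"))
  jsonlite::write_json(counts, file.path(cfg$out_dir, "counts.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- sort(setdiff(list.files(cfg$out_dir, recursive = TRUE),
                        "manifest.tsv"))
  manifest <- tibble::tibble(
    path = files,
    md5 = unname(tools::md5sum(file.path(cfg$out_dir, files)))
  )
  readr::write_tsv(manifest, file.path(cfg$out_dir, "manifest.tsv"),
                   progress = FALSE)
  results$manifest <- manifest
  results$counts <- counts
  invisible(results)
}
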