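#' Pipeline configuration
#'
#' @param threshold_fraction Primary outlier fraction (default 0.001).
#' @param fallback_fractions Fallback fractions tried when no candidate
#'   survives (default `c(0.005, 0.01)`).
#' @param min_pairs Minimum complete sibling pairs per site for a
#'   correlation (default 10).
#' @param half_width_bp meQTL cis-window half width (default 1 Mb).
#' @param min_maf Strict MAF lower bound for the scan (default 0.01).
#' @param sample_mode `"full"` — each phase analyzed on its full sample — or
#'   `"common"` — both phases restricted to the individuals (and hence
#'   pairs) present in both, trading power for a single consistent sample.
#' @param one_pair_per_sibship Pairing rule sensitivity switch (default
#'   `FALSE`: all distinct full-sib pairs).
#' @param run_meqtl Run the cis-meQTL scan on the candidate sites
#'   (default `TRUE`).
#' @param seed Seed recorded in the manifest (the screen itself is
#'   deterministic; the seed matters when the pipeline input is generated).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(threshold_fraction = 0.001,
                            fallback_fractions = c(0.005, 0.01),
                            min_pairs = 10L,
                            half_width_bp = 1e6,
                            min_maf = 0.01,
                            sample_mode = c("full", "common"),
                            one_pair_per_sibship = FALSE,
                            run_meqtl = TRUE,
                            seed = 1L) {
  structure(list(threshold_fraction = threshold_fraction,
                 fallback_fractions = fallback_fractions,
                 min_pairs = as.integer(min_pairs),
                 half_width_bp = half_width_bp,
                 min_maf = min_maf,
                 sample_mode = match.arg(sample_mode),
                 one_pair_per_sibship = one_pair_per_sibship,
                 run_meqtl = run_meqtl,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full screen on a study
#'
#' Chains the per-site statistics, the outlier-concordance screen and
#' (optionally) the cis-meQTL scan of the surviving candidates, writing all
#' tables plus a run manifest when an output directory is given. In
#' `"common"` sample mode both phases are first restricted to the shared
#' individuals, which also restricts the sibling-pair sets to the shared
#' pairs.
#'
#' @param study List with elements `ped`, `pre`, `post` and (if the scan is
#'   run) `geno` — as returned by [generate_study()] or assembled from
#'   [read_pedigree()] / [read_methylation_tsv()] / [read_genotypes_tsv()].
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional output directory for all artifacts.
#' @return A `pipeline_result` list: `stats`, `report`, `meqtl` (or `NULL`),
#'   `manifest`.
#' @export
run_pipeline <- function(study, cfg = pipeline_config(), out_dir = NULL) {
  t0 <- Sys.time()
  pre <- study$pre
  post <- study$post
  if (cfg$sample_mode == "common") {
    shared <- intersect(rownames(pre$values), rownames(post$values))
    if (!length(shared)) stop("sample_mode=common but the phases share no samples")
    .pipeline_log("common-mode restriction", n_shared = length(shared))
    pre <- subset_samples(pre, shared)
    post <- subset_samples(post, shared)
  }
  .pipeline_log("site statistics",
                n_pre = nrow(pre$values), n_post = nrow(post$values),
                n_sites = ncol(pre$values))
  stats <- build_site_stat_table(pre, post, study$ped,
                                 min_pairs = cfg$min_pairs,
                                 one_pair_per_sibship = cfg$one_pair_per_sibship)
  .pipeline_log("outlier screen",
                threshold = cfg$threshold_fraction)
  report <- run_outlier_pipeline(stats, cfg$threshold_fraction,
                                 cfg$fallback_fractions)
  scan <- NULL
  if (cfg$run_meqtl && length(report$candidates) && !is.null(study$geno)) {
    .pipeline_log("meQTL scan", n_candidates = length(report$candidates))
    scan <- meqtl_scan(post, report$candidates, study$geno, study$ped,
                       half_width_bp = cfg$half_width_bp,
                       min_maf = cfg$min_maf)
  }
  pairs <- extract_sibling_pairs(study$ped, cfg$one_pair_per_sibship)
  manifest <- list(
    package_version = as.character(utils::packageVersion("famvar")),
    seed = cfg$seed,
    sample_mode = cfg$sample_mode,
    n_samples_pre = nrow(pre$values),
    n_samples_post = nrow(post$values),
    n_sites = nrow(stats),
    n_pairs_pre = nrow(restrict_pairs(pairs, rownames(pre$values))),
    n_pairs_post = nrow(restrict_pairs(pairs, rownames(post$values))),
    threshold_fraction_requested = cfg$threshold_fraction,
    threshold_fraction_used = report$threshold_fraction,
    fallback_used = report$fallback_used,
    exhausted = report$exhausted,
    n_post_concordant = length(report$post_concordant),
    n_candidates = length(report$candidates),
    n_meqtl_tests = if (is.null(scan)) 0L else nrow(scan$results),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  result <- structure(list(stats = stats, report = report, meqtl = scan,
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_site_stats_tsv(stats, file.path(out_dir, "site_stats.tsv"))
    write_outlier_report(report, out_dir)
    if (!is.null(scan)) {
      write_meqtl_tsv(scan, file.path(out_dir, "meqtl_results.tsv"),
                      file.path(out_dir, "meqtl_lead_snps.tsv"))
    }
    cfg_path <- file.path(out_dir, "pipeline_config.json")
    jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    manifest$config_md5 <- unname(tools::md5sum(cfg_path))
    result$manifest <- manifest
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

.pipeline_log <- function(stage, ...) {
  info <- list(...)
  kv <- if (length(info)) {
    paste(names(info), unlist(info), sep = "=", collapse = " ")
  } else ""
  message(sprintf("[famvar] %s %s", stage, kv))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$report)
  if (!is.null(x$meqtl)) print(x$meqtl)
  invisible(x)
}
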