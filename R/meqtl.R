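#' Cis-window meQTL scan with a pedigree mixed model
#'
#' For each requested CpG site: restricts to samples with genotypes,
#' methylation and pedigree records; applies the MAF filter and the cis
#' window; fits the spectral mixed model once under the null (relatedness =
#' twice the pedigree kinship, or a user-supplied matrix); and Wald-tests
#' every window SNP at the null variance ratio.
#'
#' @param m A [methylation_matrix()] (typically the post-treatment phase).
#' @param sites Character vector of site ids to scan (e.g. the candidates
#'   from [run_outlier_pipeline()]).
#' @param g A [genotype_matrix()].
#' @param ped A [as_pedigree()] covering the samples.
#' @param half_width_bp Cis-window half width (default 1 Mb).
#' @param min_maf Strict MAF lower bound (default `0.01`).
#' @param covariates Optional numeric matrix of covariates (rownames =
#'   sample ids); an intercept is always included.
#' @param relatedness Optional PSD relatedness matrix overriding
#'   `2 * compute_kinship(ped)` (sample ids as dimnames).
#' @param refit_per_snp Re-optimize the variance ratio for every SNP
#'   (default `FALSE`, the usual spectral-LMM acceleration).
#' @return A `meqtl_result` list with `results` — a data frame of per-pair
#'   tests (`cpg_site_id`, `snp_id`, `chrom`, `pos`, `distance_bp`, `n`,
#'   `beta`, `se`, `stat`, `p`) — and `lead` — one row per scanned site with
#'   the minimum-p SNP (ties broken by smaller position, then snp_id).
#'   Sites with no cis-SNPs after filtering are skipped with a warning.
#' @export
meqtl_scan <- function(m, sites, g, ped, half_width_bp = 1e6, min_maf = 0.01,
                       covariates = NULL, relatedness = NULL,
                       refit_per_snp = FALSE) {
  samples <- intersect(intersect(rownames(m$values), rownames(g$dosages)),
                       ped$individual_id)
  if (!length(samples)) stop("no samples shared by methylation, genotypes and pedigree")
  if (is.null(relatedness)) {
    relatedness <- 2 * compute_kinship(ped)
  }
  gf <- maf_filter(genotype_matrix(g$dosages[samples, , drop = FALSE], g$snps),
                   min_maf)
  ann <- m$sites
  missing_sites <- setdiff(sites, ann$site_id)
  if (length(missing_sites)) {
    stop("sites absent from the methylation matrix: ",
         paste(utils::head(missing_sites, 3L), collapse = ", "))
  }
  res <- list()
  lead <- list()
  for (s in sites) {
    row <- ann[ann$site_id == s, ]
    if (is.na(row$chrom) || is.na(row$pos)) {
      warning("site ", s, " has no genomic coordinates; skipped")
      next
    }
    win <- cis_window(gf, row$chrom, row$pos, half_width_bp)
    y_all <- m$values[samples, s]
    keep <- !is.na(y_all)
    if (ncol(win$dosages) == 0L) {
      warning("site ", s, ": no cis-SNPs within ", half_width_bp,
              " bp after MAF filter; skipped")
      next
    }
    ids <- samples[keep]
    X <- NULL
    if (!is.null(covariates)) {
      X <- cbind(intercept = 1, covariates[ids, , drop = FALSE])
    }
    fit <- fit_null_lmm(y_all[keep], X = X,
                        R = relatedness[ids, ids, drop = FALSE])
    site_res <- vector("list", ncol(win$dosages))
    for (j in seq_len(ncol(win$dosages))) {
      tst <- tryCatch(test_snp(fit, win$dosages[keep, j],
                               refit_delta = refit_per_snp),
                      error = function(e) NULL)
      if (is.null(tst)) next
      site_res[[j]] <- data.frame(
        cpg_site_id = s,
        snp_id = win$snps$snp_id[j],
        chrom = win$snps$chrom[j],
        pos = win$snps$pos[j],
        distance_bp = abs(win$snps$pos[j] - row$pos),
        n = tst$n, beta = tst$beta_snp, se = tst$se,
        stat = tst$stat, p = tst$p,
        stringsAsFactors = FALSE
      )
    }
    site_res <- do.call(rbind, site_res)
    if (is.null(site_res) || !nrow(site_res)) {
      warning("site ", s, ": all cis-SNPs untestable; skipped")
      next
    }
    o <- order(site_res$p, site_res$pos, site_res$snp_id)
    res[[s]] <- site_res
    lead[[s]] <- site_res[o[1L], , drop = FALSE]
  }
  results <- if (length(res)) do.call(rbind, res) else
    data.frame(cpg_site_id = character(0), snp_id = character(0),
               chrom = character(0), pos = integer(0),
               distance_bp = integer(0), n = integer(0), beta = numeric(0),
               se = numeric(0), stat = numeric(0), p = numeric(0))
  leads <- if (length(lead)) do.call(rbind, lead) else results
  rownames(results) <- rownames(leads) <- NULL
  structure(list(results = results, lead = leads), class = "meqtl_result")
}

#' @export
print.meqtl_result <- function(x, ...) {
  cat(sprintf("meqtl_result: %d SNP-site tests across %d sites\n",
              nrow(x$results), nrow(x$lead)))
  if (nrow(x$lead)) {
    cat("lead SNPs:\n")
    print(x$lead[, c("cpg_site_id", "snp_id", "pos", "beta", "p")])
  }
  invisible(x)
}

#' Write meQTL scan results
#'
#' @param scan A `meqtl_result`.
#' @param path Per-pair results TSV path.
#' @param lead_path Lead-SNP summary TSV path (optional).
#' @return `path`, invisibly.
#' @export
write_meqtl_tsv <- function(scan, path, lead_path = NULL) {
  data.table::fwrite(scan$results, path, sep = "\t")
  if (!is.null(lead_path)) data.table::fwrite(scan$lead, lead_path, sep = "\t")
  invisible(path)
}
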