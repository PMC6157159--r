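#' Descending ranks with a deterministic tie rule
#'
#' Rank 1 is the largest value. Ties are broken by lexicographic `site_id`
#' order and missing values rank after all non-missing ones (again by id), so
#' the ranks are always a permutation of `1..N` and the whole screen is
#' reproducible byte-for-byte.
#'
#' @param values Numeric vector of per-site statistics (`NA` allowed).
#' @param site_ids Character vector of the same length.
#' @return Integer vector of ranks, named by `site_ids`.
#' @export
rank_descending <- function(values, site_ids) {
  stopifnot(length(values) == length(site_ids))
  ord <- order(-values, site_ids, na.last = TRUE)
  r <- integer(length(values))
  r[ord] <- seq_along(values)
  names(r) <- site_ids
  r
}

#' Number of sites selected by a tail fraction
#'
#' @param fraction Upper-tail fraction (e.g. `0.001` for 0.1%).
#' @param n_sites Number of sites ranked.
#' @return `round(fraction * n_sites)`, at least 1.
#' @export
threshold_count <- function(fraction, n_sites) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  max(1L, as.integer(round(fraction * n_sites)))
}

#' Select upper-tail outliers by rank
#'
#' @param ranks Integer ranks from [rank_descending()].
#' @param count Number of sites to select (`1 <= count <= N`).
#' @return Character vector of the site ids with rank `<= count`; thanks to
#'   the deterministic tie rule the set has exactly `count` members.
#' @export
select_outliers <- function(ranks, count) {
  if (count < 1L || count > length(ranks)) {
    stop("threshold count ", count, " outside 1..", length(ranks))
  }
  names(ranks)[ranks <= count]
}

#' Intersection of two outlier sets
#'
#' @param set_a,set_b Character vectors of site ids.
#' @return Sites present in both sets.
#' @export
concordant_outliers <- function(set_a, set_b) intersect(set_a, set_b)

#' Candidate treatment-responsive sites
#'
#' The screen's selection rule: sites that are concordant post-treatment
#' outliers (both SD and sibling-correlation) but were *not* outliers of
#' either pre-treatment distribution at the same threshold.
#'
#' @param post_concordant Concordant post-treatment outlier sites.
#' @param sd_pre,scor_pre Pre-treatment outlier sets at the same threshold.
#' @return Character vector of candidate site ids.
#' @export
candidate_responsive_sites <- function(post_concordant, sd_pre, scor_pre) {
  setdiff(post_concordant, union(sd_pre, scor_pre))
}

#' Outlier-set turnover between phases
#'
#' @param pre_set,post_set Outlier sets selected at the same threshold.
#' @return List with `count` (`|post_set \ pre_set|`) and `fraction`
#'   (`count / |post_set|`).
#' @export
outlier_turnover <- function(pre_set, post_set) {
  if (!length(post_set)) stop("turnover fraction undefined for empty post set")
  count <- length(setdiff(post_set, pre_set))
  list(count = count, fraction = count / length(post_set))
}

#' Run the outlier-concordance screen
#'
#' Applies the rank-threshold screen to a per-site statistic table: selects
#' upper-tail outliers of the four distributions (SD and sibling correlation,
#' pre and post), intersects the two post-treatment sets, and removes sites
#' that were pre-treatment outliers. If no candidate survives at the primary
#' threshold, progressively more permissive fallback thresholds are tried in
#' order, and the threshold that produced candidates is recorded.
#'
#' @param stats A `site_stat_table` from [build_site_stat_table()].
#' @param threshold_fraction Primary upper-tail fraction (default `0.001`,
#'   i.e. 0.1%; 450 of 450,000 sites).
#' @param fallback_fractions More permissive fractions tried in order when
#'   the candidate set is empty (default `c(0.005, 0.01)`).
#' @param gene_annotation Optional data frame `site_id`, `gene` used to label
#'   report rows; never fetched from an external source.
#' @return An `outlier_report` list: `threshold_fraction` (the fraction that
#'   produced the report), `threshold_count`, `fallback_used`, `exhausted`,
#'   the four outlier sets (`sd_pre`, `sd_post`, `scor_pre`, `scor_post`),
#'   `post_concordant`, `candidates`, `turnover_sd`, `turnover_scor`, and
#'   `table_rows` — one row per post-concordant site with pre/post rank and
#'   estimate for both statistics and a `bold` flag marking candidates
#'   (outlier status changed for both statistics).
#' @export
run_outlier_pipeline <- function(stats, threshold_fraction = 0.001,
                                 fallback_fractions = c(0.005, 0.01),
                                 gene_annotation = NULL) {
  n_sites <- nrow(stats)
  fractions <- c(threshold_fraction, fallback_fractions)
  chosen <- NULL
  for (i in seq_along(fractions)) {
    sel <- .screen_at_fraction(stats, fractions[i])
    if (length(sel$candidates) || i == length(fractions)) {
      chosen <- sel
      chosen$threshold_fraction <- fractions[i]
      chosen$fallback_used <- i > 1L
      chosen$exhausted <- !length(sel$candidates)
      break
    }
  }
  chosen$table_rows <- .table1_rows(stats, chosen, gene_annotation)
  class(chosen) <- "outlier_report"
  chosen
}

.screen_at_fraction <- function(stats, fraction) {
  count <- threshold_count(fraction, nrow(stats))
  sid <- stats$site_id
  sd_pre <- select_outliers(stats::setNames(stats$rank_sd_pre, sid), count)
  sd_post <- select_outliers(stats::setNames(stats$rank_sd_post, sid), count)
  scor_pre <- select_outliers(stats::setNames(stats$rank_scor_pre, sid), count)
  scor_post <- select_outliers(stats::setNames(stats$rank_scor_post, sid), count)
  post_concordant <- concordant_outliers(sd_post, scor_post)
  candidates <- candidate_responsive_sites(post_concordant, sd_pre, scor_pre)
  list(threshold_count = count,
       sd_pre = sd_pre, sd_post = sd_post,
       scor_pre = scor_pre, scor_post = scor_post,
       post_concordant = sort(post_concordant),
       candidates = sort(candidates),
       turnover_sd = outlier_turnover(sd_pre, sd_post),
       turnover_scor = outlier_turnover(scor_pre, scor_post))
}

# Report rows in the style of a rank-and-estimate outlier table: one row per
# post-concordant site; bold marks a change of outlier status in both
# distributions (the candidate rule).
.table1_rows <- function(stats, sel, gene_annotation) {
  rows <- stats[match(sel$post_concordant, stats$site_id), , drop = FALSE]
  gene <- rep(NA_character_, nrow(rows))
  if (!is.null(gene_annotation)) {
    gene <- gene_annotation$gene[match(rows$site_id, gene_annotation$site_id)]
  }
  out <- data.frame(
    site_id = rows$site_id,
    chrom = rows$chrom,
    gene = gene,
    rank_sd_post = rows$rank_sd_post, sd_post = rows$sd_post,
    rank_sd_pre = rows$rank_sd_pre, sd_pre = rows$sd_pre,
    rank_scor_post = rows$rank_scor_post, scor_post = rows$scor_post,
    rank_scor_pre = rows$rank_scor_pre, scor_pre = rows$scor_pre,
    bold = rows$site_id %in% sel$candidates,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf(
    "outlier_report: threshold %.3f%% (%d sites)%s\n",
    100 * x$threshold_fraction, x$threshold_count,
    if (x$fallback_used) " [fallback]" else ""))
  cat(sprintf("  post concordant: %d; candidates: %d%s\n",
              length(x$post_concordant), length(x$candidates),
              if (x$exhausted) " (thresholds exhausted)" else ""))
  cat(sprintf("  turnover: SD %d/%d (%.1f%%), scor %d/%d (%.1f%%)\n",
              x$turnover_sd$count, length(x$sd_post),
              100 * x$turnover_sd$fraction,
              x$turnover_scor$count, length(x$scor_post),
              100 * x$turnover_scor$fraction))
  invisible(x)
}

#' Write an outlier report to a directory
#'
#' Emits one single-column TSV per outlier set, the rank-and-estimate table
#' of post-concordant sites, and a JSON summary (threshold used, set sizes,
#' turnover).
#'
#' @param report An `outlier_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_outlier_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sets <- c("sd_pre", "sd_post", "scor_pre", "scor_post",
            "post_concordant", "candidates")
  for (s in sets) {
    data.table::fwrite(data.frame(site_id = report[[s]]),
                       file.path(dir, paste0("outliers_", s, ".tsv")),
                       sep = "\t")
  }
  data.table::fwrite(report$table_rows, file.path(dir, "concordant_table.tsv"),
                     sep = "\t")
  summary <- list(
    threshold_fraction = report$threshold_fraction,
    threshold_count = report$threshold_count,
    fallback_used = report$fallback_used,
    exhausted = report$exhausted,
    set_sizes = lapply(report[sets], length),
    turnover_sd = report$turnover_sd,
    turnover_scor = report$turnover_scor
  )
  jsonlite::write_json(summary, file.path(dir, "outlier_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
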