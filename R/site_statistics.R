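#' Per-site standard deviation of methylation
#'
#' Sample standard deviation (n - 1 denominator) of each site's beta values
#' over the non-missing samples of one phase, with no adjustment for family
#' structure: every site is estimated on the same sample and downstream use
#' ranks the estimates rather than drawing independence-based inference.
#'
#' @param m A [methylation_matrix()].
#' @return Named numeric vector of per-site SDs, `NA` where fewer than two
#'   values are non-missing.
#' @export
site_sd <- function(m) {
  x <- m$values
  n <- colSums(!is.na(x))
  mu <- colMeans(x, na.rm = TRUE)
  ss <- colSums(sweep(x, 2L, mu, check.margin = FALSE)^2, na.rm = TRUE)
  out <- sqrt(pmax(ss, 0) / (n - 1))
  out[n < 2L] <- NA_real_
  out
}

#' Ordered sibling Spearman correlation per site
#'
#' For each CpG site, forms the vector of earlier-born siblings' beta values
#' and the vector of their later-born co-siblings' values over the supplied
#' ordered pairs, and returns the Spearman rank correlation (average ranks on
#' ties). Ordering every pair by birth keeps the two vectors consistently
#' defined, which matters because the pair correlation is not symmetric in
#' finite samples once ranks are computed within each vector.
#'
#' @param m A [methylation_matrix()].
#' @param pairs A `sibling_pairs` data frame (see [extract_sibling_pairs()]);
#'   pairs whose members are absent from `m` are dropped.
#' @param min_pairs Minimum number of complete pairs needed to report a
#'   correlation (default 10); sites below it get `NA`.
#' @return List with `scor` (named numeric vector, in `[-1, 1]` or `NA`) and
#'   `npairs` (complete-pair count per site).
#' @export
sibling_spearman <- function(m, pairs, min_pairs = 10L) {
  if (min_pairs < 3L) stop("min_pairs must be at least 3")
  pairs <- restrict_pairs(pairs, rownames(m$values))
  x <- m$values[pairs$first_id, , drop = FALSE]
  y <- m$values[pairs$second_id, , drop = FALSE]
  ok <- !is.na(x) & !is.na(y)
  npairs <- colSums(ok)
  nsite <- ncol(m$values)
  scor <- rep(NA_real_, nsite)
  names(scor) <- colnames(m$values)
  names(npairs) <- colnames(m$values)
  for (j in seq_len(nsite)) {
    if (npairs[j] < min_pairs) next
    k <- ok[, j]
    scor[j] <- stats::cor(x[k, j], y[k, j], method = "spearman")
  }
  list(scor = scor, npairs = npairs)
}

#' Heritability upper bound from a sibling correlation
#'
#' Twice the sibling correlation bounds the (narrow-sense) heritability from
#' above; the bound is clipped to the admissible `[0, 1]` range.
#'
#' @param scor Sibling correlation(s) in `[-1, 1]` (`NA` allowed).
#' @return `min(max(2 * scor, 0), 1)`, elementwise.
#' @export
heritability_upper_bound <- function(scor) {
  bad <- !is.na(scor) & (scor < -1 | scor > 1)
  if (any(bad)) stop("sibling correlation outside [-1, 1]")
  pmin(pmax(2 * scor, 0), 1)
}

#' Assemble the per-site statistic table
#'
#' Computes SD and ordered sibling Spearman correlation for each site in the
#' pre- and post-treatment samples, together with descending ranks (1 =
#' largest) within each of the four distributions.
#'
#' @param pre,post [methylation_matrix()] objects sharing the same sites.
#' @param ped A [as_pedigree()] covering both phases' samples.
#' @param min_pairs Passed to [sibling_spearman()].
#' @param one_pair_per_sibship Passed to [extract_sibling_pairs()].
#' @return A `site_stat_table` data frame with columns `site_id`, `chrom`,
#'   `pos`, `sd_pre`, `sd_post`, `scor_pre`, `scor_post`, `n_pre`, `n_post`,
#'   `npairs_pre`, `npairs_post` and the four rank columns `rank_sd_pre`,
#'   `rank_sd_post`, `rank_scor_pre`, `rank_scor_post`.
#' @export
build_site_stat_table <- function(pre, post, ped, min_pairs = 10L,
                                  one_pair_per_sibship = FALSE) {
  if (!identical(colnames(pre$values), colnames(post$values))) {
    stop("pre and post matrices do not share the same site_ids in order")
  }
  pairs <- extract_sibling_pairs(ped, one_pair_per_sibship)
  sp_pre <- sibling_spearman(pre, pairs, min_pairs)
  sp_post <- sibling_spearman(post, pairs, min_pairs)
  sid <- colnames(pre$values)
  tab <- data.frame(
    site_id = sid,
    chrom = pre$sites$chrom,
    pos = pre$sites$pos,
    sd_pre = unname(site_sd(pre)),
    sd_post = unname(site_sd(post)),
    scor_pre = unname(sp_pre$scor),
    scor_post = unname(sp_post$scor),
    n_pre = unname(colSums(!is.na(pre$values))),
    n_post = unname(colSums(!is.na(post$values))),
    npairs_pre = unname(sp_pre$npairs),
    npairs_post = unname(sp_post$npairs),
    stringsAsFactors = FALSE
  )
  tab$rank_sd_pre <- rank_descending(tab$sd_pre, sid)
  tab$rank_sd_post <- rank_descending(tab$sd_post, sid)
  tab$rank_scor_pre <- rank_descending(tab$scor_pre, sid)
  tab$rank_scor_post <- rank_descending(tab$scor_post, sid)
  class(tab) <- c("site_stat_table", "data.frame")
  tab
}

#' Read / write a site statistic table as TSV
#'
#' @param tab A `site_stat_table`.
#' @param path TSV path.
#' @return `path` invisibly (writer); the table (reader).
#' @export
write_site_stats_tsv <- function(tab, path) {
  data.table::fwrite(as.data.frame(tab), path, sep = "\t")
  invisible(path)
}

#' @rdname write_site_stats_tsv
#' @export
read_site_stats_tsv <- function(path) {
  tab <- data.table::fread(path, sep = "\t", data.table = FALSE,
                           colClasses = list(character = "site_id"))
  class(tab) <- c("site_stat_table", "data.frame")
  tab
}
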