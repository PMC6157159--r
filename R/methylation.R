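#' Construct a methylation beta-value matrix
#'
#' @param values Numeric matrix, samples in rows, CpG sites in columns;
#'   beta values in `[0, 1]`, `NA` allowed.
#' @param sites Data frame of site annotation with columns `site_id`,
#'   `chrom`, `pos` (1-based bp), one row per column of `values` and in the
#'   same order. `chrom`/`pos` may be `NA` for sites never passed to the
#'   meQTL scan.
#' @param phase `"pre"` or `"post"` treatment phase label.
#' @return A `methylation_matrix` object: a list with elements `values`
#'   (dimnames set to sample/site ids), `sites` and `phase`.
#' @export
methylation_matrix <- function(values, sites, phase = c("pre", "post")) {
  phase <- match.arg(phase)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have sample ids as rownames")
  if (!all(c("site_id", "chrom", "pos") %in% names(sites))) {
    stop("sites must have columns site_id, chrom, pos")
  }
  if (nrow(sites) != ncol(values)) {
    stop("sites has ", nrow(sites), " rows but values has ", ncol(values),
         " columns")
  }
  if (anyDuplicated(sites$site_id)) stop("site_id must be unique")
  rng <- range(values, na.rm = TRUE)
  if (is.finite(rng[1L]) && (rng[1L] < 0 || rng[2L] > 1)) {
    stop("beta values must lie in [0, 1]")
  }
  colnames(values) <- sites$site_id
  structure(list(values = values,
                 sites = as.data.frame(sites, stringsAsFactors = FALSE),
                 phase = phase),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("methylation_matrix (%s): %d samples x %d sites\n",
              x$phase, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read / write methylation matrices as TSV
#'
#' The matrix file is tab-delimited with a `sample_id` first column and one
#' column per site; the annotation file has columns `site_id`, `chrom`,
#' `pos`.
#'
#' @param path Matrix TSV path.
#' @param sites_path Site-annotation TSV path.
#' @param phase Phase label for the returned object.
#' @return A `methylation_matrix` (reader); `path` invisibly (writer).
#' @export
read_methylation_tsv <- function(path, sites_path, phase = c("pre", "post")) {
  phase <- match.arg(phase)
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  ann <- data.table::fread(sites_path, sep = "\t", data.table = FALSE,
                           colClasses = list(character = "site_id"))
  ann <- ann[match(colnames(m), ann$site_id), , drop = FALSE]
  if (anyNA(ann$site_id)) stop("site annotation does not cover all sites")
  methylation_matrix(m, ann, phase)
}

#' @rdname read_methylation_tsv
#' @param m A `methylation_matrix`.
#' @export
write_methylation_tsv <- function(m, path, sites_path) {
  df <- data.frame(sample_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  data.table::fwrite(m$sites, sites_path, sep = "\t")
  invisible(path)
}

#' Subset a methylation matrix by samples
#'
#' @param m A `methylation_matrix`.
#' @param sample_ids Samples to retain (order preserved as given).
#' @return A `methylation_matrix` on the intersection of `sample_ids` with
#'   the samples present.
#' @export
subset_samples <- function(m, sample_ids) {
  keep <- intersect(sample_ids, rownames(m$values))
  methylation_matrix(m$values[keep, , drop = FALSE], m$sites, m$phase)
}
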