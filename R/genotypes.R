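#' Construct a genotype dosage matrix
#'
#' @param dosages Integer/numeric matrix, samples in rows, SNPs in columns,
#'   values in `{0, 1, 2}` (`NA` allowed), rownames = sample ids.
#' @param snps Data frame with columns `snp_id`, `chrom`, `pos` (1-based),
#'   one row per column of `dosages` in order.
#' @return A `genotype_matrix` object (list with `dosages`, `snps`).
#' @export
genotype_matrix <- function(dosages, snps) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages))) stop("dosages must have sample rownames")
  if (!all(c("snp_id", "chrom", "pos") %in% names(snps))) {
    stop("snps must have columns snp_id, chrom, pos")
  }
  if (nrow(snps) != ncol(dosages)) stop("snps rows must match dosage columns")
  bad <- !is.na(dosages) & !(dosages %in% c(0, 1, 2))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  colnames(dosages) <- snps$snp_id
  structure(list(dosages = dosages,
                 snps = as.data.frame(snps, stringsAsFactors = FALSE)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Minor allele frequency per SNP
#'
#' @param g A [genotype_matrix()].
#' @return Named numeric vector `min(p, 1 - p)` of the alternate-allele
#'   frequency `p`, computed from non-missing dosages; `NA` when a SNP has no
#'   calls.
#' @export
snp_maf <- function(g) {
  p <- colMeans(g$dosages, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Filter SNPs by minor allele frequency
#'
#' Retains SNPs with MAF strictly greater than `min_maf` (the conventional
#' "MAF > 1%" filter), MAF computed from non-missing dosages.
#'
#' @param g A [genotype_matrix()].
#' @param min_maf Strict lower bound (default `0.01`).
#' @return The filtered `genotype_matrix`.
#' @export
maf_filter <- function(g, min_maf = 0.01) {
  maf <- snp_maf(g)
  keep <- !is.na(maf) & maf > min_maf
  genotype_matrix(g$dosages[, keep, drop = FALSE],
                  g$snps[keep, , drop = FALSE])
}

#' Restrict a genotype matrix to a cis window
#'
#' @param g A [genotype_matrix()].
#' @param cpg_chrom,cpg_pos Chromosome and 1-based position of the CpG.
#' @param half_width_bp Window half-width; SNPs with
#'   `|pos - cpg_pos| <= half_width_bp` on `cpg_chrom` are retained (closed
#'   interval, default 1 Mb each side).
#' @return The windowed `genotype_matrix` (possibly with zero SNPs).
#' @export
cis_window <- function(g, cpg_chrom, cpg_pos, half_width_bp = 1e6) {
  keep <- g$snps$chrom == cpg_chrom &
    abs(g$snps$pos - cpg_pos) <= half_width_bp
  keep[is.na(keep)] <- FALSE
  genotype_matrix(g$dosages[, keep, drop = FALSE],
                  g$snps[keep, , drop = FALSE])
}

#' Read / write genotype dosages as TSV
#'
#' Matrix file: `sample_id` first column, then one column per SNP.
#' Annotation file: `snp_id`, `chrom`, `pos`.
#'
#' @param path,snps_path File paths.
#' @return A `genotype_matrix` (reader); `path` invisibly (writer).
#' @export
read_genotypes_tsv <- function(path, snps_path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  ann <- data.table::fread(snps_path, sep = "\t", data.table = FALSE,
                           colClasses = list(character = "snp_id"))
  ann <- ann[match(colnames(m), ann$snp_id), , drop = FALSE]
  if (anyNA(ann$snp_id)) stop("SNP annotation does not cover all SNPs")
  genotype_matrix(m, ann)
}

#' @rdname read_genotypes_tsv
#' @param g A `genotype_matrix`.
#' @export
write_genotypes_tsv <- function(g, path, snps_path) {
  df <- data.frame(sample_id = rownames(g$dosages), g$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  data.table::fwrite(g$snps, snps_path, sep = "\t")
  invisible(path)
}

#' Read biallelic genotypes from a VCF
#'
#' Parses the GT field of a (possibly minimal) VCF into alternate-allele
#' dosages. Multi-allelic records are dropped with a warning. Requires the
#' `vcfR` package.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return A [genotype_matrix()].
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_genotypes_vcf requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  biallelic <- !grepl(",", alt, fixed = TRUE)
  if (!all(biallelic)) {
    warning(sum(!biallelic), " multi-allelic records dropped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  count_alt <- function(s) {
    ifelse(is.na(s), NA_real_,
           vapply(strsplit(s, "[/|]"), function(a) {
             a <- suppressWarnings(as.numeric(a))
             if (anyNA(a)) NA_real_ else sum(a > 0)
           }, numeric(1)))
  }
  dos <- apply(gt, 2L, count_alt)
  dos <- matrix(dos, nrow = nrow(gt),
                dimnames = list(rownames(gt), colnames(gt)))
  snps <- data.frame(snp_id = rownames(gt),
                     chrom = fix[biallelic, "CHROM"],
                     pos = as.integer(fix[biallelic, "POS"]),
                     stringsAsFactors = FALSE)
  genotype_matrix(t(dos), snps)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCFv4.2 file with GT-only genotype fields (dosage 0 -> `0/0`,
#' 1 -> `0/1`, 2 -> `1/1`, missing -> `./.`), REF=A, ALT=G placeholders.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(g$dosages)),
                     collapse = "\t")), con)
  code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(g$dosages))) {
    d <- g$dosages[, j]
    gt <- ifelse(is.na(d), "./.", code[d + 1L])
    writeLines(paste(c(g$snps$chrom[j], g$snps$pos[j], g$snps$snp_id[j],
                       "A", "G", ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}
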