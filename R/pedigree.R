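#' Read a pedigree file
#'
#' Parses a whitespace-delimited pedigree file with the six standard leading
#' columns (family id, individual id, father id, mother id, sex, phenotype)
#' and validates its structure. The code `"0"` (or `NA`) marks a missing
#' parent; founders must have both parents missing.
#'
#' @param path Path to the pedigree file.
#' @param dialect One of `"fam"` (PLINK `.fam`; sixth column ignored),
#'   `"fam_birthorder"` (`.fam` layout with the phenotype column repurposed
#'   as birth order) or `"ped"` (`.ped`-like; six leading columns used, any
#'   further columns ignored).
#' @param header Logical; does the file carry a header line? Default `FALSE`,
#'   as in PLINK files.
#'
#' @return A `pedigree` data frame with columns `pedigree_id`,
#'   `individual_id`, `father_id`, `mother_id` (both `NA` for founders),
#'   `sex` (`"male"`, `"female"` or `"unknown"`) and `birth_order`
#'   (integer or `NA`).
#'
#' @details Sex is decoded from the PLINK convention (1 = male, 2 = female,
#'   anything else unknown). Structural validation rejects duplicated
#'   individual ids, parents missing from the family's record set,
#'   single-parent records, and cycles in the parentage graph (an individual
#'   listed as its own ancestor), naming an offending individual.
#'
#' @seealso [compute_kinship()], [extract_sibling_pairs()]
#' @export
read_pedigree <- function(path, dialect = c("fam", "fam_birthorder", "ped"),
                          header = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  tab <- utils::read.table(path, header = header, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 6L) {
    stop("pedigree file must have at least 6 whitespace-delimited columns")
  }
  sex_code <- tab[[5L]]
  sex <- ifelse(sex_code == "1", "male",
                ifelse(sex_code == "2", "female", "unknown"))
  birth_order <- rep(NA_integer_, nrow(tab))
  if (dialect == "fam_birthorder") {
    bo <- suppressWarnings(as.numeric(tab[[6L]]))
    bo[!is.finite(bo) | bo <= 0] <- NA_real_
    birth_order <- as.integer(bo)
  }
  ped <- data.frame(
    pedigree_id   = tab[[1L]],
    individual_id = tab[[2L]],
    father_id     = ifelse(tab[[3L]] == "0", NA_character_, tab[[3L]]),
    mother_id     = ifelse(tab[[4L]] == "0", NA_character_, tab[[4L]]),
    sex           = sex,
    birth_order   = birth_order,
    stringsAsFactors = FALSE
  )
  as_pedigree(ped)
}

#' Construct a validated pedigree object
#'
#' @param x Data frame with columns `pedigree_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`, `birth_order`.
#' @return `x`, validated, with class `pedigree` prepended.
#' @export
as_pedigree <- function(x) {
  required <- c("pedigree_id", "individual_id", "father_id", "mother_id",
                "sex", "birth_order")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("pedigree is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  rownames(x) <- NULL
  if (anyDuplicated(x$individual_id)) {
    dup <- x$individual_id[duplicated(x$individual_id)][1L]
    stop("duplicated individual_id in pedigree: ", dup)
  }
  one_parent <- xor(is.na(x$father_id), is.na(x$mother_id))
  if (any(one_parent)) {
    stop("individual ", x$individual_id[one_parent][1L],
         " has exactly one recorded parent; founders must have none")
  }
  # parents must exist within the same pedigree record set
  for (fam in unique(x$pedigree_id)) {
    rows <- x[x$pedigree_id == fam, ]
    parents <- stats::na.omit(c(rows$father_id, rows$mother_id))
    absent <- setdiff(unique(parents), rows$individual_id)
    if (length(absent)) {
      stop("parent ", absent[1L], " of pedigree ", fam,
           " has no record in that pedigree")
    }
  }
  .pedigree_topo_order(x)  # errors on cycles
  class(x) <- c("pedigree", "data.frame")
  x
}

# Topological order of individuals (parents before children); errors with the
# name of an individual on a parentage cycle.
.pedigree_topo_order <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$individual_id
  fa <- idx[ped$father_id]
  mo <- idx[ped$mother_id]
  placed <- rep(FALSE, n)
  order_out <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(fa) | placed[ifelse(is.na(fa), 1L, fa)]) &
      (is.na(mo) | placed[ifelse(is.na(mo), 1L, mo)])
    if (!any(ready)) break
    order_out <- c(order_out, which(ready))
    placed[ready] <- TRUE
  }
  if (length(order_out) < n) {
    bad <- ped$individual_id[!placed][1L]
    stop("parentage cycle detected in pedigree involving individual ", bad)
  }
  order_out
}

#' Pedigree kinship matrix by the recursive tabular method
#'
#' Computes expected kinship coefficients `phi(i, j)` — the probability that
#' two alleles drawn at random, one from each individual, are identical by
#' descent — for all pairs of pedigree members. Founders within and across
#' pedigrees are assumed unrelated, so the matrix is block-diagonal across
#' pedigrees.
#'
#' @param ped A [as_pedigree()] object.
#' @return A symmetric numeric matrix with individual ids as dimnames;
#'   diagonal entries are `0.5 (1 + f)` where `f` is the individual's
#'   inbreeding coefficient (`0.5` when non-inbred). Twice this matrix is
#'   the additive relatedness used as the mixed-model covariance.
#'
#' @details The recursion processes individuals with parents before children:
#'   `phi(i, i) = 0.5 + 0.5 phi(father_i, mother_i)` and, for `j` processed
#'   earlier, `phi(i, j) = 0.5 (phi(father_i, j) + phi(mother_i, j))`,
#'   with founder pairs at 0.
#'
#' @export
compute_kinship <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  phi <- matrix(0, n, n, dimnames = list(ped$individual_id, ped$individual_id))
  idx <- seq_len(n)
  names(idx) <- ped$individual_id
  fa <- idx[ped$father_id]
  mo <- idx[ped$mother_id]
  ord <- .pedigree_topo_order(ped)
  seen <- integer(0)
  for (i in ord) {
    if (is.na(fa[i])) {
      phi[i, i] <- 0.5
      # founder: unrelated to everyone already placed
    } else {
      phi[i, i] <- 0.5 + 0.5 * phi[fa[i], mo[i]]
      if (length(seen)) {
        v <- 0.5 * (phi[fa[i], seen] + phi[mo[i], seen])
        phi[i, seen] <- v
        phi[seen, i] <- v
      }
    }
    seen <- c(seen, i)
  }
  phi
}

#' Enumerate ordered full-sibling pairs
#'
#' Finds all distinct pairs of full siblings (same father and same mother,
#' both recorded) and orders each pair by birth: the earlier-born member
#' first. Missing or tied birth orders fall back to lexicographic
#' `individual_id` order, so the result is deterministic.
#'
#' @param ped A [as_pedigree()] object.
#' @param one_pair_per_sibship If `TRUE`, keep only the two earliest-born
#'   siblings of each sibship (one pair); by default every sibship of size
#'   `k` contributes `choose(k, 2)` pairs.
#' @return A `sibling_pairs` data frame with columns `pedigree_id`,
#'   `first_id`, `second_id`.
#' @export
extract_sibling_pairs <- function(ped, one_pair_per_sibship = FALSE) {
  stopifnot(inherits(ped, "pedigree"))
  kids <- ped[!is.na(ped$father_id) & !is.na(ped$mother_id), , drop = FALSE]
  out <- list()
  if (nrow(kids)) {
    key <- paste(kids$pedigree_id, kids$father_id, kids$mother_id, sep = "\r")
    for (sib in split(kids, key)) {
      if (nrow(sib) < 2L) next
      # birth order, NA last, then id — the pair-ordering rule
      o <- order(sib$birth_order, sib$individual_id, na.last = TRUE)
      sib <- sib[o, , drop = FALSE]
      if (one_pair_per_sibship) sib <- sib[1:2, , drop = FALSE]
      k <- nrow(sib)
      cmb <- utils::combn(k, 2L)
      out[[length(out) + 1L]] <- data.frame(
        pedigree_id = sib$pedigree_id[1L],
        first_id  = sib$individual_id[cmb[1L, ]],
        second_id = sib$individual_id[cmb[2L, ]],
        stringsAsFactors = FALSE
      )
    }
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(pedigree_id = character(0), first_id = character(0),
               second_id = character(0), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$pedigree_id, pairs$first_id, pairs$second_id), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  class(pairs) <- c("sibling_pairs", "data.frame")
  pairs
}

#' Restrict sibling pairs to available samples
#'
#' Keeps only pairs whose two members are both in `available`; used to derive
#' phase-specific (pre-treatment, post-treatment, common-sample) pair sets.
#'
#' @param pairs A `sibling_pairs` data frame.
#' @param available Character vector of sample ids present in a phase.
#' @return The filtered `sibling_pairs` data frame.
#' @export
restrict_pairs <- function(pairs, available) {
  keep <- pairs$first_id %in% available & pairs$second_id %in% available
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a kinship matrix as TSV
#'
#' @param phi Square kinship (or relatedness) matrix with id dimnames.
#' @param path Output path.
#' @return `path`, invisibly (writer); the matrix (reader).
#' @export
write_kinship_tsv <- function(phi, path) {
  df <- data.frame(sample_id = rownames(phi), phi, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_kinship_tsv
#' @export
read_kinship_tsv <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}
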