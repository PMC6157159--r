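# Independent oracles and fixture builders used across the suite.

# Spearman correlation from first principles: average ranks on ties, then the
# Pearson product-moment formula applied to the ranks. Kept deliberately
# separate from the implementation path.
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Dense multivariate-normal log-density of y ~ N(X beta, sigma_g2 (R + delta I)),
# evaluated with generic solve/determinant — no spectral shortcut.
dense_mvn_loglik <- function(y, X, beta, sigma_g2, delta, R) {
  n <- length(y)
  V <- sigma_g2 * (R + delta * diag(n))
  r <- y - drop(X %*% beta)
  as.numeric(-0.5 * (n * log(2 * pi) + determinant(V)$modulus[1L] +
                       crossprod(r, solve(V, r))))
}

# Monte Carlo kinship by gene dropping: founders carry unique allele labels,
# transmission is resampled per replicate, and phi(i, j) is estimated as the
# probability that one random allele from i matches one from j by descent.
# Vectorized across replicates.
gene_drop_kinship <- function(ped, n_rep = 1e5) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$individual_id
  fa <- idx[ped$father_id]
  mo <- idx[ped$mother_id]
  a1 <- matrix(0L, n_rep, n)
  a2 <- matrix(0L, n_rep, n)
  lab <- 0L
  for (i in famvar:::.pedigree_topo_order(ped)) {
    if (is.na(fa[i])) {
      a1[, i] <- lab + 1L
      a2[, i] <- lab + 2L
      lab <- lab + 2L
    } else {
      pick <- stats::runif(n_rep) < 0.5
      a1[, i] <- ifelse(pick, a1[, fa[i]], a2[, fa[i]])
      pick <- stats::runif(n_rep) < 0.5
      a2[, i] <- ifelse(pick, a1[, mo[i]], a2[, mo[i]])
    }
  }
  phi <- matrix(0, n, n, dimnames = list(ped$individual_id, ped$individual_id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      phi[i, j] <- phi[j, i] <- mean(
        (a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
          (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])) / 4
    }
  }
  phi
}

# Hand-built pedigree data frames ------------------------------------------

make_ped <- function(pedigree_id, individual_id, father_id, mother_id,
                     sex = "unknown", birth_order = NA_integer_) {
  as_pedigree(data.frame(pedigree_id, individual_id, father_id, mother_id,
                         sex, birth_order, stringsAsFactors = FALSE))
}

# One nuclear family: founders pa/ma plus k children with birth orders 1..k.
nuclear_ped <- function(k = 2, fam = "f1") {
  make_ped(fam,
           c(paste0(fam, "_pa"), paste0(fam, "_ma"),
             paste0(fam, "_o", seq_len(k))),
           c(NA, NA, rep(paste0(fam, "_pa"), k)),
           c(NA, NA, rep(paste0(fam, "_ma"), k)),
           c("male", "female", rep("unknown", k)),
           c(NA, NA, seq_len(k)))
}

# Three-generation, 10-member pedigree: two founder couples, three
# second-generation children plus a married-in founder, two grandchildren.
three_gen_ped <- function() {
  make_ped("f1",
           c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J"),
           c(NA, NA, NA, NA, "A", "A", "C", NA, "E", "F"),
           c(NA, NA, NA, NA, "B", "B", "D", NA, "H", "G"),
           c("male", "female", "male", "female", "male", "male", "female",
             "female", "male", "female"))
}

# A minimal methylation matrix from a plain values matrix.
make_meth <- function(values, phase = "pre", chrom = NULL, pos = NULL) {
  ns <- ncol(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("ind%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("cg%03d", seq_len(ns))
  }
  sites <- data.frame(site_id = colnames(values),
                      chrom = if (is.null(chrom)) rep("1", ns) else chrom,
                      pos = if (is.null(pos)) seq_len(ns) * 1000L else pos,
                      stringsAsFactors = FALSE)
  methylation_matrix(values, sites, phase)
}

# Small simulation config for fast end-to-end tests.
small_sim_config <- function(seed = 1, ...) {
  sim_config(n_pedigrees = 40, n_sites = 300,
             sibship_size_distribution = c("2" = 0.5, "3" = 0.5),
             site_class_fractions = c(null = 0.9, constitutive_meqtl = 0.05,
                                      responsive = 0.05),
             snps_per_window = 5, seed = seed, ...)
}
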