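#' Simulation configuration for a synthetic pedigree methylation study
#'
#' Bundles and validates the generative parameters for a two-phase
#' (pre/post-treatment) pedigree methylation study with planted genetic
#' effects. Defaults emulate the structure the screen is designed for:
#' nuclear families whose sibling-pair count matches a ~182-pedigree family
#' study (~164 expected pairs), a latent liability with additive-genetic,
#' shared-sibship and residual components, a post-treatment batch shift, and
#' cis-SNP effects that are absent pre-treatment at "responsive" sites.
#'
#' @param n_pedigrees Number of nuclear families (default 182).
#' @param sibship_size_distribution Named probability vector over sibship
#'   sizes; names are the sizes. The default
#'   `c("1" = 0.46, "2" = 0.36, "3" = 0.18)` gives 0.90 expected sibling
#'   pairs per family, i.e. ~164 pairs at the default family count.
#' @param n_sites Number of CpG sites (default 5000).
#' @param site_class_fractions Named fractions over site classes `null`,
#'   `constitutive_meqtl` (SNP effect in both phases) and `responsive`
#'   (SNP effect post-treatment only); must sum to 1.
#' @param sigma_a2,sigma_c2,sigma_e2 Latent-scale variance components:
#'   additive polygenic, shared sibship environment, residual. Defaults
#'   `0.020 / 0.006 / 0.174` (total 0.2) give a null-site latent sibling
#'   correlation of 0.08 (familiality ~0.16, a modest typical methylation
#'   heritability) and a null beta-value SD around 0.1 at intermediate
#'   methylation, keeping null sites well below the planted sites'
#'   variability as on a real array.
#' @param responsive_ve Fraction of the post-treatment latent variance
#'   explained by the causal SNP at responsive sites (default 0.85; strong
#'   cis effects of this size are what make single-SNP methylation
#'   associations reach astronomically small p-values at modest n). The
#'   per-site allele effect is derived from the causal MAF so the fraction
#'   is exact: `beta = sqrt(ve / (1 - ve) * V0 / (2 p (1 - p)))`.
#' @param constitutive_ve Same, for constitutive meQTL sites in both phases
#'   (default 0.35).
#' @param batch_shift Latent-scale location shift added to every site
#'   post-treatment, emulating a treatment-confounded batch effect
#'   (default 0.3).
#' @param snp_maf_range Uniform range for founder minor allele frequencies
#'   of non-causal window SNPs (default `c(0.05, 0.5)`).
#' @param causal_maf_range Uniform MAF range for causal SNPs (default
#'   `c(0.2, 0.5)`): a single variant that explains most of the variance of
#'   a bounded beta value has to be common — a rare allele shifts only a few
#'   carriers and cannot spread the observed values, however large its
#'   latent effect.
#' @param snps_per_window SNPs simulated inside each meQTL-class site's
#'   +/-1 Mb window, the causal one within +/-50 kb of the CpG (default 20).
#' @param causal_offset_bp Half-range of the causal SNP's offset from its
#'   CpG (default 5e4).
#' @param post_retention Fraction of individuals retained post-treatment;
#'   whole pedigrees are kept or dropped (default 0.53, i.e. 530-from-995
#'   scale attrition).
#' @param mu_sd_null,mu_sd_meqtl SD of per-site baseline logit means: wide
#'   (2.0) for null sites, mimicking the bimodal array-wide beta
#'   distribution, and narrow (0.3) for meQTL-class sites, which sit at
#'   intermediate methylation.
#' @param seed Integer seed; every generator stage derives its stream from
#'   it, so a configuration reproduces byte-identical data.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_pedigrees = 182,
                       sibship_size_distribution = c("1" = 0.46, "2" = 0.36,
                                                     "3" = 0.18),
                       n_sites = 5000,
                       site_class_fractions = c(null = 0.99,
                                                constitutive_meqtl = 0.006,
                                                responsive = 0.004),
                       sigma_a2 = 0.020, sigma_c2 = 0.006, sigma_e2 = 0.174,
                       responsive_ve = 0.85, constitutive_ve = 0.35,
                       batch_shift = 0.3,
                       snp_maf_range = c(0.05, 0.5),
                       causal_maf_range = c(0.2, 0.5),
                       snps_per_window = 20,
                       causal_offset_bp = 5e4,
                       post_retention = 0.53,
                       mu_sd_null = 2, mu_sd_meqtl = 0.3,
                       seed = 1) {
  cfg <- list(n_pedigrees = as.integer(n_pedigrees),
              sibship_size_distribution = sibship_size_distribution,
              n_sites = as.integer(n_sites),
              site_class_fractions = site_class_fractions,
              sigma_a2 = sigma_a2, sigma_c2 = sigma_c2, sigma_e2 = sigma_e2,
              responsive_ve = responsive_ve, constitutive_ve = constitutive_ve,
              batch_shift = batch_shift,
              snp_maf_range = snp_maf_range,
              causal_maf_range = causal_maf_range,
              snps_per_window = as.integer(snps_per_window),
              causal_offset_bp = causal_offset_bp,
              post_retention = post_retention,
              mu_sd_null = mu_sd_null, mu_sd_meqtl = mu_sd_meqtl,
              seed = as.integer(seed))
  .validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

.validate_sim_config <- function(cfg) {
  f <- cfg$site_class_fractions
  if (!all(c("null", "constitutive_meqtl", "responsive") %in% names(f))) {
    stop("site_class_fractions must name null, constitutive_meqtl, responsive")
  }
  if (abs(sum(f) - 1) > 1e-12) stop("site_class_fractions must sum to 1")
  if (any(f < 0)) stop("site_class_fractions must be non-negative")
  for (v in c("sigma_a2", "sigma_c2", "sigma_e2")) {
    if (cfg[[v]] < 0) stop(v, " must be non-negative")
  }
  if (cfg$post_retention <= 0 || cfg$post_retention > 1) {
    stop("post_retention must be in (0, 1]")
  }
  for (v in c("responsive_ve", "constitutive_ve")) {
    if (cfg[[v]] < 0 || cfg[[v]] >= 1) stop(v, " must be in [0, 1)")
  }
  p <- cfg$sibship_size_distribution
  if (is.null(names(p)) || abs(sum(p) - 1) > 1e-12 || any(p < 0)) {
    stop("sibship_size_distribution must be a named probability vector")
  }
  if (cfg$n_pedigrees < 1L || cfg$n_sites < 1L) {
    stop("n_pedigrees and n_sites must be positive")
  }
  for (v in c("snp_maf_range", "causal_maf_range")) {
    r <- cfg[[v]]
    if (length(r) != 2L || r[1L] <= 0 || r[2L] > 0.5 || r[1L] > r[2L]) {
      stop(v, " must be a non-decreasing pair within (0, 0.5]")
    }
  }
  invisible(cfg)
}

# Stage-specific seed derived from the configuration seed; keeps independent
# streams for pedigree / site / genotype / methylation stages while remaining
# a deterministic function of cfg$seed (and below 2^31).
.stage_seed <- function(seed, stage) {
  (abs(seed) + stage * 1000003L) %% .Machine$integer.max
}

#' Simulate nuclear-family pedigrees
#'
#' Each family has two unrelated founders plus a sibship of sampled size,
#' with birth orders `1..k` and random offspring sex.
#'
#' @param cfg A [sim_config()].
#' @return A [as_pedigree()] data frame.
#' @export
simulate_pedigrees <- function(cfg) {
  set.seed(.stage_seed(cfg$seed, 1L))
  sizes <- as.integer(names(cfg$sibship_size_distribution))
  k <- sizes[sample.int(length(sizes), cfg$n_pedigrees, replace = TRUE,
                        prob = cfg$sibship_size_distribution)]
  rows <- vector("list", cfg$n_pedigrees)
  for (i in seq_len(cfg$n_pedigrees)) {
    fam <- sprintf("fam%04d", i)
    pa <- paste0(fam, "_pa")
    ma <- paste0(fam, "_ma")
    kid_sex <- sample(c("male", "female"), k[i], replace = TRUE)
    rows[[i]] <- data.frame(
      pedigree_id = fam,
      individual_id = c(pa, ma, sprintf("%s_o%d", fam, seq_len(k[i]))),
      father_id = c(NA, NA, rep(pa, k[i])),
      mother_id = c(NA, NA, rep(ma, k[i])),
      sex = c("male", "female", kid_sex),
      birth_order = c(NA_integer_, NA_integer_, seq_len(k[i])),
      stringsAsFactors = FALSE
    )
  }
  as_pedigree(do.call(rbind, rows))
}

#' Assign site classes, genomic layout and causal-SNP map
#'
#' Lays CpG sites out on chromosomes 1..22 with 2.5 Mb spacing (so +/-1 Mb
#' cis windows never overlap), assigns each site a class, draws baseline
#' logit means, and — for meQTL-class sites — places a causal SNP within
#' +/-`causal_offset_bp` of the CpG plus unlinked neighbors across the
#' window, with allele effects derived from the variance-explained targets.
#'
#' @param cfg A [sim_config()].
#' @return List with `sites` (site annotation: `site_id`, `chrom`, `pos`),
#'   `truth` (per site: `class`, `causal_snp`, `beta_pre`, `beta_post`,
#'   `mu`, `causal_maf`) and `snps` (SNP map: `snp_id`, `chrom`, `pos`,
#'   `maf`).
#' @export
simulate_site_classes <- function(cfg) {
  set.seed(.stage_seed(cfg$seed, 2L))
  n <- cfg$n_sites
  site_id <- sprintf("cg%07d", seq_len(n))
  chrom <- as.character(((seq_len(n) - 1L) %% 22L) + 1L)
  pos <- 1000000L + ((seq_len(n) - 1L) %/% 22L) * 2500000L

  f <- cfg$site_class_fractions
  n_resp <- round(f[["responsive"]] * n)
  n_const <- round(f[["constitutive_meqtl"]] * n)
  if (n_resp + n_const > n) stop("meQTL-class fractions exceed the site count")
  cls <- rep("null", n)
  special <- sample.int(n, n_resp + n_const)
  cls[special[seq_len(n_resp)]] <- "responsive"
  if (n_const) cls[special[n_resp + seq_len(n_const)]] <- "constitutive_meqtl"

  mu <- stats::rnorm(n, 0, ifelse(cls == "null", cfg$mu_sd_null,
                                  cfg$mu_sd_meqtl))
  v0 <- cfg$sigma_a2 + cfg$sigma_c2 + cfg$sigma_e2

  truth <- data.frame(site_id = site_id, class = cls,
                      causal_snp = NA_character_,
                      beta_pre = 0, beta_post = 0, mu = mu,
                      causal_maf = NA_real_, stringsAsFactors = FALSE)
  snp_rows <- list()
  for (i in which(cls != "null")) {
    k <- cfg$snps_per_window
    ids <- sprintf("%s_snp%02d", site_id[i], seq_len(k))
    maf <- c(stats::runif(1, cfg$causal_maf_range[1L], cfg$causal_maf_range[2L]),
             stats::runif(k - 1L, cfg$snp_maf_range[1L], cfg$snp_maf_range[2L]))
    p1 <- round(pos[i] + stats::runif(1, -cfg$causal_offset_bp,
                                      cfg$causal_offset_bp))
    pk <- round(pos[i] + stats::runif(k - 1L, -1e6, 1e6))
    snp_rows[[length(snp_rows) + 1L]] <- data.frame(
      snp_id = ids, chrom = chrom[i], pos = c(p1, pk), maf = maf,
      stringsAsFactors = FALSE
    )
    ve <- if (cls[i] == "responsive") cfg$responsive_ve else cfg$constitutive_ve
    beta <- sqrt(ve / (1 - ve) * v0 / (2 * maf[1L] * (1 - maf[1L])))
    truth$causal_snp[i] <- ids[1L]
    truth$causal_maf[i] <- maf[1L]
    truth$beta_post[i] <- beta
    truth$beta_pre[i] <- if (cls[i] == "constitutive_meqtl") beta else 0
  }
  snps <- if (length(snp_rows)) do.call(rbind, snp_rows) else
    data.frame(snp_id = character(0), chrom = character(0),
               pos = integer(0), maf = numeric(0))
  rownames(snps) <- NULL
  list(sites = data.frame(site_id = site_id, chrom = chrom, pos = pos,
                          stringsAsFactors = FALSE),
       truth = truth, snps = snps)
}

#' Gene-drop genotypes down a pedigree
#'
#' Founder alleles are drawn Bernoulli(allele frequency) per SNP under
#' Hardy-Weinberg equilibrium; each offspring receives one uniformly chosen
#' allele from each parent (Mendelian gene dropping), so the realized
#' dosage covariance among relatives matches twice the pedigree kinship.
#'
#' @param ped A [as_pedigree()].
#' @param cfg A [sim_config()] (supplies the seed).
#' @param snps SNP map with `snp_id`, `chrom`, `pos`, `maf`; by default the
#'   map from [simulate_site_classes()] on `cfg`.
#' @return A [genotype_matrix()] over all pedigree members.
#' @export
simulate_genotypes <- function(ped, cfg, snps = NULL) {
  if (is.null(snps)) snps <- simulate_site_classes(cfg)$snps
  set.seed(.stage_seed(cfg$seed, 3L))
  n <- nrow(ped)
  m <- nrow(snps)
  idx <- seq_len(n)
  names(idx) <- ped$individual_id
  fa <- idx[ped$father_id]
  mo <- idx[ped$mother_id]
  a1 <- matrix(0L, n, m)
  a2 <- matrix(0L, n, m)
  for (i in .pedigree_topo_order(ped)) {
    if (is.na(fa[i])) {
      a1[i, ] <- stats::rbinom(m, 1L, snps$maf)
      a2[i, ] <- stats::rbinom(m, 1L, snps$maf)
    } else {
      pick_f <- stats::rbinom(m, 1L, 0.5) == 1L
      pick_m <- stats::rbinom(m, 1L, 0.5) == 1L
      a1[i, ] <- ifelse(pick_f, a1[fa[i], ], a2[fa[i], ])
      a2[i, ] <- ifelse(pick_m, a1[mo[i], ], a2[mo[i], ])
    }
  }
  dos <- a1 + a2
  rownames(dos) <- ped$individual_id
  genotype_matrix(dos, snps[, c("snp_id", "chrom", "pos")])
}

# Draw the phase-persistent latent components: additive polygenic values
# (per pedigree, covariance sigma_a2 * 2 Phi) and sibship-shared environment.
# Founders get independent environment draws (they come from different
# households); full siblings share one draw.
.simulate_components <- function(ped, cfg, n_sites) {
  n <- nrow(ped)
  a <- matrix(0, n, n_sites)
  if (cfg$sigma_a2 > 0) {
    for (fam in unique(ped$pedigree_id)) {
      rows <- which(ped$pedigree_id == fam)
      sub <- ped[rows, , drop = FALSE]
      class(sub) <- c("pedigree", "data.frame")
      phi2 <- 2 * compute_kinship(sub)
      L <- t(chol(phi2 + diag(1e-10, nrow(phi2))))
      a[rows, ] <- sqrt(cfg$sigma_a2) *
        (L %*% matrix(stats::rnorm(length(rows) * n_sites),
                      nrow = length(rows)))
    }
  }
  cgrp <- ifelse(is.na(ped$father_id), ped$individual_id,
                 paste(ped$pedigree_id, ped$father_id, ped$mother_id,
                       sep = "\r"))
  grp <- match(cgrp, unique(cgrp))
  cmat <- matrix(0, n, n_sites)
  if (cfg$sigma_c2 > 0) {
    draws <- matrix(stats::rnorm(max(grp) * n_sites, 0, sqrt(cfg$sigma_c2)),
                    nrow = max(grp))
    cmat <- draws[grp, , drop = FALSE]
  }
  list(a = a, c = cmat)
}

#' Simulate a methylation beta-value matrix for one phase
#'
#' Realizes the latent model
#' `z = mu + beta_phase * dosage + a + c + batch * 1[post] + e` and maps it
#' through the logistic link to beta values in `(0, 1)`. The polygenic `a`
#' (covariance `sigma_a2 * 2 Phi` within pedigree) and sibship-shared `c`
#' persist across phases when supplied via `components` (as
#' [generate_study()] does); the residual `e` is always phase-specific.
#'
#' @param ped A [as_pedigree()].
#' @param g A [genotype_matrix()] covering the pedigree members.
#' @param truth Truth table from [simulate_site_classes()].
#' @param cfg A [sim_config()].
#' @param phase `"pre"` or `"post"`; post adds the batch shift and uses the
#'   phase-specific allele effects.
#' @param components Optional list `a`, `c` of phase-persistent latent
#'   matrices (rows aligned with `ped`); drawn internally when `NULL`.
#' @param samples Optional subset of individuals to emit (default all).
#' @param sites Site annotation (`site_id`, `chrom`, `pos`) aligned with
#'   `truth`; by default rebuilt from `cfg`.
#' @return A [methylation_matrix()] for the phase.
#' @export
simulate_methylation <- function(ped, g, truth, cfg,
                                 phase = c("pre", "post"),
                                 components = NULL, samples = NULL,
                                 sites = NULL) {
  phase <- match.arg(phase)
  if (is.null(sites)) sites <- simulate_site_classes(cfg)$sites
  set.seed(.stage_seed(cfg$seed, if (phase == "pre") 5L else 7L))
  if (is.null(components)) {
    components <- .simulate_components(ped, cfg, nrow(truth))
  }
  n <- nrow(ped)
  J <- nrow(truth)
  beta_eff <- if (phase == "pre") truth$beta_pre else truth$beta_post
  z <- matrix(truth$mu, n, J, byrow = TRUE)
  has_snp <- which(!is.na(truth$causal_snp) & beta_eff != 0)
  if (length(has_snp)) {
    dos <- g$dosages[ped$individual_id, truth$causal_snp[has_snp],
                     drop = FALSE]
    z[, has_snp] <- z[, has_snp] +
      sweep(dos, 2L, beta_eff[has_snp], `*`, check.margin = FALSE)
  }
  z <- z + components$a + components$c
  if (phase == "post") z <- z + cfg$batch_shift
  z <- z + matrix(stats::rnorm(n * J, 0, sqrt(cfg$sigma_e2)), n, J)
  rownames(z) <- ped$individual_id
  if (!is.null(samples)) z <- z[samples, , drop = FALSE]
  methylation_matrix(stats::plogis(z), sites, phase)
}

#' Generate a complete synthetic two-phase study
#'
#' One call producing a pedigree, gene-dropped genotypes, pre- and
#' post-treatment methylation matrices, and the ground-truth table. The
#' polygenic and shared-environment components are drawn once and shared by
#' the two phases (an individual's genetic value does not change with
#' treatment); the post-treatment sample is a whole-pedigree random subset
#' retaining `post_retention` of individuals, and carries the batch shift.
#' Everything is a deterministic function of `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional directory: when given, writes the pedigree
#'   (`pedigree.fam`, birth order in the sixth column), methylation and
#'   genotype TSVs with their annotation files, the truth table and the
#'   configuration JSON.
#' @return List with `ped`, `geno`, `pre`, `post`, `truth`, `sites`, `cfg`.
#' @export
generate_study <- function(cfg, dir = NULL) {
  ped <- simulate_pedigrees(cfg)
  layout <- simulate_site_classes(cfg)
  geno <- simulate_genotypes(ped, cfg, layout$snps)
  set.seed(.stage_seed(cfg$seed, 4L))
  comp <- .simulate_components(ped, cfg, nrow(layout$truth))
  pre <- simulate_methylation(ped, geno, layout$truth, cfg, "pre",
                              components = comp, sites = layout$sites)
  set.seed(.stage_seed(cfg$seed, 6L))
  retained <- .retain_pedigrees(ped, cfg$post_retention)
  post <- simulate_methylation(ped, geno, layout$truth, cfg, "post",
                               components = comp, samples = retained,
                               sites = layout$sites)
  study <- list(ped = ped, geno = geno, pre = pre, post = post,
                truth = layout$truth, sites = layout$sites, cfg = cfg)
  if (!is.null(dir)) write_study(study, dir)
  study
}

# Whole-pedigree dropout: permute pedigrees and keep a prefix whose
# cumulative size is closest to the retention target.
.retain_pedigrees <- function(ped, retention) {
  fams <- unique(ped$pedigree_id)
  sizes <- table(ped$pedigree_id)[fams]
  ord <- sample(length(fams))
  cum <- cumsum(as.integer(sizes[ord]))
  target <- retention * nrow(ped)
  n_keep <- which.min(abs(cum - target))
  keep_fams <- fams[ord[seq_len(n_keep)]]
  ped$individual_id[ped$pedigree_id %in% keep_fams]
}

#' Write a synthetic study to a directory
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ped <- study$ped
  sexcode <- c(male = "1", female = "2", unknown = "0")
  fam <- data.frame(ped$pedigree_id, ped$individual_id,
                    ifelse(is.na(ped$father_id), "0", ped$father_id),
                    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                    sexcode[ped$sex],
                    ifelse(is.na(ped$birth_order), "-9",
                           as.character(ped$birth_order)))
  utils::write.table(fam, file.path(dir, "pedigree.fam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_methylation_tsv(study$pre, file.path(dir, "methylation_pre.tsv"),
                        file.path(dir, "sites.tsv"))
  write_methylation_tsv(study$post, file.path(dir, "methylation_post.tsv"),
                        file.path(dir, "sites_post.tsv"))
  write_genotypes_tsv(study$geno, file.path(dir, "genotypes.tsv"),
                      file.path(dir, "snps.tsv"))
  data.table::fwrite(study$truth, file.path(dir, "truth.tsv"), sep = "\t")
  jsonlite::write_json(unclass(study$cfg), file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
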