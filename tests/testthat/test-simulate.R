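test_that("config validation names the offending field", {
  expect_error(sim_config(site_class_fractions = c(null = 0.5,
    constitutive_meqtl = 0.2, responsive = 0.2)), "sum to 1")
  expect_error(sim_config(sigma_a2 = -1), "sigma_a2")
  expect_error(sim_config(post_retention = 0), "post_retention")
  expect_error(sim_config(responsive_ve = 1), "responsive_ve")
  expect_error(sim_config(snp_maf_range = c(0.6, 0.7)), "snp_maf_range")
  expect_error(sim_config(sibship_size_distribution = c(0.5, 0.5)),
               "named probability")
})

test_that("default pedigree structure yields the intended sibling-pair scale", {
  ped <- simulate_pedigrees(sim_config(seed = 1))
  expect_equal(length(unique(ped$pedigree_id)), 182L)
  npairs <- nrow(extract_sibling_pairs(ped))
  # E[pairs] = 182 * 0.90 = 163.8 under the default sibship distribution
  expect_gt(npairs, 164 * 0.85)
  expect_lt(npairs, 164 * 1.15)
  # all-singleton sibships give no pairs
  ped1 <- simulate_pedigrees(sim_config(n_pedigrees = 30,
    sibship_size_distribution = c("1" = 1), seed = 2))
  expect_equal(nrow(extract_sibling_pairs(ped1)), 0L)
})

test_that("generation is deterministic under a fixed seed, on disk too", {
  cfg <- small_sim_config(seed = 123)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$ped, s2$ped)
  expect_identical(s1$geno$dosages, s2$geno$dosages)
  expect_identical(s1$pre$values, s2$pre$values)
  expect_identical(s1$post$values, s2$post$values)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(s1, d1)
  write_study(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  # a different seed changes the data
  s3 <- generate_study(small_sim_config(seed = 124))
  expect_false(identical(s1$pre$values, s3$pre$values))
})

test_that("gene dropping respects Mendelian transmission", {
  cfg <- small_sim_config(seed = 31)
  study <- generate_study(cfg)
  ped <- study$ped
  dos <- study$geno$dosages
  kids <- which(!is.na(ped$father_id))
  for (i in kids) {
    dk <- dos[ped$individual_id[i], ]
    df <- dos[ped$father_id[i], ]
    dm <- dos[ped$mother_id[i], ]
    # child allele counts must be attainable from one allele per parent
    min_k <- as.integer(df == 2) + as.integer(dm == 2)
    max_k <- as.integer(df >= 1) + as.integer(dm >= 1)
    expect_true(all(dk >= min_k & dk <= max_k))
  }
})

test_that("founder dosages match the nominal allele frequency", {
  cfg <- sim_config(n_pedigrees = 2500,
                    sibship_size_distribution = c("1" = 1),
                    n_sites = 1,
                    site_class_fractions = c(null = 0, constitutive_meqtl = 0,
                                             responsive = 1),
                    causal_maf_range = c(0.3, 0.3),
                    snp_maf_range = c(0.3, 0.3),
                    snps_per_window = 4, seed = 17)
  ped <- simulate_pedigrees(cfg)
  g <- simulate_genotypes(ped, cfg)
  founders <- ped$individual_id[is.na(ped$father_id)]  # 5000 founders
  m <- mean(g$dosages[founders, ])
  expect_lt(abs(m - 0.6), 0.02)
})

test_that("sibling dosage correlation is near one half", {
  cfg <- sim_config(n_pedigrees = 500,
                    sibship_size_distribution = c("2" = 1),
                    n_sites = 2,
                    site_class_fractions = c(null = 0, constitutive_meqtl = 0,
                                             responsive = 1),
                    snps_per_window = 10, seed = 23)
  ped <- simulate_pedigrees(cfg)
  g <- simulate_genotypes(ped, cfg)
  pairs <- extract_sibling_pairs(ped)
  # per-SNP correlations averaged (pooling SNPs of different MAF would mix
  # between-SNP mean differences into the correlation)
  r <- vapply(seq_len(ncol(g$dosages)), function(j)
    stats::cor(g$dosages[pairs$first_id, j], g$dosages[pairs$second_id, j]),
    numeric(1))
  expect_lt(abs(mean(r) - 0.5), 0.05)
})

test_that("a fully degenerate configuration yields beta values of exactly one half", {
  cfg <- sim_config(n_pedigrees = 5, n_sites = 10,
                    site_class_fractions = c(null = 1, constitutive_meqtl = 0,
                                             responsive = 0),
                    sigma_a2 = 0, sigma_c2 = 0, sigma_e2 = 0,
                    batch_shift = 0, mu_sd_null = 0, mu_sd_meqtl = 0,
                    post_retention = 1, seed = 3)
  study <- generate_study(cfg)
  expect_true(all(study$pre$values == 0.5))
  expect_true(all(study$post$values == 0.5))
})

test_that("the truth table encodes the planted classes", {
  study <- generate_study(small_sim_config(seed = 41))
  truth <- study$truth
  resp <- truth[truth$class == "responsive", ]
  expect_true(all(resp$beta_pre == 0 & resp$beta_post != 0))
  const <- truth[truth$class == "constitutive_meqtl", ]
  expect_true(all(const$beta_pre == const$beta_post & const$beta_post > 0))
  nul <- truth[truth$class == "null", ]
  expect_true(all(nul$beta_pre == 0 & nul$beta_post == 0))
  expect_true(all(is.na(nul$causal_snp)))
  # causal SNPs sit within 50 kb of their CpG
  idx <- match(truth$causal_snp[truth$class != "null"], study$geno$snps$snp_id)
  site_pos <- study$sites$pos[match(truth$site_id[truth$class != "null"],
                                    study$sites$site_id)]
  expect_true(all(abs(study$geno$snps$pos[idx] - site_pos) <= 5e4))

  all_null <- generate_study(sim_config(n_pedigrees = 5, n_sites = 20,
    site_class_fractions = c(null = 1, constitutive_meqtl = 0,
                             responsive = 0), seed = 4))
  expect_true(all(all_null$truth$class == "null"))
  expect_equal(nrow(all_null$geno$snps), 0L)
})

test_that("post-treatment retention drops whole pedigrees near the target fraction", {
  cfg <- sim_config(n_pedigrees = 100, seed = 19, n_sites = 10)
  study <- generate_study(cfg)
  post_ids <- rownames(study$post$values)
  ped <- study$ped
  kept_fams <- unique(ped$pedigree_id[ped$individual_id %in% post_ids])
  # every kept pedigree is complete
  for (fam in kept_fams) {
    members <- ped$individual_id[ped$pedigree_id == fam]
    expect_true(all(members %in% post_ids))
  }
  expect_lt(abs(length(post_ids) / nrow(ped) - 0.53), 0.05)
})

test_that("responsive sites gain variability after treatment", {
  cfg <- sim_config(n_pedigrees = 60, n_sites = 400,
                    sibship_size_distribution = c("2" = 1),
                    site_class_fractions = c(null = 0.5,
                                             constitutive_meqtl = 0,
                                             responsive = 0.5),
                    post_retention = 1, snps_per_window = 2, seed = 29)
  study <- generate_study(cfg)
  resp <- study$truth$site_id[study$truth$class == "responsive"]
  sd_pre <- site_sd(study$pre)[resp]
  sd_post <- site_sd(study$post)[resp]
  tt <- stats::t.test(sd_post, sd_pre, paired = TRUE, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
  # and higher expected post SD / scor than null sites
  nul <- study$truth$site_id[study$truth$class == "null"]
  expect_gt(mean(site_sd(study$post)[resp]), mean(site_sd(study$post)[nul]))
  pairs <- extract_sibling_pairs(study$ped)
  sp <- sibling_spearman(study$post, pairs)$scor
  expect_gt(mean(sp[resp]), mean(sp[nul]))
})

test_that("the batch shift moves post means but preserves null-site SD ranks", {
  cfg <- sim_config(n_pedigrees = 150, n_sites = 800, seed = 37)
  study <- generate_study(cfg)
  nul <- study$truth$site_id[study$truth$class == "null"]
  shared <- intersect(rownames(study$pre$values), rownames(study$post$values))
  mean_shift <- mean(qlogis(study$post$values[shared, nul])) -
    mean(qlogis(study$pre$values[shared, nul]))
  expect_gt(mean_shift, 0.2)  # batch_shift = 0.3 on the latent scale
  rc <- stats::cor(site_sd(study$pre)[nul], site_sd(study$post)[nul],
                   method = "spearman")
  expect_gt(rc, 0.9)
})
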