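#!/usr/bin/env Rscript
# Step 2 — per-site variability and familiality, both phases.
#
# For every CpG site: the sample SD over each phase's full sample, and the
# Spearman correlation between earlier- and later-born members of each full
# sibling pair (the familiality surrogate; twice this correlation bounds the
# heritability of the site's methylation from above). Ranks (1 = largest)
# are assigned within each of the four distributions.

library(famvar)

ped <- read_pedigree("results/study/pedigree.fam", dialect = "fam_birthorder")
pre <- read_methylation_tsv("results/study/methylation_pre.tsv",
                            "results/study/sites.tsv", phase = "pre")
post <- read_methylation_tsv("results/study/methylation_post.tsv",
                             "results/study/sites_post.tsv", phase = "post")

stats <- build_site_stat_table(pre, post, ped)
write_site_stats_tsv(stats, "results/site_stats.tsv")

message(sprintf("sites: %d; median SD pre/post: %.3f / %.3f",
                nrow(stats), median(stats$sd_pre), median(stats$sd_post)))
message(sprintf("median scor pre/post: %.3f / %.3f (pairs: %d / %d)",
                median(stats$scor_pre, na.rm = TRUE),
                median(stats$scor_post, na.rm = TRUE),
                max(stats$npairs_pre), max(stats$npairs_post)))
top <- stats[order(stats$rank_scor_post), ][1:5, ]
message("five most familial sites post-treatment (heritability bound = 2*scor, capped at 1):")
print(data.frame(site = top$site_id, scor_post = round(top$scor_post, 3),
                 h2_upper = round(heritability_upper_bound(top$scor_post), 3)))
message("site statistics written to results/site_stats.tsv")
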