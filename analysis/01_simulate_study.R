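#!/usr/bin/env Rscript
# Step 1 — generate the synthetic two-phase pedigree methylation study.
#
# The default configuration emulates the study structure the screen targets:
# 182 nuclear families (~164 sibling pairs pre-treatment), 5,000 CpG sites of
# which a handful carry planted cis-SNP effects that are present only
# post-treatment ("responsive") or in both phases ("constitutive"), a
# post-treatment batch shift, and whole-pedigree attrition to ~53% of
# individuals after treatment.

library(famvar)

seed <- 20260924 %% 10000
cfg <- sim_config(seed = seed)
study <- generate_study(cfg, dir = "results/study")

pairs <- extract_sibling_pairs(study$ped)
message(sprintf("pedigrees: %d; individuals: %d; sibling pairs (pre): %d",
                length(unique(study$ped$pedigree_id)), nrow(study$ped),
                nrow(pairs)))
message(sprintf("post-treatment sample: %d individuals, %d sibling pairs",
                nrow(study$post$values),
                nrow(restrict_pairs(pairs, rownames(study$post$values)))))
print(table(study$truth$class))
message("study written to results/study/")
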