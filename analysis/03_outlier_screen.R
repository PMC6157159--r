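#!/usr/bin/env Rscript
# Step 3 — the outlier-concordance screen.
#
# Upper-tail outliers (0.1% of sites, with 0.5% and 1% fallbacks) are taken
# from the four rank distributions; sites outlying in BOTH post-treatment
# distributions but in NEITHER pre-treatment distribution are the candidate
# treatment-responsive CpG sites. Turnover quantifies how much the outlier
# sets change between phases.

library(famvar)

stats <- read_site_stats_tsv("results/site_stats.tsv")
report <- run_outlier_pipeline(stats, threshold_fraction = 0.001,
                               fallback_fractions = c(0.005, 0.01))
write_outlier_report(report, "results/outliers")

print(report)
truth_path <- "results/study/truth.tsv"
if (file.exists(truth_path)) {
  truth <- data.table::fread(truth_path, data.table = FALSE)
  cls <- truth$class[match(report$candidates, truth$site_id)]
  message("candidate classes against simulation truth: ",
          paste(sprintf("%s=%d", names(table(cls)), table(cls)),
                collapse = ", "))
  resp <- truth$site_id[truth$class == "responsive"]
  message(sprintf("recall of planted responsive sites: %.2f",
                  mean(resp %in% report$candidates)))
}
writeLines(report$candidates, "results/candidates.txt")
message("outlier report written to results/outliers/; candidates to results/candidates.txt")
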