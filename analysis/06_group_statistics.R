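#!/usr/bin/env Rscript
# Group-level statistics, two ways:
#   (a) on the simulated session: counts-by-area table and anterior-vs-
#       posterior contrasts (Fisher's exact tests, odds-ratio CIs), plus a
#       permutation median test comparing mean auROC responses between
#       discovered excitatory and inhibitory units;
#   (b) on the published reference count table: the five region contrasts
#       whose odds-ratio CIs the package reproduces.
# Writes results/group_stats.json.

suppressPackageStartupMessages(library(vocalmod))

units <- read.csv("results/response_profiles.csv")
disc <- read.csv("results/discovered_types.csv")
units$type <- "NR"
units$type[match(disc$unit_id, units$unit_id)] <- disc$type

part <- assign_part(units$ap_mm)
region_part <- paste0(units$region, "-",
                      ifelse(part == "anterior", "A", "P"))
counts <- build_count_table(units$type, region_part)
cat("simulated counts-by-area table:\n")
print(counts)

out <- list()
if (all(c("M1-A", "M1-P", "M2-A", "M2-P") %in% rownames(counts))) {
  tabs <- region_contrast_tables(counts)
  out$simulated <- lapply(tabs, function(tb) {
    ci <- odds_ratio_ci(tb)
    list(fisher_p = fisher_exact_p(tb), or = ci$or,
         ci = c(ci$lower, ci$upper))
  })
}

# E vs I contrast of mean auROC responses around first calls
vec <- read.csv("results/response_vectors.csv")
post <- rowMeans(vec[, c(12:16, 22:26)])  # columns after unit_id
fam <- substr(units$type[match(vec$unit_id, units$unit_id)], 1, 1)
if (sum(fam == "E") >= 2 && sum(fam == "I") >= 2) {
  pm <- permutation_median_test(post[fam == "E"], post[fam == "I"],
                                seed = 1)
  cat(sprintf(
    "E vs I mean auROC: diff %.3f, p %.4g, 95%% CI [%.3f, %.3f]\n",
    pm$statistic, pm$p.value, pm$ci[1], pm$ci[2]))
  out$e_vs_i_auroc <- list(median_diff = pm$statistic, p = pm$p.value,
                           ci = pm$ci)
}

ref_tabs <- region_contrast_tables(usv_response_counts())
out$reference <- lapply(ref_tabs, function(tb) {
  ci <- odds_ratio_ci(tb)
  list(fisher_p = fisher_exact_p(tb), or = ci$or,
       ci = c(round(ci$lower, 2), round(ci$upper, 2)))
})
cat("reference contrasts (odds ratio [95% CI]):\n")
for (nm in names(ref_tabs)) {
  r <- out$reference[[nm]]
  cat(sprintf("  %-14s %.2f [%.2f, %.2f]\n", nm, r$or, r$ci[1], r$ci[2]))
}

jsonlite::write_json(out, "results/group_stats.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
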