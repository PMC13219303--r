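#!/usr/bin/env Rscript
# Stage 2: outlier pre-screen and careless-responding detection.
#
# Reproduces the screening flow: univariate outliers on standardized totals
# (|z| > 4) are removed first, then the instructed-response item defines the
# primary careless flag; longstring and even-odd consistency supply the
# extended (union) definition with cuts at two standard deviations above the
# unscreened means.

library(carescreen)

data_dir <- "results/data"
out_dir <- "results/screen"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

design <- read_design(file.path(data_dir, "design_key.yaml"))
m <- read_responses(file.path(data_dir, "responses.csv"), design)

totals <- scale_scores(recode_reverse(m, design), design)
out_fl <- outlier_flag(totals, 4)
cat(sum(out_fl), "of", length(out_fl),
    "respondents removed as |z| > 4 outliers;", sum(!out_fl), "retained\n")
m <- subset_respondents(m, !out_fl)

sr <- screen_sample(m, design)
utils::write.csv(sr, file.path(out_dir, "flags.csv"), row.names = FALSE)
thresholds <- list(longstring_cut = attr(sr, "longstring_cut"),
                   evenodd_cut = attr(sr, "evenodd_cut"),
                   z_cut = attr(sr, "z_cut"),
                   n = nrow(sr),
                   n_primary = sum(sr$flag_primary),
                   n_extended = sum(sr$flag_extended),
                   prevalence_primary_pct =
                     careless_prevalence(sum(sr$flag_primary), nrow(sr)),
                   prevalence_extended_pct =
                     careless_prevalence(sum(sr$flag_extended), nrow(sr)))
jsonlite::write_json(thresholds, file.path(out_dir, "thresholds.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("primary (instructed item): %d flagged (%.2f%%)\n",
            thresholds$n_primary, thresholds$prevalence_primary_pct))
cat(sprintf("extended (union, cuts %.2f / %.3f): %d flagged (%.2f%%)\n",
            thresholds$longstring_cut, thresholds$evenodd_cut,
            thresholds$n_extended, thresholds$prevalence_extended_pct))

# convergence of the post-hoc indices with the instructed-item flag
for (idx in c("longstring", "evenodd")) {
  es <- cohens_d(sr[[idx]][sr$flag_primary], sr[[idx]][!sr$flag_primary])
  cat(sprintf("%s careless vs attentive: d = %.2f [%.2f, %.2f] (%s)\n",
              idx, es$cohens_d, es$ci[1], es$ci[2], es$d_label))
}
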