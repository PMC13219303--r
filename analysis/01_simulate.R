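#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# Emulates the study conditions: 1,112 respondents on the 37-item
# three-factor battery (instructed item at position 26), 11.33% careless
# prevalence with an agree-skewed careless mixture, plus the two criterion
# scales (19-item 0..10, 9-item 1..7) presented after the focal instrument —
# 65 battery items in all.

library(carescreen)

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- default_sdas_config(seed = 2025,
                           criterion_block = default_criterion_blocks())
study <- assemble_study(cfg)
m <- study$responses

write_design(study$design, file.path(out_dir, "design_key.yaml"))
write_responses(m, file.path(out_dir, "responses.csv"))
utils::write.csv(data.frame(respondent_id = m$respondent_ids,
                            truth = m$truth_labels),
                 file.path(out_dir, "truth_labels.csv"), row.names = FALSE)

tab <- table(m$truth_labels)
cat("simulated", nrow(m$values), "respondents x", ncol(m$values),
    "battery items\n")
cat("careless:", sum(m$truth_labels != "attentive"),
    sprintf("(%.2f%%), mixture:\n",
            100 * mean(m$truth_labels != "attentive")))
print(tab)
cat("wrote", file.path(out_dir, c("design_key.yaml", "responses.csv",
                                  "truth_labels.csv")), sep = "\n  ")
cat("\n")
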