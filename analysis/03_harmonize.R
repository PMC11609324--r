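#!/usr/bin/env Rscript
# Stage 3 - remove site/scanner effects from the connectivity features.
#
# Parametric empirical-Bayes location/scale adjustment with age, sex and
# the six psychopathology sum scores preserved as covariates.

suppressPackageStartupMessages(library(ernfc))

features <- read_tsv_table("results/cohort_features.tsv")
harmonized <- harmonize_features(features)

site_sd <- function(d) {
  mean(sapply(feature_keys(), function(k) {
    sd(sapply(split(d[[k]], d$site_id), mean))
  }))
}
cat(sprintf("mean between-site SD of features: %.4f before, %.4f after\n",
            site_sd(features), site_sd(harmonized)))

write_tsv_table(harmonized, "results/cohort_features_harmonized.tsv")
write_combat_model(attr(harmonized, "combat_model"),
                   "results/combat_model.json")
cat("wrote results/cohort_features_harmonized.tsv and results/combat_model.json\n")
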