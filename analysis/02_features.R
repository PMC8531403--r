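#!/usr/bin/env Rscript
# Step 2: build the Fisher-z edge feature table.
#
# Each subject's ROI-by-time series is correlated (Pearson), the strict
# lower triangle is vectorized in the canonical edge order and Fisher
# z-transformed: one row per subject, one column per edge. The synthetic
# series are generated stationary and trend-free, so no additional
# cleaning is applied here; for real acquisitions clean_series() would
# run first (detrend, nuisance regression, 0.01-0.08 Hz bandpass).

library(fcmvpa)

cohort <- read_cohort("results/analysis/cohort")
feats <- fc_feature_table(cohort$series)
stopifnot(nrow(feats) == nrow(cohort$phenotype))

utils::write.csv(
  data.frame(subject_id = rownames(feats), round(feats, 8),
             check.names = FALSE),
  "results/analysis/features.csv", row.names = FALSE)
cat(sprintf("feature table: %d subjects x %d edges -> %s\n",
            nrow(feats), ncol(feats), "results/analysis/features.csv"))
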