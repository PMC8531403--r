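#!/usr/bin/env Rscript
# Step 1: simulate the two-site cohort.
#
# Two scanners with the study's acquisition asymmetry (170 usable volumes
# at TR 2.0 s vs 440 at TR 0.8 s, noisier site 2), 27/11 and 26/36
# patients/controls, a 20-ROI parcellation (190 edges), a sparse set of
# 15 edges shifted by +0.3 Fisher-z in patients, and a preoperative JOA
# score driven by 5 low-noise score-linked edges. Writes the cohort as plain text under
# results/analysis/cohort/.

library(fcmvpa)

out <- "results/analysis/cohort"
cfg <- synthetic_config(n_rois = 20, n_disc_edges = 15, n_score_edges = 5,
                        score_noise_sd = 0.3, seed = 20211008)
cohort <- generate_cohort(cfg)
write_cohort(cohort, out)

print(cohort)
ph <- cohort$phenotype
pat <- subset(ph, group == "patient")
cat(sprintf("patient pre-JOA: %.1f +/- %.1f; recovery: %.1f +/- %.1f\n",
            mean(pat$joa_pre), sd(pat$joa_pre),
            mean(pat$joa_post - pat$joa_pre),
            sd(pat$joa_post - pat$joa_pre)))
cat("cohort written to", out, "\n")
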