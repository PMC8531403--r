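#!/usr/bin/env Rscript
# Step 6: Bland-Altman agreement between predicted and actual scores.
#
# For every prediction analysis (target x site/direction): bias, SD of
# the differences, 95% limits of agreement (bias +/- 1.96 SD) and the
# fraction of points within them. Writes the LOA table and a panel of
# difference-vs-mean plots.

library(fcmvpa)

predictions <- read.csv("results/analysis/predictions.csv")
keys <- unique(predictions[, c("target", "analysis")])

agree <- do.call(rbind, lapply(seq_len(nrow(keys)), function(k) {
  sub <- subset(predictions, target == keys$target[k] &
                  analysis == keys$analysis[k])
  ba <- bland_altman(sub$predicted, sub$actual)
  data.frame(target = keys$target[k], analysis = keys$analysis[k],
             n = nrow(sub), bias = ba$bias, sd = ba$sd,
             loa_low = ba$loa_low, loa_high = ba$loa_high,
             within_loa = ba$within_loa)
}))
write.csv(agree, "results/analysis/agreement.csv", row.names = FALSE)
print(agree, digits = 3)
cat(sprintf("overall fraction of points within the LOA: %.3f\n",
            weighted.mean(agree$within_loa, agree$n)))

grDevices::png("results/analysis/bland_altman.png", width = 1600,
               height = 1200, res = 150)
par(mfrow = c(ceiling(nrow(keys) / 3), 3), mar = c(4, 4, 2, 1))
for (k in seq_len(nrow(keys))) {
  sub <- subset(predictions, target == keys$target[k] &
                  analysis == keys$analysis[k])
  plot(bland_altman(sub$predicted, sub$actual),
       main = paste(keys$target[k], keys$analysis[k]), pch = 19)
}
dev.off()
cat("plots -> results/analysis/bland_altman.png\n")
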