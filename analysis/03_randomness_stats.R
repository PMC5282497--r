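#!/usr/bin/env Rscript
# Inferential summary of the cohort run: is the radial and longitudinal
# organization non-random (against equal thirds and against the
# volume-weighted Monte-Carlo null), and is it reproducible across
# subjects? Reads the tables written by 02_image_analysis.R.

library(spermtopo)

stats <- read.csv("results/pipeline/stats_tests.csv")

pooled <- stats[stats$subject == "pooled", ]
cat("pooled tests (one per channel x axis x null):\n")
print(pooled[, c("target", "axis", "null_kind", "chi2", "df", "p")],
      row.names = FALSE, digits = 3)

per_subject <- stats[!(stats$subject %in% c("pooled", "between-subjects")), ]
agg <- aggregate(p ~ target + axis, per_subject,
                 function(p) c(n = length(p), significant = sum(p < 0.05)))
cat("\nper-subject rejections of the equal-thirds null (p < 0.05):\n")
print(cbind(agg[1:2], n = agg$p[, 1], significant = agg$p[, 2]),
      row.names = FALSE)

homog <- stats[stats$subject == "between-subjects", ]
cat("\nbetween-subject homogeneity (reproducibility; p > 0.05 = no subject effect):\n")
print(homog[, c("target", "axis", "chi2", "df", "p")],
      row.names = FALSE, digits = 3)

verdict <- data.frame(
  check = c("all pooled equal-thirds tests reject randomness",
            "all per-subject tests reject randomness",
            "no between-subject heterogeneity"),
  result = c(all(pooled$p[pooled$null_kind == "equal_thirds"] < 0.05),
             all(per_subject$p < 0.05),
             all(homog$p > 0.05)))
write.csv(verdict, "results/03_stats_verdicts.csv", row.names = FALSE)
print(verdict, row.names = FALSE)
cat("wrote results/03_stats_verdicts.csv\n")
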