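#!/usr/bin/env Rscript
# Step 1 - structural calibration.
#
# The published description of the rescue model leaves several mechanics
# open: how the printed rate columns map onto per-cycle transition
# probabilities, the within-cycle ordering of rescue and death, how the
# rescued-victims survival column acts, and which fixed cost components the
# intervention arm carries. This script searches the full switch grid
# against the published base case (both arms' costs and QALYs and the 5%
# ICER, each at 10% relative tolerance, plus cost-saving dominance of the
# 15% arm) and writes the ranked report. The winner is frozen as the
# package's default configuration; this script documents that choice.

suppressPackageStartupMessages(library(rescueCEA))
dir.create("results", showWarnings = FALSE)

cal <- calibrate_model(tolerance = 0.10)
write.csv(cal$report, "results/calibration_report.csv", row.names = FALSE)

cat("configurations searched:", nrow(cal$report), "\n")
cat("passing at 10% with 15%-arm dominance:", sum(cal$report$pass), "\n\n")
cat("winning configuration (frozen as the package default):\n")
str(unclass(cal$config), give.head = FALSE)
cat("\nwinner residual (max relative error over the five base-case",
    "quantities):", sprintf("%.3f", cal$best$max_rel_err), "\n\n")

restricted <- subset(cal$report,
                     rate_input == "cumulative" &
                       rescued_survival_mode %in% c("cohort_cumulative",
                                                    "at_rescue") &
                       components == "all_three")
cat("best residual under the margin-preserving reading with the full fixed",
    "cost stack:", sprintf("%.3f", min(restricted$max_rel_err)),
    "- the published base case is not reachable there, which is why the",
    "additional switches exist.\n")
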