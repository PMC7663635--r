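#!/usr/bin/env Rscript
# Step 3 - one-way (tornado) sensitivity of the 5%-improvement ICER.
#
# Each input is scaled by +/-25% with all others at base; the model is
# re-run and the ICER recomputed. Writes the tornado table and diagram.

suppressPackageStartupMessages(library(rescueCEA))
dir.create("results", showWarnings = FALSE)

params <- paper_fixture()
tor <- tornado(params, pct = 0.25)

out <- data.frame(variable = tor$variable,
                  icer_minus25 = tor$icer_low,
                  icer_plus25 = tor$icer_high)
write.csv(out, "results/tornado.csv", row.names = FALSE)
ggplot2::ggsave("results/tornado.png", plot_tornado(tor),
                width = 6, height = 4, dpi = 150)

cat("base-case ICER: $", round(attr(tor, "base_icer")), "/QALY\n\n", sep = "")
print(transform(out, icer_minus25 = round(icer_minus25),
                icer_plus25 = round(icer_plus25)), row.names = FALSE)
cat("\nAV programme cost is the most influential input in this model;",
    "\nunder the frozen from-rescue survival interpretation a proportional",
    "\nrescaling of the rescued-survival column cancels out of the",
    "\nsurvival-from-rescue ratios except where clamped at 1, so the",
    "\ndownward perturbation leaves the ICER at base.\n")
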