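#!/usr/bin/env Rscript
# Simulate the four-group study design (sham control n = 5, RDN n = 5,
# HF n = 4, RDN-HF n = 4) and measure every subject's CV and APD80 at
# pacing cycle lengths 400-150 ms. Sham and RDN draw from the control
# phenotype; HF from the failing phenotype; RDN-HF is modeled as partial
# remodeling (diffusivity and recovery rate scaled to lie between the
# presets), reflecting the hypothesis that denervation blunts but does
# not abolish remodeling.
#
# Writes results/cohort_measurements.csv (one row per subject per CL).

suppressMessages(library(cardiomap))
dir.create("results", showWarnings = FALSE)

design <- data.frame(
  label = c("sham", "rdn", "hf", "rdn_hf"),
  phenotype = c("control", "control", "hf", "hf"),
  n = c(5L, 5L, 4L, 4L),
  # relative to each group's phenotype preset: RDN-HF sits between the
  # presets (hf * 1.75 diffusivity ~ 70% of control; repol * 1.33 ~ 80%)
  diffusivity_scale = c(1, 1, 1, 1.75),
  repol_scale = c(1, 1, 1, 4 / 3))

cat("simulating 18 subjects x 5 cycle lengths (several minutes) ...\n")
coh <- simulate_cohort(design, seed = 20,
                       cls = c(400, 300, 250, 200, 150))
write.csv(coh, "results/cohort_measurements.csv", row.names = FALSE)

for (g in design$label) {
  d <- coh[coh$group == g & coh$cl_ms == 400, ]
  cat(sprintf("  %-7s CL 400: CV %5.1f +/- %4.1f cm/s, APD80 %6.1f +/- %4.1f ms (n = %d)\n",
              g, mean(d$cv_cm_s), sd(d$cv_cm_s),
              mean(d$apd80_ms), sd(d$apd80_ms), nrow(d)))
}
cat("wrote results/cohort_measurements.csv\n")
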