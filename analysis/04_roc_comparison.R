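#!/usr/bin/env Rscript
# Stage 4: ROC estimator comparison.
# For each patient group vs controls, contrasts the nonparametric
# (Mann-Whitney, DeLong CI) AUC with the parametric binormal estimate on
# the fitted intelligibility thresholds. The two disagree where group
# threshold distributions are far from normal. Requires stage 2 output.

library(vocometrics)

seed <- 20260927L
fits <- read.csv("results/study/fits.csv")
ctrl <- fits$threshold[fits$group == "Controls" & is.finite(fits$threshold)]

rows <- lapply(setdiff(unique(fits$group), "Controls"), function(g) {
  cas <- fits$threshold[fits$group == g & is.finite(fits$threshold)]
  emp <- suppressWarnings(empirical_auc(cas, ctrl))
  bin <- suppressWarnings(binormal_auc(cas, ctrl,
                                       seed = derive_seed(seed, "boot", g)))
  data.frame(group = g, n_case = length(cas), n_control = length(ctrl),
             auc_empirical = emp$auc, ci_lo_delong = emp$ci_lo,
             ci_hi_delong = emp$ci_hi, auc_binormal = bin$auc,
             ci_lo_boot = bin$ci_lo, ci_hi_boot = bin$ci_hi)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/study/roc_comparison.csv", row.names = FALSE)

cat("Diagnostic discrimination of the 50% intelligibility threshold",
    "(each group vs Controls):\n\n")
print(tab, row.names = FALSE, digits = 3)
cat("\nHigher fitted thresholds mark patients; AUC = 1 would be a perfect",
    "classifier.\nThe empirical estimator is the primary one here: control",
    "thresholds are tightly\nclustered while patient thresholds are skewed,",
    "so the binormal normality\nassumption is doubtful for some contrasts.\n")
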