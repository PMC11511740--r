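#!/usr/bin/env Rscript
# Biomarker discrimination between diabetic (DN) and hypertensive (HN)
# nephropathy in the 50-59 age band: every observed value of the
# resistive index and of the single-kidney mean RBF is scanned as a
# cut-off, AUCs are computed by the trapezoid rule, and the optimal
# cut-offs by Youden's J = sensitivity + specificity - 1.

library(renopulse)

n_sample <- as.integer(commandArgs(TRUE)[1])
if (is.na(n_sample)) n_sample <- 80
seed <- 20240901

dir.create("results", showWarnings = FALSE)
st <- run_ageing_study(n_per_group = n_sample, seed = seed, groups = "50-59")
cat(sprintf("50-59 healthy subjects kept: %d\n", length(st$subjects)))

ds <- run_disease_study(st$subjects)
for (nm in names(ds$roc)) {
  cat(nm, ": ")
  print(ds$roc[[nm]])
  r <- ds$roc[[nm]]
  write.csv(data.frame(threshold = r$thresholds,
                       sensitivity = r$sensitivity,
                       specificity = r$specificity),
            sprintf("results/roc_%s.csv", nm), row.names = FALSE)
}
summary <- do.call(rbind, lapply(names(ds$roc), function(nm) {
  r <- ds$roc[[nm]]
  data.frame(comparison = nm, auc = r$auc, direction = r$direction,
             cutoff = r$best$cutoff, sensitivity = r$best$sensitivity,
             specificity = r$best$specificity, youden_j = r$best$youden_j)
}))
print(summary, row.names = FALSE, digits = 4)
jsonlite::write_json(summary, "results/roc_summary.json", dataframe = "rows",
                     auto_unbox = TRUE, digits = NA)
cat("Wrote results/roc_*.csv and results/roc_summary.json\n")
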