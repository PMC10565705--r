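# Core serial-dependence analysis: DoG model family, width grid search and
# BIC comparison, applied to the previous-probe effect (all cleaned trials)
# and to the distractor effect (distractor-present trials), per cohort.
# Also writes the smoothed group bias curves that figures are drawn from
# (models themselves are fit to unsmoothed single-trial data).

source("analysis/_common.R")

comparisons <- list(); peaks <- list(); curves <- list()
for (exp in c(1, 2)) {
  clean <- ensure_clean(exp)
  for (pred in c("prev_probe", "distractor")) {
    d <- if (pred == "distractor")
      sd_data(clean[clean$distractor_present, ], pred) else sd_data(clean, pred)
    fam <- fit_model_family(d)
    cat(sprintf("\n== experiment %d, %s predictor (n = %d) ==\n",
                exp, pred, fam$fits$d0$n_obs))
    print(fam$comparison)
    if (nrow(fam$best$peaks)) print(fam$best$peaks, digits = 3)
    cmp <- as.data.frame(fam$comparison)
    cmp$experiment <- exp; cmp$predictor <- pred
    cmp$best <- cmp$model == fam$best$name
    comparisons[[paste(exp, pred)]] <- cmp
    if (nrow(fam$best$peaks)) {
      pk <- fam$best$peaks
      pk$experiment <- exp; pk$predictor <- pred; pk$model <- fam$best$name
      peaks[[paste(exp, pred)]] <- pk
    }
    cv <- smooth_curve(d$delta, d$error)
    cv$experiment <- exp; cv$predictor <- pred
    curves[[paste(exp, pred)]] <- cv
  }
}
write.csv(do.call(rbind, comparisons), "results/model_comparison.csv",
          row.names = FALSE)
write.csv(do.call(rbind, peaks), "results/peak_biases.csv", row.names = FALSE)
write.csv(do.call(rbind, curves), "results/smoothed_curves.csv",
          row.names = FALSE)
cat("\nwrote results/model_comparison.csv, peak_biases.csv, smoothed_curves.csv\n")
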