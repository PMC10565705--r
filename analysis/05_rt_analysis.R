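# Discrimination-task RT: attentional capture (present minus absent, per
# location condition) and the inverse-Gaussian identity-link mixed model
# with participant random intercepts.

source("analysis/_common.R")

coefs <- list(); caps <- list()
for (exp in c(1, 2)) {
  clean <- ensure_clean(exp)
  fit <- fit_rt_model(clean)
  cap <- capture_effect(clean)
  cat(sprintf("\n== experiment %d ==\n", exp))
  print(fit)
  print(cap$group, digits = 4)
  co <- fit$coefficients; co$experiment <- exp
  coefs[[exp]] <- co
  cg <- cap$group; cg$experiment <- exp
  caps[[exp]] <- cg
}
write.csv(do.call(rbind, coefs), "results/rt_model.csv", row.names = FALSE)
write.csv(do.call(rbind, caps), "results/capture_effect.csv", row.names = FALSE)
cat("\nwrote results/rt_model.csv and results/capture_effect.csv\n")
cat("generative fixed effects were 489.29 / +4.128 / +18.53 / -10.97 ms\n")
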