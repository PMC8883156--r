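#!/usr/bin/env Rscript
# Stage 3: convert oddity responses to sensitivity (d') and compare
# environments.
#
# Laboratory records are aggregated per observer (d' per observer, then
# mean +/- SEM); crowd records are pooled (one proportion correct per
# condition). The cross-environment regression quantifies how well crowd
# sensitivity tracks laboratory sensitivity, and the per-observer
# accuracy summaries quantify individual differences.

suppressPackageStartupMessages(library(matodd))

responses <- read_response_table("results/responses.csv")
lab <- responses[responses$environment == "lab", ]
crowd <- responses[responses$environment == "crowd", ]

sens_lab <- aggregate_sensitivity(lab, "per_observer")
sens_crowd <- aggregate_sensitivity(crowd, "pooled")
utils::write.csv(sens_lab, "results/sensitivity_lab.csv", row.names = FALSE)
utils::write.csv(sens_crowd, "results/sensitivity_crowd.csv",
                 row.names = FALSE)

key <- function(d) paste(d$task, d$illumination_condition, d$object,
                         d$difficulty)
idx <- match(key(sens_lab), key(sens_crowd))
fit <- cross_environment_regression(sens_lab$d_prime,
                                    sens_crowd$d_prime[idx])
cat(sprintf("crowd ~ lab d': slope %.2f, intercept %.2f, R^2 %.2f (n = %d)\n",
            fit$slope, fit$intercept, fit$r_squared, fit$n))

acc <- observer_accuracy(lab)
sds <- unique(acc[c("task", "illumination_condition", "sd_accuracy")])
utils::write.csv(acc, "results/observer_accuracy_lab.csv",
                 row.names = FALSE)
cat("per-observer accuracy SD by task (illumination condition 1):\n")
s1 <- sds[sds$illumination_condition == 1, ]
for (i in seq_len(nrow(s1)))
  cat(sprintf("  %s: %.2f\n", s1$task[i], s1$sd_accuracy[i]))
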