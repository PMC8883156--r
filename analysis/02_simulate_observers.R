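#!/usr/bin/env Rscript
# Stage 2: simulate the behavioral experiments.
#
# Synthetic observers perform every oddity task of the full design
# (six tasks x five objects under illumination condition 1; five tasks x
# five objects under conditions 2 and 3). The laboratory experiment has
# 20 observers x 10 repetitions per condition; the crowdsourcing
# experiment has 416/411/405 observers (illumination conditions 1/2/3)
# with one judgment each and attenuated sensitivity (factor 0.7).

suppressPackageStartupMessages(library(matodd))

dir.create("results", showWarnings = FALSE)
master_seed <- 20L

conds <- design_conditions()
lab <- simulate_response_table(conds, n_observers = 20, n_reps = 10,
                               environment = "lab", seed = master_seed)

crowd <- do.call(rbind, lapply(1:3, function(ic) {
  n_obs <- c(416, 411, 405)[ic]
  simulate_response_table(conds[conds$illumination_condition == ic, ],
                          n_observers = n_obs, n_reps = 1,
                          environment = "crowd", seed = master_seed + ic)
}))

responses <- rbind(lab, crowd)
write_response_table(responses, "results/responses.csv")
cat(sprintf("lab: %d trials from %d observers; crowd: %d trials\n",
            nrow(lab), length(unique(lab$observer_id)), nrow(crowd)))
cat(sprintf("overall accuracy: lab %.3f, crowd %.3f\n",
            mean(lab$correct), mean(crowd$correct)))
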