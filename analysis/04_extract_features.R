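#!/usr/bin/env Rscript
# Stage 4: compute texture-statistics feature distances per condition.
#
# For every task condition of a reduced corpus (illumination condition 1,
# objects 1-2) the condition's stimulus set (anchor and target renders
# across the five poses) is rendered, each image is reduced to the
# 96-parameter PS color feature vector (CIE L*a*b*, 4-scale x
# 4-orientation steerable pyramid, 32 parameters per channel), and the
# per-feature mean pairwise absolute differences form the predictors of
# the regression stage.

suppressPackageStartupMessages(library(matodd))

dir.create("results", showWarnings = FALSE)
conds <- design_conditions(objects = 1:2, illums = 1)
cat(sprintf("extracting features for %d conditions...\n", nrow(conds)))

t0 <- Sys.time()
features <- condition_feature_sets(conds, variant = "ps_color", size = 128)
cat(sprintf("done in %.1f min\n",
            as.numeric(Sys.time() - t0, units = "mins")))

# per-feature distance matrix (conditions x 96 features)
sens_lab <- read.csv("results/sensitivity_lab.csv")
sens_lab <- sens_lab[sens_lab$illumination_condition == 1 &
                       sens_lab$object %in% 1:2, ]
dp <- setNames(sens_lab$d_prime,
               sprintf("%s_i%d_o%d_d%g", sens_lab$task,
                       sens_lab$illumination_condition, sens_lab$object,
                       sens_lab$difficulty))
ds <- assemble_dataset(features, dp[names(features)])
write_feature_table(ds$X, "results/feature_distances.csv")
utils::write.csv(data.frame(condition = rownames(ds$X), d_prime = ds$y,
                            task = ds$task),
                 "results/regression_targets.csv", row.names = FALSE)
cat(sprintf("feature-distance matrix: %d conditions x %d features\n",
            nrow(ds$X), ncol(ds$X)))
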