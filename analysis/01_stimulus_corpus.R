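#!/usr/bin/env Rscript
# Stage 1: generate a demonstration stimulus corpus.
#
# Renders bumpy-sphere object images along each material dimension's
# parameter grid and writes them (with a hash manifest) under
# results/stimuli/. The full study corpus uses five objects and three
# illumination conditions; this driver renders a reduced corpus (two
# objects, illumination conditions 1 and 2) that exercises every task.

suppressPackageStartupMessages(library(matodd))

out <- "results/stimuli"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

conds <- design_conditions(objects = 1:2, illums = 1:2)
cat(sprintf("design: %d condition rows over %d task/illum/object units\n",
            nrow(conds),
            nrow(unique(conds[c("task", "illumination_condition",
                                "object")]))))

manifest <- write_stimulus_corpus(out, conds, size = 128)
cat(sprintf("wrote %d PNG images under %s\n", nrow(manifest), out))

# sanity: the gloss-contrast grid maps onto the printed perceptual values
c_vals <- contrast_gloss_grid(task_grids()$GC)
cat("GC contrast-gloss values (truncated to 3 decimals):",
    paste(trunc(c_vals * 1000) / 1000, collapse = ", "), "\n")
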