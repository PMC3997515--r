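#!/usr/bin/env Rscript
# Stage 1: simulate the study conditions — a genome-scale two-signal
# factorial experiment (4 treatments x 2 replicate cultures) in which ~5%
# of genes respond to at least one signal and a small minority of the
# responders carry a non-additive interaction term.
suppressPackageStartupMessages(library(combsig))

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

params <- simulation_params(seed = 20140423 %% 2^20)  # defaults = study conditions
d <- generate_dataset(params)
write_dataset(d, "results/data")

cat("Simulated", nrow(d$expression), "genes x", ncol(d$expression), "samples\n")
print(table(d$truth$class))
cat("written: results/data/{expression,design,truth}.tsv\n")
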