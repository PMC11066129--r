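#!/usr/bin/env Rscript

# Step 2: fit the competitor induction Hill model to the western-blot
# HA/Myc series, selecting the integer Hill coefficient that maximizes
# adjusted R-squared.

suppressPackageStartupMessages(library(ccturnover))

western <- read_western_tsv("results/simulated/western.tsv")
ind <- fit_induction(western, n_range = 1:10)
stopifnot(ind$converged)
print(ind)

out <- data.frame(X_P = ind$X_P, t_half_ind = ind$t_half_ind, n = ind$n,
                  adj_r2 = ind$adj_r2)
write_tsv(out, "results/induction_fit.tsv")
message("wrote results/induction_fit.tsv")
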