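#!/usr/bin/env Rscript
# Stage 4: probabilistic sensitivity analysis. 1,000 Monte Carlo
# iterations over the assigned gamma/beta/normal distributions; incremental
# scatter and acceptability curve to results/.

suppressPackageStartupMessages(library(nsclcCEA))
dir.create("results", showWarnings = FALSE)

wtp <- 38201
psa <- run_psa(n_iter = 1000, seed = 20230726)
write.csv(psa$samples[, c("iter", "delta_cost", "delta_qaly")],
          "results/psa_samples.csv", row.names = FALSE)
cc <- ceac(psa)
write.csv(cc, "results/ceac.csv", row.names = FALSE)

acc <- mean(wtp * psa$samples$delta_qaly - psa$samples$delta_cost > 0)
cat(sprintf("Acceptability at WTP $%d/QALY: %.1f%% of %d iterations\n",
            wtp, 100 * acc, psa$n_iter))
cat(sprintf("Median incremental cost $%.0f, median incremental QALYs %.3f\n",
            median(psa$samples$delta_cost), median(psa$samples$delta_qaly)))
cat("Wrote results/psa_samples.csv and results/ceac.csv\n")
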