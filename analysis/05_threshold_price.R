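#!/usr/bin/env Rscript
# Stage 5: cemiplimab price-threshold analysis at the Chinese
# willingness-to-pay threshold, by the closed-form deterministic solve and
# by bisection on the probabilistic acceptability.

suppressPackageStartupMessages(library(nsclcCEA))
dir.create("results", showWarnings = FALSE)

wtp <- 38201
det <- threshold_price(wtp, "deterministic")
psa <- run_psa(n_iter = 1000, seed = 20230726)
p50 <- threshold_price(wtp, "psa50", psa = psa)

tab <- data.frame(mode = c("deterministic", "psa50"),
                  price_per_100mg = c(det$price, p50$price),
                  fraction_of_base = c(det$fraction_of_base,
                                       p50$fraction_of_base))
write.csv(tab, "results/threshold.csv", row.names = FALSE)
print(tab, row.names = FALSE)
cat(sprintf("Cemiplimab becomes cost-effective below about $%.0f per 100 mg (%.1f%% of the list price)\n",
            p50$price, 100 * p50$fraction_of_base))
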