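#!/usr/bin/env Rscript
# Step 5 -- scale individual estimates to assemblage-level areal demand.
#
# Each census record is matched to its species x nearest-cm cell of the
# estimate grid; per-transect totals are divided by transect area and
# averaged within sites.

library(fishamr)

census <- read.csv("scratch/sim/census.csv")
estimates <- read.csv("results/estimates.csv")

sites <- site_totals(census, estimates)
shares <- relative_abundance(census)
write.csv(sites, "results/site_totals.csv", row.names = FALSE)
write.csv(shares, "results/relative_abundance.csv", row.names = FALSE)

cat(sprintf("assemblage totals for %d sites\n", nrow(sites)))
cat(sprintf("SMR density:      %.4f-%.4f g O2/m2/d\n",
            min(sites$smr_mean), max(sites$smr_mean)))
cat(sprintf("AMRfield density: %.4f-%.4f g O2/m2/d\n",
            min(sites$amr_mean), max(sites$amr_mean)))
cat(sprintf("AMRfield/SMR ratio across sites: %.2f-%.2f\n",
            min(sites$ratio), max(sites$ratio)))
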