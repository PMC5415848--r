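#!/usr/bin/env Rscript
# Helix-propensity ranking of the H3 10-mer variants over the observed
# helical segment (residues 3-8). The double-Ala mutant (K4A/Q5A) should
# score as the most helix-favoring and the double-Gly mutant as the least,
# the same ordering the binding data and helical-content measurements
# support.

library(helixread)

dir.create("results", showWarnings = FALSE)

scale <- load_propensity_scale()
cat("Scale:", attr(scale, "scale_name"), "\n")

variants <- c(WT = "ARTKQTARKS", AA = "ARTAATARKS", GG = "ARTGGTARKS")
rk <- rank_variants(variants, window = 3:8, scale = scale)
write.csv(rk, "results/propensity_ranking.csv", row.names = FALSE)
print(rk, row.names = FALSE)
cat("Ordering (most helix-favoring first):",
    paste(names(variants)[match(rk$sequence, variants)], collapse = " > "),
    "\n")
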