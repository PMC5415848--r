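#!/usr/bin/env Rscript
# Regenerates every input the downstream analyses consume: a synthetic
# conformer ensemble with a planted helicity fraction, free/bound HSQC peak
# lists with planted shifted residues, a noisy single-site titration, a
# planted acidic-wall alignment, and verbatim copies of the packaged
# thermodynamic tables. Everything is seeded, so re-running reproduces the
# same files byte for byte.

library(helixread)

seed <- 1L
dir <- "results/fixtures"
paths <- make_fixtures(seed = seed, dir = dir)

cat("Synthetic inputs written to", dir, "(seed", seed, "):\n")
for (k in names(paths)) cat(sprintf("  %-10s %s\n", k, paths[[k]]))
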