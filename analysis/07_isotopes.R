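#!/usr/bin/env Rscript
# 13C label incorporation: simulate GC-MS mass-isotopomer readouts of a
# U-13C-glucose tracing experiment, correct for natural 13C abundance, and
# report percent of each metabolite pool carrying one or more 13C atoms.

library(glucoscope)
dir.create("results", showWarnings = FALSE)

metabolites <- data.frame(
  metabolite = c("pyruvate", "ribose-5-phosphate", "citrate", "glutamate"),
  n_carbons = c(3, 5, 6, 5),
  p = c(0.6, 0.45, 0.25, 0.2))   # per-carbon tracer labeling probability

rows <- lapply(seq_len(nrow(metabolites)), function(i) {
  m <- metabolites[i, ]
  sm <- simulate_mid(m$n_carbons, m$p, q = 0.0107, n_molecules = 2e5,
                     seed = i)
  M <- natural_abundance_matrix(m$n_carbons, 0.0107)
  corr <- correct_mid(sm$mid, M)
  data.frame(metabolite = m$metabolite, n_carbons = m$n_carbons,
             percent_labeled = percent_labeled(corr$mid),
             percent_expected = sm$truth$percent_labeled_expected,
             residual = corr$residual)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/label_incorporation.csv", row.names = FALSE)
print(tab, digits = 4)
cat("percent labeled = 100 * (1 - M+0) after natural-abundance correction;\n",
    "agreement with the binomial closed form validates the correction chain.\n")
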