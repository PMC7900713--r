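#!/usr/bin/env Rscript
# Single-cell dose-response classification: cells exposed to stepped inhibitor
# doses (0, 0.05, 0.1, 0.5 uM at hourly intervals) are classified as non-,
# weak or strong responders from their baseline-normalized FRET shifts, and
# cells whose final ratio stays above the untreated control median are
# flagged refractory.

library(glucoscope)
dir.create("results", showWarnings = FALSE)

sim <- simulate_dose_cohort(n_cells = 600, refractory_fraction = 0.11,
                            seed = 1)
res <- dose_response_analysis(sim$traces, sim$control_traces, sim$schedule)
write.csv(res$calls, "results/responders.csv", row.names = FALSE)

m <- merge(res$calls, sim$truth, by = "cell_id")
cat(sprintf("classified %d cells (%d excluded for missing assay frames)\n",
            nrow(res$calls), res$n_excluded))
print(table(truth = m$class.y, call = m$class.x))
cat(sprintf("class agreement with ground truth: %.1f%%\n",
            100 * mean(m$class.x == m$class.y)))
cat(sprintf("refractory fraction: %.1f%% (95%% CI %.1f-%.1f%%); generating %.1f%%\n",
            100 * res$refractory_fraction, 100 * res$refractory_ci[1],
            100 * res$refractory_ci[2], 100 * mean(sim$truth$refractory)))
cat("refractory cells keep their FRET ratio above the control median at the\n",
    "maximal dose; the constitutively high non-responding subpopulation was\n",
    "generated at 11%.\n")
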