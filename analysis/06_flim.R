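#!/usr/bin/env Rscript
# FLIM: per-pixel bi-exponential TCSPC fits with a measured IRF. High glucose
# increases FRET and therefore shortens the donor lifetime, so a two-region
# field (low vs high glucose) should map to long vs short mean lifetimes.

library(glucoscope)
dir.create("results", showWarnings = FALSE)

irf <- gaussian_irf(sigma_ns = 0.2)
region_map <- matrix(1L, 14, 14); region_map[, 8:14] <- 2L
cube <- simulate_tcspc_cube(region_map,
  list(`1` = list(tau = c(1.8, 2.9), amps = c(0.35, 0.65)),  # low glucose
       `2` = list(tau = c(1.1, 2.2), amps = c(0.65, 0.35))), # high glucose
  irf, photons = 3000, seed = 1)

lt <- lifetime_map(cube$counts, irf, threshold = 100)
summ <- data.frame(
  region = c("low_glucose", "high_glucose"),
  true_mean_tau_ns = cube$truth$mean_tau,
  fitted_median_ns = c(median(lt$mean_tau[, 1:6], na.rm = TRUE),
                       median(lt$mean_tau[, 9:14], na.rm = TRUE)),
  n_valid = c(sum(lt$valid[, 1:6]), sum(lt$valid[, 9:14])))
write.csv(summ, "results/flim_summary.csv", row.names = FALSE)
print(summ)
cat(sprintf("pixels above the strict 100-photon mask: %d of %d\n",
            sum(lt$valid), length(lt$valid)))
cat("the high-glucose region shows the shorter amplitude-weighted mean\n",
    "lifetime, the FLIM counterpart of the ratiometric readout.\n")
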