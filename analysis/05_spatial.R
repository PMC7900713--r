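#!/usr/bin/env Rscript
# Spatial profiling: the high-glucose layer at a scratch-wound border (an
# exponential gradient from the edge, length scale ~200 um), the static-field
# kymograph control, wound closure, and tumor center-periphery band profiles
# (ratio-of-sums FRET and nuclei density every 100 um from the outline).

library(glucoscope)
dir.create("results", showWarnings = FALSE)

# scratch border gradient
fld <- simulate_spatial_field("scratch", image_shape = c(200, 400),
                              scale_um = 200, um_per_px = 2,
                              poisson_noise = TRUE, seed = 1)
pr <- radial_band_profile(fld$donor, fld$acceptor, fld$region, 2, 50)
fit <- fit_gradient_scale(pr$bin_mid_um, pr$ratio)
write.csv(pr, "results/scratch_profile.csv", row.names = FALSE)
cat(sprintf("scratch gradient: fitted length scale %.0f um (generated 200 um)\n",
            fit$scale_um))

# kymograph of the (static) field: distance bands x time
ratio_img <- fld$acceptor / pmax(fld$donor, 1)
ky <- build_kymograph(rep(list(ratio_img), 6), rep(list(fld$region), 6),
                      times_h = 0:5, um_per_px = 2, bin_um = 50)
write.csv(data.frame(distance_um = ky$distance_um, ky$value),
          "results/kymograph.csv", row.names = FALSE)
cat(sprintf("kymograph: %d distance bands x %d time bins; static field drift %.1e\n",
            nrow(ky$value), ncol(ky$value),
            max(apply(ky$value, 1, function(v)
              if (all(is.na(v))) 0 else diff(range(v))))))

# wound closure from occupancy areas
occ0 <- fld$region
occ24 <- fld$region; occ24[, 1:45] <- TRUE   # front advanced 45 px
a0 <- wound_area(occ0, 2); a24 <- wound_area(occ24, 2)
wc <- wound_closure(a0, a24)
cat(sprintf("wound closure 0-24 h: %.1f%%\n", wc$closure_pct))

# tumor center-periphery profiles
tm <- simulate_spatial_field("tumor", image_shape = c(300, 300),
                             scale_um = 200, um_per_px = 2, seed = 2)
pt <- radial_band_profile(tm$donor, tm$acceptor, tm$region, 2, 100)
dp <- density_profile(tm$nuclei, tm$region, 2, 100)
write.csv(merge(pt, dp, by = c("bin_start_um", "bin_mid_um")),
          "results/tumor_profile.csv", row.names = FALSE)
cat(sprintf("tumor: FRET falls from %.2f (edge) to %.2f (center); nuclei density rises %.2f -> %.2f per 100 um^2\n",
            pt$ratio[1], tail(na.omit(pt$ratio), 1),
            dp$density[1], tail(na.omit(dp$density), 1)))
cat("the high-glucose rim and the inverse density relationship mirror the\n",
    "edge-high FRET pattern of tumor margins.\n")
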