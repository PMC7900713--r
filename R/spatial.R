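#' Simulate a spatial FRET field (scratch wound or tumor geometry)
#'
#' "scratch": a cell-free wound occupies columns to the left of `edge_px`;
#' the cell region's true ratio decays from the wound edge with an
#' exponential length scale (`ratio = base + amp * exp(-d/scale)`), matching
#' the high-glucose layer that forms at a newly created border. "tumor": a
#' circular region whose ratio decays from the outline inward with the same
#' law, plus nuclei whose density ramps linearly from the edge toward the
#' center. Donor intensity is uniform inside the region; the acceptor image
#' is donor times the true ratio; optional Poisson noise.
#'
#' @param kind "scratch" or "tumor".
#' @param image_shape c(height, width) px.
#' @param um_per_px microns per pixel (required; no default in analysis code,
#'   but the generator uses 2).
#' @param scale_um gradient length scale (um); `Inf` gives a flat field.
#' @param base_ratio,amp gradient floor and amplitude (ratio units).
#' @param donor_level donor intensity inside the region.
#' @param edge_px scratch only: first cell-occupied column.
#' @param radius_px tumor only: region radius (default 45% of min dim).
#' @param density_range tumor only: c(edge, center) nuclei per 100 um^2 for
#'   the linear ramp.
#' @param poisson_noise add Poisson noise to both channels.
#' @param seed RNG seed.
#' @return list: donor, acceptor (matrices), region (logical mask),
#'   nuclei (tumor: data.frame x, y in px), truth (generator parameters).
#' @export
simulate_spatial_field <- function(kind = c("scratch", "tumor"),
                                   image_shape = c(200, 300), um_per_px = 2,
                                   scale_um = 200, base_ratio = 1.4,
                                   amp = 0.8, donor_level = 1000,
                                   edge_px = 60, radius_px = NULL,
                                   density_range = c(0.5, 2),
                                   poisson_noise = FALSE, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(scale_um > 0)
  set.seed(seed)
  h <- image_shape[1]; w <- image_shape[2]
  nuclei <- NULL
  if (kind == "scratch") {
    region <- matrix(FALSE, h, w)
    region[, edge_px:w] <- TRUE
    col_d <- (col(region) - edge_px) * um_per_px
    ratio <- base_ratio + amp * exp(-pmax(col_d, 0) / scale_um)
  } else {
    if (is.null(radius_px)) radius_px <- round(0.45 * min(h, w))
    cy <- h / 2; cx <- w / 2
    rr <- sqrt((row(matrix(0, h, w)) - cy)^2 + (col(matrix(0, h, w)) - cx)^2)
    region <- rr <= radius_px
    d_um <- pmax(radius_px - rr, 0) * um_per_px   # distance from outline inward
    ratio <- base_ratio + amp * exp(-d_um / scale_um)
    # nuclei density rises linearly from edge to center
    max_d <- radius_px * um_per_px
    dens <- function(d) density_range[1] +
      (density_range[2] - density_range[1]) * d / max_d   # per 100 um^2
    lam <- dens(d_um) / 100 * um_per_px^2
    lam[!region] <- 0
    counts <- matrix(stats::rpois(length(lam), lam), h, w)
    idx <- which(counts > 0, arr.ind = TRUE)
    reps <- counts[counts > 0]
    nuclei <- data.frame(x = rep(idx[, 2], reps), y = rep(idx[, 1], reps))
  }
  donor <- matrix(0, h, w); acceptor <- matrix(0, h, w)
  donor[region] <- donor_level
  acceptor[region] <- donor_level * ratio[region]
  if (poisson_noise) {
    donor[] <- stats::rpois(length(donor), donor)
    acceptor[] <- stats::rpois(length(acceptor), acceptor)
  }
  list(donor = donor, acceptor = acceptor, region = region, nuclei = nuclei,
       truth = list(kind = kind, scale_um = scale_um, base_ratio = base_ratio,
                    amp = amp, um_per_px = um_per_px,
                    density_range = if (kind == "tumor") density_range))
}

#' Kymograph of FRET ratio vs distance from the wound edge over time
#'
#' For each frame, locates the wound edge (first cell-occupied column,
#' wound on the left) unless given, bins cell pixels by distance from the
#' current edge, and averages the ratio per (distance band, time bin).
#'
#' @param ratio_stack list of ratio matrices (one per frame).
#' @param occupancy_stack list of logical matrices (TRUE where cells are).
#' @param times_h frame times (h).
#' @param um_per_px microns per pixel.
#' @param bin_um distance band width (um).
#' @param time_bin_h time bin width (h); default one bin per frame.
#' @param edge_x optional per-frame wound-edge column (px).
#' @return list of class `kymograph`: `value` (bands x time bins, NA where no
#'   cells), `distance_um` (band starts), `time_h` (bin starts).
#' @export
build_kymograph <- function(ratio_stack, occupancy_stack, times_h,
                            um_per_px, bin_um = 100, time_bin_h = NULL,
                            edge_x = NULL) {
  stopifnot(length(ratio_stack) == length(occupancy_stack),
            length(ratio_stack) == length(times_h))
  nf <- length(ratio_stack)
  if (is.null(edge_x)) {
    edge_x <- vapply(occupancy_stack, function(m) {
      occ_cols <- which(colSums(m) > 0)
      if (length(occ_cols) == 0) NA_real_ else min(occ_cols)
    }, numeric(1))
  }
  w <- ncol(ratio_stack[[1]])
  max_d <- (w - min(edge_x, na.rm = TRUE)) * um_per_px
  breaks <- seq(0, max_d + bin_um, by = bin_um)
  if (is.null(time_bin_h)) {
    tbin <- seq_len(nf); tstarts <- times_h
  } else {
    tstarts <- seq(min(times_h), max(times_h), by = time_bin_h)
    tbin <- findInterval(times_h, tstarts)
  }
  nb <- length(breaks) - 1
  nt <- length(unique(tbin))
  sums <- matrix(0, nb, nt); cnts <- matrix(0, nb, nt)
  for (f in seq_len(nf)) {
    if (is.na(edge_x[f])) next
    occ <- occupancy_stack[[f]]
    d_um <- (col(occ) - edge_x[f]) * um_per_px
    keep <- occ & d_um >= 0
    b <- findInterval(d_um[keep], breaks, rightmost.closed = TRUE)
    tb <- tbin[f]
    s <- tapply(ratio_stack[[f]][keep], b, sum)
    n <- tapply(rep(1, sum(keep)), b, sum)
    bi <- as.integer(names(s))
    sums[bi, tb] <- sums[bi, tb] + s
    cnts[bi, tb] <- cnts[bi, tb] + n
  }
  value <- sums / cnts
  value[cnts == 0] <- NA
  structure(list(value = value, distance_um = breaks[-length(breaks)],
                 time_h = if (is.null(time_bin_h)) tstarts else
                   tstarts[sort(unique(tbin))]),
            class = "kymograph")
}

#' Percent wound closure between two time points
#'
#' `100 * (area_0h - area_24h) / area_0h`; negative closure (wound growth) is
#' allowed but flagged.
#'
#' @param area_0h,area_24h wound areas (any consistent unit); `area_0h > 0`.
#' @return list(closure_pct, flagged).
#' @export
wound_closure <- function(area_0h, area_24h) {
  stopifnot(area_0h > 0, area_24h >= 0)
  closure <- 100 * (area_0h - area_24h) / area_0h
  list(closure_pct = closure, flagged = closure < 0)
}

#' Wound area from an occupancy mask
#'
#' Area of the cell-free region in um^2.
#'
#' @param occupancy logical matrix (TRUE = cells).
#' @param um_per_px microns per pixel.
#' @export
wound_area <- function(occupancy, um_per_px) {
  sum(!occupancy) * um_per_px^2
}

#' Center-periphery FRET profile by distance-to-outline banding
#'
#' Assigns every region pixel its distance from the region outline (inward
#' positive, from the Euclidean distance transform), bins distances every
#' `bin_um`, and computes the ratio-of-sums FRET per band: channel
#' intensities are summed over the band first, then divided
#' (sum(acceptor)/sum(donor)), the banding equivalent of re-slicing the
#' outline to a straight line and sum-projecting before division. Bands with
#' zero donor sum are returned as NA and flagged.
#'
#' @param donor,acceptor intensity matrices.
#' @param region logical region mask (closed outline interior).
#' @param um_per_px microns per pixel.
#' @param bin_um band width in um (100 for FRET profiles; 50 for stain
#'   profiles).
#' @return data.frame: bin_start_um, bin_mid_um, ratio, donor_sum,
#'   acceptor_sum, n_px, flagged.
#' @export
radial_band_profile <- function(donor, acceptor, region, um_per_px,
                                bin_um = 100) {
  stopifnot(identical(dim(donor), dim(region)),
            identical(dim(acceptor), dim(region)))
  d_um <- edge_distance_um(region, um_per_px)
  breaks <- seq(0, max(d_um[region]) + bin_um, by = bin_um)
  b <- findInterval(d_um[region], breaks, rightmost.closed = TRUE)
  ds <- tapply(donor[region], b, sum)
  as_ <- tapply(acceptor[region], b, sum)
  np <- tapply(rep(1, sum(region)), b, sum)
  nb <- length(breaks) - 1
  out <- data.frame(bin_start_um = breaks[seq_len(nb)],
                    bin_mid_um = breaks[seq_len(nb)] + bin_um / 2,
                    donor_sum = 0, acceptor_sum = 0, n_px = 0L)
  bi <- as.integer(names(ds))
  out$donor_sum[bi] <- ds
  out$acceptor_sum[bi] <- as_
  out$n_px[bi] <- np
  out$flagged <- out$donor_sum == 0
  out$ratio <- ifelse(out$flagged, NA_real_, out$acceptor_sum / out$donor_sum)
  out
}

# distance (um) from the region outline, inward positive; 0 outside.
# A region with no background pixels in view has its outline taken as the
# image border (implemented by padding with a one-pixel background ring).
edge_distance_um <- function(region, um_per_px) {
  if (all(region)) {
    pad <- matrix(0, nrow(region) + 2, ncol(region) + 2)
    pad[2:(nrow(region) + 1), 2:(ncol(region) + 1)] <- 1
    dm <- EBImage::distmap(EBImage::Image(pad))
    d <- as.matrix(EBImage::imageData(dm))
    return(d[2:(nrow(region) + 1), 2:(ncol(region) + 1)] * um_per_px)
  }
  dm <- EBImage::distmap(EBImage::Image(region * 1))
  as.matrix(EBImage::imageData(dm)) * um_per_px
}

#' Nuclei density per distance band
#'
#' Counts nuclei (centroids) per distance-from-outline band and divides by
#' the band area, on the same axis as [radial_band_profile()].
#'
#' @param nuclei data.frame with `x`, `y` in px (column, row).
#' @param region logical region mask.
#' @param um_per_px microns per pixel.
#' @param bin_um band width (um).
#' @return data.frame: bin_start_um, bin_mid_um, count, band_area_um2,
#'   density (per 100 um^2; NA for zero-area bands).
#' @export
density_profile <- function(nuclei, region, um_per_px, bin_um = 100) {
  d_um <- edge_distance_um(region, um_per_px)
  breaks <- seq(0, max(d_um[region]) + bin_um, by = bin_um)
  nb <- length(breaks) - 1
  area <- tapply(rep(um_per_px^2, sum(region)),
                 findInterval(d_um[region], breaks, rightmost.closed = TRUE),
                 sum)
  px <- cbind(pmin(pmax(round(nuclei$y), 1), nrow(region)),
              pmin(pmax(round(nuclei$x), 1), ncol(region)))
  nd <- d_um[px]
  cnt <- tapply(rep(1, nrow(nuclei)),
                findInterval(nd, breaks, rightmost.closed = TRUE), sum)
  out <- data.frame(bin_start_um = breaks[seq_len(nb)],
                    bin_mid_um = breaks[seq_len(nb)] + bin_um / 2,
                    count = 0, band_area_um2 = 0)
  out$band_area_um2[as.integer(names(area))] <- area
  out$count[as.integer(names(cnt))] <- cnt
  out$density <- ifelse(out$band_area_um2 > 0,
                        out$count / out$band_area_um2 * 100, NA_real_)
  out
}

#' Fit an exponential length scale to a distance profile
#'
#' Least-squares fit of `value = base + amp * exp(-d / scale)` to band
#' midpoints, used to recover gradient length scales from kymograph bands or
#' radial profiles.
#'
#' @param distance_um,value profile points (NA values dropped).
#' @return list(base, amp, scale_um, converged).
#' @export
fit_gradient_scale <- function(distance_um, value) {
  ok <- !is.na(value)
  d <- distance_um[ok]; v <- value[ok]
  if (length(d) < 4) stop("need at least 4 profile points")
  base0 <- min(v); amp0 <- max(v) - min(v)
  scale0 <- max(d[v - base0 > amp0 * exp(-1)], d[2])
  fit <- try(minpack.lm::nlsLM(v ~ base + amp * exp(-d / sc),
                               start = list(base = base0, amp = amp0,
                                            sc = scale0),
                               lower = c(-Inf, 0, 1e-6)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(base = NA_real_, amp = NA_real_, scale_um = NA_real_,
                converged = FALSE))
  co <- stats::coef(fit)
  list(base = unname(co["base"]), amp = unname(co["amp"]),
       scale_um = unname(co["sc"]), converged = TRUE)
}
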