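# Independent oracles used to validate fits and aggregations. Each oracle is
# deliberately naive (brute force, enumeration, fixed-step integration) and
# shares no code with the implementation it checks.

# grid-search least squares for y = plateau + span * exp(-k (t - t0)):
# profile out the linear parameters at every k on a dense grid
oracle_decay_grid <- function(time, y, t0, k_range = c(1e-3, 2),
                              n_grid = 1e4) {
  ks <- exp(seq(log(k_range[1]), log(k_range[2]), length.out = n_grid))
  best <- c(k = NA, rss = Inf)
  for (k in ks) {
    basis <- exp(-k * (time - t0))
    fit <- stats::lm.fit(cbind(1, basis), y)
    rss <- sum(fit$residuals^2)
    if (rss < best["rss"]) best <- c(k = k, rss = rss)
  }
  best
}

# fixed-step RK4 integration of the glucose ODE on the frame grid
# (independent of the deSolve-based generator)
oracle_rk4_trace <- function(cell, schedule, times, fine = 100) {
  if (is.null(cell$Km)) cell$Km <- 2.0
  if (is.null(cell$Kup)) cell$Kup <- 1.7
  f <- function(G, u) cell$Vup * u - cell$Vcon * G / (cell$Km + G)
  out <- numeric(length(times)); out[1] <- G <- cell$G0
  for (i in seq_along(times)[-1]) {
    dt <- (times[i] - times[i - 1]) / fine
    tcur <- times[i - 1]
    for (s in seq_len(fine)) {
      gext <- media_glucose(schedule, tcur + dt / 2)
      u <- gext / (cell$Kup + gext)
      k1 <- f(G, u); k2 <- f(G + dt / 2 * k1, u)
      k3 <- f(G + dt / 2 * k2, u); k4 <- f(G + dt * k3, u)
      G <- max(G + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
      tcur <- tcur + dt
    }
    out[i] <- G
  }
  out
}

# ECDF sup-distance by direct evaluation at all sample points
oracle_ks_distance <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(p) mean(a <= p), numeric(1))
  Fb <- vapply(pts, function(p) mean(b <= p), numeric(1))
  max(abs(Fa - Fb))
}

# pixel-by-pixel loop version of the ratio-of-sums radial profile
oracle_radial_profile <- function(donor, acceptor, region, dist_um, bin_um,
                                  n_bins) {
  ds <- numeric(n_bins); as_ <- numeric(n_bins)
  for (i in seq_len(nrow(region))) for (j in seq_len(ncol(region))) {
    if (!region[i, j]) next
    b <- min(floor(dist_um[i, j] / bin_um) + 1, n_bins)
    ds[b] <- ds[b] + donor[i, j]
    as_[b] <- as_[b] + acceptor[i, j]
  }
  ifelse(ds > 0, as_ / ds, NA_real_)
}

# O(n^2) double-loop discrete convolution
oracle_convolution <- function(a, b) {
  n <- length(a)
  out <- numeric(n)
  for (k in seq_len(n)) {
    s <- 0
    for (j in seq_len(k)) s <- s + a[j] * b[k - j + 1]
    out[k] <- s
  }
  out
}

# standard error of a ratio of Poisson-mean channel means over m pixels
oracle_ratio_se <- function(donor_mean, true_ratio, n_px) {
  true_ratio * sqrt(1 / (donor_mean * n_px) +
                    1 / (donor_mean * true_ratio * n_px))
}
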