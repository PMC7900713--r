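#' One-phase exponential decay fit
#'
#' Least-squares fit of `y(t) = plateau + span * exp(-k (t - t0))` to a trace
#' segment from `t0` onward, as used to derive the half-life of the glucose
#' signal drop after wash-out into 0 mM medium. Initial guesses come from the
#' segment endpoints (plateau from the tail, span from the first sample) and a
#' log-linear slope; the Levenberg-Marquardt fit then iterates to a parameter
#' tolerance of 1e-8.
#'
#' @param time,y numeric vectors (minutes, ratio units).
#' @param t0 start of the fit window (default first sample).
#' @param t_end optional end of the fit window.
#' @return object of class `decay_fit`: list(k, plateau, span, t_half, rss,
#'   window, converged, n). `t_half = log(2)/k`.
#' @export
fit_one_phase_decay <- function(time, y, t0 = min(time), t_end = max(time)) {
  keep <- time >= t0 & time <= t_end
  tt <- time[keep]; yy <- y[keep]
  if (length(tt) < 5) stop("need at least 5 samples after t0")
  if (stats::sd(yy) == 0) stop("constant input; no decay to fit")
  plateau0 <- mean(utils::tail(yy, max(3, length(yy) %/% 10)))
  span0 <- yy[1] - plateau0
  if (abs(span0) < 1e-12) span0 <- diff(range(yy))
  pos <- yy - plateau0
  usable <- pos > max(pos, na.rm = TRUE) * 0.05
  k0 <- if (sum(usable) >= 3) {
    sl <- stats::coef(stats::lm(log(pos[usable]) ~ tt[usable]))[2]
    max(-sl, 1e-4)
  } else 0.1
  fit <- try(minpack.lm::nlsLM(
    yy ~ plateau + span * exp(-k * (tt - t0)),
    start = list(plateau = plateau0, span = span0, k = k0),
    lower = c(-Inf, -Inf, 1e-8),
    control = minpack.lm::nls.lm.control(maxiter = 200, ptol = 1e-8,
                                         ftol = 1e-10)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(k = NA_real_, plateau = NA_real_, span = NA_real_,
                          t_half = NA_real_, rss = NA_real_,
                          window = c(t0, t_end), converged = FALSE,
                          n = length(tt),
                          diagnostics = attr(fit, "condition")$message),
                     class = "decay_fit"))
  }
  co <- stats::coef(fit)
  structure(list(k = unname(co["k"]), plateau = unname(co["plateau"]),
                 span = unname(co["span"]),
                 t_half = log(2) / unname(co["k"]),
                 rss = sum(stats::resid(fit)^2), window = c(t0, t_end),
                 converged = TRUE, n = length(tt)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("one-phase decay: k = %.4g /min (t1/2 = %.3g min), plateau = %.3g, span = %.3g\n",
              x$k, x$t_half, x$plateau, x$span))
  invisible(x)
}

#' Glucose consumption rate from the post-wash-out signal drop
#'
#' Consumption is the initial rate of signal loss after the switch to 0 mM
#' glucose: the negative of the slope of ratio vs time over a short window
#' (default 3 min) starting at the wash-out. The slope is an OLS fit by
#' default; `mode = "two_point"` uses the difference between the last and
#' first samples of the window instead.
#'
#' @param time,ratio trace vectors (minutes, ratio units).
#' @param washout_time media-switch time (min).
#' @param window window length (min) after wash-out.
#' @param mode "ols" or "two_point".
#' @return consumption rate in ratio-units/min (positive for a dropping
#'   signal).
#' @export
consumption_rate <- function(time, ratio, washout_time, window = 3,
                             mode = c("ols", "two_point")) {
  mode <- match.arg(mode)
  keep <- time >= washout_time & time <= washout_time + window
  if (sum(keep) < 3) stop("fewer than 3 samples in the consumption window")
  -window_slope(time[keep], ratio[keep], mode)
}

window_slope <- function(tt, yy, mode) {
  if (mode == "two_point") {
    (yy[length(yy)] - yy[1]) / (tt[length(tt)] - tt[1])
  } else {
    unname(stats::coef(stats::lm(yy ~ tt))[2])
  }
}

#' Uptake rate by kinetic decomposition of wash-out/wash-in traces
#'
#' The refill slope is the OLS slope of the ratio over the initial window
#' after wash-in to high-glucose medium; since the cell keeps consuming while
#' refilling, the uptake rate is the consumption rate plus the refill slope
#' (exact identity by construction).
#'
#' @inheritParams consumption_rate
#' @param washin_time wash-in media-switch time (min); must give a window
#'   disjoint from the consumption window.
#' @return object of class `flux_estimate`: list(consumption, refill_slope,
#'   uptake, windows).
#' @export
uptake_rate <- function(time, ratio, washout_time, washin_time, window = 3,
                        mode = c("ols", "two_point")) {
  mode <- match.arg(mode)
  if (washin_time <= washout_time + window)
    stop("wash-in window overlaps the consumption window")
  cons <- consumption_rate(time, ratio, washout_time, window, mode)
  keep <- time >= washin_time & time <= washin_time + window
  if (sum(keep) < 3) stop("fewer than 3 samples in the refill window")
  refill <- window_slope(time[keep], ratio[keep], mode)
  structure(list(consumption = cons, refill_slope = refill,
                 uptake = cons + refill,
                 windows = list(consumption = c(washout_time, washout_time + window),
                                refill = c(washin_time, washin_time + window))),
            class = "flux_estimate")
}

#' Per-cell trace stability over a long imaging window
#'
#' Mean and variance of the ratio over the window plus the endpoint pair
#' (signal at the start vs at `window_h` hours) used for start-vs-end scatter
#' plots of metabolic-state stability.
#'
#' @param time minutes; @param ratio ratio units.
#' @param window_h window length in hours (trace must span it).
#' @param gap_tol flag the result if more than this fraction of expected
#'   frames is missing.
#' @return list(mean, variance, ratio_start, ratio_end, flagged).
#' @export
trace_stability <- function(time, ratio, window_h = 10, gap_tol = 0.2) {
  if (max(time) - min(time) < window_h * 60)
    stop("trace does not span the stability window")
  keep <- time <= min(time) + window_h * 60
  tt <- time[keep]; yy <- ratio[keep]
  dt <- stats::median(diff(sort(tt)))
  expected <- floor(window_h * 60 / dt) + 1
  flagged <- length(tt) < (1 - gap_tol) * expected
  list(mean = mean(yy), variance = stats::var(yy),
       ratio_start = yy[which.min(tt)],
       ratio_end = yy[which.max(tt)], flagged = flagged)
}

#' Population endpoint correlation of trace stability
#'
#' Applies [trace_stability()] per cell and returns the per-cell summaries
#' with the population Pearson correlation between start and end signals.
#'
#' @param traces long data.frame with cell_id, time, ratio.
#' @inheritParams trace_stability
#' @return list(per_cell = data.frame, endpoint_r).
#' @export
cohort_stability <- function(traces, window_h = 10) {
  per <- do.call(rbind, lapply(split(traces, traces$cell_id), function(d) {
    s <- trace_stability(d$time, d$ratio, window_h)
    data.frame(cell_id = d$cell_id[1], mean = s$mean, variance = s$variance,
               ratio_start = s$ratio_start, ratio_end = s$ratio_end,
               flagged = s$flagged)
  }))
  rownames(per) <- NULL
  list(per_cell = per,
       endpoint_r = stats::cor(per$ratio_start, per$ratio_end))
}

#' Kinetic decomposition of a wash-out/wash-in cohort
#'
#' Runs the one-phase decay fit over the wash-out segment and the
#' consumption/uptake slope decomposition for every cell of a long-format
#' trace table.
#'
#' @param traces data.frame with cell_id, time, ratio.
#' @param washout_time,washin_time media-switch times (min).
#' @param window slope window (min).
#' @param decay_end end of the decay-fit segment (default `washin_time`).
#' @return data.frame: cell_id, k, t_half, plateau, span, converged,
#'   consumption, refill, uptake.
#' @export
cohort_kinetics <- function(traces, washout_time = 10, washin_time = 40,
                            window = 3, decay_end = washin_time) {
  do.call(rbind, lapply(split(traces, traces$cell_id), function(d) {
    fit <- fit_one_phase_decay(d$time, d$ratio, t0 = washout_time,
                               t_end = decay_end)
    fl <- uptake_rate(d$time, d$ratio, washout_time, washin_time, window)
    data.frame(cell_id = d$cell_id[1], k = fit$k, t_half = fit$t_half,
               plateau = fit$plateau, span = fit$span,
               converged = fit$converged, consumption = fl$consumption,
               refill = fl$refill_slope, uptake = fl$uptake,
               row.names = NULL)
  }))
}
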