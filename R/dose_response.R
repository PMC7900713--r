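#' Stepped inhibitor dose schedule
#'
#' Times (h) at which each concentration starts, plus per-step assay times at
#' which the FRET ratio is read out. The default assay time for a step is just
#' before the next step begins (or `end_h` for the last step).
#'
#' @param time_h step start times (strictly increasing, first at 0).
#' @param conc_uM concentrations; must be non-decreasing unless
#'   `washout = TRUE` (reversibility experiments end in 0).
#' @param assay_h optional assay times per step.
#' @param end_h end of the experiment (default: last step + median spacing).
#' @param washout allow decreasing concentrations.
#' @return data.frame of class `dose_schedule`: time_h, conc_uM, assay_h.
#' @export
dose_schedule <- function(time_h = c(0, 1, 2, 3),
                          conc_uM = c(0, 0.05, 0.1, 0.5),
                          assay_h = NULL, end_h = NULL, washout = FALSE) {
  if (length(time_h) == 0) stop("empty dose schedule")
  stopifnot(length(time_h) == length(conc_uM))
  if (any(diff(time_h) <= 0)) stop("step times must be strictly increasing")
  if (!washout && any(diff(conc_uM) < 0))
    stop("concentrations must be non-decreasing (set washout = TRUE to allow)")
  if (is.null(end_h))
    end_h <- max(time_h) + stats::median(diff(c(time_h, NA)), na.rm = TRUE)
  if (is.null(assay_h))
    assay_h <- c(time_h[-1], end_h) - 5 / 60
  sched <- data.frame(time_h = time_h, conc_uM = conc_uM, assay_h = assay_h)
  attr(sched, "end_h") <- end_h
  class(sched) <- c("dose_schedule", "data.frame")
  sched
}

#' Simulate a single-cell stepped dose-response cohort
#'
#' Generates per-cell FRET traces under a stepped inhibitor schedule. Each
#' non-refractory cell belongs to a responder class with a class-specific
#' fractional decline at each dose step (reached with a ~15 min relaxation
#' after the step); refractory cells have a constitutively high baseline
#' (upper tail of the population) and do not respond at any dose. An
#' untreated control cohort is generated from the same baseline distribution.
#'
#' Ground truth records the class, and the refractory flag in its operational
#' sense: whether the cell's noise-free ratio at the final assay time exceeds
#' the control-population median. Constitutively refractory cells always
#' satisfy it; occasional non-responders with an above-median baseline do too,
#' which is inherent to a median-referenced definition.
#'
#' @param schedule a [dose_schedule()].
#' @param mix named fractions c(non=, weak=, strong=) summing to 1 (applied to
#'   the non-refractory cells).
#' @param refractory_fraction fraction of constitutively refractory cells.
#' @param n_cells,n_control treated and control cohort sizes.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline ratio params.
#' @param effects list of per-step response fractions by class (fraction of
#'   baseline remaining at each step, first step = pre-dose = 1).
#' @param tau_min response relaxation time constant after each step (min).
#' @param frame_interval_min imaging interval; @param noise_sd frame noise.
#' @param seed RNG seed.
#' @return list: `traces` (cell_id, time_h, ratio), `control_traces`,
#'   `truth` (cell_id, class, refractory, baseline, final_ratio_true),
#'   `control_median_true` (analytic median of the control baseline law).
#' @export
simulate_dose_cohort <- function(schedule = dose_schedule(),
                                 mix = c(non = 0.3, weak = 0.4, strong = 0.3),
                                 refractory_fraction = 0.11,
                                 n_cells = 600, n_control = 300,
                                 baseline_meanlog = log(1.8),
                                 baseline_sdlog = 0.2,
                                 effects = list(
                                   non = c(1, 1.00, 0.99, 0.98),
                                   weak = c(1, 0.95, 0.85, 0.70),
                                   strong = c(1, 0.65, 0.55, 0.45)),
                                 tau_min = 15,
                                 frame_interval_min = 5, noise_sd = 0.02,
                                 seed = 1L) {
  if (nrow(schedule) == 0) stop("empty dose schedule")
  if (abs(sum(mix) - 1) > 1e-9) stop("class mix must sum to 1")
  stopifnot(refractory_fraction >= 0, refractory_fraction <= 1)
  if (any(vapply(effects, length, integer(1)) != nrow(schedule)))
    stop("each class effect vector needs one entry per dose step")
  set.seed(seed)
  end_h <- attr(schedule, "end_h")
  tt <- seq(0, end_h, by = frame_interval_min / 60)
  n <- n_cells
  refr <- stats::runif(n) < refractory_fraction
  cls <- sample(names(mix), n, replace = TRUE, prob = mix)
  cls[refr] <- "non"
  baseline <- stats::rlnorm(n, baseline_meanlog, baseline_sdlog)
  # constitutively high cells: resample the upper 30% tail of the baseline law
  nref <- sum(refr)
  if (nref > 0) {
    u <- stats::runif(nref, 0.7, 1)
    baseline[refr] <- stats::qlnorm(u, baseline_meanlog, baseline_sdlog)
  }
  # piecewise-exponential approach to each step's class target level
  target_at <- function(frac, t) {
    lvl <- rep(frac[1], length(t))
    entry <- frac[1]
    for (s in seq_len(nrow(schedule))[-1]) {
      t0 <- schedule$time_h[s]
      t1 <- if (s < nrow(schedule)) schedule$time_h[s + 1] else Inf
      inseg <- t >= t0 & t < t1
      lvl[inseg] <- frac[s] + (entry - frac[s]) *
        exp(-(t[inseg] - t0) * 60 / tau_min)
      if (is.finite(t1))
        entry <- frac[s] + (entry - frac[s]) * exp(-(t1 - t0) * 60 / tau_min)
    }
    lvl
  }
  mk_traces <- function(ids, base, fracs) {
    do.call(rbind, lapply(seq_along(ids), function(i) {
      lvl <- target_at(fracs[[i]], tt)
      data.frame(cell_id = ids[i], time_h = tt,
                 ratio = base[i] * lvl + stats::rnorm(length(tt), 0, noise_sd))
    }))
  }
  fracs <- lapply(seq_len(n), function(i) {
    if (refr[i]) rep(1, nrow(schedule)) else effects[[cls[i]]]
  })
  traces <- mk_traces(seq_len(n), baseline, fracs)
  ctrl_base <- stats::rlnorm(n_control, baseline_meanlog, baseline_sdlog)
  control <- mk_traces(seq_len(n_control), ctrl_base,
                       replicate(n_control, rep(1, nrow(schedule)),
                                 simplify = FALSE))
  control_median_true <- exp(baseline_meanlog)
  final_assay <- schedule$assay_h[nrow(schedule)]
  final_true <- vapply(seq_len(n), function(i)
    baseline[i] * target_at(fracs[[i]], final_assay), numeric(1))
  truth <- data.frame(cell_id = seq_len(n), class = cls,
                      constitutive = refr,
                      refractory = final_true > control_median_true,
                      baseline = baseline, final_ratio_true = final_true)
  list(traces = traces, control_traces = control, truth = truth,
       control_median_true = control_median_true, schedule = schedule)
}

#' Per-step ratio and normalized FRET shift for one cell
#'
#' Samples the trace at each dose step's assay time (mean of frames within
#' `half_window_h`) and computes the baseline-normalized shift
#' `(ratio_i - ratio_0) / ratio_0`.
#'
#' @param time_h,ratio the cell's trace.
#' @param schedule a [dose_schedule()].
#' @param half_window_h averaging half-window around each assay time (h).
#' @param normalized `FALSE` returns absolute shifts `ratio_i - ratio_0`.
#' @return data.frame: step, conc_uM, assay_h, ratio, shift; or NULL (cell
#'   excluded) if any assay window has no frames.
#' @export
per_step_response <- function(time_h, ratio, schedule,
                              half_window_h = 5 / 60, normalized = TRUE) {
  vals <- vapply(schedule$assay_h, function(a) {
    keep <- abs(time_h - a) <= half_window_h + 1e-9
    if (!any(keep)) return(NA_real_)
    mean(ratio[keep])
  }, numeric(1))
  if (any(is.na(vals))) return(NULL)
  shift <- if (normalized) (vals - vals[1]) / vals[1] else vals - vals[1]
  data.frame(step = seq_len(nrow(schedule)), conc_uM = schedule$conc_uM,
             assay_h = schedule$assay_h, ratio = vals, shift = shift)
}

#' Classify a cell's dose response from its per-step shifts
#'
#' "strong" if the shift at the lowest non-zero dose is already at or below
#' `-T_strong`; "non" if the shift at the final (maximal) dose stays above
#' `-T_non`; "weak" otherwise.
#'
#' @param steps output of [per_step_response()].
#' @param T_strong,T_non ordered thresholds (T_strong > T_non).
#' @return class string.
#' @export
classify_responder <- function(steps, T_strong = 0.2, T_non = 0.05) {
  stopifnot(T_strong > T_non)
  nz <- which(steps$conc_uM > 0)
  if (length(nz) == 0) stop("schedule has no non-zero dose")
  first_shift <- steps$shift[nz[1]]
  final_shift <- steps$shift[nrow(steps)]
  if (first_shift <= -T_strong) return("strong")
  if (final_shift >= -T_non) return("non")
  "weak"
}

#' Flag refractory cells against an untreated control population
#'
#' A treated cell is refractory when its ratio at the final (maximal) dose is
#' strictly greater than the median of the control population, i.e. complete
#' pathway inhibition failed to push its glucose level below the typical
#' untreated cell.
#'
#' @param treated_final per-cell ratios of the treated cohort at the final
#'   assay time.
#' @param control control-population ratios (n >= 20).
#' @param conf_level confidence level of the binomial CI on the fraction.
#' @return list: refractory (logical per cell), fraction, ci (binomial),
#'   control_median, n.
#' @export
flag_refractory <- function(treated_final, control, conf_level = 0.95) {
  if (length(control) < 20) stop("control population too small (n < 20)")
  med <- stats::median(control)
  flag <- treated_final > med
  n <- length(flag)
  bt <- stats::binom.test(sum(flag), n, conf.level = conf_level)
  list(refractory = flag, fraction = mean(flag),
       ci = unname(bt$conf.int), control_median = med, n = n)
}

#' Dose-response analysis of a treated cohort
#'
#' Applies [per_step_response()] and [classify_responder()] per cell and
#' [flag_refractory()] against the control, excluding (and counting) cells
#' with missing assay frames.
#'
#' @param traces long data.frame: cell_id, time_h, ratio (treated).
#' @param control_traces same format, untreated; control ratios are taken at
#'   the final assay time.
#' @param schedule a [dose_schedule()].
#' @param T_strong,T_non classification thresholds.
#' @param normalized use baseline-normalized shifts.
#' @return list: calls (cell_id, class, refractory, final_ratio, per-step
#'   shifts wide), refractory_fraction, refractory_ci, n_excluded.
#' @export
dose_response_analysis <- function(traces, control_traces, schedule,
                                   T_strong = 0.2, T_non = 0.05,
                                   normalized = TRUE) {
  cells <- split(traces, traces$cell_id)
  rows <- list(); excluded <- 0L
  for (d in cells) {
    st <- per_step_response(d$time_h, d$ratio, schedule,
                            normalized = normalized)
    if (is.null(st)) { excluded <- excluded + 1L; next }
    rows[[length(rows) + 1]] <- data.frame(
      cell_id = d$cell_id[1],
      class = classify_responder(st, T_strong, T_non),
      final_ratio = st$ratio[nrow(st)],
      t(stats::setNames(st$shift, paste0("shift_", seq_len(nrow(st))))))
  }
  calls <- do.call(rbind, rows)
  final_assay <- schedule$assay_h[nrow(schedule)]
  ctrl <- vapply(split(control_traces, control_traces$cell_id), function(d) {
    keep <- abs(d$time_h - final_assay) <= 5 / 60 + 1e-9
    mean(d$ratio[keep])
  }, numeric(1))
  fr <- flag_refractory(calls$final_ratio, ctrl)
  calls$refractory <- fr$refractory
  list(calls = calls, refractory_fraction = fr$fraction,
       refractory_ci = fr$ci, control_median = fr$control_median,
       n_excluded = excluded)
}
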