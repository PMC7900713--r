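#' Simulate a single-cell glucose biosensor trace
#'
#' Integrates the intracellular glucose balance
#' \deqn{dG/dt = V_{up}\,u(G_{ext}(t)) - V_{con}\,\frac{G}{K_m + G}}
#' where `u(G_ext) = G_ext/(K_up + G_ext)` is the saturable media dependence of
#' transport, under the media schedule of `config` (e.g. wash-out to 0 mM at
#' 10 min, wash-in to 25 mM at 40 min), and emits the biosensor ratio
#' `R(G(t))` plus Gaussian measurement noise at every frame.
#'
#' The consumption Michaelis constant `Km` is set above the operating glucose
#' range by default so that wash-out decays are close to single-exponential,
#' matching the one-phase decays this class of biosensor experiment shows.
#'
#' @param config a [scenario_config()]; supplies media schedule, frame grid and
#'   `noise_sd`.
#' @param model a [biosensor_model()].
#' @param cell list with elements `Vup` (mM/min), `Vcon` (mM/min), `G0` (mM),
#'   and optionally `Km` (mM, default 2) and `Kup` (mM, default 1.7).
#' @param seed optional seed for the measurement noise; `NULL` leaves the RNG
#'   state alone (cohort generators seed once upstream).
#' @param fine integer subdivision of the frame interval used by the
#'   integrator's output grid (1 = frames only). The ODE solver is adaptive, so
#'   this only controls where the solution is sampled.
#' @return data.frame with columns `time` (min), `G` (mM), `ratio`.
#' @export
simulate_cell_trace <- function(config, model, cell, seed = NULL, fine = 1L) {
  if (cell$Vup < 0 || cell$Vcon < 0) stop("rates must be non-negative")
  if (is.null(cell$Km)) cell$Km <- 2.0
  if (is.null(cell$Kup)) cell$Kup <- 1.7
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, by = config$frame_interval / fine,
               length.out = fine * floor(config$duration / config$frame_interval) + 1)
  sol <- integrate_glucose(cell, config$glucose_schedule, times)
  ratio <- biosensor_ratio(model, sol$G)
  if (config$noise_sd > 0)
    ratio <- ratio + stats::rnorm(length(ratio), 0, config$noise_sd)
  data.frame(time = sol$time, G = sol$G, ratio = ratio)
}

# piecewise integration of the glucose ODE across media-schedule breakpoints
integrate_glucose <- function(cell, schedule, times) {
  rhs <- function(t, y, p) {
    G <- max(y[1], 0)
    list(p$Vup * p$u - p$Vcon * G / (p$Km + G))
  }
  out_t <- numeric(0); out_g <- numeric(0)
  G <- cell$G0
  brks <- sort(unique(c(schedule$time[schedule$time < max(times)], max(times))))
  for (i in seq_len(length(brks) - 1)) {
    t0 <- brks[i]
    t1 <- brks[i + 1]
    last <- i == length(brks) - 1
    seg <- times[times >= t0 & (times < t1 | (last & times <= t1))]
    grid <- unique(c(t0, seg, t1))
    u <- media_glucose(schedule, t0) / (cell$Kup + media_glucose(schedule, t0))
    p <- list(Vup = cell$Vup, Vcon = cell$Vcon, Km = cell$Km, u = u)
    sol <- deSolve::ode(y = c(G = G), times = grid, func = rhs, parms = p,
                        method = "lsoda", rtol = 1e-9, atol = 1e-12)
    keep <- sol[, "time"] %in% seg
    out_t <- c(out_t, sol[keep, "time"])
    out_g <- c(out_g, pmax(sol[keep, "G"], 0))
    G <- max(sol[nrow(sol), "G"], 0)
  }
  data.frame(time = out_t, G = out_g)
}

# analytic instantaneous ratio-rate dR/dt at time t+ (just after any media switch)
ratio_rate_at <- function(model, cell, schedule, t, G) {
  u <- media_glucose(schedule, t) / (cell$Kup + media_glucose(schedule, t))
  dG <- cell$Vup * u - cell$Vcon * G / (cell$Km + G)
  h <- model$hill
  dRdG <- (model$R_max - model$R_min) *
    h * model$Kd^h * G^(h - 1) / (model$Kd^h + G^h)^2
  dRdG * dG
}

#' Simulate a wash-out/wash-in cohort with kinetic ground truth
#'
#' Generates `config$n_cells` heterogeneous cells at steady state in the
#' starting medium, then runs the media schedule (default: 25 mM from 0, 0 mM
#' from 10 min, 25 mM from 40 min) through [simulate_cell_trace()]. Ground
#' truth records, per cell, the generating transport parameters and the
#' model-implied instantaneous signal rates that the kinetics stage estimates:
#' the consumption rate (initial rate of signal drop at wash-out), the refill
#' rate (initial rate of signal rise at wash-in), and their sum, the uptake
#' rate.
#'
#' High-state cells sit at higher steady ratio and consume/take up glucose
#' faster than low-state cells, reproducing the coupling between steady-state
#' glucose level and flux that motivates the wash-out/wash-in decomposition.
#'
#' @param config a [scenario_config()]; its `glucose_schedule` should contain a
#'   wash-out (0 mM) and a wash-in step.
#' @param model a [biosensor_model()].
#' @return list with `traces` (long data.frame: cell_id, time, ratio, G) and
#'   `truth` (one row per cell: state, Vup_mM, Vcon_mM, G0, consumption,
#'   refill, uptake in ratio-units/min, washout_time, washin_time).
#' @export
simulate_washout_cohort <- function(config,
                                    model = biosensor_model()) {
  set.seed(config$seed)
  sched <- config$glucose_schedule
  zero_steps <- sched$time[sched$glucose_mM == 0]
  if (length(zero_steps) < 1) stop("schedule must contain a wash-out (0 mM) step")
  washout <- zero_steps[1]
  later <- sched$time[sched$time > washout & sched$glucose_mM > 0]
  washin <- if (length(later)) later[1] else NA_real_
  n <- config$n_cells
  frac_high <- config$state_mix[["high"]]
  state <- ifelse(stats::runif(n) < frac_high, "high", "low")
  target <- ifelse(state == "high",
                   stats::rnorm(n, 2.2, 0.12), stats::rnorm(n, 1.5, 0.10))
  target <- pmin(pmax(target, model$R_min + 0.1), model$R_max - 0.2)
  Gstar <- biosensor_inverse(model, target)
  Km <- 2.0; Kup <- 1.7
  occ <- Gstar / (model$Kd + Gstar)
  Vcon <- (0.25 + 0.45 * occ) * exp(stats::rnorm(n, 0, 0.2))
  u0 <- media_glucose(sched, 0) / (Kup + media_glucose(sched, 0))
  Vup <- Vcon * (Gstar / (Km + Gstar)) / u0
  traces <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    cell <- list(Vup = Vup[i], Vcon = Vcon[i], G0 = Gstar[i], Km = Km, Kup = Kup)
    tr <- simulate_cell_trace(config, model, cell)
    traces[[i]] <- data.frame(cell_id = i, tr)
    G_wo <- tr$G[which.min(abs(tr$time - washout))]
    cons <- -ratio_rate_at(model, cell, sched, washout, G_wo)
    refill <- NA_real_
    if (!is.na(washin)) {
      G_wi <- tr$G[which.min(abs(tr$time - washin))]
      refill <- ratio_rate_at(model, cell, sched, washin, G_wi)
    }
    truth[[i]] <- data.frame(cell_id = i, state = state[i], Vup_mM = Vup[i],
                             Vcon_mM = Vcon[i], G0 = Gstar[i],
                             consumption = cons, refill = refill,
                             uptake = cons + refill,
                             washout_time = washout, washin_time = washin)
  }
  list(traces = do.call(rbind, traces), truth = do.call(rbind, truth))
}

#' Simulate a dividing lineage cohort with heritable metabolic state
#'
#' Each founder carries a standardized latent glycolytic state drawn from the
#' high/low mixture of `config$state_mix`; at every division the track ends and
#' two daughter tracks begin, each inheriting
#' `state_child = rho * state_parent + sqrt(1 - rho^2) * innovation`
#' (an AR(1) process across generations, so parent-daughter correlation is
#' `rho` and grandparent-granddaughter correlation `rho^2`). The emitted ratio
#' is a per-cell baseline (linear in the state) plus a slow
#' Ornstein-Uhlenbeck within-cell fluctuation and frame-level measurement
#' noise. Cell-cycle lengths are Gamma-distributed with mean
#' `1/division_rate` hours (CV ~0.16); positions follow a small random walk so
#' the cohort can be rendered into imagery.
#'
#' @param config a [scenario_config()]; `division_rate` 0 gives non-dividing
#'   tracks spanning the full duration.
#' @param baseline_mean,baseline_sd mean ratio and state-to-ratio scale.
#' @param ou_sd,ou_tau within-cell fluctuation SD (ratio units) and correlation
#'   time (min).
#' @param image_shape c(height, width) in px for the random-walk positions.
#' @return list with `traces` (cell_id, parent_id, frame, time, ratio, x, y)
#'   and `lineage` (cell_id, parent_id, generation, birth_time, death_time,
#'   divided, state, baseline_ratio).
#' @export
simulate_lineage_cohort <- function(config,
                                    baseline_mean = 1.8, baseline_sd = 0.25,
                                    ou_sd = 0.03, ou_tau = 60,
                                    image_shape = c(512, 512)) {
  set.seed(config$seed)
  rho <- config$heritability_rho
  n0 <- config$n_cells
  frac_high <- config$state_mix[["high"]]
  comp <- stats::runif(n0) < frac_high
  raw <- ifelse(comp, stats::rnorm(n0, 1, 0.5), stats::rnorm(n0, -1, 0.5))
  # standardize to the mixture's analytic moments so AR(1) stays unit-variance
  mmean <- frac_high * 1 + (1 - frac_high) * (-1)
  mvar <- 0.25 + frac_high * (1 - mmean)^2 + (1 - frac_high) * (-1 - mmean)^2
  state0 <- (raw - mmean) / sqrt(mvar)
  cycle_min <- function(k) {
    if (config$division_rate <= 0) return(rep(Inf, k))
    mean_cycle <- 60 / config$division_rate
    stats::rgamma(k, shape = 40, scale = mean_cycle / 40)
  }
  tgrid <- frame_times(config)
  dt <- config$frame_interval
  a_ou <- exp(-dt / ou_tau)
  nxt_id <- 0L
  queue <- lapply(seq_len(n0), function(i) {
    list(parent = NA_integer_, gen = 1L, birth = 0,
         state = state0[i],
         x = stats::runif(1, 20, image_shape[2] - 20),
         y = stats::runif(1, 20, image_shape[1] - 20))
  })
  traces <- list(); lineage <- list()
  while (length(queue) > 0) {
    cellinfo <- queue[[1]]; queue <- queue[-1]
    nxt_id <- nxt_id + 1L
    id <- nxt_id
    life <- cycle_min(1)
    divided <- (cellinfo$birth + life) <= config$duration
    # division events are observed at frames: snap to the imaging grid
    death <- if (divided)
      tgrid[max(which(tgrid <= cellinfo$birth + life))]
    else config$duration
    if (divided && death <= cellinfo$birth) {
      nxt_frames <- which(tgrid > cellinfo$birth)
      if (length(nxt_frames) == 0) {
        divided <- FALSE; death <- config$duration
      } else death <- tgrid[min(nxt_frames)]
    }
    idx <- which(tgrid >= cellinfo$birth & tgrid <= death)
    nf <- length(idx)
    baseline <- baseline_mean + baseline_sd * cellinfo$state
    ou <- numeric(nf)
    if (nf > 0) {
      ou[1] <- stats::rnorm(1, 0, ou_sd)
      if (nf > 1)
        for (j in 2:nf)
          ou[j] <- a_ou * ou[j - 1] + stats::rnorm(1, 0, ou_sd * sqrt(1 - a_ou^2))
      xs <- cumsum(c(cellinfo$x, stats::rnorm(nf - 1, 0, 0.7)))
      ys <- cumsum(c(cellinfo$y, stats::rnorm(nf - 1, 0, 0.7)))
      xs <- pmin(pmax(xs, 10), image_shape[2] - 10)
      ys <- pmin(pmax(ys, 10), image_shape[1] - 10)
      ratio <- baseline + ou +
        if (config$noise_sd > 0) stats::rnorm(nf, 0, config$noise_sd) else 0
      traces[[id]] <- data.frame(cell_id = id, parent_id = cellinfo$parent,
                                 frame = idx, time = tgrid[idx],
                                 ratio = ratio, x = xs, y = ys)
    }
    lineage[[id]] <- data.frame(cell_id = id, parent_id = cellinfo$parent,
                                generation = cellinfo$gen,
                                birth_time = cellinfo$birth, death_time = death,
                                divided = divided, state = cellinfo$state,
                                baseline_ratio = baseline)
    if (divided) {
      for (d in 1:2) {
        innov <- if (rho < 1) stats::rnorm(1) else 0
        queue[[length(queue) + 1]] <- list(
          parent = id, gen = cellinfo$gen + 1L, birth = death,
          state = rho * cellinfo$state + sqrt(max(0, 1 - rho^2)) * innov,
          x = cellinfo$x + stats::rnorm(1, 0, 3),
          y = cellinfo$y + stats::rnorm(1, 0, 3))
      }
    }
  }
  list(traces = do.call(rbind, traces), lineage = do.call(rbind, lineage))
}

#' Simulate sorted subpopulations relaxing back to the population mean
#'
#' Ornstein-Uhlenbeck state dynamics: a sorted (high or low) subpopulation
#' starts displaced from the population mean and relaxes with time constant
#' `tau_days`, emulating sorted high-/low-glucose cells followed over days.
#'
#' @param n_cells cells per subpopulation.
#' @param start_offset initial displacement from the mean (ratio units;
#'   positive for the high sort).
#' @param tau_days relaxation time constant (days).
#' @param duration_days,sample_interval_h follow-up length and sampling.
#' @param mean_ratio population mean; @param state_sd stationary SD.
#' @param noise_sd frame-level measurement noise.
#' @param seed RNG seed.
#' @return long data.frame: cell_id, time_h, ratio.
#' @export
simulate_sorted_cohort <- function(n_cells = 200, start_offset = 0.5,
                                   tau_days = 2, duration_days = 8,
                                   sample_interval_h = 6, mean_ratio = 1.8,
                                   state_sd = 0.1, noise_sd = 0.02,
                                   seed = 1L) {
  set.seed(seed)
  tt <- seq(0, duration_days * 24, by = sample_interval_h)
  a <- exp(-(sample_interval_h / 24) / tau_days)
  sig <- state_sd * sqrt(1 - a^2)
  out <- lapply(seq_len(n_cells), function(i) {
    x <- numeric(length(tt))
    x[1] <- start_offset + stats::rnorm(1, 0, state_sd / 2)
    for (j in seq_along(tt)[-1]) x[j] <- a * x[j - 1] + stats::rnorm(1, 0, sig)
    data.frame(cell_id = i, time_h = tt,
               ratio = mean_ratio + x + stats::rnorm(length(tt), 0, noise_sd))
  })
  do.call(rbind, out)
}
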