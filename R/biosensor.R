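#' Glucose FRET biosensor response model
#'
#' Saturable (Hill) mapping from intracellular glucose concentration to the
#' emitted acceptor/donor FRET ratio. The sensor reads
#' \deqn{R(G) = R_{min} + (R_{max}-R_{min}) \frac{G^h}{K_d^h + G^h}}
#' so the ratio rises monotonically from `R_min` (apo sensor, 0 mM glucose) to
#' `R_max` at saturation, with half-saturation at `Kd`.
#'
#' Defaults are placeholders for a periplasmic binding-protein glucose sensor
#' (Kd in the high-micromolar range, hyperbolic binding) and are fully
#' configurable; the analysis never depends on their absolute values.
#'
#' @param R_min ratio at 0 glucose (unitless acceptor/donor).
#' @param R_max ratio at sensor saturation; must exceed `R_min`.
#' @param Kd half-saturation glucose concentration (mM).
#' @param hill Hill coefficient (1 = hyperbolic binding).
#' @return An object of class `biosensor_model`.
#' @export
#' @examples
#' m <- biosensor_model()
#' biosensor_ratio(m, c(0, m$Kd, Inf))
biosensor_model <- function(R_min = 1.0, R_max = 3.0, Kd = 0.6, hill = 1) {
  stopifnot(R_min > 0, R_max > R_min, Kd > 0, hill > 0)
  structure(list(R_min = R_min, R_max = R_max, Kd = Kd, hill = hill),
            class = "biosensor_model")
}

#' Emitted FRET ratio for a glucose concentration
#'
#' @param model a [biosensor_model()].
#' @param G intracellular glucose (mM), vectorized; `Inf` gives `R_max`.
#' @return FRET ratio(s), same length as `G`.
#' @export
biosensor_ratio <- function(model, G) {
  stopifnot(inherits(model, "biosensor_model"), all(G >= 0))
  occ <- ifelse(is.infinite(G), 1, G^model$hill / (model$Kd^model$hill + G^model$hill))
  occ[G == 0] <- 0
  model$R_min + (model$R_max - model$R_min) * occ
}

#' Inverse of the biosensor response
#'
#' Glucose concentration that yields a given ratio; used by generators that
#' specify targets in ratio units.
#'
#' @param model a [biosensor_model()].
#' @param R ratio(s) in `(R_min, R_max)`.
#' @return glucose (mM).
#' @export
biosensor_inverse <- function(model, R) {
  stopifnot(all(R > model$R_min), all(R < model$R_max))
  occ <- (R - model$R_min) / (model$R_max - model$R_min)
  model$Kd * (occ / (1 - occ))^(1 / model$hill)
}

#' Scenario configuration for synthetic time-lapse cohorts
#'
#' Bundles and validates the parameters shared by the trace generators: cohort
#' size, imaging duration and frame interval, the extracellular glucose media
#' schedule (a step function of time), the high/low glycolytic state mixture,
#' cross-generation heritability, division rate, and measurement noise.
#'
#' @param n_cells number of founder cells.
#' @param duration total imaged time (minutes).
#' @param frame_interval time between frames (minutes).
#' @param glucose_schedule data.frame with columns `time` (min) and
#'   `glucose_mM`: extracellular glucose from each `time` onward. Must start at
#'   time 0 and be sorted.
#' @param state_mix named fractions of `high` / `low` glycolytic founders,
#'   summing to 1.
#' @param heritability_rho cross-generation state correlation in \[0, 1\].
#' @param division_rate divisions per hour per cell (0 = no divisions).
#' @param noise_sd Gaussian measurement noise on the emitted ratio (ratio units).
#' @param seed integer RNG seed; the generators are deterministic given
#'   (config, seed).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_cells = 200,
                            duration = 70,
                            frame_interval = 0.5,
                            glucose_schedule = data.frame(time = 0, glucose_mM = 25),
                            state_mix = c(high = 0.5, low = 0.5),
                            heritability_rho = 0.8,
                            division_rate = 0,
                            noise_sd = 0.02,
                            seed = 1L) {
  stopifnot(n_cells >= 1, frame_interval > 0, duration >= frame_interval,
            is.data.frame(glucose_schedule),
            all(c("time", "glucose_mM") %in% names(glucose_schedule)))
  if (abs(sum(state_mix) - 1) > 1e-9)
    stop("state_mix fractions must sum to 1")
  if (heritability_rho < 0 || heritability_rho > 1)
    stop("heritability_rho must lie in [0, 1]")
  if (division_rate < 0) stop("division_rate must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  sched <- glucose_schedule[order(glucose_schedule$time), , drop = FALSE]
  if (!identical(sched$time, glucose_schedule$time))
    stop("glucose_schedule times must be sorted increasing")
  if (sched$time[1] != 0) stop("glucose_schedule must start at time 0")
  if (any(sched$time < 0) || any(sched$time > duration))
    stop("glucose_schedule times must lie within [0, duration]")
  if (any(sched$glucose_mM < 0)) stop("glucose concentrations must be >= 0")
  structure(list(n_cells = as.integer(n_cells), duration = duration,
                 frame_interval = frame_interval, glucose_schedule = sched,
                 state_mix = state_mix, heritability_rho = heritability_rho,
                 division_rate = division_rate, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Extracellular glucose at given times under a media schedule
#'
#' Step function: the concentration set at the most recent schedule time.
#'
#' @param schedule data.frame(time, glucose_mM), sorted.
#' @param t times (minutes), vectorized.
#' @return glucose (mM) at each `t`.
#' @export
media_glucose <- function(schedule, t) {
  idx <- findInterval(t, schedule$time)
  idx[idx < 1] <- 1
  schedule$glucose_mM[idx]
}

# frame time grid for a config (duration/frame_interval + 1 samples from 0)
frame_times <- function(config) {
  seq(0, by = config$frame_interval,
      length.out = floor(config$duration / config$frame_interval) + 1)
}
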