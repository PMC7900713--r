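#' Synchronize lineage traces to each founder's first mitosis
#'
#' Relabels the time axis so that every founder's first division occurs at
#' T = 0; all progeny of that founder are shifted by the same offset, so one
#' track gives rise to two tracks on a common axis. Founders that never
#' divide are excluded (with a warning listing how many).
#'
#' @param traces long data.frame: cell_id, parent_id, frame, time, ratio, ...
#' @param lineage data.frame: cell_id, parent_id, death_time, divided.
#' @return `traces` restricted to synchronizable families, with extra columns
#'   `founder_id` and `time_sync` (min, 0 = founder's first mitosis).
#' @export
synchronize_to_mitosis <- function(traces, lineage) {
  founder <- founder_map(lineage)
  founders <- lineage$cell_id[is.na(lineage$parent_id)]
  div_time <- stats::setNames(lineage$death_time, lineage$cell_id)
  divided <- stats::setNames(lineage$divided, lineage$cell_id)
  ok_founders <- founders[divided[as.character(founders)]]
  dropped <- length(founders) - length(ok_founders)
  if (length(ok_founders) == 0) {
    warning("no founder divided; nothing to synchronize")
    out <- traces[0, , drop = FALSE]
    out$founder_id <- integer(0); out$time_sync <- numeric(0)
    return(out)
  }
  if (dropped > 0)
    warning(sprintf("%d founder(s) without a division excluded", dropped))
  fid <- founder[as.character(traces$cell_id)]
  keep <- fid %in% ok_founders
  out <- traces[keep, , drop = FALSE]
  out$founder_id <- fid[keep]
  out$time_sync <- out$time - div_time[as.character(out$founder_id)]
  rownames(out) <- NULL
  out
}

# cell_id -> founder cell_id, walking parent links
founder_map <- function(lineage) {
  parent <- stats::setNames(lineage$parent_id, lineage$cell_id)
  vapply(lineage$cell_id, function(id) {
    while (!is.na(parent[as.character(id)])) id <- parent[as.character(id)]
    as.integer(id)
  }, integer(1), USE.NAMES = TRUE) -> f
  names(f) <- lineage$cell_id
  f
}

#' Per-cell summary ratio for heritability statistics
#'
#' Mean ratio over the final `window` minutes of each track (for dividing
#' cells, the period leading up to mitosis).
#'
#' @param traces long data.frame: cell_id, time, ratio.
#' @param window summary window (min) before the end of each track.
#' @return data.frame: cell_id, summary_ratio, n_frames.
#' @export
cell_summary_ratio <- function(traces, window = 120) {
  out <- do.call(rbind, lapply(split(traces, traces$cell_id), function(d) {
    keep <- d$time >= max(d$time) - window
    data.frame(cell_id = d$cell_id[1],
               summary_ratio = mean(d$ratio[keep]),
               n_frames = sum(keep))
  }))
  rownames(out) <- NULL
  out
}

#' Cross-generation correlation of metabolic state
#'
#' Pearson correlation of per-cell summary ratios between ancestors and
#' descendants: parent vs daughter (every daughter contributes one pair) and
#' grandparent vs granddaughter. Under AR(1) inheritance with correlation
#' rho, the expected values are rho and rho^2, so a decline across
#' generations is the heritable-state signature.
#'
#' @param traces long data.frame: cell_id, time, ratio.
#' @param lineage data.frame: cell_id, parent_id.
#' @param window summary window (min), see [cell_summary_ratio()].
#' @param one_per_family subsample a single daughter per parent for
#'   independent pairs (default uses all progeny).
#' @param min_pairs flag results based on fewer pairs than this.
#' @return data.frame with rows `parent_daughter` and
#'   `grandparent_granddaughter`: r, n_pairs, low_n.
#' @export
generation_correlation <- function(traces, lineage, window = 120,
                                   one_per_family = FALSE, min_pairs = 10) {
  summ <- cell_summary_ratio(traces, window)
  sr <- stats::setNames(summ$summary_ratio, summ$cell_id)
  parent <- stats::setNames(lineage$parent_id, lineage$cell_id)
  kids <- lineage[!is.na(lineage$parent_id), , drop = FALSE]
  if (one_per_family)
    kids <- kids[!duplicated(kids$parent_id), , drop = FALSE]
  pd <- data.frame(anc = parent[as.character(kids$cell_id)],
                   dec = kids$cell_id)
  gp <- parent[as.character(pd$anc)]
  gg <- data.frame(anc = gp, dec = pd$dec)[!is.na(gp), , drop = FALSE]
  corr_of <- function(pairs) {
    a <- sr[as.character(pairs$anc)]; d <- sr[as.character(pairs$dec)]
    ok <- !is.na(a) & !is.na(d)
    n <- sum(ok)
    r <- if (n >= 3) stats::cor(a[ok], d[ok]) else NA_real_
    c(r = r, n = n)
  }
  r1 <- corr_of(pd); r2 <- corr_of(gg)
  data.frame(comparison = c("parent_daughter", "grandparent_granddaughter"),
             r = c(r1["r"], r2["r"]),
             n_pairs = as.integer(c(r1["n"], r2["n"])),
             low_n = c(r1["n"], r2["n"]) < min_pairs,
             row.names = NULL)
}

#' Mean and variance traces of mitosis-synchronized cohorts
#'
#' Bins founders by their ratio at the first mitosis (T = 0) into `n_bins`
#' quantile bins; every bin's trace pools the founder and all progeny of its
#' member families, giving the per-time mean and variance of the bin.
#'
#' @param sync_traces output of [synchronize_to_mitosis()].
#' @param n_bins number of T=0 ratio bins (>= 2; default quartiles).
#' @return data.frame: bin, time_sync, mean, var, n.
#' @export
binned_cohort_traces <- function(sync_traces, n_bins = 4) {
  stopifnot(n_bins >= 2)
  at0 <- do.call(rbind, lapply(split(sync_traces, sync_traces$founder_id),
    function(d) {
      # the ratio at first mitosis is read from the founder's own track
      f <- d[d$cell_id == d$founder_id[1], , drop = FALSE]
      i <- which.min(abs(f$time_sync))
      data.frame(founder_id = d$founder_id[1], r0 = f$ratio[i])
    }))
  if (length(unique(at0$r0)) == 1) {
    bins <- stats::setNames(rep(1L, nrow(at0)), at0$founder_id)
  } else {
    br <- unique(stats::quantile(at0$r0, probs = seq(0, 1, length.out = n_bins + 1)))
    bins <- stats::setNames(
      as.integer(cut(at0$r0, breaks = br, include.lowest = TRUE)),
      at0$founder_id)
  }
  sync_traces$bin <- bins[as.character(sync_traces$founder_id)]
  agg <- stats::aggregate(ratio ~ bin + time_sync, data = sync_traces,
                          FUN = function(v) c(mean(v), stats::var(v), length(v)))
  data.frame(bin = agg$bin, time_sync = agg$time_sync,
             mean = agg$ratio[, 1], var = agg$ratio[, 2], n = agg$ratio[, 3])
}

#' Return-to-mean kinetics of sorted subpopulations
#'
#' For a sorted (e.g. FACS-isolated high- or low-glucose) subpopulation
#' followed over days, computes the population median distance from a global
#' reference at each sampling time and fits an exponential convergence
#' `|median - reference| = d0 * exp(-t / tau)`.
#'
#' @param traces long data.frame: cell_id, time_h, ratio.
#' @param reference global population reference value (ratio units).
#' @param sample_interval_h spacing of the sampling grid (default daily).
#' @param tol relative tolerance on non-monotone convergence before the rate
#'   is flagged unreliable.
#' @return list(distances = data.frame(time_h, median, distance), rate,
#'   tau_h, flagged).
#' @export
return_to_mean <- function(traces, reference, sample_interval_h = 24,
                           tol = 0.25) {
  tt <- seq(min(traces$time_h), max(traces$time_h), by = sample_interval_h)
  if (length(tt) < 2) stop("need at least 2 sampling times")
  med <- vapply(tt, function(t0) {
    keep <- abs(traces$time_h - t0) <= sample_interval_h / 2
    stats::median(traces$ratio[keep])
  }, numeric(1))
  dist <- med - reference
  absd <- abs(dist)
  up_moves <- diff(absd) > tol * max(absd)
  flagged <- any(up_moves)
  fit <- try(minpack.lm::nlsLM(absd ~ d0 * exp(-tt / tau),
                               start = list(d0 = max(absd),
                                            tau = diff(range(tt)) / 2),
                               lower = c(0, 1e-6)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    rate <- NA_real_; tau <- NA_real_; flagged <- TRUE
  } else {
    tau <- unname(stats::coef(fit)["tau"]); rate <- 1 / tau
  }
  list(distances = data.frame(time_h = tt, median = med, distance = dist),
       rate = rate, tau_h = tau, flagged = flagged)
}
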