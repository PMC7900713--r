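lineage_sim <- function(rho, n = 60, seed = 1, ...) {
  sc <- scenario_config(n_cells = n, duration = 3000, frame_interval = 5,
                        heritability_rho = rho, division_rate = 1 / 18,
                        noise_sd = 0.02, seed = seed)
  simulate_lineage_cohort(sc, ...)
}

test_that("synchronization puts every first mitosis at T = 0 and keeps all samples", {
  sim <- lineage_sim(0.8, n = 30)
  sync <- synchronize_to_mitosis(sim$traces, sim$lineage)
  # every founder's division lands exactly at time_sync 0
  founders <- unique(sync$founder_id)
  div_t <- vapply(founders, function(f) {
    d <- sync[sync$cell_id == f, ]
    max(d$time_sync)
  }, numeric(1))
  expect_true(all(abs(div_t) < 1e-9))
  # sample-count conservation over synchronizable families
  fmap <- glucoscope:::founder_map(sim$lineage)
  divided <- sim$lineage$cell_id[is.na(sim$lineage$parent_id) &
                                 sim$lineage$divided]
  expect_equal(nrow(sync),
               sum(fmap[as.character(sim$traces$cell_id)] %in% divided))
  # founder dividing at raw time t maps T=0 to t
  f1 <- founders[1]
  raw_div <- sim$lineage$death_time[sim$lineage$cell_id == f1]
  d <- sync[sync$founder_id == f1, ]
  expect_equal(unique(d$time - d$time_sync), raw_div)
})

test_that("a cohort without divisions synchronizes to nothing, with a warning", {
  sc <- scenario_config(n_cells = 5, duration = 300, frame_interval = 5,
                        division_rate = 0, noise_sd = 0, seed = 2)
  sim <- simulate_lineage_cohort(sc)
  expect_warning(out <- synchronize_to_mitosis(sim$traces, sim$lineage),
                 "no founder divided")
  expect_equal(nrow(out), 0)
})

test_that("deterministic inheritance gives generation correlations of 1", {
  sc0 <- scenario_config(n_cells = 25, duration = 3000, frame_interval = 5,
                         heritability_rho = 1, division_rate = 1 / 18,
                         noise_sd = 0, seed = 3)
  sim <- simulate_lineage_cohort(sc0, ou_sd = 0)
  gcor <- generation_correlation(sim$traces, sim$lineage)
  expect_equal(gcor$r, c(1, 1), tolerance = 1e-9)
})

test_that("AR(1) inheritance is recovered: r_pd ~ rho and r_gg ~ rho^2", {
  sim <- lineage_sim(0.8, n = 170)
  gcor <- generation_correlation(sim$traces, sim$lineage)
  expect_gte(gcor$n_pairs[1], 500)
  expect_lt(abs(gcor$r[1] - 0.8), 0.05)
  expect_lt(abs(gcor$r[2] - 0.64), 0.07)
  # the correlation declines across generations
  expect_lt(gcor$r[2], gcor$r[1])
})

test_that("r_gg tracks r_pd^2 across heritability levels", {
  for (rho in c(0.5, 0.8)) {
    gcor <- generation_correlation(lineage_sim(rho, n = 120,
                                               seed = 8)$traces,
                                   lineage_sim(rho, n = 120,
                                               seed = 8)$lineage)
    expect_lt(abs(gcor$r[2] - gcor$r[1]^2), 0.08)
  }
})

test_that("low-n comparisons are flagged", {
  # two founders, one division each: 4 parent-daughter pairs, 0 gg pairs
  lin <- data.frame(cell_id = 1:6,
                    parent_id = c(NA, NA, 1, 1, 2, 2),
                    generation = c(1, 1, 2, 2, 2, 2),
                    birth_time = c(0, 0, 100, 100, 100, 100),
                    death_time = c(100, 100, 300, 300, 300, 300),
                    divided = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  tr <- do.call(rbind, lapply(1:6, function(i)
    data.frame(cell_id = i, time = seq(0, 95, 5) + lin$birth_time[i],
               ratio = 1.5 + 0.1 * i)))
  gcor <- generation_correlation(tr, lin)
  expect_true(all(gcor$low_n))
})

test_that("binned cohort traces are flat for heritable cohorts and merge under rho = 0", {
  sim <- lineage_sim(0.95, n = 80, seed = 10, ou_sd = 0.02)
  sync <- synchronize_to_mitosis(sim$traces, sim$lineage)
  bins <- binned_cohort_traces(sync, n_bins = 4)
  # broadly flat: each bin's total drift over the window stays well below the
  # between-bin separation at T = 0
  at0 <- vapply(split(bins[abs(bins$time_sync) < 5, ],
                      bins$bin[abs(bins$time_sync) < 5]),
                function(d) mean(d$mean), numeric(1))
  spread0 <- diff(range(at0))
  for (b in unique(bins$bin)) {
    d <- bins[bins$bin == b & bins$time_sync >= 0, ]
    if (nrow(d) < 20) next
    slope <- coef(lm(mean ~ time_sync, d))[2]
    drift <- abs(slope) * diff(range(d$time_sync))
    expect_lt(drift, 0.25 * spread0)
  }
  # rho = 0: the pre-division bin separation has regressed to the grand mean
  # well before T = +20 h
  sim0 <- lineage_sim(0, n = 80, seed = 11)
  sync0 <- synchronize_to_mitosis(sim0$traces, sim0$lineage)
  bins0 <- binned_cohort_traces(sync0, n_bins = 4)
  grand <- mean(sim0$traces$ratio)
  pre <- bins0[bins0$time_sync >= -200 & bins0$time_sync < 0, ]
  late <- bins0[bins0$time_sync >= 1200, ]
  spread_pre <- vapply(split(pre, pre$bin),
                       function(d) mean(d$mean) - grand, numeric(1))
  spread_late <- vapply(split(late, late$bin),
                        function(d) mean(d$mean) - grand, numeric(1))
  expect_lt(max(abs(spread_late)), max(abs(spread_pre)) / 2)
})

test_that("all-identical cells fall into a single bin with the common trace", {
  tr <- do.call(rbind, lapply(1:10, function(i)
    data.frame(cell_id = i, parent_id = NA, frame = 1:20,
               time = seq(0, 95, 5), ratio = 1.5)))
  lin <- data.frame(cell_id = 1:10, parent_id = NA, generation = 1,
                    birth_time = 0, death_time = 50, divided = TRUE,
                    state = 0, baseline_ratio = 1.5)
  sync <- synchronize_to_mitosis(tr, lin)
  bins <- binned_cohort_traces(sync, n_bins = 4)
  expect_equal(length(unique(bins$bin)), 1)
  expect_true(all(bins$mean == 1.5))
})

test_that("return-to-mean recovers the OU relaxation time and rate ordering", {
  pop <- simulate_sorted_cohort(n_cells = 300, start_offset = 0.5,
                                tau_days = 2, duration_days = 10,
                                sample_interval_h = 6, seed = 12)
  rt <- return_to_mean(pop, reference = 1.8)
  expect_lt(abs(rt$tau_h - 48) / 48, 0.25)
  # a subpopulation starting at the mean stays at distance ~0
  at_mean <- simulate_sorted_cohort(n_cells = 300, start_offset = 0,
                                    seed = 13)
  rt0 <- return_to_mean(at_mean, reference = 1.8)
  expect_true(all(abs(rt0$distances$distance) < 0.02))
  # asymmetric relaxation: the faster subpopulation is detected as faster
  fast <- simulate_sorted_cohort(n_cells = 300, start_offset = 0.5,
                                 tau_days = 1, seed = 14)
  slow <- simulate_sorted_cohort(n_cells = 300, start_offset = -0.5,
                                 tau_days = 3, seed = 15)
  expect_lt(return_to_mean(fast, 1.8)$tau_h,
            return_to_mean(slow, 1.8)$tau_h)
})
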