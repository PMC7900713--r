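washout_config <- function(n_cells = 5, noise_sd = 0, seed = 1) {
  scenario_config(n_cells = n_cells, duration = 70, frame_interval = 0.5,
                  glucose_schedule = data.frame(time = c(0, 10, 40),
                                                glucose_mM = c(25, 0, 25)),
                  noise_sd = noise_sd, seed = seed)
}

test_that("scenario_config validates its invariants", {
  expect_error(scenario_config(state_mix = c(high = 0.6, low = 0.5)),
               "sum to 1")
  expect_error(scenario_config(frame_interval = 0), "frame_interval")
  expect_error(scenario_config(heritability_rho = 1.2), "heritability_rho")
  expect_error(scenario_config(
    glucose_schedule = data.frame(time = c(0, 90), glucose_mM = c(25, 0)),
    duration = 70), "within")
  expect_error(scenario_config(
    glucose_schedule = data.frame(time = c(10, 0), glucose_mM = c(25, 0))),
    "sorted|start at time 0")
})

test_that("trace with no substrate sits at the sensor floor", {
  sc <- scenario_config(duration = 20, frame_interval = 0.5,
                        glucose_schedule = data.frame(time = 0, glucose_mM = 0),
                        noise_sd = 0)
  m <- biosensor_model()
  tr <- simulate_cell_trace(sc, m, list(Vup = 0.1, Vcon = 0.2, G0 = 0))
  expect_equal(tr$ratio, rep(m$R_min, nrow(tr)), tolerance = 1e-10)
  expect_equal(nrow(tr), 20 / 0.5 + 1)
})

test_that("pure consumption gives a strictly decreasing signal", {
  sc <- scenario_config(duration = 30, frame_interval = 0.5,
                        glucose_schedule = data.frame(time = 0, glucose_mM = 0),
                        noise_sd = 0)
  tr <- simulate_cell_trace(sc, biosensor_model(),
                            list(Vup = 0, Vcon = 0.3, G0 = 1))
  expect_true(all(diff(tr$G) < 0))
  expect_true(all(diff(tr$ratio) < 0))
})

test_that("negative rates are rejected", {
  sc <- washout_config()
  expect_error(simulate_cell_trace(sc, biosensor_model(),
                                   list(Vup = -0.1, Vcon = 0.2, G0 = 1)),
               "non-negative")
})

test_that("generated trace matches an independent fixed-step RK4 integration", {
  sc <- washout_config(noise_sd = 0)
  m <- biosensor_model()
  cell <- list(Vup = 0.05, Vcon = 0.4, G0 = 0.8)
  tr <- simulate_cell_trace(sc, m, cell)
  G_oracle <- oracle_rk4_trace(cell, sc$glucose_schedule, tr$time)
  expect_equal(tr$G, G_oracle, tolerance = 1e-6)
})

test_that("simulators are deterministic in config+seed and vary with seed", {
  a <- simulate_washout_cohort(washout_config(noise_sd = 0.02, seed = 3))
  b <- simulate_washout_cohort(washout_config(noise_sd = 0.02, seed = 3))
  c <- simulate_washout_cohort(washout_config(noise_sd = 0.02, seed = 4))
  expect_identical(a, b)
  expect_false(identical(a$traces$ratio, c$traces$ratio))
})

test_that("perfect inheritance copies the parent baseline exactly", {
  sc <- scenario_config(n_cells = 10, duration = 1500, frame_interval = 5,
                        heritability_rho = 1, division_rate = 1 / 12,
                        noise_sd = 0, seed = 2)
  sim <- simulate_lineage_cohort(sc, ou_sd = 0)
  kids <- sim$lineage[!is.na(sim$lineage$parent_id), ]
  expect_gt(nrow(kids), 0)
  par_base <- sim$lineage$baseline_ratio[match(kids$parent_id,
                                               sim$lineage$cell_id)]
  expect_equal(kids$baseline_ratio, par_base)
})

test_that("zero heritability gives parent-daughter correlation compatible with 0", {
  sc <- scenario_config(n_cells = 120, duration = 2200, frame_interval = 5,
                        heritability_rho = 0, division_rate = 1 / 15,
                        noise_sd = 0.02, seed = 5)
  sim <- simulate_lineage_cohort(sc)
  gcor <- generation_correlation(sim$traces, sim$lineage)
  n <- gcor$n_pairs[1]
  expect_gte(n, 500)
  # 95% CI of r under the null, allowing for sibling clustering (~2x variance)
  expect_lt(abs(gcor$r[1]), 1.96 * sqrt(2) / sqrt(n))
})

test_that("no divisions means full-length tracks and an edgeless tree", {
  sc <- scenario_config(n_cells = 8, duration = 500, frame_interval = 5,
                        division_rate = 0, noise_sd = 0, seed = 1)
  sim <- simulate_lineage_cohort(sc)
  expect_true(all(is.na(sim$lineage$parent_id)))
  spans <- tapply(sim$traces$time, sim$traces$cell_id,
                  function(t) max(t) - min(t))
  expect_true(all(spans == 500))
})

test_that("child generation is parent generation + 1 and the tree is acyclic", {
  sc <- scenario_config(n_cells = 20, duration = 2000, frame_interval = 5,
                        heritability_rho = 0.5, division_rate = 1 / 12,
                        noise_sd = 0.01, seed = 7)
  lin <- simulate_lineage_cohort(sc)$lineage
  kids <- lin[!is.na(lin$parent_id), ]
  pg <- lin$generation[match(kids$parent_id, lin$cell_id)]
  expect_equal(kids$generation, pg + 1L)
  # every child has exactly one parent and ids only reference earlier cells
  expect_true(all(kids$parent_id < kids$cell_id))
})

test_that("tcspc histograms follow the decay law and photon budget", {
  n <- 128; bw <- 12.5 / 128
  delta <- c(1, rep(0, n - 1))
  h <- simulate_tcspc(tau = c(2, 5), amps = c(1, 0), irf = delta,
                      photons = 1e4, bin_width_ns = bw, noise = FALSE)
  t <- (seq_len(n) - 0.5) * bw
  expected <- exp(-t / 2); expected <- expected / sum(expected) * 1e4
  expect_equal(h, expected, tolerance = 1e-10)
  tot <- sum(simulate_tcspc(photons = 1e4, seed = 11))
  expect_lt(abs(tot - 1e4), 3 * sqrt(1e4))
  expect_error(simulate_tcspc(bin_width_ns = 0), "bin_width")
})

test_that("simulated MIDs match binomial closed forms", {
  expect_equal(simulate_mid(3, p = 0, q = 0, seed = 1)$mid, c(1, 0, 0, 0))
  q <- 0.0107
  m1 <- simulate_mid(3, p = 0, q = q, n_molecules = 4e5, seed = 2)$mid[2]
  expect_equal(m1, 3 * q * (1 - q)^2, tolerance = 0.02)
  frac <- 1 - simulate_mid(3, p = 0.5, q = 0, n_molecules = 4e5,
                           seed = 3)$mid[1]
  expect_equal(frac, 0.875, tolerance = 0.01)
})

test_that("image stacks survive the TIFF writer/reader", {
  set.seed(9)
  masks <- list(matrix(sample(0:300, 400, TRUE), 20, 20),
                matrix(sample(0:300, 400, TRUE), 20, 20))
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack_tiff(masks, f, type = "label")
  expect_identical(read_stack_tiff(f, type = "label"), masks)
  stack <- list(matrix(runif(400, 0, 3000), 20, 20))
  write_stack_tiff(stack, f)
  back <- read_stack_tiff(f)
  # float pages are stored as 32-bit fixed point scaled by 2^-16
  expect_lt(max(abs(back[[1]] - stack[[1]])), 65536 * 2^-31)
})
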