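two_disk_frame <- function() {
  img <- matrix(0, 60, 60)
  img[10:20, 10:20] <- 100
  img[40:50, 35:45] <- 150
  img
}

test_that("segmentation labels disjoint bright objects deterministically", {
  seg <- segment_cells(two_disk_frame(), min_area = 10)
  expect_equal(max(seg), 2)
  blank <- segment_cells(matrix(0, 30, 30))
  expect_equal(max(blank), 0)
})

test_that("segmentation recovers >= 95% of rendered cells at IoU >= 0.5", {
  set.seed(1)
  n <- 50; side <- ceiling(sqrt(n)); pitch <- 45
  tr <- data.frame(cell_id = 1:n, frame = 1, ratio = runif(n, 1.2, 2.6),
                   x = 25 + pitch * ((0:(n - 1)) %% side) + runif(n, -3, 3),
                   y = 25 + pitch * ((0:(n - 1)) %/% side) + runif(n, -3, 3))
  mv <- render_movie(tr, c(360, 360), cell_radius = 7, donor_levels = 1000,
                     poisson_noise = TRUE, seed = 2)
  seg <- segment_cells(mv$donor[[1]], min_area = 30)
  matched <- 0
  for (lab in seq_len(max(seg))) {
    px <- seg == lab
    best <- as.integer(names(which.max(table(mv$masks[[1]][px]))))
    if (best == 0) next
    truthpx <- mv$masks[[1]] == best
    if (sum(px & truthpx) / sum(px | truthpx) >= 0.5) matched <- matched + 1
  }
  expect_gte(matched / n, 0.95)
})

test_that("FRET measurement is exact on uniform cells and under background", {
  mask <- matrix(0L, 20, 20); mask[5:15, 5:15] <- 1L
  donor <- matrix(0, 20, 20); donor[mask == 1] <- 100
  acceptor <- matrix(0, 20, 20); acceptor[mask == 1] <- 200
  m <- measure_cell_fret(donor, acceptor, mask, background = "none")
  expect_equal(m$ratio, 2.0)
  m2 <- measure_cell_fret(donor + 10, acceptor + 10, mask,
                          background = c(10, 10))
  expect_equal(m2$ratio, 2.0)
  # modal background estimation finds the constant offset
  m3 <- measure_cell_fret(donor + 10, acceptor + 10, mask)
  expect_equal(m3$ratio, 2.0)
  # non-positive donor after background is flagged, not dropped
  m4 <- measure_cell_fret(donor * 0, acceptor, mask, background = c(5, 0))
  expect_true(m4$flagged)
  expect_true(is.na(m4$ratio))
  expect_equal(nrow(m4), 1)
})

test_that("ratio is invariant under simultaneous channel scaling", {
  set.seed(4)
  mask <- matrix(0L, 30, 30); mask[3:12, 3:12] <- 1L; mask[20:28, 15:25] <- 2L
  donor <- matrix(runif(900, 50, 150), 30, 30)
  acceptor <- matrix(runif(900, 100, 250), 30, 30)
  m1 <- measure_cell_fret(donor, acceptor, mask, background = "none")
  m2 <- measure_cell_fret(donor * 3.7, acceptor * 3.7, mask,
                          background = "none")
  expect_equal(m1$ratio, m2$ratio)
})

test_that("noise-free render round-trips ratios to machine precision, noisy within 3 SE", {
  set.seed(5)
  n <- 20
  tr <- data.frame(cell_id = 1:n, frame = 1, ratio = runif(n, 1.2, 2.5),
                   x = 20 + 40 * ((0:(n - 1)) %% 5),
                   y = 20 + 40 * ((0:(n - 1)) %/% 5))
  mv <- render_movie(tr, c(200, 220), cell_radius = 6, donor_levels = 1000)
  m <- measure_cell_fret(mv$donor[[1]], mv$acceptor[[1]], mv$masks[[1]],
                         background = "none")
  m <- m[order(m$label), ]
  expect_equal(m$ratio, tr$ratio, tolerance = 1e-12)
  mvp <- render_movie(tr, c(200, 220), cell_radius = 6, donor_levels = 1000,
                      poisson_noise = TRUE, seed = 6)
  mp <- measure_cell_fret(mvp$donor[[1]], mvp$acceptor[[1]], mvp$masks[[1]],
                          background = "none")
  mp <- mp[order(mp$label), ]
  se <- oracle_ratio_se(1000, tr$ratio, mp$n_px)
  expect_true(all(abs(mp$ratio - tr$ratio) < 3 * se))
})

test_that("empty trace set renders to all-zero stacks and masks", {
  mv <- render_movie(data.frame(cell_id = integer(0), frame = integer(0),
                                ratio = numeric(0), x = numeric(0),
                                y = numeric(0)), c(40, 40))
  expect_true(all(mv$donor[[1]] == 0))
  expect_true(all(mv$masks[[1]] == 0))
})

test_that("tracking follows cells, detects a division, and links accurately", {
  # single stationary cell
  tr <- data.frame(cell_id = 1, frame = rep(1:10, each = 1), ratio = 2,
                   x = 25, y = 25)
  mv <- render_movie(tr, c(50, 50), cell_radius = 4)
  t1 <- track_cells(mv$masks)
  expect_equal(length(unique(t1$cell_id)), 1)
  expect_equal(nrow(t1), 10)
  # division into two separating daughters
  div <- rbind(
    data.frame(cell_id = 1, frame = 1:5, ratio = 2, x = 50, y = 50),
    data.frame(cell_id = 2, frame = 6:10, ratio = 2, x = 50 - 2 * (1:5), y = 50),
    data.frame(cell_id = 3, frame = 6:10, ratio = 2, x = 50 + 2 * (1:5), y = 50))
  t2 <- track_cells(render_movie(div, c(100, 100), cell_radius = 4)$masks)
  kids <- unique(t2[!is.na(t2$parent_id), c("cell_id", "parent_id")])
  expect_equal(nrow(kids), 2)
  expect_equal(unique(kids$parent_id), unique(t2$cell_id[t2$frame == 1]))
})

test_that("tracking links >= 98% of frames correctly on a 50-cell movie", {
  set.seed(8)
  n <- 50; side <- 8; pitch <- 44; nf <- 15
  base <- data.frame(x = 25 + pitch * ((0:(n - 1)) %% side),
                     y = 25 + pitch * ((0:(n - 1)) %/% side))
  tr <- do.call(rbind, lapply(1:nf, function(f) data.frame(
    cell_id = 1:n, frame = f, ratio = 2,
    x = base$x + cumsum(rep(0, n)) + runif(n, -2, 2) * f / nf * 2,
    y = base$y + runif(n, -2, 2) * f / nf * 2)))
  mv <- render_movie(tr, c(380, 340), cell_radius = 6)
  tk <- track_cells(mv$masks, max_dist = 10)
  # correctness: every track should stay on one true label throughout
  per_track <- split(tk$label, tk$cell_id)
  consistent <- vapply(per_track, function(l) length(unique(l)) == 1,
                       logical(1))
  frames_ok <- sum(vapply(per_track[consistent], length, integer(1)))
  expect_gte(frames_ok / nrow(tr), 0.98)
})

test_that("quartile state calls match their definition and recover a bimodal mix", {
  cs <- classify_state(1:8)
  expect_equal(cs$label[7:8], c("high", "high"))
  expect_equal(cs$label[1:2], c("low", "low"))
  expect_equal(sum(cs$label == "mid"), 4)
  expect_warning(cs2 <- classify_state(rep(2, 10)), "identical")
  expect_true(all(cs2$label == "mid"))
  set.seed(10)
  n <- 200
  high <- rbinom(n, 1, 0.25) == 1
  ratios <- ifelse(high, rnorm(n, 2.4, 0.08), rnorm(n, 1.6, 0.15))
  calls <- classify_state(ratios)
  called_high <- calls$label == "high"
  jac <- sum(called_high & high) / sum(called_high | high)
  expect_gte(jac, 0.8)
})

test_that("KS comparison matches the brute-force ECDF sup-distance", {
  expect_equal(compare_distributions(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(compare_distributions(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(compare_distributions(c(0, 0, 0), c(1, 1, 1))$D, 1)
  expect_error(compare_distributions(numeric(0), 1:3), "n >= 2")
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(sample(10:80, 1)); b <- rnorm(sample(10:80, 1), sd = 2)
    expect_equal(compare_distributions(a, b)$D, oracle_ks_distance(a, b),
                 tolerance = 1e-12)
  }
})

test_that("KS test power matches a direct Monte-Carlo oracle within 3%", {
  set.seed(12)
  nsim <- 600; n <- 100
  crit <- 1.358 * sqrt(2 / n)  # asymptotic 5% critical value for D
  rej_impl <- rej_oracle <- logical(nsim)
  for (i in seq_len(nsim)) {
    a <- rnorm(n); b <- rnorm(n, mean = 1)
    rej_impl[i] <- compare_distributions(a, b)$p_value < 0.05
    rej_oracle[i] <- oracle_ks_distance(a, b) > crit
  }
  expect_lt(abs(mean(rej_impl) - mean(rej_oracle)), 0.03)
})
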