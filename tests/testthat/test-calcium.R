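test_that("behavior-to-frame alignment preserves polynomial headings", {
  t_hi <- seq(0.005, 60, 0.005)
  ramp <- structure(list(t = t_hi, heading = NA,
                         heading_unwrapped = 0.5 * t_hi,  # 0.5 rad/s
                         v_rot = rep(0.5 * 180 / pi, length(t_hi)),
                         v_fwd = rep(3, length(t_hi)), dt = 0.005),
                    class = "behavior_trace")
  frames <- seq(0.2, 59.8, by = 1 / 11.4)
  fb <- align_behavior_to_frames(ramp, frames)
  inner <- seq(10, length(frames) - 10)
  expect_equal(fb$v_rot[inner], rep(0.5 * 180 / pi, length(inner)),
               tolerance = 1e-6)
  const <- ramp; const$heading_unwrapped <- rep(1, length(t_hi))
  fc <- align_behavior_to_frames(const, frames)
  expect_equal(max(abs(fc$v_rot)), 0, tolerance = 1e-9)
  expect_error(align_behavior_to_frames(ramp, c(-1, 2)), "outside")
})

test_that("dF/F uses the lowest-decile baseline", {
  raw <- matrix(5, nrow = 100, ncol = 2)
  d0 <- compute_dff(raw, t = 1:100, smooth = FALSE)
  expect_true(all(d0$dff == 0))
  raw2 <- raw; raw2[50, 1] <- 10
  d2 <- compute_dff(raw2, t = 1:100, smooth = FALSE)
  expect_equal(d2$dff[50, 1] + 1, 2, tolerance = 1e-12)  # ratio 2 pre-smoothing
  expect_equal(d2$f0, c(5, 5), ignore_attr = TRUE)
  expect_error(compute_dff(matrix(0, 10, 1), t = 1:10), "baseline")
  expect_error(compute_dff(matrix(-1, 10, 1), t = 1:10), "non-negative")
})

test_that("PVA matches the complex-sum oracle and its boundary cases", {
  ang <- (seq_len(16) - 0.5) * 2 * pi / 16
  u <- pva(rep(1, 16), ang)
  expect_lt(u$strength, 1e-12)
  single <- rep(0, 16); single[4] <- 3
  s <- pva(single, ang)
  expect_equal(s$angle, ang[4], tolerance = 1e-12)
  expect_equal(s$strength, 1, tolerance = 1e-12)
  set.seed(21)
  w <- matrix(runif(16 * 5), nrow = 5)
  got <- pva(w, ang)
  for (f in 1:5) {
    z <- sum(w[f, ] * exp(1i * ang))
    expect_equal(got$angle[f], Arg(z), tolerance = 1e-12)
    expect_equal(got$strength[f], Mod(z) / sum(w[f, ]), tolerance = 1e-12)
  }
  na_out <- pva(rep(0, 16), ang)
  expect_true(is.na(na_out$angle) && is.na(na_out$strength))
})

test_that("PVA strength never increases when uniform mass is added", {
  ang <- (seq_len(16) - 0.5) * 2 * pi / 16
  set.seed(31)
  for (i in 1:25) {
    w <- runif(16)
    s0 <- pva(w, ang)$strength
    s1 <- pva(w + runif(1, 0.1, 2), ang)$strength
    expect_lte(s1, s0 + 1e-12)
  }
})

test_that("bump metrics recover analytic widths", {
  ang <- (seq_len(16) - 0.5) * 2 * pi / 16
  kappa <- 3
  prof <- exp(kappa * (cos(ang - ang[8]) - 1))
  bm <- bump_metrics(prof, ang)
  fwhm_true <- 2 * acos(1 - log(2) / kappa) * 180 / pi
  expect_equal(bm$fwhm, fwhm_true, tolerance = 22.5)  # one sector width
  hat <- rep(0, 16); hat[7:8] <- 1
  bh <- bump_metrics(hat, ang)
  expect_equal(bh$fwhm, 2 * 22.5, tolerance = 22.5 / 2)
  expect_true(bump_metrics(rep(2, 16), ang)$flat)
})

test_that("indicator convolution has unit DC gain and the analytic peak time", {
  dt <- 0.01
  imp <- c(1 / dt, rep(0, 599))
  resp <- convolve_velocity(imp, dt)
  t_peak_true <- log(0.63 / 0.13) * (0.13 * 0.63) / (0.63 - 0.13)
  expect_equal((which.max(resp) - 1) * dt, t_peak_true, tolerance = dt)
  const <- convolve_velocity(rep(2.5, 800), dt)
  expect_equal(const[length(const)], 2.5, tolerance = 0.01)
  expect_true(all(convolve_velocity(rep(0, 100), dt) == 0))
})

test_that("noduli difference correlates with convolved velocity and flips with sides", {
  tr <- generate_ou_track(ou_params(duration = 1000, seed = 14))
  b <- generate_behavior(tr, seed = 15)
  nod <- generate_roi_series(recording_truth(noise_sd = 0), b, "noduli",
                             seed = 16)
  d <- compute_dff(nod)
  nb <- nod$frame_behavior
  R <- noduli_difference_correlation(d$dff[, 1], d$dff[, 2], nb$v_rot, nb$dt)
  expect_gt(abs(R), 0.9)
  expect_equal(noduli_difference_correlation(d$dff[, 2], d$dff[, 1],
                                             nb$v_rot, nb$dt), -R,
               tolerance = 1e-12)
  set.seed(17)
  Rs <- noduli_difference_correlation(d$dff[, 1], d$dff[, 2],
                                      sample(nb$v_rot), nb$dt)
  expect_lt(abs(Rs), 0.1)
})

test_that("noduli regression finds the driving predictor and its latency", {
  set.seed(18)
  n <- 20000; dt <- 0.025
  v <- as.numeric(arima.sim(list(ar = exp(-dt / 0.12)), n)) * 30
  v_fwd <- abs(rnorm(n, 5, 2))
  k <- 4  # 100 ms at 25 ms bins
  drive <- pmax(-v, 0)
  dff <- c(rep(0, k), drive[seq_len(n - k)]) / 50 + rnorm(n, 0, 0.05)
  reg <- noduli_regression(dff, v, v_fwd, dt)
  peak <- reg[which.max(reg$cw), ]
  expect_equal(peak$shift, 0.100, tolerance = 0.026)
  expect_gt(peak$cw, 3 * max(abs(reg$fwd)))
  pure <- noduli_regression(rnorm(n, 0, 0.05), v, v_fwd, dt)
  expect_lt(max(abs(pure[, c("ccw", "cw", "fwd")])), 0.01)
})

test_that("ring registration is exact on constructed shifts", {
  ang <- (seq_len(16) - 0.5) * 2 * pi / 16
  template <- exp(2 * (cos(ang - ang[8]) - 1))
  n <- 24
  shifts <- sample(0:15, n, replace = TRUE)
  frames <- t(vapply(shifts, function(k) flyring:::.circ_shift(template, k),
                     numeric(16)))
  reg <- register_eb(frames, frames)
  expect_equal(reg, matrix(rep(template, n), nrow = n, byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
  # frames already peaked at 8 are untouched
  ready <- matrix(rep(template, 3), nrow = 3, byrow = TRUE)
  expect_equal(register_eb(ready, ready), ready, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("bridge registration puts the reference peak at glomerulus 14", {
  tr <- generate_ou_track(ou_params(duration = 200, seed = 19))
  b <- generate_behavior(tr, seed = 20)
  truth <- recording_truth(noise_sd = 0.02)
  epg <- generate_roi_series(truth, b, "EPG", geometry = "PB18", seed = 21)
  pen <- generate_roi_series(truth, b, "PEN", geometry = "PB18", seed = 22)
  de <- compute_dff(epg); dp <- compute_dff(pen)
  reg_e <- register_bridge(de$dff, de$dff, "EPG")
  reg_p <- register_bridge(dp$dff, de$dff, "PEN")
  mean_prof <- colMeans(reg_e[, 10:17])
  expect_identical(which.max(mean_prof) + 9L, 14L)
  # registration only permutes ROIs within rings: totals preserved
  expect_equal(rowSums(reg_p[, c(1:8, 11:18)]),
               rowSums(dp$dff[, c(1:8, 11:18)]), tolerance = 1e-12)
})

test_that("turn detection matches a brute-force scan", {
  t <- seq(0.02, 60, 0.02)
  const <- rep(30, length(t))
  tc <- detect_turns(const, t)
  expect_identical(nrow(tc), 1L)
  expect_identical(c(tc$start, tc$end), c(1L, length(t)))
  sq <- rep(c(rep(0, 100), rep(40, 50)), 20)
  ts <- seq_along(sq) * 0.02
  expect_identical(nrow(detect_turns(sq, ts)), 20L)
  tr <- generate_ou_track(ou_params(duration = 100, seed = 23))
  got <- detect_turns(tr$v, tr$t)
  above <- abs(tr$v) > 15   # oracle scan
  expect_identical(nrow(got), sum(diff(c(FALSE, above)) == 1))
  for (i in seq_len(nrow(got)))
    expect_true(all(above[got$start[i]:got$end[i]]))
})

test_that("turn PVA analysis recovers slope and the analytic R^2 under noise", {
  tr <- generate_ou_track(ou_params(duration = 600, seed = 24))
  heading <- integrated_heading(tr)
  turns <- detect_turns(tr$v, tr$t)
  strength <- rep(0.5, length(heading))
  perfect <- turn_pva_analysis(turns, atan2(sin(heading), cos(heading)),
                               strength, heading)
  expect_equal(perfect$slope, 1, tolerance = 1e-6)
  expect_equal(perfect$r_squared, 1, tolerance = 1e-6)
  set.seed(25)
  sigma <- 10 * pi / 180
  noisy_angle <- heading + rnorm(length(heading), 0, sigma)
  noisy <- turn_pva_analysis(turns, atan2(sin(noisy_angle), cos(noisy_angle)),
                             strength, heading)
  expect_equal(noisy$slope, 1, tolerance = 0.15)
  dh_var <- var(noisy$turns$delta_heading)
  r2_pred <- dh_var / (dh_var + 2 * (10)^2)
  expect_lt(abs(noisy$r_squared - r2_pred), 0.12)
  # strength gating removes every turn
  expect_error(turn_pva_analysis(turns, heading, rep(0, length(heading)),
                                 heading),
               "retained")
})

test_that("bootstrap p values match exhaustive enumeration on tiny samples", {
  a <- c(1.0, 2.0, 3.5); bb <- c(2.5, 4.0, 5.0)
  got <- bootstrap_mean_diff(a, bb, n_reps = 20000, seed = 1)
  pool <- c(a, bb)
  draws <- as.matrix(expand.grid(rep(list(seq_along(pool)), 3)))
  means <- rowMeans(matrix(pool[draws], nrow = nrow(draws)))
  diffs <- outer(means, means, "-")   # all (a-draw, b-draw) pairs
  p_exact <- mean(abs(diffs) >= abs(mean(a) - mean(bb)))
  expect_equal(got$p_value, p_exact, tolerance = 0.02)
  same <- bootstrap_mean_diff(c(1, 2, 3), c(1, 2, 3), n_reps = 2000, seed = 2)
  expect_gt(same$p_value, 0.5)
  far <- bootstrap_mean_diff(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1),
                             n_reps = 10000, seed = 3)
  expect_lte(far$p_value, 1e-4 + 1e-9)
})
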