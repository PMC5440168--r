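test_that("spike detection finds inserted waveforms with refractory lockout", {
  fs <- 10000
  set.seed(41)
  v <- rnorm(fs * 30, 0, 0.05)
  wave <- 1.5 * sin(seq(0, pi, length.out = 21))  # 2 ms biphasic-ish bump
  at <- sort(sample(seq(1000, length(v) - 1000, by = 3000), 50))
  for (i in at) v[i:(i + 20)] <- v[i:(i + 20)] + wave
  st <- detect_spikes(v, fs, threshold = 0.6)
  expect_identical(length(st$spike_times), 50L)
  expect_s3_class(attr(st, "robustness"), "data.frame")

  quiet <- detect_spikes(rnorm(fs * 2, 0, 0.01), fs, threshold = 0.6)
  expect_identical(length(quiet$spike_times), 0L)

  # two spikes 1 ms apart collapse to one
  v2 <- rep(0, fs)
  v2[5000:5020] <- v2[5000:5020] + wave
  v2[5010:5030] <- v2[5010:5030] + wave
  got <- suppressWarnings(detect_spikes(v2, fs, threshold = 0.6))
  expect_identical(length(got$spike_times), 1L)
  expect_error(detect_spikes(v2, 1000, threshold = 1), "4 kHz")
})

test_that("rate smoothing conserves spike mass", {
  none <- spike_train(numeric(0), 100, source = "synthetic")
  expect_true(all(smooth_rate(none)$rate == 0))
  sp <- poisson_spikes(10, 300, seed = 42)
  sr <- smooth_rate(sp)
  expect_equal(mean(sr$rate), 10, tolerance = 0.5 / 10)
  expect_equal(sum(sr$rate) * 0.05, length(sp$spike_times),
               tolerance = 0.01)
})

test_that("sigmoid fit recovers noiseless parameters to 1%", {
  v <- rep(seq(-180, 180, by = 2), 40)
  rate <- 8 / (1 + exp(-0.02 * (v + 0))) + 2
  fit <- fit_sigmoid_tuning(rate, v, dt = 0.05)
  expect_equal(fit$r_max, 8, tolerance = 0.01)
  expect_equal(fit$s, -0.02, tolerance = 0.01)
  expect_equal(fit$r_min, 2, tolerance = 0.01)
  expect_lt(abs(fit$inflexion), 2)  # binning shifts the centre slightly
  expect_gt(fit$r_squared, 0.999)
  expect_gt(fit$rate_modulation, 7)
  flat <- fit_sigmoid_tuning(rep(5, length(v)) + rnorm(length(v), 0, 1e-4),
                             v, dt = 0.05)
  expect_lt(flat$rate_modulation, 0.1)
})

test_that("compound von Mises fit localizes a single-component truth", {
  set.seed(43)
  th <- runif(40000, -pi, pi)
  rate <- 3 + 10 * exp(2 * (cos(th - 0.8) - 1)) + rnorm(40000, 0, 0.3)
  fit <- fit_vonmises_heading(rate, th)
  expect_lt(abs(atan2(sin(fit$theta01 - 0.8), cos(fit$theta01 - 0.8))) *
              180 / pi, 5)
  unif <- fit_vonmises_heading(rep(4, 40000) + rnorm(40000, 0, 0.05), th)
  mods <- abs(c(unif$g1, unif$g2))
  expect_lt(max(mods), 0.5)
})

test_that("heading index follows the Bessel-ratio law and its invariances", {
  centers <- seq(-pi, pi, length.out = 33)[-33] + pi / 32
  unif <- tuning_indices(rep(2, 32), centers)
  expect_lt(unif$H, 1e-12)
  one <- rep(0, 32); one[7] <- 4
  single <- tuning_indices(one, centers)
  expect_equal(single$H, 1, tolerance = 1e-12)
  expect_equal(single$preferred_heading, centers[7], tolerance = 1e-12)
  for (kappa in c(0.5, 2, 8)) {
    r <- exp(kappa * cos(centers - 1))
    H <- tuning_indices(r, centers)$H
    expect_equal(H, bessel_series(kappa, 1) / bessel_series(kappa, 0),
                 tolerance = 0.01)
  }
  # invariant under positive rescaling; reduced by a uniform pedestal
  set.seed(44)
  r <- runif(32)
  H0 <- tuning_indices(r, centers)$H
  expect_equal(tuning_indices(3.7 * r, centers)$H, H0, tolerance = 1e-12)
  expect_lt(tuning_indices(r + 1, centers)$H, H0)
})

test_that("shuffle nulls are deterministic and separate tuned from untuned cells", {
  tr <- generate_ou_track(ou_params(duration = 200, seed = 45))
  b <- generate_behavior(tr, seed = 46)
  tuned <- generate_conjunctive_spikes(conjunctive_truth(kappa_h = 4),
                                       b, seed = 47)
  n1 <- shuffle_null(tuned, b, n = 100, seed = 5)
  n2 <- shuffle_null(tuned, b, n = 100, seed = 5)
  expect_identical(n1$H_null, n2$H_null)
  expect_gt(n1$H, n1$H_95)
  untuned <- poisson_spikes(6, 200, seed = 48)
  n3 <- shuffle_null(untuned, b, n = 100, seed = 5)
  expect_lt(n3$H, 2 * n3$H_95)  # same order as its null
  expect_error(shuffle_null(poisson_spikes(5, 50, seed = 1), b), "100 fragments")
})

test_that("spike-triggered average recovers a constructed response lag", {
  dt <- 0.005
  t <- seq(dt, 400, dt)
  set.seed(49)
  v <- rep(0, length(t))
  centers <- seq(5, 395, by = 2.5)
  for (ct in centers) {
    idx <- which(abs(t - ct) < 0.3)
    v[idx] <- v[idx] + 80 * exp(-(t[idx] - ct)^2 / (2 * 0.05^2)) *
      sample(c(-1, 1), 1)
  }
  spikes <- spike_train(centers + 0.123, max(t), source = "synthetic")
  sta <- spike_triggered_average(v, t, spikes)
  expect_lt(abs(sta$peak_lag + 0.123), 2 * dt)
  # spikes unrelated to velocity give a flat STA
  rand <- poisson_spikes(2, 390, seed = 50)
  flatsta <- spike_triggered_average(v, t, rand)
  expect_lt(max(abs(flatsta$sta)), 0.5 * max(abs(sta$sta)))
  # no qualifying epochs
  expect_error(spike_triggered_average(rep(1, length(t)), t, spikes),
               "threshold")
})

test_that("GLM lag regression localizes constructed delays", {
  set.seed(51)
  dt <- 0.02
  v <- as.numeric(arima.sim(list(ar = exp(-dt / 0.12)), 30000)) * 40
  k <- round(0.130 / dt)
  resp <- c(rep(0, k), pmax(v, 0)[seq_len(length(v) - k)]) / 20 +
    rnorm(length(v), 0, 0.3)
  g <- glm_lag_regression(resp, v, dt)
  expect_lt(abs(g$lag - 0.13), 0.021)
  # velocity as its own response peaks at zero shift
  auto <- glm_lag_regression(v, v, dt)
  expect_lt(abs(auto$lag), 0.021)
  # unrelated response: no usable lag
  noise <- glm_lag_regression(rnorm(length(v)), v, dt)
  expect_lt(max(abs(noise$coefficients$ccw), na.rm = TRUE), 0.05)
  # Poisson branch converges on counts
  counts <- rpois(length(v), exp(0.5 + 0.3 * scale(pmax(v, 0))))
  gp <- glm_lag_regression(counts, v, dt, shifts = seq(-0.2, 0.2, 0.02),
                           family = "poisson")
  expect_true(all(gp$coefficients$converged))
  expect_lt(abs(gp$lag), 0.021)
})

test_that("2-D maps respect their occupancy masks", {
  set.seed(52)
  x <- runif(5000, -60, 60); y <- runif(5000, 0, 10)
  uni <- tuning_heatmap_2d(rep(3, 5000), x, y, seq(-60, 60, 12), seq(0, 10, 1),
                           min_samples = 5)
  expect_true(all(abs(uni$map[uni$counts >= 5] - 3) < 1e-12))
  # a cell visited 7 times is masked at the 8-bin heading-map threshold
  xx <- c(rep(5, 7), rep(30, 100)); yy <- c(rep(0.5, 7), rep(5.5, 100))
  m <- tuning_heatmap_2d(rep(1, 107), xx, yy, c(0, 10, 20, 40),
                         c(0, 1, 6), min_samples = 8)
  expect_true(is.na(m$map[1, 1]))
  expect_false(is.na(m$map[3, 2]))
})

test_that("conditional tuning separates multiplicative from additive cells", {
  tr <- generate_ou_track(ou_params(tau = 1.5, duration = 900, seed = 53))
  b <- generate_behavior(tr, seed = 54)
  dt <- 0.05
  tt <- seq(dt, 900, dt)
  vv <- approx(b$t, b$v_rot, tt, rule = 2)$y
  hh <- approx(b$t, b$heading_unwrapped, tt, rule = 2)$y
  sig_part <- 1 / (1 + exp(-0.08 * vv))
  vm_part <- exp(2 * (cos(hh) - 1))
  set.seed(55)
  mult <- 2 + 12 * sig_part * vm_part + rnorm(length(tt), 0, 0.4)
  addv <- 2 + 6 * sig_part + 6 * vm_part + rnorm(length(tt), 0, 0.4)

  fit_m <- fit_vonmises_heading(mult, hh, require_full = FALSE)
  cm <- conditional_tuning(mult, vv, hh, dt, fit_m)
  # modulation is f(-150) - f(150): negative for this CCW-preferring cell,
  # and larger in magnitude within the preferred heading quadrant
  expect_lt(cm$rotation_modulation["preferred"], 0)
  expect_gt(abs(cm$rotation_modulation["preferred"]),
            abs(cm$rotation_modulation["nonpreferred"]))
  expect_gt(abs(cm$rotation_modulation["nonpreferred"]), 0)
  fit_a <- fit_vonmises_heading(addv, hh, require_full = FALSE)
  ca <- conditional_tuning(addv, vv, hh, dt, fit_a)
  expect_equal(unname(ca$rotation_modulation["preferred"]),
               unname(ca$rotation_modulation["nonpreferred"]),
               tolerance = 0.35 * abs(ca$rotation_modulation["preferred"]))
  # preferred heading stable across turn directions
  d_pref <- atan2(sin(cm$ccw$theta01 - cm$cw$theta01),
                  cos(cm$ccw$theta01 - cm$cw$theta01)) * 180 / pi
  expect_lt(abs(d_pref), 10)
})

test_that("epoch selection demands wide velocity coverage of every heading", {
  t <- seq(0.02, 600, 0.02)
  still <- epoch_selector(rep(0, length(t)), rep(0.3, length(t)), t)
  expect_identical(nrow(still), 0L)
  set.seed(56)
  v <- runif(length(t), -200, 200)
  heading <- runif(length(t), -pi, pi)
  vigorous <- epoch_selector(v, heading, t)
  expect_identical(nrow(vigorous), 2L)  # both 5-minute windows qualify
  expect_true(all(vigorous$span >= 250))
  # bandwidth utility vs brute-force percentile oracle
  vv <- rnorm(5000, 0, 50)
  bw <- behavioral_bandwidth(vv)
  keep <- abs(vv)[abs(vv) >= 5]
  expect_equal(unname(bw["bandwidth"]),
               unname(diff(quantile(keep, c(0.1, 0.9)))), tolerance = 1e-9)
})
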