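test_that("von Mises profile is a normalized density with mode at the offset", {
  th <- seq(0, 2 * pi, length.out = 4001)[-4001]
  f <- von_mises_profile(th, 0, 12)
  expect_equal(sum(f) * (2 * pi / 4000), 1, tolerance = 1e-6)
  for (delta in c(0, 1.1, -2.4)) {
    g <- von_mises_profile(th, delta, 7)
    expect_equal(th[which.max(g)], delta %% (2 * pi), tolerance = 2 * pi / 4000)
  }
  # independent evaluation through the Bessel series
  expect_equal(von_mises_profile(0, 0, 12),
               exp(12) / (2 * pi * bessel_series(12, 0)),
               tolerance = 1e-10)
  expect_error(von_mises_profile(0, 0, -1), "kappa")
})

test_that("topology has 54 E-PG and 18 P-EN units with mirror kernels", {
  expect_identical(default_topo$N, 54L)
  expect_identical(ncol(default_topo$epg_angles) * 2L, 54L)
  expect_identical(ncol(default_topo$pen_angles) * 2L, 18L)
  expect_true(all(lengths(default_topo$glom_membership) == 3L))

  # kernel peaks are separated by 2 * delta_shift
  th <- seq(-pi, pi, length.out = 20001)
  kl <- von_mises_profile(th, 35 * pi / 180, 12)
  kr <- von_mises_profile(th, -35 * pi / 180, 12)
  sep <- (th[which.max(kl)] - th[which.max(kr)]) * 180 / pi
  expect_equal(sep, 70, tolerance = 0.05)

  # mirror symmetry of the weight matrices (reflect both grids) and the
  # circulant block structure
  row_refl <- c(3, 2, 1, 27:4)
  col_refl <- c(1, 9:2)
  expect_equal(max(abs(default_topo$W_pe_left -
                       default_topo$W_pe_right[row_refl, col_refl])), 0,
               tolerance = 1e-12)
  W <- default_topo$W_pe_left
  shifted <- W[c(4:27, 1:3), c(2:9, 1)]
  expect_equal(max(abs(W - shifted)), 0, tolerance = 1e-12)

  p0 <- circuit_params(delta_shift = 0)
  t0 <- build_topology(p0)
  expect_equal(t0$W_pe_left, t0$W_pe_right)
})

test_that("parameter validation rejects inconsistent settings", {
  expect_error(circuit_params(tau_E = -1), "time constants")
  expect_error(circuit_params(kappa = 0), "kappa")
  expect_error(circuit_params(efficacy = 1.5), "efficacy")
  expect_error(circuit_params(dt = 0.02), "dt")
})

test_that("single step from rest rises toward the bias-driven point and stays non-negative", {
  st <- circuit_state(E = rep(0, 54), P_left = rep(0, 9), P_right = rep(0, 9))
  for (i in 1:20) st <- step_circuit(st, 0, default_params, default_topo)
  expect_true(all(st$P_left > 0))
  expect_true(all(is.finite(st$E)), all(st$E >= 0))
  expect_error(step_circuit(st, NaN, default_params, default_topo), "finite")
})

test_that("R step and compiled integrator agree", {
  st <- seeded_bump_state(default_params)
  n_steps <- 40L  # one 20 ms input sample
  st_r <- st
  for (i in seq_len(n_steps))
    st_r <- step_circuit(st_r, 35, default_params, default_topo)
  sim <- simulate_circuit(default_params,
                          velocity_input(c(0.02, 0.04), c(35, 35)),
                          topology = default_topo, init = st, settle = 0)
  expect_equal(as.numeric(sim$E[1, ]), st_r$E, tolerance = 1e-10)
  expect_equal(as.numeric(sim$P_left[1, ]), st_r$P_left, tolerance = 1e-10)
})

test_that("mirror symmetry: reflecting the circuit and negating velocity commute with stepping", {
  # index of the unit at -theta on each grid
  refl_index <- function(ang) sapply(seq_along(ang), function(i)
    which.min(abs(atan2(sin(ang + ang[i]), cos(ang + ang[i])))))
  refl_e <- refl_index(default_topo$epg_angles["left", ])
  refl_p <- refl_index(default_topo$pen_angles["left", ])
  st <- seeded_bump_state(default_params, angle = 0.7)
  mirror <- function(s) circuit_state(
    E = c(s$E[seq_len(27)][refl_e], s$E[27 + seq_len(27)][refl_e]),
    P_left = s$P_right[refl_p], P_right = s$P_left[refl_p], t = s$t)
  a <- st; b <- mirror(st)
  for (i in 1:50) {
    a <- step_circuit(a, 40, default_params, default_topo)
    b <- step_circuit(b, -40, default_params, default_topo)
  }
  expect_equal(mirror(a)$E, b$E, tolerance = 1e-9)
  expect_equal(mirror(a)$P_left, b$P_left, tolerance = 1e-9)
})

test_that("halving the step reproduces a full step at second order (local error)", {
  st <- seeded_bump_state(default_params)
  for (i in 1:200) st <- step_circuit(st, 30, default_params, default_topo)
  local_err <- function(dt) {
    p1 <- default_params; p1$dt <- dt
    p2 <- default_params; p2$dt <- dt / 2
    one <- step_circuit(st, 30, p1, default_topo)
    two <- step_circuit(step_circuit(st, 30, p2, default_topo),
                        30, p2, default_topo)
    max(abs(one$E - two$E), abs(one$P_left - two$P_left))
  }
  e1 <- local_err(1e-3)
  e2 <- local_err(5e-4)
  expect_lt(e2, e1)              # converging
  expect_gt(e1 / e2, 2.5)        # ~4 expected for O(dt^2) local error
  expect_lt(e1 / e2, 6.5)
})

test_that("zero-velocity simulation settles into one stationary bump", {
  sim <- quick_sim(0, 5)
  ang <- bump_deg(sim)
  expect_lt(diff(range(ang[sim$t > 3])), 1)  # < 1 degree drift once settled
  prof <- colMeans(sim$E[sim$t > 4, 1:27])
  ext <- diff(sign(diff(c(prof[27], prof, prof[1]))))
  n_max <- sum(ext < 0 & prof > 0.1 * max(prof))
  expect_identical(n_max, 1L)
  expect_true(all(sim$E >= 0), all(sim$P_left >= 0), all(sim$P_right >= 0))
})

test_that("constant drive above threshold advances the bump monotonically", {
  sim <- quick_sim(35, 10)
  ang <- bump_deg(sim)
  late <- ang[sim$t > 1]
  expect_gt(late[length(late)] - late[1], 200)
  # monotone up to small numerical jitter
  expect_gt(mean(diff(late) > -0.5), 0.99)
})

test_that("the attractor is rotationally equivariant across glomeruli", {
  shift <- 2 * pi / 9
  sim0 <- simulate_circuit(default_params, constant_velocity_input(0, 3),
                           topology = default_topo,
                           init = seeded_bump_state(default_params, 0))
  sim1 <- simulate_circuit(default_params, constant_velocity_input(0, 3),
                           topology = default_topo,
                           init = seeded_bump_state(default_params, shift))
  d <- atan2(sin(atan2(sim1$bump_sin, sim1$bump_cos) -
                 atan2(sim0$bump_sin, sim0$bump_cos) - shift),
             cos(atan2(sim1$bump_sin, sim1$bump_cos) -
                 atan2(sim0$bump_sin, sim0$bump_cos) - shift))
  expect_lt(max(abs(d)) * 180 / pi, 0.5)
})

test_that("runaway parameterizations raise an instability error", {
  bad <- circuit_params(beta = 0, rate_ceiling = 1e3)  # no inhibition
  expect_error(quick_sim(0, 2, params = bad, topology = build_topology(bad)),
               "diverged")
})
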