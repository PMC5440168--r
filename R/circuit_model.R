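#' @useDynLib flyring, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Parameters of the E-PG / P-EN firing-rate model
#'
#' Bundles the constants of the recurrent loop between E-PG ("compass")
#' neurons and the left/right P-EN populations: membrane time constants,
#' excitatory gain, global inhibition, the von Mises connectivity kernel and
#' its angular offset, the constant drive to the P-EN units, and the synaptic
#' efficacy scaling used to emulate synaptic blockade.
#'
#' @param tau_E time constant of the E-PG units (s).
#' @param tau_P time constant of the P-EN units (s).
#' @param alpha excitatory gain (dimensionless).
#' @param beta global-inhibition gain (dimensionless).
#' @param kappa von Mises concentration of the connectivity kernels.
#' @param delta_shift angular offset of the shifted kernel component
#'   (degrees); sets the structural phase shift of the loop.
#' @param n_glomeruli_per_side protocerebral-bridge glomeruli per side.
#' @param n_epg_per_glom E-PG units per glomerulus.
#' @param bias constant positive drive to the P-EN units (model units).
#' @param efficacy scaling in \[0, 1\] applied to the P-EN to E-PG weights
#'   only; 1 is the intact circuit, 0 removes the feedback.
#' @param w_scale normalization of the P-EN to E-PG kernel weights
#'   (dimensionless).  Sets where the loop sits between no self-sustained
#'   bump (too small) and amplitude divergence (too large); the default was
#'   fixed once so the default circuit operates in its documented regime: a
#'   single stationary bump at rest with graded multi-glomerulus P-EN
#'   activity, near-linear velocity integration, and saturation near
#'   `delta_shift / (tau_E + tau_P)`.
#' @param velocity_gain conversion from degrees/s of angular velocity to
#'   model drive units.  The default was calibrated once (see
#'   [calibrate_velocity_gain()]) so that the low-velocity transfer slope of
#'   the default circuit is 1.
#' @param dt integration step (s); must satisfy `dt <= tau_P / 10`.
#' @param rate_ceiling firing-rate value treated as divergence.
#'
#' @return an object of class `circuit_params`.
#' @export
circuit_params <- function(tau_E = 0.080, tau_P = 0.065,
                           alpha = 10, beta = 25,
                           kappa = 12, delta_shift = 35,
                           n_glomeruli_per_side = 9L, n_epg_per_glom = 3L,
                           bias = 1, efficacy = 1,
                           w_scale = .default_w_scale,
                           velocity_gain = .default_velocity_gain,
                           dt = 5e-4, rate_ceiling = 1e6) {
  p <- list(tau_E = tau_E, tau_P = tau_P, alpha = alpha, beta = beta,
            kappa = kappa, delta_shift = delta_shift,
            n_glomeruli_per_side = as.integer(n_glomeruli_per_side),
            n_epg_per_glom = as.integer(n_epg_per_glom),
            bias = bias, efficacy = efficacy, w_scale = w_scale,
            velocity_gain = velocity_gain, dt = dt,
            rate_ceiling = rate_ceiling)
  class(p) <- "circuit_params"
  validate_circuit_params(p)
  p
}

# Kernel weight normalization fixing the loop's operating regime (see
# circuit_params), and the drive units per (deg/s) calibrated on the default
# circuit so that the bump-velocity transfer curve has slope 1 in its
# linear regime.
.default_w_scale <- 0.008
.default_velocity_gain <- 0.0073

validate_circuit_params <- function(p) {
  stopifnot(inherits(p, "circuit_params"))
  if (p$tau_E <= 0 || p$tau_P <= 0) stop("time constants must be positive")
  if (p$kappa <= 0) stop("kappa must be positive")
  if (p$efficacy < 0 || p$efficacy > 1) stop("efficacy must lie in [0, 1]")
  if (p$dt > p$tau_P / 10) stop("dt must not exceed tau_P / 10")
  if (p$n_glomeruli_per_side < 1 || p$n_epg_per_glom < 1)
    stop("unit counts must be positive")
  invisible(p)
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("E-PG/P-EN ring-attractor parameters\n")
  cat(sprintf("  tau_E %.0f ms, tau_P %.0f ms, alpha %g, beta %g\n",
              1e3 * x$tau_E, 1e3 * x$tau_P, x$alpha, x$beta))
  cat(sprintf("  kernel: kappa %g, offset %g deg; efficacy %g; bias %g\n",
              x$kappa, x$delta_shift, x$efficacy, x$bias))
  cat(sprintf("  %d glomeruli/side x %d E-PG each (N = %d); dt %.2g ms\n",
              x$n_glomeruli_per_side, x$n_epg_per_glom,
              2L * x$n_glomeruli_per_side * x$n_epg_per_glom, 1e3 * x$dt))
  invisible(x)
}

#' von Mises density on the circle
#'
#' `f(theta | delta, kappa) = exp(kappa cos(theta - delta)) / (2 pi I0(kappa))`,
#' the building block of the P-EN to E-PG connectivity kernels.  Evaluated
#' with exponential scaling so large concentrations do not overflow.
#'
#' @param theta angles (radians).
#' @param delta offset of the mode (radians).
#' @param kappa concentration (> 0).
#' @return density values, integrating to 1 over the circle.
#' @export
von_mises_profile <- function(theta, delta = 0, kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa <= 0)
    stop("kappa must be a positive scalar")
  exp(kappa * (cos(theta - delta) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Build the E-PG / P-EN connectivity
#'
#' Lays out 27 E-PG and 9 P-EN units per bridge side on uniform angular
#' grids over \[0, 2pi), with each glomerulus's three E-PG units centred on
#' their P-EN's angle, and evaluates the P-EN to E-PG weight matrices from
#' the two mirror-image von Mises kernels `Kl(theta) = f(theta | +delta,
#' kappa)` and `Kr(theta) = f(theta | -delta, kappa)`.  Each side's feedback
#' is displaced by `delta_shift` in its own direction, which is what lets
#' rectified velocity input move the bump while the symmetric sum keeps it
#' stationary at rest; the saturation velocity of the loop is
#' `delta_shift / (tau_E + tau_P)`.
#'
#' Every E-PG receives from both P-EN populations through its side-specific
#' kernel, so the two bridge-side E-PG blocks share one unique bump; the
#' E-PG to P-EN inhibition is uniform (`W_inhib = beta / N` per connection,
#' `N = 54`), acting on the summed E-PG activity.
#'
#' @param params a [circuit_params()] object.
#' @return an object of class `circuit_topology` with the angular grids,
#'   glomerulus membership, weight matrices (excitatory gain and efficacy
#'   folded in) and the total E-PG count `N`.
#' @export
build_topology <- function(params) {
  validate_circuit_params(params)
  n_pen <- params$n_glomeruli_per_side
  n_epg <- n_pen * params$n_epg_per_glom
  # E-PG angles are laid out so each glomerulus's n_epg_per_glom units are
  # centred on their P-EN's angle (offset -1 places the middle unit of
  # glomerulus k exactly at pen_angles[k])
  offset <- (params$n_epg_per_glom - 1L) / 2
  epg_angles <- 2 * pi * (seq_len(n_epg) - 1L - offset) / n_epg
  pen_angles <- 2 * pi * (seq_len(n_pen) - 1L) / n_pen
  delta <- params$delta_shift * pi / 180

  kernel <- function(theta, sgn)
    von_mises_profile(theta, sgn * delta, params$kappa)
  dtheta <- outer(epg_angles, pen_angles, "-")
  gain <- params$alpha * params$efficacy * params$w_scale
  W_left <- gain * kernel(dtheta, +1)
  W_right <- gain * kernel(dtheta, -1)

  glom_membership <- lapply(seq_len(n_pen), function(k)
    (k - 1L) * params$n_epg_per_glom + seq_len(params$n_epg_per_glom))

  topo <- list(epg_angles = rbind(left = epg_angles, right = epg_angles),
               pen_angles = rbind(left = pen_angles, right = pen_angles),
               glom_membership = glom_membership,
               W_pe_left = W_left, W_pe_right = W_right,
               W_inhib = params$beta / (2L * n_epg),
               N = 2L * n_epg)
  class(topo) <- "circuit_topology"
  topo
}

#' @export
print.circuit_topology <- function(x, ...) {
  cat(sprintf("circuit topology: %d E-PG units (%d per side), %d P-EN per side\n",
              x$N, ncol(x$epg_angles), ncol(x$pen_angles)))
  invisible(x)
}

#' Instantaneous state of the circuit
#'
#' @param E firing rates of the 54 E-PG units (left block first).
#' @param P_left,P_right firing rates of the 9 P-EN units per side.
#' @param t simulation time (s).
#' @return an object of class `circuit_state`.
#' @export
circuit_state <- function(E, P_left, P_right, t = 0) {
  if (any(!is.finite(E)) || any(!is.finite(P_left)) || any(!is.finite(P_right)))
    stop("non-finite firing rate in state")
  if (any(E < 0) || any(P_left < 0) || any(P_right < 0))
    stop("firing rates must be non-negative")
  structure(list(E = as.numeric(E), P_left = as.numeric(P_left),
                 P_right = as.numeric(P_right), t = t),
            class = "circuit_state")
}

#' Deterministic seeded-bump initial state
#'
#' A von Mises-shaped E-PG profile (concentration `kappa`) centred at
#' `angle` on both bridge sides, plus a small uniform floor; P-EN rates start
#' at zero.  Settling for about 1 s from this state reaches the attractor.
#'
#' @param params a [circuit_params()] object.
#' @param angle bump centre (radians).
#' @param floor uniform additive floor on the E-PG rates.
#' @return a [circuit_state()].
#' @export
seeded_bump_state <- function(params, angle = 0, floor = 1e-3) {
  n_epg <- params$n_glomeruli_per_side * params$n_epg_per_glom
  th <- 2 * pi * (seq_len(n_epg) - 1L) / n_epg
  prof <- von_mises_profile(th, angle, params$kappa)
  prof <- prof / max(prof) + floor
  circuit_state(E = c(prof, prof),
                P_left = rep(0, params$n_glomeruli_per_side),
                P_right = rep(0, params$n_glomeruli_per_side))
}

# rectified velocity drive in model units; v in deg/s
.velocity_drive <- function(v, params) {
  list(plus = params$velocity_gain * pmax(v, 0),
       minus = params$velocity_gain * pmax(-v, 0))
}

#' Advance the circuit by one integration step
#'
#' Reference (pure-R) exponential-Euler step of the firing-rate equations:
#' the E-PG units relax toward the rectified feedback of both P-EN
#' populations through the
#' kernel weights, and each P-EN unit relaxes toward the rectified sum of
#' its glomerulus's E-PG excitation, global inhibition, the constant bias,
#' and the rectified velocity drive (`v+` to the left side, `v-` to the
#' right).  The compiled integrator used by [simulate_circuit()] performs
#' identical updates; this function is the readable single-step form used
#' for testing and exploration.
#'
#' @param state a [circuit_state()].
#' @param v signed angular velocity (deg/s); positive drives the left side.
#' @param params a [circuit_params()] object.
#' @param topology matching [build_topology()] output.
#' @return the state advanced by `params$dt`.
#' @export
step_circuit <- function(state, v, params, topology) {
  if (!is.finite(v)) stop("velocity must be finite")
  if (any(is.na(state$E))) stop("NaN in state: integration has failed")
  dt <- params$dt
  n_side <- ncol(topology$epg_angles)
  E_l <- state$E[seq_len(n_side)]
  E_r <- state$E[n_side + seq_len(n_side)]
  drv <- .velocity_drive(v, params)

  in_E <- pmax(drop(topology$W_pe_left %*% state$P_left +
                    topology$W_pe_right %*% state$P_right), 0)
  inhib <- topology$W_inhib * sum(state$E)
  a3 <- params$alpha / params$n_epg_per_glom
  exc_l <- vapply(topology$glom_membership, function(m) sum(E_l[m]), 0)
  exc_r <- vapply(topology$glom_membership, function(m) sum(E_r[m]), 0)
  in_Pl <- pmax(a3 * exc_l - inhib + params$bias + drv$plus, 0)
  in_Pr <- pmax(a3 * exc_r - inhib + params$bias + drv$minus, 0)

  dec_e <- exp(-dt / params$tau_E)
  dec_p <- exp(-dt / params$tau_P)
  circuit_state(E = c(E_l, E_r) * dec_e + (1 - dec_e) * c(in_E, in_E),
                P_left = state$P_left * dec_p + (1 - dec_p) * in_Pl,
                P_right = state$P_right * dec_p + (1 - dec_p) * in_Pr,
                t = state$t + dt)
}

#' Velocity input on a uniform time grid
#'
#' @param t time grid (s), strictly increasing and uniform.
#' @param v signed angular velocity (deg/s); positive is the counterclockwise
#'   convention that drives the left P-EN population.
#' @return an object of class `velocity_input`.
#' @export
velocity_input <- function(t, v) {
  stopifnot(length(t) == length(v), length(t) >= 2)
  dt <- diff(t)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9 * dt[1] + 1e-12)
    stop("time grid must be strictly increasing and uniform")
  structure(list(t = as.numeric(t), v = as.numeric(v), dt = dt[1]),
            class = "velocity_input")
}

#' @rdname velocity_input
#' @param value constant velocity (deg/s).
#' @param duration length of the input (s).
#' @param rate sampling rate (Hz).
#' @export
constant_velocity_input <- function(value, duration, rate = 50) {
  n <- round(duration * rate)
  velocity_input(t = seq_len(n) / rate, v = rep(value, n))
}

#' Simulate the ring attractor under a velocity input
#'
#' Integrates the firing-rate equations with the compiled exponential-Euler
#' core at step `params$dt`, holding each velocity sample constant over its
#' sampling interval, and records the state on the input grid after
#' discarding a settle window run at zero velocity.
#'
#' @param params a [circuit_params()] object.
#' @param input a [velocity_input()].
#' @param topology optional pre-built [build_topology()] output.
#' @param init a [circuit_state()] or `"seeded_bump"`.
#' @param settle zero-input settling time discarded before the input (s).
#' @param record_rates if `FALSE`, only the population-vector summaries are
#'   kept (saves memory on long runs).
#' @return an object of class `ring_sim` with fields `t`, `E` (frames x 54),
#'   `P_left`, `P_right` (frames x 9), the bump readout components, the input
#'   and the parameters.
#' @export
simulate_circuit <- function(params, input, topology = NULL,
                             init = "seeded_bump", settle = 1,
                             record_rates = TRUE) {
  validate_circuit_params(params)
  stopifnot(inherits(input, "velocity_input"), settle >= 0)
  if (is.null(topology)) topology <- build_topology(params)
  if (identical(init, "seeded_bump")) init <- seeded_bump_state(params)
  stopifnot(inherits(init, "circuit_state"))

  steps_per_sample <- round(input$dt / params$dt)
  if (steps_per_sample < 1 ||
      abs(steps_per_sample * params$dt - input$dt) > 1e-9)
    stop("input sampling interval must be a multiple of params$dt")
  drv <- .velocity_drive(input$v, params)

  out <- .ring_integrate(topology$W_pe_left, topology$W_pe_right,
                         init$E, init$P_left, init$P_right,
                         drv$plus, drv$minus,
                         as.integer(steps_per_sample),
                         as.integer(round(settle / params$dt)),
                         params$tau_E, params$tau_P,
                         params$alpha, topology$W_inhib, params$bias,
                         params$dt, params$rate_ceiling, record_rates)
  structure(list(t = input$t, E = out$E, P_left = out$P_left,
                 P_right = out$P_right,
                 bump_cos = out$bump_cos, bump_sin = out$bump_sin,
                 rate_sum = out$rate_sum,
                 input = input, params = params, topology = topology,
                 settle = settle),
            class = "ring_sim")
}

#' @export
print.ring_sim <- function(x, ...) {
  cat(sprintf("ring-attractor simulation: %.1f s at %.1f Hz (%d frames), settle %.2g s\n",
              max(x$t), 1 / x$input$dt, length(x$t), x$settle))
  invisible(x)
}

#' Calibrate the velocity gain for unit transfer slope
#'
#' Finds by bisection the `velocity_gain` at which the mean ratio of bump
#' velocity to input velocity over a set of reference velocities in the
#' linear regime equals 1.  Run once to fix the default; the packaged
#' default was obtained with this routine on the default circuit.
#'
#' @param params a [circuit_params()] object (its `velocity_gain` is ignored).
#' @param v_ref reference input velocities (deg/s) inside the linear regime.
#' @param duration simulated time per reference velocity (s).
#' @param lower,upper bisection bracket for the gain.
#' @param tol relative tolerance on the transfer ratio.
#' @return the calibrated gain (drive units per deg/s).
#' @export
calibrate_velocity_gain <- function(params, v_ref = c(30, 45, 60),
                                    duration = 10, lower = 0.005,
                                    upper = 0.2, tol = 1e-3) {
  ratio_at <- function(gain) {
    p <- params
    p$velocity_gain <- gain
    topo <- build_topology(p)
    mean(vapply(v_ref, function(v) {
      sim <- simulate_circuit(p, constant_velocity_input(v, duration),
                              topology = topo, record_rates = FALSE)
      .bump_slope_dps(sim) / v
    }, 0))
  }
  f <- function(g) ratio_at(g) - 1
  lo <- lower; hi <- upper
  if (f(lo) > 0 || f(hi) < 0) stop("gain bracket does not straddle slope 1")
  while ((hi - lo) / hi > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# slope (deg/s) of the unwrapped bump position over the second half of a run
.bump_slope_dps <- function(sim) {
  ang <- unwrap_angle(atan2(sim$bump_sin, sim$bump_cos))
  keep <- seq(floor(length(ang) / 2), length(ang))
  unname(stats::coef(stats::lm(ang[keep] ~ sim$t[keep]))[2]) * 180 / pi
}
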