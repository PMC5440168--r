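#' Unwrap a circular angle trace
#'
#' Removes 2*pi discontinuities so the trace becomes continuous; the first
#' sample is kept as-is.
#'
#' @param theta angles (radians).
#' @return unwrapped angles.
#' @export
unwrap_angle <- function(theta) {
  d <- diff(theta)
  jumps <- c(0, cumsum(round(d / (2 * pi))))
  theta - 2 * pi * jumps
}

# wrap to (-pi, pi]
.wrap_pi <- function(x) atan2(sin(x), cos(x))

#' Population-vector bump position of an E-PG rate profile
#'
#' The circular mean of the rates over the unit angles: the argument of
#' `sum(E * exp(1i * theta))`, with the resultant length normalized by the
#' summed rate as a coherence measure (the model-side analogue of the
#' imaging PVA).
#'
#' @param E rate vector over the 54 E-PG units (left block first), or a
#'   frames x 54 matrix.
#' @param topology a [build_topology()] result giving the unit angles.
#' @return a list with `angle` (radians) and `strength` in \[0, 1\]; vectors
#'   when `E` is a matrix.
#' @export
bump_position <- function(E, topology) {
  th <- c(topology$epg_angles["left", ], topology$epg_angles["right", ])
  if (is.matrix(E)) {
    if (any(rowSums(E) <= 0)) stop("bump position undefined for all-zero rates")
    cs <- E %*% cos(th)
    sn <- E %*% sin(th)
    list(angle = as.numeric(atan2(sn, cs)),
         strength = as.numeric(sqrt(cs^2 + sn^2) / rowSums(E)))
  } else {
    if (sum(E) <= 0) stop("bump position undefined for all-zero rates")
    z <- sum(E * exp(1i * th))
    list(angle = Arg(z), strength = Mod(z) / sum(E))
  }
}

#' Bump position and coherence trace of a simulation
#'
#' @param sim a [simulate_circuit()] result.
#' @return data.frame with `t`, `angle` (rad, wrapped), `strength`.
#' @export
bump_trace_sim <- function(sim) {
  data.frame(t = sim$t,
             angle = atan2(sim$bump_sin, sim$bump_cos),
             strength = sqrt(sim$bump_cos^2 + sim$bump_sin^2) / sim$rate_sum)
}

#' Bump velocity from a simulation
#'
#' First differences of the unwrapped bump position, converted to deg/s and
#' smoothed with a centred boxcar to suppress discretization chatter from
#' the 9-glomerulus grid.
#'
#' @param sim a [simulate_circuit()] result.
#' @param smooth boxcar width (s); 0 disables smoothing.
#' @return velocity trace (deg/s) on the input grid (first sample NA-free:
#'   the trace has length `length(t) - 1` aligned to interval midpoints).
#' @export
bump_velocity <- function(sim, smooth = 0.05) {
  ang <- unwrap_angle(atan2(sim$bump_sin, sim$bump_cos))
  v <- diff(ang) / sim$input$dt * 180 / pi
  if (smooth > 0) {
    w <- max(1L, round(smooth / sim$input$dt))
    if (w %% 2 == 0) w <- w + 1L
    v <- stats::filter(v, rep(1 / w, w), sides = 2)
    v <- as.numeric(v)
    v[is.na(v)] <- 0
  }
  v
}

#' Velocity transfer curve of the circuit
#'
#' For each constant input velocity, simulates the settled circuit and
#' regresses the unwrapped bump position on time; also measures the
#' sustained bump speed over the final 80% of the window (used by
#' [sticking_threshold()]).
#'
#' @param params a [circuit_params()] object.
#' @param v_grid input velocities (deg/s).
#' @param duration simulated time per grid point (s).
#' @param settle zero-input settling time (s).
#' @param topology optional pre-built topology.
#' @param coherence_min flag threshold on the minimum bump coherence.
#' @return an object of class `transfer_curve`: data.frame with `v_in`,
#'   `v_bump` (regression slope, deg/s), `v_sustained` (final-80% mean
#'   speed), `coherence`, `flagged`.
#' @export
transfer_curve <- function(params, v_grid, duration = 10, settle = 1,
                           topology = NULL, coherence_min = 0.2) {
  if (is.null(topology)) topology <- build_topology(params)
  smallest <- min(abs(v_grid[v_grid != 0]))
  if (length(smallest) && is.finite(smallest) &&
      smallest * duration < 90)
    warning("duration allows < 90 deg of travel at the smallest moving velocity")
  rows <- lapply(v_grid, function(v) {
    sim <- simulate_circuit(params, constant_velocity_input(v, duration),
                            topology = topology, settle = settle,
                            record_rates = FALSE)
    ang <- unwrap_angle(atan2(sim$bump_sin, sim$bump_cos)) * 180 / pi
    n <- length(ang)
    i0 <- max(1L, floor(0.2 * n))  # drop the onset transient
    fit <- stats::lm(ang[i0:n] ~ sim$t[i0:n])
    v_sus <- (ang[n] - ang[i0]) / (sim$t[n] - sim$t[i0])
    coh <- min(sqrt(sim$bump_cos^2 + sim$bump_sin^2) / sim$rate_sum)
    data.frame(v_in = v, v_bump = unname(stats::coef(fit)[2]),
               v_sustained = v_sus, coherence = coh,
               flagged = coh < coherence_min)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("transfer_curve", "data.frame")
  out
}

#' Sticking threshold of the bump
#'
#' The smallest input speed at which the bump sustains motion instead of
#' remaining pinned to the discrete P-EN lattice: sustained motion means a
#' mean bump speed above 1 deg/s over the final 80% of the window.
#'
#' @param curve a [transfer_curve()] computed on a grid with resolution
#'   at most 2.5 deg/s near the origin and windows of about 30 s.
#' @return threshold (deg/s); 0 with a message if the bump moves at every
#'   tested velocity.
#' @export
sticking_threshold <- function(curve) {
  stopifnot(inherits(curve, "transfer_curve"))
  nz <- curve[curve$v_in != 0, ]
  if (!nrow(nz)) stop("no nonzero velocities in curve")
  res <- min(diff(sort(unique(c(0, abs(nz$v_in))))))
  if (res > 2.5)
    stop("v_grid resolution near the origin must be <= 2.5 deg/s")
  moving <- abs(nz$v_sustained) > 1
  if (all(moving)) {
    message("bump moves at every tested velocity; returning 0")
    return(0)
  }
  if (!any(moving)) return(Inf)
  min(abs(nz$v_in[moving]))
}

#' Saturation of velocity tracking
#'
#' Finds where the bump stops tracking the input faithfully (bump velocity
#' below 90% of the input) and compares with the closed-form prediction
#' `delta_shift / (tau_E + tau_P)` for the structural phase shift and total
#' time constant of the loop.
#'
#' @param curve a [transfer_curve()].
#' @param params the [circuit_params()] the curve was computed with.
#' @param criterion tracking fraction defining saturation onset.
#' @return list with `onset` (smallest high-velocity v_in below criterion,
#'   deg/s; NA with an `open_ended` flag if tracking holds over the whole
#'   grid), `max_tracked` (largest v_in still at criterion), `v_sat_measured`
#'   (the plateau bump velocity, i.e. the largest bump velocity the circuit
#'   attains), and `prediction`.  Sub-criterion tracking in the sticking
#'   regime near the origin is not counted as saturation: only velocities
#'   above half the predicted saturation are considered for the onset.
#' @export
saturation_velocity <- function(curve, params, criterion = 0.9) {
  stopifnot(inherits(curve, "transfer_curve"))
  prediction <- params$delta_shift / (params$tau_E + params$tau_P)
  pos <- curve[curve$v_in > 0, ]
  pos <- pos[order(pos$v_in), ]
  if (!nrow(pos)) stop("curve contains no positive velocities")
  if (max(pos$v_in) < prediction)
    warning("v_grid does not extend beyond the predicted saturation velocity")
  ratio <- pos$v_bump / pos$v_in
  high <- pos$v_in > prediction / 2
  below <- ratio < criterion & high
  onset <- if (any(below)) min(pos$v_in[below]) else NA_real_
  tracked <- pos$v_in[ratio >= criterion]
  list(onset = onset, open_ended = !any(below),
       max_tracked = if (length(tracked)) max(tracked) else NA_real_,
       v_sat_measured = max(pos$v_bump),
       prediction = prediction)
}

#' Linearity score of the angular integration
#'
#' `L = gamma_sat / gamma_lin`, the ratio of the output/input velocity ratio
#' at saturation onset to the low-velocity slope of the transfer curve; 1
#' for perfectly linear integration.
#'
#' @param curve a [transfer_curve()].
#' @param params matching [circuit_params()].
#' @param linear_band absolute-velocity window (deg/s) over which the
#'   low-velocity slope is fit (above sticking, below saturation).
#' @return list with `L`, `gamma_lin`, `gamma_sat`, `v_sat_onset`.
#' @export
linearity_score <- function(curve, params, linear_band = c(20, 80)) {
  stopifnot(inherits(curve, "transfer_curve"))
  lin <- curve[abs(curve$v_in) >= linear_band[1] &
               abs(curve$v_in) <= linear_band[2], ]
  if (nrow(lin) < 2) stop("no samples in the linear band of the curve")
  gamma_lin <- unname(stats::coef(stats::lm(v_bump ~ 0 + v_in, data = lin)))
  sat <- saturation_velocity(curve, params)
  if (is.na(sat$onset)) stop("no saturation regime in the curve")
  at <- curve[curve$v_in == sat$onset, ]
  gamma_sat <- at$v_bump[1] / at$v_in[1]
  list(L = gamma_sat / gamma_lin, gamma_lin = gamma_lin,
       gamma_sat = gamma_sat, v_sat_onset = sat$onset)
}

#' Integrated heading from a velocity input
#'
#' Cumulative integral of the signed angular velocity under the
#' zero-order-hold convention of the simulator (sample `i` held over the
#' interval ending at `t[i]`), in radians, starting from 0 at time 0.
#'
#' @param input a [velocity_input()].
#' @return unwrapped heading trace (radians), same length as the grid.
#' @export
integrated_heading <- function(input) {
  stopifnot(inherits(input, "velocity_input"))
  cumsum(input$v * pi / 180) * input$dt
}

#' Ensemble variance of the integration error
#'
#' For an ensemble of runs, the variance of the difference between the
#' integrated heading and the bump position,
#' `V(t) = sum_k (theta_i_k - theta_b_k)^2 / (ns - 1)`, with the standard
#' uncertainty band `V * sqrt(2 / (ns - 1))`.  Traces must be unwrapped and
#' aligned so that the difference starts at 0.
#'
#' @param theta_i matrix (time x runs) of integrated headings (rad).
#' @param theta_b matrix (time x runs) of unwrapped bump positions (rad).
#' @return list with `V`, `band`, `n_realizations`.
#' @export
error_variance_curve <- function(theta_i, theta_b) {
  theta_i <- as.matrix(theta_i); theta_b <- as.matrix(theta_b)
  stopifnot(all(dim(theta_i) == dim(theta_b)))
  ns <- ncol(theta_i)
  if (ns < 2) stop("need at least 2 realizations (ns >= 2)")
  if (max(abs(diff(theta_b))) > 1.9 * pi || max(abs(diff(theta_i))) > 1.9 * pi)
    stop("traces appear wrapped; unwrap before computing the variance")
  d <- theta_i - theta_b
  list(V = rowSums(d^2) / (ns - 1), band = sqrt(2 / (ns - 1)),
       n_realizations = ns)
}

#' Fit the diffusion law to an error-variance curve
#'
#' Weighted least squares of `V(t) = sigma0^2 + 2 D t` over `t >= t_min`,
#' with weights from the reciprocal squared uncertainty
#' `V * sqrt(2/(ns-1))`.  The uncertainty is evaluated on a first-pass
#' unweighted fit rather than on the noisy curve itself: weights taken
#' directly from the empirical `V` correlate with its fluctuations and
#' bias the slope low.
#'
#' @param V variance curve.
#' @param t time grid (s).
#' @param t_min lower bound of the fit window (s).
#' @param n_realizations ensemble size behind `V`.
#' @return an object of class `diffusion_fit`: list with `sigma0_sq` (rad^2),
#'   `D` (rad^2/s), `t_min_fit`, `n_realizations`.
#' @export
fit_diffusion <- function(V, t, t_min = 10, n_realizations = NA_integer_) {
  keep <- t >= t_min
  if (sum(keep) < 10) stop("fewer than 10 time points beyond t_min")
  Vk <- V[keep]; tk <- t[keep]
  pass1 <- stats::lm(Vk ~ tk)
  Vhat <- pmax(stats::fitted(pass1), .Machine$double.eps)
  fit <- stats::lm(Vk ~ tk, weights = 1 / Vhat^2)
  co <- unname(stats::coef(fit))
  structure(list(sigma0_sq = co[1], D = co[2] / 2, t_min_fit = t_min,
                 n_realizations = n_realizations),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("diffusion fit: D = %.3g rad^2/s, sigma0^2 = %.3g rad^2 (t >= %g s, ns = %s)\n",
              x$D, x$sigma0_sq, x$t_min_fit, x$n_realizations))
  invisible(x)
}

#' Diffusion of the bump relative to the ideal integral
#'
#' Drives the circuit with an ensemble of Ornstein-Uhlenbeck angular-velocity
#' tracks, records the bump, and fits the long-time diffusion law of the
#' discrepancy between the integrated input and the bump position.
#'
#' @param params a [circuit_params()] object.
#' @param n_tracks ensemble size.
#' @param duration track length (s).
#' @param ou Ornstein-Uhlenbeck parameters, see [ou_params()].
#' @param t_min fit window start (s).
#' @param seed base seed; track k uses `seed + k - 1`.
#' @return list with the [fit_diffusion()] result (`fit`), `V`, `t`.
#' @export
measure_diffusion <- function(params, n_tracks = 20, duration = 1000,
                              ou = ou_params(duration = duration),
                              t_min = 10, seed = 0) {
  topo <- build_topology(params)
  th_i <- th_b <- NULL
  for (k in seq_len(n_tracks)) {
    ou_k <- ou
    ou_k$duration <- duration
    ou_k$seed <- seed + k - 1
    track <- generate_ou_track(ou_k)
    input <- velocity_input(track$t, track$v)
    sim <- simulate_circuit(params, input, topology = topo,
                            record_rates = FALSE)
    tb <- unwrap_angle(atan2(sim$bump_sin, sim$bump_cos))
    ti <- integrated_heading(input)
    tb <- tb - tb[1] + ti[1]
    th_i <- cbind(th_i, ti)
    th_b <- cbind(th_b, tb)
  }
  vc <- error_variance_curve(th_i, th_b)
  fit <- fit_diffusion(vc$V, input$t, t_min = t_min,
                       n_realizations = n_tracks)
  list(fit = fit, V = vc$V, band = vc$band, t = input$t)
}

#' Lag between the velocity input and the bump velocity
#'
#' Cross-correlates the two traces and returns the delay of the bump at the
#' cross-correlation peak, refined by parabolic interpolation around the
#' argmax.
#'
#' @param v_input input velocity trace (deg/s).
#' @param v_bump bump velocity trace on the same uniform grid (deg/s).
#' @param dt sampling interval (s).
#' @param max_lag largest lag searched (s).
#' @return lag (s); positive when the bump lags the input.
#' @export
input_output_lag <- function(v_input, v_bump, dt, max_lag = 0.5) {
  n <- min(length(v_input), length(v_bump))
  x <- v_input[seq_len(n)] - mean(v_input[seq_len(n)])
  y <- v_bump[seq_len(n)] - mean(v_bump[seq_len(n)])
  lags <- seq(-round(max_lag / dt), round(max_lag / dt))
  cc <- vapply(lags, function(k) {
    if (k >= 0) sum(x[seq_len(n - k)] * y[seq_len(n - k) + k])
    else sum(x[seq_len(n + k) - k] * y[seq_len(n + k)])
  }, 0)
  if (max(cc) - min(cc) < 1e-12 * max(abs(cc), 1))
    stop("flat cross-correlation: lag undefined")
  i <- which.max(cc)
  lag <- lags[i]
  if (i > 1 && i < length(lags)) {
    a <- cc[i - 1]; b <- cc[i]; c <- cc[i + 1]
    denom <- a - 2 * b + c
    if (abs(denom) > 0) lag <- lag + 0.5 * (a - c) / denom
  }
  lag * dt
}

#' Bump amplitude as a function of synaptic efficacy
#'
#' Simulates the circuit at zero velocity for each efficacy value and
#' measures the steady E-PG bump amplitude (peak minus mean of the
#' time-averaged profile over the final second).  With the feedback off the
#' activity stays near-uniform and no bump forms.
#'
#' @param params a [circuit_params()] object (its `efficacy` is overridden).
#' @param efficacies values in \[0, 1\].
#' @param duration simulated time per value (s).
#' @return data.frame with `efficacy` and `amplitude`.
#' @export
efficacy_sweep <- function(params, efficacies = seq(0, 1, length.out = 21),
                           duration = 3) {
  amp <- vapply(efficacies, function(eff) {
    p <- params
    p$efficacy <- eff
    sim <- simulate_circuit(p, constant_velocity_input(0, duration))
    keep <- sim$t >= max(sim$t) - 1
    prof <- colMeans(sim$E[keep, , drop = FALSE])
    max(prof) - mean(prof)
  }, 0)
  data.frame(efficacy = efficacies, amplitude = amp)
}
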