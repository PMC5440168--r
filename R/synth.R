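# Synthetic behavior, imaging and spike generators with known ground truth.
# These emulate the observables of tethered-fly experiments (ball velocity
# statistics, moving calcium bumps with indicator kinetics, conjunctively
# tuned spiking) so the analysis stages can be validated by recovery tests.

# evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Ornstein-Uhlenbeck track parameters
#'
#' Defaults reproduce the angular-velocity statistics of walking flies used
#' to drive the model: correlation time 120 ms and stationary SD 50 deg/s,
#' sampled at 50 Hz.
#'
#' @param tau correlation time (s).
#' @param sigma stationary standard deviation (deg/s).
#' @param rate sampling rate (Hz).
#' @param duration track length (s).
#' @param seed RNG seed.
#' @return an object of class `ou_params`.
#' @export
ou_params <- function(tau = 0.120, sigma = 50, rate = 50,
                      duration = 1000, seed = 0) {
  stopifnot(tau > 0, sigma >= 0, rate > 0, duration > 0)
  structure(list(tau = tau, sigma = sigma, rate = rate,
                 duration = duration, seed = seed), class = "ou_params")
}

#' Generate an Ornstein-Uhlenbeck angular-velocity track
#'
#' Uses the exact discretization of the OU process
#' `tau dv = -v dt + sqrt(2 tau) sigma dW`:
#' `v[n+1] = v[n] exp(-dt/tau) + sigma sqrt(1 - exp(-2 dt/tau)) z[n]`,
#' started from the stationary distribution, so the sample statistics match
#' the stationary law at any sampling rate.
#'
#' @param p an [ou_params()] object.
#' @return a [velocity_input()] with the generating parameters attached.
#' @export
generate_ou_track <- function(p) {
  stopifnot(inherits(p, "ou_params"))
  n <- round(p$duration * p$rate)
  dt <- 1 / p$rate
  rho <- exp(-dt / p$tau)
  v <- with_seed(p$seed, {
    z <- stats::rnorm(n)
    out <- numeric(n)
    out[1] <- p$sigma * z[1]
    sd_step <- p$sigma * sqrt(1 - rho^2)
    for (i in seq_len(n - 1L)) out[i + 1L] <- out[i] * rho + sd_step * z[i + 1L]
    out
  })
  track <- velocity_input(t = seq_len(n) * dt, v = v)
  track$ou <- p
  track
}

#' Empirical autocorrelation statistics of a velocity track
#'
#' Fits `A exp(-lag / tau)` to the empirical autocorrelation over lags in
#' `[0, 5 tau_guess]` by nonlinear least squares and reports the fitted
#' time constant together with the sample SD of the velocities.
#'
#' @param track a [velocity_input()].
#' @param tau_guess initial value for the time constant (s).
#' @return list with `tau_fit` (s), `sd` (deg/s), and `fit_failed`.
#' @export
fit_track_stats <- function(track, tau_guess = 0.12) {
  stopifnot(inherits(track, "velocity_input"))
  if (max(track$t) < 100) stop("need at least 100 s of data")
  max_lag <- ceiling(5 * tau_guess / track$dt)
  ac <- stats::acf(track$v, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  lag_s <- (seq_along(ac) - 1) * track$dt
  sd_v <- stats::sd(track$v[track$v != 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(ac ~ A * exp(-lag_s / tau),
                      start = list(A = 1, tau = tau_guess),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || stats::coef(fit)[["tau"]] <= 0)
    return(list(tau_fit = NA_real_, sd = sd_v, fit_failed = TRUE))
  list(tau_fit = stats::coef(fit)[["tau"]], sd = sd_v, fit_failed = FALSE)
}

#' Generate a full behavior trace from a velocity track
#'
#' Heading is the wrapped integral of the rotational velocity; forward
#' velocity is an independent positive process (mean-reverting noise around
#' a constant), matching the empirical near-independence of rotation and
#' forward walking.
#'
#' @param track a [velocity_input()] of rotational velocities (deg/s).
#' @param forward_mean mean forward speed (mm/s).
#' @param forward_sd SD of the forward-speed fluctuations (mm/s).
#' @param forward_tau correlation time of the fluctuations (s).
#' @param seed RNG seed for the forward process.
#' @return an object of class `behavior_trace`: list with `t`, `heading`
#'   (rad, wrapped to (-pi, pi]), `heading_unwrapped` (rad), `v_rot`
#'   (deg/s), `v_fwd` (mm/s), `dt`.
#' @export
generate_behavior <- function(track, forward_mean = 5, forward_sd = 2,
                              forward_tau = 0.3, seed = 1) {
  stopifnot(inherits(track, "velocity_input"))
  heading_u <- integrated_heading(track)
  fwd <- generate_ou_track(ou_params(tau = forward_tau, sigma = forward_sd,
                                     rate = 1 / track$dt,
                                     duration = max(track$t), seed = seed))
  structure(list(t = track$t, heading = .wrap_pi(heading_u),
                 heading_unwrapped = heading_u, v_rot = track$v,
                 v_fwd = pmax(forward_mean + fwd$v, 0), dt = track$dt),
            class = "behavior_trace")
}

#' Ground truth for a synthetic imaging recording
#'
#' @param bump_width_fwhm full width at half maximum of the calcium bump
#'   (degrees).
#' @param pen_lead_gain velocity-dependent angular lead of the P-EN bump
#'   over the E-PG bump (degrees per deg/s).
#' @param amplitude_gain fractional bump-amplitude increase per deg/s of
#'   rotational speed.
#' @param noise_sd additive Gaussian fluorescence noise (fraction of
#'   baseline).
#' @param tau_on,tau_off calcium-indicator rise and decay times (s).
#' @param baseline baseline fluorescence level (arbitrary units).
#' @return an object of class `recording_truth`.
#' @export
recording_truth <- function(bump_width_fwhm = 90, pen_lead_gain = 0.12,
                            amplitude_gain = 0.002, noise_sd = 0.05,
                            tau_on = 0.13, tau_off = 0.63, baseline = 1) {
  stopifnot(bump_width_fwhm > 0, bump_width_fwhm < 360, noise_sd >= 0)
  structure(list(bump_width_fwhm = bump_width_fwhm,
                 pen_lead_gain = pen_lead_gain,
                 amplitude_gain = amplitude_gain, noise_sd = noise_sd,
                 tau_on = tau_on, tau_off = tau_off, baseline = baseline),
            class = "recording_truth")
}

# von Mises concentration whose profile has the given FWHM (degrees)
.kappa_from_fwhm <- function(fwhm_deg) {
  half <- fwhm_deg / 2 * pi / 180
  log(2) / (1 - cos(half))
}

# unit-peak von Mises bump shape
.bump_shape <- function(theta, center, kappa) exp(kappa * (cos(theta - center) - 1))

#' Unit-area calcium-indicator kernel
#'
#' Double-exponential impulse response `exp(-t/tau_off) - exp(-t/tau_on)`
#' for `t >= 0` (rise `tau_on`, decay `tau_off`), normalized so a constant
#' input passes with gain 1.
#'
#' @param dt sampling interval (s).
#' @param tau_on,tau_off rise and decay time constants (s).
#' @param t_max kernel support (s).
#' @return kernel samples summing to `1/dt`.
#' @export
indicator_kernel <- function(dt, tau_on = 0.13, tau_off = 0.63, t_max = 4) {
  tt <- seq(0, t_max, by = dt)
  k <- exp(-tt / tau_off) - exp(-tt / tau_on)
  k / (sum(k) * dt)
}

# causal unit-DC-gain convolution of columns of x with kernel k (step dt)
.causal_convolve <- function(x, k, dt) {
  x <- as.matrix(x)
  n <- nrow(x)
  apply(x, 2, function(col) {
    full <- stats::convolve(col, rev(k), type = "open") * dt
    full[seq_len(n)]
  })
}

# geometry of the synthetic protocerebral-bridge layout: 18 glomeruli,
# left 1..9 (1 outermost), right 10..18 (18 outermost).  E-PGs occupy the
# inner 16 (2..17), P-ENs the outer 16 (1..8, 11..18); each side's 8
# occupied glomeruli map to 8 equiangular bins over [0, 2pi).
.bridge_glomeruli <- function(population) {
  if (population == "EPG") list(left = 2:9, right = 10:17)
  else list(left = 1:8, right = 11:18)
}

#' Generate a synthetic ROI fluorescence series
#'
#' Emulates the imaging observables: a moving calcium bump in 16 ellipsoid
#' body sectors centred at the heading (E-PG) or at the heading plus a
#' velocity-proportional lead (P-EN); two bumps on an 18-glomerulus bridge
#' layout with the empty-glomerulus convention; or two scalar noduli ROIs
#' driven by rectified velocity through a saturating nonlinearity.  All
#' signals are convolved with the indicator kernel, sampled at the frame
#' rate, and corrupted with additive Gaussian noise.  The ground truth is
#' returned alongside for recovery tests.
#'
#' @param truth a [recording_truth()].
#' @param behavior a [generate_behavior()] trace.
#' @param population `"EPG"`, `"PEN"` or `"noduli"`.
#' @param geometry `"EB16"`, `"PB18"` or `"noduli2"`; the noduli geometry is
#'   implied by `population = "noduli"`.
#' @param frame_rate imaging volume rate (Hz).
#' @param seed RNG seed for the noise.
#' @return an object of class `roi_series`: list with `t` (frame times),
#'   `F` (frames x ROIs raw fluorescence), `geometry`, `sector_angles`,
#'   `mask` (occupied-ROI logical, PB18 only), `population`, `truth`,
#'   `frame_behavior` (behavior sampled at the frames).
#' @export
generate_roi_series <- function(truth, behavior,
                                population = c("EPG", "PEN", "noduli"),
                                geometry = c("EB16", "PB18"),
                                frame_rate = 11.4, seed = 0) {
  stopifnot(inherits(truth, "recording_truth"),
            inherits(behavior, "behavior_trace"))
  population <- match.arg(population)
  geometry <- if (population == "noduli") "noduli2" else match.arg(geometry)

  kappa <- .kappa_from_fwhm(truth$bump_width_fwhm)
  v <- behavior$v_rot
  center <- behavior$heading_unwrapped +
    (population == "PEN") * truth$pen_lead_gain * v * pi / 180
  amp <- 1 + truth$amplitude_gain * abs(v)

  if (geometry == "EB16") {
    sector_angles <- (seq_len(16) - 0.5) * 2 * pi / 16
    sig <- amp * exp(kappa * (cos(outer(-center, sector_angles, "+")) - 1))
    mask <- rep(TRUE, 16)
  } else if (geometry == "PB18") {
    sector_angles <- rep(NA_real_, 18)
    occ <- .bridge_glomeruli(population)
    ring <- (seq_len(8) - 1) * 2 * pi / 8
    sig <- matrix(0, nrow = length(v), ncol = 18)
    for (side in c("left", "right")) {
      idx <- occ[[side]]
      sector_angles[idx] <- ring
      sig[, idx] <- amp * exp(kappa * (cos(outer(-center, ring, "+")) - 1))
    }
    mask <- seq_len(18) %in% c(occ$left, occ$right)
  } else { # noduli2: right nodulus driven by v+ (contralateral P-ENs), left by v-
    sector_angles <- NULL
    resp <- function(x) 2 / (1 + exp(-x / 60)) - 1
    sig <- cbind(left = resp(pmax(-v, 0)), right = resp(pmax(v, 0)))
    mask <- c(TRUE, TRUE)
  }

  k <- indicator_kernel(behavior$dt, truth$tau_on, truth$tau_off)
  conv <- .causal_convolve(sig, k, behavior$dt)

  frame_t <- seq(1 / frame_rate, max(behavior$t), by = 1 / frame_rate)
  idx <- findInterval(frame_t, behavior$t)
  Fmat <- truth$baseline * (1 + conv[idx, , drop = FALSE])
  Fmat <- with_seed(seed, {
    Fmat + matrix(stats::rnorm(length(Fmat), 0,
                               truth$noise_sd * truth$baseline),
                  nrow = nrow(Fmat))
  })
  Fmat[!is.na(Fmat) & Fmat < 0] <- 0
  if (geometry == "PB18") Fmat[, !mask] <- truth$baseline

  frame_behavior <- structure(list(
    t = frame_t, heading = behavior$heading[idx],
    heading_unwrapped = behavior$heading_unwrapped[idx],
    v_rot = behavior$v_rot[idx], v_fwd = behavior$v_fwd[idx],
    dt = 1 / frame_rate), class = "behavior_trace")

  structure(list(t = frame_t, F = Fmat, geometry = geometry,
                 sector_angles = sector_angles, mask = mask,
                 population = population, truth = truth,
                 frame_behavior = frame_behavior, seed = seed),
            class = "roi_series")
}

#' Ground truth of a conjunctively tuned cell
#'
#' Generative analogue of the fitted tuning forms: firing rate equal to a
#' baseline plus the product of a sigmoid of lagged rotational velocity and
#' a von Mises function of lagged heading.
#'
#' @param r_min,r_max velocity-tuning range (Hz).
#' @param s sigmoid slope (per deg/s); positive means the rate grows with
#'   counterclockwise velocity.
#' @param v0 sigmoid inflexion (deg/s).
#' @param theta0 preferred heading (rad).
#' @param kappa_h heading concentration.
#' @param lag response lag of the cell behind the behavior (s).
#' @param baseline heading/velocity-independent rate (Hz).
#' @return an object of class `conjunctive_truth`.
#' @export
conjunctive_truth <- function(r_min = 1, r_max = 15, s = 0.08, v0 = 0,
                              theta0 = 0, kappa_h = 2, lag = 0.130,
                              baseline = 2) {
  stopifnot(r_max >= r_min, r_min >= 0, lag >= 0, baseline >= 0, kappa_h > 0)
  structure(list(r_min = r_min, r_max = r_max, s = s, v0 = v0,
                 theta0 = theta0, kappa_h = kappa_h, lag = lag,
                 baseline = baseline), class = "conjunctive_truth")
}

# instantaneous rate (Hz) of the conjunctive generator at behavior samples
.conjunctive_rate <- function(truth, v, heading) {
  sig <- truth$r_min + (truth$r_max - truth$r_min) /
    (1 + exp(-truth$s * (v - truth$v0)))
  vm <- exp(truth$kappa_h * (cos(heading - truth$theta0) - 1))
  truth$baseline + sig * vm
}

#' Generate a conjunctively tuned spike train
#'
#' Inhomogeneous Poisson process by thinning: candidate spikes at the
#' maximal rate `baseline + r_max` are accepted with probability
#' `rate(t)/rate_max`, where the rate follows the lagged behavior.
#'
#' @param truth a [conjunctive_truth()].
#' @param behavior a [generate_behavior()] trace.
#' @param seed RNG seed.
#' @return an object of class `spike_train`: list with `spike_times` (s),
#'   `duration`, `source = "synthetic"`, and the generator `truth`.
#' @export
generate_conjunctive_spikes <- function(truth, behavior, seed = 0) {
  stopifnot(inherits(truth, "conjunctive_truth"),
            inherits(behavior, "behavior_trace"))
  duration <- max(behavior$t)
  rate_max <- truth$baseline + truth$r_max
  times <- with_seed(seed, {
    n_cand <- stats::rpois(1, rate_max * duration)
    cand <- sort(stats::runif(n_cand, 0, duration))
    tq <- pmax(cand - truth$lag, behavior$t[1])
    vq <- stats::approx(behavior$t, behavior$v_rot, tq, rule = 2)$y
    hu <- stats::approx(behavior$t, behavior$heading_unwrapped, tq,
                        rule = 2)$y
    lam <- .conjunctive_rate(truth, vq, hu)
    if (any(lam < 0)) stop("negative rate from tuning parameters")
    cand[stats::runif(n_cand) < lam / rate_max]
  })
  spike_train(times, duration, source = "synthetic", truth = truth)
}

#' Spike train container
#'
#' @param spike_times sorted spike times (s).
#' @param duration recording length (s).
#' @param source `"whole_cell"`, `"loose_patch"` or `"synthetic"`.
#' @param truth optional generator truth.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(spike_times, duration,
                        source = c("whole_cell", "loose_patch", "synthetic"),
                        truth = NULL) {
  source <- match.arg(source)
  spike_times <- sort(as.numeric(spike_times))
  if (length(spike_times) &&
      (spike_times[1] < 0 || spike_times[length(spike_times)] > duration))
    stop("spike times must lie within [0, duration]")
  structure(list(spike_times = spike_times, duration = duration,
                 source = source, truth = truth), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike train (%s): %d spikes over %.1f s (%.2f Hz)\n",
              x$source, length(x$spike_times), x$duration,
              length(x$spike_times) / x$duration))
  invisible(x)
}
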