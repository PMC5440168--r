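# Electrophysiology statistics: spike detection, rate smoothing, sigmoid and
# compound von Mises tuning fits, tuning indices with shuffle nulls, STA,
# GLM lag regression, 2-D heat maps, conditional tuning, and epoch utilities.

#' Detect spikes in a voltage trace
#'
#' Zero-phase band-pass filters the voltage (Butterworth, 50-1000 Hz) and
#' finds upward threshold crossings with a 2 ms refractory lockout.  A
#' robustness report counts spikes across a +/-20% window around the chosen
#' threshold; a count that varies by more than 20% across the window
#' triggers a warning (threshold near the noise floor).
#'
#' @param voltage membrane voltage (mV), uniform sampling.
#' @param fs sampling rate (Hz), at least 4 kHz.
#' @param threshold detection threshold on the filtered trace.
#' @param band band-pass corner frequencies (Hz).
#' @param refractory lockout after each spike (s).
#' @return a [spike_train()] with the robustness report in the
#'   `robustness` attribute (data.frame of threshold scale vs count).
#' @export
detect_spikes <- function(voltage, fs, threshold, band = c(50, 1000),
                          refractory = 0.002) {
  if (fs < 4000) stop("sampling rate must be at least 4 kHz")
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, voltage)
  find <- function(th) {
    up <- which(filt[-1] >= th & filt[-length(filt)] < th) + 1L
    if (!length(up)) return(integer(0))
    keep <- up[1]
    lock <- refractory * fs
    for (i in up[-1]) if (i - keep[length(keep)] > lock) keep <- c(keep, i)
    keep
  }
  idx <- find(threshold)
  scales <- seq(0.8, 1.2, by = 0.05)
  counts <- vapply(scales, function(s) length(find(s * threshold)), 0L)
  report <- data.frame(scale = scales, count = counts)
  ctr <- length(idx)
  if (ctr > 0 && (max(counts) - min(counts)) > 0.2 * ctr)
    warning("spike count varies by more than 20% across the threshold window")
  st <- spike_train((idx - 1) / fs, duration = length(voltage) / fs,
                    source = "whole_cell")
  attr(st, "robustness") <- report
  st
}

#' Smoothed firing-rate trace from spike times
#'
#' Bins spikes and convolves with a truncated Gaussian window normalized to
#' unit mass, so the integral of the rate recovers the spike count.  The
#' Gaussian is specified by its half-width at half maximum.
#'
#' @param spikes a [spike_train()].
#' @param bin bin width (s).
#' @param window total window length (s).
#' @param half_width half-width at half maximum of the Gaussian (s).
#' @return list with `t` (bin centres) and `rate` (Hz).
#' @export
smooth_rate <- function(spikes, bin = 0.05, window = 1, half_width = 0.3) {
  stopifnot(inherits(spikes, "spike_train"), spikes$duration > window)
  edges <- seq(0, spikes$duration + bin, by = bin)
  counts <- graphics::hist(spikes$spike_times, breaks = edges,
                           plot = FALSE)$counts
  sdv <- half_width / sqrt(2 * log(2))
  half_n <- floor(window / 2 / bin)
  kt <- (-half_n:half_n) * bin
  k <- exp(-kt^2 / (2 * sdv^2))
  k <- k / sum(k)
  sm <- stats::filter(counts, k, sides = 2)
  sm[is.na(sm)] <- 0
  list(t = edges[-length(edges)] + bin / 2, rate = as.numeric(sm) / bin)
}

# the four-parameter sigmoid of velocity tuning (decreasing for s > 0)
.sigmoid <- function(v, r_max, s, v0, r_min) r_max / (1 + exp(s * (v + v0))) + r_min

#' Weighted sigmoid fit of rotational-velocity tuning
#'
#' Bins the response by rotational velocity (12 deg/s bins by default),
#' after shifting the response by the cell's lag, and fits the
#' four-parameter sigmoid `r_max / (1 + exp(s (v + v0))) + r_min` by
#' weighted nonlinear least squares with the per-bin sample counts as
#' weights.  Multi-start initialization (both slope signs, several offsets)
#' guards against local minima.
#'
#' @param rate response trace (Hz or mV), uniform grid.
#' @param v rotational velocity (deg/s), same grid.
#' @param dt sampling interval (s).
#' @param bin_width velocity bin width (deg/s).
#' @param lag response lag (s): the response is paired with the velocity
#'   `lag` seconds earlier.
#' @param min_bins minimum number of populated bins.
#' @param min_count bins with fewer samples are dropped from the fit
#'   (occupancy floor, as for the heat-map masks).
#' @return object of class `sigmoid_fit`: the fitted parameters, the
#'   weighted `r_squared`, `rate_modulation` (difference of the fitted
#'   curve at +/- the reference velocity: the saturation range or 200
#'   deg/s, whichever is smaller), `bandwidth` (velocity span between 5%
#'   and 95% of the modulation), `inflexion` (`-v0`), and the binned data.
#' @export
fit_sigmoid_tuning <- function(rate, v, dt, bin_width = 12, lag = 0,
                               min_bins = 5, min_count = 8) {
  k <- round(lag / dt)
  n <- length(rate)
  if (k > 0) { rate <- rate[(1 + k):n]; v <- v[1:(n - k)] }
  else if (k < 0) { rate <- rate[1:(n + k)]; v <- v[(1 - k):n] }
  edges <- seq(floor(min(v) / bin_width) * bin_width,
               ceiling(max(v) / bin_width) * bin_width, by = bin_width)
  bi <- findInterval(v, edges, rightmost.closed = TRUE)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  ok <- sort(unique(bi))
  w <- vapply(ok, function(b) sum(bi == b), 0)
  ok <- ok[w >= min_count]
  y <- vapply(ok, function(b) mean(rate[bi == b]), 0)
  w <- vapply(ok, function(b) sum(bi == b), 0)
  x <- mids[ok]
  if (length(x) < min_bins) stop("fewer than min_bins populated velocity bins")

  span <- diff(range(y))
  starts <- expand.grid(s = c(-0.05, 0.05, -0.01, 0.01),
                        v0 = stats::quantile(x, c(0.35, 0.65)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ .sigmoid(x, r_max, s, v0, r_min),
                        start = list(r_max = max(span, 1e-3),
                                     s = starts$s[i], v0 = starts$v0[i],
                                     r_min = min(y)),
                        weights = w,
                        lower = c(-Inf, -1, min(x), -Inf),
                        upper = c(Inf, 1, max(x), Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(w * stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("sigmoid fit failed to converge from all starts")
  co <- as.list(stats::coef(best$fit))
  ybar <- sum(w * y) / sum(w)
  r2 <- 1 - best$rss / sum(w * (y - ybar)^2)
  vref <- min(200, max(abs(x)))
  modulation <- abs(.sigmoid(vref, co$r_max, co$s, co$v0, co$r_min) -
                    .sigmoid(-vref, co$r_max, co$s, co$v0, co$r_min))
  vg <- seq(-vref, vref, length.out = 2001)
  fv <- .sigmoid(vg, co$r_max, co$s, co$v0, co$r_min)
  lo <- min(fv[1], fv[length(fv)]); hi <- max(fv[1], fv[length(fv)])
  inside <- vg[fv > lo + 0.05 * (hi - lo) & fv < lo + 0.95 * (hi - lo)]
  bandwidth <- if (length(inside)) diff(range(inside)) else NA_real_
  structure(c(co, list(r_squared = r2, rate_modulation = modulation,
                       bandwidth = bandwidth, inflexion = -co$v0,
                       bins = data.frame(v = x, rate = y, n = w))),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("sigmoid tuning: r_max %.2f, slope %.3f, inflexion %.1f deg/s, r_min %.2f; R^2 %.3f, modulation %.2f\n",
              x$r_max, x$s, x$inflexion, x$r_min, x$r_squared,
              x$rate_modulation))
  invisible(x)
}

# compound von Mises rate model
.cvm <- function(th, r_min, g1, th1, k1, g2, th2, k2)
  r_min + g1 * exp(k1 * cos(th - th1)) / (2 * pi * besselI(k1, 0)) +
    g2 * exp(k2 * cos(th - th2)) / (2 * pi * besselI(k2, 0))

#' Compound von Mises fit of heading tuning
#'
#' Bins the response into 32 heading bins of 11.25 degrees and fits the sum
#' of two von Mises components plus a floor by nonlinear least squares,
#' initializing the component centres at the peak and trough of the binned
#' curve.
#'
#' @param rate response trace, uniform grid.
#' @param heading heading (rad), same grid.
#' @param n_bins number of heading bins.
#' @param require_full error if any bin is unpopulated.
#' @return object of class `vonmises_fit` with the parameters, the binned
#'   data, and `width_half_max` (degrees) of the dominant component.
#' @export
fit_vonmises_heading <- function(rate, heading, n_bins = 32,
                                 require_full = TRUE) {
  th <- .wrap_pi(heading)
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  bi <- findInterval(th, edges, rightmost.closed = TRUE)
  counts <- tabulate(bi, n_bins)
  if (require_full && any(counts == 0))
    stop("unpopulated heading bins: ", paste(which(counts == 0), collapse = ", "))
  ok <- which(counts > 0)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  y <- vapply(ok, function(b) mean(rate[bi == b]), 0)
  x <- mids[ok]
  pk <- x[which.max(y)]; tr <- x[which.min(y)]
  span <- max(diff(range(y)), 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ .cvm(x, r_min, g1, th1, k1, g2, th2, k2),
                      start = list(r_min = min(y), g1 = span, th1 = pk,
                                   k1 = 2, g2 = -span / 4, th2 = tr, k2 = 2),
                      lower = c(-Inf, -Inf, -2 * pi, 0.05, -Inf, -2 * pi, 0.05),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) stop("compound von Mises fit failed to converge")
  co <- as.list(stats::coef(fit))
  # width at half-maximal modulation of the dominant (larger |g|) component
  kdom <- if (abs(co$g1) >= abs(co$g2)) co$k1 else co$k2
  width <- 2 * acos(pmin(1, pmax(-1, 1 + log(0.5) / kdom))) * 180 / pi
  yhat <- stats::fitted(fit)
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  structure(c(co, list(theta01 = .wrap_pi(co$th1), theta02 = .wrap_pi(co$th2),
                       width_half_max = width, r_squared = r2,
                       bins = data.frame(heading = x, rate = y,
                                         n = counts[ok]))),
            class = "vonmises_fit")
}

#' @export
print.vonmises_fit <- function(x, ...) {
  cat(sprintf("compound von Mises: r_min %.2f; g1 %.2f at %.0f deg (k %.1f); g2 %.2f at %.0f deg (k %.1f); R^2 %.3f\n",
              x$r_min, x$g1, x$theta01 * 180 / pi, x$k1,
              x$g2, x$theta02 * 180 / pi, x$k2, x$r_squared))
  invisible(x)
}

#' Heading and rotation tuning indices
#'
#' The heading index H is the mean vector length of the per-bin rates over
#' the heading bins (`|sum r exp(i theta)| / sum r`, in \[0, 1\]); the
#' preferred heading is the phase of that vector.  The rotation index is
#' the weighted R-squared of the sigmoid velocity fit.
#'
#' @param bin_rates mean rate per heading bin.
#' @param bin_centers heading bin centres (rad).
#' @param sigmoid_fit optional [fit_sigmoid_tuning()] result.
#' @return list with `H`, `preferred_heading` (rad), `rotation_index`.
#' @export
tuning_indices <- function(bin_rates, bin_centers, sigmoid_fit = NULL) {
  if (all(bin_rates == 0)) stop("all-zero rates: H undefined")
  z <- sum(bin_rates * exp(1i * bin_centers))
  list(H = Mod(z) / sum(bin_rates), preferred_heading = Arg(z),
       rotation_index = if (is.null(sigmoid_fit)) NA_real_
                        else sigmoid_fit$r_squared)
}

# heading-binned mean rates for a spike train against behavior
.heading_bin_rates <- function(spikes, behavior, bin = 0.05, n_bins = 32,
                               half_width = 0.3) {
  sr <- smooth_rate(spikes, bin = bin, half_width = half_width)
  hu <- stats::approx(behavior$t, behavior$heading_unwrapped, sr$t,
                      rule = 2)$y
  th <- .wrap_pi(hu)
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  bi <- findInterval(th, edges, rightmost.closed = TRUE)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  ok <- sort(unique(bi))
  list(rates = vapply(ok, function(b) mean(sr$rate[bi == b]), 0),
       centers = mids[ok], rate_t = sr$t, rate = sr$rate)
}

#' Shuffle null distributions for tuning indices
#'
#' Chops the spike train into fixed-length fragments, randomly reassembles
#' them, and recomputes the heading index (and optionally the rotation
#' index) per repetition; significance thresholds are the 95th percentiles
#' of the null distributions.
#'
#' @param spikes a [spike_train()].
#' @param behavior a `behavior_trace` covering the recording.
#' @param fragment fragment length (s): 1 s for whole experiments, 0.5 s
#'   for short epochs.
#' @param n shuffle repetitions.
#' @param seed RNG seed.
#' @param rotation also compute the rotation-index null (one sigmoid fit
#'   per repetition; considerably slower).
#' @param bin rate bin width (s).
#' @return list with `H_null`, `H_95`, observed `H`, and when requested
#'   `rotation_null`, `rotation_95`, observed `rotation_index`.
#' @export
shuffle_null <- function(spikes, behavior, fragment = 1.0, n = 1000,
                         seed = 0, rotation = FALSE, bin = 0.05) {
  n_frag <- floor(spikes$duration / fragment)
  if (n_frag < 100) stop("recording shorter than 100 fragments")
  obs <- .heading_bin_rates(spikes, behavior, bin = bin)
  H_obs <- tuning_indices(obs$rates, obs$centers)$H
  rot_obs <- NULL
  v_rate <- stats::approx(behavior$t, behavior$v_rot, obs$rate_t, rule = 2)$y
  if (rotation)
    rot_obs <- fit_sigmoid_tuning(obs$rate, v_rate, dt = bin)$r_squared

  shuffled_H <- numeric(n)
  shuffled_rot <- if (rotation) numeric(n) else NULL
  frag_of <- pmin(floor(spikes$spike_times / fragment), n_frag - 1L)
  offset <- spikes$spike_times - frag_of * fragment
  with_seed(seed, {
    for (r in seq_len(n)) {
      perm <- sample.int(n_frag) - 1L
      new_times <- sort(perm[frag_of + 1L] * fragment + offset)
      st <- spike_train(new_times, spikes$duration, source = spikes$source)
      sh <- .heading_bin_rates(st, behavior, bin = bin)
      shuffled_H[r] <- tuning_indices(sh$rates, sh$centers)$H
      if (rotation) {
        shuffled_rot[r] <- tryCatch(
          fit_sigmoid_tuning(sh$rate, v_rate, dt = bin)$r_squared,
          error = function(e) NA_real_)
      }
    }
  })
  out <- list(H = H_obs, H_null = shuffled_H,
              H_95 = stats::quantile(shuffled_H, 0.95, names = FALSE))
  if (rotation) {
    out$rotation_index <- rot_obs
    out$rotation_null <- shuffled_rot
    out$rotation_95 <- stats::quantile(shuffled_rot, 0.95, na.rm = TRUE,
                                       names = FALSE)
  }
  out
}

#' Spike-triggered average of rotational velocity
#'
#' Averages the velocity in a +/- window around each spike that occurred
#' within a 2 s epoch whose rotational speed exceeded the inclusion
#' threshold at any point.  The peak lag is the time of the maximum
#' absolute STA relative to the spike (negative: velocity precedes).
#'
#' @param v rotational velocity (deg/s), uniform grid.
#' @param t velocity sample times (s).
#' @param spikes a [spike_train()].
#' @param window half-window around each spike (s).
#' @param min_speed epoch inclusion threshold (deg/s).
#' @param epoch epoch length (s).
#' @param min_spikes required number of qualifying spikes.
#' @return list with `lag` (s of the STA time grid), `sta`, `peak_lag` (s),
#'   `n_spikes`.
#' @export
spike_triggered_average <- function(v, t, spikes, window = 1,
                                    min_speed = 40, epoch = 2,
                                    min_spikes = 50) {
  dt <- t[2] - t[1]
  ep <- floor(t / epoch)
  fast <- vapply(split(abs(v), ep), max, 0)
  good_ep <- as.numeric(names(fast))[fast > min_speed]
  if (!length(good_ep)) stop("no epochs exceed the inclusion threshold")
  half_n <- round(window / dt)
  segs <- list()
  for (ts in spikes$spike_times) {
    if (!(floor(ts / epoch) %in% good_ep)) next
    i <- round((ts - t[1]) / dt) + 1L
    if (i - half_n < 1 || i + half_n > length(v)) next
    segs[[length(segs) + 1]] <- v[(i - half_n):(i + half_n)]
  }
  if (length(segs) < min_spikes)
    stop("fewer than ", min_spikes, " qualifying spikes")
  sta <- colMeans(do.call(rbind, segs))
  lag_grid <- (-half_n:half_n) * dt
  list(lag = lag_grid, sta = sta,
       peak_lag = lag_grid[which.max(abs(sta))], n_spikes = length(segs))
}

#' Time-shifted GLM regression of neural response on rotations
#'
#' Bins the data (20 ms), forms Z-scored predictors from the rectified
#' rotational velocities and their cubes, and fits per time shift either an
#' ordinary linear regression (membrane potential) or a log-link Poisson
#' regression (spike counts).  The response lag is the shift with the
#' maximum absolute difference between the two linear rotation
#' coefficients.
#'
#' @param response response trace on the input grid (mV, rate, or counts).
#' @param v signed rotational velocity (deg/s), same grid.
#' @param dt sampling interval of the inputs (s).
#' @param shifts time shifts (s), response relative to predictors.
#' @param family `"gaussian"` or `"poisson"`.
#' @param bin bin width (s).
#' @return list with the per-shift coefficient table `coefficients`
#'   (`shift`, `ccw`, `cw`, `ccw3`, `cw3`, `converged`) and `lag` (s; NA
#'   when all coefficients vanish).
#' @export
glm_lag_regression <- function(response, v, dt,
                               shifts = seq(-2, 2, by = 0.02),
                               family = c("gaussian", "poisson"),
                               bin = 0.02) {
  family <- match.arg(family)
  per <- max(1L, round(bin / dt))
  rebin <- function(x, f) {
    n <- floor(length(x) / per)
    f(matrix(x[seq_len(n * per)], nrow = per))
  }
  y <- rebin(response, if (family == "poisson") colSums else colMeans)
  if (family == "poisson") y <- round(y)
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  vr <- rebin(v, colMeans)
  X <- cbind(ccw = zs(pmax(vr, 0)), cw = zs(pmax(-vr, 0)),
             ccw3 = zs(pmax(vr, 0)^3), cw3 = zs(pmax(-vr, 0)^3))
  rows <- lapply(shifts, function(s) {
    k <- round(s / bin)
    n <- length(y)
    if (abs(k) >= n - 8) return(NULL)
    if (k >= 0) { yy <- y[(1 + k):n]; XX <- X[1:(n - k), , drop = FALSE] }
    else { yy <- y[1:(n + k)]; XX <- X[(1 - k):n, , drop = FALSE] }
    if (family == "gaussian") {
      co <- stats::coef(stats::lm.fit(cbind(1, XX), yy))[-1]
      conv <- TRUE
    } else {
      fit <- suppressWarnings(tryCatch(
        stats::glm.fit(cbind(1, XX), yy, family = stats::poisson()),
        error = function(e) NULL))
      if (is.null(fit) || !fit$converged) { co <- rep(NA_real_, 4); conv <- FALSE }
      else { co <- stats::coef(fit)[-1]; conv <- TRUE }
    }
    data.frame(shift = s, ccw = co[1], cw = co[2], ccw3 = co[3], cw3 = co[4],
               converged = conv)
  })
  tab <- do.call(rbind, rows)
  dcoef <- abs(tab$ccw - tab$cw)
  lag <- if (all(!tab$converged) ||
             max(dcoef, na.rm = TRUE) < 1e-8) NA_real_
         else tab$shift[which.max(dcoef)]
  list(coefficients = tab, lag = lag)
}

#' Occupancy-masked two-dimensional tuning map
#'
#' Means of the response over a 2-D grid of two behavioral variables;
#' cells visited for fewer than `min_samples` bins are masked (NA).
#'
#' @param response response values per time bin.
#' @param x,y behavioral variables per time bin.
#' @param x_breaks,y_breaks grid edges.
#' @param min_samples occupancy threshold per cell.
#' @return list with `map` (length(x_breaks)-1 x length(y_breaks)-1),
#'   `counts`, and the break vectors.
#' @export
tuning_heatmap_2d <- function(response, x, y, x_breaks, y_breaks,
                              min_samples = 50) {
  xi <- findInterval(x, x_breaks, rightmost.closed = TRUE)
  yi <- findInterval(y, y_breaks, rightmost.closed = TRUE)
  nx <- length(x_breaks) - 1; ny <- length(y_breaks) - 1
  keep <- xi >= 1 & xi <= nx & yi >= 1 & yi <= ny
  map <- matrix(NA_real_, nx, ny)
  counts <- matrix(0L, nx, ny)
  cell <- (yi[keep] - 1) * nx + xi[keep]
  sums <- tapply(response[keep], cell, sum)
  ns <- tapply(response[keep], cell, length)
  ij <- as.integer(names(sums))
  counts[ij] <- as.integer(ns)
  vals <- sums / ns
  sel <- ns >= min_samples
  map[ij[sel]] <- vals[sel]
  list(map = map, counts = counts, x_breaks = x_breaks, y_breaks = y_breaks)
}

#' Conditional tuning curves and modulation statistics
#'
#' Splits the data by heading quadrant (preferred: bins where the
#' unconditional heading curve exceeds the half-maximal positive
#' modulation above its median; non-preferred: bins below the median) and
#' by turn direction, then refits the velocity sigmoid within each heading
#' quadrant and the heading curve within each turn direction.  Rotation
#' modulation is the difference of the fitted response at -150 and +150
#' deg/s; heading modulation is the difference of the conditional heading
#' curves at the unconditional peak and trough positions.
#'
#' @param rate response trace.
#' @param v rotational velocity (deg/s), same grid.
#' @param heading heading (rad), same grid.
#' @param dt sampling interval (s).
#' @param vm_fit unconditional [fit_vonmises_heading()] fit.
#' @param bin_width sigmoid velocity bin width (deg/s).
#' @return list with `preferred` / `nonpreferred` sigmoid fits and their
#'   `rotation_modulation`, plus `cw` / `ccw` heading fits and their
#'   `heading_modulation`; empty subsets are flagged with NULL entries.
#' @export
conditional_tuning <- function(rate, v, heading, dt, vm_fit,
                               bin_width = 12.5) {
  th <- .wrap_pi(heading)
  n_bins <- 32
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  curve <- .cvm(mids, vm_fit$r_min, vm_fit$g1, vm_fit$th1, vm_fit$k1,
                vm_fit$g2, vm_fit$th2, vm_fit$k2)
  baseline <- stats::median(curve)
  pref_bins <- which(curve > baseline + (max(curve) - baseline) / 2)
  nonpref_bins <- which(curve < baseline)
  bi <- findInterval(th, edges, rightmost.closed = TRUE)

  fit_subset <- function(sel) {
    if (sum(sel) < 100) return(NULL)
    tryCatch(fit_sigmoid_tuning(rate[sel], v[sel], dt,
                                bin_width = bin_width),
             error = function(e) NULL)
  }
  pref <- fit_subset(bi %in% pref_bins)
  nonpref <- fit_subset(bi %in% nonpref_bins)
  rot_mod <- function(f) {
    if (is.null(f)) return(NA_real_)
    .sigmoid(-150, f$r_max, f$s, f$v0, f$r_min) -
      .sigmoid(150, f$r_max, f$s, f$v0, f$r_min)
  }

  fit_heading <- function(sel) {
    if (sum(sel) < 100) return(NULL)
    tryCatch(fit_vonmises_heading(rate[sel], heading[sel],
                                  require_full = FALSE),
             error = function(e) NULL)
  }
  ccw <- fit_heading(v > 0)
  cw <- fit_heading(v < 0)
  pk_pos <- mids[which.max(curve)]; tr_pos <- mids[which.min(curve)]
  head_mod <- function(f) {
    if (is.null(f)) return(NA_real_)
    .cvm(pk_pos, f$r_min, f$g1, f$th1, f$k1, f$g2, f$th2, f$k2) -
      .cvm(tr_pos, f$r_min, f$g1, f$th1, f$k1, f$g2, f$th2, f$k2)
  }
  list(preferred = pref, nonpreferred = nonpref,
       rotation_modulation = c(preferred = rot_mod(pref),
                               nonpreferred = rot_mod(nonpref)),
       ccw = ccw, cw = cw,
       heading_modulation = c(ccw = head_mod(ccw), cw = head_mod(cw)),
       preferred_bins = pref_bins, nonpreferred_bins = nonpref_bins)
}

#' Select well-sampled experimental epochs
#'
#' Scans fixed-length windows and keeps those whose heading-by-velocity
#' occupancy contains a contiguous velocity band of at least the required
#' span with non-zero counts across all heading bins (the fly rotated
#' vigorously through every heading).
#'
#' @param v rotational velocity (deg/s), uniform grid.
#' @param heading heading (rad), same grid.
#' @param t sample times (s).
#' @param window window length (s).
#' @param span_required required contiguous velocity span (deg/s).
#' @param v_bin velocity bin width (deg/s).
#' @param n_heading_bins heading bins.
#' @return data.frame of qualifying windows (`t_start`, `t_end`,
#'   `span`), with the last window's occupancy mask in the `mask`
#'   attribute.
#' @export
epoch_selector <- function(v, heading, t, window = 300,
                           span_required = 250, v_bin = 12.5,
                           n_heading_bins = 32) {
  th <- .wrap_pi(heading)
  h_edges <- seq(-pi, pi, length.out = n_heading_bins + 1)
  v_edges <- seq(floor(min(v) / v_bin) * v_bin,
                 ceiling(max(v) / v_bin) * v_bin, by = v_bin)
  rows <- list(); mask <- NULL
  dt <- t[2] - t[1]
  n_win <- floor((max(t) - t[1] + dt) / window)
  starts <- t[1] + (seq_len(n_win) - 1) * window
  for (ws in starts) {
    sel <- t >= ws & t < ws + window
    hi <- findInterval(th[sel], h_edges, rightmost.closed = TRUE)
    vi <- findInterval(v[sel], v_edges, rightmost.closed = TRUE)
    occ <- table(factor(vi, levels = seq_len(length(v_edges) - 1)),
                 factor(hi, levels = seq_len(n_heading_bins)))
    full_cols <- apply(occ > 0, 1, all)
    r <- rle(as.vector(full_cols))
    best <- if (any(r$values)) max(r$lengths[r$values]) * v_bin else 0
    if (best >= span_required) {
      rows[[length(rows) + 1]] <- data.frame(t_start = ws,
                                             t_end = ws + window,
                                             span = best)
      mask <- occ > 0
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(t_start = numeric(0), t_end = numeric(0),
                         span = numeric(0))
  attr(out, "mask") <- mask
  out
}

#' Behavioral rotational-velocity bandwidth
#'
#' The spread between the 10th and 90th percentile of the absolute
#' rotational velocity, excluding near-zero samples.
#'
#' @param v signed rotational velocity (deg/s).
#' @param exclude half-width of the excluded near-zero band (deg/s).
#' @return named vector with `p10`, `p90`, `bandwidth`.
#' @export
behavioral_bandwidth <- function(v, exclude = 5) {
  av <- abs(v)[abs(v) >= exclude]
  q <- stats::quantile(av, c(0.1, 0.9), names = FALSE)
  c(p10 = q[1], p90 = q[2], bandwidth = q[2] - q[1])
}

#' Zero-phase low-pass filter for membrane potential
#'
#' 4th-order Butterworth low-pass applied forward and backward.
#'
#' @param voltage trace (mV).
#' @param fs sampling rate (Hz).
#' @param cutoff corner frequency (Hz).
#' @return filtered trace.
#' @export
lowpass_membrane <- function(voltage, fs, cutoff = 50) {
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  signal::filtfilt(bf, voltage)
}
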