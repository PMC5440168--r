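# Imaging-side analysis: dF/F, population vector averages, bump metrics,
# bridge/EB registration, velocity binning, noduli correlations, and the
# turn-based PVA analysis used for synaptic-block experiments.

#' Align a high-rate behavior trace to imaging frames
#'
#' Takes the behavior sample at the end of each imaging volume, derives
#' rotational velocity from first differences of the unwrapped heading
#' across frames, and smooths the velocities with a Savitzky-Golay filter
#' (11 frames, 3rd-order polynomial) to suppress downsampling artifacts.
#'
#' @param behavior a [generate_behavior()]-style `behavior_trace`.
#' @param frame_times volume end times (s), within the behavior span.
#' @return a `behavior_trace` on the frame grid with smoothed `v_rot`
#'   (deg/s) and `v_fwd`.
#' @export
align_behavior_to_frames <- function(behavior, frame_times) {
  stopifnot(inherits(behavior, "behavior_trace"))
  if (min(frame_times) < min(behavior$t) || max(frame_times) > max(behavior$t))
    stop("frame times fall outside the behavior span")
  idx <- findInterval(frame_times, behavior$t)
  hu <- behavior$heading_unwrapped[idx]
  dtf <- diff(behavior$t[idx])  # actual spacing of the sampled points
  v_rot <- c(NA, diff(hu) / dtf) * 180 / pi
  v_rot[1] <- v_rot[2]
  v_fwd <- behavior$v_fwd[idx]
  if (length(frame_times) >= 11) {
    v_rot <- signal::sgolayfilt(v_rot, p = 3, n = 11)
    v_fwd <- signal::sgolayfilt(v_fwd, p = 3, n = 11)
  }
  structure(list(t = frame_times, heading = behavior$heading[idx],
                 heading_unwrapped = hu, v_rot = v_rot, v_fwd = v_fwd,
                 dt = mean(dtf)), class = "behavior_trace")
}

#' Compute dF/F from raw ROI fluorescence
#'
#' Per ROI, the baseline F0 is the mean of the lowest 10% of frames; the
#' returned series is `raw / F0 - 1` (the additive convention; the plain
#' ratio is `dff + 1`).  Optionally Savitzky-Golay smoothed over 11 frames
#' with a 3rd-order polynomial, matching the behavioral smoothing.
#'
#' @param roi a `roi_series` (see [generate_roi_series()]), or a raw
#'   frames x ROIs matrix together with `t`.
#' @param t frame times when `roi` is a bare matrix.
#' @param smooth apply the Savitzky-Golay filter.
#' @param geometry,sector_angles,mask geometry metadata for a bare matrix.
#' @return an object of class `dff_series`: list with `t`, `dff`
#'   (frames x ROIs), `geometry`, `sector_angles`, `mask`, `f0`.
#' @export
compute_dff <- function(roi, t = NULL, smooth = TRUE, geometry = NULL,
                        sector_angles = NULL, mask = NULL) {
  if (inherits(roi, "roi_series")) {
    raw <- roi$F; t <- roi$t
    geometry <- roi$geometry; sector_angles <- roi$sector_angles
    mask <- roi$mask
  } else raw <- as.matrix(roi)
  if (any(raw < 0, na.rm = TRUE)) stop("raw fluorescence must be non-negative")
  n <- nrow(raw)
  k <- max(1L, ceiling(0.1 * n))
  f0 <- apply(raw, 2, function(col) mean(sort(col)[seq_len(k)]))
  if (any(f0 <= 0)) stop("degenerate baseline: F0 = 0 in at least one ROI")
  dff <- sweep(raw, 2, f0, "/") - 1
  if (smooth && n >= 11) dff <- apply(dff, 2, signal::sgolayfilt, p = 3, n = 11)
  structure(list(t = t, dff = dff, geometry = geometry,
                 sector_angles = sector_angles,
                 mask = if (is.null(mask)) rep(TRUE, ncol(raw)) else mask,
                 f0 = f0),
            class = "dff_series")
}

#' Population vector average of sector activities
#'
#' Sums unit vectors at the sector angles weighted by the (zero-floored)
#' activities: the angle is the circular mean of activity, the strength the
#' resultant length normalized by the summed weights (in \[0, 1\]).
#'
#' @param w activity weights: a vector (one frame) or frames x ROIs matrix.
#' @param sector_angles ROI centre angles (rad).
#' @return list with `angle` (rad) and `strength`; all-zero frames give NA
#'   in both.
#' @export
pva <- function(w, sector_angles) {
  one <- is.null(dim(w))
  if (one) w <- matrix(w, nrow = 1)
  stopifnot(ncol(w) == length(sector_angles))
  w <- pmax(w, 0)
  tot <- rowSums(w)
  cs <- w %*% cos(sector_angles)
  sn <- w %*% sin(sector_angles)
  ang <- ifelse(tot > 0, atan2(sn, cs), NA_real_)
  str <- ifelse(tot > 0, sqrt(cs^2 + sn^2) / tot, NA_real_)
  if (one) list(angle = ang[1], strength = str[1])
  else list(angle = as.numeric(ang), strength = as.numeric(str))
}

#' Bump amplitude and full width at half maximum
#'
#' Amplitude is the profile maximum minus minimum; the FWHM is obtained by
#' circular linear interpolation of the half-maximum crossings on either
#' side of the (lowest-index) peak.
#'
#' @param profile activity over sectors (one frame).
#' @param sector_angles sector centre angles (rad), uniformly spaced.
#' @return list with `amplitude`, `fwhm` (degrees; NA with `flat = TRUE`
#'   for a flat profile).
#' @export
bump_metrics <- function(profile, sector_angles) {
  n <- length(profile)
  stopifnot(length(sector_angles) == n)
  amp <- max(profile) - min(profile)
  if (amp <= .Machine$double.eps * max(abs(profile), 1))
    return(list(amplitude = 0, fwhm = NA_real_, flat = TRUE))
  half <- min(profile) + amp / 2
  pk <- which.max(profile)
  step <- 2 * pi / n
  cross <- function(dir) {
    for (j in seq_len(n - 1)) {
      i0 <- ((pk - 1 + dir * (j - 1)) %% n) + 1
      i1 <- ((pk - 1 + dir * j) %% n) + 1
      if (profile[i1] <= half) {
        frac <- (profile[i0] - half) / (profile[i0] - profile[i1])
        return((j - 1 + frac) * step)
      }
    }
    pi # profile never falls below half-max on this side
  }
  list(amplitude = amp, fwhm = (cross(1) + cross(-1)) * 180 / pi,
       flat = FALSE)
}

#' Convolve a velocity trace with the calcium-indicator kernel
#'
#' Causal convolution with the unit-area double-exponential kernel (rise
#' `tau_on`, decay `tau_off`), used to compare rotational velocity with
#' indicator-filtered fluorescence.
#'
#' @param v velocity trace on a uniform grid.
#' @param dt sampling interval (s).
#' @param tau_on,tau_off kernel time constants (s).
#' @return convolved trace, same length (DC gain 1).
#' @export
convolve_velocity <- function(v, dt, tau_on = 0.13, tau_off = 0.63) {
  k <- indicator_kernel(dt, tau_on, tau_off)
  as.numeric(.causal_convolve(matrix(v, ncol = 1), k, dt))
}

#' Correlation of noduli activity difference with rotational velocity
#'
#' Pearson correlation between the right-minus-left noduli dF/F difference
#' and the indicator-convolved rotational velocity.  With the packaged sign
#' conventions (right nodulus driven by counterclockwise rotation) the
#' correlation is positive.
#'
#' @param dff_left,dff_right noduli dF/F traces.
#' @param v rotational velocity (deg/s) on the same grid.
#' @param dt sampling interval (s).
#' @return Pearson R.
#' @export
noduli_difference_correlation <- function(dff_left, dff_right, v, dt) {
  d <- dff_right - dff_left
  cv <- convolve_velocity(v, dt)
  if (stats::sd(d) == 0 || stats::sd(cv) == 0)
    stop("zero-variance input: correlation undefined")
  stats::cor(d, cv)
}

#' Time-shifted regression of noduli activity on locomotor parameters
#'
#' Ordinary least squares of one nodulus's dF/F on Z-scored rectified
#' rotational velocities (clockwise and counterclockwise) and forward
#' velocity, across a grid of time shifts between response and predictors.
#' Data are first averaged into 25 ms bins.
#'
#' @param dff response trace (one nodulus) on the behavior grid.
#' @param v_rot signed rotational velocity (deg/s).
#' @param v_fwd forward velocity.
#' @param dt sampling interval of the inputs (s).
#' @param shifts time shifts (s), response relative to predictors.
#' @param bin bin width (s).
#' @return data.frame with `shift` and coefficients `ccw` (`[v]+`), `cw`
#'   (`[-v]+`), `fwd`.
#' @export
noduli_regression <- function(dff, v_rot, v_fwd, dt,
                              shifts = seq(-0.375, 0.75, by = 0.025),
                              bin = 0.025) {
  rebin <- function(x) {
    per <- max(1L, round(bin / dt))
    n <- floor(length(x) / per)
    colMeans(matrix(x[seq_len(n * per)], nrow = per))
  }
  y <- rebin(dff)
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  X <- cbind(ccw = zs(rebin(pmax(v_rot, 0))),
             cw = zs(rebin(pmax(-v_rot, 0))),
             fwd = zs(rebin(v_fwd)))
  if (kappa(crossprod(X)) > 1e8)
    warning("predictors are nearly collinear")
  out <- lapply(shifts, function(s) {
    k <- round(s / bin)
    n <- length(y)
    if (k >= 0) { yy <- y[(1 + k):n]; XX <- X[1:(n - k), , drop = FALSE] }
    else { yy <- y[1:(n + k)]; XX <- X[(1 - k):n, , drop = FALSE] }
    co <- stats::coef(stats::lm.fit(cbind(1, XX), yy))[-1]
    data.frame(shift = s, ccw = co[1], cw = co[2], fwd = co[3])
  })
  do.call(rbind, out)
}

# ring positions (1..8) of the occupied glomeruli of a population on one
# bridge side; see .bridge_glomeruli for the layout
.ring_indices <- function(population, side) .bridge_glomeruli(population)[[side]]

# circular shift of a vector by k positions (positive moves content up)
.circ_shift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) x else c(x[(n - k + 1):n], x[1:(n - k)])
}

#' Register protocerebral-bridge frames to the right E-PG peak
#'
#' Per frame, finds the peak of the reference (E-PG) bump among the eight
#' occupied glomeruli of the right bridge half and circularly shifts that
#' ring to place the peak at glomerulus 14; the left half and the second
#' population are shifted by the same offset within their own eight-
#' glomerulus rings, skipping each population's empty glomeruli.  Ties in
#' the peak are broken toward the lowest index (count recorded in the
#' `ties` attribute).
#'
#' @param dff frames x 18 matrix of the population to register.
#' @param reference_dff frames x 18 matrix of the reference E-PG signal.
#' @param population `"EPG"` or `"PEN"`: occupancy map of `dff`.
#' @return registered frames x 18 matrix (empty glomeruli unchanged).
#' @export
register_bridge <- function(dff, reference_dff, population = c("EPG", "PEN")) {
  population <- match.arg(population)
  stopifnot(ncol(dff) == 18, ncol(reference_dff) == 18,
            nrow(dff) == nrow(reference_dff))
  ref_right <- .ring_indices("EPG", "right")      # glomeruli 10..17
  target <- match(14L, ref_right)                  # ring position of glom 14
  occ <- .bridge_glomeruli(population)
  out <- dff
  ties <- 0L
  for (f in seq_len(nrow(dff))) {
    prof <- reference_dff[f, ref_right]
    pk <- which(prof == max(prof))
    if (length(pk) > 1) ties <- ties + 1L
    shift <- target - pk[1]
    for (side in c("left", "right")) {
      idx <- occ[[side]]
      out[f, idx] <- .circ_shift(dff[f, idx], shift)
    }
  }
  attr(out, "ties") <- ties
  out
}

#' Register ellipsoid-body frames to the reference peak
#'
#' Circularly shifts each 16-sector frame so the reference population's
#' peak sits at position 8; the registered population is shifted by the
#' same amount, preserving relative offsets.
#'
#' @param dff frames x 16 matrix to register.
#' @param reference_dff frames x 16 reference (E-PG) matrix.
#' @param target peak position after registration (1-based).
#' @return registered frames x 16 matrix with a `ties` attribute.
#' @export
register_eb <- function(dff, reference_dff, target = 8L) {
  stopifnot(ncol(dff) == 16, ncol(reference_dff) == 16,
            nrow(dff) == nrow(reference_dff))
  out <- dff
  ties <- 0L
  for (f in seq_len(nrow(dff))) {
    pk <- which(reference_dff[f, ] == max(reference_dff[f, ]))
    if (length(pk) > 1) ties <- ties + 1L
    out[f, ] <- .circ_shift(dff[f, ], target - pk[1])
  }
  attr(out, "ties") <- ties
  out
}

#' Velocity-binned two-population bump offsets
#'
#' Sorts registered frames into rotational-velocity bins (width 30 deg/s),
#' averages each population's profile per bin, and reports the offset
#' between the two populations' PVAs (population A minus B), in degrees
#' (ellipsoid body) or glomeruli (bridge, one side); a peak-based offset is
#' computed alongside.
#'
#' @param reg_a,reg_b registered frames (16 columns for `"EB16"`; 18 for
#'   `"PB18"`).
#' @param v rotational velocity per frame (deg/s).
#' @param geometry `"EB16"` or `"PB18"`.
#' @param bin_width bin width (deg/s).
#' @param pop_a,pop_b population occupancy for the bridge geometry.
#' @param min_frames bins with fewer frames are dropped (count reported).
#' @return data.frame with bin edges/centres, frame counts, `pva_offset`,
#'   `peak_offset`, and per-bin mean profiles in the `profiles` attribute.
#' @export
velocity_binned_offsets <- function(reg_a, reg_b, v,
                                    geometry = c("EB16", "PB18"),
                                    bin_width = 30,
                                    pop_a = "PEN", pop_b = "EPG",
                                    min_frames = 5) {
  geometry <- match.arg(geometry)
  lo <- floor(min(v) / bin_width) * bin_width
  hi <- ceiling(max(v) / bin_width) * bin_width
  edges <- seq(lo, hi, by = bin_width)
  which_bin <- findInterval(v, edges, rightmost.closed = TRUE)
  rows <- list(); profs <- list()
  for (b in seq_len(length(edges) - 1)) {
    sel <- which_bin == b
    if (sum(sel) < min_frames) next
    ma <- colMeans(reg_a[sel, , drop = FALSE])
    mb <- colMeans(reg_b[sel, , drop = FALSE])
    if (geometry == "EB16") {
      ang <- (seq_len(16) - 0.5) * 2 * pi / 16
      pa <- pva(ma, ang); pb <- pva(mb, ang)
      off <- .wrap_pi(pa$angle - pb$angle) * 180 / pi
      pkoff <- .wrap_pi((which.max(ma) - which.max(mb)) * 2 * pi / 16) * 180 / pi
    } else {
      ring <- (seq_len(8) - 1) * 2 * pi / 8
      ia <- .ring_indices(pop_a, "right"); ib <- .ring_indices(pop_b, "right")
      pa <- pva(ma[ia], ring); pb <- pva(mb[ib], ring)
      off <- .wrap_pi(pa$angle - pb$angle) * 8 / (2 * pi)
      pkoff <- {
        d <- (which.max(ma[ia]) - which.max(mb[ib])) %% 8
        if (d > 4) d - 8 else d
      }
    }
    rows[[length(rows) + 1]] <-
      data.frame(v_lo = edges[b], v_hi = edges[b + 1],
                 v_mid = (edges[b] + edges[b + 1]) / 2,
                 n = sum(sel), pva_offset = off, peak_offset = pkoff)
    profs[[length(profs) + 1]] <- list(a = ma, b = mb)
  }
  out <- do.call(rbind, rows)
  attr(out, "profiles") <- profs
  out
}

#' Detect turns in a velocity trace
#'
#' Maximal contiguous intervals where the rotational speed exceeds the
#' threshold, with the net heading change over each turn.
#'
#' @param v signed rotational velocity (deg/s), uniform grid.
#' @param t sample times (s).
#' @param threshold speed threshold (deg/s).
#' @param heading optional unwrapped heading (rad) for per-turn changes.
#' @return data.frame with `start`, `end` (indices), `t_start`, `t_end`,
#'   `duration`, and `delta_heading` (rad) when heading is supplied.
#' @export
detect_turns <- function(v, t, threshold = 15, heading = NULL) {
  above <- abs(v) > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  out <- data.frame(start = as.integer(starts[keep]),
                    end = as.integer(ends[keep]))
  if (!nrow(out)) {
    out$t_start <- out$t_end <- out$duration <- numeric(0)
    if (!is.null(heading)) out$delta_heading <- numeric(0)
    return(out)
  }
  out$t_start <- t[out$start]
  out$t_end <- t[out$end]
  out$duration <- out$t_end - out$t_start
  if (!is.null(heading))
    out$delta_heading <- heading[out$end] - heading[out$start]
  out
}

#' Turn-by-turn PVA displacement versus heading change
#'
#' For each detected turn during which the PVA strength stays above the
#' threshold, computes the change in (shortest-arc unwrapped) PVA position
#' and the change in heading, and regresses one on the other.  Turns with
#' any frame-to-frame PVA jump above `max_jump` degrees are discarded as
#' untrackable.
#'
#' @param turns output of [detect_turns()].
#' @param pva_angle PVA angle per frame (rad, wrapped).
#' @param pva_strength PVA strength per frame.
#' @param heading unwrapped heading per frame (rad).
#' @param strength_threshold minimum PVA strength throughout a turn.
#' @param max_jump frame-to-frame jump limit (degrees).
#' @return list with `slope`, `r_squared`, `n_turns`, `n_discarded`, and
#'   the per-turn table `turns` (`delta_heading`, `delta_pva`, degrees).
#' @export
turn_pva_analysis <- function(turns, pva_angle, pva_strength, heading,
                              strength_threshold = 0.025, max_jump = 120) {
  dh <- dp <- numeric(0)
  n_disc <- 0L
  for (i in seq_len(nrow(turns))) {
    idx <- turns$start[i]:turns$end[i]
    s <- pva_strength[idx]
    if (any(is.na(s)) || any(s < strength_threshold)) next
    ang <- unwrap_angle(pva_angle[idx])
    if (length(idx) > 1 && max(abs(diff(ang))) > max_jump * pi / 180) {
      n_disc <- n_disc + 1L
      next
    }
    dh <- c(dh, (heading[idx[length(idx)]] - heading[idx[1]]) * 180 / pi)
    dp <- c(dp, (ang[length(ang)] - ang[1]) * 180 / pi)
  }
  if (length(dh) < 3) stop("fewer than 3 retained turns")
  fit <- stats::lm(dp ~ dh)
  list(slope = unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared,
       n_turns = length(dh), n_discarded = n_disc,
       turns = data.frame(delta_heading = dh, delta_pva = dp))
}

#' Bootstrap test for a difference of means
#'
#' Pooled resampling with replacement preserving the two group sizes; the
#' two-sided p value is the fraction of resampled absolute mean differences
#' at least as large as the observed one.
#'
#' @param sample_a,sample_b numeric samples.
#' @param n_reps resampling repetitions.
#' @param seed RNG seed.
#' @return list with `p_value`, `observed` difference, `n_reps`.
#' @export
bootstrap_mean_diff <- function(sample_a, sample_b, n_reps = 10000, seed = 0) {
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  obs <- mean(sample_a) - mean(sample_b)
  pool <- c(sample_a, sample_b)
  na <- length(sample_a); nb <- length(sample_b)
  diffs <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      a <- sample(pool, na, replace = TRUE)
      b <- sample(pool, nb, replace = TRUE)
      mean(a) - mean(b)
    }, 0)
  })
  list(p_value = mean(abs(diffs) >= abs(obs)), observed = obs,
       n_reps = n_reps)
}
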