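---
title: "Methods: the E-PG/P-EN ring attractor and its analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the E-PG/P-EN ring attractor and its analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyring)
```

# The model

The fly's heading representation lives in a recurrent loop between two
central-complex populations: E-PG ("compass") neurons, whose population
activity forms a single bump on the ellipsoid-body ring that tracks the
fly's heading, and P-EN neurons, split into a left-bridge and a
right-bridge subpopulation, which are conjunctively tuned to heading and
rotational velocity.  `flyring` implements this loop as a firing-rate ring
attractor with three populations:

* 54 E-PG units (27 per protocerebral-bridge side; 3 per glomerulus),
* 9 left P-EN units and 9 right P-EN units (1 per glomerulus).

The rates obey threshold-linear dynamics,

$$\tau \,\dot E(\theta_i) = -E(\theta_i) +
  \Big[\alpha \sum_k P_l(\theta_k)\,K_l(\theta_i - \theta_k) +
       \alpha \sum_k P_r(\theta_k)\,K_r(\theta_i - \theta_k)\Big]_+$$

$$\tau_p \,\dot P_{l}(\theta_k) = -P_l(\theta_k) +
  \Big[\tfrac{\alpha}{3} \textstyle\sum_{m \in \mathcal N_k} E(\theta_m)
   - \tfrac{\beta}{N} \textstyle\sum_n E(\theta_n) + 1 + v_+\Big]_+$$

and mirror-symmetrically for $P_r$ with $v_-$, where $v_+ = [v]_+$ and
$v_- = [-v]_+$ are the rectified angular velocity converted to drive units,
$\mathcal N_k$ is the set of three E-PG units sharing P-EN $k$'s
glomerulus, and $N = 54$.  The kernels are mirror-image von Mises
densities displaced by the anatomical E-PG/P-EN offset
$\Delta = 35^\circ$:

$$K_l(\theta) = w\, f(\theta \mid +\Delta, \kappa), \qquad
  K_r(\theta) = w\, f(\theta \mid -\Delta, \kappa), \qquad \kappa = 12 .$$

Defaults: $\tau = 80$ ms, $\tau_p = 65$ ms, $\alpha = 10$, $\beta = 25$,
bias $+1$.  Each bridge side's feedback pushes the bump in its own
direction; at rest the two pushes cancel and a single stationary bump
persists, while an imbalance of $v_+$ vs. $v_-$ rotates it.  The loop's
saturation velocity is set by the structural shift and the two time
constants, $\nu_\text{sat} = \Delta / (\tau + \tau_p) \approx
241^\circ/\mathrm{s}$.

## Design choices in the reconstruction

Three aspects of the loop are under-determined by its published
description, and the package fixes them as follows.

**Both P-EN populations project to every E-PG.**  If each bridge side's
E-PGs received only their own side's P-ENs, the two half-loops would
decouple: the only cross-talk (uniform inhibition) carries no angular
information, one side dies by competition, and no velocity response
exists.  A unique bump shared by both bridge sides requires the coupled
ring written above, which is also what the anatomy of the ellipsoid body
suggests: P-EN axon tiles overlap E-PG dendritic wedges regardless of
bridge side.

**Shifted-only kernels.**  We examined kernels with an additional central
(same-angle) lobe at a range of weights.  Any appreciable central lobe
anchors the bump to its current position: after slope-1 calibration the
transfer curve then saturates at 120–205$^\circ$/s, incompatible with the
closed form $\Delta/(\tau+\tau_p)$ and with faithful tracking up to
$200^\circ$/s.  With the pure shifted kernels the measured plateau is
$\approx 250^\circ$/s, within 4% of the closed form, and the transfer
curve is near-linear ($L \approx 0.95$) over the whole tracked range.

**Weight normalization `w_scale`.**  The overall scale of the
P-EN$\to$E-PG weights sets where the loop operates between two failure
modes: too small and no bump is self-sustained, too large and the active
set collapses to a single winner pinned to the lattice.  The scale is not
recoverable from the printed equations (taken literally they have no
bounded bump).  `w_scale = 0.008` was fixed once, by requiring the
documented operating regime — a single stationary bump at rest, graded
P-EN activity spanning several glomeruli, near-linear integration, and
saturation near the closed form — and is not meant to be tuned per
analysis.

**Velocity gain.**  The drive units of $v_\pm$ are arbitrary in the
equations; `velocity_gain = 0.0073` (drive units per $^\circ$/s) was
calibrated once by bisection so that the low-velocity transfer slope
$\gamma_\text{lin}$ equals 1 (`calibrate_velocity_gain()` reproduces the
procedure; on the default circuit it yields $\gamma_\text{lin} = 0.998$).

## Numerics

The integrator is exponential Euler at `dt = 0.5` ms (compiled, in
`src/`): each rate decays exactly toward its rectified input, which is
frozen over the step.  Velocity samples are held constant over their
sampling interval (zero-order hold; sample $i$ covers the interval ending
at $t_i$, and `integrated_heading()` uses the same convention).  Local
step error is second order and halving `dt` changes trajectories
negligibly (tested).  Divergent parameter sets (e.g. `beta = 0`) are
caught against a configurable rate ceiling.  A simulation starts from a
deterministic "seeded bump" (von Mises-shaped E-PG rates plus a small
floor) and discards a 1 s zero-input settle window.

## Model metrics

* **Transfer curve**: for each constant input, the slope of the unwrapped
  bump position over the final 80% of the window (the first 20% absorbs
  the onset transient).
* **Sticking threshold**: smallest input whose mean bump speed exceeds
  1$^\circ$/s over the final 80% of a 30 s window, on a grid of at most
  2.5$^\circ$/s.  The default circuit yields 10$^\circ$/s; the
  pinning–tracking trade-off behind this number is discussed under
  *Limitations*.
* **Saturation**: onset where tracking falls below 90% (considering only
  inputs above half the predicted $\nu_\text{sat}$, so the sticking region
  is not misread as saturation), the largest faithfully tracked input, and
  the plateau bump velocity compared with $\Delta/(\tau+\tau_p)$.
* **Linearity** $L = \gamma_\text{sat}/\gamma_\text{lin}$: output/input
  ratio at saturation onset over the low-velocity slope (fit over
  20–80$^\circ$/s by default).
* **Diffusion of the integration error**: 20 independent
  Ornstein–Uhlenbeck tracks of 1000 s drive the circuit; the variance
  across tracks of (integrated input $-$ bump position) is fitted with
  $V(t) = \sigma_0^2 + 2 D t$ for $t \ge 10$ s.  Weights follow the
  stated uncertainty $V\sqrt{2/(n_s-1)}$, but evaluated on a first-pass
  unweighted fit: weights taken from the noisy curve itself correlate
  with its fluctuations and bias $D$ low (visible in the Brownian
  recovery test).
* **Input–output lag**: cross-correlation peak (parabolically
  interpolated) between the input and the bump velocity, the latter from
  first differences smoothed with a centred 50 ms boxcar to suppress
  lattice chatter.
* **Efficacy sweep**: steady-state bump amplitude (peak minus mean of the
  time-averaged E-PG profile) as the P-EN$\to$E-PG weights are scaled by
  an efficacy in $[0,1]$, emulating progressive synaptic block.

# Synthetic data

The generators produce every input the analysis stages consume, with
known ground truth:

* **Velocity tracks**: exact-discretization Ornstein–Uhlenbeck process,
  $v_{n+1} = v_n e^{-\Delta t/\tau} + \sigma\sqrt{1 - e^{-2\Delta t/\tau}}\,z_n$,
  started from the stationary law; defaults $\tau = 120$ ms,
  $\sigma = 50^\circ$/s at 50 Hz match the angular-velocity statistics of
  walking flies.
* **Behavior**: heading is the integrated track; forward speed is an
  independent mean-reverting process floored at zero, so the
  forward–rotational correlation is $\approx 0$ by construction.
* **ROI fluorescence**: a von Mises bump (default FWHM 90$^\circ$)
  centred at the heading (E-PG) or heading plus a velocity-proportional
  lead (P-EN, default 0.12$^\circ$ per $^\circ$/s, i.e. $\approx
  20^\circ$ at 165$^\circ$/s), amplitude growing with speed, sampled into
  16 ellipsoid-body sectors or an 18-glomerulus bridge layout with the
  empty-glomerulus convention (E-PGs occupy the inner 16, P-ENs the outer
  16).  Noduli are two scalar ROIs driven by rectified velocity through a
  saturating nonlinearity (right nodulus by counterclockwise rotation).
  All signals pass through the calcium-indicator kernel and receive
  additive Gaussian noise.
* **Indicator kernel**: implemented as
  $e^{-t/\tau_\text{off}} - e^{-t/\tau_\text{on}}$ for $t \ge 0$ (rise
  $\tau_\text{on} = 0.13$ s, decay $\tau_\text{off} = 0.63$ s), normalized
  to unit area.  The same expression is sometimes printed with the
  exponents swapped, which is negative for $t > 0$; the orientation used
  here is the standard double-exponential impulse response, and
  downstream correlations are invariant to positive scaling.
* **Conjunctive spike trains**: inhomogeneous Poisson by thinning, rate
  $= \text{baseline} + \text{sigmoid}(v(t - \text{lag})) \cdot
  \text{vonMises}(\text{heading}(t - \text{lag}))$, default lag 130 ms.
  Defaults (baseline 2 Hz, velocity range 1–15 Hz, slope 0.08 per
  $^\circ$/s, heading concentration 2) give an observed velocity
  modulation of $\approx 4$ Hz and mean rates of $\approx 4$ Hz,
  consistent with P-EN recordings.

**What the generators do not emulate**: photon statistics, motion
artifacts, slow drift, bleed-through, or the bout structure of real
walking.  One consequence matters for recovery tests: under
120 ms-correlated drive the indicator kernel (and the 1 s rate smoothing
of the spike pipeline) averages velocity-locked signals to near zero, so
the velocity-binned P-EN/E-PG offset and the sigmoid velocity tuning are
recovered from slower, sustained-turning tracks ($\tau = 1.5$ s),
emulating the seconds-long rotations of real flies, while the
spike-triggered average — which needs sharp velocity transients — uses
the fast track.  Passing recovery tests therefore demonstrate estimator
correctness under the stated conditions, not robustness to every feature
of real recordings.

# Analysis conventions

* **$\Delta F/F$**: per ROI, $F_0$ is the mean of the lowest 10% of
  frames; the stored series is $F/F_0 - 1$ (the plain ratio is `dff + 1`).
  Optional Savitzky–Golay smoothing (11 frames, order 3) matches the
  behavioral filtering.
* **PVA**: activities are floored at zero before the vector sum, keeping
  the strength in $[0,1]$ (adding uniform mass can then only reduce it).
* **Registration**: bridge frames are registered by the right E-PG peak
  to glomerulus 14 (ties to the lowest index, counted); both halves and
  the second population shift by the same offset within their own
  8-glomerulus rings, skipping each population's empty glomeruli.
  Ellipsoid-body frames register the reference peak to position 8 of 16.
  Registration only permutes ROIs, so per-frame totals are preserved
  exactly.
* **Binning**: velocity-binned offsets use 30$^\circ$/s bins; sigmoid
  velocity tuning 12$^\circ$/s (12.5$^\circ$/s in conditional analyses);
  heading 32 bins of 11.25$^\circ$; occupancy floors of 50 bins (1 s) for
  velocity maps and 8 bins (0.2 s) for heading maps.
* **Turn analysis**: turns are maximal periods with speed
  $> 15^\circ$/s; only turns whose PVA strength stays above 0.025
  throughout are kept; within a turn the PVA is unwrapped shortest-arc,
  and a turn containing any frame-to-frame jump above 120$^\circ$ is
  discarded as untrackable.  $\Delta$PVA is regressed on
  $\Delta$heading by ordinary least squares.
* **Shuffle nulls**: the spike train is chopped into 1 s fragments
  (0.5 s for short epochs), reassembled in random order, and the indices
  recomputed; significance is the 95th percentile of 1000 shuffles.  The
  false-positive rate of this criterion on untuned cells is checked to
  lie in [2%, 9%].
* **Smoothing**: spike rates use a 1 s Gaussian window specified by its
  half-width at half maximum (0.3 s default; 0.35 s supported — both
  values appear in common use); membrane potential uses a zero-phase
  4th-order Butterworth low-pass at 50 Hz (the order is a package choice;
  only the corner frequency is standard).
* **Sigmoid fits** use weighted nonlinear least squares (bin counts as
  weights), five starting points spanning both slope signs, and bound the
  inflexion to the observed velocity range; the rotation tuning index is
  the weighted $R^2$ of this fit (weights consistent with the fit; the
  unweighted alternative gives similar values on synthetic cells).
* **Walking exclusion** is available as a threshold on combined
  rotational and forward speed; closed-loop heading is handled as a
  declared transform on input ($2\pi$ minus the stripe azimuth), never
  inside the fits.

# Problem sizes

The test suite exercises the full-scale diffusion ensemble (20 tracks of
1000 s), a 500 s lag measurement, 30 s transfer-curve windows, a
200-replicate shuffle-null calibration with 100 shuffles each, and an
8-cell tuning-recovery grid on 900 s of behavior; these sizes were chosen
so the whole suite completes in a few minutes while keeping every
estimator in its asymptotic regime.

# Limitations

* The reconstruction is slightly less lattice-pinned than the original
  implementation appears to have been: the sticking threshold measures
  10$^\circ$/s (vs. a reported 15$^\circ$/s), the bump-velocity lag
  $\approx 22$ ms (vs. $\sim 30$ ms), and the integration-error diffusion
  coefficient $\approx 1.1 \times 10^{-3}$ rad$^2$/s (vs.
  $1.82 \times 10^{-3}$).  These three quantities move together: every
  kernel or gain change that deepens pinning enough to raise them also
  drops the faithful-tracking range below 200$^\circ$/s and breaks the
  near-linearity of the transfer curve, which are the model's central
  claims.  The packaged operating point keeps the latter and accepts the
  former.
* The $\sigma_0^2$ intercept of the diffusion fit is an extrapolation
  from $t \ge 10$ s where $2Dt \gg \sigma_0^2$; its sign and magnitude
  are unstable at desk-scale ensembles.
* Rates are in arbitrary model units throughout; only ratios, angles and
  times are meaningful.
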