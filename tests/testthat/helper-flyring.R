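# Shared fixtures: default parameters and a cached topology; short
# simulations reuse these to keep the suite fast.

default_params <- circuit_params()
default_topo <- build_topology(default_params)

quick_sim <- function(v, duration, params = default_params,
                      topology = default_topo, ...) {
  simulate_circuit(params, constant_velocity_input(v, duration),
                   topology = topology, ...)
}

# unwrapped bump angle (degrees) of a simulation
bump_deg <- function(sim) unwrap_angle(atan2(sim$bump_sin, sim$bump_cos)) * 180 / pi

# modified Bessel function of the first kind, order 0/1, by its power
# series: an oracle independent of base R's besselI
bessel_series <- function(x, nu, terms = 60) {
  k <- 0:terms
  sum((x / 2)^(2 * k + nu) / (factorial(k) * factorial(k + nu)))
}

# homogeneous Poisson spike train on [0, duration]
poisson_spikes <- function(rate, duration, seed) {
  set.seed(seed)
  n <- rpois(1, rate * duration)
  spike_train(sort(runif(n, 0, duration)), duration, source = "synthetic")
}
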