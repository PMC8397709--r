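# Shared fixtures: everything is generated in code at test time.

fixture_geometry <- function(n = 25, seed = 1) {
  make_islet_geometry(n, islet_radius = 60, min_spacing = 12, seed = seed)
}

quick_sim <- function(level, seed, geometry = fixture_geometry(), ...) {
  simulate_recording(geometry, sim_params(level, seed = seed, ...))
}

# Independent oracle: Pearson correlation from the textbook
# covariance / (sd * sd) formula, computed without stats::cor.
pearson_formula <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# Independent oracle: continuous-time boxcar convolution of the calcium
# transient kernel (numerical integration), used to predict the half-max
# crossing the detector should find on a smoothed noiseless transient.
smoothed_kernel_value <- function(t, rise, decay, width_s) {
  k <- function(u) ifelse(u > 0, {
    t_peak <- rise * log1p(decay / rise)
    peak <- (1 - exp(-t_peak / rise)) * exp(-t_peak / decay)
    (1 - exp(-u / rise)) * exp(-u / decay) / peak
  }, 0)
  vapply(t, function(ti) {
    stats::integrate(k, ti - width_s / 2, ti + width_s / 2,
                     rel.tol = 1e-9)$value / width_s
  }, numeric(1))
}

smoothed_half_max_time <- function(rise, decay, width_s) {
  peak_t <- stats::optimize(function(t) -smoothed_kernel_value(t, rise, decay, width_s),
                            c(0, width_s + 10 * rise + 2 * decay))$minimum
  peak_v <- smoothed_kernel_value(peak_t, rise, decay, width_s)
  stats::uniroot(function(t) smoothed_kernel_value(t, rise, decay, width_s) - peak_v / 2,
                 c(-width_s, peak_t), tol = 1e-8)$root
}
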