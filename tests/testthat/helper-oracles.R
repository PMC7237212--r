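# Independent oracles used across the suite. These deliberately avoid the
# package's own fast paths: brute-force loops, closed forms and direct sums.

# Brute-force space-time convolution of a movie with an LN unit's separable
# kernel (triple sum over x, y and past frames), with the package's Off
# negation and rectifier applied on top. O(nx ny nt^2) — tiny movies only.
brute_ln_response <- function(movie, unit, t_support = 0.5) {
  d <- dim(movie$values)
  pc <- movie_pixel_centers(movie)
  dt <- 1 / movie$frame_rate
  n_lags <- round(t_support * movie$frame_rate)
  g <- numeric(d[3])
  for (t in seq_len(d[3])) {
    acc <- 0
    for (l in 0:min(n_lags, t - 1)) {
      tk <- eval_temporal_kernel(unit$temporal, l * dt)
      for (i in seq_len(d[1])) {
        for (j in seq_len(d[2])) {
          fv <- eval_spatial_kernel(unit$sigma,
                                    pc$x[i] - unit$center[1],
                                    pc$y[j] - unit$center[2])
          s <- movie$values[i, j, t - l]
          if (unit$polarity == "off") s <- -s
          acc <- acc + s * fv * tk * movie$pixel_pitch^2 * dt
        }
      }
    }
    g[t] <- acc
  }
  list(drive = g, values = pmax(0, unit$m * g - unit$theta))
}

# Direct upper-tail Poisson sum P(X >= r) = 1 - sum_{k < r} e^-l l^k / k!
poisson_tail_oracle <- function(r, lambda) {
  if (r == 0) return(1)
  1 - sum(exp(-lambda) * lambda^(0:(r - 1)) / factorial(0:(r - 1)))
}

# Closed-form solutions of the depression ODE dw/dt = (1-w)/tau - a(w-wmin) r
# for r = 0 (pure recovery) and constant r.
synapse_recovery_closed <- function(w0, t, tau) 1 - (1 - w0) * exp(-t / tau)

synapse_constant_r_closed <- function(w0, t, tau, a, wmin, r) {
  k <- 1 / tau + a * r
  wstar <- (1 / tau + a * wmin * r) / k
  wstar + (w0 - wstar) * exp(-k * t)
}

# Small random movie fixture
random_movie <- function(nx = 10, ny = 10, nt = 20, seed = 1, pitch = 1) {
  set.seed(seed)
  vals <- array(runif(nx * ny * nt, -1, 1), dim = c(nx, ny, nt))
  stimulus_movie(vals, pixel_pitch = pitch, frame_rate = 60,
                 origin = c(-nx / 2 * pitch, -ny / 2 * pitch))
}

# First-occurrence scan (novelty oracle)
first_occurrence_scan <- function(locs) {
  seen <- c()
  out <- integer(length(locs))
  for (i in seq_along(locs)) {
    out[i] <- as.integer(!(locs[i] %in% seen))
    seen <- c(seen, locs[i])
  }
  out
}

# Compact default circuit shared by circuit-level tests (calibration cached
# once per test run)
test_circuit <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- calibrate_circuit(circuit_config())
    cached
  }
})
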