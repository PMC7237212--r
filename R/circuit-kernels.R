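#' Temporal kernel of an LN unit
#'
#' Difference-of-gamma-like temporal filter
#' \deqn{T(t) = (t/\tau_1)^{n_1} e^{-n_1(t/\tau_1 - 1)} -
#'              b\,(t/\tau_2)^{n_2} e^{-n_2(t/\tau_2 - 1)}}
#' with `T(t) = 0` for `t < 0` (causality). The first (positive) lobe peaks
#' at exactly `t = tau1` with value 1.
#'
#' @param params list with `tau1`, `n1`, `tau2`, `n2`, `b` (times in
#'   seconds, exponents dimensionless).
#' @param t time(s) since stimulus, seconds; vectorized.
#' @return kernel value(s).
#' @export
eval_temporal_kernel <- function(params, t) {
  stopifnot(params$tau1 > 0, params$tau2 > 0, params$n1 > 0, params$n2 > 0)
  out <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  out[pos] <-
    (tp / params$tau1)^params$n1 *
      exp(-params$n1 * (tp / params$tau1 - 1)) -
    params$b * (tp / params$tau2)^params$n2 *
      exp(-params$n2 * (tp / params$tau2 - 1))
  out
}

#' Spatial kernel of an LN unit
#'
#' Isotropic Gaussian `exp(-(x^2 + y^2) / (2 sigma^2))` in center-relative
#' coordinates (degrees).
#'
#' @param sigma Gaussian width, degrees.
#' @param x,y center-relative coordinates, degrees; vectorized.
#' @export
eval_spatial_kernel <- function(sigma, x, y) {
  stopifnot(sigma > 0)
  exp(-(x^2 + y^2) / (2 * sigma^2))
}

#' Construct an LN unit
#'
#' A linear-nonlinear element: the stimulus is convolved with a separable
#' space-time kernel `F(x,y) T(t)` and passed through a half-wave rectifier
#' `N(g) = max(0, m g - theta)`. Off polarity means the stimulus contrast is
#' negated before convolution, so darkening drives the unit positively.
#'
#' @param center `(x, y)` of the receptive-field center, degrees.
#' @param sigma spatial Gaussian width, degrees.
#' @param temporal temporal-kernel parameter list (`tau1`, `n1`, `tau2`,
#'   `n2`, `b`).
#' @param m,theta rectifier gain and threshold.
#' @param polarity `"off"` (the only supported polarity: both model inputs
#'   are Off-type).
#' @return an object of class `ln_unit`.
#' @export
ln_unit <- function(center, sigma, temporal, m = 1, theta = 0,
                    polarity = "off") {
  stopifnot(sigma > 0, m >= 0, polarity == "off")
  structure(list(center = as.numeric(center), sigma = sigma,
                 temporal = temporal, m = m, theta = theta,
                 polarity = polarity),
            class = "ln_unit")
}

#' Rate trace
#'
#' Nonnegative firing-rate samples on a regular time grid; the linear
#' (pre-rectification) drive is kept alongside when available.
#'
#' @param values nonnegative rate samples.
#' @param dt sample interval, seconds.
#' @param drive optional pre-rectification drive `g(t)`.
#' @export
rate_trace <- function(values, dt, drive = NULL) {
  stopifnot(dt > 0)
  structure(list(values = values, dt = dt, drive = drive),
            class = "rate_trace")
}

#' Response of an LN unit to a stimulus movie
#'
#' Computes the discrete space-time convolution of the (sign-adjusted)
#' stimulus with the separable kernel, approximating the continuous integral
#' with pixel-area and frame-interval weights, then applies the rectifier.
#' The spatial kernel is truncated at `spatial_cutoff * sigma` and the
#' temporal kernel at `t_support` seconds; pixels outside the movie field
#' are gray (contribute zero).
#'
#' Sign convention: for Off units the stimulus contrast is negated before
#' convolution, so darkening contributes positive linear drive. Note that
#' the default temporal kernels, being fits to measured alpha-RGC
#' receptive fields, are themselves biphasic; the combination of the two
#' conventions fixes the model's response phase (see the methods
#' vignette for the alternatives considered).
#'
#' @param movie a [stimulus_movie()]; its sampling should be finer than
#'   `sigma / 2`.
#' @param unit an [ln_unit()].
#' @param t_support temporal kernel support, seconds.
#' @param spatial_cutoff spatial truncation radius in units of `sigma`.
#' @return a [rate_trace()] (with the drive `g(t)` attached).
#' @export
ln_response <- function(movie, unit, t_support = 0.5, spatial_cutoff = 3) {
  d <- dim(movie$values)
  if (d[3] < 1) stop("movie must contain at least one frame")
  if (movie$pixel_pitch > unit$sigma / 2) {
    warning("movie pixel pitch is coarser than sigma / 2; ",
            "the spatial integral may be inaccurate")
  }
  pc <- movie_pixel_centers(movie)
  cut <- spatial_cutoff * unit$sigma
  sx <- which(abs(pc$x - unit$center[1]) <= cut)
  sy <- which(abs(pc$y - unit$center[2]) <= cut)
  dt <- 1 / movie$frame_rate
  nt <- d[3]
  if (length(sx) == 0 || length(sy) == 0) {
    return(rate_trace(numeric(nt), dt, drive = numeric(nt)))
  }
  fx <- exp(-(pc$x[sx] - unit$center[1])^2 / (2 * unit$sigma^2))
  fy <- exp(-(pc$y[sy] - unit$center[2])^2 / (2 * unit$sigma^2))
  fw <- as.vector(outer(fx, fy)) * movie$pixel_pitch^2
  sub <- movie$values[sx, sy, , drop = FALSE]
  dim(sub) <- c(length(sx) * length(sy), nt)
  a <- as.numeric(crossprod(sub, fw))
  if (unit$polarity == "off") a <- -a
  n_lags <- round(t_support * movie$frame_rate)
  tk <- eval_temporal_kernel(unit$temporal, (0:n_lags) / movie$frame_rate)
  g <- numeric(nt)
  for (l in 0:min(n_lags, nt - 1)) {
    idx <- (l + 1):nt
    g[idx] <- g[idx] + tk[l + 1] * a[idx - l] * dt
  }
  rate_trace(pmax(0, unit$m * g - unit$theta), dt, drive = g)
}
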