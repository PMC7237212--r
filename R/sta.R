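#' Spike-triggered average from a checkerboard run
#'
#' Averages the stimulus segments preceding each spike: lag 0 is the frame
#' containing the spike, lag `l` the frame `l` steps earlier. Spikes in the
#' first `n_lags` frames (whose history is incomplete) are skipped; when
#' several spikes fall in one frame the frame's history enters the average
#' once per spike.
#'
#' @param spike_times spike times, seconds, on the movie's clock.
#' @param movie the checkerboard [stimulus_movie()].
#' @param n_lags number of pre-spike lags (default 30, i.e. 500 ms at
#'   60 Hz).
#' @return an object of class `sta`: list with `values` (array
#'   `[nx, ny, n_lags + 1]`, contrast units), `n_spikes`, `n_lags`,
#'   `lag_step` (s), plus the movie geometry (`pixel_pitch`, `origin`).
#' @export
compute_sta <- function(spike_times, movie, n_lags = 30) {
  d <- dim(movie$values)
  frames <- floor(spike_times * movie$frame_rate) + 1
  frames <- frames[frames > n_lags & frames <= d[3]]
  if (length(frames) == 0) {
    stop("no usable spikes after the first n_lags frames")
  }
  mat <- movie$values
  dim(mat) <- c(d[1] * d[2], d[3])
  out <- array(0, dim = c(d[1], d[2], n_lags + 1))
  for (l in 0:n_lags) {
    out[, , l + 1] <- rowSums(mat[, frames - l, drop = FALSE]) /
      length(frames)
  }
  structure(list(values = out, n_spikes = length(frames), n_lags = n_lags,
                 lag_step = 1 / movie$frame_rate,
                 pixel_pitch = movie$pixel_pitch, origin = movie$origin),
            class = "sta")
}

#' Space-time separation of an STA by singular value decomposition
#'
#' Unfolds the STA into a (space x lag) matrix and decomposes it into a sum
#' of rank-1 terms, each the outer product of a purely spatial map and a
#' purely temporal course, ordered by decreasing contribution to the total
#' variance. Typically the first term captures the receptive-field center
#' and the second the surround.
#'
#' Sign convention: the SVD sign ambiguity is resolved per component so
#' that the temporal course's largest-magnitude extremum is negative (the
#' natural orientation for Off cells, which dominate these recordings);
#' the spatial map's sign is adjusted to compensate.
#'
#' @param sta an [compute_sta()] result.
#' @param n_components number of components to return.
#' @return an object of class `sta_decomposition`: list of `components`
#'   (each with `spatial` matrix, `temporal` vector, `singular_value`,
#'   `variance_explained`) plus `singular_values` (all of them).
#' @export
svd_separate <- function(sta, n_components = 2) {
  d <- dim(sta$values)
  m <- sta$values
  dim(m) <- c(d[1] * d[2], d[3])
  if (!all(is.finite(m))) stop("STA contains non-finite values")
  s <- svd(m)
  var_frac <- s$d^2 / sum(s$d^2)
  n_components <- min(n_components, length(s$d))
  comps <- lapply(seq_len(n_components), function(k) {
    spat <- matrix(s$u[, k], d[1], d[2])
    temp <- s$v[, k]
    ext <- which.max(abs(temp))
    if (temp[ext] > 0) {
      temp <- -temp
      spat <- -spat
    }
    list(spatial = spat, temporal = temp, singular_value = s$d[k],
         variance_explained = var_frac[k])
  })
  structure(list(components = comps, singular_values = s$d,
                 lag_step = sta$lag_step, pixel_pitch = sta$pixel_pitch,
                 origin = sta$origin),
            class = "sta_decomposition")
}

#' Write an STA decomposition as CSV (one row per component element)
#'
#' @param dec an [svd_separate()] result.
#' @param path output path.
#' @export
write_sta_decomposition <- function(dec, path) {
  rows <- lapply(seq_along(dec$components), function(k) {
    cp <- dec$components[[k]]
    rbind(
      data.frame(component = k, kind = "temporal",
                 index = seq_along(cp$temporal) - 1, value = cp$temporal,
                 singular_value = cp$singular_value,
                 variance_explained = cp$variance_explained),
      data.frame(component = k, kind = "spatial",
                 index = seq_along(as.vector(cp$spatial)) - 1,
                 value = as.vector(cp$spatial),
                 singular_value = cp$singular_value,
                 variance_explained = cp$variance_explained))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
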