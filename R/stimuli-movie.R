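#' Stimulus movies
#'
#' A stimulus movie is a space-time field of Weber contrast values sampled on
#' a regular pixel grid: 0 is the gray background, -1 full black and +1 full
#' white. Pixel `(i, j)` covers the half-open square
#' `[x0 + (i-1) * pitch, x0 + i * pitch) x [y0 + (j-1) * pitch, y0 + j * pitch)`
#' with `(x0, y0)` the lower-left corner of the field in degrees of visual
#' angle (x = azimuth, y = elevation). Frame `k` shows the scene at time
#' `(k - 1) / frame_rate`.
#'
#' @param values numeric array `[nx, ny, nt]` of contrasts in `[-1, 1]`.
#' @param pixel_pitch degrees per sample.
#' @param frame_rate frames per second.
#' @param origin lower-left corner `(x, y)` of the field, degrees.
#' @return an object of class `stimulus_movie`.
#' @export
stimulus_movie <- function(values, pixel_pitch = 1, frame_rate = 60,
                           origin = c(0, 0)) {
  stopifnot(length(dim(values)) == 3L, pixel_pitch > 0, frame_rate > 0,
            dim(values)[3] >= 1L)
  rng <- range(values)
  if (rng[1] < -1 - 1e-9 || rng[2] > 1 + 1e-9) {
    stop("contrast values must lie in [-1, 1]")
  }
  structure(
    list(values = values, pixel_pitch = pixel_pitch, frame_rate = frame_rate,
         origin = as.numeric(origin)),
    class = "stimulus_movie"
  )
}

#' @export
print.stimulus_movie <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<stimulus_movie> %d x %d px (%.3g deg/px), %d frames @ %g Hz (%.3g s)\n",
    d[1], d[2], x$pixel_pitch, d[3], x$frame_rate, d[3] / x$frame_rate))
  invisible(x)
}

#' Frame times of a movie
#' @param movie a `stimulus_movie`.
#' @return numeric vector of frame onset times in seconds.
#' @export
movie_times <- function(movie) {
  (seq_len(dim(movie$values)[3]) - 1) / movie$frame_rate
}

#' Pixel-center coordinates of a movie
#' @param movie a `stimulus_movie`.
#' @return list with components `x` and `y` (degrees).
#' @export
movie_pixel_centers <- function(movie) {
  d <- dim(movie$values)
  p <- movie$pixel_pitch
  list(x = movie$origin[1] + (seq_len(d[1]) - 0.5) * p,
       y = movie$origin[2] + (seq_len(d[2]) - 0.5) * p)
}

# Field geometry helper: choose an origin/size whose pixel grid covers
# [xlim, ylim], snapped outward to whole pixels.
field_geometry <- function(xlim, ylim, pixel_pitch) {
  x0 <- floor(xlim[1] / pixel_pitch) * pixel_pitch
  y0 <- floor(ylim[1] / pixel_pitch) * pixel_pitch
  nx <- ceiling((xlim[2] - x0) / pixel_pitch - 1e-9)
  ny <- ceiling((ylim[2] - y0) / pixel_pitch - 1e-9)
  list(origin = c(x0, y0), nx = max(1L, as.integer(nx)),
       ny = max(1L, as.integer(ny)))
}

# Logical pixel mask of a disk: a pixel belongs to the disk iff its center
# lies within the radius (no anti-aliasing, so pixel counts are exactly
# checkable against a brute-force rasterization).
disk_mask <- function(cx, cy, radius, px, py) {
  if (radius <= 0) {
    return(matrix(FALSE, length(px), length(py)))
  }
  dx2 <- (px - cx)^2
  dy2 <- (py - cy)^2
  outer(dx2, dy2, `+`) <= radius^2
}

#' Looming-stimulus movie
#'
#' A dark disk expands linearly from 0 deg to `final_diameter` at
#' `speed` deg/s, remains stationary for `hold` seconds, then the field
#' returns to gray. Total stimulus duration is
#' `final_diameter / speed + hold`.
#'
#' @param center disk center `(x, y)` in degrees.
#' @param final_diameter final disk diameter, degrees.
#' @param speed linear expansion rate of the diameter, deg/s.
#' @param hold stationary period after full expansion, seconds.
#' @param contrast Weber contrast of the disk (negative for dark disks).
#' @param screen_bounds optional `list(x = c(min, max), y = c(min, max))`;
#'   when given, the movie covers the whole screen and a disk leaving the
#'   screen is an error. By default the field snugly covers the final disk.
#' @param pixel_pitch,frame_rate sampling of the movie.
#' @return a [stimulus_movie()].
#' @export
loom_movie <- function(center = c(0, 0), final_diameter = 30, speed = 60,
                       hold = 0.25, contrast = -1, screen_bounds = NULL,
                       pixel_pitch = 1, frame_rate = 60) {
  stopifnot(final_diameter > 0, speed > 0, hold >= 0,
            abs(contrast) <= 1)
  duration <- final_diameter / speed + hold
  n_frames <- max(1L, round(duration * frame_rate))
  r_final <- final_diameter / 2
  geom <- movie_geom_for_disk(center, r_final, screen_bounds, pixel_pitch)
  px <- geom$origin[1] + (seq_len(geom$nx) - 0.5) * pixel_pitch
  py <- geom$origin[2] + (seq_len(geom$ny) - 0.5) * pixel_pitch
  vals <- array(0, dim = c(geom$nx, geom$ny, n_frames))
  for (k in seq_len(n_frames)) {
    t <- (k - 1) / frame_rate
    r <- min(speed * t, final_diameter) / 2
    check_disk_on_screen(center, r, screen_bounds, k)
    if (r > 0) {
      vals[, , k][disk_mask(center[1], center[2], r, px, py)] <- contrast
    }
  }
  stimulus_movie(vals, pixel_pitch, frame_rate, geom$origin)
}

movie_geom_for_disk <- function(center, r_max, screen_bounds, pixel_pitch) {
  if (is.null(screen_bounds)) {
    field_geometry(center[1] + c(-r_max, r_max),
                   center[2] + c(-r_max, r_max), pixel_pitch)
  } else {
    field_geometry(screen_bounds$x, screen_bounds$y, pixel_pitch)
  }
}

check_disk_on_screen <- function(center, r, screen_bounds, frame) {
  if (is.null(screen_bounds) || r <= 0) return(invisible())
  if (center[1] - r < screen_bounds$x[1] || center[1] + r > screen_bounds$x[2] ||
      center[2] - r < screen_bounds$y[1] || center[2] + r > screen_bounds$y[2]) {
    stop(sprintf("disk exceeds screen bounds at frame %d", frame))
  }
  invisible()
}

#' Other figural stimulus movies
#'
#' Renders the non-looming figural stimuli, all with parameters mirroring the
#' standard looming stimulus so that their durations match:
#' \describe{
#'   \item{contract_dark / contract_white}{a disk shrinks from
#'     `final_diameter` to 0 deg at `speed` deg/s; the stationary period of
#'     `hold` seconds is at the end of the contraction.}
#'   \item{expand_white}{a bright disk expanding like the looming stimulus.}
#'   \item{dimming}{a disk of fixed `final_diameter` whose contrast ramps
#'     linearly from 0 to `contrast` over the whole duration.}
#'   \item{moving_dark}{a dark disk of `final_diameter` translating at
#'     `speed` deg/s along a straight path centred on `center` (direction
#'     `direction` radians); the path length is `speed * duration` so the
#'     traversal takes the looming duration.}
#' }
#'
#' @param kind one of `"contract_dark"`, `"contract_white"`,
#'   `"expand_white"`, `"dimming"`, `"moving_dark"`.
#' @param center reference location `(x, y)`, degrees.
#' @param final_diameter disk diameter, degrees.
#' @param speed deg/s (disk-edge expansion rate, or translation speed for
#'   `moving_dark`).
#' @param hold stationary period, seconds (ignored for `moving_dark`).
#' @param contrast disk contrast; defaults to -1 for dark kinds and +1 for
#'   white kinds.
#' @param duration total stimulus duration; defaults to the matched looming
#'   duration `final_diameter / speed_loom + hold` with `speed_loom = 60`.
#' @param direction direction of motion for `moving_dark`, radians.
#' @inheritParams loom_movie
#' @return a [stimulus_movie()].
#' @export
figural_movie <- function(kind, center = c(0, 0), final_diameter = 30,
                          speed = 60, hold = 0.25, contrast = NULL,
                          duration = NULL, direction = 0,
                          screen_bounds = NULL, pixel_pitch = 1,
                          frame_rate = 60) {
  kinds <- c("contract_dark", "contract_white", "expand_white", "dimming",
             "moving_dark")
  if (!kind %in% kinds) {
    stop("unknown figural stimulus kind: ", kind)
  }
  if (is.null(contrast)) {
    contrast <- if (kind %in% c("contract_white", "expand_white")) 1 else -1
  }
  r_final <- final_diameter / 2
  if (kind == "expand_white") {
    return(loom_movie(center, final_diameter, speed, hold, contrast,
                      screen_bounds, pixel_pitch, frame_rate))
  }
  if (kind == "moving_dark") {
    if (is.null(duration)) duration <- final_diameter / 60 + hold
    half_path <- speed * duration / 2
    u <- c(cos(direction), sin(direction))
    if (is.null(screen_bounds)) {
      ext <- abs(u) * half_path + r_final
      geom <- field_geometry(center[1] + c(-ext[1], ext[1]),
                             center[2] + c(-ext[2], ext[2]), pixel_pitch)
    } else {
      geom <- field_geometry(screen_bounds$x, screen_bounds$y, pixel_pitch)
    }
    n_frames <- max(1L, round(duration * frame_rate))
    px <- geom$origin[1] + (seq_len(geom$nx) - 0.5) * pixel_pitch
    py <- geom$origin[2] + (seq_len(geom$ny) - 0.5) * pixel_pitch
    vals <- array(0, dim = c(geom$nx, geom$ny, n_frames))
    for (k in seq_len(n_frames)) {
      t <- (k - 1) / frame_rate
      pos <- center + (t - duration / 2) * speed * u
      check_disk_on_screen(pos, r_final, screen_bounds, k)
      vals[, , k][disk_mask(pos[1], pos[2], r_final, px, py)] <- contrast
    }
    return(stimulus_movie(vals, pixel_pitch, frame_rate, geom$origin))
  }
  # contract_dark, contract_white, dimming share the loom geometry/duration
  if (is.null(duration)) duration <- final_diameter / speed + hold
  n_frames <- max(1L, round(duration * frame_rate))
  geom <- movie_geom_for_disk(center, r_final, screen_bounds, pixel_pitch)
  px <- geom$origin[1] + (seq_len(geom$nx) - 0.5) * pixel_pitch
  py <- geom$origin[2] + (seq_len(geom$ny) - 0.5) * pixel_pitch
  vals <- array(0, dim = c(geom$nx, geom$ny, n_frames))
  for (k in seq_len(n_frames)) {
    t <- (k - 1) / frame_rate
    if (kind == "dimming") {
      r <- r_final
      c_t <- contrast * t / duration
    } else {
      r <- max(final_diameter - speed * t, 0) / 2
      c_t <- contrast
    }
    check_disk_on_screen(center, r, screen_bounds, k)
    if (r > 0 && c_t != 0) {
      vals[, , k][disk_mask(center[1], center[2], r, px, py)] <- c_t
    }
  }
  stimulus_movie(vals, pixel_pitch, frame_rate, geom$origin)
}

#' Flickering-checkerboard movie
#'
#' The field is tiled with square checkers whose contrast is drawn
#' independently every frame as full black (-1) or full white (+1); the
#' movie is fully determined by `seed`.
#'
#' @param duration seconds (at least one frame).
#' @param checker checker side, degrees; must be at least one pixel.
#' @param rate frame rate, Hz.
#' @param seed RNG seed.
#' @param bounds `list(x=, y=)` field extent in degrees.
#' @param pixel_pitch degrees per pixel.
#' @return a [stimulus_movie()].
#' @export
checkerboard_movie <- function(duration = 300, checker = 3, rate = 60,
                               seed = 1,
                               bounds = list(x = c(-15, 15), y = c(-15, 15)),
                               pixel_pitch = 1) {
  if (checker < pixel_pitch) {
    stop("checker size must be at least one pixel")
  }
  n_frames <- round(duration * rate)
  if (n_frames < 1) stop("duration must cover at least one frame")
  n_cx <- ceiling((bounds$x[2] - bounds$x[1]) / checker - 1e-9)
  n_cy <- ceiling((bounds$y[2] - bounds$y[1]) / checker - 1e-9)
  geom <- field_geometry(bounds$x, bounds$y, pixel_pitch)
  # map each pixel to its checker (checkers anchored at the field origin)
  px <- (seq_len(geom$nx) - 0.5) * pixel_pitch
  py <- (seq_len(geom$ny) - 0.5) * pixel_pitch
  ix <- pmin(n_cx, floor(px / checker) + 1L)
  iy <- pmin(n_cy, floor(py / checker) + 1L)
  pix_of_checker <- as.vector(outer(ix, (iy - 1L) * n_cx, `+`))
  vals <- with_seed(seed, {
    draws <- matrix(sample(c(-1, 1), n_cx * n_cy * n_frames, replace = TRUE),
                    nrow = n_cx * n_cy, ncol = n_frames)
    array(draws[pix_of_checker, ], dim = c(geom$nx, geom$ny, n_frames))
  })
  m <- stimulus_movie(vals, pixel_pitch, rate, geom$origin)
  m$checker <- checker
  m$seed <- seed
  m
}
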