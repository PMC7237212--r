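#' Stimulus protocols
#'
#' A protocol is an ordered, temporally disjoint sequence of stimulus events
#' (trials). Each event carries its kind, center location, onset, duration
#' and rendering parameters, so any event can be re-rendered in isolation
#' with [render_event()].
#'
#' @param events data frame with columns `kind`, `x`, `y`, `onset`,
#'   `duration`, `final_diameter`, `speed`, `hold`, `contrast`.
#' @param grid optional location grid, as returned by [loom_grid()].
#' @param seed integer seed that generated the protocol (if random).
#' @param screen_bounds `list(x = c(min,max), y = c(min,max))`, degrees.
#' @return an object of class `protocol`.
#' @export
protocol <- function(events, grid = NULL, seed = NULL,
                     screen_bounds = default_screen_bounds()) {
  needed <- c("kind", "x", "y", "onset", "duration")
  stopifnot(all(needed %in% names(events)))
  events <- events[order(events$onset), , drop = FALSE]
  rownames(events) <- NULL
  if (any(events$onset < 0) || any(events$duration <= 0)) {
    stop("event onsets must be >= 0 and durations > 0")
  }
  ends <- events$onset + events$duration
  if (nrow(events) > 1 &&
      any(events$onset[-1] < ends[-nrow(events)] - 1e-9)) {
    stop("protocol events overlap in time")
  }
  if (any(events$x < screen_bounds$x[1] | events$x > screen_bounds$x[2] |
          events$y < screen_bounds$y[1] | events$y > screen_bounds$y[2])) {
    stop("event center outside screen bounds")
  }
  structure(list(events = events, grid = grid, seed = seed,
                 screen_bounds = screen_bounds),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("<protocol> %d events over %.1f s (%s)\n",
              nrow(x$events), protocol_duration(x),
              paste(unique(x$events$kind), collapse = ", ")))
  invisible(x)
}

#' Default screen bounds (degrees)
#'
#' Abstract screen covering the stimulus grid plus the largest disk.
#' @export
default_screen_bounds <- function() {
  list(x = c(-50, 50), y = c(-50, 50))
}

#' Total protocol duration (end of last event), seconds
#' @param p a `protocol`.
#' @export
protocol_duration <- function(p) {
  if (nrow(p$events) == 0) return(0)
  max(p$events$onset + p$events$duration)
}

#' Regular grid of loom locations
#'
#' @param nrow,ncol grid dimensions (default the standard 5 x 5).
#' @param spacing center-to-center spacing, degrees (default 15).
#' @param center grid center `(x, y)`, degrees.
#' @return list with `centers` (n x 2 matrix, row-major from the lower-left),
#'   `nrow`, `ncol`, `spacing`, `center`.
#' @export
loom_grid <- function(nrow = 5, ncol = 5, spacing = 15, center = c(0, 0)) {
  gx <- (seq_len(ncol) - (ncol + 1) / 2) * spacing + center[1]
  gy <- (seq_len(nrow) - (nrow + 1) / 2) * spacing + center[2]
  centers <- as.matrix(expand.grid(x = gx, y = gy))
  list(centers = centers, nrow = nrow, ncol = ncol, spacing = spacing,
       center = center)
}

loom_event_row <- function(x, y, onset, final_diameter, speed, hold,
                           contrast) {
  data.frame(kind = "loom_dark", x = x, y = y, onset = onset,
             duration = final_diameter / speed + hold,
             final_diameter = final_diameter, speed = speed, hold = hold,
             contrast = contrast)
}

#' Repeated-loom protocol
#'
#' `n_trials` identical looming stimuli at one location, separated by a
#' gray-screen inter-stimulus interval.
#'
#' @param n_trials number of trials (>= 1).
#' @param isi inter-stimulus interval (gap between offset and next onset), s.
#' @param location `(x, y)` of the loom center, degrees.
#' @param final_diameter,speed,hold,contrast loom parameters.
#' @param screen_bounds screen extent.
#' @return a [protocol()].
#' @export
repeat_loom_protocol <- function(n_trials = 10, isi = 2, location = c(0, 0),
                                 final_diameter = 30, speed = 60, hold = 0.25,
                                 contrast = -1,
                                 screen_bounds = default_screen_bounds()) {
  stopifnot(n_trials >= 1, isi > 0)
  dur <- final_diameter / speed + hold
  onsets <- (seq_len(n_trials) - 1) * (dur + isi)
  ev <- do.call(rbind, lapply(onsets, function(o) {
    loom_event_row(location[1], location[2], o, final_diameter, speed, hold,
                   contrast)
  }))
  protocol(ev, seed = NULL, screen_bounds = screen_bounds)
}

#' Random-loom protocol
#'
#' Looming stimuli presented at locations drawn uniformly and independently
#' from a 5 x 5 grid with ~15 deg spacing; reproducible by seed.
#'
#' @param n_trials number of trials (60-120 in the standard experiment).
#' @param isi inter-stimulus interval, seconds.
#' @param grid a [loom_grid()].
#' @param seed RNG seed.
#' @inheritParams repeat_loom_protocol
#' @return a [protocol()] whose `events` carry a `location` column with the
#'   1-based grid index of each trial.
#' @export
random_loom_protocol <- function(n_trials = 100, isi = 3, grid = loom_grid(),
                                 seed = 1, final_diameter = 30, speed = 60,
                                 hold = 0.25, contrast = -1,
                                 screen_bounds = default_screen_bounds()) {
  stopifnot(n_trials >= 1, isi > 0)
  r_final <- final_diameter / 2
  if (any(grid$centers[, 1] - r_final < screen_bounds$x[1]) ||
      any(grid$centers[, 1] + r_final > screen_bounds$x[2]) ||
      any(grid$centers[, 2] - r_final < screen_bounds$y[1]) ||
      any(grid$centers[, 2] + r_final > screen_bounds$y[2])) {
    stop("loom grid (plus final disk size) does not fit the screen bounds")
  }
  locs <- with_seed(seed,
                    sample.int(nrow(grid$centers), n_trials, replace = TRUE))
  dur <- final_diameter / speed + hold
  onsets <- (seq_len(n_trials) - 1) * (dur + isi)
  ev <- do.call(rbind, lapply(seq_len(n_trials), function(k) {
    loom_event_row(grid$centers[locs[k], 1], grid$centers[locs[k], 2],
                   onsets[k], final_diameter, speed, hold, contrast)
  }))
  ev$location <- locs
  protocol(ev, grid = grid, seed = seed, screen_bounds = screen_bounds)
}

#' Recovery-from-habituation protocol
#'
#' Eight looming stimuli at a single location, separated by inter-stimulus
#' intervals of 1.5, 2, 6, 11, 21, 61 and 121 s, in this order.
#'
#' @param location `(x, y)` of the loom center.
#' @param isis the seven inter-stimulus intervals, seconds.
#' @inheritParams repeat_loom_protocol
#' @return a [protocol()]; `events` carry an `isi_before` column (NA for the
#'   first event).
#' @export
recovery_protocol <- function(location = c(0, 0),
                              isis = c(1.5, 2, 6, 11, 21, 61, 121),
                              final_diameter = 30, speed = 60, hold = 0.25,
                              contrast = -1,
                              screen_bounds = default_screen_bounds()) {
  dur <- final_diameter / speed + hold
  onsets <- cumsum(c(0, isis + dur))
  ev <- do.call(rbind, lapply(onsets, function(o) {
    loom_event_row(location[1], location[2], o, final_diameter, speed, hold,
                   contrast)
  }))
  ev$isi_before <- c(NA, isis)
  protocol(ev, seed = NULL, screen_bounds = screen_bounds)
}

#' Render one protocol event as a movie
#'
#' @param p a `protocol`.
#' @param k event index.
#' @param screen_bounds optional bounds overriding snug framing.
#' @param pixel_pitch,frame_rate movie sampling.
#' @return a [stimulus_movie()].
#' @export
render_event <- function(p, k, screen_bounds = NULL, pixel_pitch = 1,
                         frame_rate = 60) {
  render_single_event(p$events[k, ], screen_bounds, pixel_pitch, frame_rate)
}

# Render one event row (independent of any protocol container).
render_single_event <- function(ev, screen_bounds = NULL, pixel_pitch = 1,
                                frame_rate = 60) {
  if (ev$kind == "loom_dark") {
    loom_movie(c(ev$x, ev$y), ev$final_diameter, ev$speed, ev$hold,
               ev$contrast, screen_bounds, pixel_pitch, frame_rate)
  } else if (ev$kind == "checkerboard") {
    checkerboard_movie(ev$duration, checker = ev$final_diameter,
                       rate = frame_rate, seed = ev$speed,
                       bounds = screen_bounds %||% list(
                         x = c(ev$x - 15, ev$x + 15),
                         y = c(ev$y - 15, ev$y + 15)),
                       pixel_pitch = pixel_pitch)
  } else {
    figural_movie(ev$kind, c(ev$x, ev$y), ev$final_diameter, ev$speed,
                  ev$hold, ev$contrast, duration = ev$duration,
                  screen_bounds = screen_bounds, pixel_pitch = pixel_pitch,
                  frame_rate = frame_rate)
  }
}

#' Write / read a protocol as JSON
#'
#' Events, grid specification, seed and screen bounds round-trip exactly;
#' movies are always re-rendered on demand (checkerboards are stored as
#' seed plus parameters, never as pixel data).
#'
#' @param p a `protocol`.
#' @param path file path.
#' @return `read_protocol` returns a `protocol`.
#' @export
write_protocol <- function(p, path) {
  obj <- list(events = p$events, seed = p$seed,
              screen_bounds = p$screen_bounds)
  if (!is.null(p$grid)) {
    obj$grid <- p$grid[c("nrow", "ncol", "spacing", "center")]
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- NULL
  if (!is.null(obj$grid)) {
    grid <- loom_grid(obj$grid$nrow, obj$grid$ncol, obj$grid$spacing,
                      unlist(obj$grid$center))
  }
  sb <- lapply(obj$screen_bounds, unlist)
  protocol(as.data.frame(obj$events), grid = grid, seed = obj$seed,
           screen_bounds = sb)
}
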