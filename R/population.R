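#' Construct a synthetic SC population
#'
#' Builds a table of virtual neurons emulating the two response classes seen
#' across the depth of the superior colliculus:
#' \describe{
#'   \item{sSC}{superficial neurons: each is a single Off-type LN unit with a
#'     small receptive field (`rf_sigma` ~ 2-5 deg) tiling the stimulated
#'     span retinotopically. They respond to any figural stimulus crossing
#'     the receptive field, reliably on every repeat, with a maintained
#'     Poisson baseline.}
#'   \item{dSC}{deep neurons: each reads out the widefield unit of the
#'     circuit model, so it is looming-selective, position-invariant with a
#'     short fixed latency, and habituates almost completely after a single
#'     presentation at a grid location, recovering over minutes.}
#' }
#'
#' `gain` is calibrated in spikes: for an sSC neuron it is the expected
#' number of stimulus-period spikes fired for a standard loom centered on
#' its receptive field; for a dSC neuron it is the expected number of
#' spikes per rate-unit-second of widefield output (a fresh loom delivers
#' about one rate-unit-second, see [circuit_config()]).
#'
#' @param n_sSC,n_dSC group sizes (>= 0).
#' @param span retinotopic span to tile, `list(x = c(min,max), y =
#'   c(min,max))` degrees; defaults to the standard 5 x 5 loom grid extent.
#' @param seed RNG seed; the same seed reproduces the table exactly.
#' @param circuit a [circuit_config()] shared by the dSC group.
#' @return a data frame of class `neuron_population` with one row per
#'   neuron (id, layer, depth_um, rf_x, rf_y, rf_sigma, baseline_hz, gain,
#'   habituating, latency_jitter_s and per-kind tuning multipliers); the
#'   circuit configuration is attached as attribute `circuit`.
#' @export
make_population <- function(n_sSC = 50, n_dSC = 50,
                            span = list(x = c(-30, 30), y = c(-30, 30)),
                            seed = 1, circuit = circuit_config()) {
  stopifnot(n_sSC >= 0, n_dSC >= 0)
  kinds <- c("loom_dark", "contract_dark", "expand_white", "contract_white",
             "dimming", "moving_dark", "checkerboard")
  with_seed(seed, {
    rows <- list()
    if (n_sSC > 0) {
      nx <- ceiling(sqrt(n_sSC))
      ny <- ceiling(n_sSC / nx)
      gx <- seq(span$x[1], span$x[2], length.out = nx)
      gy <- seq(span$y[1], span$y[2], length.out = ny)
      lattice <- expand.grid(x = gx, y = gy)[seq_len(n_sSC), ]
      s_tab <- data.frame(
        id = sprintf("sSC_%03d", seq_len(n_sSC)),
        layer = "sSC",
        depth_um = round(stats::runif(n_sSC, -350, -50)),
        rf_x = lattice$x + stats::runif(n_sSC, -2, 2),
        rf_y = lattice$y + stats::runif(n_sSC, -2, 2),
        rf_sigma = stats::runif(n_sSC, 2, 5),
        baseline_hz = 10^stats::runif(n_sSC, log10(0.1), log10(15)),
        gain = stats::runif(n_sSC, 50, 80),
        habituating = FALSE,
        latency_jitter_s = stats::runif(n_sSC, 0.001, 0.004))
      for (k in kinds) {
        s_tab[[paste0("tune_", k)]] <- stats::runif(n_sSC, 0.6, 1.4)
      }
      rows$s <- s_tab
    }
    if (n_dSC > 0) {
      gc <- circuit$grid$center
      d_tab <- data.frame(
        id = sprintf("dSC_%03d", seq_len(n_dSC)),
        layer = "dSC",
        depth_um = round(stats::runif(n_dSC, 50, 600)),
        rf_x = gc[1] + stats::runif(n_dSC, -7.5, 7.5),
        rf_y = gc[2] + stats::runif(n_dSC, -7.5, 7.5),
        rf_sigma = stats::runif(n_dSC, 35, 45),
        baseline_hz = 10^stats::runif(n_dSC, log10(0.1), log10(15)),
        gain = stats::runif(n_dSC, 30, 50),
        habituating = TRUE,
        latency_jitter_s = stats::runif(n_dSC, 0.0005, 0.003))
      for (k in kinds) d_tab[[paste0("tune_", k)]] <- 1
      rows$d <- d_tab
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    structure(tab, circuit = circuit, seed = seed,
              class = c("neuron_population", "data.frame"))
  })
}

# Stimulus-period LN response integral (unnormalized) of an sSC-style unit
# to a standard loom centered on its receptive field. Only the stimulus
# period is counted, matching the definition of the neural response as the
# spike count during the stimulus period, so `gain` is directly the
# expected stimulus-period count for a centered loom.
ssc_loom_integral <- function(sigma, circuit) {
  mv <- loom_movie(c(0, 0), pixel_pitch = circuit$pixel_pitch,
                   frame_rate = circuit$frame_rate)
  u <- ln_unit(c(0, 0), sigma, circuit$center)
  r <- ln_response(mv, u, circuit$t_support)
  sum(r$values) * r$dt
}

#' Generate spike trains for a population and protocol
#'
#' Each neuron's rate is `baseline + gain * (model drive)`: the drive of an
#' sSC neuron is its own Off LN response to each stimulus event, the drive
#' of a dSC neuron is the widefield output of the circuit model simulated
#' continuously through the whole protocol (so habituation carries across
#' events and recovers through the gaps). Spikes are drawn from an
#' inhomogeneous Poisson process, exactly for the piecewise-constant rate at
#' the stimulus frame resolution; event-driven spikes receive the neuron's
#' small latency jitter. Reproducible given `seed`.
#'
#' @param population a [make_population()] table.
#' @param protocol a [protocol()].
#' @param seed RNG seed.
#' @param circuit overrides the population's attached circuit config.
#' @return an object of class `population_recording`: list with `spikes`
#'   (per-neuron sorted spike-time vectors, seconds, 1 microsecond
#'   resolution), `neurons`, `protocol`, `seed`, `duration`.
#' @export
generate_spikes <- function(population, protocol, seed = 1,
                            circuit = NULL) {
  circuit <- circuit %||% attr(population, "circuit") %||% circuit_config()
  circuit <- calibrate_circuit(circuit)
  ev <- protocol$events
  n_ev <- nrow(ev)
  fr <- circuit$frame_rate
  dt <- 1 / fr
  total_t <- protocol_duration(protocol) + 1

  # deterministic drives, shared where possible
  any_d <- any(population$layer == "dSC")
  wf_traces <- NULL
  if (any_d && n_ev > 0) {
    sim <- simulate_protocol(circuit, protocol, keep_traces = TRUE)
    wf_traces <- sim$traces
  }
  memo <- new.env(parent = emptyenv())
  cal <- new.env(parent = emptyenv())
  ssc_drive <- function(nr, k) {
    # returns event-local rate vector (Hz, gain-scaled) or NULL if too far
    e <- ev[k, ]
    dx <- round(e$x - nr$rf_x, 4)
    dy <- round(e$y - nr$rf_y, 4)
    reach <- event_radius(e) + 3 * nr$rf_sigma
    if (sqrt(dx^2 + dy^2) > reach) return(NULL)
    sig <- event_signature(e, circuit)
    mv <- event_local_movie(e, circuit, memo)
    key <- paste(sig, dx, dy, round(nr$rf_sigma, 4), sep = "|")
    if (is.null(memo[[key]])) {
      # event-local movie: the unit sits at its offset from the event
      u <- ln_unit(c(-dx, -dy), nr$rf_sigma, circuit$center)
      memo[[key]] <- ln_response(mv, u, circuit$t_support)$values
    }
    ckey <- as.character(round(nr$rf_sigma, 6))
    if (is.null(cal[[ckey]])) {
      cal[[ckey]] <- ssc_loom_integral(nr$rf_sigma, circuit)
    }
    tune <- nr[[paste0("tune_", e$kind)]] %||% 1
    nr$gain * tune / cal[[ckey]] * memo[[key]]
  }

  spikes <- vector("list", nrow(population))
  with_seed(seed, {
    for (j in seq_len(nrow(population))) {
      nr <- population[j, ]
      st <- numeric(0)
      # maintained baseline over the whole recording
      nb <- stats::rpois(1, nr$baseline_hz * total_t)
      if (nb > 0) st <- stats::runif(nb, 0, total_t)
      for (k in seq_len(n_ev)) {
        if (nr$layer == "dSC") {
          tune <- nr[[paste0("tune_", ev$kind[k])]] %||% 1
          rate <- nr$gain * tune * wf_traces[[k]]$rate
        } else {
          rate <- ssc_drive(nr, k)
        }
        if (is.null(rate)) next
        if (any(rate < 0)) {
          warning("negative drive clipped to zero for neuron ", nr$id)
          rate <- pmax(0, rate)
        }
        mu_k <- sum(rate) * dt
        if (mu_k <= 0) next
        n_k <- stats::rpois(1, mu_k)
        if (n_k == 0) next
        f <- sample.int(length(rate), n_k, replace = TRUE, prob = rate)
        jit <- stats::rnorm(1, 0, nr$latency_jitter_s)
        tt <- ev$onset[k] + (f - 1 + stats::runif(n_k)) * dt + jit
        st <- c(st, tt[tt >= 0 & tt <= total_t])
      }
      spikes[[j]] <- unique(sort(round(st, 6)))
    }
  })
  structure(list(spikes = spikes, neurons = population, protocol = protocol,
                 seed = seed, duration = total_t),
            class = "population_recording")
}

#' @export
print.population_recording <- function(x, ...) {
  cat(sprintf("<population_recording> %d neurons, %d spikes, %.1f s\n",
              length(x$spikes), sum(lengths(x$spikes)), x$duration))
  invisible(x)
}

#' Build the trial table of stimulus-period counts
#'
#' One row per neuron x event with the stimulus-period spike count `count`
#' (r'), the background expectation `mu` extrapolated from the
#' stimulus-free window just preceding the event, the per-location repeat
#' index and the novelty flag (first occurrence at that location).
#'
#' Background windows are clipped to stimulus-free time: they start no
#' earlier than the end of the previous event (and no earlier than the
#' recording start); a clipped window is flagged in `bg_truncated` and
#' `mu` is computed from the available portion (0 if none).
#'
#' @param recording a [generate_spikes()] recording.
#' @param protocol defaults to the recording's protocol.
#' @param window background window length, seconds (the experimentally
#'   typical 5-10 s; default 5).
#' @return a data frame of class `trial_table`.
#' @export
build_trial_table <- function(recording, protocol = NULL, window = 5) {
  protocol <- protocol %||% recording$protocol
  ev <- protocol$events
  n_ev <- nrow(ev)
  loc_key <- paste(round(ev$x, 6), round(ev$y, 6))
  repeat_idx <- stats::ave(seq_len(n_ev), loc_key, FUN = seq_along)
  novel <- !duplicated(loc_key)
  location <- if (!is.null(ev$location)) ev$location else
    match(loc_key, unique(loc_key))
  prev_end <- c(-Inf, (ev$onset + ev$duration)[-n_ev])
  rows <- vector("list", nrow(recording$neurons))
  for (j in seq_len(nrow(recording$neurons))) {
    st <- recording$spikes[[j]]
    cnt <- mu <- numeric(n_ev)
    trunc <- logical(n_ev)
    for (k in seq_len(n_ev)) {
      on <- ev$onset[k]
      cnt[k] <- sum(st >= on & st < on + ev$duration[k])
      bg0 <- max(on - window, prev_end[k], 0)
      bw <- on - bg0
      trunc[k] <- bw < window - 1e-9
      mu[k] <- if (bw > 0) {
        sum(st >= bg0 & st < on) / bw * ev$duration[k]
      } else 0
    }
    rows[[j]] <- data.frame(
      neuron = recording$neurons$id[j], layer = recording$neurons$layer[j],
      depth_um = recording$neurons$depth_um[j],
      trial = seq_len(n_ev), kind = ev$kind, x = ev$x, y = ev$y,
      location = location, onset = ev$onset, duration = ev$duration,
      count = cnt, mu = mu, bg_truncated = trunc,
      repeat_idx = repeat_idx, novel = novel)
  }
  structure(do.call(rbind, rows),
            class = c("trial_table", "data.frame"))
}
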