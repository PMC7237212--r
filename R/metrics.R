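#' Background activity preceding a stimulus event
#'
#' Baseline firing rate is estimated from the window just preceding the
#' event and extrapolated to the stimulus period:
#' `mu = (count in window / window length) * duration`.
#'
#' @param spike_times sorted spike times of one neuron, seconds.
#' @param onset stimulus onset, seconds.
#' @param duration stimulus period, seconds.
#' @param window background window length, seconds (> 0).
#' @param start earliest usable time (recording start or end of the
#'   previous stimulus); windows reaching past it are truncated and
#'   flagged.
#' @return list with `mu`, `rate_hz`, `window_used` and `truncated`.
#' @export
background_activity <- function(spike_times, onset, duration, window = 5,
                                start = 0) {
  stopifnot(window > 0, duration > 0)
  bg0 <- max(onset - window, start)
  bw <- onset - bg0
  truncated <- bw < window - 1e-9
  if (bw <= 0) {
    return(list(mu = 0, rate_hz = 0, window_used = 0, truncated = TRUE))
  }
  n <- sum(spike_times >= bg0 & spike_times < onset)
  list(mu = n / bw * duration, rate_hz = n / bw, window_used = bw,
       truncated = truncated)
}

#' Poisson significance test for a stimulus-period spike count
#'
#' Tests whether a count `r_prime` exceeds what the baseline would produce,
#' under a Poisson noise model with mean equal to the background activity
#' `mu`. When the background is very low (`mu < 1`) the Poisson mean is
#' floored at one so that chance firing of 1-2 spikes is never declared a
#' visual response. The p-value is the upper tail `P(X >= r_prime)`.
#'
#' @param r_prime observed stimulus-period spike count (integer >= 0).
#' @param mu background activity (expected count).
#' @param alpha significance cutoff (default 0.005).
#' @return list with `p`, `lambda_used`, `significant`, `alpha`.
#' @export
poisson_response_test <- function(r_prime, mu, alpha = 0.005) {
  stopifnot(r_prime >= 0, abs(r_prime - round(r_prime)) < 1e-9, mu >= 0)
  lambda <- if (mu < 1) 1 else mu
  p <- stats::ppois(r_prime - 1, lambda, lower.tail = FALSE)
  list(p = p, lambda_used = lambda, significant = p < alpha, alpha = alpha)
}

#' Bonferroni-corrected significance cutoff
#'
#' @param alpha nominal cutoff.
#' @param n_tests number of stimulus presentations tested.
#' @export
bonferroni_alpha <- function(alpha, n_tests) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

corrected_count <- function(r_prime, mu) pmax(0, r_prime - mu)

#' Looming selectivity index
#'
#' `(r_L - r_O) / (r_L + r_O)` on background-corrected counts
#' `r = r' - mu` (clamped at zero), comparing the response to the looming
#' stimulus with the response to another stimulus. A neuron is included
#' only if at least one of the two responses passes the Poisson
#' significance test.
#'
#' @param rL_prime,muL first-presentation loom count and its background.
#' @param rO_prime,muO other-stimulus count and its background.
#' @param alpha significance cutoff for inclusion.
#' @return list with `r_L`, `r_O`, `index` (NA when `r_L + r_O = 0`) and
#'   `included` (FALSE when neither response is significant, in which case
#'   no index is computed).
#' @export
selectivity_index <- function(rL_prime, muL, rO_prime, muO, alpha = 0.005) {
  sigL <- poisson_response_test(rL_prime, muL, alpha)$significant
  sigO <- poisson_response_test(rO_prime, muO, alpha)$significant
  if (!sigL && !sigO) {
    return(list(r_L = NA_real_, r_O = NA_real_, index = NA_real_,
                included = FALSE))
  }
  rL <- corrected_count(rL_prime, muL)
  rO <- corrected_count(rO_prime, muO)
  idx <- if (rL + rO > 0) (rL - rO) / (rL + rO) else NA_real_
  list(r_L = rL, r_O = rO, index = idx, included = TRUE)
}

#' @rdname selectivity_index
#' @param mean_checker_rate average firing rate during the flickering
#'   checkerboard, Hz.
#' @param t_L looming-stimulus duration, seconds; the checkerboard
#'   comparison response is `r_O = <r_C> * t_L - mu`.
#' @export
selectivity_vs_checkerboard <- function(rL_prime, muL, mean_checker_rate,
                                        t_L, alpha = 0.005) {
  rO_prime <- mean_checker_rate * t_L
  selectivity_index(rL_prime, muL, rO_prime, muL, alpha = alpha)
}

#' Habituation index
#'
#' `1 - r_i / r_1` on background-corrected counts, where `r_1` is the
#' response to the first presentation and `r_i` to the i-th (default the
#' 10th). Included only if the first response passes the significance
#' test; undefined when `r_1 <= 0` after correction.
#'
#' @param counts vector of per-trial stimulus-period counts `r'_1..r'_n`.
#' @param mu background activity (single value or per trial).
#' @param i repeat index to compare against the first trial.
#' @param alpha significance cutoff for the first-trial inclusion rule.
#' @return list with `r` (corrected counts), `index`, `i_used`,
#'   `included`.
#' @export
habituation_index <- function(counts, mu, i = 10, alpha = 0.005) {
  stopifnot(length(counts) >= i, i >= 2)
  mu <- rep_len(mu, length(counts))
  if (!poisson_response_test(counts[1], mu[1], alpha)$significant) {
    return(list(r = NULL, index = NA_real_, i_used = i, included = FALSE))
  }
  r <- corrected_count(counts, mu)
  if (r[1] <= 0) {
    return(list(r = r, index = NA_real_, i_used = i, included = FALSE))
  }
  list(r = r, index = 1 - r[i] / r[1], i_used = i, included = TRUE)
}

#' Recovery from habituation
#'
#' For a recovery protocol (a series of looms at one location with
#' increasing inter-stimulus intervals), computes per neuron the fraction
#' `r_i / r_1` of the initial response recovered at every trial, and
#' population quartiles (25/50/75) per layer group.
#'
#' @param counts matrix `neurons x trials` of stimulus-period counts.
#' @param mu background activity: vector (one per neuron) or matrix
#'   matching `counts`.
#' @param layer character vector of layer labels per neuron.
#' @param isis inter-stimulus interval preceding each trial from the
#'   second on.
#' @param alpha significance cutoff for first-trial inclusion.
#' @return list with `fractions` (neurons x trials matrix, NA rows for
#'   excluded neurons) and `quartiles` (data frame: layer, trial, isi,
#'   q25, median, q75, n).
#' @export
recovery_curve <- function(counts, mu, layer = rep("dSC", nrow(counts)),
                           isis = c(1.5, 2, 6, 11, 21, 61, 121),
                           alpha = 0.005) {
  counts <- as.matrix(counts)
  mu_m <- if (is.matrix(mu)) mu else
    matrix(mu, nrow(counts), ncol(counts))
  frac <- matrix(NA_real_, nrow(counts), ncol(counts))
  for (j in seq_len(nrow(counts))) {
    if (!poisson_response_test(counts[j, 1], mu_m[j, 1], alpha)$significant)
      next
    r <- corrected_count(counts[j, ], mu_m[j, ])
    if (r[1] <= 0) next
    frac[j, ] <- r / r[1]
  }
  isi_of_trial <- c(NA, rep_len(isis, ncol(counts) - 1))
  qs <- do.call(rbind, lapply(unique(layer), function(lay) {
    sel <- layer == lay & !is.na(frac[, 1])
    do.call(rbind, lapply(seq_len(ncol(counts)), function(k) {
      v <- frac[sel, k]
      data.frame(layer = lay, trial = k, isi = isi_of_trial[k],
                 q25 = unname(stats::quantile(v, 0.25, na.rm = TRUE)),
                 median = unname(stats::median(v, na.rm = TRUE)),
                 q75 = unname(stats::quantile(v, 0.75, na.rm = TRUE)),
                 n = sum(sel))
    }))
  }))
  list(fractions = frac, quartiles = qs)
}

#' Receptive-field size from gridded loom responses
#'
#' From the random-loom experiment: the per-location response `r(x)` is the
#' maximum background-corrected count over repeats at that location, with
#' locations whose responses never deviate significantly from baseline
#' (Bonferroni-corrected over all presentations) set to zero. The
#' receptive-field center is the response-weighted center of mass `c`, the
#' spread is the mean radial distance
#' `Delta = sum(||x - c|| r(x)) / sum(r(x))`, and the size is
#' `2 * Delta + spacing` — the grid spacing is added because a
#' single-location responder has `Delta = 0` yet the measurement cannot
#' resolve below the inter-stimulus distance.
#'
#' @param counts per-trial counts of one neuron.
#' @param mu per-trial background activity.
#' @param x,y per-trial stimulus locations, degrees.
#' @param spacing grid spacing, degrees (default 15).
#' @param alpha nominal cutoff; corrected by the number of presentations.
#' @return list with `r_loc` (data frame location/x/y/response), `center`,
#'   `delta`, `size` (degrees) and `included` (`FALSE` with size NA when no
#'   location is significantly responsive).
#' @export
rf_size <- function(counts, mu, x, y, spacing = 15, alpha = 0.005) {
  stopifnot(length(counts) == length(mu), length(counts) == length(x))
  a_corr <- bonferroni_alpha(alpha, length(counts))
  key <- paste(round(x, 6), round(y, 6))
  locs <- !duplicated(key)
  r_loc <- vapply(key[locs], function(k) {
    sel <- key == k
    sig <- vapply(which(sel), function(i) {
      poisson_response_test(counts[i], mu[i], a_corr)$significant
    }, logical(1))
    if (!any(sig)) return(0)
    max(corrected_count(counts[sel][sig], mu[sel][sig]))
  }, numeric(1))
  lx <- x[locs]
  ly <- y[locs]
  tot <- sum(r_loc)
  if (tot <= 0) {
    return(list(r_loc = data.frame(x = lx, y = ly, response = r_loc),
                center = c(NA_real_, NA_real_), delta = NA_real_,
                size = NA_real_, spacing = spacing, included = FALSE))
  }
  cx <- sum(lx * r_loc) / tot
  cy <- sum(ly * r_loc) / tot
  delta <- sum(sqrt((lx - cx)^2 + (ly - cy)^2) * r_loc) / tot
  list(r_loc = data.frame(x = lx, y = ly, response = r_loc),
       center = c(cx, cy), delta = delta, size = 2 * delta + spacing,
       spacing = spacing, included = TRUE)
}

#' First-spike latency variability
#'
#' Latency is the time of the first spike in the stimulus period, required
#' to be at least `min_latency` (30 ms) after onset to exclude spikes not
#' driven by the stimulus. A neuron is included only when (i) its mean
#' background activity is below one spike per stimulus period and (ii) it
#' responds significantly (Bonferroni-corrected over presentations) on at
#' least `min_trials` trials. The variability is the sample standard
#' deviation (n - 1 denominator) over the latencies of significant trials.
#'
#' @param spike_times one neuron's sorted spike times, seconds.
#' @param onsets,durations per-trial stimulus windows.
#' @param mu per-trial background activity.
#' @param alpha nominal cutoff; corrected by the number of presentations.
#' @param min_trials minimum number of significant trials (default 5).
#' @param min_latency earliest admissible first spike, seconds.
#' @return list with `latencies` (per included trial, seconds), `sd`,
#'   `n_trials_used`, `included`, `reason`.
#' @export
latency_stats <- function(spike_times, onsets, durations, mu,
                          alpha = 0.005, min_trials = 5,
                          min_latency = 0.030) {
  stopifnot(length(onsets) == length(durations))
  mu <- rep_len(mu, length(onsets))
  if (mean(mu) >= 1) {
    return(list(latencies = numeric(0), sd = NA_real_, n_trials_used = 0,
                included = FALSE, reason = "background >= 1"))
  }
  a_corr <- bonferroni_alpha(alpha, length(onsets))
  lat <- numeric(0)
  n_sig <- 0
  for (k in seq_along(onsets)) {
    cnt <- sum(spike_times >= onsets[k] &
                 spike_times < onsets[k] + durations[k])
    if (!poisson_response_test(cnt, mu[k], a_corr)$significant) next
    n_sig <- n_sig + 1
    sp <- spike_times[spike_times >= onsets[k] + min_latency &
                        spike_times < onsets[k] + durations[k]]
    if (length(sp)) lat <- c(lat, sp[1] - onsets[k])
  }
  if (n_sig < min_trials) {
    return(list(latencies = lat, sd = NA_real_, n_trials_used = n_sig,
                included = FALSE,
                reason = sprintf("only %d significant trials", n_sig)))
  }
  list(latencies = lat,
       sd = if (length(lat) >= 2) stats::sd(lat) else NA_real_,
       n_trials_used = n_sig, included = TRUE, reason = "ok")
}
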