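test_that("temporal kernel matches its closed form", {
  cfg <- circuit_config()
  p <- cfg$center
  # the positive lobe alone is exactly 1 at t = tau1, so the full kernel
  # equals 1 - b * (second term); evaluate the second term directly
  t1 <- p$tau1
  second <- (t1 / p$tau2)^p$n2 * exp(-p$n2 * (t1 / p$tau2 - 1))
  expect_equal(eval_temporal_kernel(p, t1), 1 - p$b * second,
               tolerance = 1e-12)
  expect_equal(eval_temporal_kernel(p, 0), 0)
  expect_equal(eval_temporal_kernel(p, -0.1), 0)   # causal
  # direct scalar evaluation at t = 0.104 s with the printed values
  v <- 1 - 1.34 * (0.104 / 0.0912)^3.94 *
    exp(-3.94 * (0.104 / 0.0912 - 1))
  expect_equal(eval_temporal_kernel(p, 0.104), v, tolerance = 1e-12)
})

test_that("spatial kernel is a unit-peak isotropic Gaussian", {
  expect_equal(eval_spatial_kernel(4, 0, 0), 1)
  expect_equal(eval_spatial_kernel(4, 4, 0), exp(-0.5))
  expect_equal(eval_spatial_kernel(4, 0, -4), exp(-0.5))
  th <- seq(0, 2 * pi, length.out = 9)
  vals <- eval_spatial_kernel(3, 5 * cos(th), 5 * sin(th))
  expect_true(all(abs(vals - vals[1]) < 1e-12))
})

test_that("LN response is linear pre-rectification and zero on gray", {
  cfg <- circuit_config()
  u <- ln_unit(c(0, 0), 3, cfg$center)
  gray <- stimulus_movie(array(0, dim = c(8, 8, 12)), origin = c(-4, -4))
  r0 <- ln_response(gray, u)
  expect_true(all(r0$values == 0) && all(r0$drive == 0))
  mv <- random_movie(8, 8, 15, seed = 2)
  r1 <- ln_response(mv, u)
  mv2 <- mv
  mv2$values <- mv$values * 0.5
  r2 <- ln_response(mv2, u)
  expect_equal(r2$drive, 0.5 * r1$drive, tolerance = 1e-12)
})

test_that("separable fast path equals the brute-force convolution", {
  cfg <- circuit_config()
  u <- ln_unit(c(0, 0), 2.5, cfg$center)
  mv <- random_movie(10, 10, 20, seed = 5)
  fast <- ln_response(mv, u)
  slow <- brute_ln_response(mv, u)
  expect_lt(max(abs(fast$drive - slow$drive)) /
              max(abs(slow$drive)), 1e-10)
  expect_equal(fast$values, slow$values, tolerance = 1e-10)
})

test_that("detector output is the rectified difference of unit rates", {
  cfg <- test_circuit()
  det <- looming_detector(c(0, 0), cfg)
  mv <- random_movie(12, 12, 25, seed = 8)
  rc <- ln_response(mv, det$center_unit)
  rs <- ln_response(mv, det$surround_unit)
  out <- detector_response(det, mv)
  expect_equal(out$values, pmax(0, rc$values - rs$values))
  # surround >= center everywhere implies silence
  expect_true(all(out$values[rs$values >= rc$values] == 0))
})

test_that("local detector prefers the loom over other figural stimuli", {
  cfg <- test_circuit()
  det <- looming_detector(c(0, 0), cfg)
  pad <- round(cfg$t_support * cfg$frame_rate)
  integ <- function(mv) {
    r <- detector_response(det, scloom:::pad_movie(mv, pad),
                           scale = cfg$norm_scale)
    sum(r$values) * r$dt
  }
  loom <- integ(loom_movie(c(0, 0)))
  others <- vapply(c("contract_white", "dimming", "moving_dark"),
                   function(k) integ(figural_movie(k, c(0, 0))), numeric(1))
  expect_true(all(loom > others))
})

test_that("synapse integrator matches the closed-form ODE solutions", {
  tau <- 1
  syn <- depressing_synapse(w = 0.3, tau_rec = tau, a = 1, w_min = 0)
  # pure recovery from w0 at r = 0, stepped at tau / 1e4
  w <- syn$w
  dt <- tau / 1e4
  for (i in 1:5000) w <- scloom:::advance_weights(w, 0, dt, tau, 1, 0)
  expect_lt(abs(w - synapse_recovery_closed(0.3, 0.5, tau)) /
              synapse_recovery_closed(0.3, 0.5, tau), 1e-6)
  # constant rate: trajectory and steady state
  r <- 4
  w <- 1
  for (i in 1:5000) w <- scloom:::advance_weights(w, r, dt, tau, 1, 0.1)
  expect_equal(w, synapse_constant_r_closed(1, 0.5, tau, 1, 0.1, r),
               tolerance = 1e-4)
  k <- 1 / tau + 1 * r
  wstar <- (1 / tau + 1 * 0.1 * r) / k
  for (i in 1:(5 * ceiling(1 / (k * dt)))) {
    w <- scloom:::advance_weights(w, r, dt, tau, 1, 0.1)
  }
  expect_lt(abs(w - wstar) / wstar, 0.01)
  # a = 0: pure recovery regardless of rate
  s0 <- depressing_synapse(w = 0.5, tau_rec = tau, a = 0)
  s0 <- synapse_step(s0, r = 100, dt = 0.01)
  expect_equal(s0$w, synapse_recovery_closed(0.5, 0.01, tau),
               tolerance = 1e-5)
})

test_that("weights stay clamped and the integrator converges under refinement", {
  tau <- 0.2
  w1 <- 1
  w2 <- 1
  for (i in 1:100) w1 <- scloom:::advance_weights(w1, 50, 0.01, tau, 1, 0)
  for (i in 1:200) w2 <- scloom:::advance_weights(w2, 50, 0.005, tau, 1, 0)
  expect_true(w1 >= 0 && w1 <= 1)
  expect_lt(abs(w1 - w2), 1e-4)
})

test_that("widefield pooling is linear in the synaptic weights", {
  cfg <- test_circuit()
  mv <- scloom:::pad_movie(loom_movie(c(0, 0)), 30)
  full <- widefield_response(cfg, mv, w0 = 1)
  half <- widefield_response(cfg, mv, w0 = 0.5)
  f1 <- which(full$rate$values > 0)[1]   # first active frame: weights
  expect_equal(half$rate$values[f1],     # still at their initial values
               0.5 * full$rate$values[f1], tolerance = 1e-3)
  expect_true(all(full$weights >= cfg$w_min & full$weights <= 1))
})

test_that("far-separated simultaneous looms pool additively", {
  cfg <- test_circuit()
  sb <- list(x = c(-50, 50), y = c(-50, 50))
  a <- loom_movie(c(-30, -30), screen_bounds = sb)
  b <- loom_movie(c(30, 30), screen_bounds = sb)
  both <- a
  both$values <- pmin(a$values, b$values)
  ia <- sum(widefield_response(cfg, a)$rate$values)
  ib <- sum(widefield_response(cfg, b)$rate$values)
  iboth <- sum(widefield_response(cfg, both)$rate$values)
  expect_equal(iboth, ia + ib, tolerance = 0.01)
})

test_that("protocol simulation handles empty and repeated stimulation", {
  cfg <- test_circuit()
  empty <- protocol(repeat_loom_protocol(1, 1)$events[0, ])
  s0 <- simulate_protocol(cfg, empty)
  expect_null(s0$events)
  expect_equal(s0$w_final, rep(1, nrow(cfg$grid$centers)))
  s2 <- simulate_protocol(cfg, repeat_loom_protocol(2, 2))
  expect_lt(s2$events$peak[2], s2$events$peak[1])
  expect_lt(s2$events$integral[2], s2$events$integral[1])
})

test_that("widefield response is position invariant across the grid", {
  cfg <- test_circuit()
  g <- loom_grid()
  ev <- lapply(seq_len(25), function(i) {
    widefield_naive_loom(cfg, g$centers[i, ])
  })
  ints <- vapply(ev, `[[`, numeric(1), "integral")
  lats <- vapply(ev, `[[`, numeric(1), "latency")
  expect_lt(stats::sd(ints) / mean(ints), 0.10)
  expect_lt(diff(range(lats)), 1 / cfg$frame_rate + 1e-12)
})

test_that("habituation does not touch synapses of silent detectors", {
  cfg <- test_circuit()
  sim <- simulate_protocol(cfg, repeat_loom_protocol(10, 2,
                                                     location = c(-45, -45)))
  d <- sqrt(rowSums(sweep(cfg$grid$centers, 2, c(-45, -45))^2))
  expect_true(all(sim$w_final[d > 40] == 1))
  expect_lt(min(sim$w_final), 0.01)
})

test_that("recovery simulation shows depression then interval-dependent recovery", {
  cfg <- test_circuit()
  sim <- simulate_protocol(cfg, recovery_protocol())
  fr <- sim$events$integral / sim$events$integral[1]
  expect_true(all(fr[-1] < 1))              # every repeat is suppressed
  expect_lt(min(fr), 0.30)                  # deep suppression at short ISIs
  expect_gt(fr[8], fr[5])                   # the 121 s interval recovers most
  expect_gt(fr[8], min(fr))
})

test_that("simulation traces export as tidy time/unit/value rows", {
  cfg <- test_circuit()
  sim <- simulate_protocol(cfg, repeat_loom_protocol(1, 1),
                           keep_traces = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_simulation(sim, path)
  tab <- utils::read.csv(path)
  expect_setequal(unique(tab$quantity), c("rate", "weight"))
  n_det <- nrow(cfg$grid$centers)
  nf <- length(sim$traces[[1]]$rate)
  expect_equal(nrow(tab), nf * (1 + n_det))
  expect_equal(tab$value[tab$unit == "widefield"], sim$traces[[1]]$rate)
  expect_error(write_simulation(simulate_protocol(
    cfg, repeat_loom_protocol(1, 1)), path), "keep_traces")
})

test_that("simulation warns when events fall outside the detector grid", {
  cfg <- circuit_config(grid = loom_grid(nrow = 3, ncol = 3, spacing = 15))
  p <- repeat_loom_protocol(1, 1, location = c(45, 45))
  expect_warning(simulate_protocol(cfg, p), "outside the detector grid")
})
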