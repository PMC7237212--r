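test_that("background activity extrapolates the pre-stimulus rate", {
  expect_equal(background_activity(numeric(0), 20, 0.5)$mu, 0)
  # 20 spikes in a 10 s window before onset, 0.5 s stimulus -> mu = 1
  st <- seq(10.25, 19.75, length.out = 20)
  b <- background_activity(st, onset = 20, duration = 0.5, window = 10)
  expect_equal(b$mu, 1.0)
  expect_false(b$truncated)
  b2 <- background_activity(st, onset = 20, duration = 1.5, window = 10)
  expect_equal(b2$mu, 3 * b$mu)                       # linear in duration
  b3 <- background_activity(st, onset = 3, duration = 0.5, window = 10)
  expect_true(b3$truncated)
  expect_equal(b3$window_used, 3)
})

test_that("Poisson response test reproduces the worked tail probabilities", {
  # mu = 0.5 floors the Poisson mean at 1
  t5 <- poisson_response_test(5, 0.5)
  expect_equal(t5$lambda_used, 1)
  expect_equal(t5$p, poisson_tail_oracle(5, 1), tolerance = 1e-12)
  expect_equal(t5$p, 0.00366, tolerance = 1e-3)
  expect_true(t5$significant)
  t4 <- poisson_response_test(4, 0.5)
  expect_equal(t4$p, 0.0190, tolerance = 1e-3)
  expect_false(t4$significant)
  expect_equal(poisson_response_test(0, 5)$p, 1)       # P(X >= 0) = 1
})

test_that("Poisson tail agrees with the direct cumulative-sum oracle", {
  for (lambda in c(1, 2.5, 7, 13, 20)) {
    for (r in c(0, 1, 3, 10, 25, 50)) {
      expect_lt(abs(poisson_response_test(r, lambda)$p -
                      poisson_tail_oracle(r, lambda)), 1e-12)
    }
  }
})

test_that("null calibration: false-positive rate stays at or below alpha", {
  set.seed(21)
  mu <- 2
  counts <- rpois(10000, mu)
  sig <- vapply(counts, function(r) {
    poisson_response_test(r, mu)$significant
  }, logical(1))
  se <- sqrt(0.005 * 0.995 / 10000)
  expect_lte(mean(sig), 0.005 + 3 * se)
})

test_that("Bonferroni correction divides the cutoff", {
  expect_equal(bonferroni_alpha(0.005, 1), 0.005)
  expect_equal(bonferroni_alpha(0.005, 100), 5e-5)
  ns <- 1:50
  expect_true(all(diff(bonferroni_alpha(0.005, ns)) < 0))
})

test_that("selectivity index identities and inclusion rules hold", {
  # equal responses -> 0; absent comparison -> 1; antisymmetry
  s0 <- selectivity_index(20, 1, 20, 1)
  expect_equal(s0$index, 0)
  s1 <- selectivity_index(20, 1, 0, 1)
  expect_equal(s1$index, 1)
  sAB <- selectivity_index(20, 1, 8, 1)
  sBA <- selectivity_index(8, 1, 20, 1)
  expect_equal(sAB$index, -sBA$index)
  # scale invariance of the index for included neurons
  sk <- selectivity_index(60, 3, 24, 3)
  expect_equal(sk$index, sAB$index)
  # neither response significant -> excluded
  sx <- selectivity_index(1, 0.5, 0, 0.5)
  expect_false(sx$included)
  expect_true(is.na(sx$index))
  # checkerboard variant: r_O = <r_C> * t_L - mu
  sc <- selectivity_vs_checkerboard(20, 1, mean_checker_rate = 4, t_L = 0.75)
  expect_equal(sc$r_O, 4 * 0.75 - 1)
  expect_equal(sc$index, (19 - 2) / (19 + 2))
})

test_that("habituation index spans facilitation to complete habituation", {
  expect_equal(habituation_index(c(20, rep(1, 8), 0), 0)$index, 1)
  expect_equal(habituation_index(c(20, rep(1, 8), 20), 0)$index, 0)
  expect_equal(habituation_index(c(10, rep(1, 8), 20), 0)$index, -1)
  # scale invariance
  h1 <- habituation_index(c(20, rep(2, 8), 5), 1)
  h2 <- habituation_index(c(60, rep(6, 8), 15), 3)
  expect_equal(h1$index, h2$index)
  # inclusion requires a significant first response
  expect_false(habituation_index(c(2, rep(0, 9)), 0.5)$included)
  # first response at background only -> undefined
  expect_false(habituation_index(c(8, rep(0, 9)), 8)$included)
  # robustness note: i = 4, 7, 10 give the same answer on a clean series
  cnt <- c(20, 1, 1, 1, 1, 1, 1, 1, 1, 1)
  idx <- vapply(c(4, 7, 10), function(i) {
    habituation_index(cnt, 0, i = i)$index
  }, numeric(1))
  expect_true(all(abs(idx - idx[1]) < 1e-12))
})

test_that("recovery fractions and quartiles follow the definitions", {
  counts <- rbind(rep(20, 8),                 # full recovery everywhere
                  c(20, rep(0, 7)))           # silent after the first
  rc <- recovery_curve(counts, mu = c(0, 0), layer = c("dSC", "dSC"))
  expect_equal(rc$fractions[1, ], rep(1, 8))
  expect_equal(rc$fractions[2, -1], rep(0, 7))
  med <- rc$quartiles$median[rc$quartiles$trial == 8]
  expect_equal(med, 0.5)                       # median of {1, 0}
  expect_equal(rc$quartiles$isi[rc$quartiles$trial == 8], 121)
  # non-significant first response is excluded
  rcx <- recovery_curve(rbind(c(1, rep(0, 7))), mu = 0.5)
  expect_true(all(is.na(rcx$fractions)))
})

test_that("receptive-field size follows the corrected mean radial distance", {
  g <- loom_grid()
  x <- g$centers[, 1]
  y <- g$centers[, 2]
  # single responsive location -> size = spacing
  cnt <- rep(0, 25)
  cnt[13] <- 30
  est <- rf_size(cnt, rep(0.2, 25), x, y)
  expect_equal(est$delta, 0)
  expect_equal(est$size, 15)
  # two equal responses 30 deg apart -> center at midpoint, size 45
  cnt2 <- rep(0, 25)
  sel <- which(y == 0 & x %in% c(-15, 15))
  cnt2[sel] <- 40
  est2 <- rf_size(cnt2, rep(0.2, 25), x, y)
  expect_equal(est2$center, c(0, 0))
  expect_equal(est2$delta, 15)
  expect_equal(est2$size, 45)
  # uniform response over the full grid vs exhaustive-sum oracle
  cnt3 <- rep(40, 25)
  est3 <- rf_size(cnt3, rep(0.2, 25), x, y)
  delta_oracle <- mean(sqrt(x^2 + y^2))
  expect_equal(est3$delta, delta_oracle, tolerance = 1e-12)
  expect_equal(est3$size, 2 * delta_oracle + 15)
  # translation equivariance
  est3b <- rf_size(cnt3, rep(0.2, 25), x + 7, y - 11)
  expect_equal(est3b$center, est3$center + c(7, -11))
  expect_equal(est3b$delta, est3$delta)
  expect_equal(est3b$size, est3$size)
  # nothing significant -> excluded
  estx <- rf_size(rep(1, 25), rep(0.5, 25), x, y)
  expect_false(estx$included)
  expect_true(is.na(estx$size))
})

test_that("latency statistics apply the timing and inclusion rules", {
  onsets <- (0:9) * 3
  dur <- rep(0.75, 10)
  # every trial: burst of spikes with the first at exactly 50 ms
  st <- as.vector(vapply(onsets, function(o) o + c(0.05, 0.1, 0.15, 0.2,
                                                   0.25, 0.3, 0.35, 0.4),
                         numeric(8)))
  ls <- latency_stats(st, onsets, dur, mu = rep(0.1, 10))
  expect_true(ls$included)
  expect_lt(ls$sd, 1e-12)
  expect_true(all(abs(ls$latencies - 0.05) < 1e-9))
  # spikes before 30 ms never count as the response latency
  st2 <- sort(c(st, onsets + 0.010))
  ls2 <- latency_stats(st2, onsets, dur, mu = rep(0.1, 10))
  expect_true(all(abs(ls2$latencies - 0.05) < 1e-9))
  # neurons with high background are excluded outright
  lsx <- latency_stats(st, onsets, dur, mu = rep(1.2, 10))
  expect_false(lsx$included)
  expect_match(lsx$reason, "background")
  # fewer than five significant trials excludes the neuron
  ls5 <- latency_stats(st[1:24], onsets[1:3], dur[1:3], mu = rep(0.1, 3))
  expect_false(ls5$included)
})

test_that("latency sd uses the sample (n-1) denominator", {
  onsets <- (0:4) * 3
  lat <- c(0.05, 0.07, 0.09, 0.07, 0.07)
  st <- as.vector(vapply(seq_along(onsets), function(i) {
    onsets[i] + c(lat[i], lat[i] + 0.05, lat[i] + 0.1, lat[i] + 0.15,
                  lat[i] + 0.2, lat[i] + 0.25)
  }, numeric(6)))
  ls <- latency_stats(st, onsets, rep(0.75, 5), mu = rep(0.1, 5))
  expect_true(ls$included)
  expect_equal(ls$latencies, lat)
  expect_equal(ls$sd, stats::sd(lat))          # {0.05,0.07,0.09,...} n-1 form
  expect_equal(stats::sd(c(0.05, 0.07, 0.09)), 0.02)
})
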