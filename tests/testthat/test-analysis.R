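test_that("IPSP amplitude follows the max/min rule", {
  dt <- 0.1
  t <- seq(0, 100, by = dt)
  base <- rep(-70, length(t))
  shape <- 0.05 * exp(-t / 12) - 0.23 * exp(-t / 8) # max +, larger min -
  rec <- extract_ipsp(base + shape, base, 0, window_ms = 100, dt_ms = dt)
  expect_equal(rec$amplitude_mv, min(shape))      # -0.18 lobe dominates
  expect_lt(rec$amplitude_mv, 0)
  flipped <- extract_ipsp(base - shape, base, 0, window_ms = 100,
                          dt_ms = dt)
  expect_equal(flipped$amplitude_mv, -min(shape)) # sign tracks the lobe
  # identically equal traces are excluded, not zero-amplitude
  z <- extract_ipsp(base, base, 0, window_ms = 100, dt_ms = dt)
  expect_true(z$excluded)
  expect_true(is.na(z$amplitude_mv))
  expect_error(extract_ipsp(base, base[-1], 0, 100, dt), "misaligned")
})

test_that("double-exponential fits recover noiseless parameters", {
  t <- seq(0, 80, by = 0.25)
  v <- 0.12 * (exp(-t / 10.5) - exp(-t / 6.3))
  f <- fit_double_exponential(t, v)
  expect_true(f$accepted)
  expect_lt(abs(f$T1 - 10.5) / 10.5, 0.01)
  expect_lt(abs(f$T2 - 6.3) / 6.3, 0.01)
  # peak of the fitted curve at the closed-form location
  v2 <- -0.4 * (exp(-t / 10.4) - exp(-t / 4.4)) # hyperpolarizing IPSP
  f2 <- fit_double_exponential(t, v2)
  tpk <- syn_peak_time(f2$T2, f2$T1)
  expect_lt(abs(tpk - 6.5612), 0.05)
  expect_gt(f2$r_squared, 0.99)
})

test_that("parameter recovery holds to 5% under 5% peak noise", {
  set.seed(42)
  t <- seq(0, 100, by = 0.1) # sampling density of the IPSP protocol
  cases <- data.frame(T1 = c(9, 12, 14, 10.4, 11),
                      T2 = c(4, 6, 7, 4.4, 2.5))
  for (i in seq_len(nrow(cases))) {
    T1 <- cases$T1[i]; T2 <- cases$T2[i]
    clean <- 0.2 * (exp(-t / T1) - exp(-t / T2))
    noisy <- clean + rnorm(length(t), sd = 0.05 * max(clean))
    f <- fit_double_exponential(t, noisy)
    expect_true(f$accepted)
    expect_lt(abs(f$T1 - T1) / T1, 0.05)
    expect_lt(abs(f$T2 - T2) / T2, 0.05)
  }
})

test_that("pure noise is rejected by the R-squared filter", {
  set.seed(7)
  t <- seq(0, 80, by = 0.5)
  f <- fit_double_exponential(t, rnorm(length(t)))
  expect_false(f$accepted)
  expect_error(fit_double_exponential(t[1:5], rnorm(5)), "at least 10")
})

test_that("the one-sample z-test matches the closed form", {
  expect_equal(one_sample_ztest(c(9, 10, 11), 10)$z, 0)
  expect_true(one_sample_ztest(c(9, 10, 11), 10)$equivalent)
  # frozen from the closed form: (10.2 - 6.3) / (3.6 / sqrt(47))
  m <- 10.2; s <- 3.6; n <- 47; mu <- 6.3
  expect_equal((m - mu) / (s / sqrt(n)), 7.42696, tolerance = 1e-6)
  # build a sample with that exact mean/sd and check the pipeline
  set.seed(1)
  x <- scale(rnorm(n))[, 1] * s + m
  zt <- one_sample_ztest(x, mu)
  expect_equal(zt$z, 7.42696, tolerance = 1e-6)
  expect_false(zt$equivalent)
  # the (-1.96, 1.96) interval is open: |z| = 1.96 is not equivalent
  y <- c(-1, 1) # mean 0, sd sqrt(2), se exactly 1
  expect_equal(one_sample_ztest(y, -1.96)$z, 1.96)
  expect_false(one_sample_ztest(y, -1.96)$equivalent)
  expect_error(one_sample_ztest(5, 0), "at least 2")
  expect_error(one_sample_ztest(c(3, 3, 3), 0), "variance")
})

test_that("peri-event histograms bin single events correctly", {
  h <- perievent_histogram(list(110), 100, c(-50, 50), 10)
  expect_equal(sum(h$counts), 1)
  expect_equal(h$counts[h$mids == 15], 1) # offset 10 -> the [10, 20) bin
  h0 <- perievent_histogram(list(numeric(0), numeric(0)), c(10, 20),
                            c(-50, 50), 5)
  expect_true(all(h0$counts == 0))
  expect_error(perievent_histogram(list(1), numeric(0), c(-50, 50), 5),
               "empty event")
})

test_that("histogram totals equal the exhaustive pair count", {
  for (s in 1:5) {
    set.seed(s)
    raster <- lapply(1:6, function(i) sort(runif(sample(0:30, 1), 0, 500)))
    events <- sort(runif(8, 0, 500))
    w <- c(-40, 60); bs <- 7
    h <- perievent_histogram(raster, events, w, bs)
    spikes <- unlist(raster)
    brute <- sum(vapply(events, function(ev) {
      sum(spikes - ev >= w[1] & spikes - ev < h$breaks[length(h$breaks)])
    }, numeric(1)))
    expect_equal(sum(h$counts), brute)
    # events near the recording edge are truncated, not dropped
    h_edge <- perievent_histogram(raster, c(1, 499), w, bs)
    expect_equal(h_edge$n_events, 2)
  }
})

test_that("suppression fractions mirror the ON/OFF spike counts", {
  off <- list(seq(6, 30, length.out = 1000) + 100)  # 1000 spikes in window
  on <- list(seq(6, 30, length.out = 126) + 100)
  s <- suppression_fraction(on, off, 100, window = c(5, 30))
  expect_equal(s$fraction_remaining, 0.126)
  s2 <- suppression_fraction(off, off, 100, window = c(5, 30))
  expect_equal(s2$fraction_remaining, 1)
  expect_error(suppression_fraction(on, list(numeric(0)), 100,
                                    window = c(5, 30)),
               "undefined")
})

test_that("ensemble spike sd uses the population convention", {
  # offsets -1, 0, +1 around one event
  expect_equal(ensemble_spike_sd(list(c(99, 100, 101)), 100,
                                 window = c(-5, 5)),
               sqrt(2 / 3))
  expect_equal(ensemble_spike_sd(list(c(10, 135)), c(0, 125),
                                 window = c(0, 30)), 0)
  expect_error(ensemble_spike_sd(list(c(10)), c(0), window = c(0, 30)),
               "fewer than 2")
})

test_that("rate statistics summarize per-cell counts", {
  raster <- rep(list(seq_len(13) * 150), 20) # 13 spikes in 2 s each
  rs <- rate_stats(raster, 2000)
  expect_equal(rs$mean_hz, 6.5)
  expect_equal(rs$sd_hz, 0)
  expect_equal(sum(rs$hist), 20) # histogram mass = number of cells
  expect_equal(rate_stats(list(numeric(0)), 1000)$mean_hz, 0)
})
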