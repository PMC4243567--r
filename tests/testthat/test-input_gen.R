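test_that("zero jitter and zero shift recover the constant-ISI train", {
  expect_equal(generate_train(input_train_spec(100, 100)),
               seq(10, 100, by = 10))
  expect_equal(generate_train(input_train_spec(8, 2000)),
               seq(125, 2000, by = 125))
})

test_that("uncorrelated specs use ISI/4 jitter and one-ISI shift", {
  s1 <- uncorrelated_spec(1000, 2000)
  expect_equal(s1$jitter_sd, 0.25)
  expect_equal(s1$shift_max, 1)
  s2 <- uncorrelated_spec(8, 2000)
  expect_equal(s2$jitter_sd, 31.25)
  expect_equal(s2$shift_max, 125)
})

test_that("clipped trains preserve the requested rate", {
  rates <- vapply(1:120, function(s) {
    length(generate_train(uncorrelated_spec(600, 2000, seed = s))) / 2
  }, numeric(1))
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 600), 3 * se)
  # small-jitter trains keep the nominal count up to edge effects
  # (re-draw, not thinning: only window-edge spikes can be gained/lost)
  counts <- vapply(1:30, function(s) {
    length(generate_train(input_train_spec(100, 1000, jitter_sd = 0.5,
                                           shift_max = 0, seed = s)))
  }, integer(1))
  expect_true(all(abs(counts - 100) <= 2))
  expect_lt(abs(mean(counts) - 100), 1)
})

test_that("the Gaussian re-draw has the requested displacement sd", {
  # ISI = 50 ms >> sigma, so nearest-scaffold pairing is unambiguous
  disp <- unlist(lapply(1:60, function(s) {
    tr <- generate_train(input_train_spec(20, 2000, jitter_sd = 2.5,
                                          shift_max = 0, seed = s))
    tr <- tr[tr > 60 & tr < 1940]
    tr - 50 * round(tr / 50)
  }))
  expect_lt(abs(sd(disp) - 2.5), 0.1)
})

test_that("trains are reproducible per seed and differ across seeds", {
  a <- generate_train(uncorrelated_spec(200, 500, seed = 9))
  b <- generate_train(uncorrelated_spec(200, 500, seed = 9))
  c <- generate_train(uncorrelated_spec(200, 500, seed = 10))
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_true(all(diff(a) > 0))          # strictly increasing
  expect_true(all(a > 0 & a <= 500))     # inside the window
})

test_that("ensemble plans share one exact rhythm across members", {
  plan <- ensemble_inputs(2744, 0.5, 8, uncorrelated_spec(600, 2000),
                          seed = 3)
  expect_equal(which(plan$membership), 1:1372)
  expect_length(plan$shared_rhythm, 16) # 8 events/s for 2 s
  all_in <- ensemble_inputs(10, 1, 8, uncorrelated_spec(600, 1000))
  expect_true(all(all_in$membership))
})

test_that("synchronized FSI plans duplicate inputs; independent ones differ", {
  idp <- synchronized_fsi_inputs(4, "identical", burst_period = 125,
                                 burst_len = 40, noise_freq = 7,
                                 n_syn = 10L, duration = 1000, seed = 2)
  expect_identical(idp$trains[[1]], idp$trains[[2]])
  expect_identical(idp$trains[[1]], idp$trains[[4]])
  expect_equal(idp$burst_onsets, seq(0, 875, by = 125)) # 8 onsets in 1 s
  # all gated spikes fall inside the burst windows
  phases <- unlist(idp$trains[[1]]) %% 125
  expect_true(all(phases < 40))
  ind <- synchronized_fsi_inputs(4, "independent", noise_freq = 7,
                                 n_syn = 10L, duration = 1000, seed = 2)
  expect_false(identical(ind$trains[[1]], ind$trains[[2]]))
  expect_error(synchronized_fsi_inputs(2, "interleaved"))
})

test_that("raster TSV round trips preserve trains", {
  trains <- list(c(1.5, 20, 300), numeric(0), c(7, 7.5))
  path <- tempfile(fileext = ".tsv")
  write_raster_tsv(trains, path, meta = list(seed = 4))
  back <- read_raster_tsv(path, n_ids = 3)
  expect_equal(back, trains)
  expect_true(file.exists(paste0(path, ".json")))
  unlink(c(path, paste0(path, ".json")))
})
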