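test_that("RR files parse in order, tolerate comments and incidental delimiters", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("# subject s01", "850", "", "950,", "  1020  "), path)
  rr <- read_rr_file(path)
  expect_s3_class(rr, "rr_series")
  expect_equal(rr$intervals, c(850, 950, 1020))
  expect_identical(rr$source, "rr_file")
})

test_that("RR parse errors and warnings follow the contract", {
  bad <- tempfile(fileext = ".txt")
  writeLines(c("abc"), bad)
  expect_error(read_rr_file(bad), "line 1")

  empty <- tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_warning(rr <- read_rr_file(empty), "no intervals")
  expect_length(rr$intervals, 0)

  neg <- tempfile(fileext = ".txt")
  writeLines(c("900", "-5"), neg)
  expect_error(read_rr_file(neg), "positive")

  # second-scale values are not silently converted
  expect_warning(rr_series(c(0.85, 0.95)), "milliseconds")
})

test_that("RR write/read round-trips values at printed precision", {
  vals <- c(850.25, 912.333333333, 1004.5)
  path <- tempfile(fileext = ".txt")
  write_rr_file(rr_series(vals), path)
  expect_equal(read_rr_file(path)$intervals, vals)
})

test_that("EKG reader stores samples and sampling rate, validating both", {
  path <- tempfile(fileext = ".txt")
  writeLines(as.character(seq_len(300)), path)
  sig <- read_ekg_file(path, 100)
  expect_length(sig$samples, 300)
  expect_equal(length(sig$samples) / sig$sampling_rate_hz, 3)
  expect_error(read_ekg_file(path, 0), "positive")

  # round-trip of a synthetic pulse train through disk is exact
  pt <- simulate_ekg_pulsetrain(c(900, 950, 880), noise_sd = 0.05, seed = 2)
  p2 <- tempfile(fileext = ".txt")
  writeLines(formatC(pt$ekg$samples, digits = 17, format = "g"), p2)
  expect_equal(read_ekg_file(p2, 100)$samples, pt$ekg$samples)
})

test_that("peak detector recovers planted impulse trains and honours the refractory rule", {
  # impulses every 90 samples at 100 Hz
  rr <- rep(900, 20)
  pt <- simulate_ekg_pulsetrain(rr, sampling_rate_hz = 100, noise_sd = 0)
  det <- detect_r_peaks(pt$ekg, refractory_ms = 300)
  expect_equal(as.integer(det), as.integer(pt$peaks))
  expect_length(det, length(rr) + 1)

  # flat zero signal has no peaks
  flat <- ekg_signal(rep(0, 1000), 100)
  expect_length(detect_r_peaks(flat), 0)

  # two impulses 100 ms apart with a 300 ms refractory keep exactly one
  x <- numeric(500)
  x[c(200, 210)] <- c(1, 0.8)
  one <- detect_r_peaks(ekg_signal(x, 100), refractory_ms = 300)
  expect_length(one, 1)

  # signal shorter than one refractory window warns and returns empty
  expect_warning(short <- detect_r_peaks(ekg_signal(c(0, 1, 0), 100),
                                         refractory_ms = 300),
                 "refractory")
  expect_length(short, 0)
})

test_that("RR derivation from peaks follows the index arithmetic", {
  rr <- rr_from_peaks(peak_indices(c(0, 90, 185)), 100)
  expect_equal(rr$intervals, c(900, 950))
  expect_identical(rr$source, "ekg_derived")

  expect_error(rr_from_peaks(peak_indices(0L), 100), "two peaks")
  expect_error(peak_indices(c(5, 5, 9)), "increasing")

  # constant spacing gives constant intervals; length = peaks - 1
  pk <- peak_indices(seq(0, 800, by = 80))
  out <- rr_from_peaks(pk, 100)
  expect_true(all(out$intervals == 800))
  expect_length(out$intervals, length(pk) - 1)
})

test_that("detection plus derivation recovers generator RR series on clean signals", {
  set.seed(42)
  for (rep in 1:5) {
    rr_true <- round(runif(30, 700, 1200))
    pt <- simulate_ekg_pulsetrain(rr_true, sampling_rate_hz = 100,
                                  noise_sd = 0)
    det <- detect_r_peaks(pt$ekg, refractory_ms = 250)
    expect_equal(as.integer(det), as.integer(pt$peaks))
    rr_hat <- rr_from_peaks(det, 100)
    # exact up to the 10 ms sample quantisation of the pulse placement
    expect_true(all(abs(rr_hat$intervals - rr_true) <= 10))
  }
})
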