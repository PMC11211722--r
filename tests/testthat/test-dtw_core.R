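test_that("extract_window maps time windows to the right samples", {
  w <- waveform(rnorm(1000), fs = 500, t0 = -200)
  ww <- extract_window(w, c(150, 400))
  expect_length(ww$samples, 126L)
  expect_equal(ww$t0, 150)
  expect_equal(ww$fs, 500)

  # full-span window is the identity
  full <- extract_window(w, c(-200, -200 + 999 * 2))
  expect_identical(full$samples, w$samples)

  # count verified against brute-force index enumeration
  w2 <- waveform(rnorm(200), fs = 250, t0 = 0)
  t <- time_axis(w2)
  oracle_count <- sum(t >= 150 & t <= 400)
  expect_length(extract_window(w2, c(150, 400))$samples, oracle_count)
  expect_identical(oracle_count, 63L)

  expect_error(extract_window(w, c(-400, 100)), "outside")
  expect_error(extract_window(w, c(400, 150)), "start < end")
})

test_that("z-scoring standardizes within the window and rejects constants", {
  w <- waveform(c(1, 2, 3), fs = 100)
  z <- zscore_waveform(w)
  expect_equal(mean(z$samples), 0)
  expect_equal(sd(z$samples), 1)
  expect_true(all(diff(z$samples) > 0))  # shape preserved

  # idempotence up to floating tolerance
  z2 <- zscore_waveform(z)
  expect_equal(z2$samples, z$samples, tolerance = 1e-12)

  # hand-computed: mean 0.25, sample SD (n - 1 divisor) 0.5
  z3 <- zscore_waveform(waveform(c(0, 0, 1, 0), fs = 100))
  expect_equal(z3$samples, c(-0.5, -0.5, 1.5, -0.5))

  expect_error(zscore_waveform(waveform(rep(2, 5), fs = 100)), "constant")
})

test_that("dtw_align matches exhaustive path enumeration and emits valid paths", {
  fs <- 100
  # exhaustive over all pairs of length-2 and length-3 series, 3-value alphabet
  series <- c(alphabet_series(2), alphabet_series(3))
  for (q in series) {
    for (r in series) {
      al <- dtw_align(waveform(r, fs), waveform(q, fs))
      expect_equal(al$cumulative_distance, brute_force_dtw(q, r))
    }
  }

  # sampled longer pairs (lengths 4-6), continuous amplitudes
  set.seed(42)
  for (i in 1:100) {
    nq <- sample(4:6, 1); nr <- sample(4:6, 1)
    q <- round(rnorm(nq), 2); r <- round(rnorm(nr), 2)
    al <- dtw_align(waveform(r, fs), waveform(q, fs))
    expect_equal(al$cumulative_distance, brute_force_dtw(q, r))
    expect_valid_path(al$path, nq, nr)
  }

  # worked example: reference [0,1,0], query [0,0,1,0]
  al <- dtw_align(waveform(c(0, 1, 0), fs), waveform(c(0, 0, 1, 0), fs))
  expect_equal(al$cumulative_distance, brute_force_dtw(c(0, 0, 1, 0), c(0, 1, 0)))
  expect_equal(al$cumulative_distance, 0)
  expect_valid_path(al$path, 4L, 3L)
  # query's extra early sample pushes the path below the diagonal: area > 0
  expect_gt(dtw_area(al), 0)

  expect_error(dtw_align(waveform(1:3, 100), waveform(1:3, 200)), "sampling rate")
})

test_that("dtw_area sums signed horizontal distances", {
  diag_path <- cbind(x = 1:5, y = 1:5)
  expect_identical(dtw_area(diag_path), 0)

  path <- cbind(x = c(0, 1, 2, 3, 3) + 1, y = c(0, 0, 1, 2, 3) + 1)
  expect_identical(dtw_area(path), 3)
  expect_identical(dtw_distances(path), c(0, 1, 1, 1, 0))
})

test_that("area is antisymmetric under role swap for pure shifts", {
  for (shift in c(8, 20, 40)) {
    ref <- zscore_waveform(extract_window(gauss_bump(300), c(100, 600)))
    qry <- zscore_waveform(extract_window(gauss_bump(300 + shift), c(100, 600)))
    a_fwd <- dtw_area(dtw_align(ref, qry))
    a_rev <- dtw_area(dtw_align(qry, ref))
    expect_gt(a_fwd, 0)  # reference leads
    expect_equal(a_rev, -a_fwd, tolerance = 0.02 * abs(a_fwd) + 2)
  }
})

test_that("identical inputs give exactly zero area and latency", {
  w <- zscore_waveform(gauss_bump(300))
  res <- dtw_latency(w, w, standardize = FALSE)
  expect_identical(res$area, 0)
  expect_identical(res$latency_ms, 0)
  expect_identical(res$cumulative_distance, 0)
  # path is the main diagonal
  expect_identical(res$path[, "x"], res$path[, "y"])
})

test_that("latency recovers injected shifts within 25% and monotonically", {
  fs <- 250
  shifts_ms <- c(20, 40, 80)
  est <- vapply(shifts_ms, function(s) {
    dtw_latency(gauss_bump(300, fs = fs), gauss_bump(300 + s, fs = fs),
                window = c(100, 700))$latency_ms
  }, numeric(1))
  expect_true(all(abs(est - shifts_ms) <= 0.25 * shifts_ms))
  expect_true(all(diff(est) >= 0))
})

test_that("latency_ms converts the median distance by the sampling rate", {
  expect_equal(dtw_latency_ms(rep(9, 5), fs = 500), 18)
  expect_equal(dtw_latency_ms(c(-1, 0, 1), fs = 500), 0)
  expect_equal(dtw_latency_ms(c(2, 3, 10), fs = 250), 12)
  expect_error(dtw_latency_ms(numeric(0), fs = 500), "empty")
})
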