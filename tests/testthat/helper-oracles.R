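# Independent oracles used across the suite.

# Brute-force DTW: enumerate every monotone path from (1, 1) to (nx, ny)
# with steps {(1,0), (0,1), (1,1)} and return the minimal cumulative
# |query[x] - reference[y]| cost. Feasible for lengths <= 6.
brute_force_dtw <- function(query, reference) {
  nx <- length(query); ny <- length(reference)
  best <- Inf
  recurse <- function(i, j, acc) {
    acc <- acc + abs(query[i] - reference[j])
    if (acc >= best) return(invisible())
    if (i == nx && j == ny) {
      best <<- acc
      return(invisible())
    }
    if (i < nx && j < ny) recurse(i + 1, j + 1, acc)
    if (j < ny) recurse(i, j + 1, acc)
    if (i < nx) recurse(i + 1, j, acc)
  }
  recurse(1L, 1L, 0)
  best
}

# Check the structural invariants of a warping path (1-based indices).
expect_valid_path <- function(path, nx, ny) {
  expect_identical(unname(path[1, ]), c(1L, 1L))
  expect_identical(unname(path[nrow(path), ]), c(nx, ny))
  if (nrow(path) > 1) {
    steps <- diff(path)
    expect_true(all(steps >= 0 & steps <= 1))
    expect_true(all(rowSums(steps) >= 1))
  }
}

# Exact sign-flip permutation p-value by enumerating all 2^n flip patterns,
# using the same grand-average -> window -> z-score -> DTW-area pipeline.
exact_permutation_p <- function(cond_a, cond_b, window) {
  n <- nrow(cond_a$data)
  obs <- dtw_latency(grand_average(cond_a), grand_average(cond_b),
                     window = window)$area
  areas <- vapply(0:(2^n - 1), function(mask) {
    flip <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    da <- cond_a$data; db <- cond_b$data
    da[flip, ] <- cond_b$data[flip, , drop = FALSE]
    db[flip, ] <- cond_a$data[flip, , drop = FALSE]
    ga <- erp_dataset(da, cond_a$fs, cond_a$t0)
    gb <- erp_dataset(db, cond_b$fs, cond_b$t0)
    dtw_latency(grand_average(ga), grand_average(gb), window = window)$area
  }, numeric(1))
  list(observed = obs, p = mean(abs(areas) >= abs(obs)))
}

# Smooth unimodal test bump as a waveform.
gauss_bump <- function(center_ms, width_ms = 40, fs = 250,
                       span = c(-200, 1000), amplitude = 1) {
  t <- seq(span[1], span[2], by = 1000 / fs)
  waveform(amplitude * exp(-(t - center_ms)^2 / (2 * width_ms^2)),
           fs = fs, t0 = span[1])
}

# All series of a given length over a small amplitude alphabet.
alphabet_series <- function(len, alphabet = c(-1, 0, 1)) {
  grid <- do.call(expand.grid, rep(list(alphabet), len))
  lapply(seq_len(nrow(grid)), function(i) as.numeric(grid[i, ]))
}
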