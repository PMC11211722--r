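#' Construct an ERP waveform
#'
#' A waveform is an ordered series of amplitudes (microvolts or z-units)
#' sampled at a fixed rate, together with the time of its first sample
#' relative to stimulus onset. Sample `i` (1-based) sits at time
#' `t0 + (i - 1) * 1000 / fs` milliseconds.
#'
#' @param samples numeric vector of amplitudes; length >= 2, all finite.
#' @param fs sampling rate in Hz; must be positive.
#' @param t0 time of the first sample relative to stimulus onset, in ms.
#' @return An object of class `erp_waveform`.
#' @examples
#' w <- waveform(sin(seq(0, 2 * pi, length.out = 100)), fs = 250, t0 = -100)
#' w
#' @export
waveform <- function(samples, fs, t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("a waveform needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("waveform samples must all be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("`t0` must be a single finite number (ms)", call. = FALSE)
  structure(list(samples = samples, fs = fs, t0 = t0),
            class = "erp_waveform")
}

#' @export
print.erp_waveform <- function(x, ...) {
  cat(sprintf("<erp_waveform> %d samples @ %g Hz, t = [%g, %g] ms\n",
              length(x$samples), x$fs, x$t0,
              x$t0 + (length(x$samples) - 1) * 1000 / x$fs))
  invisible(x)
}

#' @export
length.erp_waveform <- function(x) length(x$samples)

#' Sample times of a waveform
#'
#' @param w an [waveform()] object.
#' @return Numeric vector of sample times in ms relative to stimulus onset.
#' @export
time_axis <- function(w) {
  stopifnot(inherits(w, "erp_waveform"))
  w$t0 + (seq_along(w$samples) - 1) * 1000 / w$fs
}

# Map a time in ms to the nearest 1-based sample index.
time_to_index <- function(w, t_ms) {
  as.integer(round((t_ms - w$t0) * w$fs / 1000)) + 1L
}

#' Extract a time window from a waveform
#'
#' Returns the samples whose times fall inside `[window[1], window[2]]` ms
#' (both ends inclusive); `t0` is updated to the time of the first retained
#' sample, the sampling rate is unchanged. Window endpoints are mapped to
#' sample indices by rounding `(t - t0) * fs / 1000`.
#'
#' @param w an [waveform()] object.
#' @param window numeric length-2, `c(start_ms, end_ms)` with start < end;
#'   must lie within the waveform's time span and cover at least 2 samples.
#' @return The windowed `erp_waveform`.
#' @examples
#' w <- waveform(rnorm(1000), fs = 500, t0 = -200)
#' length(extract_window(w, c(150, 400)))  # 126 samples
#' @export
extract_window <- function(w, window) {
  stopifnot(inherits(w, "erp_waveform"))
  if (length(window) != 2L || !all(is.finite(window)) || window[1] >= window[2])
    stop("`window` must be c(start_ms, end_ms) with start < end", call. = FALSE)
  span <- c(w$t0, w$t0 + (length(w$samples) - 1) * 1000 / w$fs)
  if (window[1] < span[1] - 1e-9 || window[2] > span[2] + 1e-9)
    stop(sprintf("window [%g, %g] ms outside waveform span [%g, %g] ms",
                 window[1], window[2], span[1], span[2]), call. = FALSE)
  i0 <- max(1L, time_to_index(w, window[1]))
  i1 <- min(length(w$samples), time_to_index(w, window[2]))
  # keep only samples truly inside the window (rounding can step just outside)
  t <- w$t0 + (c(i0, i1) - 1) * 1000 / w$fs
  if (t[1] < window[1] - 1e-9) i0 <- i0 + 1L
  if (t[2] > window[2] + 1e-9) i1 <- i1 - 1L
  if (i1 - i0 + 1L < 2L)
    stop("window maps to fewer than 2 samples at this sampling rate",
         call. = FALSE)
  waveform(w$samples[i0:i1], fs = w$fs, t0 = w$t0 + (i0 - 1) * 1000 / w$fs)
}

#' z-score a waveform
#'
#' Standardizes the samples to mean 0 and sample standard deviation 1
#' (divisor `n - 1`). Waveforms must be standardized before DTW so that the
#' warping path reflects differences in contour, not gross amplitude
#' differences; apply after [extract_window()].
#'
#' @param w an [waveform()] object with non-constant samples.
#' @return The standardized `erp_waveform`.
#' @export
zscore_waveform <- function(w) {
  stopifnot(inherits(w, "erp_waveform"))
  s <- sd(w$samples)
  if (!is.finite(s) || s == 0)
    stop("cannot z-score a constant waveform", call. = FALSE)
  waveform((w$samples - mean(w$samples)) / s, fs = w$fs, t0 = w$t0)
}
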