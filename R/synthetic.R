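#' Smooth unimodal component template
#'
#' Builds a template deflection for a synthetic ERP component: a Gaussian
#' bump (or an asymmetric gamma-shaped bump, to mimic the skewed P3) of
#' given center, width, amplitude and polarity, zero elsewhere.
#'
#' @param center_ms peak time (ms relative to stimulus onset).
#' @param width_ms bump scale in ms: the Gaussian SD, or the gamma mode
#'   scale for `shape = "gamma"`.
#' @param amplitude peak magnitude (> 0); the signed peak is
#'   `amplitude * polarity`.
#' @param polarity +1 for a positive-going deflection (e.g. P3), -1 for a
#'   negative-going one (e.g. N2pc).
#' @param fs sampling rate (Hz).
#' @param span epoch `c(t0, t_end)` in ms; the bump (center +/- 3 widths)
#'   must fit inside it.
#' @param shape `"gaussian"` (default) or `"gamma"` (right-skewed, mode at
#'   `center_ms`).
#' @return A [waveform()] covering the span.
#' @export
make_template <- function(center_ms, width_ms, amplitude = 1, polarity = -1,
                          fs = 500, span = c(-200, 1000),
                          shape = c("gaussian", "gamma")) {
  shape <- match.arg(shape)
  stopifnot(width_ms > 0, amplitude >= 0, polarity %in% c(-1, 1))
  if (center_ms - 3 * width_ms < span[1] || center_ms + 3 * width_ms > span[2])
    stop("bump (center +/- 3 widths) does not fit inside the epoch span",
         call. = FALSE)
  t <- seq(span[1], span[2], by = 1000 / fs)
  y <- switch(shape,
    gaussian = exp(-(t - center_ms)^2 / (2 * width_ms^2)),
    gamma = {
      # shape k = 4; scaled so the mode sits at center_ms
      k <- 4
      theta <- width_ms / sqrt(k)           # mode-to-inflection scale
      onset <- center_ms - (k - 1) * theta
      x <- pmax(t - onset, 0) / theta
      g <- x^(k - 1) * exp(-x)
      g / max(g)
    })
  waveform(polarity * amplitude * y, fs = fs, t0 = span[1])
}

#' Specification for a synthetic two-component ERP experiment
#'
#' Bundles the parameters of the generator: group size, sampling, epoch
#' span, the two component templates (an early negative N2pc-like bump and
#' a later, broader positive P3-like bump), the per-participant latency
#' model, the cross-component latency coupling
#' `latency2 = a + b * latency1 + e`, the condition shift applied to both
#' components in the "late" condition, and the EEG-noise amplitude.
#'
#' Defaults emulate the study conditions the inference tools target: 23
#' participants, two conditions whose components are delayed by ~20 ms in
#' the late condition, unit-slope latency coupling, and noise small
#' relative to the component amplitudes.
#'
#' @param n_participants group size (default 23).
#' @param fs sampling rate in Hz (default 500).
#' @param span epoch `c(t0, t_end)` in ms (default -200 to 1000).
#' @param comp1,comp2 template parameter lists: `center_ms`, `width_ms`,
#'   `amplitude`, `polarity`, and optionally `shape`.
#' @param latency_sd SD (ms) of per-participant latency jitter around the
#'   template centers (population mean 0).
#' @param coupling_a,coupling_b intercept (ms) and slope of the
#'   latency2-on-latency1 coupling.
#' @param coupling_sd SD (ms) of the coupling residual.
#' @param condition_shift_ms delay added to both components in the late
#'   condition (default 20).
#' @param noise_lambda amplitude of additive EEG-spectrum noise (default
#'   0.1; component amplitudes are 1 and 2, so this is a high-SNR regime).
#' @param max_retries resampling budget per participant when a drawn
#'   latency would push a bump outside the epoch.
#' @return A list of class `erp_synth_spec`.
#' @export
synth_spec <- function(n_participants = 23L, fs = 500, span = c(-200, 1000),
                       comp1 = list(center_ms = 275, width_ms = 40,
                                    amplitude = 1, polarity = -1),
                       comp2 = list(center_ms = 500, width_ms = 90,
                                    amplitude = 2, polarity = 1),
                       latency_sd = 20, coupling_a = 0, coupling_b = 1,
                       coupling_sd = 10, condition_shift_ms = 20,
                       noise_lambda = 0.1, max_retries = 100L) {
  stopifnot(n_participants >= 2, latency_sd >= 0, coupling_sd >= 0,
            noise_lambda >= 0, condition_shift_ms >= 0)
  structure(list(n_participants = as.integer(n_participants), fs = fs,
                 span = span, comp1 = comp1, comp2 = comp2,
                 latency_sd = latency_sd, coupling_a = coupling_a,
                 coupling_b = coupling_b, coupling_sd = coupling_sd,
                 condition_shift_ms = condition_shift_ms,
                 noise_lambda = noise_lambda,
                 max_retries = as.integer(max_retries)),
            class = "erp_synth_spec")
}

template_fits <- function(comp, latency, shift, span) {
  c0 <- comp$center_ms + latency + shift
  c0 - 3 * comp$width_ms >= span[1] && c0 + 3 * comp$width_ms <= span[2]
}

participant_wave <- function(comp, latency, shift, spec) {
  args <- comp
  args$center_ms <- comp$center_ms + latency + shift
  args$fs <- spec$fs
  args$span <- spec$span
  w <- do.call(make_template, args)
  if (spec$noise_lambda > 0)
    w$samples <- w$samples +
      eeg_noise(length(w$samples), spec$fs, spec$noise_lambda)
  w
}

#' Generate a synthetic two-component, two-condition ERP dataset
#'
#' For each participant a component-1 latency is drawn from
#' `N(0, latency_sd)` and the component-2 latency follows the coupling model
#' `a + b * latency1 + e`; both components are emitted as template bumps
#' delayed by those latencies, with independent EEG-spectrum noise added to
#' every epoch. A "late" condition repeats the procedure with the same
#' latencies shifted by `condition_shift_ms` (fresh noise). Draws that
#' would push a bump outside the epoch are rejected and resampled (bounded
#' retries, count reported). Ground-truth latencies are stored alongside
#' the data.
#'
#' @param spec an [synth_spec()].
#' @param seed optional integer seed; all randomness (latency draws, noise)
#'   flows from it.
#' @return A list of class `erp_synth_data`: `comp1` and `comp2`, each with
#'   `early` and `late` [erp_dataset()]s; `ground_truth` data frame (`id`,
#'   `latency1_ms`, `latency2_ms`); `retries` (rejected latency draws);
#'   `spec`.
#' @export
generate_erp <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "erp_synth_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_participants
  shift <- spec$condition_shift_ms

  lat1 <- lat2 <- numeric(n)
  retries <- 0L
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(spec$max_retries)) {
      l1 <- rnorm(1, 0, spec$latency_sd)
      l2 <- spec$coupling_a + spec$coupling_b * l1 + rnorm(1, 0, spec$coupling_sd)
      if (template_fits(spec$comp1, l1, 0, spec$span) &&
          template_fits(spec$comp1, l1, shift, spec$span) &&
          template_fits(spec$comp2, l2, 0, spec$span) &&
          template_fits(spec$comp2, l2, shift, spec$span)) {
        ok <- TRUE; break
      }
      retries <- retries + 1L
    }
    if (!ok) stop("could not draw latencies keeping bumps inside the epoch",
                  call. = FALSE)
    lat1[i] <- l1; lat2[i] <- l2
  }

  build <- function(comp, lats, shift, component, condition) {
    m <- t(vapply(seq_len(n), function(i)
      participant_wave(comp, lats[i], shift, spec)$samples,
      numeric(length(seq(spec$span[1], spec$span[2], by = 1000 / spec$fs)))))
    erp_dataset(m, fs = spec$fs, t0 = spec$span[1], component = component,
                condition = condition)
  }

  structure(list(
    comp1 = list(early = build(spec$comp1, lat1, 0, "comp1", "early"),
                 late = build(spec$comp1, lat1, shift, "comp1", "late")),
    comp2 = list(early = build(spec$comp2, lat2, 0, "comp2", "early"),
                 late = build(spec$comp2, lat2, shift, "comp2", "late")),
    ground_truth = data.frame(id = paste0("P", seq_len(n)),
                              latency1_ms = lat1, latency2_ms = lat2),
    retries = retries,
    spec = spec), class = "erp_synth_data")
}

#' @export
print.erp_synth_data <- function(x, ...) {
  cat(sprintf("<erp_synth_data> %d participants, 2 components x 2 conditions, fs = %g Hz\n",
              x$spec$n_participants, x$spec$fs))
  cat(sprintf("  condition shift %g ms, coupling b = %g, noise lambda = %g\n",
              x$spec$condition_shift_ms, x$spec$coupling_b, x$spec$noise_lambda))
  invisible(x)
}
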