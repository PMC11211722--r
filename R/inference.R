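#' Paired sign-flip permutation test on the DTW area
#'
#' Tests whether two within-participant conditions differ in latency. The
#' observed statistic is the signed DTW area between the two grand averages
#' (condition A as the reference), after windowing and z-scoring. Under the
#' null each iteration flips every participant's pair of ERPs between
#' conditions independently with probability 1/2 (a fair coin), recomputes
#' both grand averages, and stores the DTW area; the two-tailed p-value is
#' the proportion of absolute null areas at least as large as the absolute
#' observed area.
#'
#' @param cond_a,cond_b [erp_dataset()]s with the same participants, fs, t0
#'   and sample count; `cond_a` is the reference, so a positive observed
#'   area means condition A leads in time.
#' @param window `c(start_ms, end_ms)` analysis window.
#' @param n_perm number of permutations (default 10,000).
#' @param seed optional integer seed for reproducibility.
#' @param strict if TRUE use the strict comparison `|null| > |observed|`;
#'   the default non-strict `>=` convention cannot return p = 0.
#' @return Object of class `erp_permutation`: `observed` (an `erp_dtw`
#'   result), `observed_area`, `null_areas`, `p`, `n_perm`, `strict`.
#' @examples
#' set.seed(1)
#' syn <- generate_erp(synth_spec(n_participants = 12, condition_shift_ms = 40,
#'                                noise_lambda = 0.05), seed = 1)
#' permutation_test(syn$comp1$early, syn$comp1$late, window = c(150, 400),
#'                  n_perm = 200, seed = 2)
#' @export
permutation_test <- function(cond_a, cond_b, window, n_perm = 10000L,
                             seed = NULL, strict = FALSE) {
  stopifnot(inherits(cond_a, "erp_dataset"), inherits(cond_b, "erp_dataset"))
  if (!identical(dim(cond_a$data), dim(cond_b$data)) ||
      cond_a$fs != cond_b$fs || cond_a$t0 != cond_b$t0)
    stop("conditions must match in participants, fs, t0 and length", call. = FALSE)
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  # windowing selects columns, so it commutes with averaging across rows:
  # window the participant matrices once, average per permutation.
  wa <- window_matrix(cond_a, window)
  wb <- window_matrix(cond_b, window)
  n <- nrow(wa)

  observed <- dtw_latency(waveform(colMeans(wa), cond_a$fs, window_t0(cond_a, window)),
                          waveform(colMeans(wb), cond_b$fs, window_t0(cond_b, window)),
                          standardize = TRUE)

  null_areas <- numeric(n_perm)
  for (it in seq_len(n_perm)) {
    flip <- runif(n) < 0.5
    pa <- wa; pb <- wb
    pa[flip, ] <- wb[flip, , drop = FALSE]
    pb[flip, ] <- wa[flip, , drop = FALSE]
    ga <- colMeans(pa); gb <- colMeans(pb)
    null_areas[it] <- dtw_area(dtw_align_vec(zscore_vec(ga), zscore_vec(gb),
                                             fs = cond_a$fs))
  }
  cmp <- if (strict) abs(null_areas) > abs(observed$area)
         else abs(null_areas) >= abs(observed$area)
  structure(list(observed = observed,
                 observed_area = observed$area,
                 null_areas = null_areas,
                 p = mean(cmp),
                 n_perm = n_perm,
                 strict = strict),
            class = "erp_permutation")
}

#' @export
print.erp_permutation <- function(x, ...) {
  cat(sprintf("<erp_permutation> observed area %g, latency %.3g ms, p = %.4g (%s, %d flips)\n",
              x$observed_area, x$observed$latency_ms, x$p,
              if (x$strict) "strict" else "non-strict", x$n_perm))
  invisible(x)
}

# window the rows of an erp_dataset once, returning a plain matrix
window_matrix <- function(ds, window) {
  w1 <- extract_window(waveform(ds$data[1, ], ds$fs, ds$t0), window)
  i0 <- time_to_index(waveform(ds$data[1, ], ds$fs, ds$t0), w1$t0)
  ds$data[, i0:(i0 + length(w1$samples) - 1L), drop = FALSE]
}

window_t0 <- function(ds, window) {
  extract_window(waveform(ds$data[1, ], ds$fs, ds$t0), window)$t0
}

# z-score helper on bare vectors (degenerate input -> error), DTW-ready
zscore_vec <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("constant grand average after windowing",
                                    call. = FALSE)
  (x - mean(x)) / s
}

# dtw_align working on bare numeric vectors when fs is supplied
dtw_align_vec <- function(reference, query, fs) {
  res <- dtw_path_cpp(query, reference)
  structure(list(path = res$path + 1L,
                 cumulative_distance = res$cumulative_distance,
                 fs = fs),
            class = "erp_alignment")
}

#' Shared-sample bootstrap of cross-component latency coupling
#'
#' Assesses whether the latencies of two ERP components covary across
#' participants. Participant waveforms are windowed and standardized, and
#' each bootstrap repetition draws one sample of participants with
#' replacement (size n, the observed participant count) that is reused for
#' both components; each component's bootstrap grand average is aligned by
#' DTW against that component's true observed grand average (the reference),
#' yielding one paired (component 1, component 2) DTW area per repetition.
#' The two area distributions are z-scored and correlated (Pearson and
#' Spearman). Marginal moments are computed on the raw areas, before
#' z-scoring.
#'
#' @param comp1,comp2 [erp_dataset()]s indexed by the same participants
#'   (e.g. N2pc and P3 in one condition).
#' @param window1,window2 analysis windows for the two components.
#' @param n_boot number of bootstrap repetitions (default 10,000).
#' @param seed optional integer seed.
#' @return Object of class `erp_coupling`: raw `areas` (n_boot x 2 matrix),
#'   z-scored `z_areas`, `r_pearson`, `r_spearman`, per-component `moments`,
#'   `n_boot`, `n_participants`, and `skipped` (repetitions dropped because a
#'   bootstrap grand average was constant in its window).
#' @export
bootstrap_coupling <- function(comp1, comp2, window1, window2,
                               n_boot = 10000L, seed = NULL) {
  stopifnot(inherits(comp1, "erp_dataset"), inherits(comp2, "erp_dataset"))
  if (nrow(comp1$data) != nrow(comp2$data))
    stop("components must be indexed by the same participants", call. = FALSE)
  if (n_boot < 2) stop("`n_boot` must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(comp1$data)

  z1 <- standardize_rows(window_matrix(comp1, window1))
  z2 <- standardize_rows(window_matrix(comp2, window2))
  obs1 <- zscore_vec(colMeans(z1))
  obs2 <- zscore_vec(colMeans(z2))

  areas <- matrix(NA_real_, n_boot, 2,
                  dimnames = list(NULL, c("comp1", "comp2")))
  skipped <- 0L
  it <- 1L
  while (it <= n_boot) {
    idx <- sample.int(n, n, replace = TRUE)
    g1 <- colMeans(z1[idx, , drop = FALSE])
    g2 <- colMeans(z2[idx, , drop = FALSE])
    if (sd(g1) == 0 || sd(g2) == 0) {
      skipped <- skipped + 1L
      if (skipped > 100L * n_boot)
        stop("too many degenerate bootstrap grand averages", call. = FALSE)
      next
    }
    areas[it, 1] <- dtw_area(dtw_align_vec(obs1, zscore_vec(g1), comp1$fs))
    areas[it, 2] <- dtw_area(dtw_align_vec(obs2, zscore_vec(g2), comp2$fs))
    it <- it + 1L
  }
  build_coupling(areas, n, skipped = skipped, removed = 0L)
}

standardize_rows <- function(m) {
  t(apply(m, 1L, function(r) {
    s <- sd(r)
    if (!is.finite(s) || s == 0)
      stop("constant participant waveform in window; cannot standardize",
           call. = FALSE)
    (r - mean(r)) / s
  }))
}

build_coupling <- function(areas, n_participants, skipped, removed) {
  z_areas <- apply(areas, 2L, function(a) (a - mean(a)) / sd(a))
  structure(list(areas = areas,
                 z_areas = z_areas,
                 r_pearson = cor(z_areas[, 1], z_areas[, 2], method = "pearson"),
                 r_spearman = cor(z_areas[, 1], z_areas[, 2], method = "spearman"),
                 moments = list(comp1 = marginal_moments(areas[, 1]),
                                comp2 = marginal_moments(areas[, 2])),
                 n_boot = nrow(areas),
                 n_participants = n_participants,
                 skipped = skipped,
                 removed = removed),
            class = "erp_coupling")
}

#' @export
print.erp_coupling <- function(x, ...) {
  cat(sprintf("<erp_coupling> %d paired bootstrap areas (n = %d participants)\n",
              x$n_boot, x$n_participants))
  cat(sprintf("  Pearson r = %.3f, Spearman r = %.3f", x$r_pearson, x$r_spearman))
  if (x$removed > 0) cat(sprintf("  [%d outlier pair(s) removed]", x$removed))
  if (x$skipped > 0) cat(sprintf("  [%d degenerate repetition(s) skipped]", x$skipped))
  cat("\n")
  invisible(x)
}

#' Remove paired outliers from a coupling result
#'
#' A bootstrap pair is removed if either of its DTW areas lies more than
#' `k_sd` standard deviations from the mean of its own marginal
#' distribution; the partner value from the same repetition is always
#' removed with it, preserving pairing. Correlations, z-scores and moments
#' are recomputed on the survivors.
#'
#' @param coupling an `erp_coupling` from [bootstrap_coupling()].
#' @param k_sd exclusion threshold in marginal standard deviations
#'   (default 5).
#' @return A new `erp_coupling` with `removed` set to the number of pairs
#'   dropped.
#' @export
exclude_outlier_pairs <- function(coupling, k_sd = 5) {
  stopifnot(inherits(coupling, "erp_coupling"))
  if (!is.numeric(k_sd) || k_sd <= 0) stop("`k_sd` must be > 0", call. = FALSE)
  a <- coupling$areas
  keep <- rep(TRUE, nrow(a))
  for (j in 1:2) {
    mu <- mean(a[, j]); s <- sd(a[, j])
    keep <- keep & abs(a[, j] - mu) <= k_sd * s
  }
  if (!any(keep)) stop("all pairs removed as outliers", call. = FALSE)
  build_coupling(a[keep, , drop = FALSE], coupling$n_participants,
                 skipped = coupling$skipped, removed = sum(!keep))
}

#' Compare two correlation coefficients with Fisher's Z transformation
#'
#' Tests whether two independent correlations differ:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(v1 + v2)` with sampling variance
#' `v = 1/(n - 3)` for Pearson correlations and `v = 1.06/(n - 3)` for
#' Spearman rank correlations (the adjusted standard error); the two-tailed
#' p-value comes from the standard normal.
#'
#' @param r1,r2 correlation coefficients, strictly inside (-1, 1).
#' @param n1,n2 sample sizes (> 3) behind each correlation.
#' @param method `"pearson"` or `"spearman"`.
#' @return Object of class `erp_cor_comparison`: `r1`, `r2`, `n1`, `n2`,
#'   `z`, `p`, `method`.
#' @export
compare_correlations <- function(r1, n1, r2, n2,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3", call. = FALSE)
  k <- if (method == "pearson") 1 else 1.06
  z <- (atanh(r1) - atanh(r2)) / sqrt(k / (n1 - 3) + k / (n2 - 3))
  structure(list(r1 = r1, r2 = r2, n1 = n1, n2 = n2, z = z,
                 p = 2 * pnorm(-abs(z)), method = method),
            class = "erp_cor_comparison")
}

#' @export
print.erp_cor_comparison <- function(x, ...) {
  cat(sprintf("<erp_cor_comparison> %s r1 = %.3f (n = %d) vs r2 = %.3f (n = %d): z = %.3f, p = %.4g\n",
              x$method, x$r1, x$n1, x$r2, x$n2, x$z, x$p))
  invisible(x)
}

#' Variance, skewness and kurtosis of a distribution
#'
#' Sample variance (divisor n - 1), skewness as the standardized third
#' central moment `g1 = m3 / m2^(3/2)`, and excess kurtosis
#' `g2 = m4 / m2^2 - 3`, with `m_k` the biased central moments (divisor n).
#' These are the conventions used when summarizing bootstrap area marginals.
#'
#' @param values numeric vector, length >= 3.
#' @return Named list: `variance`, `skewness`, `kurtosis`.
#' @export
marginal_moments <- function(values) {
  if (length(values) < 3) stop("need at least 3 values", call. = FALSE)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  m3 <- mean((values - m)^3)
  m4 <- mean((values - m)^4)
  list(variance = var(values),
       skewness = m3 / m2^1.5,
       kurtosis = m4 / m2^2 - 3)
}
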