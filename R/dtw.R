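#' Align two waveforms with dynamic time warping
#'
#' Builds the full local-cost matrix between the reference (plotted on the
#' y-axis by convention) and the query (x-axis), with cost
#' `|query[x] - reference[y]|`, and finds the monotone warping path of
#' minimal cumulative cost under the symmetric step set
#' \{(1,0), (0,1), (1,1)\}, with no slope or band constraint. Ties during
#' backtracking are broken deterministically: diagonal move first, then the
#' vertical (reference-axis) move.
#'
#' Both inputs should already be windowed to the interval of interest and
#' z-scored (see [extract_window()], [zscore_waveform()]); alignment of
#' unstandardized waveforms would mix amplitude and latency differences.
#'
#' @param reference,query [waveform()] objects with equal sampling rates.
#' @return An object of class `erp_alignment`: a list with
#'   \item{path}{integer matrix, columns `x` (query index) and `y`
#'     (reference index), 1-based, from `(1, 1)` to `(nx, ny)`;}
#'   \item{cumulative_distance}{the minimal cumulative cost;}
#'   \item{fs}{the common sampling rate.}
#' @seealso [dtw_area()], [dtw_latency()]
#' @export
dtw_align <- function(reference, query) {
  stopifnot(inherits(reference, "erp_waveform"), inherits(query, "erp_waveform"))
  if (reference$fs != query$fs)
    stop("reference and query must share a sampling rate", call. = FALSE)
  res <- dtw_path_cpp(query$samples, reference$samples)
  path <- res$path + 1L  # 0-based C++ indices -> 1-based
  colnames(path) <- c("x", "y")
  structure(list(path = path,
                 cumulative_distance = res$cumulative_distance,
                 fs = reference$fs),
            class = "erp_alignment")
}

#' @export
print.erp_alignment <- function(x, ...) {
  cat(sprintf("<erp_alignment> path length %d, cumulative distance %.4g, area %g\n",
              nrow(x$path), x$cumulative_distance, dtw_area(x)))
  invisible(x)
}

#' Signed DTW area of a warping path
#'
#' The sum of horizontal distances `x - y` over all points of the warping
#' path: the signed displacement of the path from the main diagonal, in
#' sample-index units. A positive area means the reference leads the query
#' in time (the path lies below the diagonal); zero for identical series.
#' This area is the statistic used for permutation and bootstrap inference.
#'
#' @param alignment an `erp_alignment` from [dtw_align()], or a two-column
#'   path matrix with columns `x` and `y`.
#' @return Signed area (numeric scalar, sample-index units).
#' @export
dtw_area <- function(alignment) {
  path <- if (inherits(alignment, "erp_alignment")) alignment$path else alignment
  sum(as.numeric(path[, 1]) - as.numeric(path[, 2]))
}

#' Horizontal distance distribution of a warping path
#'
#' Each path point `(x, y)` has horizontal distance `x - y` to the main
#' diagonal; the multiset of these distances summarizes where the alignment
#' placed the query relative to the reference.
#'
#' @inheritParams dtw_area
#' @return Numeric vector of `x - y` distances, one per path point.
#' @export
dtw_distances <- function(alignment) {
  path <- if (inherits(alignment, "erp_alignment")) alignment$path else alignment
  as.numeric(path[, 1]) - as.numeric(path[, 2])
}

#' Convert a distance distribution to a latency in milliseconds
#'
#' The median of the horizontal distance distribution, converted from
#' sample-index units to ms by dividing by `fs / 1000`. A positive latency
#' means the query lags the reference.
#'
#' @param distances numeric vector of horizontal path distances (samples).
#' @param fs sampling rate in Hz.
#' @return Latency in ms.
#' @export
dtw_latency_ms <- function(distances, fs) {
  if (length(distances) == 0)
    stop("empty distance distribution", call. = FALSE)
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  median(distances) / (fs / 1000)
}

#' DTW latency analysis of a reference/query pair
#'
#' Convenience wrapper running the full pipeline on a pair of waveforms:
#' optional window extraction, z-scoring, DTW alignment, and derivation of
#' the signed area, the distance distribution, and the latency estimate.
#'
#' @inheritParams dtw_align
#' @param window optional `c(start_ms, end_ms)` applied to both waveforms.
#' @param standardize z-score after windowing (default TRUE; disable only if
#'   the inputs are already standardized).
#' @return An object of class `erp_dtw`: list with `area`, `distances`,
#'   `latency_ms`, `cumulative_distance`, `path`, `fs`.
#' @examples
#' t <- seq(-200, 798, by = 2)
#' bump <- function(c0) exp(-(t - c0)^2 / (2 * 30^2))
#' ref <- waveform(bump(250), fs = 500, t0 = -200)
#' qry <- waveform(bump(280), fs = 500, t0 = -200)
#' dtw_latency(ref, qry, window = c(150, 400))
#' @export
dtw_latency <- function(reference, query, window = NULL, standardize = TRUE) {
  if (!is.null(window)) {
    reference <- extract_window(reference, window)
    query <- extract_window(query, window)
  }
  if (standardize) {
    reference <- zscore_waveform(reference)
    query <- zscore_waveform(query)
  }
  al <- dtw_align(reference, query)
  d <- dtw_distances(al)
  structure(list(area = dtw_area(al),
                 distances = d,
                 latency_ms = dtw_latency_ms(d, al$fs),
                 cumulative_distance = al$cumulative_distance,
                 path = al$path,
                 fs = al$fs),
            class = "erp_dtw")
}

#' @export
print.erp_dtw <- function(x, ...) {
  cat(sprintf("<erp_dtw> area %g (samples), latency %.3g ms, cumulative distance %.4g\n",
              x$area, x$latency_ms, x$cumulative_distance))
  invisible(x)
}
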