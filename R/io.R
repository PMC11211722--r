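#' Construct a participant-by-time ERP dataset
#'
#' Holds one ERP component in one condition for a group of participants:
#' a numeric matrix with one row per participant and one column per time
#' sample, plus the sampling rate, time of the first sample, and labels.
#'
#' @param data numeric matrix, participants in rows, samples in columns.
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample relative to stimulus onset (ms).
#' @param component,condition optional character labels (e.g. "N2pc",
#'   "correct").
#' @param ids participant identifiers; unique, defaults to `P1..Pn`.
#' @return An object of class `erp_dataset`.
#' @export
erp_dataset <- function(data, fs, t0 = 0, component = "", condition = "",
                        ids = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 1L || ncol(data) < 2L)
    stop("`data` needs at least 1 participant and 2 samples", call. = FALSE)
  if (!all(is.finite(data)))
    stop("`data` must be all finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  if (is.null(ids)) ids <- paste0("P", seq_len(nrow(data)))
  ids <- as.character(ids)
  if (length(ids) != nrow(data) || anyDuplicated(ids))
    stop("`ids` must be unique, one per participant", call. = FALSE)
  rownames(data) <- NULL
  structure(list(data = data, fs = fs, t0 = t0,
                 component = as.character(component)[1],
                 condition = as.character(condition)[1],
                 ids = ids),
            class = "erp_dataset")
}

#' @export
print.erp_dataset <- function(x, ...) {
  lab <- paste0(x$component, if (nzchar(x$condition)) paste0("/", x$condition))
  cat(sprintf("<erp_dataset>%s %d participants x %d samples @ %g Hz, t0 = %g ms\n",
              if (nzchar(lab)) paste0(" [", lab, "]") else "",
              nrow(x$data), ncol(x$data), x$fs, x$t0))
  invisible(x)
}

#' @export
dim.erp_dataset <- function(x) dim(x$data)

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write an ERP dataset to a delimited matrix with a JSON sidecar
#'
#' The matrix is written as a headerless CSV (one row per participant, full
#' floating precision); sampling rate, time origin, labels and participant
#' IDs go into a JSON sidecar named after the CSV with extension `.json`.
#'
#' @param ds an [erp_dataset()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_erp_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "erp_dataset"))
  lines <- apply(ds$data, 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = TRUE), collapse = ","))
  writeLines(lines, path)
  meta <- list(fs = ds$fs, t0 = ds$t0, component = ds$component,
               condition = ds$condition, ids = ds$ids)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ERP dataset written by [write_erp_dataset()]
#'
#' @param path CSV path; the JSON sidecar `<path-sans-ext>.json` must exist.
#' @return An [erp_dataset()].
#' @export
read_erp_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing sidecar header: ", sc, call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$fs) || is.null(meta$t0))
    stop("sidecar must define `fs` and `t0`: ", sc, call. = FALSE)
  rows <- strsplit(readLines(path), ",", fixed = TRUE)
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != stats::median(lens))
    stop(sprintf("ragged matrix in %s: row(s) %s have %s values, expected %d",
                 path, paste(bad, collapse = ", "),
                 paste(lens[bad], collapse = ", "), stats::median(lens)),
         call. = FALSE)
  }
  m <- matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
  if (anyNA(m)) stop("non-numeric values in ", path, call. = FALSE)
  erp_dataset(m, fs = meta$fs, t0 = meta$t0,
              component = meta$component %||% "",
              condition = meta$condition %||% "",
              ids = meta$ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Grand average across participants
#'
#' Pointwise mean waveform across the rows of an ERP dataset. With integer
#' `weights` (replication multiplicities, e.g. bootstrap counts), the
#' average is computed by materializing each row `weights[i]` times and
#' averaging, so it is exactly the mean of the corresponding resample.
#'
#' @param ds an [erp_dataset()].
#' @param weights optional nonnegative integer multiplicities, one per
#'   participant, summing to at least 1.
#' @return A [waveform()].
#' @export
grand_average <- function(ds, weights = NULL) {
  stopifnot(inherits(ds, "erp_dataset"))
  m <- ds$data
  if (!is.null(weights)) {
    if (length(weights) != nrow(m) || any(weights < 0) ||
        any(weights != round(weights)))
      stop("`weights` must be nonnegative integer multiplicities, one per row",
           call. = FALSE)
    if (sum(weights) < 1) stop("`weights` must select at least one row", call. = FALSE)
    m <- m[rep(seq_len(nrow(m)), times = weights), , drop = FALSE]
  }
  waveform(colMeans(m), fs = ds$fs, t0 = ds$t0)
}

#' Contralateral-minus-ipsilateral difference waves
#'
#' Computes the lateralized difference (e.g. the N2pc: PO7/PO8 contralateral
#' minus ipsilateral to the attended item) row by row. A more negative
#' contralateral deflection yields a negative-going difference.
#'
#' @param contra,ipsi matched [erp_dataset()]s (same participants, fs, t0,
#'   sample count).
#' @return An [erp_dataset()] of difference waves.
#' @export
contra_ipsi_difference <- function(contra, ipsi) {
  stopifnot(inherits(contra, "erp_dataset"), inherits(ipsi, "erp_dataset"))
  if (!identical(dim(contra$data), dim(ipsi$data)) ||
      contra$fs != ipsi$fs || contra$t0 != ipsi$t0 ||
      !identical(contra$ids, ipsi$ids))
    stop("`contra` and `ipsi` must match in participants, fs, t0 and length",
         call. = FALSE)
  erp_dataset(contra$data - ipsi$data, fs = contra$fs, t0 = contra$t0,
              component = contra$component, condition = contra$condition,
              ids = contra$ids)
}

#' Zero-phase low-pass filter
#'
#' Applies a Butterworth low-pass filter forward and backward
#' ([signal::filtfilt()]) to every participant waveform, so the filter is
#' zero-phase and has unit DC gain. ERP practice for slow components such as
#' the P3 commonly uses a 25 Hz cutoff.
#'
#' @param ds an [erp_dataset()].
#' @param cutoff_hz cutoff frequency; must be below the Nyquist rate.
#' @param order filter order per pass (default 4).
#' @return The filtered [erp_dataset()].
#' @export
lowpass <- function(ds, cutoff_hz, order = 4L) {
  stopifnot(inherits(ds, "erp_dataset"))
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= ds$fs / 2)
    stop("`cutoff_hz` must lie in (0, fs/2)", call. = FALSE)
  bf <- signal::butter(order, cutoff_hz / (ds$fs / 2), type = "low")
  n <- ncol(ds$data)
  pad <- min(n - 1L, as.integer(ceiling(6 * ds$fs / cutoff_hz)))
  filt <- t(apply(ds$data, 1L, function(r) {
    # odd-reflection padding suppresses the forward-backward edge transients
    ext <- c(2 * r[1] - r[(pad + 1):2], r, 2 * r[n] - r[(n - 1):(n - pad)])
    signal::filtfilt(bf, ext)[(pad + 1):(pad + n)]
  }))
  erp_dataset(filt, fs = ds$fs, t0 = ds$t0, component = ds$component,
              condition = ds$condition, ids = ds$ids)
}

#' Default analysis configuration
#'
#' Bundles the analysis defaults used throughout: component windows of
#' 150-400 ms (N2pc) and 250-800 ms (P3), 10,000 permutations and bootstrap
#' repetitions, a +/-5 SD outlier rule, the non-strict p-value convention,
#' and SNR windows of 200-400 ms (signal) vs -50-100 ms (baseline).
#'
#' @param ... named overrides of any default.
#' @return A named list of class `erp_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(window_n2pc = c(150, 400),
              window_p3 = c(250, 800),
              n_perm = 10000L,
              n_boot = 10000L,
              outlier_sd = 5,
              strict_p = FALSE,
              snr_signal_window = c(200, 400),
              snr_baseline_window = c(-50, 100),
              lowpass_hz = 25,
              lowpass_order = 4L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(over)] <- over
  structure(cfg, class = "erp_config")
}
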