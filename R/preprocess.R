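# Per-recording standardization, overlapped fixed-length segmentation and
# window-level quality control. Deliberately minimal: no filtering, no
# resampling, no ICA/ASR -- robustness comes from z-scoring and subject-level
# aggregation at evaluation time.

#' Z-score a recording per channel
#'
#' Standardizes each channel independently over the full recording (mean
#' removal, division by the within-recording standard deviation). The SD is
#' floored at `1e-8`; an (effectively) all-constant channel triggers a
#' warning and survives as all-zeros, to be caught by window-level QC.
#'
#' @param rec An [eeg_recording()].
#' @return The recording with `data` in z-units (`meta$zscored = TRUE`).
#' @export
zscore_recording <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2L) stop("need at least 2 samples to z-score", call. = FALSE)
  mu <- colMeans(rec$data)
  sdv <- apply(rec$data, 2, stats::sd)
  if (any(sdv < 1e-8, na.rm = TRUE)) {
    warning("constant channel(s) in recording ", rec$subject_id,
            ": SD floored at 1e-8 (", paste(EEG_CHANNELS[which(sdv < 1e-8)], collapse = ", "),
            ")", call. = FALSE)
  }
  sdv <- pmax(sdv, 1e-8)
  rec$data <- sweep(sweep(rec$data, 2, mu), 2, sdv, "/")
  rec$meta$zscored <- TRUE
  rec
}

#' Segmentation stride for a target overlap
#'
#' `S = round(L * (1 - p/100))`, the number of samples between the starts of
#' consecutive windows. At the final operating point `L = 3840`, `p = 50` the
#' stride is 1920 samples (7.68 s at 250 Hz).
#'
#' @param L Window length in samples.
#' @param p Overlap percent in `[0, 100)`.
#' @return Integer stride in samples.
#' @export
segment_stride <- function(L, p) {
  stopifnot(L >= 1, p >= 0, p < 100)
  S <- as.integer(round(L * (1 - p / 100)))
  max(S, 1L)
}

#' Segment recordings into fixed-length overlapped windows
#'
#' Cuts each (already z-scored) recording into `N = floor((T - L)/S) + 1`
#' contiguous windows of `L` samples starting at 0, S, 2S, ...; the trailing
#' partial window is discarded. Recordings shorter than one full window
#' contribute no windows and are reported in the `excluded` field.
#'
#' @param recs An [eeg_recording()] or a list of them.
#' @param L Window length in samples (e.g. 3840 = 15.36 s at 250 Hz).
#' @param p Target overlap percent (stride is derived via [segment_stride()]).
#' @return An object of class `eeg_windows`: list with
#'   * `windows` — N x L x 3 array in z-units,
#'   * `info` — tibble with `subject_id`, `label`, `start_sample` (0-based),
#'   * `params` — list `(L, p, S, fs)`,
#'   * `extremes` — per-window recording-level channel min/max (for clipping QC),
#'   * `excluded` — tibble of recordings shorter than one window.
#' @export
segment_windows <- function(recs, L, p = 50) {
  if (inherits(recs, "eeg_recording")) recs <- list(recs)
  stopifnot(length(recs) >= 1L, L >= 1)
  fs <- unique(vapply(recs, function(r) r$fs, 0))
  if (length(fs) != 1L) stop("all recordings must share one sampling rate", call. = FALSE)
  S <- segment_stride(L, p)
  pieces <- vector("list", length(recs))
  excluded <- list()
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    T_ <- nrow(rec$data)
    if (T_ < L) {
      excluded[[length(excluded) + 1L]] <- tibble::tibble(
        subject_id = rec$subject_id, n_samples = T_, reason = "shorter_than_window")
      next
    }
    n <- (T_ - L) %/% S + 1L
    starts <- (seq_len(n) - 1L) * S
    idx <- outer(starts, seq_len(L), "+")      # n x L sample indices (1-based)
    w <- array(0, c(n, L, 3L))
    for (ch in 1:3) w[, , ch] <- rec$data[as.vector(idx), ch]
    rmin <- apply(rec$data, 2, min); rmax <- apply(rec$data, 2, max)
    pieces[[i]] <- list(
      w = w,
      info = tibble::tibble(subject_id = rec$subject_id, label = rec$label,
                            start_sample = as.integer(starts)),
      rmin = matrix(rmin, n, 3, byrow = TRUE),
      rmax = matrix(rmax, n, 3, byrow = TRUE))
  }
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (!length(pieces)) {
    windows <- array(0, c(0L, L, 3L))
    info <- tibble::tibble(subject_id = character(), label = character(),
                           start_sample = integer())
    ext <- list(min = matrix(0, 0, 3), max = matrix(0, 0, 3))
  } else {
    windows <- abind3(lapply(pieces, `[[`, "w"))
    info <- dplyr::bind_rows(lapply(pieces, `[[`, "info"))
    ext <- list(min = do.call(rbind, lapply(pieces, `[[`, "rmin")),
                max = do.call(rbind, lapply(pieces, `[[`, "rmax")))
  }
  structure(
    list(windows = windows, info = info,
         params = list(L = as.integer(L), p = p, S = S, fs = fs),
         extremes = ext,
         excluded = if (length(excluded)) dplyr::bind_rows(excluded) else
           tibble::tibble(subject_id = character(), n_samples = integer(),
                          reason = character())),
    class = "eeg_windows")
}

# bind a list of n_i x L x 3 arrays along the first margin
abind3 <- function(arrs) {
  ns <- vapply(arrs, function(a) dim(a)[1], 0L)
  L <- dim(arrs[[1]])[2]
  out <- array(0, c(sum(ns), L, 3L))
  at <- 0L
  for (a in arrs) {
    n <- dim(a)[1]
    if (n > 0) out[at + seq_len(n), , ] <- a
    at <- at + n
  }
  out
}

#' @export
print.eeg_windows <- function(x, ...) {
  cat(sprintf("<eeg_windows> %d windows of %d samples (p=%g%%, S=%d, fs=%g Hz) from %d subjects\n",
              nrow(x$info), x$params$L, x$params$p, x$params$S, x$params$fs,
              length(unique(x$info$subject_id))))
  invisible(x)
}

#' @export
dim.eeg_windows <- function(x) dim(x$windows)

subset_windows <- function(ws, keep) {
  ws$windows <- ws$windows[keep, , , drop = FALSE]
  ws$info <- ws$info[keep, , drop = FALSE]
  ws$extremes$min <- ws$extremes$min[keep, , drop = FALSE]
  ws$extremes$max <- ws$extremes$max[keep, , drop = FALSE]
  ws
}

longest_run <- function(flag) {
  if (!any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}

#' Window-level quality control
#'
#' Removes windows with non-finite values (NaN/Inf), (near-)zero variance on
#' any channel, or obvious clipping/saturation. A window is flagged as
#' clipped when any channel contains a run of at least `clip_run` consecutive
#' samples pinned (within `1e-12`) at that channel's recording-level minimum
#' or maximum -- the canonical rail-saturation signature. Each removed window
#' is counted once, by the first matching cause in the order
#' nonfinite, zero_variance, clipping.
#'
#' @param ws An `eeg_windows` object from [segment_windows()].
#' @param clip_run Minimum plateau length in samples (default 25, i.e. 0.1 s
#'   at 250 Hz).
#' @param var_tol Zero-variance threshold (default `1e-12`).
#' @param exclude_frac Recording-level threshold: subjects losing more than
#'   this fraction of their windows to QC are flagged in the report (default
#'   0.20, an interpretive operationalization of "more than 20% contamination").
#' @return A list with `windows` (the retained `eeg_windows`) and `report`,
#'   a `qc_report`: tibble of per-subject removal counts by cause plus totals.
#' @export
qc_filter <- function(ws, clip_run = 25L, var_tol = 1e-12, exclude_frac = 0.20) {
  stopifnot(inherits(ws, "eeg_windows"))
  n <- dim(ws$windows)[1]
  cause <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    w <- ws$windows[i, , ]
    if (!all(is.finite(w))) { cause[i] <- "nonfinite"; next }
    v <- apply(w, 2, stats::var)
    if (any(v <= var_tol)) { cause[i] <- "zero_variance"; next }
    clipped <- FALSE
    for (ch in 1:3) {
      at_rail <- abs(w[, ch] - ws$extremes$min[i, ch]) < 1e-12 |
                 abs(w[, ch] - ws$extremes$max[i, ch]) < 1e-12
      if (longest_run(at_rail) >= clip_run) { clipped <- TRUE; break }
    }
    if (clipped) cause[i] <- "clipping"
  }
  keep <- is.na(cause)
  report <- tibble::tibble(subject_id = ws$info$subject_id, cause = cause) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_windows = dplyr::n(),
      nonfinite = sum(.data$cause == "nonfinite", na.rm = TRUE),
      zero_variance = sum(.data$cause == "zero_variance", na.rm = TRUE),
      clipping = sum(.data$cause == "clipping", na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(
      removed = .data$nonfinite + .data$zero_variance + .data$clipping,
      removed_frac = .data$removed / .data$n_windows,
      flagged_recording = .data$removed_frac > exclude_frac)
  class(report) <- c("qc_report", class(report))
  list(windows = subset_windows(ws, keep), report = report)
}

#' Serialize a QC report to JSON
#'
#' @param report A `qc_report` from [qc_filter()].
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
qc_report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(as.data.frame(report), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
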