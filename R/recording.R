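#' EEG recording objects
#'
#' A `eeg_recording` holds one subject's continuous three-channel EEG in the
#' canonical frontal montage (Fp1, Fz, Fp2), together with its sampling rate,
#' subject identifier and (optionally) its class label.
#'
#' @param data Numeric matrix with exactly 3 columns, one sample per row,
#'   columns ordered as Fp1, Fz, Fp2. Amplitudes are in native units on
#'   ingest and in z-units after [zscore_recording()].
#' @param fs Sampling rate in Hz (positive scalar).
#' @param subject_id Subject identifier (scalar character).
#' @param label Class label: `"HC"`, `"MDD"` or `NA` when unknown.
#' @param meta Named list of free-form provenance (source file, units, ...).
#'
#' @return An object of class `eeg_recording`: a list with fields
#'   `subject_id`, `label`, `fs`, `channel_names`, `data` (T x 3 matrix) and
#'   `meta`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(750), ncol = 3), fs = 250, subject_id = "S01")
#' rec
#' @export
eeg_recording <- function(data, fs, subject_id = "S1", label = NA_character_,
                          meta = list()) {
  data <- as.matrix(data)
  if (ncol(data) != 3L) {
    stop("an EEG recording must have exactly 3 channels (Fp1, Fz, Fp2), got ",
         ncol(data), call. = FALSE)
  }
  if (nrow(data) < 1L) stop("recording must contain at least one sample", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar sampling rate in Hz", call. = FALSE)
  }
  if (!is.na(label) && !label %in% EEG_CLASSES) {
    stop("`label` must be one of ", paste(EEG_CLASSES, collapse = ", "), " or NA",
         call. = FALSE)
  }
  storage.mode(data) <- "double"
  colnames(data) <- EEG_CHANNELS
  structure(
    list(subject_id = as.character(subject_id), label = as.character(label),
         fs = as.numeric(fs), channel_names = EEG_CHANNELS, data = data,
         meta = meta),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  dur <- nrow(x$data) / x$fs
  cat(sprintf("<eeg_recording> subject %s  label %s  %d samples @ %g Hz (%.2f s)\n",
              x$subject_id, ifelse(is.na(x$label), "?", x$label),
              nrow(x$data), x$fs, dur))
  invisible(x)
}

#' @describeIn eeg_recording Convert a recording to a tibble with a `time`
#'   column (seconds) and one column per channel.
#' @param x An `eeg_recording`.
#' @param ... Unused.
#' @export
#' @exportS3Method tibble::as_tibble
as_tibble.eeg_recording <- function(x, ...) {
  tibble::tibble(
    time = (seq_len(nrow(x$data)) - 1) / x$fs,
    Fp1 = x$data[, 1], Fz = x$data[, 2], Fp2 = x$data[, 3]
  )
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)
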