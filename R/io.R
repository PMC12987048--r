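# EDF and CSV ingest/egress. All readers harmonize to the canonical
# (Fp1, Fz, Fp2) channel order; native units are kept (per-recording z-scoring
# downstream makes amplitude scale irrelevant).

# Default alias table for channel-name resolution. EDF label dialects vary
# across vendors ("EEG Fp1-LE", "Fp1-A1", "FP1", ...): matching is
# case-insensitive on a cleaned label with non-alphanumeric boundaries.
default_channel_aliases <- function() {
  list(Fp1 = c("fp1"), Fz = c("fz"), Fp2 = c("fp2"))
}

resolve_channels <- function(labels, channel_map = NULL) {
  norm <- tolower(trimws(labels))
  idx <- integer(3)
  names(idx) <- EEG_CHANNELS
  aliases <- default_channel_aliases()
  for (ch in EEG_CHANNELS) {
    hit <- integer(0)
    if (!is.null(channel_map)) {
      mapped <- names(channel_map)[channel_map == ch]
      if (length(mapped)) hit <- which(norm %in% tolower(trimws(mapped)))
    }
    if (!length(hit)) {
      for (al in aliases[[ch]]) {
        pat <- paste0("(^|[^a-z0-9])", al, "([^a-z0-9]|$)")
        hit <- which(grepl(pat, norm))
        if (length(hit)) break
      }
    }
    if (!length(hit)) {
      stop(sprintf("channel '%s' could not be resolved among EDF labels: %s",
                   ch, paste(sQuote(labels), collapse = ", ")), call. = FALSE)
    }
    idx[ch] <- hit[1]
  }
  idx
}

edf_field <- function(raw, at, len) {
  trimws(rawToChar(raw[(at + 1):(at + len)]))
}

#' Read an EDF/EDF+ file into a three-channel recording
#'
#' Reads a European Data Format file, resolves the frontal channels Fp1, Fz
#' and Fp2 (case-insensitive, alias-aware, so vendor labels such as
#' `"EEG Fp1-LE"` match), converts digital values to physical units and
#' returns them in canonical channel order. Non-target channels are dropped.
#'
#' @param path Path to an EDF/EDF+ file.
#' @param channel_map Optional named character vector mapping raw EDF labels
#'   to standard names, e.g. `c("EEG FP1-LE" = "Fp1")`; consulted before the
#'   built-in alias matching.
#' @param subject_id,label Subject identifier and class label to attach;
#'   `subject_id = NULL` uses the EDF patient-identification field (or the
#'   file name when that is empty).
#' @return An [eeg_recording()].
#' @seealso [write_edf()], [read_csv3()]
#' @export
read_edf <- function(path, channel_map = NULL, subject_id = NULL,
                     label = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256L)
  if (length(hdr) < 256L) stop("not a valid EDF file (truncated header): ", path, call. = FALSE)
  patient <- edf_field(hdr, 8, 80)
  n_records <- as.integer(edf_field(hdr, 236, 8))
  rec_dur <- as.numeric(edf_field(hdr, 244, 8))
  ns <- as.integer(edf_field(hdr, 252, 4))
  if (is.na(ns) || ns < 1L) stop("not a valid EDF file (bad signal count): ", path, call. = FALSE)
  sig <- readBin(con, "raw", 256L * ns)
  fld <- function(at, len) {
    vapply(seq_len(ns) - 1L, function(i) edf_field(sig, at * ns + i * len, len), "")
  }
  labels <- fld(0, 16)
  pmin <- as.numeric(fld(16 + 80 + 8, 8))
  pmax <- as.numeric(fld(16 + 80 + 8 + 8, 8))
  dmin <- as.numeric(fld(16 + 80 + 8 + 16, 8))
  dmax <- as.numeric(fld(16 + 80 + 8 + 24, 8))
  nsamp <- as.integer(fld(16 + 80 + 8 + 32 + 80, 8))
  idx <- resolve_channels(labels, channel_map)
  fs_per <- nsamp[idx] / rec_dur
  if (length(unique(fs_per)) != 1L) {
    stop("inconsistent sampling rates across Fp1/Fz/Fp2 in ", path, ": ",
         paste(fs_per, collapse = ", "), call. = FALSE)
  }
  # read all records, keep only target signals
  per_rec_n <- sum(nsamp)
  out <- lapply(idx, function(i) vector("list", n_records))
  offsets <- c(0L, cumsum(nsamp))
  for (r in seq_len(n_records)) {
    rec <- readBin(con, "integer", n = per_rec_n, size = 2L, signed = TRUE,
                   endian = "little")
    if (length(rec) < per_rec_n) stop("EDF data truncated at record ", r, call. = FALSE)
    for (k in seq_along(idx)) {
      i <- idx[k]
      out[[k]][[r]] <- rec[(offsets[i] + 1L):offsets[i + 1L]]
    }
  }
  cols <- lapply(seq_along(idx), function(k) {
    i <- idx[k]
    dig <- as.numeric(unlist(out[[k]], use.names = FALSE))
    (dig - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i]) + pmin[i]
  })
  if (is.null(subject_id)) {
    subject_id <- if (nzchar(patient)) patient else sub("\\.edf$", "", basename(path), ignore.case = TRUE)
  }
  eeg_recording(do.call(cbind, cols), fs = fs_per[1], subject_id = subject_id,
                label = label,
                meta = list(source = path, format = "edf",
                            source_labels = labels[idx]))
}

#' Write a recording as a minimal EDF file
#'
#' Serializes a three-channel recording as a single-record EDF file with
#' 16-bit samples, scaling amplitudes linearly onto the digital range.
#' Mainly intended for producing interoperable fixtures and exports; reading
#' the file back reproduces the samples within 16-bit quantization of the
#' amplitude range.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  dat <- rec$data
  T_ <- nrow(dat)
  pmin <- apply(dat, 2, min); pmax <- apply(dat, 2, max)
  flat <- pmax - pmin < 1e-12
  pmax[flat] <- pmin[flat] + 1       # avoid zero amplitude range
  dmin <- -32768; dmax <- 32767
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  num <- function(x, w) {
    s <- formatC(x, digits = 7, format = "g")
    if (nchar(s) > w) s <- formatC(x, digits = w - 3, format = "g")
    pad(s, w)
  }
  hdr <- paste0(
    pad("0", 8), pad(rec$subject_id, 80), pad("eegscreen export", 80),
    pad("01.01.26", 8), pad("00.00.00", 8), pad(256 + 256 * 3, 8), pad("", 44),
    pad(1, 8), num(T_ / rec$fs, 8), pad(3, 4)
  )
  sig <- paste0(
    paste(pad(paste("EEG", EEG_CHANNELS), 16), collapse = ""),
    paste(rep(pad("", 80), 3), collapse = ""),
    paste(rep(pad("uV", 8), 3), collapse = ""),
    paste(vapply(pmin, num, "", w = 8), collapse = ""),
    paste(vapply(pmax, num, "", w = 8), collapse = ""),
    paste(rep(pad(dmin, 8), 3), collapse = ""),
    paste(rep(pad(dmax, 8), 3), collapse = ""),
    paste(rep(pad("", 80), 3), collapse = ""),
    paste(rep(pad(T_, 8), 3), collapse = ""),
    paste(rep(pad("", 32), 3), collapse = "")
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(hdr, sig)), con)
  # header physical min/max are re-parsed so writer and reader agree exactly
  pmin_h <- as.numeric(vapply(pmin, num, "", w = 8))
  pmax_h <- as.numeric(vapply(pmax, num, "", w = 8))
  for (ch in 1:3) {
    dig <- round((dat[, ch] - pmin_h[ch]) / (pmax_h[ch] - pmin_h[ch]) *
                   (dmax - dmin) + dmin)
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a three-column CSV recording
#'
#' Reads amplifier CSV exports whose first three numeric columns are Fp1, Fz
#' and Fp2 in order (extra columns are ignored). A single header line is
#' auto-detected by a non-numeric first row. Row order is preserved.
#'
#' @param path Path to a CSV file (comma separator, `.` decimal, UTF-8).
#' @param fs Sampling rate in Hz to attach (the CSV itself carries none).
#' @param subject_id,label Subject identifier and class label to attach.
#' @return An [eeg_recording()].
#' @seealso [write_csv3()]
#' @export
read_csv3 <- function(path, fs, subject_id = NULL, label = NA_character_) {
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (nrow(raw) == 0L) stop("empty CSV file: ", path, call. = FALSE)
  if (ncol(raw) < 3L) {
    stop("CSV must have at least 3 columns (Fp1, Fz, Fp2), got ", ncol(raw),
         ": ", path, call. = FALSE)
  }
  first_num <- suppressWarnings(as.numeric(unlist(raw[1, 1:3])))
  has_header <- anyNA(first_num)
  body <- if (has_header) raw[-1, , drop = FALSE] else raw
  if (nrow(body) == 0L) stop("CSV contains a header but no data rows: ", path, call. = FALSE)
  mat <- matrix(NA_real_, nrow(body), 3L)
  for (j in 1:3) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & nzchar(body[[j]]))
    if (anyNA(v) && length(bad)) {
      stop(sprintf("unparseable numeric value %s in column %d, row %d of %s",
                   sQuote(body[[j]][bad[1]]), j,
                   bad[1] + as.integer(has_header), path), call. = FALSE)
    }
    mat[, j] <- v
  }
  if (is.null(subject_id)) subject_id <- sub("\\.csv$", "", basename(path), ignore.case = TRUE)
  eeg_recording(mat, fs = fs, subject_id = subject_id, label = label,
                meta = list(source = path, format = "csv3"))
}

#' Write a recording as a three-column CSV
#'
#' Writes the Fp1/Fz/Fp2 samples with a header row at full double precision,
#' so that [read_csv3()] reproduces the array bit-for-bit for finite inputs.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_csv3 <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  txt <- apply(rec$data, 2, function(x) sprintf("%.17g", x))
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = 1L)
  lines <- c(paste(EEG_CHANNELS, collapse = ","),
             apply(txt, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Write and read subject-level prediction tables
#'
#' `write_predictions()` serializes a subject-prediction tibble (as produced
#' by [majority_vote()]) to CSV with columns
#' `subject_id, voted_label, n_windows, votes_HC, votes_MDD, confidence`,
#' one row per subject, ordered by `subject_id`. `read_predictions()` parses
#' such a file back.
#'
#' @param preds Tibble with the columns above.
#' @param path CSV file path.
#' @return `write_predictions()` returns `path` invisibly;
#'   `read_predictions()` returns a tibble.
#' @export
write_predictions <- function(preds, path) {
  cols <- c("subject_id", "voted_label", "n_windows", "votes_HC", "votes_MDD",
            "confidence")
  missing <- setdiff(cols, names(preds))
  if (length(missing)) {
    stop("predictions table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- as.data.frame(preds[cols])
  out <- out[order(out$subject_id), , drop = FALSE]
  out$confidence <- sprintf("%.17g", out$confidence)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df) |>
    dplyr::mutate(n_windows = as.integer(.data$n_windows),
                  votes_HC = as.integer(.data$votes_HC),
                  votes_MDD = as.integer(.data$votes_MDD),
                  confidence = as.numeric(.data$confidence))
}
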