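# Spectral-statistical feature protocol: Welch PSD, relative band powers over
# the canonical EEG bands, Gaussian differential entropy, the 3 x 8 per-channel
# map and the 17-dimensional global window vector.

#' Canonical EEG band scheme
#'
#' Seven contiguous bands tiling 0.5-100 Hz: delta (0.5-4), theta (4-8),
#' alpha (8-13), beta (13-30), gamma_low (30-45), gamma_mid (45-70),
#' gamma_high (70-100). Band membership on the discrete Welch grid is
#' half-open `[lo, hi)` with the last band closed at 100 Hz, so the seven
#' bands partition the total range exactly and relative powers sum to 1.
#'
#' @return A tibble with columns `band`, `f_lo`, `f_hi`.
#' @export
band_scheme <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma_low", "gamma_mid",
             "gamma_high"),
    f_lo = c(0.5, 4, 8, 13, 30, 45, 70),
    f_hi = c(4, 8, 13, 30, 45, 70, 100))
}

#' Welch power spectral density
#'
#' Averaged modified periodogram with a periodic Hann window of length
#' `2 * fs` samples, 50% overlap (segment step `fs`), per-segment constant
#' detrending (mean removal), and one-sided density scaling. The frequency
#' resolution is `0.5` Hz for any `fs` (segment length `2 * fs`), and the
#' integral of the PSD over `[0, fs/2]` approximates the signal variance.
#'
#' @param x Numeric vector, one channel of one window; must contain at least
#'   one full Welch segment (`length(x) >= 2 * fs`).
#' @param fs Sampling rate in Hz.
#' @return A tibble with columns `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs) {
  L <- length(x)
  nper <- as.integer(round(2 * fs))
  if (L < nper) {
    stop("welch_psd() needs at least one full segment of 2*fs = ", nper,
         " samples; got ", L, ". Use longer windows.", call. = FALSE)
  }
  step <- as.integer(round(fs))
  n_seg <- (L - nper) %/% step + 1L
  w <- 0.5 * (1 - cos(2 * pi * (0:(nper - 1)) / nper))   # periodic Hann
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nper %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in seq_len(n_seg)) {
    seg <- x[((s - 1L) * step + 1L):((s - 1L) * step + nper)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(nfreq)])^2 * scale
    acc <- acc + sp
  }
  psd <- acc / n_seg
  psd[2:(nfreq - 1L)] <- 2 * psd[2:(nfreq - 1L)]   # one-sided (not DC/Nyquist)
  tibble::tibble(freq = (seq_len(nfreq) - 1) * fs / nper, psd = psd)
}

#' Relative band powers
#'
#' Integrates the PSD over each band of a [band_scheme()] by the rectangle
#' rule (bin sum times grid step) and normalizes by the total 0.5-100 Hz
#' power. Because the bands tile the total range on the discrete grid, the
#' seven values sum to exactly 1.
#'
#' @param freqs,psd Frequency grid (Hz) and one-sided PSD, e.g. from
#'   [welch_psd()]. The grid must cover 0.5-100 Hz.
#' @param scheme Band definition tibble (default [band_scheme()]).
#' @return Named numeric vector of 7 relative powers in band order.
#' @export
relative_band_powers <- function(freqs, psd, scheme = band_scheme()) {
  if (max(freqs) < max(scheme$f_hi)) {
    stop("frequency grid must reach ", max(scheme$f_hi), " Hz; got max ",
         max(freqs), " Hz (sampling rate too low?)", call. = FALSE)
  }
  df <- freqs[2] - freqs[1]
  last <- which.max(scheme$f_hi)
  band_power <- vapply(seq_len(nrow(scheme)), function(i) {
    in_band <- freqs >= scheme$f_lo[i] &
      (if (i == last) freqs <= scheme$f_hi[i] else freqs < scheme$f_hi[i])
    sum(psd[in_band]) * df
  }, 0)
  total <- sum(band_power)
  if (total <= 0) {
    stop("degenerate window: total 0.5-100 Hz power is zero (should have been removed by QC)",
         call. = FALSE)
  }
  stats::setNames(band_power / total, scheme$band)
}

#' Differential entropy under a Gaussian assumption
#'
#' `h = 1/2 * ln(2 * pi * e * sigma^2)` in nats, with `sigma^2` the sample
#' variance of the window. Variance is floored at `1e-12` so degenerate
#' input stays finite. For a unit-variance (z-scored) window this equals
#' `1/2 * ln(2*pi*e)` (about 1.41894), and it grows by 1 nat per factor
#' `e^2` of variance.
#'
#' @param x Numeric vector (one channel of one window), `length(x) >= 2`.
#' @return Differential entropy in nats.
#' @export
differential_entropy <- function(x) {
  stopifnot(length(x) >= 2L)
  0.5 * log(2 * pi * exp(1) * max(stats::var(x), 1e-12))
}

# biased (population) third/fourth standardized moments; kurtosis is Pearson
# (non-excess). Convention fixed and documented; the moments are computed on
# z-scored windows so the mean is near 0 but not assumed to be.
moments4 <- function(x) {
  n <- length(x)
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  c(mean = m,
    sd = stats::sd(x),
    skewness = if (m2 > 0) mean(d^3) / m2^1.5 else 0,
    kurtosis = if (m2 > 0) mean(d^4) / m2^2 else 0)
}

#' Per-channel spectral-statistical map
#'
#' The 3 x 8 per-window map: for each channel (Fp1, Fz, Fp2) the seven
#' relative band powers in [band_scheme()] order followed by the
#' differential entropy (nats).
#'
#' @param window L x 3 matrix, one QC-passed z-scored window.
#' @param fs Sampling rate in Hz.
#' @return 3 x 8 matrix with channel rownames and feature colnames.
#' @export
per_channel_map <- function(window, fs) {
  stopifnot(is.matrix(window), ncol(window) == 3L)
  out <- matrix(0, 3, 8, dimnames = list(EEG_CHANNELS,
                                         c(band_scheme()$band, "DE")))
  for (ch in 1:3) {
    p <- welch_psd(window[, ch], fs)
    out[ch, 1:7] <- relative_band_powers(p$freq, p$psd)
    out[ch, 8] <- differential_entropy(window[, ch])
  }
  out
}

# the five spectral-balance ratios, from channel-averaged relative powers
RATIO_DEFS <- list(
  ratio_delta_gamma_low = c("delta", "gamma_low"),
  ratio_delta_gamma_mid = c("delta", "gamma_mid"),
  ratio_theta_beta      = c("theta", "beta"),
  ratio_theta_gamma_mid = c("theta", "gamma_mid"),
  ratio_alpha_gamma_low = c("alpha", "gamma_low"))

#' Global 17-dimensional window vector
#'
#' Elements 1-12 are the four distributional moments (mean, SD, skewness,
#' Pearson kurtosis) per channel in channel order; elements 13-17 are five
#' spectral-balance ratios of channel-averaged relative band powers:
#' delta/gamma_low, delta/gamma_mid, theta/beta, theta/gamma_mid,
#' alpha/gamma_low. Differential entropy is deliberately excluded here (it
#' lives only in the per-channel map). Ratio denominators are floored at
#' `1e-12`.
#'
#' @param window L x 3 matrix, one QC-passed z-scored window.
#' @param relpowers 3 x 7 matrix of per-channel relative band powers (the
#'   first seven columns of [per_channel_map()]).
#' @return Named numeric vector of length 17.
#' @export
global_vector <- function(window, relpowers) {
  stopifnot(is.matrix(window), ncol(window) == 3L,
            nrow(relpowers) == 3L, ncol(relpowers) == 7L)
  mom <- lapply(1:3, function(ch) {
    stats::setNames(moments4(window[, ch]),
                    paste(EEG_CHANNELS[ch], c("mean", "sd", "skewness", "kurtosis"),
                          sep = "_"))
  })
  avg <- colMeans(relpowers)
  names(avg) <- band_scheme()$band
  ratios <- vapply(RATIO_DEFS, function(rd) {
    avg[[rd[1]]] / max(avg[[rd[2]]], 1e-12)
  }, 0)
  c(unlist(mom), ratios)
}

#' Compute feature bundles for a window set
#'
#' For every window, computes the three model inputs: the raw z-scored
#' window (L x 3), the 3 x 8 per-channel spectral-statistical map, and the
#' 17-dimensional global vector. All three derive from the same window;
#' feature computation is deterministic.
#'
#' @param ws A (QC-filtered) `eeg_windows` object.
#' @return An object of class `eeg_features`: list with `raw` (N x L x 3),
#'   `map` (N x 3 x 8), `glob` (N x 17 matrix), `info` (window provenance
#'   tibble) and `params`.
#' @export
compute_features <- function(ws) {
  stopifnot(inherits(ws, "eeg_windows"))
  n <- dim(ws$windows)[1]
  map <- array(0, c(n, 3L, 8L))
  glob <- matrix(0, n, 17L)
  for (i in seq_len(n)) {
    w <- ws$windows[i, , ]
    m <- per_channel_map(w, ws$params$fs)
    map[i, , ] <- m
    glob[i, ] <- global_vector(w, m[, 1:7, drop = FALSE])
  }
  colnames(glob) <- global_vector_names()
  structure(list(raw = ws$windows, map = map, glob = glob, info = ws$info,
                 params = ws$params),
            class = "eeg_features")
}

global_vector_names <- function() {
  c(as.vector(t(outer(EEG_CHANNELS, c("mean", "sd", "skewness", "kurtosis"),
                      paste, sep = "_"))),
    names(RATIO_DEFS))
}

#' @export
print.eeg_features <- function(x, ...) {
  cat(sprintf("<eeg_features> %d windows: raw %dx3, map 3x8, global 17\n",
              dim(x$raw)[1], dim(x$raw)[2]))
  invisible(x)
}

#' Flatten features to a tibble
#'
#' One row per window: provenance (`subject_id`, `label`, `start_sample`),
#' the 24 per-channel map values (`map_<channel>_<feature>`), and the 17
#' global values. This is the interoperability surface for classical
#' (feature-only) baselines.
#'
#' @param x An `eeg_features` object.
#' @param ... Unused.
#' @export
#' @exportS3Method tibble::as_tibble
as_tibble.eeg_features <- function(x, ...) {
  n <- dim(x$map)[1]
  feat_names <- c(band_scheme()$band, "DE")
  map_cols <- list()
  for (ch in 1:3) for (f in 1:8) {
    map_cols[[paste("map", EEG_CHANNELS[ch], feat_names[f], sep = "_")]] <-
      x$map[, ch, f]
  }
  dplyr::bind_cols(x$info, tibble::as_tibble(map_cols),
                   tibble::as_tibble(as.data.frame(x$glob)))
}

#' Export window features as CSV
#'
#' @param x An `eeg_features` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_features <- function(x, path) {
  utils::write.csv(as.data.frame(as_tibble(x)), path, row.names = FALSE)
  invisible(path)
}
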