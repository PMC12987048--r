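# Synthetic eyes-closed frontal EEG cohorts. Each channel is spectrally
# shaped noise: a 1/f^beta background partitioned into the seven canonical
# bands with class- and subject-conditioned log band weights, plus a
# narrowband alpha peak. Band weights control the programmed relative band
# powers exactly in expectation, which is what makes parameter-recovery
# tests possible.

#' Specification of a synthetic cohort
#'
#' Defaults emulate a small portable-device cohort: 12 healthy controls and
#' 8 patients, one continuous 90 s eyes-closed recording per subject at
#' 250 Hz. Class structure is encoded as per-band mean log band weights;
#' the default patient contrast follows the frontal-slowing direction
#' (relative theta and low-gamma up, high-gamma and delta down), with
#' between-subject variation as an additive log-scale random effect so
#' band powers stay positive.
#'
#' @param n_hc,n_mdd Subject counts per class.
#' @param fs Sampling rate in Hz.
#' @param duration_s Recording duration in seconds.
#' @param base_log_power Named length-7 vector of baseline log band weights
#'   (HC class), in [band_scheme()] order. The softmax of these is the
#'   programmed HC relative band-power profile.
#' @param mdd_shift Named length-7 vector added to `base_log_power` for the
#'   patient class.
#' @param subject_effect_sd SD of the per-subject, per-band log-weight
#'   random effect.
#' @param channel_jitter_sd SD of the small per-channel log-weight jitter
#'   around the subject's weights.
#' @param alpha_peak_hz,alpha_peak_sd Centre (Hz) and width of the
#'   narrowband alpha component.
#' @param alpha_peak_frac Fraction of alpha-band power carried by the peak
#'   (the rest follows the 1/f background shape).
#' @param one_over_f_exponent Spectral background exponent beta.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_hc = 12L, n_mdd = 8L, fs = 250, duration_s = 90,
                        base_log_power = c(delta = log(0.35), theta = log(0.15),
                                           alpha = log(0.25), beta = log(0.12),
                                           gamma_low = log(0.06),
                                           gamma_mid = log(0.04),
                                           gamma_high = log(0.03)),
                        mdd_shift = c(delta = -0.30, theta = 0.45, alpha = 0,
                                      beta = 0, gamma_low = 0.30,
                                      gamma_mid = 0, gamma_high = -0.45),
                        subject_effect_sd = 0.30, channel_jitter_sd = 0.05,
                        alpha_peak_hz = 10, alpha_peak_sd = 1,
                        alpha_peak_frac = 0.6, one_over_f_exponent = 1) {
  bands <- band_scheme()$band
  stopifnot(n_hc >= 0, n_mdd >= 0, fs > 0, duration_s > 0,
            setequal(names(base_log_power), bands),
            setequal(names(mdd_shift), bands),
            subject_effect_sd >= 0, channel_jitter_sd >= 0,
            alpha_peak_frac >= 0, alpha_peak_frac <= 1,
            all(is.finite(base_log_power)))
  structure(list(n_hc = as.integer(n_hc), n_mdd = as.integer(n_mdd), fs = fs,
                 duration_s = duration_s,
                 base_log_power = base_log_power[bands],
                 mdd_shift = mdd_shift[bands],
                 subject_effect_sd = subject_effect_sd,
                 channel_jitter_sd = channel_jitter_sd,
                 alpha_peak_hz = alpha_peak_hz, alpha_peak_sd = alpha_peak_sd,
                 alpha_peak_frac = alpha_peak_frac,
                 one_over_f_exponent = one_over_f_exponent),
            class = "cohort_spec")
}

# target one-sided power spectrum on the FFT grid for one channel, given the
# channel's band weights (linear scale). Shape within each band follows
# 1/f^beta; the alpha band additionally carries a Gaussian peak.
shaped_spectrum <- function(freqs, w, spec) {
  sc <- band_scheme()
  S <- numeric(length(freqs))
  last <- which.max(sc$f_hi)
  for (i in seq_len(nrow(sc))) {
    in_band <- freqs >= sc$f_lo[i] &
      (if (i == last) freqs <= sc$f_hi[i] else freqs < sc$f_hi[i])
    if (!any(in_band)) next
    shape <- 1 / pmax(freqs[in_band], 0.5)^spec$one_over_f_exponent
    if (sc$band[i] == "alpha" && spec$alpha_peak_frac > 0) {
      peak <- exp(-0.5 * ((freqs[in_band] - spec$alpha_peak_hz) /
                            spec$alpha_peak_sd)^2)
      shape <- (1 - spec$alpha_peak_frac) * shape / sum(shape) +
        spec$alpha_peak_frac * peak / sum(peak)
    } else {
      shape <- shape / sum(shape)
    }
    S[in_band] <- w[i] * shape
  }
  S
}

#' Simulate one eyes-closed frontal recording
#'
#' Draws the subject's per-band log weights (class mean plus subject random
#' effect), then synthesizes each channel by FFT-domain spectral shaping of
#' white noise: exact band control, fast, and deterministic under seed. The
#' three channels share the subject's band weights up to a small
#' independent jitter. Consumes the current RNG stream.
#'
#' @param class `"HC"` or `"MDD"`.
#' @param spec A [cohort_spec()].
#' @param subject_id Subject identifier to attach.
#' @return An [eeg_recording()] with the class label attached.
#' @export
simulate_recording <- function(class = c("HC", "MDD"), spec = cohort_spec(),
                               subject_id = "SIM1") {
  class <- match.arg(class)
  T_ <- as.integer(round(spec$duration_s * spec$fs))
  mu <- spec$base_log_power + if (class == "MDD") spec$mdd_shift else 0
  subj_logw <- mu + stats::rnorm(7, 0, spec$subject_effect_sd)
  freqs <- seq(0, spec$fs / 2, length.out = T_ %/% 2 + 1)
  dat <- matrix(0, T_, 3)
  for (ch in 1:3) {
    logw <- subj_logw + stats::rnorm(7, 0, spec$channel_jitter_sd)
    S <- shaped_spectrum(freqs, exp(logw), spec)
    amp_half <- sqrt(S)
    # mirror onto the full FFT grid (hermitian layout for a real signal)
    amp <- c(amp_half, rev(amp_half[2:(length(amp_half) - if (T_ %% 2 == 0) 1 else 0)]))
    z <- stats::fft(stats::rnorm(T_))
    dat[, ch] <- Re(stats::fft(z * amp, inverse = TRUE)) / T_
  }
  eeg_recording(dat, fs = spec$fs, subject_id = subject_id, label = class,
                meta = list(synthetic = TRUE, class = class))
}

#' Simulate a labeled cohort
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional seed; the cohort is deterministic given the seed.
#' @param id_prefix Prefix for generated subject IDs.
#' @return List with `recordings` (list of [eeg_recording()]) and
#'   `manifest` (tibble `subject_id`, `label`, `duration_s`).
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = NULL,
                            id_prefix = "SIM") {
  if (!is.null(seed)) set.seed(seed)
  labels <- c(rep("HC", spec$n_hc), rep("MDD", spec$n_mdd))
  n <- length(labels)
  ids <- sprintf("%s%03d", id_prefix, seq_len(n))
  recordings <- vector("list", n)
  for (i in seq_len(n)) {
    recordings[[i]] <- simulate_recording(labels[i], spec, subject_id = ids[i])
  }
  manifest <- tibble::tibble(subject_id = ids, label = labels,
                             duration_s = rep(spec$duration_s, n))
  list(recordings = recordings, manifest = manifest)
}

#' Subject-level spectral contrast check
#'
#' Runs the canonical analysis pattern on a cohort: z-score, segment,
#' QC-filter, compute relative band powers, aggregate windows to one mean
#' value per subject (avoiding pseudo-replication), then compare classes
#' with Cliff's delta (MDD vs HC), a two-sided Mann-Whitney test, and
#' percentile bootstrap CIs of each class mean.
#'
#' @param recordings List of labeled [eeg_recording()]s (both classes
#'   present), e.g. `simulate_cohort(...)$recordings`.
#' @param band Band name from [band_scheme()].
#' @param channel `"Fp1"`, `"Fz"`, `"Fp2"`, or `NULL` to average channels.
#' @param L,p Segmentation parameters (defaults 3840 samples, 50%).
#' @param B,level Bootstrap resamples and CI level.
#' @param seed Optional seed for the bootstrap.
#' @return List with `delta` (Cliff's delta, positive when the MDD class is
#'   higher), `p_value` (Mann-Whitney), `hc_mean`, `mdd_mean`, `hc_ci`,
#'   `mdd_ci`, and the per-subject aggregated tibble `subjects`.
#' @export
verify_spectral_contrast <- function(recordings, band, channel = NULL,
                                     L = 3840, p = 50, B = 4000L,
                                     level = 0.95, seed = NULL) {
  stopifnot(band %in% band_scheme()$band)
  ws <- segment_windows(lapply(recordings, zscore_recording), L = L, p = p)
  ws <- qc_filter(ws)$windows
  feats <- compute_features(ws)
  ch_idx <- if (is.null(channel)) 1:3 else match(channel, EEG_CHANNELS)
  if (anyNA(ch_idx)) stop("unknown channel: ", channel, call. = FALSE)
  b_idx <- match(band, band_scheme()$band)
  val <- apply(feats$map[, ch_idx, b_idx, drop = FALSE], 1, mean)
  subjects <- tibble::tibble(subject_id = feats$info$subject_id,
                             label = feats$info$label, value = val) |>
    dplyr::group_by(.data$subject_id, .data$label) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  x <- subjects$value[subjects$label == "MDD"]
  y <- subjects$value[subjects$label == "HC"]
  if (!length(x) || !length(y)) stop("both classes must be present", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  list(delta = cliffs_delta(x, y),
       p_value = stats::wilcox.test(x, y, exact = FALSE)$p.value,
       mdd_mean = mean(x), hc_mean = mean(y),
       mdd_ci = if (length(x) >= 2) bootstrap_mean_ci(x, B, level) else c(lo = NA, hi = NA),
       hc_ci = if (length(y) >= 2) bootstrap_mean_ci(y, B, level) else c(lo = NA, hi = NA),
       band = band, channel = if (is.null(channel)) "mean" else channel,
       subjects = subjects)
}
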