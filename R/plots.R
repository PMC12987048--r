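# ggplot2 visualization helpers: signal traces, Welch spectra, training
# history, vote confidence, and group spectral contrasts.

#' Plot a recording's channel traces
#'
#' @param object An [eeg_recording()].
#' @param max_seconds Plot at most this many seconds from the start.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.eeg_recording <- function(object, max_seconds = 10, ...) {
  d <- as_tibble(object)
  d <- d[d$time <= max_seconds, ]
  d <- tidyr::pivot_longer(d, -"time", names_to = "channel",
                           values_to = "amplitude")
  d$channel <- factor(d$channel, levels = EEG_CHANNELS)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = "amplitude",
                  title = sprintf("subject %s (%s)", object$subject_id,
                                  ifelse(is.na(object$label), "?", object$label)))
}

#' Plot Welch spectra of a recording
#'
#' Per-channel Welch PSD on a log power scale with the canonical band
#' boundaries marked.
#'
#' @param rec An [eeg_recording()] (ideally z-scored).
#' @param fmax Upper frequency limit for the plot (Hz).
#' @return A ggplot object.
#' @export
plot_psd <- function(rec, fmax = 100) {
  stopifnot(inherits(rec, "eeg_recording"))
  d <- purrr::map_dfr(1:3, function(ch) {
    p <- welch_psd(rec$data[, ch], rec$fs)
    p$channel <- EEG_CHANNELS[ch]
    p
  })
  d <- d[d$freq > 0 & d$freq <= fmax, ]
  d$channel <- factor(d$channel, levels = EEG_CHANNELS)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$freq, y = .data$psd,
                                  colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = band_scheme()$f_hi, linetype = "dotted",
                        colour = "grey60") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "PSD (power/Hz)",
                  colour = "channel")
}

#' Plot training history of a fitted model
#'
#' Accuracy and loss per epoch for training and validation streams, plus
#' the learning-rate schedule.
#'
#' @param object A trained `eeg_model` (with a `history` tibble).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.eeg_model <- function(object, ...) {
  h <- object$history
  if (is.null(h) || !nrow(h)) stop("model has no training history", call. = FALSE)
  d <- tidyr::pivot_longer(h, c("loss", "accuracy", "val_loss", "val_accuracy",
                                "lr"),
                           names_to = "metric", values_to = "value")
  d$panel <- ifelse(grepl("loss", d$metric), "loss",
                    ifelse(d$metric == "lr", "learning rate", "accuracy"))
  d$stream <- ifelse(grepl("^val_", d$metric), "validation", "training")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$stream)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel), scales = "free_y",
                        ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL)
}

#' Plot per-subject vote confidence
#'
#' One point per subject: the mean predicted probability of the voted class,
#' coloured by voted label, with the window count annotated. The dashed
#' line marks 0.9.
#'
#' @param preds Subject predictions from [majority_vote()].
#' @return A ggplot object.
#' @export
plot_vote_confidence <- function(preds) {
  d <- dplyr::arrange(preds, .data$voted_label, .data$confidence)
  d$subject_id <- factor(d$subject_id, levels = d$subject_id)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$subject_id, y = .data$confidence,
                                  colour = .data$voted_label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = paste0("K=", .data$n_windows)),
                       vjust = -1, size = 2.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0.9, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(HC = "#2166ac", MDD = "#b2182b")) +
    ggplot2::coord_cartesian(ylim = c(0.5, 1.02)) +
    ggplot2::labs(x = NULL, y = "vote confidence", colour = "voted label") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot a subject-level spectral group contrast
#'
#' Class means with bootstrap CIs and per-subject points for one band and
#' channel, as produced by [verify_spectral_contrast()].
#'
#' @param contrast Result of [verify_spectral_contrast()].
#' @return A ggplot object.
#' @export
plot_spectral_contrast <- function(contrast) {
  s <- contrast$subjects
  ci <- tibble::tibble(
    label = c("HC", "MDD"),
    mean = c(contrast$hc_mean, contrast$mdd_mean),
    lo = c(contrast$hc_ci["lo"], contrast$mdd_ci["lo"]),
    hi = c(contrast$hc_ci["hi"], contrast$mdd_ci["hi"]))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$label, colour = .data$label)) +
    ggplot2::geom_jitter(ggplot2::aes(y = .data$value), width = 0.08,
                         alpha = 0.6) +
    ggplot2::geom_pointrange(data = ci,
                             ggplot2::aes(y = .data$mean, ymin = .data$lo,
                                          ymax = .data$hi),
                             linewidth = 0.9, size = 0.5) +
    ggplot2::scale_colour_manual(values = c(HC = "#2166ac", MDD = "#b2182b"),
                                 guide = "none") +
    ggplot2::labs(x = NULL,
                  y = sprintf("relative %s power (%s)", contrast$band,
                              contrast$channel),
                  title = sprintf("Cliff's delta = %.2f, p = %.2g",
                                  contrast$delta, contrast$p_value))
}
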