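# Label-preserving training-time augmentations. These run only inside the
# training loop; the inference path never touches them.

#' Augmentation configurations
#'
#' `augment_config()` parameterizes the training-time recipe for the hybrid
#' model: additive Gaussian noise (sd 0.01 z-units, probability 0.7), slow
#' linear drift (channel-wise ramp up to 3% of the channel's within-window
#' peak-to-peak amplitude, probability 0.3), per-channel amplitude scaling
#' (factors from N(1, 0.1^2), probability 0.5), and optional MixUp with
#' Beta(0.2, 0.2) mixing. `se_augment_config()` is the separate recipe used
#' for the squeeze-and-excitation baseline: noise sd 0.02, circular temporal
#' shifts up to 10% of the window length, and amplitude scaling with sd
#' 0.05, each applied with probability 0.5.
#'
#' @param noise_sd,p_noise Gaussian noise sd (z-units) and gate probability.
#' @param drift_max_frac,p_drift Maximum drift as a fraction of the channel
#'   peak-to-peak amplitude, and gate probability.
#' @param scale_sd,p_scale Amplitude-scaling sd and gate probability.
#' @param mixup_alpha,mixup_enabled Beta parameter for MixUp and its switch.
#' @return A list of class `augment_config` / `se_augment_config`.
#' @export
augment_config <- function(noise_sd = 0.01, p_noise = 0.7,
                           drift_max_frac = 0.03, p_drift = 0.3,
                           scale_sd = 0.1, p_scale = 0.5,
                           mixup_alpha = 0.2, mixup_enabled = TRUE) {
  stopifnot(p_noise >= 0, p_noise <= 1, p_drift >= 0, p_drift <= 1,
            p_scale >= 0, p_scale <= 1, noise_sd >= 0, scale_sd >= 0,
            drift_max_frac >= 0, mixup_alpha > 0)
  structure(list(noise_sd = noise_sd, p_noise = p_noise,
                 drift_max_frac = drift_max_frac, p_drift = p_drift,
                 scale_sd = scale_sd, p_scale = p_scale,
                 mixup_alpha = mixup_alpha, mixup_enabled = mixup_enabled),
            class = "augment_config")
}

#' @rdname augment_config
#' @param shift_max_frac Maximum circular shift as a fraction of the window
#'   length.
#' @param p_op Shared gate probability for the three SE-recipe operations.
#' @export
se_augment_config <- function(noise_sd = 0.02, shift_max_frac = 0.10,
                              scale_sd = 0.05, p_op = 0.5) {
  stopifnot(p_op >= 0, p_op <= 1, noise_sd >= 0, scale_sd >= 0,
            shift_max_frac >= 0)
  structure(list(noise_sd = noise_sd, shift_max_frac = shift_max_frac,
                 scale_sd = scale_sd, p_op = p_op),
            class = "se_augment_config")
}

#' Augment one training window
#'
#' Applies, independently and in the order noise, drift, scale, each
#' operation with its configured probability (see [augment_config()]).
#' Consumes the current RNG stream; seed at the call site for
#' reproducibility. Shape and finiteness are preserved.
#'
#' @param w L x 3 window matrix in z-units.
#' @param cfg An [augment_config()].
#' @return Augmented L x 3 matrix.
#' @export
augment_window <- function(w, cfg = augment_config()) {
  L <- nrow(w)
  if (stats::runif(1) < cfg$p_noise && cfg$noise_sd > 0) {
    w <- w + matrix(stats::rnorm(L * 3, sd = cfg$noise_sd), L, 3)
  }
  if (stats::runif(1) < cfg$p_drift && cfg$drift_max_frac > 0) {
    ramp <- seq(0, 1, length.out = L)
    for (ch in 1:3) {
      amp <- diff(range(w[, ch])) * cfg$drift_max_frac
      d <- stats::runif(1, -amp, amp)
      w[, ch] <- w[, ch] + ramp * d
    }
  }
  if (stats::runif(1) < cfg$p_scale && cfg$scale_sd > 0) {
    fac <- stats::rnorm(3, mean = 1, sd = cfg$scale_sd)
    w <- sweep(w, 2, fac, "*")
  }
  w
}

#' Augment one window with the squeeze-and-excitation baseline recipe
#'
#' Additive Gaussian noise, a circular temporal shift applied jointly to all
#' channels (offset uniform in `[-shift_max_frac * L, shift_max_frac * L]`
#' samples, wrap-around), and per-channel amplitude scaling, each gated
#' independently with probability `p_op`.
#'
#' @param w L x 3 window matrix in z-units.
#' @param cfg An [se_augment_config()].
#' @return Augmented L x 3 matrix.
#' @export
se_augment_window <- function(w, cfg = se_augment_config()) {
  L <- nrow(w)
  if (stats::runif(1) < cfg$p_op && cfg$noise_sd > 0) {
    w <- w + matrix(stats::rnorm(L * 3, sd = cfg$noise_sd), L, 3)
  }
  if (stats::runif(1) < cfg$p_op && cfg$shift_max_frac > 0) {
    m <- floor(cfg$shift_max_frac * L)
    s <- as.integer(round(stats::runif(1, -m, m)))
    w <- circular_shift(w, s)
  }
  if (stats::runif(1) < cfg$p_op && cfg$scale_sd > 0) {
    fac <- stats::rnorm(3, mean = 1, sd = cfg$scale_sd)
    w <- sweep(w, 2, fac, "*")
  }
  w
}

# rotate rows by s samples (positive s delays the signal), wrap-around
circular_shift <- function(w, s) {
  L <- nrow(w)
  s <- ((s %% L) + L) %% L
  if (s == 0) return(w)
  w[c((L - s + 1L):L, 1L:(L - s)), , drop = FALSE]
}

#' MixUp a training batch
#'
#' Pairs every item with a random permutation partner, draws one mixing
#' weight `lambda ~ Beta(alpha, alpha)` per pair, and forms the convex
#' combination of the two items and of their one-hot labels. The same
#' `lambda` is applied identically to all three input representations (raw
#' window, per-channel map, global vector), keeping the three views of each
#' mixed example consistent. Label rows stay on the simplex. A batch of one
#' passes through unchanged.
#'
#' @param X List with arrays `raw` (B x L x 3), `map` (B x 3 x 8) and
#'   `glob` (B x 17); any subset of these elements may be present.
#' @param Y B x 2 matrix of (one-hot or already soft) labels.
#' @param alpha Beta distribution parameter (default 0.2).
#' @return List `(X, Y)` with the mixed batch.
#' @export
mixup_batch <- function(X, Y, alpha = 0.2) {
  B <- nrow(Y)
  if (B < 2L) return(list(X = X, Y = Y))
  perm <- sample.int(B)
  lam <- stats::rbeta(B, alpha, alpha)
  mix_arr <- function(a) {
    b <- a
    if (length(dim(a)) == 3L) {
      a2 <- a[perm, , , drop = FALSE]
      lam_b <- array(rep(lam, times = prod(dim(a)[-1])), dim(a))
      b <- lam_b * a + (1 - lam_b) * a2
    } else {
      a2 <- a[perm, , drop = FALSE]
      b <- lam * a + (1 - lam) * a2
    }
    b
  }
  list(X = lapply(X, mix_arr), Y = lam * Y + (1 - lam) * Y[perm, , drop = FALSE])
}
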