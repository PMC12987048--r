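# Shared fixtures, all generated in code at test time.

# deterministic white-noise recording
noise_recording <- function(T_ = 5000, fs = 250, subject_id = "S1",
                            label = "HC", seed = 1) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(T_ * 3), ncol = 3), fs = fs,
                subject_id = subject_id, label = label)
}

# pure-tone recording (same sinusoid on all channels unless phases given)
tone_recording <- function(freq = 10, T_ = 5000, fs = 250, amp = 1,
                           subject_id = "S1") {
  t <- (seq_len(T_) - 1) / fs
  x <- amp * sin(2 * pi * freq * t)
  eeg_recording(cbind(x, x, x), fs = fs, subject_id = subject_id)
}

# tiny hybrid configuration for fast structural/gradient tests
tiny_hybrid_config <- function(...) {
  hybrid_config(emb_raw = 8, head_units = 8, map_filters = c(4, 6),
                raw_filters = c(4, 5, 6), wd = 1e-3, ...)
}

# small synthetic feature set with a linearly separable class signal in the
# global vector; enough for the training machinery to learn quickly
toy_features <- function(n_subjects = 8, windows_per_subject = 6, L = 64,
                         seed = 7, sep = 3) {
  set.seed(seed)
  n <- n_subjects * windows_per_subject
  labels_subj <- rep(c("HC", "MDD"), length.out = n_subjects)
  subject_id <- rep(sprintf("T%02d", seq_len(n_subjects)),
                    each = windows_per_subject)
  label <- rep(labels_subj, each = windows_per_subject)
  glob <- matrix(rnorm(n * 17), n, 17)
  glob[label == "MDD", 1:4] <- glob[label == "MDD", 1:4] + sep
  colnames(glob) <- eegscreen:::global_vector_names()
  structure(list(
    raw = array(rnorm(n * L * 3), c(n, L, 3)),
    map = array(rnorm(n * 3 * 8), c(n, 3, 8)),
    glob = glob,
    info = tibble::tibble(subject_id = subject_id, label = label,
                          start_sample = 0L),
    params = list(L = L, p = 0, S = L, fs = 250)),
    class = "eeg_features")
}

toy_split <- function(features, seed = 1) {
  manifest <- dplyr::distinct(features$info[c("subject_id", "label")])
  suppressWarnings(subject_split(manifest, dev_frac = 0.75, train_frac = 0.7,
                                 seed = seed))
}
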