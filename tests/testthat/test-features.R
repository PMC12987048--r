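# Welch spectra, band powers, differential entropy, and the two feature
# containers (3 x 8 map, 17-dim global vector).

test_that("Welch PSD integrates to the signal variance on white noise (Parseval)", {
  set.seed(21)
  x <- rnorm(3840)
  p <- welch_psd(x, 250)
  expect_equal(p$freq[2] - p$freq[1], 0.5)
  expect_equal(sum(p$psd) * 0.5, var(x), tolerance = 0.05)
  expect_true(all(p$psd >= 0))
})

test_that("a pure 10 Hz tone concentrates spectral mass in the 10 Hz bin", {
  rec <- tone_recording(freq = 10, T_ = 3840)
  p <- welch_psd(rec$data[, 1], 250)
  expect_equal(p$freq[which.max(p$psd)], 10)
  # Hann tapering spreads an on-bin tone into the two neighbouring bins
  expect_gt(sum(p$psd[abs(p$freq - 10) <= 0.5]) / sum(p$psd), 0.99)
})

test_that("constant detrending yields an all-zero PSD for constant input", {
  p <- welch_psd(rep(3.3, 1000), 250)
  expect_true(all(abs(p$psd) < 1e-25))
})

test_that("windows shorter than one Welch segment are refused", {
  expect_error(welch_psd(rnorm(300), 250), "2\\*fs")
})

test_that("relative band powers sum to one and localize a tone in alpha", {
  rec <- tone_recording(freq = 10, T_ = 3840)
  p <- welch_psd(rec$data[, 1], 250)
  rp <- relative_band_powers(p$freq, p$psd)
  expect_equal(sum(rp), 1, tolerance = 1e-9)
  expect_gt(rp["alpha"], 0.99)
  expect_true(all(rp[setdiff(names(rp), "alpha")] < 0.01))
})

test_that("white-noise relative powers match bandwidth fractions", {
  # flat-spectrum closed form: each band's share is its bin count / 200
  set.seed(33)
  sc <- band_scheme()
  grid_share <- c(7, 8, 10, 34, 30, 50, 61) / 200   # bins per band at 0.5 Hz
  rp_acc <- rep(0, 7)
  n_rep <- 40
  for (i in seq_len(n_rep)) {
    x <- rnorm(3840)
    p <- welch_psd(x, 250)
    rp_acc <- rp_acc + relative_band_powers(p$freq, p$psd)
  }
  expect_equal(unname(rp_acc / n_rep), grid_share, tolerance = 0.03)
  # coarse bandwidth/99.5 closed form for theta
  expect_equal(unname(rp_acc[2] / n_rep), 4 / 99.5, tolerance = 0.05)
})

test_that("differential entropy has the Gaussian closed form and log-linearity", {
  set.seed(5)
  x <- rnorm(3840)
  x <- (x - mean(x)) / sd(x)                       # exactly unit variance
  expect_equal(differential_entropy(x), 0.5 * log(2 * pi * exp(1)),
               tolerance = 1e-9)
  expect_equal(differential_entropy(x * exp(1)),
               differential_entropy(x) + 1, tolerance = 1e-9)
  # direct formula oracle on an arbitrary sample
  y <- rnorm(1000, sd = 3.7)
  expect_equal(differential_entropy(y), 0.5 * log(2 * pi * exp(1) * var(y)))
  # strict monotonicity in variance
  vs <- c(0.25, 0.5, 1, 2, 4)
  des <- vapply(vs, function(v) differential_entropy(x * sqrt(v)), 0)
  expect_true(all(diff(des) > 0))
})

test_that("per-channel map has identical rows for identical channels and sums to 1", {
  rec <- tone_recording(freq = 6, T_ = 3840)      # theta-dominant
  m <- per_channel_map(rec$data, 250)
  expect_identical(dim(m), c(3L, 8L))
  expect_equal(m[1, ], m[2, ])
  expect_equal(m[1, ], m[3, ])
  expect_equal(unname(rowSums(m[, 1:7])), rep(1, 3), tolerance = 1e-9)
  # theta column is the row-wise max among bands for a 6 Hz dominant signal
  expect_equal(unname(apply(m[, 1:7], 1, which.max)), rep(2, 3))
})

test_that("global vector moments match a brute-force oracle and ratios behave", {
  set.seed(44)
  w <- matrix(rnorm(3840 * 3, mean = c(0, 1, -2), sd = c(1, 2, 0.5)), 3840, 3,
              byrow = TRUE)
  rp <- matrix(1 / 7, 3, 7)
  g <- global_vector(w, rp)
  expect_length(g, 17L)
  for (ch in 1:3) {
    x <- w[, ch]
    d <- x - mean(x)
    expect_equal(unname(g[(ch - 1) * 4 + 1]), mean(x))
    expect_equal(unname(g[(ch - 1) * 4 + 2]), sd(x))
    expect_equal(unname(g[(ch - 1) * 4 + 3]), mean(d^3) / mean(d^2)^1.5)
    expect_equal(unname(g[(ch - 1) * 4 + 4]), mean(d^4) / mean(d^2)^2)
  }
  # equal average band powers give ratio 1 (e.g. delta/gamma_low)
  expect_equal(unname(g[13:17]), rep(1, 5))
  # symmetric signal (integer number of cycles): near-zero skewness
  s <- tone_recording(freq = 10, T_ = 5000)$data
  gs <- global_vector(s, rp)
  expect_lt(abs(gs["Fp1_skewness"]), 1e-10)
})

test_that("feature computation is deterministic and bundles stay aligned", {
  rec <- zscore_recording(noise_recording(4000, seed = 10))
  ws <- segment_windows(rec, L = 1280, p = 50)
  f1 <- compute_features(ws)
  f2 <- compute_features(ws)
  expect_identical(f1$map, f2$map)
  expect_identical(f1$glob, f2$glob)
  expect_identical(dim(f1$raw)[1], dim(f1$map)[1])
  # flattening: 3 provenance + 24 map + 17 global columns
  tbl <- tibble::as_tibble(f1)
  expect_equal(ncol(tbl), 3 + 24 + 17)
  expect_equal(tbl$map_Fp1_delta, f1$map[, 1, 1])
  path <- withr::local_tempfile(fileext = ".csv")
  export_features(f1, path)
  expect_equal(nrow(utils::read.csv(path)), nrow(tbl))
})
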