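# Synthetic cohort generator: determinism, programmed spectral structure,
# and the subject-level contrast analysis.

fast_spec <- function(..., duration_s = 30) cohort_spec(duration_s = duration_s, ...)

test_that("cohorts are deterministic given a seed and carry a consistent manifest", {
  spec <- fast_spec(n_hc = 3, n_mdd = 2)
  c1 <- simulate_cohort(spec, seed = 7)
  c2 <- simulate_cohort(spec, seed = 7)
  expect_identical(c1$recordings[[4]]$data, c2$recordings[[4]]$data)
  expect_equal(nrow(c1$manifest), 5L)
  expect_identical(c1$manifest$label, c(rep("HC", 3), rep("MDD", 2)))
  expect_identical(c1$manifest$subject_id,
                   vapply(c1$recordings, function(r) r$subject_id, ""))
  expect_equal(anyDuplicated(c1$manifest$subject_id), 0L)
  empty <- simulate_cohort(fast_spec(n_hc = 0, n_mdd = 0))
  expect_length(empty$recordings, 0L)
  expect_equal(nrow(empty$manifest), 0L)
})

test_that("recordings have the requested shape and sampling rate", {
  set.seed(1)
  rec <- simulate_recording("HC", fast_spec())
  expect_equal(nrow(rec$data), 30 * 250)
  expect_equal(rec$fs, 250)
  expect_identical(colnames(rec$data), c("Fp1", "Fz", "Fp2"))
  expect_true(all(is.finite(rec$data)))
})

test_that("estimated relative band powers recover the programmed fractions", {
  # no subject effect / channel jitter: the expected relative powers are the
  # softmax of the programmed log weights
  spec <- cohort_spec(duration_s = 90, subject_effect_sd = 0,
                      channel_jitter_sd = 0)
  set.seed(2)
  rec <- zscore_recording(simulate_recording("HC", spec))
  ws <- segment_windows(rec, L = 3840, p = 50)
  f <- compute_features(ws)
  est <- colMeans(apply(f$map[, , 1:7], c(1, 3), mean))
  prog <- exp(spec$base_log_power) / sum(exp(spec$base_log_power))
  expect_equal(unname(est), unname(prog), tolerance = 0.10)
})

test_that("an alpha-dominant spec with a pure narrow peak is recovered as alpha power", {
  base <- c(delta = -20, theta = -20, alpha = 0, beta = -20, gamma_low = -20,
            gamma_mid = -20, gamma_high = -20)
  spec <- cohort_spec(duration_s = 30, base_log_power = base,
                      subject_effect_sd = 0, channel_jitter_sd = 0,
                      alpha_peak_frac = 1)
  set.seed(3)
  rec <- zscore_recording(simulate_recording("HC", spec))
  m <- per_channel_map(rec$data[1:3840, ], 250)
  expect_gt(min(m[, "alpha"]), 0.99)
})

test_that("the programmed class contrast is recovered by the feature pipeline", {
  spec <- fast_spec(n_hc = 10, n_mdd = 10)
  cohort <- simulate_cohort(spec, seed = 11)
  theta <- verify_spectral_contrast(cohort$recordings, "theta", L = 3840,
                                    p = 50, B = 500, seed = 1)
  gh <- verify_spectral_contrast(cohort$recordings, "gamma_high", L = 3840,
                                 p = 50, B = 500, seed = 1)
  expect_gt(theta$delta, 0)          # MDD theta elevated
  expect_lt(gh$delta, 0)             # MDD high gamma reduced
  # CIs exclude each other for a 1.5-SD programmed gap
  expect_gt(theta$mdd_mean, theta$hc_mean)
  expect_lt(gh$mdd_mean, gh$hc_mean)
})

test_that("identical class specifications yield a near-zero delta", {
  spec <- fast_spec(n_hc = 8, n_mdd = 8,
                    mdd_shift = c(delta = 0, theta = 0, alpha = 0, beta = 0,
                                  gamma_low = 0, gamma_mid = 0,
                                  gamma_high = 0))
  cohort <- simulate_cohort(spec, seed = 13)
  res <- verify_spectral_contrast(cohort$recordings, "theta", L = 3840,
                                  p = 50, B = 200, seed = 2)
  expect_lt(abs(res$delta), 0.6)     # within sampling error of 0 at n=8+8
  expect_gt(res$p_value, 0.01)
})

test_that("subject aggregation first makes the contrast immune to window duplication", {
  spec <- fast_spec(n_hc = 5, n_mdd = 5)
  cohort <- simulate_cohort(spec, seed = 17)
  res <- verify_spectral_contrast(cohort$recordings, "theta", L = 3840, p = 50,
                                  B = 200, seed = 3)
  # duplicating every window per subject leaves per-subject means, hence
  # delta, unchanged
  per_subject <- res$subjects
  dup_delta <- cliffs_delta(
    rep(per_subject$value[per_subject$label == "MDD"], 2),
    rep(per_subject$value[per_subject$label == "HC"], 2))
  expect_equal(dup_delta, res$delta)
})

test_that("simulated cohorts survive the io round trip", {
  spec <- fast_spec(n_hc = 1, n_mdd = 1, duration_s = 10)
  cohort <- simulate_cohort(spec, seed = 19)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "rec.csv")
  write_csv3(cohort$recordings[[1]], p)
  back <- read_csv3(p, fs = 250)
  expect_identical(back$data, cohort$recordings[[1]]$data)
})
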