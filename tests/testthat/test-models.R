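# Architecture construction: shape chains, parameter counts, probability
# outputs, and analytic-vs-numeric gradient agreement of the network engine.

test_that("hybrid raw branch reduces 3840 -> 960 -> 240 -> 60 and concat is 352 wide", {
  m <- build_hybrid(hybrid_config(), L = 3840, seed = 1)
  # trace the temporal chain through the pooling stages
  X <- array(rnorm(2 * 3840 * 3), c(2, 3840, 3))
  lens <- integer(0)
  for (ly in m$branches$raw) {
    r <- eegscreen:::nn_forward_layer(ly, X, training = FALSE)
    X <- r$out
    if (ly$type == "maxpool") lens <- c(lens, dim(X)[2])
  }
  expect_identical(lens, c(960L, 240L, 60L))
  expect_identical(dim(X), c(2L, 192L))          # emb_raw
  # concat width = emb_raw + map_emb + glob_emb = 192 + 128 + 32
  expect_identical(m$branches$head[[2]]$c_in, 352)
})

test_that("window lengths not divisible by 64 are rejected with the pooling chain cited", {
  expect_error(build_hybrid(L = 1000), "divisible by 64")
  expect_error(build_hybrid(L = 1000), "L/64")
})

test_that("hybrid parameter count matches independent arithmetic", {
  cf <- hybrid_config()       # final selected configuration
  L <- 3840
  conv_p <- function(k, cin, f) k * cin * f + f
  dense_p <- function(cin, f) cin * f + f
  bn_p <- function(c) 2 * c
  raw <- conv_p(11, 3, 96) + bn_p(96) + conv_p(7, 96, 192) + bn_p(192) +
    conv_p(5, 192, 256) + bn_p(256) + dense_p(60 * 256, 192)
  map <- conv_p(3, 3, 48) + conv_p(3, 48, 96) + bn_p(96) + dense_p(96, 128)
  glob <- dense_p(17, 64) + dense_p(64, 32)
  head <- bn_p(352) + dense_p(352, 384) + dense_p(384, 2)
  m <- build_hybrid(cf, L = L, seed = 1)
  expect_identical(m$n_params, raw + map + glob + head)
  # deterministic given config
  expect_identical(build_hybrid(cf, L = L, seed = 9)$n_params, m$n_params)
})

test_that("softmax outputs are valid probabilities, including on zero input", {
  m <- build_hybrid(tiny_hybrid_config(), L = 64, seed = 2)
  X <- list(raw = array(0, c(3, 64, 3)), map = array(0, c(3, 3, 8)),
            glob = matrix(0, 3, 17))
  p <- eegscreen:::nn_softmax(eegscreen:::model_forward(m, X)$logits)
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-12)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("Conv1D-raw follows its documented configuration", {
  m <- build_conv1d_raw(L = 2560, seed = 3)
  layers <- m$branches$main
  convs <- Filter(function(l) l$type == "conv1d", layers)
  expect_identical(vapply(convs, `[[`, 0, "k")[1:3], c(11, 7, 5))
  expect_identical(vapply(convs, `[[`, 0, "f")[1:3], c(64, 128, 256))
  drops <- vapply(Filter(function(l) l$type == "dropout", layers), `[[`, 0, "rate")
  expect_identical(drops, c(0.25, 0.35, 0.45, 0.5))
  expect_equal(m$lr_init, 8e-4)
  # temporal chain 2560 -> 640 -> 160 -> 40; flatten feeds 40*256
  expect_identical(layers[[which(vapply(layers, `[[`, "", "type") == "flatten") + 1]]$c_in,
                   40 * 256)
  X <- list(raw = array(rnorm(2 * 2560 * 3), c(2, 2560, 3)))
  expect_identical(dim(eegscreen:::model_forward(m, X)$logits), c(2L, 2L))
})

test_that("Conv1D-SE adds sigmoid-gated SE blocks and floors odd pooled lengths", {
  m <- build_conv1d_se(L = 6000, seed = 4)
  ses <- Filter(function(l) l$type == "se", m$branches$main)
  expect_length(ses, 3L)
  expect_identical(vapply(ses, function(l) as.integer(l$cr), 0L),
                   c(8L, 16L, 32L))                        # r = 8
  # temporal chain with flooring: 6000 -> 1500 -> 375 -> 93
  X <- array(rnorm(1 * 6000 * 3), c(1, 6000, 3))
  lens <- integer(0)
  for (ly in m$branches$main) {
    r <- eegscreen:::nn_forward_layer(ly, X, training = FALSE)
    X <- r$out
    if (ly$type == "maxpool") lens <- c(lens, dim(X)[2])
    if (ly$type == "flatten") break
  }
  expect_identical(lens, c(1500L, 375L, 93L))
})

test_that("an SE gate of all ones is the identity rescaling and gates lie in (0,1)", {
  set.seed(8)
  se <- eegscreen:::nn_init_layer(eegscreen:::nn_se(8))
  X <- array(rnorm(2 * 16 * 8), c(2, 16, 8))
  fw <- eegscreen:::nn_forward_layer(se, X, training = FALSE)
  expect_true(all(fw$cache$g > 0 & fw$cache$g < 1))        # sigmoid range
  # force the gate to saturate at ~1: identity rescaling
  se$W2[] <- 0; se$b2[] <- 100
  fw1 <- eegscreen:::nn_forward_layer(se, X, training = FALSE)
  expect_equal(fw1$out, X, tolerance = 1e-10)
})

test_that("analytic gradients match numeric differentiation for both model families", {
  eps <- 1e-6
  check_model <- function(m, X, Y, n_per_param = 2) {
    for (bn in names(m$branches)) {
      for (i in seq_along(m$branches[[bn]])) {
        if (m$branches[[bn]][[i]]$type == "dropout") m$branches[[bn]][[i]]$rate <- 0
      }
    }
    lossfn <- function(mm) {
      fw <- eegscreen:::model_forward(mm, X, training = TRUE)
      eegscreen:::nn_ce_loss(fw$logits, Y)$loss + eegscreen:::model_l2(mm)
    }
    fw <- eegscreen:::model_forward(m, X, training = TRUE)
    cl <- eegscreen:::nn_ce_loss(fw$logits, Y)
    gr <- eegscreen:::model_backward(m, fw$caches, cl$dlogits)
    maxerr <- 0
    for (bn in names(m$branches)) {
      for (li in seq_along(m$branches[[bn]])) {
        ly <- m$branches[[bn]][[li]]
        for (pn in ly$param_names) {
          p <- ly[[pn]]
          for (kk in sample(length(p), min(n_per_param, length(p)))) {
            m2 <- m
            m2$branches[[bn]][[li]][[pn]][kk] <- p[kk] + eps
            lp <- lossfn(m2)
            m2$branches[[bn]][[li]][[pn]][kk] <- p[kk] - eps
            lm <- lossfn(m2)
            g_num <- (lp - lm) / (2 * eps)
            g_an <- gr[[bn]][[li]][[pn]][kk]
            maxerr <- max(maxerr, abs(g_num - g_an) /
                            max(1e-6, abs(g_num) + abs(g_an)))
          }
        }
      }
    }
    maxerr
  }
  set.seed(15)
  mh <- build_hybrid(tiny_hybrid_config(), L = 64, seed = 16)
  Xh <- list(raw = array(rnorm(3 * 64 * 3), c(3, 64, 3)),
             map = array(rnorm(3 * 24), c(3, 3, 8)),
             glob = matrix(rnorm(3 * 17), 3))
  Yh <- eegscreen:::one_hot(c("HC", "MDD", "HC"))
  expect_lt(check_model(mh, Xh, Yh), 1e-3)
  ms <- build_conv1d_se(L = 128, seed = 17)
  Xs <- list(raw = array(rnorm(4 * 128 * 3), c(4, 128, 3)))
  Ys <- eegscreen:::one_hot(c("HC", "MDD", "HC", "MDD"))
  expect_lt(check_model(ms, Xs, Ys), 1e-3)
})

test_that("prediction refuses mismatched window lengths and returns simplex rows", {
  m <- build_hybrid(tiny_hybrid_config(), L = 64, seed = 5)
  f <- toy_features(n_subjects = 4, windows_per_subject = 2, L = 64)
  pr <- predict_windows(m, f)
  expect_equal(pr$p_HC + pr$p_MDD, rep(1, nrow(pr)), tolerance = 1e-12)
  f128 <- toy_features(n_subjects = 2, windows_per_subject = 2, L = 128)
  expect_error(predict_windows(m, f128), "length mismatch")
})

test_that("model summaries, checkpoints and history accessors work", {
  m <- build_hybrid(tiny_hybrid_config(), L = 64, seed = 6)
  td <- tidy(m)
  expect_true(all(c("branch", "type", "n_params") %in% names(td)))
  expect_equal(sum(td$n_params), m$n_params)
  js <- jsonlite::fromJSON(model_summary_json(m))
  expect_equal(js$n_params, m$n_params)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(glance(m2)$n_params, m$n_params)
})
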