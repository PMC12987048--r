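# Confusion metrics, MCC, Wilson intervals, majority voting and the group
# comparison primitives.

test_that("a perfect confusion table scores 1 everywhere", {
  r <- confusion_metrics(list(tp = 7, tn = 5, fp = 0, fn = 0))
  expect_equal(r$accuracy, 1)
  expect_equal(unname(r$precision), c(1, 1))
  expect_equal(unname(r$recall), c(1, 1))
  expect_equal(r$mcc, 1)
  expect_equal(r$balanced_accuracy, 1)
})

test_that("MCC equals the phi coefficient of indicator vectors on random tables", {
  set.seed(50)
  for (i in 1:200) {
    c_ <- list(tp = sample(0:30, 1), tn = sample(0:30, 1),
               fp = sample(0:30, 1), fn = sample(0:30, 1))
    if (c_$tp + c_$tn + c_$fp + c_$fn == 0) next
    y <- rep(c(1, 0, 0, 1), unlist(c_))         # truth indicators (MDD = 1)
    p <- rep(c(1, 0, 1, 0), unlist(c_))         # prediction indicators
    phi <- suppressWarnings(cor(y, p))
    expect_equal(mcc(c_), if (is.na(phi)) 0 else phi, tolerance = 1e-12)
  }
})

test_that("zero marginals return MCC 0 by convention", {
  expect_equal(mcc(list(tp = 0, tn = 5, fp = 0, fn = 3)), 0)
  expect_equal(mcc(list(tp = 4, tn = 0, fp = 2, fn = 0)), 0)
})

test_that("Wilson bounds are symmetric under k <-> n-k and contain k/n", {
  ci <- wilson_ci(0, 20)
  ci2 <- wilson_ci(20, 20)
  expect_equal(unname(ci["lo"]), 0)
  expect_equal(unname(ci["hi"]), 1 - unname(ci2["lo"]), tolerance = 1e-12)
  set.seed(51)
  for (i in 1:50) {
    n <- sample(1:500, 1); k <- sample(0:n, 1)
    ci <- wilson_ci(k, n)
    expect_lte(ci["lo"], k / n + 1e-12)
    expect_gte(ci["hi"], k / n - 1e-12)
    expect_true(ci["lo"] >= 0 && ci["hi"] <= 1)
  }
})

test_that("majority vote reproduces the worked 7-vs-4 example and breaks ties to HC", {
  set.seed(52)
  probs <- rbind(matrix(c(0.2, 0.8), 7, 2, byrow = TRUE),
                 matrix(c(0.9, 0.1), 4, 2, byrow = TRUE))
  v <- majority_vote(probs)
  expect_identical(v$voted_label, "MDD")
  expect_equal(v$votes_MDD, 7)
  expect_equal(v$votes_HC, 4)
  expect_equal(v$n_windows, 11)
  # confidence = brute-force mean of the voted-class column
  expect_equal(v$confidence, mean(probs[, 2]))
  # 2-2 tie resolves to the first class index (HC)
  tie <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.1, 0.9), c(0.3, 0.7))
  expect_identical(majority_vote(tie)$voted_label, "HC")
  expect_error(majority_vote(tie[0, , drop = FALSE]), "no windows")
})

test_that("voting is idempotent under window duplication", {
  set.seed(53)
  tbl <- tibble::tibble(
    subject_id = rep(c("A", "B", "C"), each = 9),
    p_MDD = runif(27))
  tbl$p_HC <- 1 - tbl$p_MDD
  v1 <- majority_vote(tbl)
  v2 <- majority_vote(dplyr::bind_rows(tbl, tbl))
  expect_identical(v1$voted_label, v2$voted_label)
  expect_equal(v1$confidence, v2$confidence)
  expect_equal(v2$n_windows, 2 * v1$n_windows)
})

test_that("subject-level report carries sensitivity/specificity with Wilson CIs", {
  preds <- tibble::tibble(
    subject_id = sprintf("U%02d", 1:20),
    voted_label = rep(c("HC", "MDD"), c(12, 8)))
  truth <- tibble::tibble(subject_id = preds$subject_id,
                          label = preds$voted_label)
  r <- subject_level_report(preds, truth)
  expect_equal(r$accuracy, 1)
  expect_equal(unname(r$specificity), 1)
  expect_equal(unname(r$sensitivity), 1)
  expect_equal(unname(r$specificity_ci["lo"]), 0.757, tolerance = 2e-3)
  expect_equal(unname(r$sensitivity_ci["lo"]), 0.676, tolerance = 2e-3)
  # permutation invariance
  perm <- sample(20)
  r2 <- subject_level_report(preds[perm, ], truth)
  expect_equal(glance(r2), glance(r))
  # missing prediction is an error
  expect_error(subject_level_report(preds[-1, ], truth), "U01")
})

test_that("tidy/glance views of a metric report are consistent", {
  r <- confusion_metrics(list(tp = 212, tn = 186, fp = 8, fn = 20),
                         level = "window")
  td <- tidy(r)
  expect_identical(td$class, c("HC", "MDD", "macro avg", "weighted avg"))
  expect_equal(unname(td$support[1:2]), c(194, 232))
  g <- glance(r)
  expect_true(g$descriptive)                     # window level is flagged
  expect_equal(g$accuracy, r$accuracy)
  js <- jsonlite::fromJSON(metrics_json(r))
  expect_equal(js$summary$mcc, r$mcc)
})

test_that("Cliff's delta matches exhaustive pair counting", {
  expect_equal(cliffs_delta(2:4, -(1:3)), 1)      # complete separation
  expect_equal(cliffs_delta(1:5, 1:5), 0)         # identical samples
  set.seed(54)
  for (i in 1:50) {
    x <- rnorm(sample(2:12, 1)); y <- rnorm(sample(2:12, 1))
    bf <- 0
    for (xi in x) for (yj in y) bf <- bf + sign(xi - yj)
    expect_equal(cliffs_delta(x, y), bf / (length(x) * length(y)))
  }
})

test_that("bootstrap mean CI is deterministic, degenerate on constants, and covers", {
  expect_equal(unname(bootstrap_mean_ci(rep(3.3, 10), B = 100, seed = 1)),
               c(3.3, 3.3))
  x <- rnorm(30)
  ci <- bootstrap_mean_ci(x, B = 2000, seed = 2)
  expect_lte(ci["lo"], mean(x))
  expect_gte(ci["hi"], mean(x))
  expect_identical(bootstrap_mean_ci(x, B = 500, seed = 7),
                   bootstrap_mean_ci(x, B = 500, seed = 7))
  # coverage simulation: percentile bootstrap of the mean, Gaussian samples
  set.seed(55)
  n_rep <- 400
  hits <- 0
  for (i in seq_len(n_rep)) {
    z <- rnorm(40)
    ci <- bootstrap_mean_ci(z, B = 400)
    hits <- hits + (ci["lo"] <= 0 && ci["hi"] >= 0)
  }
  expect_gt(hits / n_rep, 0.90)
  expect_lt(hits / n_rep, 0.99)
})
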