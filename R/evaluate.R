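# Window- and subject-level metrics: confusion-derived scores, Matthews
# correlation, Wilson intervals, majority voting with vote confidence, and
# the subject-level spectral group-comparison primitives (Cliff's delta,
# bootstrap CI of the mean). MDD is the positive class throughout.

#' Confusion counts for the binary HC/MDD task
#'
#' @param truth,pred Character vectors of true and predicted labels
#'   ("HC"/"MDD"), aligned.
#' @return A `confusion_counts` list with `tp`, `tn`, `fp`, `fn`
#'   (MDD = positive class).
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) >= 1L)
  structure(list(tp = sum(truth == "MDD" & pred == "MDD"),
                 tn = sum(truth == "HC" & pred == "HC"),
                 fp = sum(truth == "HC" & pred == "MDD"),
                 fn = sum(truth == "MDD" & pred == "HC")),
            class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the phi
#' coefficient of the 2x2 table. Returns 0 when any marginal is zero (the
#' standard convention keeping the metric defined on degenerate tables).
#'
#' @param c A [confusion_counts()] object or a list with `tp,tn,fp,fn`.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(c) {
  denom <- (c$tp + c$fp) * (c$tp + c$fn) * (c$tn + c$fp) * (c$tn + c$fn)
  if (denom == 0) return(0)
  (c$tp * c$tn - c$fp * c$fn) / sqrt(denom)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Standard Wilson bounds at `level` with `z = qnorm(1 - (1-level)/2)`,
#' clipped to `[0, 1]`; the interval always contains `k/n`. Preferred over
#' the Wald interval for its small-sample coverage.
#'
#' @param k Number of successes (`0 <= k <= n`).
#' @param n Number of trials (`n >= 1`).
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(lo, hi)`.
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  d <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / d
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / d
  c(lo = max(0, centre - half), hi = min(1, centre + half))
}

#' Full metric report from confusion counts
#'
#' Accuracy, per-class precision/recall/F1 with support, macro (unweighted)
#' and weighted (support-weighted) averages, balanced accuracy (mean of the
#' two recalls), MCC, and the 95% Wilson interval on accuracy. Zero
#' denominators in precision/recall/F1 yield 0.
#'
#' @param counts A [confusion_counts()].
#' @param level `"window"` or `"subject"`. Window-level reports are flagged
#'   descriptive: overlapping windows are correlated, so window counts do
#'   not behave like independent test cases.
#' @param ci_level Confidence level for the Wilson interval.
#' @return A `metrics_report` list; see [tidy.metrics_report()] and
#'   [glance.metrics_report()].
#' @export
confusion_metrics <- function(counts, level = c("subject", "window"),
                              ci_level = 0.95) {
  level <- match.arg(level)
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  stopifnot(total >= 1)
  sdiv <- function(a, b) if (b == 0) 0 else a / b
  prec <- c(HC = sdiv(tn, tn + fn), MDD = sdiv(tp, tp + fp))
  rec <- c(HC = sdiv(tn, tn + fp), MDD = sdiv(tp, tp + fn))
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  support <- c(HC = tn + fp, MDD = tp + fn)
  acc <- (tp + tn) / total
  structure(list(
    counts = counts, level = level, descriptive = level == "window",
    accuracy = acc,
    precision = prec, recall = rec, f1 = f1, support = support,
    macro = c(precision = mean(prec), recall = mean(rec), f1 = mean(f1)),
    weighted = c(precision = sum(prec * support) / total,
                 recall = sum(rec * support) / total,
                 f1 = sum(f1 * support) / total),
    balanced_accuracy = mean(rec),
    mcc = mcc(counts),
    wilson_ci = wilson_ci(tp + tn, total, ci_level),
    ci_level = ci_level),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s-level%s\n", x$level,
              if (x$descriptive) " (descriptive: overlapping windows are correlated)" else ""))
  print(as.data.frame(tidy(x)), digits = 4)
  cat(sprintf("accuracy %.4f (Wilson %g%% CI %.4f-%.4f)  balanced acc %.4f  MCC %.4f\n",
              x$accuracy, 100 * x$ci_level, x$wilson_ci["lo"], x$wilson_ci["hi"],
              x$balanced_accuracy, x$mcc))
  invisible(x)
}

#' Tidy a metric report into a per-class table
#'
#' One row per class plus macro and weighted average rows, mirroring the
#' conventional classification-report layout.
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.metrics_report <- function(x, ...) {
  tibble::tibble(
    class = c("HC", "MDD", "macro avg", "weighted avg"),
    precision = c(x$precision, x$macro["precision"], x$weighted["precision"]),
    recall = c(x$recall, x$macro["recall"], x$weighted["recall"]),
    f1 = c(x$f1, x$macro["f1"], x$weighted["f1"]),
    support = c(x$support, sum(x$support), sum(x$support)))
}

#' @describeIn tidy.metrics_report One-row summary (accuracy, balanced
#'   accuracy, MCC, Wilson bounds, level flag).
#' @export
#' @exportS3Method generics::glance
glance.metrics_report <- function(x, ...) {
  tibble::tibble(level = x$level, accuracy = x$accuracy,
                 balanced_accuracy = x$balanced_accuracy, mcc = x$mcc,
                 ci_lo = unname(x$wilson_ci["lo"]), ci_hi = unname(x$wilson_ci["hi"]),
                 n = sum(x$support), descriptive = x$descriptive)
}

#' Serialize a metric report to JSON
#'
#' @param x A `metrics_report`.
#' @param path Optional output path.
#' @export
metrics_json <- function(x, path = NULL) {
  js <- jsonlite::toJSON(list(summary = as.data.frame(glance(x)),
                              per_class = as.data.frame(tidy(x))),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Majority voting over a subject's windows
#'
#' Each window votes for its argmax class; the subject label is the modal
#' class. Exact ties resolve deterministically by argmax over the
#' vote-count vector, i.e. to the first class index (HC). The vote
#' confidence is the mean, over all K windows, of the probability assigned
#' to the voted class.
#'
#' @param window_probs Either a K x 2 matrix of `(p_HC, p_MDD)` rows for a
#'   single subject, or a tibble with columns `subject_id`, `p_HC`, `p_MDD`
#'   (e.g. from [predict_windows()]) covering any number of subjects.
#' @return Tibble with one row per subject: `subject_id`, `n_windows`,
#'   `votes_HC`, `votes_MDD`, `voted_label`, `confidence`.
#' @export
majority_vote <- function(window_probs) {
  if (is.matrix(window_probs)) {
    window_probs <- tibble::tibble(subject_id = "S1",
                                   p_HC = window_probs[, 1],
                                   p_MDD = window_probs[, 2])
  }
  stopifnot(all(c("subject_id", "p_HC", "p_MDD") %in% names(window_probs)))
  if (nrow(window_probs) == 0L) stop("no windows to vote over", call. = FALSE)
  vote_one <- function(d) {
    probs <- cbind(d$p_HC, d$p_MDD)
    votes_w <- max.col(probs, ties.method = "first")
    votes <- c(sum(votes_w == 1L), sum(votes_w == 2L))
    voted <- which.max(votes)                    # tie -> HC (first index)
    tibble::tibble(n_windows = nrow(probs),
                   votes_HC = votes[1], votes_MDD = votes[2],
                   voted_label = EEG_CLASSES[voted],
                   confidence = mean(probs[, voted]))
  }
  window_probs |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(~ vote_one(.x)) |>
    dplyr::ungroup()
}

#' Subject-level metric report from voted predictions
#'
#' Joins voted labels to the true subject labels, builds the subject-level
#' confusion table (MDD positive) and reports the full metric set plus
#' sensitivity (MDD recall) and specificity (HC recall) with per-class
#' Wilson intervals.
#'
#' @param preds Tibble from [majority_vote()] (needs `subject_id`,
#'   `voted_label`).
#' @param truth Tibble with `subject_id` and `label`, or a named character
#'   vector of labels.
#' @param ci_level Confidence level.
#' @return A `metrics_report` with extra fields `sensitivity`,
#'   `specificity`, `sensitivity_ci`, `specificity_ci`.
#' @export
subject_level_report <- function(preds, truth, ci_level = 0.95) {
  if (!is.data.frame(truth)) {
    truth <- tibble::tibble(subject_id = names(truth), label = unname(truth))
  }
  truth <- dplyr::distinct(truth[c("subject_id", "label")])
  missing <- setdiff(truth$subject_id, preds$subject_id)
  if (length(missing)) {
    stop("no prediction for subject(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  j <- dplyr::inner_join(preds, truth, by = "subject_id")
  rep_ <- confusion_metrics(confusion_counts(j$label, j$voted_label),
                            level = "subject", ci_level = ci_level)
  c_ <- rep_$counts
  rep_$sensitivity <- rep_$recall["MDD"]
  rep_$specificity <- rep_$recall["HC"]
  rep_$sensitivity_ci <- wilson_ci(c_$tp, c_$tp + c_$fn, ci_level)
  rep_$specificity_ci <- wilson_ci(c_$tn, c_$tn + c_$fp, ci_level)
  rep_
}

#' Cliff's delta effect size
#'
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n_x * n_y)`, computed
#' exactly over all pairs. +1 means complete separation with `x` above `y`;
#' 0 means stochastic equality.
#'
#' @param x,y Nonempty numeric samples.
#' @return Delta in `[-1, 1]`.
#' @export
cliffs_delta <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  d <- outer(x, y, "-")
  (sum(d > 0) - sum(d < 0)) / (length(x) * length(y))
}

#' Percentile bootstrap confidence interval of the mean
#'
#' @param values Numeric vector with at least 2 values.
#' @param B Number of bootstrap resamples (default 4000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional seed; the interval is deterministic given the seed.
#' @return Named numeric vector `c(lo, hi)`.
#' @export
bootstrap_mean_ci <- function(values, B = 4000L, level = 0.95, seed = NULL) {
  stopifnot(length(values) >= 2L)
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  means <- vapply(seq_len(B), function(i) mean(values[sample.int(n, n, replace = TRUE)]), 0)
  q <- stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  c(lo = q[1], hi = q[2])
}
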