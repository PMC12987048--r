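# End-to-end orchestration: preprocessing -> features -> subject-independent
# split -> two-stage hyperparameter search -> final fit -> subject-level
# majority-vote evaluation.

#' Run the full screening pipeline on labeled recordings
#'
#' Applies the canonical chain to a list of labeled recordings: per-recording
#' z-scoring, overlapped segmentation, window QC, feature extraction,
#' subject-independent splitting, stage-1 randomized hyperparameter search on
#' the development subjects, stage-2 refinement with a final fit on combined
#' train+val, and a single evaluation on the held-out test subjects with
#' majority voting.
#'
#' @param recordings List of labeled [eeg_recording()]s.
#' @param L,p Window length (samples) and overlap percent.
#' @param dev_frac,train_frac Split fractions (see [subject_split()]).
#' @param n_trials,short_epochs Stage-1 budget.
#' @param refine_k,refine_epochs,final_epochs Stage-2 budget.
#' @param augment_cfg Training-time [augment_config()] (`NULL` disables).
#' @param batch_size Mini-batch size.
#' @param patience_early,patience_plateau Callback patiences (epochs).
#' @param seed Seed covering the split, search, initialization and training.
#' @param verbose Progress lines.
#' @return A list of class `eeg_pipeline_fit`: `split`, `qc`, `trials`,
#'   `refinement`, `config`, `model`, `window_preds`, `subject_preds`,
#'   `report` (subject-level [confusion_metrics()]), `window_report`.
#' @export
run_pipeline <- function(recordings, L = 3840, p = 50, dev_frac = 0.80,
                         train_frac = 0.85, n_trials = 12L, short_epochs = 40L,
                         refine_k = 3L, refine_epochs = 150L,
                         final_epochs = 150L, augment_cfg = augment_config(),
                         batch_size = 64L, patience_early = 15L,
                         patience_plateau = 5L, seed = 42L, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  recs <- lapply(recordings, zscore_recording)
  ws <- segment_windows(recs, L = L, p = p)
  qc <- qc_filter(ws)
  feats <- compute_features(qc$windows)
  manifest <- dplyr::distinct(feats$info[c("subject_id", "label")])
  split <- subject_split(manifest, dev_frac = dev_frac, train_frac = train_frac)
  assert_no_leakage(split, feats$info)
  trials <- random_search(feats, split, n_trials = n_trials,
                          epochs = short_epochs, L = L,
                          augment_cfg = augment_cfg, batch_size = batch_size,
                          patience_early = patience_early,
                          patience_plateau = patience_plateau,
                          verbose = verbose)
  ref <- refine_top_k(trials, feats, split, k = refine_k,
                      epochs = refine_epochs, final_epochs = final_epochs,
                      L = L, augment_cfg = augment_cfg,
                      batch_size = batch_size,
                      patience_early = patience_early,
                      patience_plateau = patience_plateau, verbose = verbose)
  test_idx <- which(feats$info$subject_id %in% split$test)
  test_feats <- subset_features(feats, test_idx)
  window_preds <- predict_windows(ref$model, test_feats, batch_size)
  subject_preds <- majority_vote(window_preds)
  truth <- dplyr::distinct(test_feats$info[c("subject_id", "label")])
  report <- subject_level_report(subject_preds, truth)
  window_report <- confusion_metrics(
    confusion_counts(window_preds$label, window_preds$pred_label),
    level = "window")
  structure(list(split = split, qc = qc$report, trials = trials,
                 refinement = ref$refinement, config = ref$config,
                 model = ref$model, window_preds = window_preds,
                 subject_preds = subject_preds, report = report,
                 window_report = window_report,
                 params = list(L = L, p = p, fs = recs[[1]]$fs)),
            class = "eeg_pipeline_fit")
}

#' @export
print.eeg_pipeline_fit <- function(x, ...) {
  cat("<eeg_pipeline_fit>\n")
  print(x$split)
  cat(sprintf("selected config: emb_raw=%d head_units=%d lr=%g\n",
              x$config$emb_raw, x$config$head_units, x$config$lr_init))
  cat(sprintf("subject-level test accuracy %.3f (%d subjects); window-level %.3f\n",
              x$report$accuracy, sum(x$report$support),
              x$window_report$accuracy))
  invisible(x)
}

#' Reference classical baseline on the 17-dimensional global vector
#'
#' The feature-only comparison point: an L2-regularized logistic regression
#' (ridge) on the standardized global window vector, trained on the training
#' subjects with inverse-frequency class weights, evaluated on the held-out
#' test subjects at window level and aggregated by majority voting. The
#' scaler is fitted on training windows only.
#'
#' @param features An `eeg_features` object.
#' @param split A [subject_split()].
#' @param lambda Ridge penalty passed to [glmnet::glmnet()].
#' @return List with `window_preds`, `subject_preds`, `report` (subject
#'   level) and `window_report`.
#' @export
classical_baseline <- function(features, split, lambda = 1e-2) {
  tr_idx <- which(features$info$subject_id %in% union(split$train, split$val))
  te_idx <- which(features$info$subject_id %in% split$test)
  stopifnot(length(tr_idx) > 0, length(te_idx) > 0)
  Xtr <- features$glob[tr_idx, , drop = FALSE]
  mu <- colMeans(Xtr); sdv <- pmax(apply(Xtr, 2, stats::sd), 1e-8)
  std <- function(X) sweep(sweep(X, 2, mu), 2, sdv, "/")
  ytr <- factor(features$info$label[tr_idx], levels = EEG_CLASSES)
  cw <- class_weights(features$info$label[tr_idx])
  fit <- glmnet::glmnet(std(Xtr), ytr, family = "binomial", alpha = 0,
                        lambda = lambda, weights = cw[as.character(ytr)])
  p_mdd <- as.vector(stats::predict(fit, std(features$glob[te_idx, , drop = FALSE]),
                                    type = "response"))
  window_preds <- dplyr::bind_cols(
    features$info[te_idx, ],
    tibble::tibble(p_HC = 1 - p_mdd, p_MDD = p_mdd,
                   pred_label = ifelse(p_mdd > 0.5, "MDD", "HC")))
  subject_preds <- majority_vote(window_preds)
  truth <- dplyr::distinct(features$info[te_idx, c("subject_id", "label")])
  list(window_preds = window_preds, subject_preds = subject_preds,
       report = subject_level_report(subject_preds, truth),
       window_report = confusion_metrics(
         confusion_counts(window_preds$label, window_preds$pred_label),
         level = "window"))
}
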