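# Subject-independent training protocol: group-aware splitting, inverse-
# frequency class weights, Adam training with early stopping and
# learning-rate plateau reduction, and the two-stage randomized
# hyperparameter search with refinement.

#' Subject-independent (group-aware) split
#'
#' Randomly partitions subjects (never windows) into a development and a
#' held-out test set, then splits the development subjects into training and
#' validation subsets. All windows of a subject follow that subject, so the
#' window-level partitions are leakage-free by construction. Counts are
#' rounded to whole subjects (`round(dev_frac * N)` development subjects,
#' `round(train_frac * n_dev)` training subjects).
#'
#' @param manifest Data frame with columns `subject_id` and `label`, one row
#'   per subject or per window (duplicates are collapsed).
#' @param dev_frac Fraction of subjects in the development set (default 0.80).
#' @param train_frac Fraction of development subjects used for training
#'   (default 0.85; the rest form the validation set).
#' @param seed Optional seed; the split is deterministic given the seed.
#' @return A `subject_split`: list with character vectors `train`, `val`,
#'   `test`, `dev`, and an `assignments` tibble (`subject_id`, `label`,
#'   `partition`).
#' @export
subject_split <- function(manifest, dev_frac = 0.80, train_frac = 0.85,
                          seed = NULL) {
  subj <- dplyr::distinct(tibble::as_tibble(manifest[c("subject_id", "label")]))
  if (anyDuplicated(subj$subject_id)) {
    stop("a subject maps to more than one label", call. = FALSE)
  }
  n <- nrow(subj)
  if (n < 3L) stop("need at least 3 subjects to split", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ord <- sample.int(n)
  n_dev <- max(1L, min(n - 1L, as.integer(round(dev_frac * n))))
  dev <- subj$subject_id[ord[seq_len(n_dev)]]
  test <- subj$subject_id[ord[(n_dev + 1L):n]]
  n_train <- max(1L, min(n_dev - 1L, as.integer(round(train_frac * n_dev))))
  train <- dev[seq_len(n_train)]
  val <- dev[(n_train + 1L):n_dev]
  split <- structure(list(train = train, val = val, test = test, dev = dev,
                          assignments = dplyr::mutate(
                            subj,
                            partition = dplyr::case_when(
                              .data$subject_id %in% train ~ "train",
                              .data$subject_id %in% val ~ "val",
                              TRUE ~ "test"))),
                     class = "subject_split")
  for (part in c("train", "val", "test")) {
    lab <- subj$label[subj$subject_id %in% split[[part]]]
    miss <- setdiff(EEG_CLASSES, lab[!is.na(lab)])
    if (length(miss)) {
      warning(sprintf("partition '%s' has no %s subjects (small cohort)",
                      part, paste(miss, collapse = "/")), call. = FALSE)
    }
  }
  assert_no_leakage(split)
  split
}

#' @export
print.subject_split <- function(x, ...) {
  cat(sprintf("<subject_split> train %d / val %d / test %d subjects\n",
              length(x$train), length(x$val), length(x$test)))
  invisible(x)
}

#' Leakage audit for a subject split
#'
#' Asserts that the train/validation/test subject sets are pairwise
#' disjoint. When a window table is supplied, additionally verifies by
#' brute-force scan that no subject's windows land in more than one
#' partition.
#'
#' @param split A [subject_split()].
#' @param window_info Optional window provenance tibble with `subject_id`.
#' @return `TRUE` invisibly; error if any leakage is detected.
#' @export
assert_no_leakage <- function(split, window_info = NULL) {
  parts <- list(train = split$train, val = split$val, test = split$test)
  for (i in 1:2) for (j in (i + 1):3) {
    common <- intersect(parts[[i]], parts[[j]])
    if (length(common)) {
      stop("subject leakage between ", names(parts)[i], " and ", names(parts)[j],
           ": ", paste(common, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(window_info)) {
    assign_of <- function(s) {
      hit <- vapply(parts, function(p) s %in% p, TRUE)
      if (sum(hit) != 1L) stop("subject ", s, " is in ", sum(hit),
                               " partitions", call. = FALSE)
      names(parts)[hit]
    }
    per_window <- vapply(window_info$subject_id, assign_of, "")
    tab <- table(window_info$subject_id,
                 factor(per_window, levels = names(parts)))
    if (any(rowSums(tab > 0) > 1L)) stop("window-level leakage detected", call. = FALSE)
  }
  invisible(TRUE)
}

#' Inverse-frequency class weights
#'
#' `w_c = N_total / (2 * N_c)` from the training window counts, so the
#' minority class gets weight > 1 and the mean-normalized weights are
#' invariant to the total count.
#'
#' @param train_labels Character vector of window labels ("HC"/"MDD").
#' @return Named numeric vector `c(HC = ..., MDD = ...)`.
#' @export
class_weights <- function(train_labels) {
  counts <- table(factor(train_labels, levels = EEG_CLASSES))
  if (any(counts == 0)) {
    stop("both classes must be present in the training set; counts: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
         call. = FALSE)
  }
  n <- sum(counts)
  stats::setNames(as.numeric(n / (2 * counts)), EEG_CLASSES)
}

subset_features <- function(features, idx) {
  structure(list(raw = features$raw[idx, , , drop = FALSE],
                 map = features$map[idx, , , drop = FALSE],
                 glob = features$glob[idx, , drop = FALSE],
                 info = features$info[idx, , drop = FALSE],
                 params = features$params),
            class = "eeg_features")
}

one_hot <- function(labels) {
  Y <- matrix(0, length(labels), 2L, dimnames = list(NULL, EEG_CLASSES))
  Y[cbind(seq_along(labels), match(labels, EEG_CLASSES))] <- 1
  Y
}

# inference-mode loss/accuracy over a feature subset
model_evaluate <- function(model, features, batch_size = 64L) {
  n <- dim(features$raw)[1]
  if (n == 0L) return(list(loss = NA_real_, accuracy = NA_real_))
  Y <- one_hot(features$info$label)
  loss <- 0; correct <- 0
  for (at in seq(1L, n, by = batch_size)) {
    ix <- at:min(at + batch_size - 1L, n)
    X <- list(raw = features$raw[ix, , , drop = FALSE],
              map = features$map[ix, , , drop = FALSE],
              glob = features$glob[ix, , drop = FALSE])
    fw <- model_forward(model, X, training = FALSE)
    cl <- nn_ce_loss(fw$logits, Y[ix, , drop = FALSE])
    loss <- loss + cl$loss * length(ix)
    correct <- correct + sum(max.col(cl$p, ties.method = "first") ==
                               max.col(Y[ix, , drop = FALSE], ties.method = "first"))
  }
  list(loss = loss / n, accuracy = correct / n)
}

#' Train a model under the subject-independent protocol
#'
#' Minimizes class-weighted (soft-label) cross-entropy with Adam.
#' Augmentations (and MixUp, when enabled in `augment_cfg`) are bound to the
#' training stream only; validation batches always run un-augmented in
#' inference mode. Validation accuracy is monitored for learning-rate
#' plateau reduction (halving after `patience_plateau` stale epochs, floored
#' at `lr_min`) and early stopping (`patience_early` stale epochs, best
#' weights restored). When the split has no validation subjects (the final
#' fit on combined train+val), the model trains for the full epoch budget
#' without early stopping.
#'
#' @param model An `eeg_model` from one of the builders.
#' @param features An `eeg_features` object covering all subjects.
#' @param split A [subject_split()].
#' @param augment_cfg An [augment_config()], or `NULL` to disable
#'   augmentation entirely.
#' @param epochs Maximum number of epochs.
#' @param batch_size Mini-batch size (default 64).
#' @param patience_early,patience_plateau Early-stopping and
#'   plateau patience in epochs.
#' @param lr_factor,lr_min Learning-rate decay factor and floor.
#' @param seed Optional seed covering shuffling, augmentation and dropout.
#' @param use_val Use the split's validation subjects (`TRUE`) or fold them
#'   into training (`FALSE`, the final-fit rule).
#' @param verbose Print one line per epoch.
#' @return The trained `eeg_model` with a `history` tibble
#'   (`epoch, loss, accuracy, val_loss, val_accuracy, lr`).
#' @export
train_model <- function(model, features, split, augment_cfg = augment_config(),
                        epochs = 40L, batch_size = 64L, patience_early = 15L,
                        patience_plateau = 5L, lr_factor = 0.5, lr_min = 1e-5,
                        seed = NULL, use_val = TRUE, verbose = FALSE) {
  stopifnot(inherits(model, "eeg_model"), inherits(features, "eeg_features"))
  if (!is.null(seed)) set.seed(seed)
  train_subj <- if (use_val) split$train else union(split$train, split$val)
  tr_idx <- which(features$info$subject_id %in% train_subj)
  va_idx <- if (use_val) which(features$info$subject_id %in% split$val) else integer(0)
  if (!length(tr_idx)) stop("empty training stream: no windows for training subjects",
                            call. = FALSE)
  tr <- subset_features(features, tr_idx)
  va <- subset_features(features, va_idx)
  Y <- one_hot(tr$info$label)
  cw <- class_weights(tr$info$label)
  opt <- lapply(model$branches, adam_init)
  lr <- model$lr_init
  hist <- list()
  best <- list(metric = -Inf, branches = model$branches, epoch = 0L)
  stale_stop <- 0L; stale_lr <- 0L; step_t <- 0L
  n_tr <- length(tr_idx)
  monitor_val <- length(va_idx) > 0L
  if (epochs < 1L) {
    model$history <- tibble::tibble(epoch = integer(), loss = numeric(),
                                    accuracy = numeric(), val_loss = numeric(),
                                    val_accuracy = numeric(), lr = numeric())
    return(model)
  }
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n_tr)
    ep_loss <- 0; ep_correct <- 0
    for (at in seq(1L, n_tr, by = batch_size)) {
      ix <- ord[at:min(at + batch_size - 1L, n_tr)]
      raw <- tr$raw[ix, , , drop = FALSE]
      if (!is.null(augment_cfg)) {
        for (b in seq_along(ix)) {
          raw[b, , ] <- augment_window(raw[b, , ], augment_cfg)
        }
      }
      X <- list(raw = raw,
                map = tr$map[ix, , , drop = FALSE],
                glob = tr$glob[ix, , drop = FALSE])
      Yb <- Y[ix, , drop = FALSE]
      if (!is.null(augment_cfg) && isTRUE(augment_cfg$mixup_enabled) &&
          length(ix) >= 2L) {
        mx <- mixup_batch(X, Yb, augment_cfg$mixup_alpha)
        X <- mx$X; Yb <- mx$Y
      }
      wts <- as.vector(Yb %*% cw)     # soft labels blend the class weights
      fw <- model_forward(model, X, training = TRUE)
      model <- fw$model
      cl <- nn_ce_loss(fw$logits, Yb, wts)
      grads <- model_backward(model, fw$caches, cl$dlogits)
      step_t <- step_t + 1L
      for (bn in names(model$branches)) {
        st <- adam_step(model$branches[[bn]], grads[[bn]], opt[[bn]], lr, step_t)
        model$branches[[bn]] <- st$layers
        opt[[bn]] <- st$opt
      }
      ep_loss <- ep_loss + cl$loss * length(ix)
      ep_correct <- ep_correct + sum(max.col(cl$p, ties.method = "first") ==
                                       max.col(Yb, ties.method = "first"))
    }
    ev <- if (monitor_val) model_evaluate(model, va, batch_size) else
      list(loss = NA_real_, accuracy = NA_real_)
    hist[[ep]] <- tibble::tibble(
      epoch = ep, loss = ep_loss / n_tr + model_l2(model),
      accuracy = ep_correct / n_tr,
      val_loss = ev$loss, val_accuracy = ev$accuracy, lr = lr)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.4f  val_acc %s  lr %.2g",
                      ep, hist[[ep]]$loss, hist[[ep]]$accuracy,
                      ifelse(monitor_val, sprintf("%.4f", ev$accuracy), "--"), lr))
    }
    metric <- if (monitor_val) ev$accuracy else ep_correct / n_tr
    if (!is.finite(metric)) metric <- -Inf
    if (metric > best$metric + 1e-12) {
      best <- list(metric = metric, branches = model$branches, epoch = ep)
      stale_stop <- 0L; stale_lr <- 0L
    } else {
      stale_stop <- stale_stop + 1L; stale_lr <- stale_lr + 1L
    }
    if (monitor_val && stale_lr >= patience_plateau && lr > lr_min) {
      lr <- max(lr * lr_factor, lr_min)
      stale_lr <- 0L
    }
    if (monitor_val && stale_stop >= patience_early) break
  }
  if (monitor_val) model$branches <- best$branches   # restore best-val weights
  model$trained <- TRUE
  model$history <- dplyr::bind_rows(hist)
  model
}

#' The stage-1 randomized search space
#'
#' Candidate sets for the eight tuned hyperparameters of the hybrid model.
#' The sets are exactly the values explored across the 12 stage-1 trials:
#' `emb_raw` {128, 192, 256}, `head_units` {128, 256, 384}, `lr_init`
#' {5e-4, 8e-4, 1e-3}, `map_drop` {0.25, 0.30, 0.35}, `map_filters`
#' {(32,64), (48,96)}, `raw_drop` {(0.25,0.35,0.45), (0.3,0.4,0.5)},
#' `raw_filters` {(64,128,256), (96,192,256)}, `wd` {5e-5, 1e-4}.
#'
#' @return Named list of candidate value sets (tuples as list elements).
#' @export
search_space <- function() {
  list(emb_raw = list(128, 192, 256),
       head_units = list(128, 256, 384),
       lr_init = list(5e-4, 8e-4, 1e-3),
       map_drop = list(0.25, 0.30, 0.35),
       map_filters = list(c(32, 64), c(48, 96)),
       raw_drop = list(c(0.25, 0.35, 0.45), c(0.3, 0.4, 0.5)),
       raw_filters = list(c(64, 128, 256), c(96, 192, 256)),
       wd = list(5e-5, 1e-4))
}

space_config <- function(space, pick) {
  args <- lapply(seq_along(space), function(j) space[[j]][[pick[j]]])
  names(args) <- names(space)
  do.call(hybrid_config, args)
}

#' Stage-1 randomized hyperparameter search
#'
#' Samples `n_trials` configurations uniformly without replacement from the
#' full grid of a [search_space()], trains each briefly with early stopping
#' on the training subjects, and ranks them by best validation accuracy.
#' The held-out test subjects are never touched.
#'
#' @param features,split,augment_cfg As in [train_model()].
#' @param space A [search_space()].
#' @param n_trials Number of sampled configurations (default 12); capped at
#'   the grid size.
#' @param epochs Short-run epoch budget per trial (default 40).
#' @param L Window length for the built models.
#' @param batch_size,patience_early,patience_plateau Passed to [train_model()].
#' @param seed Seed for sampling and training.
#' @param verbose Progress lines.
#' @return Tibble sorted by descending `val_acc`: `trial`, `val_acc`, the
#'   eight hyperparameters (tuples formatted as `"(a, b, c)"`), and a
#'   `config` list-column with the [hybrid_config()] objects.
#' @export
random_search <- function(features, split, space = search_space(),
                          n_trials = 12L, epochs = 40L, L = 3840,
                          augment_cfg = augment_config(), batch_size = 64L,
                          patience_early = 15L, patience_plateau = 5L,
                          seed = NULL, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- vapply(space, length, 0L)
  grid_n <- prod(sizes)
  n_trials <- min(n_trials, grid_n)
  picks <- sample.int(grid_n, n_trials)       # without replacement
  rows <- vector("list", n_trials)
  fmt_tuple <- function(v) if (length(v) > 1L)
    paste0("(", paste(v, collapse = ", "), ")") else as.character(v)
  for (t in seq_len(n_trials)) {
    ix <- picks[t] - 1L
    pick <- integer(length(sizes))
    for (j in seq_along(sizes)) {
      pick[j] <- ix %% sizes[j] + 1L
      ix <- ix %/% sizes[j]
    }
    cfg <- space_config(space, pick)
    model <- build_hybrid(cfg, L = L)
    model <- train_model(model, features, split, augment_cfg = augment_cfg,
                         epochs = epochs, batch_size = batch_size,
                         patience_early = patience_early,
                         patience_plateau = patience_plateau)
    val_acc <- max(model$history$val_accuracy, na.rm = TRUE)
    if (verbose) message(sprintf("trial %d/%d: val_acc %.4f", t, n_trials, val_acc))
    rows[[t]] <- tibble::tibble(
      trial = t, val_acc = val_acc,
      emb_raw = cfg$emb_raw, head_units = cfg$head_units,
      lr_init = cfg$lr_init, map_drop = cfg$map_drop,
      map_filters = fmt_tuple(cfg$map_filters),
      raw_drop = fmt_tuple(cfg$raw_drop),
      raw_filters = fmt_tuple(cfg$raw_filters), wd = cfg$wd,
      config = list(cfg))
  }
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$val_acc))
}

#' Stage-2 refinement and final fit
#'
#' Retrains the `k` best short-run configurations for longer, selects the
#' winner by refinement-stage validation accuracy (not the short-run peak,
#' which can collapse under extended optimization), and retrains that
#' configuration once on the combined training and validation subjects
#' before any test evaluation.
#'
#' @param trials Ranked trial table from [random_search()].
#' @param features,split,augment_cfg As in [train_model()].
#' @param k Number of top candidates to refine (clamped to the table size).
#' @param epochs Refinement epoch budget (default 150).
#' @param final_epochs Epoch budget for the final train+val fit. The default
#'   `NULL` retrains for the epoch at which the winning refinement run
#'   reached its best validation accuracy — the usual rule when the final
#'   fit has no validation subjects left to monitor.
#' @param L,batch_size,patience_early,patience_plateau As in [random_search()].
#' @param verbose Progress lines.
#' @return List with `config` (winning [hybrid_config()]), `model` (the
#'   final model fitted on train+val), `refinement` (tibble of refinement
#'   val accuracies) and `selected_trial`.
#' @export
refine_top_k <- function(trials, features, split, k = 3L, epochs = 150L,
                         final_epochs = NULL, L = 3840,
                         augment_cfg = augment_config(), batch_size = 64L,
                         patience_early = 15L, patience_plateau = 5L,
                         verbose = FALSE) {
  k <- min(k, nrow(trials))
  stopifnot(k >= 1L)
  top <- trials[seq_len(k), , drop = FALSE]
  ref_acc <- numeric(k)
  best_epoch <- integer(k)
  for (i in seq_len(k)) {
    model <- build_hybrid(top$config[[i]], L = L)
    model <- train_model(model, features, split, augment_cfg = augment_cfg,
                         epochs = epochs, batch_size = batch_size,
                         patience_early = patience_early,
                         patience_plateau = patience_plateau)
    ref_acc[i] <- max(model$history$val_accuracy, na.rm = TRUE)
    best_epoch[i] <- which.max(model$history$val_accuracy)
    if (verbose) message(sprintf("refine %d/%d (trial %d): val_acc %.4f",
                                 i, k, top$trial[i], ref_acc[i]))
  }
  win <- which.max(ref_acc)   # refinement-stage accuracy decides
  if (is.null(final_epochs)) final_epochs <- best_epoch[win]
  refinement <- tibble::tibble(trial = top$trial, short_run_val_acc = top$val_acc,
                               refine_val_acc = ref_acc)
  final_cfg <- top$config[[win]]
  final <- build_hybrid(final_cfg, L = L)
  final <- train_model(final, features, split, augment_cfg = augment_cfg,
                       epochs = final_epochs, batch_size = batch_size,
                       use_val = FALSE)
  list(config = final_cfg, model = final, refinement = refinement,
       selected_trial = top$trial[win])
}
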