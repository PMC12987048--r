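# The three architectures: hybrid Conv1D/feature fusion, plain Conv1D on raw
# windows, and Conv1D with squeeze-and-excitation channel attention.

#' Hyperparameters of the hybrid fusion network
#'
#' Defaults are the final selected configuration (refinement-stage winner):
#' 192-unit raw embedding, 384-unit fusion head, initial learning rate 5e-4,
#' map-branch dropout 0.35, map filters (48, 96), raw-branch dropouts
#' (0.3, 0.4, 0.5), raw filters (96, 192, 256), L2 weight decay 1e-4.
#' Fixed constants (not searched): raw kernels (11, 7, 5) with pool size 4,
#' map kernel 3 with pool size 2, 128-unit map embedding, 64/32-unit global
#' branch, 0.5 dropout after the raw embedding and in the fusion head.
#'
#' @param emb_raw Raw-branch embedding width.
#' @param head_units Fusion-head hidden width.
#' @param lr_init Initial Adam learning rate.
#' @param map_drop Dropout rate in the map branch.
#' @param map_filters Two filter counts for the map-branch convolutions.
#' @param raw_drop Three dropout rates for the raw-branch blocks.
#' @param raw_filters Three filter counts for the raw-branch blocks.
#' @param wd L2 weight-decay coefficient applied to every conv/dense kernel.
#' @param head_drop Fusion-head dropout rate (fixed design constant).
#' @return A list of class `hybrid_config`.
#' @export
hybrid_config <- function(emb_raw = 192, head_units = 384, lr_init = 5e-4,
                          map_drop = 0.35, map_filters = c(48, 96),
                          raw_drop = c(0.3, 0.4, 0.5),
                          raw_filters = c(96, 192, 256), wd = 1e-4,
                          head_drop = 0.5) {
  stopifnot(length(map_filters) == 2L, length(raw_drop) == 3L,
            length(raw_filters) == 3L,
            all(c(map_drop, raw_drop, head_drop) >= 0),
            all(c(map_drop, raw_drop, head_drop) < 1))
  structure(list(emb_raw = emb_raw, head_units = head_units,
                 lr_init = lr_init, map_drop = map_drop,
                 map_filters = map_filters, raw_drop = raw_drop,
                 raw_filters = raw_filters, wd = wd, head_drop = head_drop),
            class = "hybrid_config")
}

new_eeg_model <- function(kind, branches, config, L, lr_init) {
  m <- structure(list(kind = kind, branches = branches, config = config,
                      L = as.integer(L), lr_init = lr_init,
                      trained = FALSE, history = NULL),
                 class = "eeg_model")
  m$n_params <- sum(vapply(m$branches, nn_count_params, 0))
  m
}

#' Build the hybrid Conv1D/feature-fusion model
#'
#' Three parallel branches. Raw branch on the L x 3 z-scored window: three
#' Conv1D blocks (kernels 11/7/5, `raw_filters`, same padding, ReLU, L2),
#' each followed by max-pool 4, batch normalization and dropout — for
#' L = 3840 the temporal chain is 3840 -> 960 -> 240 -> 60 — then flatten,
#' a `emb_raw`-unit dense embedding and 0.5 dropout. Map branch on the 3 x 8
#' per-channel map, consumed as a length-8 sequence with 3 channels:
#' Conv1D(3, `map_filters[1]`) -> max-pool 2 -> Conv1D(3, `map_filters[2]`)
#' -> batch norm -> dropout -> global average pooling -> 128-unit dense ->
#' dropout. Global branch on the 17-dim vector: dense 64 -> dense 32. The
#' embeddings are concatenated (`emb_raw` + 128 + 32 wide), batch-normalized
#' and passed through a `head_units` dense layer, dropout, and a 2-class
#' softmax output. Every conv/dense kernel carries the configured L2.
#'
#' @param config A [hybrid_config()].
#' @param L Window length in samples; must be divisible by 64 so the three
#'   pool-4 stages leave an integral length.
#' @param seed Optional seed for weight initialization.
#' @return An `eeg_model` of kind `"hybrid"`.
#' @export
build_hybrid <- function(config = hybrid_config(), L = 3840, seed = NULL) {
  if (L %% 64 != 0) {
    stop("L must be divisible by 64 (three max-pool stages of size 4 reduce ",
         "L -> L/4 -> L/16 -> L/64); got L = ", L, call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  cf <- config
  raw <- list(
    nn_conv1d(11, cf$raw_filters[1], 3, cf$wd), nn_maxpool(4),
    nn_batchnorm(cf$raw_filters[1]), nn_dropout(cf$raw_drop[1]),
    nn_conv1d(7, cf$raw_filters[2], cf$raw_filters[1], cf$wd), nn_maxpool(4),
    nn_batchnorm(cf$raw_filters[2]), nn_dropout(cf$raw_drop[2]),
    nn_conv1d(5, cf$raw_filters[3], cf$raw_filters[2], cf$wd), nn_maxpool(4),
    nn_batchnorm(cf$raw_filters[3]), nn_dropout(cf$raw_drop[3]),
    nn_flatten(),
    nn_dense(cf$emb_raw, (L %/% 64) * cf$raw_filters[3], cf$wd),
    nn_dropout(0.5))
  map <- list(
    nn_conv1d(3, cf$map_filters[1], 3, cf$wd), nn_maxpool(2),
    nn_conv1d(3, cf$map_filters[2], cf$map_filters[1], cf$wd),
    nn_batchnorm(cf$map_filters[2]), nn_dropout(cf$map_drop),
    nn_gap(),
    nn_dense(128, cf$map_filters[2], cf$wd), nn_dropout(cf$map_drop))
  glob <- list(
    nn_dense(64, 17, cf$wd), nn_dense(32, 64, cf$wd))
  head <- list(
    nn_batchnorm(cf$emb_raw + 128 + 32),
    nn_dense(cf$head_units, cf$emb_raw + 128 + 32, cf$wd),
    nn_dropout(cf$head_drop),
    nn_dense(2, cf$head_units, cf$wd, act = "linear"))
  branches <- lapply(list(raw = raw, map = map, glob = glob, head = head),
                     nn_init_seq)
  new_eeg_model("hybrid", branches, cf, L, cf$lr_init)
}

#' Build the plain Conv1D baseline on raw windows
#'
#' Three Conv1D blocks (64, 128, 256 filters; kernels 11, 7, 5; same
#' padding; ReLU; L2 5e-5), each followed by max-pool 4, batch
#' normalization and dropout (0.25, 0.35, 0.45), then flatten, a 256-unit
#' dense layer, 0.5 dropout and a 2-class softmax. The reference operating
#' point is L = 2560 samples (10.24 s at 250 Hz); Adam starts at 8e-4.
#'
#' @param L Window length in samples (>= 64).
#' @param wd L2 coefficient (default 5e-5).
#' @param lr_init Initial learning rate (default 8e-4).
#' @param seed Optional seed for weight initialization.
#' @return An `eeg_model` of kind `"conv1d_raw"`.
#' @export
build_conv1d_raw <- function(L = 2560, wd = 5e-5, lr_init = 8e-4, seed = NULL) {
  if (L < 64) stop("L must be at least 64 samples", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  L3 <- L %/% 4 %/% 4 %/% 4
  main <- nn_init_seq(list(
    nn_conv1d(11, 64, 3, wd), nn_maxpool(4), nn_batchnorm(64), nn_dropout(0.25),
    nn_conv1d(7, 128, 64, wd), nn_maxpool(4), nn_batchnorm(128), nn_dropout(0.35),
    nn_conv1d(5, 256, 128, wd), nn_maxpool(4), nn_batchnorm(256), nn_dropout(0.45),
    nn_flatten(),
    nn_dense(256, L3 * 256, wd), nn_dropout(0.5),
    nn_dense(2, 256, wd, act = "linear")))
  new_eeg_model("conv1d_raw", list(main = main), list(wd = wd), L, lr_init)
}

#' Build the squeeze-and-excitation Conv1D baseline
#'
#' Same backbone as [build_conv1d_raw()] with an SE module after each
#' convolution: global average pooling over time, a bottleneck MLP with
#' reduction ratio 8 and sigmoid output, and channel-wise multiplicative
#' rescaling of the feature maps. Reference operating point L = 6000
#' samples (24 s at 250 Hz); Adam starts at 1e-3. Non-divisible pooled
#' lengths are floored (6000 -> 1500 -> 375 -> 93).
#'
#' @inheritParams build_conv1d_raw
#' @return An `eeg_model` of kind `"conv1d_se"`.
#' @export
build_conv1d_se <- function(L = 6000, wd = 5e-5, lr_init = 1e-3, seed = NULL) {
  if (L < 64) stop("L must be at least 64 samples", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  L3 <- L %/% 4 %/% 4 %/% 4
  main <- nn_init_seq(list(
    nn_conv1d(11, 64, 3, wd), nn_se(64), nn_maxpool(4), nn_batchnorm(64),
    nn_dropout(0.25),
    nn_conv1d(7, 128, 64, wd), nn_se(128), nn_maxpool(4), nn_batchnorm(128),
    nn_dropout(0.35),
    nn_conv1d(5, 256, 128, wd), nn_se(256), nn_maxpool(4), nn_batchnorm(256),
    nn_dropout(0.45),
    nn_flatten(),
    nn_dense(256, L3 * 256, wd), nn_dropout(0.5),
    nn_dense(2, 256, wd, act = "linear")))
  new_eeg_model("conv1d_se", list(main = main), list(wd = wd), L, lr_init)
}

# forward pass for any model kind. X: list(raw = [B,L,3], map = [B,3,8],
# glob = [B,17]); conv-only models use raw alone. Returns logits, caches and
# the (batchnorm-updated) model.
model_forward <- function(model, X, training = FALSE) {
  if (model$kind == "hybrid") {
    r <- nn_forward_seq(model$branches$raw, X$raw, training)
    mp_in <- aperm(X$map, c(1, 3, 2))       # [B, 8 features, 3 channels]
    m <- nn_forward_seq(model$branches$map, mp_in, training)
    g <- nn_forward_seq(model$branches$glob, X$glob, training)
    emb <- cbind(r$out, m$out, g$out)
    h <- nn_forward_seq(model$branches$head, emb, training)
    model$branches$raw <- r$layers; model$branches$map <- m$layers
    model$branches$glob <- g$layers; model$branches$head <- h$layers
    list(logits = h$out, model = model,
         caches = list(raw = r$caches, map = m$caches, glob = g$caches,
                       head = h$caches,
                       widths = c(ncol(r$out), ncol(m$out), ncol(g$out))))
  } else {
    f <- nn_forward_seq(model$branches$main, X$raw, training)
    model$branches$main <- f$layers
    list(logits = f$out, model = model, caches = list(main = f$caches))
  }
}

model_backward <- function(model, caches, dlogits) {
  if (model$kind == "hybrid") {
    bh <- nn_backward_seq(model$branches$head, caches$head, dlogits)
    w <- caches$widths
    demb <- bh$dx
    d_raw <- demb[, seq_len(w[1]), drop = FALSE]
    d_map <- demb[, w[1] + seq_len(w[2]), drop = FALSE]
    d_glob <- demb[, w[1] + w[2] + seq_len(w[3]), drop = FALSE]
    br <- nn_backward_seq(model$branches$raw, caches$raw, d_raw)
    bm <- nn_backward_seq(model$branches$map, caches$map, d_map)
    bg <- nn_backward_seq(model$branches$glob, caches$glob, d_glob)
    list(raw = br$grads, map = bm$grads, glob = bg$grads, head = bh$grads)
  } else {
    list(main = nn_backward_seq(model$branches$main, caches$main, dlogits)$grads)
  }
}

model_l2 <- function(model) sum(vapply(model$branches, nn_l2_penalty, 0))

#' Predict window-level class probabilities
#'
#' Runs the network in inference mode (no dropout, batch-norm running
#' statistics, no augmentation) and returns one row per window with the
#' softmax probabilities for both classes.
#'
#' @param model A trained `eeg_model`.
#' @param features An `eeg_features` object from [compute_features()].
#' @param batch_size Inference batch size.
#' @return Tibble: window provenance plus `p_HC`, `p_MDD`, `pred_label`.
#' @export
predict_windows <- function(model, features, batch_size = 64L) {
  stopifnot(inherits(model, "eeg_model"), inherits(features, "eeg_features"))
  if (dim(features$raw)[2] != model$L) {
    stop("window length mismatch: model expects L = ", model$L,
         " samples, features have L = ", dim(features$raw)[2],
         " (training and inference must use the same segmentation)",
         call. = FALSE)
  }
  n <- dim(features$raw)[1]
  probs <- matrix(0, n, 2)
  for (at in seq(1L, n, by = batch_size)) {
    ix <- at:min(at + batch_size - 1L, n)
    X <- list(raw = features$raw[ix, , , drop = FALSE],
              map = features$map[ix, , , drop = FALSE],
              glob = features$glob[ix, , drop = FALSE])
    fw <- model_forward(model, X, training = FALSE)
    probs[ix, ] <- nn_softmax(fw$logits)
  }
  dplyr::bind_cols(features$info,
                   tibble::tibble(p_HC = probs[, 1], p_MDD = probs[, 2],
                                  pred_label = EEG_CLASSES[max.col(probs,
                                                                   ties.method = "first")]))
}

#' @export
print.eeg_model <- function(x, ...) {
  cat(sprintf("<eeg_model:%s> L=%d, %s parameters, %s\n", x$kind, x$L,
              format(x$n_params, big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' @describeIn build_hybrid Layer-by-layer summary of a built model: one row
#'   per layer with branch, type, main shape parameters and trainable
#'   parameter count.
#' @param x An `eeg_model`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.eeg_model <- function(x, ...) {
  rows <- list()
  for (bn in names(x$branches)) {
    for (ly in x$branches[[bn]]) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        branch = bn, type = ly$type,
        detail = switch(ly$type,
          conv1d = sprintf("k=%d, filters=%d", ly$k, ly$f),
          dense = sprintf("units=%d, act=%s", ly$f, ly$act),
          maxpool = sprintf("pool=%d", ly$m),
          batchnorm = sprintf("channels=%d", ly$c),
          dropout = sprintf("rate=%g", ly$rate),
          se = sprintf("channels=%d, bottleneck=%d", ly$c, ly$cr),
          ""),
        n_params = sum(vapply(ly$param_names, function(pn) length(ly[[pn]]), 0)))
    }
  }
  dplyr::bind_rows(rows)
}

#' @describeIn build_hybrid One-row model summary (kind, window length,
#'   parameter count, training status and best validation accuracy).
#' @export
#' @exportS3Method generics::glance
glance.eeg_model <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, L = x$L, n_params = x$n_params, trained = x$trained,
    best_val_accuracy = if (!is.null(x$history) && nrow(x$history))
      max(x$history$val_accuracy, na.rm = TRUE) else NA_real_)
}

#' Export a model summary as JSON
#'
#' @param model An `eeg_model`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @export
model_summary_json <- function(model, path = NULL) {
  js <- jsonlite::toJSON(list(kind = model$kind, L = model$L,
                              n_params = model$n_params,
                              layers = as.data.frame(tidy(model))),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Save or load a trained model
#'
#' Models are serialized with R's native RDS format, the package's
#' checkpoint format.
#'
#' @param model An `eeg_model`.
#' @param path File path (conventionally `.rds`).
#' @return `load_model()` returns the `eeg_model`; `save_model()` returns
#'   `path` invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "eeg_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "eeg_model")) stop("not an eeg_model checkpoint: ", path, call. = FALSE)
  m
}
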