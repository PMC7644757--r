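#' Training control parameters
#'
#' @param epochs Training epochs (default 40).
#' @param learning_rate RMSprop learning rate (default 2e-3).
#' @param batch_size Windows per gradient step (default 8); the gradient is
#'   the mean per-nucleotide loss gradient over the batch.
#' @param l1_first,l1_rest L1 regularisation strengths for the first layer's
#'   weights and for all remaining weights (default 0: unregularised).
#' @param early_stopping Stop when validation F1 has not improved for
#'   `patience` epochs (requires validation windows, i.e. a `"test"` split).
#' @param patience Early-stopping patience in epochs.
#' @param verbose Print per-epoch loss.
#' @return A list of class `zdna_control`.
#' @export
zdna_control <- function(epochs = 40, learning_rate = 2e-3, batch_size = 8,
                         l1_first = 0, l1_rest = 0,
                         early_stopping = FALSE, patience = 5,
                         verbose = FALSE) {
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 batch_size = batch_size, l1_first = l1_first,
                 l1_rest = l1_rest, early_stopping = early_stopping,
                 patience = patience, verbose = verbose),
            class = "zdna_control")
}

window_xy <- function(store, labels, ws, channels) {
  lab_track <- lapply(labels, function(l) {
    if (inherits(l, "sparse_track")) l else as_sparse_track(l)
  })
  X <- vector("list", nrow(ws))
  y <- vector("list", nrow(ws))
  for (i in seq_len(nrow(ws))) {
    Xi <- window_matrix(store, ws$chrom[i], ws$start[i], ws$end[i])
    X[[i]] <- Xi[, channels, drop = FALSE]
    y[[i]] <- track_slice(lab_track[[ws$chrom[i]]], ws$start[i], ws$end[i])
  }
  list(X = X, y = y)
}

#' Fit a per-nucleotide Z-DNA segmentation model
#'
#' Trains the architecture described by `spec` on the `"train"` windows of
#' `windows` (all windows if no split is assigned), minimising per-nucleotide
#' two-class cross-entropy with RMSprop. Every nucleotide of every training
#' window is a labelled example; the model emits a Z-DNA probability for
#' each position of its input.
#'
#' @param spec A [model_spec()].
#' @param windows A [tile_and_select()] window set (optionally with a split
#'   from [stratified_split()]; `"test"` windows serve as the validation set
#'   when early stopping is on).
#' @param store A [build_feature_store()].
#' @param labels Named per-chromosome list of binary label vectors or
#'   [sparse_track()]s (see [encode_labels()]).
#' @param channels Channel names to train on (default: all store channels).
#' @param control A [zdna_control()].
#' @param seed Integer seed; fixes initialisation, shuffling and dropout, so
#'   identical calls give identical fits.
#' @return An object of class `zdna_model`.
#' @export
zdna_fit <- function(spec, windows, store, labels,
                     channels = store$channel_names,
                     control = zdna_control(), seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  missing_ch <- setdiff(channels, store$channel_names)
  if (length(missing_ch)) stop("channels not in store: ", paste(missing_ch, collapse = ", "))
  train_ws <- if (all(is.na(windows$split))) windows else windows[windows$split == "train", , drop = FALSE]
  if (nrow(train_ws) == 0) stop("empty training split")
  val_ws <- if (all(is.na(windows$split))) windows[0, ] else windows[windows$split == "test", , drop = FALSE]

  dat <- window_xy(store, labels, train_ws, channels)
  val <- if (nrow(val_ws)) window_xy(store, labels, val_ws, channels) else NULL

  set.seed(seed)
  layers <- init_layers(spec, length(channels))
  cache <- rmsprop_init(layers)
  n <- length(dat$X)
  log_rows <- list()
  best_f1 <- -Inf; best_layers <- layers; stall <- 0L

  for (epoch in seq_len(control$epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0; nb <- 0
    for (bstart in seq(1, n, by = control$batch_size)) {
      idx <- ord[bstart:min(bstart + control$batch_size - 1, n)]
      grads <- zero_grads(layers)
      bloss <- 0
      for (w in idx) {
        fwd <- nn_forward(layers, dat$X[[w]], train = TRUE)
        cl <- ce_loss(fwd$logits, dat$y[[w]])
        bloss <- bloss + cl$loss
        grads <- add_grads(grads, nn_backward(layers, fwd, cl$dLogits)$grads)
      }
      grads <- scale_grads(grads, 1 / length(idx))
      if (!is.finite(bloss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      st <- rmsprop_step(layers, grads, cache, control$learning_rate,
                         l1_first = control$l1_first, l1_rest = control$l1_rest)
      layers <- st$layers; cache <- st$cache
      epoch_loss <- epoch_loss + bloss / length(idx); nb <- nb + 1
    }
    epoch_loss <- epoch_loss / nb +
      l1_penalty_value(layers, control$l1_first, control$l1_rest)
    val_f1 <- NA_real_
    if (!is.null(val)) {
      p <- unlist(lapply(val$X, function(x) nn_probs(layers, x)))
      yv <- unlist(val$y)
      val_f1 <- f1_score(p > 0.5, yv)
    }
    log_rows[[epoch]] <- data.frame(epoch = epoch, loss = epoch_loss, val_f1 = val_f1)
    if (control$verbose)
      message(sprintf("epoch %d: loss %.5f%s", epoch, epoch_loss,
                      if (!is.na(val_f1)) sprintf(", val F1 %.3f", val_f1) else ""))
    if (control$early_stopping && !is.null(val)) {
      if (isTRUE(val_f1 > best_f1)) {
        best_f1 <- val_f1; best_layers <- layers; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= control$patience) break
      }
    }
  }
  if (control$early_stopping && !is.null(val) && best_f1 > -Inf) layers <- best_layers

  structure(list(
    spec = spec,
    layers = layers,
    channel_names = channels,
    channel_classes = store$classes[channels],
    training_log = do.call(rbind, log_rows),
    control = control,
    seed = seed,
    n_train_windows = n
  ), class = "zdna_model")
}

#' @export
print.zdna_model <- function(x, ...) {
  cat("Per-nucleotide Z-DNA segmentation model\n")
  print(x$spec)
  cat(sprintf("  %d input channels, trained on %d windows (%d epochs, final loss %.4f)\n",
              length(x$channel_names), x$n_train_windows,
              nrow(x$training_log), utils::tail(x$training_log$loss, 1)))
  invisible(x)
}

#' @export
summary.zdna_model <- function(object, ...) {
  npar <- sum(vapply(object$layers, function(l) sum(lengths(lapply(l$par, length))),
                     numeric(1)))
  cat("Per-nucleotide Z-DNA segmentation model\n\nArchitecture:\n")
  print(object$spec)
  cat(sprintf("\nParameters: %d\nInput channels (%d): %s%s\n",
              npar, length(object$channel_names),
              paste(utils::head(object$channel_names, 8), collapse = ", "),
              if (length(object$channel_names) > 8) ", ..." else ""))
  cat("\nTraining log (last 5 epochs):\n")
  print(utils::tail(object$training_log, 5), row.names = FALSE)
  if (spec_is_cnn_only(object$spec))
    cat(sprintf("\nReceptive field: %d nt\n", receptive_field(object$spec)))
  invisible(object)
}

#' Extract first-layer channel weights from a fitted model
#'
#' For each input channel, the first-layer weight of maximal absolute value
#' (sign preserved) — the quantity feature-importance ranking is built on.
#'
#' @param object A [zdna_fit()] model.
#' @param ... Unused.
#' @return Named numeric vector, one entry per input channel.
#' @export
coef.zdna_model <- function(object, ...) {
  first <- object$layers[[1]]
  C <- length(object$channel_names)
  w <- numeric(C)
  if (first$type == "conv") {
    for (ci in seq_len(C)) {
      rows <- seq(ci, first$k * C, by = C)
      v <- first$par$W[rows, , drop = FALSE]
      w[ci] <- v[which.max(abs(v))]
    }
  } else {
    M <- if (first$type == "dense") first$par$W else first$par$Wx_f
    for (ci in seq_len(C)) {
      v <- M[ci, ]
      w[ci] <- v[which.max(abs(v))]
    }
  }
  stats::setNames(w, object$channel_names)
}

#' @export
plot.zdna_model <- function(x, ...) {
  graphics::plot(x$training_log$epoch, x$training_log$loss, type = "b",
                 xlab = "epoch", ylab = "training loss",
                 main = "Training loss", ...)
  invisible(x)
}

#' Per-nucleotide probabilities over a genomic range
#'
#' Evaluates the model over `[start, end)` of one chromosome. Convolutional
#' models are evaluated in chunks with an overlap of at least the receptive
#' field half-width, so chunked prediction is bit-identical to a single
#' pass; models with a recurrent block are evaluated in a single pass
#' (their context is unbounded).
#'
#' @param object A [zdna_fit()] model.
#' @param store A [build_feature_store()] whose channels include the model's.
#' @param chrom Chromosome name (default: first in the store).
#' @param start,end 0-based half-open range (default: whole chromosome).
#' @param chunk_size Chunk length for convolutional models.
#' @param ... Unused.
#' @return Numeric vector of Z-DNA probabilities in `[0, 1]`, length `end - start`.
#' @export
predict.zdna_model <- function(object, store, chrom = NULL, start = NULL,
                               end = NULL, chunk_size = 100000L, ...) {
  if (is.null(chrom)) chrom <- names(store$chroms)[1]
  fm <- store$chroms[[chrom]]
  if (is.null(fm)) stop("unknown chromosome: ", chrom)
  if (is.null(start)) start <- 0
  if (is.null(end)) end <- fm$length
  missing_ch <- setdiff(object$channel_names, store$channel_names)
  if (length(missing_ch))
    stop("store lacks model channels: ", paste(missing_ch, collapse = ", "))
  n <- end - start
  if (n == 0) return(numeric(0))
  cnn <- !spec_has_recurrent(object$spec)
  halo <- if (cnn) (receptive_field_any(object$spec) - 1) / 2 else 0
  if (!cnn || n <= chunk_size) {
    X <- window_matrix(store, chrom, start, end)[, object$channel_names, drop = FALSE]
    return(nn_probs(object$layers, X))
  }
  out <- numeric(n)
  for (cs in seq(start, end - 1, by = chunk_size)) {
    ce <- min(cs + chunk_size, end)
    xs <- max(start, cs - halo)
    xe <- min(end, ce + halo)
    X <- window_matrix(store, chrom, xs, xe)[, object$channel_names, drop = FALSE]
    p <- nn_probs(object$layers, X)
    out[(cs - start + 1):(ce - start)] <- p[(cs - xs + 1):(ce - xs)]
  }
  out
}

# receptive field including dense-only models (always defined for non-RNN)
receptive_field_any <- function(spec) {
  if (spec_has_recurrent(spec)) stop("unbounded context")
  rf <- 1
  for (b in spec$blocks) if (b$type == "conv") rf <- rf + sum(b$kernel_size - 1)
  as.integer(rf)
}

#' Residuals of a fitted segmentation model
#'
#' Label minus fitted probability, per nucleotide, over the model's training
#' windows.
#'
#' @param object A [zdna_fit()] model.
#' @param store,labels,windows The training inputs (see [zdna_fit()]).
#' @param ... Unused.
#' @return Numeric vector of per-nucleotide residuals.
#' @export
residuals.zdna_model <- function(object, store, labels, windows, ...) {
  ws <- if (all(is.na(windows$split))) windows else windows[windows$split == "train", , drop = FALSE]
  dat <- window_xy(store, labels, ws, object$channel_names)
  p <- unlist(lapply(dat$X, function(x) nn_probs(object$layers, x)))
  unlist(dat$y) - p
}
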