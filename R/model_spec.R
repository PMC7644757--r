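#' Architecture building blocks for per-nucleotide segmentation models
#'
#' Models are assembled from up to three blocks applied in fixed order:
#' convolutional, recurrent, dense. Every model ends in exactly one dense
#' block whose final layer has two output units (not-Z / Z); the per-position
#' class-1 softmax probability is the reported score. Convolutions are 1-d,
#' stride 1, with `(kernel_size - 1) / 2` zero padding so the output keeps
#' the input length (the segmentation contract); a rectifier sits between
#' consecutive convolutional layers.
#'
#' @param n_layers Number of layers in the block (1 or 2 for conv/recurrent).
#' @param n_kernels Kernels per convolutional layer, 1..17 (recycled to
#'   `n_layers`).
#' @param kernel_size Odd kernel width, 1..17 (recycled to `n_layers`).
#' @param channel_pool If `TRUE`, a per-position max over kernels follows the
#'   last convolutional layer, collapsing the block output to one channel.
#' @return A block description list.
#' @name blocks
NULL

#' @rdname blocks
#' @export
conv_block <- function(n_layers = 1, n_kernels = 8, kernel_size = 5,
                       channel_pool = FALSE) {
  stopifnot(n_layers %in% c(1, 2))
  n_kernels <- rep_len(n_kernels, n_layers)
  kernel_size <- rep_len(kernel_size, n_layers)
  if (any(kernel_size < 1 | kernel_size > 17 | kernel_size %% 2 == 0))
    stop("kernel_size must be odd and in 1..17")
  if (any(n_kernels < 1 | n_kernels > 17)) stop("n_kernels must be in 1..17")
  list(type = "conv", n_layers = n_layers, n_kernels = n_kernels,
       kernel_size = kernel_size, channel_pool = isTRUE(channel_pool))
}

#' @rdname blocks
#' @param hidden_size LSTM hidden state size (recurrent) or width of
#'   intermediate dense layers.
#' @param bidirectional Run the LSTM in both directions and concatenate.
#' @export
recurrent_block <- function(n_layers = 1, hidden_size = 32, bidirectional = TRUE) {
  stopifnot(n_layers %in% c(1, 2), hidden_size >= 1)
  list(type = "recurrent", n_layers = n_layers,
       hidden_size = as.integer(hidden_size), bidirectional = isTRUE(bidirectional))
}

#' @rdname blocks
#' @param dropout Dropout probability applied to the input of every dense
#'   layer during training (default 0.5).
#' @export
dense_block <- function(n_layers = 1, hidden_size = 32, dropout = 0.5) {
  stopifnot(n_layers >= 1, dropout >= 0, dropout < 1)
  list(type = "dense", n_layers = n_layers,
       hidden_size = as.integer(hidden_size), dropout = dropout)
}

#' Assemble a model specification from blocks
#'
#' Valid orders: dense alone; conv then dense; recurrent then dense; conv
#' then recurrent then dense (the hybrid). Exactly one dense block, placed
#' last.
#'
#' @param ... Blocks from [conv_block()], [recurrent_block()], [dense_block()].
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(...) {
  blocks <- list(...)
  if (length(blocks) == 1 && is.list(blocks[[1]]) && is.null(blocks[[1]]$type))
    blocks <- blocks[[1]]
  types <- vapply(blocks, function(b) b$type, character(1))
  if (sum(types == "dense") != 1 || types[length(types)] != "dense")
    stop("a model spec needs exactly one dense block, placed last")
  body <- types[-length(types)]
  if (!identical(body, intersect(c("conv", "recurrent"), body)))
    stop("block order must be conv, then recurrent, then dense")
  structure(list(blocks = blocks), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  for (b in x$blocks) {
    desc <- switch(b$type,
      conv = sprintf("conv: %d layer(s), kernels [%s], kernel size [%s]%s",
                     b$n_layers, paste(b$n_kernels, collapse = ","),
                     paste(b$kernel_size, collapse = ","),
                     if (b$channel_pool) ", channel max-pool" else ""),
      recurrent = sprintf("recurrent: %d %sLSTM layer(s), hidden %d",
                          b$n_layers, if (b$bidirectional) "bidirectional " else "",
                          b$hidden_size),
      dense = sprintf("dense: %d layer(s), hidden %d, dropout %.2f, 2 output units",
                      b$n_layers, b$hidden_size, b$dropout))
    cat(" ", desc, "\n")
  }
  invisible(x)
}

spec_has_recurrent <- function(spec) {
  any(vapply(spec$blocks, function(b) b$type, character(1)) == "recurrent")
}

spec_is_cnn_only <- function(spec) {
  types <- vapply(spec$blocks, function(b) b$type, character(1))
  !("recurrent" %in% types) && ("conv" %in% types)
}

#' Receptive field of a convolutional segmentation model
#'
#' The contiguous input span that can influence one output position of a
#' stride-1 stack: `1 + sum(kernel_size - 1)` over all convolutional layers
#' (dense layers are per-position and add nothing). Two kernel-5 layers give
#' 9 nucleotides: the farthest second-layer tap sits 2 positions away and
#' the farthest first-layer tap another 2 beyond it, so no input farther
#' than 4 nucleotides from the centre can reach the output. Models with a
#' recurrent block have unbounded context and are rejected.
#'
#' @param spec A CNN-only [model_spec()].
#' @return Receptive field width in nucleotides (odd integer).
#' @export
receptive_field <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec_has_recurrent(spec))
    stop("receptive field is unbounded for models with a recurrent block")
  rf <- 1
  for (b in spec$blocks) {
    if (b$type == "conv") rf <- rf + sum(b$kernel_size - 1)
  }
  as.integer(rf)
}

#' Enumerate a hyperparameter grid of model specifications
#'
#' Takes candidate values per block hyperparameter and returns the
#' deduplicated Cartesian product in deterministic order. Omitting `conv`
#' (or `recurrent`) omits that block from every spec; passing `NA` inside
#' `n_layers` additionally allows specs without the block.
#'
#' @param conv Named list of candidates for [conv_block()] arguments, or `NULL`.
#' @param recurrent Named list of candidates for [recurrent_block()] arguments,
#'   or `NULL`.
#' @param dense Named list of candidates for [dense_block()] arguments.
#' @return List of [model_spec()] objects.
#' @export
enumerate_grid <- function(conv = NULL, recurrent = NULL,
                           dense = list(n_layers = 1)) {
  if (is.null(conv) && is.null(recurrent) && is.null(dense))
    stop("empty grid")
  fill <- function(cand, fun) {
    if (is.null(cand)) return(list(NULL))
    grid <- expand.grid(cand, stringsAsFactors = FALSE)
    if (nrow(grid) == 0) stop("empty grid")
    lapply(seq_len(nrow(grid)), function(i) {
      args <- as.list(grid[i, , drop = FALSE])
      names(args) <- names(grid)
      if (!is.null(args$n_layers) && is.na(args$n_layers)) return(NA)
      do.call(fun, args)
    })
  }
  convs <- fill(conv, conv_block)
  recs <- fill(recurrent, recurrent_block)
  denses <- fill(dense, dense_block)
  specs <- list()
  for (cb in convs) for (rb in recs) for (db in denses) {
    if (is.null(db) || identical(db, NA)) next
    blocks <- Filter(function(b) is.list(b), list(cb, rb, db))
    specs[[length(specs) + 1]] <- model_spec(blocks)
  }
  keys <- vapply(specs, function(s) paste(deparse(s$blocks), collapse = ""), character(1))
  specs[!duplicated(keys)]
}
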