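#' Feature importance by L1-pruned first-layer weights
#'
#' Trains the given convolutional architecture with L1 regularisation in
#' the loss (proximal soft-thresholding, so unnecessary weights reach exact
#' zero). Each input feature is then scored by its first-convolutional-layer
#' weight of maximal absolute value; features whose first-layer weights are
#' all exactly zero are dropped as pruned. Scores are normalised per sign
#' group — positive weights by the largest positive weight, negative
#' weights by the magnitude of the most negative weight — so the top
#' feature of each sign scores +1 / -1. Recurrent architectures are not
#' amenable to this analysis and are rejected; use a convolutional spec.
#'
#' @param spec A CNN-only [model_spec()].
#' @param windows,store,labels,channels,seed As in [zdna_fit()].
#' @param l1 Length-2 numeric: L1 strength on the first convolutional
#'   layer's weights and on all remaining weights (default `c(1e-3, 1e-2)`).
#' @param control A [zdna_control()]; its `l1_first`/`l1_rest` are
#'   overridden by `l1`.
#' @return An `importance_report` `data.frame` with columns `channel`,
#'   `class`, `raw_weight`, `score` (in `[-1, 1]`), `rank` (within sign
#'   group, 1 = strongest); attribute `model` holds the fitted model.
#' @export
l1_importance <- function(spec, windows, store, labels,
                          channels = store$channel_names,
                          l1 = c(1e-3, 1e-2),
                          control = zdna_control(), seed = 1) {
  if (!spec_is_cnn_only(spec))
    stop("feature importance requires a CNN-only model spec")
  control$l1_first <- l1[1]
  control$l1_rest <- l1[2]
  fit <- zdna_fit(spec, windows, store, labels, channels = channels,
                  control = control, seed = seed)
  out <- importance_from_weights(coef(fit), fit$channel_classes)
  attr(out, "model") <- fit
  out
}

# Per-sign-group normalisation of raw first-layer weights: positive weights
# divided by the largest positive, negatives by the magnitude of the most
# negative; exactly-zero (pruned) features dropped.
importance_from_weights <- function(w, classes) {
  keep <- w != 0
  w <- w[keep]
  cls <- classes[names(w)]
  score <- numeric(length(w))
  pos <- w > 0; neg <- w < 0
  if (any(pos)) score[pos] <- w[pos] / max(w[pos])
  if (any(neg)) score[neg] <- -abs(w[neg]) / max(abs(w[neg]))
  rank_in_sign <- integer(length(w))
  rank_in_sign[pos] <- rank(-w[pos], ties.method = "first")
  rank_in_sign[neg] <- rank(-abs(w[neg]), ties.method = "first")
  out <- data.frame(channel = names(w), class = unname(cls),
                    raw_weight = unname(w), score = score,
                    rank = rank_in_sign, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$score)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("importance_report", "data.frame")
  out
}

#' Write an importance report as TSV
#'
#' @param report An [l1_importance()] report.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_importance_tsv <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

objective_and_grad <- function(layers, X) {
  fwd <- nn_forward(layers, X, train = FALSE)
  P <- softmax_rows(fwd$logits)
  centre <- (nrow(X) + 1) / 2
  p1 <- P[centre, 2]
  dLogits <- matrix(0, nrow(X), 2)
  dLogits[centre, ] <- c(-P[centre, 1] * p1, p1 * (1 - p1))
  list(value = p1, grad = nn_backward(layers, fwd, dLogits)$dInput)
}

#' Input patch maximising the central Z-DNA probability
#'
#' Saliency-style input optimisation for a frozen convolutional model: a
#' trainable input patch of width equal to the receptive field is ascended
#' with RMSprop on the predicted Z-DNA probability of the central
#' nucleotide, clipping every value to `value_range` after each iteration.
#' The extended range (-1 to 1 rather than the data's 0 to 1) lets both
#' positively and negatively influencing features show up.
#'
#' @param model A frozen CNN-only [zdna_fit()] model.
#' @param learning_rate RMSprop learning rate for the input (default 1e-2).
#' @param iterations Maximum ascent iterations.
#' @param value_range Clip interval for input values (default `c(-1, 1)`).
#' @param init Optional starting patch (`W x C` matrix); default zeros.
#' @param tol Convergence tolerance on the objective.
#' @return A `W x C` matrix (rows = offsets `-(W-1)/2 .. (W-1)/2`, columns =
#'   model channels) with attributes `objective` (achieved central
#'   probability) and `converged`. The best-so-far patch is returned even
#'   without convergence.
#' @export
maximize_input <- function(model, learning_rate = 1e-2, iterations = 300,
                           value_range = c(-1, 1), init = NULL, tol = 1e-7) {
  if (spec_has_recurrent(model$spec))
    stop("input maximisation requires a CNN-only model")
  W <- receptive_field_any(model$spec)
  C <- length(model$channel_names)
  X <- if (is.null(init)) matrix(0, W, C) else {
    stopifnot(nrow(init) == W, ncol(init) == C)
    pmin(pmax(init, value_range[1]), value_range[2])
  }
  cache <- matrix(0, W, C)
  best <- -Inf; best_X <- X; last_gain_at <- 0L
  for (it in seq_len(iterations)) {
    og <- objective_and_grad(model$layers, X)
    if (og$value > best + tol) { best <- og$value; best_X <- X; last_gain_at <- it }
    else if (og$value > best) { best <- og$value; best_X <- X }
    cache <- 0.9 * cache + 0.1 * og$grad^2
    X <- X + learning_rate * og$grad / (sqrt(cache) + 1e-8)
    X <- pmin(pmax(X, value_range[1]), value_range[2])
  }
  final <- objective_and_grad(model$layers, X)$value
  if (final >= best) { best_X <- X; best <- final }
  converged <- (iterations - last_gain_at) >= 10  # objective plateaued
  dimnames(best_X) <- list(seq_len(W) - 1 - (W - 1) / 2, model$channel_names)
  structure(best_X, objective = best, converged = converged)
}

# Euclidean projection of a vector onto the probability simplex
# (Duchi et al. 2008): exact, yields exact zeros.
simplex_project <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  tau <- (css[rho] - 1) / rho
  pmax(v - tau, 0)
}

#' Extract the sequence motif a frozen CNN has learned
#'
#' One-hot sequence channels cannot be maximised independently — the four
#' values at a position are a probability assignment over bases. The motif
#' is therefore found by constrained maximisation of the central Z-DNA
#' probability over the sequence channels only, with each position's four
#' values restricted to the probability simplex (non-negative, summing
#' to 1) and all non-sequence channels held fixed. The solver is projected
#' gradient ascent with steps normalised by the largest gradient entry (so
#' relative gradient magnitudes are preserved, which a per-coordinate
#' adaptive step would destroy) and exact Euclidean simplex projection
#' after every step; an infeasible start is corrected by projection. On
#' linear models this reaches the per-column argmax vertex exactly; for
#' saturated objectives the common sigmoid factor cancels in the
#' normalisation, so progress never stalls. The result is a 4 x W
#' weight matrix over the receptive field, interpretable as a per-position
#' Z-DNA-favouring base distribution.
#'
#' @param model A frozen CNN-only [zdna_fit()] model whose channels include
#'   the four `seq_*` channels.
#' @param fixed_input Patch supplying the non-sequence channel values
#'   (`W x C`, typically from [maximize_input()]); `"zero"` fixes them at 0;
#'   default runs [maximize_input()] internally.
#' @param learning_rate,iterations Ascent parameters.
#' @return A `motif_matrix`: 4 x W matrix (rows A, C, G, T; columns offsets
#'   `-(W-1)/2 .. (W-1)/2`), every column on the simplex; attribute
#'   `objective` holds the achieved central probability.
#' @export
extract_motif <- function(model, fixed_input = NULL, learning_rate = 1e-2,
                          iterations = 300) {
  if (spec_has_recurrent(model$spec))
    stop("motif extraction requires a CNN-only model")
  seq_idx <- which(model$channel_classes == "seq")
  if (length(seq_idx) != 4)
    stop("model must carry the four one-hot sequence channels")
  W <- receptive_field_any(model$spec)
  C <- length(model$channel_names)
  X <- if (is.null(fixed_input)) maximize_input(model) else if (identical(fixed_input, "zero"))
    matrix(0, W, C) else fixed_input
  X <- matrix(as.numeric(X), W, C)
  # feasible start for the sequence part
  for (t in seq_len(W)) X[t, seq_idx] <- simplex_project(X[t, seq_idx])
  best <- -Inf; best_X <- X
  for (it in seq_len(iterations)) {
    og <- objective_and_grad(model$layers, X)
    if (og$value > best) { best <- og$value; best_X <- X }
    g <- og$grad[, seq_idx, drop = FALSE]
    gmax <- max(abs(g))
    if (gmax == 0) break
    X[, seq_idx] <- X[, seq_idx] + learning_rate * g / gmax
    for (t in seq_len(W)) X[t, seq_idx] <- simplex_project(X[t, seq_idx])
  }
  final <- objective_and_grad(model$layers, X)$value
  if (final >= best) { best <- final; best_X <- X }
  motif <- t(best_X[, seq_idx, drop = FALSE])
  rownames(motif) <- sub("^seq_", "", model$channel_names[seq_idx])
  colnames(motif) <- seq_len(W) - 1 - (W - 1) / 2
  structure(motif, objective = best, class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("<motif_matrix> width %d, central objective %.4f\n",
              ncol(x), attr(x, "objective")))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Write a motif in MEME minimal format
#'
#' @param motif A [extract_motif()] matrix (4 x W, columns on the simplex).
#' @param path Output path.
#' @param name Motif name in the file.
#' @return `path`, invisibly.
#' @export
write_meme_motif <- function(motif, path, name = "zdna_motif") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d", ncol(motif))),
             con)
  for (j in seq_len(ncol(motif))) {
    writeLines(paste(sprintf("%.6f", motif[, j]), collapse = " "), con)
  }
  invisible(path)
}
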