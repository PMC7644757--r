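# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Small two-chromosome fixture: 2 x 20 kb, 6 planted regions, 2 informative
# + 2 noise tracks. Used wherever a test needs a realistic but fast
# genome/store/labels triple.
tiny_fixture <- function() {
  if (!is.null(.fixture_env$tiny)) return(.fixture_env$tiny)
  sim <- synth_generate(synth_config(
    n_chromosomes = 2, chromosome_length = 20000, n_regions = 6,
    n_informative_tracks = 2, n_noise_tracks = 2, seed = 3
  ))
  store <- build_feature_store(sim$genome, sim$tracks)
  labels <- synth_labels(sim)
  ws <- tile_and_select(labels, window_length = 1000, background_ratio = 3, seed = 5)
  .fixture_env$tiny <- list(sim = sim, store = store, labels = labels, ws = ws)
  .fixture_env$tiny
}

# A quick CNN fit on the tiny fixture, shared across prediction tests.
tiny_cnn_fit <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit)
  fx <- tiny_fixture()
  spec <- model_spec(conv_block(1, 3, 5), dense_block(1))
  ws <- stratified_split(fx$ws, 0.8, seed = 5)
  .fixture_env$fit <- zdna_fit(spec, ws, fx$store, fx$labels,
                               control = zdna_control(epochs = 25, batch_size = 4),
                               seed = 2)
  .fixture_env$fit
}

# Hand-built linear model: one conv layer of a single kernel spanning the
# whole patch (no rectifier), then a 1 -> 2 linear read-out, so the central
# class-1 logit difference is exactly <w_patch, input patch>. Closed-form
# optima are known on the box and on the per-column simplex.
make_linear_model <- function(w_patch, channel_names,
                              classes = rep("marker", length(channel_names))) {
  W <- nrow(w_patch); C <- ncol(w_patch)
  stopifnot(C == length(channel_names), W %% 2 == 1)
  conv_W <- matrix(0, W * C, 1)
  for (j in seq_len(W)) conv_W[(j - 1) * C + seq_len(C), 1] <- w_patch[j, ]
  layers <- list(
    list(type = "conv", k = W, cin = C, cout = 1L, relu = FALSE,
         par = list(W = conv_W, b = 0)),
    list(type = "dense", cin = 1L, cout = 2L, relu = FALSE, dropout = 0,
         par = list(W = matrix(c(-0.5, 0.5), 1, 2), b = c(0, 0)))
  )
  structure(list(
    spec = model_spec(conv_block(1, 1, W), dense_block(1, dropout = 0)),
    layers = layers,
    channel_names = channel_names,
    channel_classes = stats::setNames(classes, channel_names),
    training_log = data.frame(epoch = 1, loss = NA_real_, val_f1 = NA_real_),
    control = zdna_control(), seed = 1, n_train_windows = 0
  ), class = "zdna_model")
}

# Dense-scan oracle for region assembly: threshold, join gaps < join_gap,
# drop lengths < min_length, by explicit O(L) interval walking.
assemble_oracle <- function(v, threshold, join_gap = 11, min_length = 11) {
  above <- which(v > threshold)
  if (!length(above)) return(data.frame(start = numeric(0), end = numeric(0)))
  runs <- list()
  s <- above[1]; prev <- above[1]
  for (p in above[-1]) {
    if (p == prev + 1) prev <- p
    else { runs[[length(runs) + 1]] <- c(s, prev); s <- p; prev <- p }
  }
  runs[[length(runs) + 1]] <- c(s, prev)
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    if (r[1] - last[2] - 1 < join_gap) merged[[length(merged)]] <- c(last[1], r[2])
    else merged[[length(merged) + 1]] <- r
  }
  m <- do.call(rbind, merged)
  df <- data.frame(start = m[, 1] - 1, end = m[, 2])  # to 0-based half-open
  df[df$end - df$start >= min_length, , drop = FALSE]
}

# Exhaustive-sweep oracle for threshold selection (candidates = observed
# values, predictions = prob >= candidate, ties to the smallest threshold).
threshold_oracle <- function(p, y) {
  cand <- sort(unique(p))
  f1s <- vapply(cand, function(t) {
    pred <- p >= t
    tp <- sum(pred & y == 1); fp <- sum(pred & y == 0); fn <- sum(!pred & y == 1)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  min(cand[f1s == max(f1s)])
}

# Brute-force pairwise-concordance AUC (midrank tie convention).
auc_bruteforce <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}
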