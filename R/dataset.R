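#' Tile chromosomes into fixed windows and select the training universe
#'
#' Every chromosome is evenly cut into non-overlapping windows of
#' `window_length` nucleotides (the trailing partial window is dropped), so
#' window boundaries never depend on where the labelled sites fall. The
#' selected set contains every window overlapping at least one labelled
#' nucleotide plus `background_ratio` times as many label-free windows
#' sampled uniformly without replacement genome-wide under the seed.
#'
#' @param labels Named list (one entry per chromosome) of per-nucleotide
#'   binary label vectors or binary [sparse_track()]s.
#' @param window_length Window size in nucleotides (default 5000).
#' @param background_ratio Background windows per labelled window (default 3).
#' @param seed Integer seed fixing the background sample.
#' @return An object of class `window_set`: a `data.frame` with columns
#'   `chrom`, `start`, `end`, `contains_z`, `split` (NA until
#'   [stratified_split()]), `fold` (NA until [make_folds()]); attributes
#'   `window_length` and `seed`.
#' @export
tile_and_select <- function(labels, window_length = 5000, background_ratio = 3,
                            seed = 1) {
  stopifnot(window_length >= 1, background_ratio >= 0)
  if (is.null(names(labels))) stop("labels must be a named per-chromosome list")
  tiles <- list()
  for (ch in names(labels)) {
    lab <- labels[[ch]]
    if (inherits(lab, "sparse_track")) {
      L <- lab$length
      nw <- floor(L / window_length)
      if (nw == 0) next
      cz <- logical(nw)
      if (nrow(lab$runs)) {
        for (i in seq_len(nrow(lab$runs))) {
          w0 <- floor(lab$runs$start[i] / window_length)
          w1 <- floor((lab$runs$end[i] - 1) / window_length)
          cz[(w0 + 1):min(w1 + 1, nw)] <- TRUE
        }
      }
    } else {
      L <- length(lab)
      nw <- floor(L / window_length)
      if (nw == 0) next
      idx <- seq_len(nw * window_length)
      cz <- tapply(lab[idx] != 0, rep(seq_len(nw), each = window_length), any)
    }
    starts <- (seq_len(nw) - 1) * window_length
    tiles[[ch]] <- data.frame(chrom = ch, start = starts,
                              end = starts + window_length,
                              contains_z = as.logical(cz),
                              stringsAsFactors = FALSE)
  }
  all_win <- do.call(rbind, tiles)
  if (is.null(all_win) || nrow(all_win) == 0) stop("no complete windows")
  z_win <- all_win[all_win$contains_z, , drop = FALSE]
  bg_pool <- all_win[!all_win$contains_z, , drop = FALSE]
  n_bg <- background_ratio * nrow(z_win)
  if (n_bg > nrow(bg_pool)) {
    warning(sprintf("only %d background windows available (%d requested); taking all",
                    nrow(bg_pool), n_bg))
    n_bg <- nrow(bg_pool)
  }
  if (n_bg > 0) {
    set.seed(seed)
    bg <- bg_pool[sort(sample.int(nrow(bg_pool), n_bg)), , drop = FALSE]
  } else {
    bg <- bg_pool[0, , drop = FALSE]
  }
  ws <- rbind(z_win, bg)
  ws <- ws[order(ws$chrom, ws$start), , drop = FALSE]
  rownames(ws) <- NULL
  ws$split <- NA_character_
  ws$fold <- NA_integer_
  structure(ws, window_length = window_length, seed = seed,
            class = c("window_set", "data.frame"))
}

.strata <- function(ws) interaction(ws$chrom, ws$contains_z, drop = TRUE)

#' Stratified train/test split of a window set
#'
#' Within every (chromosome, label presence) stratum the windows are split at
#' `train_fraction` (default 4:1): the per-stratum test size is
#' `round(n * (1 - train_fraction))`, remainder to train. Deterministic
#' under the seed. Strata with fewer than 2 windows go wholly to train with
#' a warning.
#'
#' @param ws A [tile_and_select()] window set.
#' @param train_fraction Fraction assigned to train (default 0.8).
#' @param seed Integer seed.
#' @return `ws` with the `split` column filled (`"train"` / `"test"`).
#' @export
stratified_split <- function(ws, train_fraction = 0.8, seed = 1) {
  stopifnot(nrow(ws) > 0, train_fraction >= 0, train_fraction <= 1)
  set.seed(seed)
  ws$split <- "train"
  st <- .strata(ws)
  for (s in levels(st)) {
    idx <- which(st == s)
    n <- length(idx)
    if (n < 2) {
      if (train_fraction < 1) warning("stratum '", s, "' has < 2 windows; all to train")
      next
    }
    n_test <- round(n * (1 - train_fraction))
    if (n_test > 0) ws$split[sample(idx, n_test)] <- "test"
  }
  ws
}

#' Assign cross-validation folds, stratified by chromosome and label presence
#'
#' Each (chromosome, label presence) stratum is spread cyclically over the
#' `k` folds after an in-stratum shuffle; the cyclic counter carries over
#' between strata so global fold sizes differ by at most one.
#'
#' @param ws A [tile_and_select()] window set.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return `ws` with the `fold` column filled (values in `1..k`).
#' @export
make_folds <- function(ws, k = 5, seed = 1) {
  stopifnot(k >= 2, nrow(ws) > 0)
  set.seed(seed)
  st <- .strata(ws)
  counter <- 0L
  for (s in levels(st)) {
    idx <- which(st == s)
    idx <- idx[sample.int(length(idx))]
    ws$fold[idx] <- ((counter + seq_along(idx) - 1L) %% k) + 1L
    counter <- counter + length(idx)
  }
  ws
}

#' Write a window set as BED6 for inspection
#'
#' Name field carries `split:fold`, score is 1000 for labelled windows.
#'
#' @param ws A window set.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(ws, path) {
  tab <- data.frame(
    ws$chrom, as.integer(ws$start), as.integer(ws$end),
    paste0(ifelse(is.na(ws$split), ".", ws$split), ":",
           ifelse(is.na(ws$fold), ".", ws$fold)),
    ifelse(ws$contains_z, 1000L, 0L), ".",
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
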