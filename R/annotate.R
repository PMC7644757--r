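#' Average per-nucleotide probability tracks
#'
#' @param tracks List of probability tracks, each a named per-chromosome
#'   list of numeric vectors in `[0, 1]`.
#' @param provenance Character vector of contributing model ids.
#' @return An object of class `probability_track`: named per-chromosome
#'   list of averaged vectors with a `provenance` attribute.
#' @export
average_probability_tracks <- function(tracks, provenance = NULL) {
  stopifnot(length(tracks) >= 1)
  chroms <- names(tracks[[1]])
  out <- lapply(chroms, function(ch) {
    m <- vapply(tracks, function(t) t[[ch]], numeric(length(tracks[[1]][[ch]])))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    rowMeans(m)
  })
  names(out) <- chroms
  structure(out, provenance = provenance %||%
              paste0("model", seq_along(tracks)),
            class = "probability_track")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-fold whole-genome annotation
#'
#' Implements the annotation scheme: with `k` stratified folds on the
#' window set, `k` models are trained, each on the windows of the other
#' `k - 1` folds, and every model predicts over the full genome. The final
#' per-nucleotide probability is the arithmetic mean of all `k` model
#' predictions; fold order does not matter.
#'
#' @param windows A window set with folds from [make_folds()].
#' @param spec A [model_spec()].
#' @param store A [build_feature_store()].
#' @param labels Named per-chromosome list of label vectors/tracks.
#' @param channels Channels to train on (default all).
#' @param control A [zdna_control()].
#' @param seed Integer seed; fold `i` trains with seed `seed + i`.
#' @return A `probability_track` whose `provenance` lists the `k` fold
#'   models; attribute `models` keeps the fitted models.
#' @export
cross_fold_annotate <- function(windows, spec, store, labels,
                                channels = store$channel_names,
                                control = zdna_control(), seed = 1) {
  if (all(is.na(windows$fold))) stop("windows need a fold assignment; see make_folds()")
  folds <- sort(unique(windows$fold))
  models <- list()
  tracks <- list()
  for (f in folds) {
    train_ws <- windows[windows$fold != f, , drop = FALSE]
    train_ws$split <- NA_character_
    fit <- zdna_fit(spec, train_ws, store, labels, channels = channels,
                    control = control, seed = seed + f)
    models[[paste0("fold", f)]] <- fit
    tracks[[paste0("fold", f)]] <- stats::setNames(
      lapply(names(store$chroms), function(ch) predict(fit, store, chrom = ch)),
      names(store$chroms)
    )
  }
  out <- average_probability_tracks(tracks, provenance = names(tracks))
  attr(out, "models") <- models
  out
}

#' Select the F1-maximising probability threshold
#'
#' Sweeps the finite candidate set of observed probability values and
#' returns the candidate maximising nucleotide-level F1 of
#' `probability >= candidate` against the labels; ties go to the smallest
#' threshold. (The published genome-scale instance of this procedure
#' yielded 0.343; that value ships as the config default for annotation
#' without labels at hand.)
#'
#' @param track A `probability_track` or named per-chromosome list of
#'   probability vectors.
#' @param labels Named per-chromosome list of binary label vectors or
#'   [sparse_track()]s covering the same chromosomes.
#' @return The selected threshold (numeric scalar).
#' @export
select_threshold <- function(track, labels) {
  chroms <- names(track)
  p <- unlist(lapply(chroms, function(ch) as.numeric(track[[ch]])), use.names = FALSE)
  y <- unlist(lapply(chroms, function(ch) {
    l <- labels[[ch]]
    if (inherits(l, "sparse_track")) track_dense(l) else as.numeric(l)
  }), use.names = FALSE)
  stopifnot(length(p) == length(y))
  P <- sum(y != 0)
  if (P == 0) stop("no positive labels; threshold undefined")
  o <- order(p, decreasing = TRUE)
  ps <- p[o]; ys <- as.numeric(y[o] != 0)
  tp_cum <- cumsum(ys)
  # last index of each distinct value group == prediction set {p >= value}
  grp_last <- which(ps != c(ps[-1], NA_real_) | seq_along(ps) == length(ps))
  tp <- tp_cum[grp_last]
  k <- grp_last
  f1 <- 2 * tp / (k + P)
  best <- max(f1)
  cand <- ps[grp_last][f1 == best]
  min(cand)
}

#' Assemble discrete Z-DNA regions from a probability track
#'
#' Three steps: (1) take maximal runs of `probability > threshold`
#' (strictly greater); (2) join runs separated by a gap of less than
#' `join_gap` bp; (3) drop joined intervals shorter than `min_length` bp.
#' The 11 bp defaults correspond to one turn of the DNA helix: calls
#' shorter than a helix turn are unlikely to be real, and gaps below a turn
#' do not separate structures. A gap of exactly `join_gap` is not merged; an
#' interval of exactly `min_length` is kept.
#'
#' @param track A `probability_track` or named per-chromosome list of
#'   probability vectors.
#' @param threshold Probability cutoff in `[0, 1]` (see [select_threshold()]).
#' @param join_gap Strict upper bound (bp) on gaps that get joined.
#' @param min_length Minimum interval length (bp) kept after joining.
#' @return Interval `data.frame` (`chrom`, `start`, `end`, `score` = mean
#'   probability over the interval).
#' @export
assemble_regions <- function(track, threshold, join_gap = 11, min_length = 11) {
  stopifnot(threshold >= 0, threshold <= 1)
  pieces <- list()
  for (ch in names(track)) {
    v <- as.numeric(track[[ch]])
    r <- rle(v > threshold)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (!any(keep)) next
    df <- data.frame(chrom = ch, start = starts[keep], end = ends[keep],
                     stringsAsFactors = FALSE)
    df <- merge_regions(df, gap_lt = join_gap)
    df <- df[df$end - df$start >= min_length, , drop = FALSE]
    if (nrow(df)) {
      df$score <- vapply(seq_len(nrow(df)), function(i) {
        mean(v[(df$start[i] + 1):df$end[i]])
      }, numeric(1))
      pieces[[ch]] <- df
    }
  }
  if (!length(pieces))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), score = numeric(0)))
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Combine two region annotations
#'
#' Union of the two interval sets with intervals closer than `proximity`
#' bp (strictly) merged into one.
#'
#' @param a,b Interval `data.frame`s on the same genome.
#' @param proximity Strict merge distance in bp (default 10).
#' @return Merged interval `data.frame`.
#' @export
combine_annotations <- function(a, b, proximity = 10) {
  both <- rbind(a[, c("chrom", "start", "end")], b[, c("chrom", "start", "end")])
  if (nrow(both) == 0) return(both)
  merge_regions(both, gap_lt = proximity)
}

#' Write a probability track as bedGraph
#'
#' Constant stretches are run-length collapsed; the output loads as a UCSC
#' genome browser custom track.
#'
#' @param track A `probability_track` or named per-chromosome list.
#' @param path Output path.
#' @param digits Rounding applied before collapsing (default 4).
#' @return `path`, invisibly.
#' @export
write_probability_bedgraph <- function(track, path, digits = 4) {
  rows <- list()
  for (ch in names(track)) {
    v <- round(as.numeric(track[[ch]]), digits)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    rows[[ch]] <- data.frame(chrom = ch, start = ends - r$lengths, end = ends,
                             value = r$values, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(tab$chrom,
                               IRanges::IRanges(tab$start + 1, tab$end),
                               score = tab$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a real-valued bedGraph track
#'
#' @param path bedGraph file.
#' @param lengths Named vector of chromosome lengths.
#' @return Named list of [sparse_track()]s (positions not covered carry 0).
#' @export
read_bedgraph_track <- function(path, lengths) {
  df <- granges_to_regions(rtracklayer::import(path, format = "bedGraph"))
  stats::setNames(lapply(names(lengths), function(ch) {
    sub <- df[df$chrom == ch & df$score != 0, , drop = FALSE]
    if (!nrow(sub)) return(sparse_track(lengths[[ch]]))
    sparse_track(lengths[[ch]],
                 data.frame(start = sub$start, end = pmin(sub$end, lengths[[ch]]),
                            value = sub$score))
  }), names(lengths))
}
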