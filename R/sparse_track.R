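#' Run-length encoded genome-length feature track
#'
#' Genome-scale feature tracks (binary peak calls, per-base energies, scaled
#' signals) are mostly long constant stretches. Storing every channel of the
#' per-chromosome feature matrix densely would not fit in RAM for a mammalian
#' genome, so channels are kept as run-length encoded vectors: an ordered set
#' of constant runs over a default background value, with random-access
#' slicing. All coordinates are 0-based half-open (BED convention).
#'
#' @param length Track length in nucleotides (positive integer).
#' @param runs A `data.frame` with columns `start`, `end`, `value`: sorted,
#'   non-overlapping runs within `[0, length)`; no run may carry
#'   `default_value`. `NULL` means no runs (constant track).
#' @param default_value Value of every position not covered by a run.
#' @return An object of class `sparse_track`.
#' @seealso [as_sparse_track()], [track_slice()], [track_dense()]
#' @export
sparse_track <- function(length, runs = NULL, default_value = 0) {
  length <- as.numeric(length)
  if (!is.finite(length) || length < 1) stop("track length must be a positive integer")
  if (is.null(runs)) {
    runs <- data.frame(start = numeric(0), end = numeric(0), value = numeric(0))
  }
  runs <- as.data.frame(runs)[, c("start", "end", "value")]
  if (nrow(runs)) {
    o <- order(runs$start)
    runs <- runs[o, , drop = FALSE]
    rownames(runs) <- NULL
    if (any(runs$start < 0) || any(runs$end > length) || any(runs$end <= runs$start))
      stop("runs must satisfy 0 <= start < end <= length")
    if (nrow(runs) > 1 && any(runs$start[-1] < runs$end[-nrow(runs)]))
      stop("runs must be non-overlapping")
    if (any(!is.finite(runs$value))) stop("run values must be finite")
    if (any(runs$value == default_value))
      stop("runs must not carry the default value")
  }
  structure(
    list(length = length, runs = runs, default_value = default_value),
    class = "sparse_track"
  )
}

#' Compress a dense vector into a sparse track
#'
#' Performs a maximal run-length scan: every maximal constant segment whose
#' value differs from `default_value` becomes one run. Compression is exact;
#' [track_dense()] round-trips element-wise.
#'
#' @param values Finite numeric vector (the dense track).
#' @param default_value Background value stored implicitly.
#' @return A [sparse_track()].
#' @export
as_sparse_track <- function(values, default_value = 0) {
  if (length(values) == 0) stop("cannot encode an empty vector")
  if (any(!is.finite(values))) stop("values must be finite")
  r <- rle(as.numeric(values))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != default_value
  sparse_track(
    length = length(values),
    runs = data.frame(start = starts[keep], end = ends[keep], value = r$values[keep]),
    default_value = default_value
  )
}

#' @export
print.sparse_track <- function(x, ...) {
  cat(sprintf(
    "<sparse_track> length %d, %d run(s), default %g\n",
    as.integer(x$length), nrow(x$runs), x$default_value
  ))
  invisible(x)
}

#' @export
length.sparse_track <- function(x) as.integer(x$length)

#' Materialise a sparse track as a dense vector
#'
#' @param track A [sparse_track()].
#' @return Numeric vector of length `length(track)`.
#' @export
track_dense <- function(track) {
  track_slice(track, 0, track$length)
}

#' Random-access slice of a sparse track
#'
#' Returns the dense sub-vector over the 0-based half-open interval
#' `[start, end)`. `track_slice(t, 0, length(t))` equals [track_dense()].
#'
#' @param track A [sparse_track()].
#' @param start,end 0-based half-open slice bounds, `0 <= start <= end <= length`.
#' @return Numeric vector of length `end - start`.
#' @export
track_slice <- function(track, start, end) {
  stopifnot(inherits(track, "sparse_track"))
  if (start < 0 || end > track$length || start > end)
    stop("slice out of range: need 0 <= start <= end <= length")
  n <- end - start
  out <- rep(track$default_value, n)
  if (n == 0 || nrow(track$runs) == 0) return(out)
  rs <- track$runs$start; re <- track$runs$end; rv <- track$runs$value
  hit <- which(re > start & rs < end)
  for (i in hit) {
    a <- max(rs[i], start) - start
    b <- min(re[i], end) - start
    out[(a + 1):b] <- rv[i]
  }
  out
}

#' Write a named set of sparse tracks to a single text archive
#'
#' One entry per named track; the plain-text format keeps the archive
#' portable and diffable. Entries can be read back selectively by name with
#' [read_track_archive()].
#'
#' @param tracks Named list of [sparse_track()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_track_archive <- function(tracks, path) {
  stopifnot(is.list(tracks), length(tracks) > 0, !is.null(names(tracks)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("ZTRK\t1\t%d", length(tracks)), con)
  for (nm in names(tracks)) {
    t <- tracks[[nm]]
    stopifnot(inherits(t, "sparse_track"))
    writeLines(sprintf("track\t%s\t%d\t%.17g\t%d",
                       nm, as.integer(t$length), t$default_value, nrow(t$runs)), con)
    if (nrow(t$runs)) {
      writeLines(sprintf("%d\t%d\t%.17g", as.integer(t$runs$start),
                         as.integer(t$runs$end), t$runs$value), con)
    }
  }
  invisible(path)
}

#' Read sparse tracks from a text archive
#'
#' @param path Archive written by [write_track_archive()].
#' @param names Character vector of entry names to load, or `NULL` for all.
#'   Runs of unrequested entries are skipped without being parsed.
#' @return Named list of [sparse_track()] objects.
#' @export
read_track_archive <- function(path, names = NULL) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "ZTRK"))
    stop("not a track archive: ", path)
  out <- list()
  i <- 2L
  while (i <= length(lines)) {
    hdr <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (hdr[1] != "track") stop("malformed archive at line ", i)
    nm <- hdr[2]
    len <- as.numeric(hdr[3]); def <- as.numeric(hdr[4]); nr <- as.integer(hdr[5])
    if (is.null(names) || nm %in% names) {
      runs <- if (nr > 0) {
        m <- matrix(as.numeric(unlist(strsplit(lines[i + seq_len(nr)], "\t", fixed = TRUE))),
                    ncol = 3, byrow = TRUE)
        data.frame(start = m[, 1], end = m[, 2], value = m[, 3])
      } else NULL
      out[[nm]] <- sparse_track(len, runs, def)
    }
    i <- i + 1L + nr
  }
  if (!is.null(names)) {
    missing <- setdiff(names, base::names(out))
    if (length(missing)) stop("entries not in archive: ", paste(missing, collapse = ", "))
    out <- out[names]
  }
  out
}
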