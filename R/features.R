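#' Read a dinucleotide B-Z transition energy table
#'
#' The table is a TSV with columns `dinucleotide` and `energy` (kcal/mol, one
#' row per each of the 16 dinucleotides) plus two commented header keys
#' `bz_junction` and `zz_junction` carrying the B-Z and Z-Z junction
#' energies. The package ships a literature-derived default table
#' (`system.file("extdata", "zhunt_energy.tsv", package = "zdnascan")`).
#'
#' @param path Path to the TSV; defaults to the shipped table.
#' @return A list with elements `dinucleotide` (named numeric of length 16),
#'   `bz_junction` and `zz_junction`.
#' @export
read_energy_table <- function(path = system.file("extdata", "zhunt_energy.tsv",
                                                 package = "zdnascan")) {
  lines <- readLines(path)
  key_lines <- grep("^#\\s*\\w+\\t", lines, value = TRUE)
  keys <- list()
  for (kl in key_lines) {
    parts <- strsplit(sub("^#\\s*", "", kl), "\t", fixed = TRUE)[[1]]
    if (length(parts) == 2) keys[[parts[1]]] <- as.numeric(parts[2])
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  e <- stats::setNames(as.numeric(tab$energy), toupper(tab$dinucleotide))
  all16 <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
  missing <- setdiff(all16, names(e))
  if (length(missing)) stop("energy table incomplete, missing: ",
                            paste(missing, collapse = ", "))
  if (any(!is.finite(e))) stop("energy table has non-finite values")
  if (is.null(keys$bz_junction) || is.null(keys$zz_junction))
    stop("energy table must define '# bz_junction' and '# zz_junction' header keys")
  list(dinucleotide = e[all16], bz_junction = keys$bz_junction,
       zz_junction = keys$zz_junction)
}

.BASES <- c("A", "C", "G", "T")
.IUPAC_AMBIG <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' One-hot encode a DNA sequence
#'
#' @param sequence DNA as a character string or `Biostrings::DNAString`;
#'   lowercase accepted. Ambiguity codes (N etc.) become all-zero columns.
#' @return A 4 x L binary matrix with rows A, C, G, T; every unambiguous
#'   base gives a column summing to 1.
#' @export
one_hot_encode <- function(sequence) {
  chars <- toupper(strsplit(as.character(sequence), "")[[1]])
  bad <- setdiff(unique(chars), c(.BASES, .IUPAC_AMBIG))
  if (length(bad)) stop("non-IUPAC characters in sequence: ",
                        paste(bad, collapse = ", "))
  L <- length(chars)
  m <- matrix(0, nrow = 4, ncol = L, dimnames = list(.BASES, NULL))
  for (b in .BASES) m[b, chars == b] <- 1
  m
}

#' Per-nucleotide B-Z transition energy channels
#'
#' Position `i` carries the transition energy of the dinucleotide step
#' `(i, i+1)`; the final position repeats the preceding step's value.
#' Dinucleotides containing an ambiguous base get the table's maximum
#' (least Z-favourable) energy. Two additional constant channels carry the
#' B-Z and Z-Z junction energies.
#'
#' @param sequence DNA character string or `DNAString`.
#' @param table Energy table from [read_energy_table()].
#' @return A list of numeric vectors `dinucleotide`, `bz_junction`,
#'   `zz_junction`, each of length `nchar(sequence)`.
#' @export
energy_channels <- function(sequence, table = read_energy_table()) {
  chars <- toupper(strsplit(as.character(sequence), "")[[1]])
  L <- length(chars)
  if (L < 2) stop("sequence must have at least 2 nucleotides")
  bad <- setdiff(unique(chars), c(.BASES, .IUPAC_AMBIG))
  if (length(bad)) stop("non-IUPAC characters in sequence: ",
                        paste(bad, collapse = ", "))
  emax <- max(table$dinucleotide)
  steps <- paste0(chars[-L], chars[-1])
  ev <- unname(table$dinucleotide[steps])
  ev[is.na(ev)] <- emax
  list(
    dinucleotide = c(ev, ev[L - 1]),
    bz_junction = rep(table$bz_junction, L),
    zz_junction = rep(table$zz_junction, L)
  )
}

#' Aggregate one marker across tissues as presence-in-any-tissue
#'
#' Element-wise logical OR over binary tracks: the marker channel is 1
#' wherever at least one tissue shows a peak.
#'
#' @param tissue_tracks Non-empty list of binary [sparse_track()]s of equal
#'   length (default value 0, run value 1).
#' @return A binary [sparse_track()].
#' @export
aggregate_marker <- function(tissue_tracks) {
  if (!length(tissue_tracks)) stop("need at least one tissue track")
  lens <- vapply(tissue_tracks, function(t) t$length, numeric(1))
  if (length(unique(lens)) != 1) stop("all tissue tracks must have equal length")
  L <- lens[1]
  allruns <- do.call(rbind, lapply(tissue_tracks, function(t) t$runs[, c("start", "end")]))
  if (is.null(allruns) || nrow(allruns) == 0) return(sparse_track(L))
  ir <- IRanges::reduce(IRanges::IRanges(start = allruns$start + 1, end = allruns$end))
  sparse_track(L, data.frame(start = IRanges::start(ir) - 1,
                             end = IRanges::end(ir), value = 1))
}

#' Linearly scale a track to the unit interval
#'
#' Min-max scaling over the whole track (background included where the track
#' has uncovered positions): the minimum maps to 0 and the maximum to 1.
#' Binary 0/1 tracks are unchanged; a constant track maps to all zeros.
#' Scaling is idempotent.
#'
#' @param track A [sparse_track()].
#' @return A [sparse_track()] with values in `[0, 1]`.
#' @export
scale_channel <- function(track) {
  stopifnot(inherits(track, "sparse_track"))
  covered <- sum(track$runs$end - track$runs$start)
  vals <- track$runs$value
  if (covered < track$length) vals <- c(vals, track$default_value)
  vmin <- min(vals); vmax <- max(vals)
  if (vmax == vmin) return(sparse_track(track$length, NULL, 0))
  sc <- function(v) (v - vmin) / (vmax - vmin)
  new_def <- if (covered < track$length) sc(track$default_value) else 0
  runs <- track$runs
  runs$value <- sc(runs$value)
  runs <- runs[runs$value != new_def, , drop = FALSE]
  sparse_track(track$length, runs, new_def)
}

#' Encode labelled intervals as a per-nucleotide boolean vector
#'
#' Nucleotides inside any labelled interval get 1, all others 0; overlapping
#' input intervals are merged silently.
#'
#' @param regions Interval `data.frame` (columns `start`, `end`, 0-based
#'   half-open; a `chrom` column, if present, is ignored — pass one
#'   chromosome at a time).
#' @param length Chromosome length.
#' @return Binary numeric vector of `length`.
#' @export
encode_labels <- function(regions, length) {
  v <- numeric(length)
  if (!is.null(regions) && nrow(regions)) {
    if (any(regions$start < 0) || any(regions$end > length))
      stop("regions outside [0, length)")
    for (i in seq_len(nrow(regions))) {
      v[(regions$start[i] + 1):regions$end[i]] <- 1
    }
  }
  v
}

#' Build the multi-channel feature matrix for one chromosome
#'
#' Channel order is fixed: the four one-hot sequence channels (`seq_A`,
#' `seq_C`, `seq_G`, `seq_T`), then the three energy channels, then the
#' marker channels in the order given. Every channel is stored as a
#' [sparse_track()] and min-max scaled to `[0, 1]`.
#'
#' @param sequence Chromosome DNA (character string or `DNAString`).
#' @param marker_tracks Named list of binary [sparse_track()]s (already
#'   tissue-aggregated, see [aggregate_marker()]), or `NULL`.
#' @param energy_table Energy table from [read_energy_table()], or `NULL` to
#'   omit energy channels.
#' @param chrom Chromosome name recorded on the object.
#' @return An object of class `feature_matrix`: list with `chrom`, `length`,
#'   `channels` (named list of sparse tracks) and `classes` (channel class
#'   per channel: `seq`, `energy` or `marker`).
#' @export
feature_matrix <- function(sequence, marker_tracks = NULL,
                           energy_table = read_energy_table(),
                           chrom = "chr1") {
  seqchar <- as.character(sequence)
  L <- nchar(seqchar)
  ohe <- one_hot_encode(seqchar)
  channels <- list()
  classes <- character(0)
  for (b in .BASES) {
    channels[[paste0("seq_", b)]] <- as_sparse_track(ohe[b, ])
    classes <- c(classes, "seq")
  }
  if (!is.null(energy_table)) {
    ec <- energy_channels(seqchar, energy_table)
    for (nm in names(ec)) {
      channels[[paste0("energy_", nm)]] <- scale_channel(as_sparse_track(ec[[nm]]))
      classes <- c(classes, "energy")
    }
  }
  if (!is.null(marker_tracks)) {
    for (nm in names(marker_tracks)) {
      t <- marker_tracks[[nm]]
      if (t$length != L) stop("marker track '", nm, "' length mismatch")
      channels[[nm]] <- scale_channel(t)
      classes <- c(classes, "marker")
    }
  }
  structure(list(chrom = chrom, length = L, channels = channels,
                 classes = stats::setNames(classes, names(channels))),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d nt, %d channels (%s)\n",
              x$chrom, as.integer(x$length), length(x$channels),
              paste(sprintf("%d %s", table(x$classes)[unique(x$classes)],
                            unique(x$classes)), collapse = ", ")))
  invisible(x)
}

#' Build a whole-genome feature store
#'
#' Applies [feature_matrix()] per chromosome. Marker intervals are converted
#' to binary tracks per chromosome; an optional blacklist of excluded
#' intervals is subtracted from every marker first.
#'
#' @param genome Named character vector or `Biostrings::DNAStringSet`, one
#'   entry per chromosome.
#' @param markers Named list of interval `data.frame`s (one per marker,
#'   columns `chrom`, `start`, `end`), or `NULL`.
#' @param energy_table See [feature_matrix()].
#' @param blacklist Optional interval `data.frame` of excluded regions.
#' @return An object of class `feature_store`: list with `chroms` (named
#'   list of [feature_matrix()]), `channel_names`, `classes`.
#' @export
build_feature_store <- function(genome, markers = NULL,
                                energy_table = read_energy_table(),
                                blacklist = NULL) {
  seqs <- if (inherits(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else genome
  if (is.null(names(seqs))) stop("genome must be named by chromosome")
  chroms <- names(seqs)
  store_chroms <- list()
  for (ch in chroms) {
    L <- nchar(seqs[[ch]])
    mtracks <- NULL
    if (!is.null(markers)) {
      mtracks <- lapply(markers, function(df) {
        df <- df[df$chrom == ch, , drop = FALSE]
        if (!is.null(blacklist)) df <- subtract_regions(df, blacklist[blacklist$chrom == ch, , drop = FALSE])
        if (nrow(df) == 0) return(sparse_track(L))
        df <- merge_regions(df)
        sparse_track(L, data.frame(start = df$start, end = pmin(df$end, L), value = 1))
      })
    }
    store_chroms[[ch]] <- feature_matrix(seqs[[ch]], mtracks, energy_table, chrom = ch)
  }
  channel_names <- names(store_chroms[[1]]$channels)
  for (ch in chroms) {
    if (!identical(names(store_chroms[[ch]]$channels), channel_names))
      stop("channel sets differ across chromosomes")
  }
  structure(list(chroms = store_chroms, channel_names = channel_names,
                 classes = store_chroms[[1]]$classes),
            class = "feature_store")
}

#' @export
print.feature_store <- function(x, ...) {
  cat(sprintf("<feature_store> %d chromosome(s), %d channels\n",
              length(x$chroms), length(x$channel_names)))
  invisible(x)
}

#' Materialise the dense input matrix for a genomic window
#'
#' @param store A [build_feature_store()] object.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open window bounds.
#' @return Numeric matrix of dimension `(end - start) x n_channels`.
#' @export
window_matrix <- function(store, chrom, start, end) {
  fm <- store$chroms[[chrom]]
  if (is.null(fm)) stop("unknown chromosome: ", chrom)
  X <- vapply(fm$channels, function(t) track_slice(t, start, end),
              numeric(end - start))
  if (end - start == 1) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(fm$channels)))
  X
}
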