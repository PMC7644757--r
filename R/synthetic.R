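#' Configuration for the synthetic fixture generator
#'
#' The generator emulates the statistical structure the predictor assumes:
#' a multi-chromosome genome of i.i.d. background sequence, planted
#' Z-prone purine-pyrimidine motif repeats at the labelled regions (mean
#' region length 400 nt, the average size of labelled elements under the
#' segmentation framing), binary feature tracks correlated with the labels
#' through interval-level dropout/spurious-peak noise (mimicking ChIP-seq
#' peak dropout rather than per-base noise), and uninformative tracks of
#' matched interval density.
#'
#' @param n_chromosomes Number of chromosomes (default 3, so stratified
#'   splitting and folding are exercised).
#' @param chromosome_length Length of each chromosome in nt.
#' @param n_regions Total number of planted Z-DNA regions.
#' @param region_length_mean,region_length_sd Gamma-distributed region
#'   lengths (defaults: mean 400 nt, sd 100 nt).
#' @param planted_motif Motif tiled across every planted region (default
#'   alternating `"GC"`; `"GGGC"` is the other classic Z-prone pattern).
#' @param n_informative_tracks,n_noise_tracks Numbers of label-correlated
#'   and matched-density random tracks.
#' @param track_flip_probability Interval-level Bernoulli noise on
#'   informative tracks, in `[0, 0.5)`: each true interval is dropped with
#'   this probability and a matching number of spurious intervals is added.
#' @param seed Integer seed; outputs are byte-identical under a fixed seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_chromosomes = 3, chromosome_length = 100000,
                         n_regions = 12, region_length_mean = 400,
                         region_length_sd = 100, planted_motif = "GC",
                         n_informative_tracks = 4, n_noise_tracks = 6,
                         track_flip_probability = 0.1, seed = 1) {
  stopifnot(n_chromosomes >= 1, chromosome_length >= 1, n_regions >= 1,
            n_informative_tracks >= 1, n_noise_tracks >= 0,
            track_flip_probability >= 0, track_flip_probability < 0.5)
  structure(as.list(environment()), class = "synth_config")
}

random_intervals <- function(n, chrom_lengths, len_mean, len_sd, min_gap = 200) {
  shape <- (len_mean / len_sd)^2
  rate <- len_mean / len_sd^2
  placed <- lapply(names(chrom_lengths), function(ch) cbind(numeric(0), numeric(0)))
  names(placed) <- names(chrom_lengths)
  out <- list()
  tries <- 0
  while (length(out) < n) {
    tries <- tries + 1
    if (tries > 50 * n) stop("requested intervals exceed genome capacity")
    len <- max(20, round(stats::rgamma(1, shape = shape, rate = rate)))
    ch <- sample(names(chrom_lengths), 1)
    L <- chrom_lengths[[ch]]
    if (len + 2 * min_gap >= L) next
    s <- sample.int(L - len, 1) - 1
    e <- s + len
    prev <- placed[[ch]]
    if (nrow(prev) && any(pmax(prev[, 1], s - min_gap) < pmin(prev[, 2], e + min_gap)))
      next
    placed[[ch]] <- rbind(prev, c(s, e))
    out[[length(out) + 1]] <- data.frame(chrom = ch, start = s, end = e,
                                         stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Generate a synthetic genome with planted Z-DNA regions and feature tracks
#'
#' Background sequence is i.i.d. uniform over ACGT; every planted region
#' carries `planted_motif` tiled to its length. Informative tracks are the
#' label intervals with interval-level Bernoulli noise; noise tracks are
#' random intervals of matched count and length distribution. When `dir` is
#' given, the fixture is also written to disk as `genome.fa`, `labels.bed`,
#' `tracks/<name>.bed` and `manifest.yaml`.
#'
#' @param config A [synth_config()].
#' @param dir Optional output directory.
#' @return A list with `genome` (named character vector), `labels`
#'   (interval `data.frame`), `tracks` (named list of interval
#'   `data.frame`s) and `manifest` (which tracks are informative, the
#'   planted motif matrix, the config).
#' @export
synth_generate <- function(config = synth_config(), dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  lens <- stats::setNames(rep(config$chromosome_length, length(chroms)), chroms)

  genome <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), lens[[ch]], replace = TRUE), collapse = "")
  }, character(1))

  labels <- random_intervals(config$n_regions, lens,
                             config$region_length_mean, config$region_length_sd)
  for (i in seq_len(nrow(labels))) {
    len <- labels$end[i] - labels$start[i]
    tile <- substr(strrep(config$planted_motif,
                          ceiling(len / nchar(config$planted_motif))), 1, len)
    ch <- labels$chrom[i]
    genome[[ch]] <- paste0(substr(genome[[ch]], 1, labels$start[i]), tile,
                           substr(genome[[ch]], labels$end[i] + 1, lens[[ch]]))
  }

  tracks <- list()
  p <- config$track_flip_probability
  for (t in seq_len(config$n_informative_tracks)) {
    keep <- stats::runif(nrow(labels)) >= p
    tr <- labels[keep, , drop = FALSE]
    n_spur <- stats::rbinom(1, nrow(labels), p)
    if (n_spur > 0) {
      tr <- rbind(tr, random_intervals(n_spur, lens, config$region_length_mean,
                                       config$region_length_sd))
    }
    tracks[[sprintf("inf_%02d", t)]] <- tr[order(tr$chrom, tr$start), , drop = FALSE]
  }
  for (t in seq_len(config$n_noise_tracks)) {
    tracks[[sprintf("noise_%02d", t)]] <-
      random_intervals(nrow(labels), lens, config$region_length_mean,
                       config$region_length_sd)
  }

  manifest <- list(
    chromosomes = as.list(lens),
    informative_tracks = grep("^inf_", names(tracks), value = TRUE),
    noise_tracks = grep("^noise_", names(tracks), value = TRUE),
    planted_motif = config$planted_motif,
    config = unclass(config)
  )
  sim <- list(genome = genome, labels = labels, tracks = tracks,
              manifest = manifest)

  if (!is.null(dir)) {
    dir.create(file.path(dir, "tracks"), recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome),
                                file.path(dir, "genome.fa"))
    write_bed_regions(labels, file.path(dir, "labels.bed"))
    for (nm in names(tracks)) {
      write_bed_regions(tracks[[nm]], file.path(dir, "tracks", paste0(nm, ".bed")))
    }
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  }
  sim
}

#' Per-chromosome label tracks of a synthetic fixture
#'
#' @param sim A [synth_generate()] result.
#' @return Named list of binary [sparse_track()]s.
#' @export
synth_labels <- function(sim) {
  lens <- sim$manifest$chromosomes
  stats::setNames(lapply(names(lens), function(ch) {
    df <- sim$labels[sim$labels$chrom == ch, , drop = FALSE]
    if (!nrow(df)) return(sparse_track(lens[[ch]]))
    sparse_track(lens[[ch]], data.frame(start = df$start, end = df$end, value = 1))
  }), names(lens))
}

#' One-hot position weight matrix of a planted motif
#'
#' @param motif Motif string (e.g. `"GC"`).
#' @param width Optional width to tile to (e.g. a model's receptive field);
#'   default the motif length.
#' @param phase Tiling offset into the motif (0-based).
#' @return 4 x width one-hot matrix with rows A, C, G, T.
#' @export
planted_motif_matrix <- function(motif, width = NULL, phase = 0) {
  chars <- strsplit(toupper(motif), "")[[1]]
  if (is.null(width)) width <- length(chars)
  tiled <- chars[((phase + seq_len(width) - 1) %% length(chars)) + 1]
  m <- matrix(0, 4, width, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(width)) m[tiled[j], j] <- 1
  m
}
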