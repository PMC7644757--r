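#' Genomic interval helpers
#'
#' Intervals are carried as plain data frames with columns `chrom`, `start`,
#' `end` (plus optional `score`), 0-based half-open as in BED. GRanges are
#' used at the file boundary (via rtracklayer) and converted on the way in.
#'
#' @param chrom,start,end,score Vectors of equal length (score optional).
#' @return A `data.frame` of intervals.
#' @export
region_set <- function(chrom, start, end, score = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (!is.null(score)) df$score <- as.numeric(score)
  if (any(df$end <= df$start)) stop("regions must have end > start")
  if (any(df$start < 0)) stop("regions must have start >= 0")
  df[order(df$chrom, df$start), , drop = FALSE]
}

granges_to_regions <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (!is.null(gr$score)) df$score <- as.numeric(gr$score)
  df
}

regions_to_granges <- function(df) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
  if (!is.null(df$score)) gr$score <- df$score
  gr
}

#' Read intervals from a BED file
#'
#' @param path BED3+ file.
#' @return Interval `data.frame` (0-based half-open).
#' @export
read_bed_regions <- function(path) {
  granges_to_regions(rtracklayer::import(path, format = "BED"))
}

#' Write intervals to a BED file
#'
#' @param regions Interval `data.frame`; a `score` column, if present, is
#'   written to the BED score field (scaled to 0-1000 integer).
#' @param path Output path.
#' @param names Optional per-interval name field.
#' @return `path`, invisibly.
#' @export
write_bed_regions <- function(regions, path, names = NULL) {
  n <- nrow(regions)
  cols <- list(regions$chrom, as.integer(regions$start), as.integer(regions$end))
  if (!is.null(names) || !is.null(regions$score)) {
    cols[[4]] <- if (is.null(names)) rep(".", n) else names
    if (!is.null(regions$score)) {
      cols[[5]] <- as.integer(pmin(1000, pmax(0, round(1000 * regions$score))))
    }
  }
  tab <- do.call(data.frame, c(cols, list(stringsAsFactors = FALSE)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge intervals, joining those separated by small gaps
#'
#' Intervals on the same chromosome separated by a gap strictly smaller than
#' `gap_lt` are merged into one (overlapping and bookended intervals are
#' always merged). Never merges across chromosomes.
#'
#' @param regions Interval `data.frame`.
#' @param gap_lt Strict upper bound on gaps that get merged; `gap_lt = 1`
#'   merges only touching/overlapping intervals.
#' @return Merged interval `data.frame`.
#' @export
merge_regions <- function(regions, gap_lt = 1) {
  if (nrow(regions) == 0) return(region_set(character(0), numeric(0) + 1, numeric(0) + 2)[0, ])
  gr <- regions_to_granges(regions)
  red <- GenomicRanges::reduce(gr, min.gapwidth = gap_lt)
  granges_to_regions(red)
}

#' Subtract excluded intervals (e.g. a blacklist) from a region set
#'
#' @param regions,excluded Interval `data.frame`s.
#' @return `regions` with every excluded base removed.
#' @export
subtract_regions <- function(regions, excluded) {
  if (nrow(regions) == 0 || is.null(excluded) || nrow(excluded) == 0) return(regions)
  kept <- GenomicRanges::setdiff(regions_to_granges(regions),
                                 regions_to_granges(excluded))
  granges_to_regions(kept)
}
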