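#' Nucleotide-level classification metrics
#'
#' ROC AUC is computed as the rank (Wilcoxon) statistic over all nucleotides
#' with midrank tie handling; precision, recall and F1 are taken from the
#' confusion table at `probabilities > threshold`. Both metrics are robust
#' to the heavy class imbalance of the segmentation framing (positives are
#' roughly 1 in 50 nucleotides at genome scale).
#'
#' @param probabilities Numeric vector of per-nucleotide scores.
#' @param labels Binary vector of the same length.
#' @param threshold Classification threshold for F1/precision/recall.
#' @param stratum Label recorded on the report (e.g. a chromosome name).
#' @return A one-row `data.frame` (class `metric_report`) with columns
#'   `stratum`, `roc_auc`, `f1`, `precision`, `recall`, `threshold`, `n`,
#'   `n_pos`. AUC is `NA` when labels are single-class.
#' @export
nucleotide_metrics <- function(probabilities, labels, threshold = 0.5,
                               stratum = "all") {
  stopifnot(length(probabilities) == length(labels))
  labels <- as.numeric(labels != 0)
  n1 <- sum(labels); n0 <- length(labels) - n1
  auc <- if (n1 == 0 || n0 == 0) NA_real_ else {
    r <- rank(probabilities, ties.method = "average")
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  pred <- probabilities > threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(data.frame(stratum = stratum, roc_auc = auc, f1 = f1,
                       precision = precision, recall = recall,
                       threshold = threshold, n = length(labels), n_pos = n1,
                       stringsAsFactors = FALSE),
            class = c("metric_report", "data.frame"))
}

f1_score <- function(pred, labels) {
  tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Per-chromosome metric breakdown
#'
#' @param probabilities Named per-chromosome list of score vectors.
#' @param labels Named per-chromosome list of binary label vectors (or
#'   [sparse_track()]s).
#' @param threshold Classification threshold.
#' @return A `data.frame` with one [nucleotide_metrics()] row per chromosome
#'   plus a pooled `"all"` row; chromosomes without positives carry `NA` AUC.
#' @export
per_chromosome_metrics <- function(probabilities, labels, threshold = 0.5) {
  stopifnot(length(probabilities) >= 1)
  chroms <- names(probabilities)
  dense <- lapply(labels[chroms], function(l) {
    if (inherits(l, "sparse_track")) track_dense(l) else as.numeric(l)
  })
  rows <- lapply(chroms, function(ch) {
    nucleotide_metrics(probabilities[[ch]], dense[[ch]], threshold, stratum = ch)
  })
  pooled <- nucleotide_metrics(unlist(probabilities[chroms], use.names = FALSE),
                               unlist(dense, use.names = FALSE),
                               threshold, stratum = "all")
  out <- do.call(rbind, c(rows, list(pooled)))
  rownames(out) <- NULL
  out
}

#' Tolerance-window comparison of predictions against true regions
#'
#' Asks whether a method hits a true region at all rather than demanding
#' exact nucleotides: a true region counts as recalled if at least one
#' predicted nucleotide falls within the region extended by `flank` on each
#' side; precision is the fraction of predicted nucleotides lying within
#' `flank` of any true region.
#'
#' @param predicted_nucleotides Integer vector of predicted positions
#'   (0-based) on one chromosome.
#' @param true_regions Interval `data.frame` (columns `start`, `end`).
#' @param flank Non-negative flank in bp (the comparison protocol uses
#'   0, 50, 100, 150, 200).
#' @return A one-row `data.frame` with `flank`, `recall`, `precision`, `f1`,
#'   `n_regions`, `n_predicted`. With no predictions, recall is 0 and
#'   precision is reported as 0 with a warning.
#' @export
tolerance_hit_rate <- function(predicted_nucleotides, true_regions, flank = 0) {
  stopifnot(flank >= 0)
  n_reg <- nrow(true_regions)
  if (length(predicted_nucleotides) == 0) {
    warning("no predicted nucleotides; precision reported as 0")
    return(data.frame(flank = flank, recall = 0, precision = 0, f1 = 0,
                      n_regions = n_reg, n_predicted = 0L))
  }
  ext_start <- pmax(0, true_regions$start - flank)
  ext_end <- true_regions$end + flank
  p <- sort(unique(as.numeric(predicted_nucleotides)))
  hit_region <- vapply(seq_len(n_reg), function(i) {
    any(p >= ext_start[i] & p < ext_end[i])
  }, logical(1))
  recall <- if (n_reg > 0) mean(hit_region) else NA_real_
  in_any <- rep(FALSE, length(p))
  for (i in seq_len(n_reg)) in_any <- in_any | (p >= ext_start[i] & p < ext_end[i])
  precision <- mean(in_any)
  f1 <- if (is.na(recall) || precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  data.frame(flank = flank, recall = recall, precision = precision, f1 = f1,
             n_regions = n_reg, n_predicted = length(p))
}

#' Sequence-only sliding-window energy baseline
#'
#' A dinucleotide-energy stand-in for sequence-only Z-DNA propensity
#' scoring: the per-nucleotide score is the negated mean B-Z transition
#' energy over a centred odd window, min-max scaled to `[0, 1]`, so
#' energetically Z-favourable stretches (alternating purine-pyrimidine,
#' CG-rich) score high.
#'
#' @param sequence DNA character string or `DNAString`.
#' @param table Energy table from [read_energy_table()].
#' @param window Odd window width in nucleotides.
#' @return Numeric score vector of length `nchar(sequence)`, in `[0, 1]`.
#' @export
baseline_energy_score <- function(sequence, table = read_energy_table(),
                                  window = 11) {
  if (window %% 2 == 0) stop("window must be odd")
  e <- energy_channels(sequence, table)$dinucleotide
  L <- length(e)
  if (window > L) stop("window larger than sequence")
  half <- (window - 1) / 2
  cs <- cumsum(c(0, e))
  lo <- pmax(0, seq_len(L) - 1 - half)
  hi <- pmin(L, seq_len(L) + half)
  sc <- -(cs[hi + 1] - cs[lo + 1]) / (hi - lo)
  rng <- range(sc)
  # constant sequence: guard against cumsum round-off masquerading as signal
  if ((rng[2] - rng[1]) <= 1e-9 * max(1, abs(rng[1]))) return(rep(0, L))
  (sc - rng[1]) / (rng[2] - rng[1])
}
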