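test_that("probability averaging is the arithmetic mean, invariant to order", {
  stubs <- lapply(seq(0.1, 0.5, 0.1), function(v) list(chr1 = rep(v, 20)))
  avg <- average_probability_tracks(stubs)
  expect_equal(avg$chr1, rep(0.3, 20))
  expect_length(attr(avg, "provenance"), 5)

  set.seed(31)
  perm <- sample(5)
  avg2 <- average_probability_tracks(stubs[perm])
  expect_equal(avg2$chr1, avg$chr1)
})

test_that("threshold selection maximises F1 over observed candidates, ties low", {
  expect_equal(select_threshold(list(chr1 = c(0.2, 0.6, 0.7)),
                                list(chr1 = c(0, 1, 1))), 0.6)

  # exact probabilities: F1 at the selected threshold is 1
  set.seed(32)
  y <- rbinom(500, 1, 0.2)
  p <- ifelse(y == 1, 0.9, 0.1)
  thr <- select_threshold(list(c1 = p), list(c1 = y))
  expect_equal(zdnascan:::f1_score(p >= thr, y), 1)

  expect_error(select_threshold(list(c1 = runif(10)), list(c1 = rep(0, 10))),
               "no positive")
})

test_that("threshold selection equals the exhaustive sweep oracle", {
  set.seed(33)
  for (i in 1:8) {
    n <- sample(100:800, 1)
    p <- round(runif(n), 2)
    y <- rbinom(n, 1, 0.25)
    if (sum(y) == 0) next
    expect_equal(select_threshold(list(x = p), list(x = y)), threshold_oracle(p, y))
  }
})

test_that("region assembly applies threshold, gap-join and length-filter in order", {
  # two runs separated by a 5 nt gap (< 11) merge and survive
  v <- numeric(60)
  v[1:15] <- 0.9; v[21:35] <- 0.9
  r <- assemble_regions(list(chr1 = v), 0.5)
  expect_equal(r[, c("chrom", "start", "end")],
               data.frame(chrom = "chr1", start = 0, end = 35))

  # a lone 8 nt run is dropped; an 11 nt run is kept (rule is "shorter than")
  v2 <- numeric(60); v2[10:17] <- 0.9
  expect_equal(nrow(assemble_regions(list(chr1 = v2), 0.5)), 0)
  v3 <- numeric(60); v3[10:20] <- 0.9
  r3 <- assemble_regions(list(chr1 = v3), 0.5)
  expect_equal(r3$end - r3$start, 11)

  # a gap of exactly 11 is not merged (rule is "less than")
  v4 <- numeric(80); v4[1:20] <- 0.9; v4[32:51] <- 0.9   # gap = 11
  expect_equal(nrow(assemble_regions(list(chr1 = v4), 0.5)), 2)
  v5 <- numeric(80); v5[1:20] <- 0.9; v5[31:50] <- 0.9   # gap = 10
  expect_equal(nrow(assemble_regions(list(chr1 = v5), 0.5)), 1)

  # thresholding is strictly greater-than
  v6 <- rep(0.5, 30)
  expect_equal(nrow(assemble_regions(list(chr1 = v6), 0.5)), 0)
})

test_that("region assembly equals the dense-scan oracle on long random tracks", {
  set.seed(34)
  for (i in 1:4) {
    v <- round(runif(1e5), 1)
    got <- assemble_regions(list(chr1 = v), 0.7)
    want <- assemble_oracle(v, 0.7)
    expect_equal(got[, c("start", "end")], want, ignore_attr = TRUE)
    # scores are the mean probability over each interval
    if (nrow(got)) {
      expect_equal(got$score[1], mean(v[(got$start[1] + 1):got$end[1]]))
    }
  }
})

test_that("assembly is idempotent and threshold-monotone in coverage", {
  set.seed(35)
  v <- round(runif(5000), 1)
  r1 <- assemble_regions(list(chr1 = v), 0.6)
  # re-encode the calls as a binary indicator and re-assemble
  ind <- encode_labels(r1[, c("start", "end")], 5000)
  r2 <- assemble_regions(list(chr1 = ind), 0.5)
  expect_equal(r1[, c("start", "end")], r2[, c("start", "end")])

  cov_at <- function(thr) {
    r <- assemble_regions(list(chr1 = v), thr, join_gap = 11, min_length = 0)
    sum(r$end - r$start)
  }
  expect_true(all(diff(vapply(seq(0.9, 0.1, -0.2), cov_at, numeric(1))) >= 0))
})

test_that("combining annotations unions intervals and merges near neighbours", {
  a <- region_set("chr1", c(0, 100), c(20, 130))
  b <- region_set("chr1", 50, 70)
  comb <- combine_annotations(a, b)
  expect_equal(nrow(comb), 3)

  close_b <- region_set("chr1", 25, 40)  # 5 bp from a's first region
  comb2 <- combine_annotations(a, close_b)
  expect_equal(comb2$start[1], 0)
  expect_equal(comb2$end[1], 40)

  expect_equal(combine_annotations(a, a[0, ]), a[, c("chrom", "start", "end")],
               ignore_attr = TRUE)

  # exactly-10 bp separation stays separate (rule is "closer than")
  c10 <- region_set("chr1", 30, 45)
  expect_equal(nrow(combine_annotations(region_set("chr1", 0, 20), c10)), 2)
})

test_that("cross-fold annotation trains one model per fold and averages them", {
  fx <- tiny_fixture()
  ws <- make_folds(fx$ws, k = 5, seed = 6)
  spec <- model_spec(conv_block(1, 2, 3), dense_block(1))
  track <- cross_fold_annotate(ws, spec, fx$store, fx$labels,
                               control = zdna_control(epochs = 3, batch_size = 4),
                               seed = 7)
  expect_length(attr(track, "provenance"), 5)
  expect_named(attr(track, "models"), paste0("fold", 1:5))
  expect_length(track$chr1, 20000)
  expect_true(all(unlist(track) >= 0 & unlist(track) <= 1))

  no_folds <- fx$ws
  expect_error(cross_fold_annotate(no_folds, spec, fx$store, fx$labels),
               "fold assignment")
})

test_that("a trained model recovers the planted regions end to end", {
  # high signal-to-noise fixture: no track dropout
  sim <- synth_generate(synth_config(
    n_chromosomes = 2, chromosome_length = 20000, n_regions = 6,
    n_informative_tracks = 2, n_noise_tracks = 2,
    track_flip_probability = 0, seed = 13
  ))
  store <- build_feature_store(sim$genome, sim$tracks)
  labels <- synth_labels(sim)
  ws <- tile_and_select(labels, 1000, 3, seed = 14)
  spec <- model_spec(conv_block(1, 3, 5), dense_block(1))
  fit <- zdna_fit(spec, ws, store, labels,
                  control = zdna_control(epochs = 30, batch_size = 4), seed = 15)
  track <- structure(lapply(names(store$chroms), function(ch) predict(fit, store, ch)),
                     names = names(store$chroms))
  thr <- select_threshold(track, labels)
  calls <- assemble_regions(track, thr)
  called <- unlist(lapply(names(labels), function(ch) {
    encode_labels(calls[calls$chrom == ch, c("start", "end")], 20000)
  }))
  truth <- unlist(lapply(labels, track_dense), use.names = FALSE)
  jaccard <- sum(called & truth) / sum(called | truth)
  expect_gt(jaccard, 0.8)
})

test_that("probability tracks round-trip through bedGraph", {
  set.seed(36)
  track <- list(chr1 = round(runif(500), 2), chr2 = rep(0.25, 100))
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_probability_bedgraph(track, path)
  back <- read_bedgraph_track(path, c(chr1 = 500, chr2 = 100))
  expect_equal(track_dense(back$chr1), track$chr1)
  expect_equal(track_dense(back$chr2), track$chr2)
})
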