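test_that("one-hot encoding is exact and handles ambiguity codes", {
  m <- one_hot_encode("ACGT")
  expect_equal(m, diag(4), ignore_attr = TRUE)
  expect_equal(rownames(m), c("A", "C", "G", "T"))

  n <- one_hot_encode("NN")
  expect_equal(colSums(n), c(0, 0))

  gc <- one_hot_encode("GCGC")
  expect_equal(gc["G", ], c(1, 0, 1, 0))
  expect_equal(gc["C", ], c(0, 1, 0, 1))

  expect_equal(one_hot_encode("acgt"), one_hot_encode("ACGT"))
  expect_error(one_hot_encode("ACXT"), "non-IUPAC")
})

test_that("argmax decoding inverts one-hot encoding at unambiguous positions", {
  set.seed(1)
  s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  m <- one_hot_encode(s)
  decoded <- rownames(m)[apply(m, 2, which.max)]
  expect_equal(paste(decoded, collapse = ""), s)
})

test_that("energy channels follow the dinucleotide table with last-position repeat", {
  tab <- read_energy_table()
  e <- energy_channels("GC", tab)
  expect_equal(e$dinucleotide, rep(tab$dinucleotide[["GC"]], 2))

  e4 <- energy_channels("GCGC", tab)
  expect_equal(e4$dinucleotide,
               c(tab$dinucleotide[["GC"]], tab$dinucleotide[["CG"]],
                 tab$dinucleotide[["GC"]], tab$dinucleotide[["GC"]]))

  expect_equal(e4$bz_junction, rep(tab$bz_junction, 4))
  expect_equal(e4$zz_junction, rep(tab$zz_junction, 4))

  # ambiguous steps get the least Z-favourable energy
  en <- energy_channels("GNC", tab)
  expect_equal(en$dinucleotide[1:2], rep(max(tab$dinucleotide), 2))
})

test_that("the shipped energy table is complete and incomplete tables are rejected", {
  tab <- read_energy_table()
  expect_length(tab$dinucleotide, 16)
  expect_true(all(is.finite(tab$dinucleotide)))
  expect_true(is.finite(tab$bz_junction) && is.finite(tab$zz_junction))
  # alternating purine-pyrimidine steps must be the Z-cheapest
  expect_equal(sort(names(sort(tab$dinucleotide)[1:2])), c("CG", "GC"))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# bz_junction\t5", "# zz_junction\t4",
               "dinucleotide\tenergy", "GC\t0.7"), bad)
  expect_error(read_energy_table(bad), "incomplete")
})

test_that("marker aggregation is element-wise OR, order-independent", {
  a <- as_sparse_track(c(0, 1, 0))
  b <- as_sparse_track(c(1, 1, 0))
  expect_equal(track_dense(aggregate_marker(list(a, b))), c(1, 1, 0))
  expect_equal(track_dense(aggregate_marker(list(a))), c(0, 1, 0))

  set.seed(2)
  tracks <- lapply(1:3, function(i) as_sparse_track(rbinom(60, 1, 0.2)))
  want <- as.numeric(Reduce(`|`, lapply(tracks, track_dense)))
  expect_equal(track_dense(aggregate_marker(tracks)), want)
  expect_equal(track_dense(aggregate_marker(rev(tracks))), want)

  expect_error(aggregate_marker(list()), "at least one")
  expect_error(aggregate_marker(list(a, as_sparse_track(c(0, 1)))), "equal length")
})

test_that("unit scaling maps min to 0 and max to 1 and is idempotent", {
  expect_equal(track_dense(scale_channel(as_sparse_track(c(2, 4, 6)))),
               c(0, 0.5, 1))
  expect_equal(track_dense(scale_channel(sparse_track(5, NULL, 3))), rep(0, 5))
  bin <- as_sparse_track(c(0, 1, 1, 0))
  expect_equal(track_dense(scale_channel(bin)), c(0, 1, 1, 0))

  set.seed(3)
  t <- as_sparse_track(sample(c(-2, 0, 5, 9), 50, replace = TRUE))
  once <- scale_channel(t)
  expect_true(all(track_dense(once) >= 0 & track_dense(once) <= 1))
  expect_equal(track_dense(scale_channel(once)), track_dense(once))
})

test_that("label encoding marks exactly the covered nucleotides, merging overlaps", {
  expect_equal(encode_labels(data.frame(start = 2, end = 5), 7),
               c(0, 0, 1, 1, 1, 0, 0))
  expect_equal(encode_labels(data.frame(start = numeric(0), end = numeric(0)), 4),
               rep(0, 4))
  expect_equal(encode_labels(data.frame(start = c(0, 2), end = c(3, 4)), 6),
               c(1, 1, 1, 1, 0, 0))
  expect_error(encode_labels(data.frame(start = 2, end = 9), 7), "outside")
})

test_that("feature matrices carry OHE, energy and marker channels in fixed order", {
  fx <- tiny_fixture()
  fm <- fx$store$chroms$chr1
  n_markers <- length(fx$sim$tracks)
  expect_equal(length(fm$channels), 4 + 3 + n_markers)
  expect_equal(names(fm$channels)[1:7],
               c("seq_A", "seq_C", "seq_G", "seq_T", "energy_dinucleotide",
                 "energy_bz_junction", "energy_zz_junction"))
  expect_equal(unname(fm$classes[1:4]), rep("seq", 4))
  # identical channel sets across chromosomes
  expect_identical(names(fx$store$chroms$chr1$channels),
                   names(fx$store$chroms$chr2$channels))
  # all channels in [0,1]
  for (ch in fm$channels) {
    v <- track_slice(ch, 0, 500)
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("window_matrix equals per-channel dense slices", {
  fx <- tiny_fixture()
  X <- window_matrix(fx$store, "chr2", 100, 400)
  expect_equal(dim(X), c(300, length(fx$store$channel_names)))
  for (nm in c("seq_G", "inf_01", "energy_dinucleotide")) {
    expect_equal(X[, nm],
                 track_slice(fx$store$chroms$chr2$channels[[nm]], 100, 400))
  }
})

test_that("blacklisted intervals are removed from marker channels", {
  genome <- c(chr1 = paste(rep("ACGT", 50), collapse = ""))
  markers <- list(m1 = data.frame(chrom = "chr1", start = 10, end = 60))
  bl <- data.frame(chrom = "chr1", start = 30, end = 40)
  store <- build_feature_store(genome, markers, energy_table = NULL, blacklist = bl)
  v <- track_dense(store$chroms$chr1$channels$m1)
  expect_equal(sum(v), 40)
  expect_true(all(v[31:40] == 0))
})
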