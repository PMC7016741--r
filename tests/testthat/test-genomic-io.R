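# Window extraction, summarization and encoding.

test_that("interval merging maps overlapping records to per-base means", {
  # single record: covered bases take its value, the rest 0
  v <- merge_intervals_to_per_base(data.frame(start = 0, end = 10, value = 3), 20)
  expect_equal(v, c(rep(3, 10), rep(0, 10)))
  # overlap: base 7 covered by both (0,10,2) and (5,15,4) -> mean 3
  v <- merge_intervals_to_per_base(
    data.frame(start = c(0, 5), end = c(10, 15), value = c(2, 4)), 20)
  expect_equal(v[8], 3)        # base 7, 0-based
  expect_equal(v[3], 2)
  expect_equal(v[13], 4)
  expect_equal(v[16], 0)
})

test_that("interval merging agrees with brute-force accumulation on random input", {
  set.seed(31)
  L <- 500
  recs <- data.frame(start = sample(0:(L - 20), 50, replace = TRUE))
  recs$end <- recs$start + sample(1:20, 50, replace = TRUE)
  recs$value <- round(stats::runif(50, -2, 5), 3)
  expect_equal(merge_intervals_to_per_base(recs, L), brute_force_per_base(recs, L))
})

test_that("interval merging rejects out-of-bounds records", {
  expect_error(merge_intervals_to_per_base(data.frame(start = -1, end = 5, value = 1), 10),
               "negative")
  expect_error(merge_intervals_to_per_base(data.frame(start = 0, end = 11, value = 1), 10),
               "exceeds")
})

test_that("extract_window centers on floor((start+end)/2) and errors out of bounds", {
  trk <- seq_len(10000) - 1          # track value = 0-based position
  # even-length element: center 5005, window [4005, 6005)
  w <- extract_window(trk, 5000, 5010, 2000)
  expect_equal(length(w), 2000)
  expect_equal(w[1], 4005)
  expect_equal(w[2000], 6004)
  # odd-length element: center = floor((5000+5011)/2) = 5005 as well
  w_odd <- extract_window(trk, 5000, 5011, 2000)
  expect_equal(w_odd[1], 4005)
  # near the start the window leaves the chromosome
  expect_error(extract_window(trk, 1000, 1010, 3000), "outside the chromosome")
  # constant track gives constant window
  expect_equal(unique(extract_window(rep(2.5, 10000), 5000, 5010, 2000)), 2.5)
})

test_that("sliding-window mean yields the published CNN-format dimensions", {
  expect_equal(nrow(sliding_window_mean(matrix(0, 3000, 22), 50, 10)), 296)
  expect_equal(nrow(sliding_window_mean(matrix(0, 2000, 22), 50, 10)), 196)
  # L == window: single row equal to the column means
  m <- matrix(stats::rnorm(50 * 3), 50, 3)
  expect_equal(as.vector(sliding_window_mean(m, 50, 10)), colMeans(m))
})

test_that("sliding-window mean agrees with a naive loop oracle", {
  set.seed(5)
  m <- matrix(stats::rnorm(200 * 4), 200, 4)
  got <- sliding_window_mean(m, 50, 10)
  W <- (200 - 50) %/% 10 + 1
  naive <- t(vapply(seq_len(W), function(w) {
    colMeans(m[((w - 1) * 10 + 1):((w - 1) * 10 + 50), , drop = FALSE])
  }, numeric(4)))
  expect_equal(got, naive, tolerance = 1e-12)
  expect_error(sliding_window_mean(matrix(0, 10, 2), 50, 10), "window larger")
})

test_that("region mean is the per-track mean and concatenates to 44 features", {
  m <- matrix(stats::rnorm(3000 * 22), 3000, 22)
  expect_equal(region_mean(m), colMeans(m), tolerance = 1e-12)
  expect_equal(region_mean(matrix(4, 10, 3)), rep(4, 3))
  expect_length(c(region_mean(m), region_mean(matrix(0, 2000, 22))), 44)
  expect_error(region_mean(matrix(0, 0, 3)), "empty")
})

test_that("sliding window with window = step = L reduces to the region mean", {
  m <- matrix(stats::rnorm(120 * 5), 120, 5)
  expect_equal(as.vector(sliding_window_mean(m, 120, 120)), region_mean(m),
               tolerance = 1e-12)
})

test_that("one-hot encoding follows the A/C/G/T channel order with N as zeros", {
  expect_equal(unname(one_hot_encode("ACGT")), diag(4))
  expect_equal(one_hot_encode("NN"), matrix(0L, 2, 4, dimnames = list(NULL, c("A","C","G","T"))))
  expect_error(one_hot_encode("ACGU"), "outside")
  # case-insensitive, and every non-N row sums to 1
  set.seed(9)
  s <- paste(sample(c("a", "c", "G", "T", "N"), 3000, replace = TRUE), collapse = "")
  oh <- one_hot_encode(s)
  expect_true(all(rowSums(oh) %in% c(0, 1)))
  expect_equal(rowSums(oh) == 0, strsplit(toupper(s), "")[[1]] == "N")
})

test_that("central crop takes the middle rows and preserves planted content", {
  oh <- one_hot_encode(paste(rep("A", 3000), collapse = ""))
  oh[, 1] <- seq_len(3000)           # tag rows by position
  cr <- central_crop(oh, 600)
  expect_equal(unname(cr[1, 1]), 1201)   # offset floor((3000-600)/2) = 1200
  expect_equal(unname(cr[600, 1]), 1800)
  expect_equal(central_crop(oh, 3000), oh)
  expect_error(central_crop(oh, 3001), "larger")
  # a motif in the center survives cropping; one at the edge does not
  seq_mid <- paste0(strrep("A", 1495), "CGCGCGCGCG", strrep("A", 1495))
  seq_edge <- paste0("CGCGCGCGCG", strrep("A", 2990))
  has_motif <- function(oh) any(oh[, "C"] == 1)
  expect_true(has_motif(central_crop(one_hot_encode(seq_mid), 600)))
  expect_false(has_motif(central_crop(one_hot_encode(seq_edge), 600)))
})

test_that("sequence matching returns the unique exact hit or none", {
  ref <- c(chr1 = "ACGTACGTACGTACGT")
  expect_equal(match_sequence("chr1", 4, 12, ref, c("TTTT", "ACGTACGT", "GGGG")), 2L)
  expect_true(is.na(match_sequence("chr1", 4, 12, ref, character(0))))
  # one-base perturbation: no match
  expect_true(is.na(match_sequence("chr1", 4, 12, ref, c("ACGTACGA"))))
  expect_error(match_sequence("chr1", 4, 12, ref, c("ACGTACGT", "ACGTACGT")),
               "ambiguous")
})

test_that("bedGraph round trip reproduces per-base tracks exactly", {
  # a micro dataset: per-base noise defeats run-length compression, so the
  # round-trip check uses few pairs and tracks to keep file sizes sane
  d <- generate_dataset(synthetic_config(n_pairs = 12, imbalance_ratio = 5,
                                         n_chromosomes = 3, n_tracks = 2,
                                         seed = 23))
  dir <- withr::local_tempdir()
  write_tracks_bedgraph(d, dir)
  back <- tracks_from_bedgraph(dir, d$chrom_lengths, d$assays)
  for (ch in names(d$tracks)) {
    expect_equal(back[[ch]], d$tracks[[ch]], tolerance = 1e-10)
  }
})

test_that("pair tables round trip and reject inter-chromosomal pairs", {
  d <- small_dataset()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pair_table(d$pairs, path)
  back <- read_pair_table(path)
  expect_equal(back$enh_start, d$pairs$enh_start)
  expect_equal(back$label, d$pairs$label)
  expect_equal(back$enhancer_id, d$pairs$enhancer_id)
  bad <- utils::read.table(path, header = TRUE, sep = "\t")
  bad$chrom2[1] <- "chr99"
  path2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(bad, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_pair_table(path2), "intra-chromosomal")
})

test_that("FASTA round trip preserves chromosome sequences", {
  skip_if_not_installed("Biostrings")
  d <- small_dataset()
  path <- withr::local_tempfile(fileext = ".fasta")
  write_sequences_fasta(d, path)
  back <- read_sequences_fasta(path)
  expect_equal(sort(names(back)), sort(names(d$sequences)))
  expect_equal(back[["chr1"]], d$sequences[["chr1"]])
})

test_that("featurization produces consistent formats for the same pairs", {
  d <- small_dataset()
  Xm <- featurize_pairs(d, "epi_mean")
  expect_equal(dim(Xm), c(nrow(d$pairs), 44))
  Xc <- featurize_pairs(d, "epi_cnn")
  expect_equal(dim(Xc$enhancer), c(nrow(d$pairs), 296, 22))
  expect_equal(dim(Xc$promoter), c(nrow(d$pairs), 196, 22))
  # CNN-format window means average back to the region mean
  i <- 3
  expect_equal(mean(Xc$enhancer[i, , 1]), unname(Xm[i, 1]), tolerance = 0.02)
  Xs <- featurize_pairs(d, "sequence_crop")
  expect_equal(dim(Xs$enhancer), c(nrow(d$pairs), 600, 4))
  expect_equal(dim(Xs$promoter), c(nrow(d$pairs), 400, 4))
  expect_true(all(apply(Xs$enhancer[1, , ], 1, sum) == 1))
})
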