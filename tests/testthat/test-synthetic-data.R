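# Synthetic dataset generator: determinism, imbalance, duplication,
# chromosome structure, planted signal and the leak feature.

test_that("identical configs give byte-identical datasets", {
  d1 <- generate_dataset(synthetic_config(n_pairs = 60, seed = 42))
  d2 <- generate_dataset(synthetic_config(n_pairs = 60, seed = 42))
  expect_identical(d1$pairs, d2$pairs)
  expect_identical(d1$tracks, d2$tracks)
  expect_identical(d1$sequences, d2$sequences)
  d3 <- generate_dataset(synthetic_config(n_pairs = 60, seed = 43))
  expect_false(identical(d3$pairs, d1$pairs))
})

test_that("the realized class balance matches the configured imbalance", {
  d <- generate_dataset(synthetic_config(n_pairs = 2100, imbalance_ratio = 20,
                                         seed = 1))
  n_pos <- sum(d$pairs$label)
  expect_true(abs(n_pos - 100) <= 20)
  # and within 3 binomial SDs of the target fraction
  p0 <- 1 / 21
  expect_lt(abs(n_pos / 2100 - p0), 3 * sqrt(p0 * (1 - p0) / 2100) + 1e-9)
  expect_error(generate_dataset(synthetic_config(n_pairs = 10, imbalance_ratio = 20)),
               "cannot realize ratio")
})

test_that("duplication_factor 1 gives distinct enhancers; > 1 reuses them", {
  d1 <- generate_dataset(synthetic_config(n_pairs = 100, duplication_factor = 1,
                                          seed = 2))
  expect_equal(anyDuplicated(d1$pairs$enhancer_id), 0)
  d5 <- generate_dataset(synthetic_config(n_pairs = 200, duplication_factor = 5,
                                          seed = 2))
  reuse <- mean(table(d5$pairs$enhancer_id))
  expect_gt(reuse, 2.5)     # mean pairs per enhancer ~ duplication factor
})

test_that("pairs are intra-chromosomal, distal and inside window bounds", {
  d <- small_dataset()
  p <- d$pairs
  ce <- (p$enh_start + p$enh_end) %/% 2
  cp <- (p$prom_start + p$prom_end) %/% 2
  expect_true(all(abs(ce - cp) > 10000))
  half_e <- d$config$enhancer_len %/% 2
  half_p <- d$config$promoter_len %/% 2
  lens <- d$chrom_lengths[p$chrom]
  expect_true(all(ce - half_e >= 0 & ce + half_e <= lens))
  expect_true(all(cp - half_p >= 0 & cp + half_p <= lens))
  expect_setequal(unique(p$chrom), names(d$chrom_lengths)[table(factor(p$chrom, names(d$chrom_lengths))) > 0])
})

test_that("planted epigenomic effect separates classes in the signal tracks", {
  d <- small_dataset()      # epi_effect = 1 = 2 * noise_sd
  X <- featurize_pairs(d, "epi_mean")
  y <- attr(X, "labels")
  sig <- d$signal_tracks[1]
  gap <- mean(X[y == 1, sig]) - mean(X[y == 0, sig])
  expect_gt(gap, 0.5)       # planted shift of 1 on the signal tracks
  # non-signal tracks carry no shift
  ns <- max(d$signal_tracks) + 1
  expect_lt(abs(mean(X[y == 1, ns]) - mean(X[y == 0, ns])), 0.5)
})

test_that("a null configuration carries no label signal in the features", {
  d0 <- generate_dataset(synthetic_config(n_pairs = 210, epi_effect = 0,
                                          seq_motif_rate = 0, seed = 5))
  X <- featurize_pairs(d0, "epi_mean")
  y <- attr(X, "labels")
  # univariate AUROC of every feature stays near chance
  aucs <- apply(X, 2, function(col) auroc(col, y))
  se <- auroc_null_se(sum(y == 1), sum(y == 0))
  expect_true(all(abs(aucs - 0.5) < 4 * se))
})

test_that("the planted motif lands in the central crop of positive pairs", {
  dm <- generate_dataset(synthetic_config(n_pairs = 84, imbalance_ratio = 5,
                                          seq_motif_rate = 1, seed = 11))
  Xs <- featurize_pairs(dm, "sequence_crop")
  y <- attr(Xs, "labels")
  motif <- epiholdout:::MOTIF_10MER
  has_motif <- function(oh) {
    s <- paste(c("A", "C", "G", "T")[apply(oh, 1, which.max)], collapse = "")
    grepl(motif, s, fixed = TRUE)
  }
  hit_pos <- mean(vapply(which(y == 1), function(i) has_motif(Xs$enhancer[i, , ]), logical(1)))
  hit_neg <- mean(vapply(which(y == 0), function(i) has_motif(Xs$enhancer[i, , ]), logical(1)))
  expect_gt(hit_pos, 0.9)
  expect_lt(hit_neg, 0.3)   # background hits are rare
})

test_that("plant_leak_feature is identity at 0, errors below 0, and fingerprints elements", {
  d <- small_dataset()
  expect_error(plant_leak_feature(d, -1), ">= 0")
  expect_identical(plant_leak_feature(d, 0), d)
  dl <- plant_leak_feature(d, 2)
  expect_equal(dl$leak_strength, 2)
  # pairs sharing an enhancer share the offset: their enhancer-mean features
  # move by the same amount
  X0 <- featurize_pairs(d, "epi_mean")
  X1 <- featurize_pairs(dl, "epi_mean")
  shift <- X1[, 1] - X0[, 1]
  dup_id <- names(which(table(d$pairs$enhancer_id) >= 2))[1]
  members <- which(d$pairs$enhancer_id == dup_id)
  expect_lt(stats::sd(shift[members]), 1e-8)
  expect_gt(stats::sd(shift), 0.5)   # distinct elements got distinct offsets
})
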