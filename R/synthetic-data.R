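# Synthetic EPI benchmark generator: datasets with the statistical and
# structural properties the chromosome-held-out analysis assumes -- planted
# class-dependent epigenomic signal, ~1:20 class imbalance, enhancer/promoter
# reuse across pairs (label-clustered within elements), per-pair chromosome
# assignment over a fixed 23-chromosome universe, and an optional planted
# element-memorization leak.

ASSAYS_22 <- c("H3K27ac", "H3K27me3", "H3K4me1", "H2AZ", "H3K4me2", "H3K9ac",
               "H3K4me3", "H4K20me1", "H3K79me2", "H3K36me3", "H3K9me3",
               "POLR2A", "CTCF", "EP300", "MAFK", "MAZ", "MXI1", "RAD21",
               "RCOR1", "RFX5", "DNase", "Methylation")

MOTIF_10MER <- "TGCATGACGT"   # fixed planted k-mer

#' Synthetic dataset configuration
#'
#' The defaults are the study conditions: ~1:20 positive:negative imbalance,
#' 23 named chromosomes (chr1-chr22, chrX), 22 epigenomic tracks, 3000 bp
#' enhancer and 2000 bp promoter windows.
#'
#' @param n_pairs Number of enhancer-promoter candidate pairs.
#' @param imbalance_ratio Negatives per positive (20).
#' @param n_chromosomes Number of chromosomes (23: chr1-chr22 and chrX).
#' @param n_tracks Number of epigenomic assays (22).
#' @param enhancer_len,promoter_len Extraction window widths in bp.
#' @param epi_effect Planted per-base mean shift in the signal tracks inside
#'   positive elements' windows.
#' @param seq_motif_rate Probability that a positive pair's elements carry
#'   the planted 10-mer motif in their central crop region.
#' @param duplication_factor Mean number of pairs sharing one enhancer
#'   (>= 1); 1 means every pair has its own elements.
#' @param noise_sd Per-base Gaussian noise scale before 50-bp smoothing.
#' @param seed Random seed; identical configs give byte-identical datasets.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_pairs, imbalance_ratio = 20, n_chromosomes = 23,
                             n_tracks = 22, enhancer_len = 3000,
                             promoter_len = 2000, epi_effect = 1,
                             seq_motif_rate = 0, duplication_factor = 1,
                             noise_sd = 0.5, seed = 1) {
  stopifnot(n_pairs >= 1, imbalance_ratio >= 1, n_chromosomes >= 3,
            n_tracks >= 1, enhancer_len >= 100, promoter_len >= 100,
            epi_effect >= 0, seq_motif_rate >= 0, seq_motif_rate <= 1,
            duplication_factor >= 1, noise_sd >= 0)
  structure(list(n_pairs = as.integer(n_pairs),
                 imbalance_ratio = imbalance_ratio,
                 n_chromosomes = as.integer(n_chromosomes),
                 n_tracks = as.integer(n_tracks),
                 enhancer_len = as.integer(enhancer_len),
                 promoter_len = as.integer(promoter_len),
                 epi_effect = epi_effect, seq_motif_rate = seq_motif_rate,
                 duplication_factor = duplication_factor,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

default_chromosomes <- function(n) {
  base <- c(paste0("chr", 1:22), "chrX")
  if (n <= 23) base[seq_len(n)] else c(base, paste0("chrE", seq_len(n - 23)))
}

# fixed relative sizes: proportional to reversed name order, so chr1 carries
# the most pairs and the weighted AUROC aggregation is exercised
chrom_weights <- function(n) {
  w <- rev(seq_len(n)) + n / 2
  w / sum(w)
}

smooth_ma <- function(x, k = 50) {
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2, circular = TRUE))
}

#' Generate a synthetic EPI dataset
#'
#' Builds per-chromosome reference sequences and 22 per-base signal tracks
#' (track-specific baseline plus 50-bp-smoothed Gaussian noise, mimicking the
#' base-to-base autocorrelation of real coverage), draws enhancer and
#' promoter elements from per-chromosome pools of size about
#' `n_pairs / duplication_factor` so elements recur across pairs, forms
#' same-chromosome pairs at center distance > 10 kb, and assigns positives at
#' the enhancer-element level (whole elements switch on) until the
#' 1/(1+imbalance_ratio) positive share is reached. Positive elements get a
#' mean shift of `epi_effect` in the first third of the tracks across their
#' extraction window, and with probability `seq_motif_rate` a fixed 10-mer
#' planted in the central crop region of both windows.
#'
#' @param config A [synthetic_config()].
#' @return An `ep_dataset`: list with `pairs` (data frame), `tracks` (named
#'   list of length x tracks matrices), `sequences` (named character),
#'   `chrom_lengths`, `assays`, `signal_tracks` (indices of shifted tracks)
#'   and `config`.
#' @examples
#' d <- generate_dataset(synthetic_config(n_pairs = 60, seed = 1))
#' table(d$pairs$label)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_pairs < (1 + config$imbalance_ratio))
    stop("cannot realize ratio: n_pairs < 1 + imbalance_ratio")
  set.seed(config$seed)
  chroms <- default_chromosomes(config$n_chromosomes)
  w <- chrom_weights(config$n_chromosomes)
  pair_chrom <- sample(chroms, config$n_pairs, replace = TRUE, prob = w)
  npc <- table(factor(pair_chrom, levels = chroms))

  max_win <- max(config$enhancer_len, config$promoter_len)
  pools_e <- list(); pools_p <- list()
  chrom_lengths <- integer(0)
  half <- max_win %/% 2 + 2L
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    n_here <- as.integer(npc[[ch]])
    pe <- max(1L, as.integer(round(max(n_here, 1) / config$duplication_factor)))
    pp <- pe
    # length scales with the pair count (not the pool size), so element
    # density -- and window overlap -- stays comparable across duplication
    # factors
    len <- as.integer(2L * half + 20000L + 400L * max(n_here, pe + pp))
    chrom_lengths[ch] <- len
    centers_e <- sample(seq.int(half, len - half), pe, replace = TRUE)
    centers_p <- sample(seq.int(half, len - half), pp, replace = TRUE)
    el <- sample(200:1000, pe, replace = TRUE)
    pl <- sample(200:1000, pp, replace = TRUE)
    pools_e[[ch]] <- data.frame(center = centers_e, start = centers_e - el %/% 2,
                                end = centers_e - el %/% 2 + el)
    pools_p[[ch]] <- data.frame(center = centers_p, start = centers_p - pl %/% 2,
                                end = centers_p - pl %/% 2 + pl)
  }

  # pair assembly: round-robin element assignment realizes the duplication
  # factor exactly in expectation (and distinct elements when it is 1)
  pairs <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    n_here <- as.integer(npc[[ch]])
    if (n_here == 0) next
    pe <- nrow(pools_e[[ch]]); pp <- nrow(pools_p[[ch]])
    ei <- sample(rep_len(seq_len(pe), n_here))
    pi <- sample(rep_len(seq_len(pp), n_here))
    # enforce >10 kb center distance: prefer another pool promoter, else
    # re-draw the chosen promoter element's position
    len <- chrom_lengths[[ch]]
    for (j in seq_len(n_here)) {
      ce <- pools_e[[ch]]$center[ei[j]]
      if (abs(ce - pools_p[[ch]]$center[pi[j]]) > 10000) next
      cand <- which(abs(ce - pools_p[[ch]]$center) > 10000)
      if (length(cand) > 0) {
        pi[j] <- if (length(cand) == 1) cand else sample(cand, 1)
      } else {
        ok_pos <- setdiff(seq.int(half, len - half),
                          seq.int(ce - 10000L, ce + 10000L))
        if (length(ok_pos) == 0) stop("chromosome ", ch,
                                      " too short for a >10 kb pair")
        newc <- if (length(ok_pos) == 1) ok_pos else sample(ok_pos, 1)
        plen_j <- pools_p[[ch]]$end[pi[j]] - pools_p[[ch]]$start[pi[j]]
        pools_p[[ch]]$center[pi[j]] <- newc
        pools_p[[ch]]$start[pi[j]] <- newc - plen_j %/% 2
        pools_p[[ch]]$end[pi[j]] <- newc - plen_j %/% 2 + plen_j
      }
    }
    pairs[[ci]] <- data.frame(
      chrom = ch,
      enh_start = pools_e[[ch]]$start[ei], enh_end = pools_e[[ch]]$end[ei],
      prom_start = pools_p[[ch]]$start[pi], prom_end = pools_p[[ch]]$end[pi],
      enhancer_id = paste0(ch, "_E", ei), promoter_id = paste0(ch, "_P", pi),
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs)
  pairs <- pairs[sample(nrow(pairs)), ]
  rownames(pairs) <- NULL

  # element-level positive assignment: whole enhancers switch on, so labels
  # cluster within elements (the reuse structure real EPI data has); this is
  # what makes element memorization predictive under random splits
  n_pos <- max(1L, as.integer(round(config$n_pairs / (1 + config$imbalance_ratio))))
  pairs$label <- 0L
  eids <- unique(pairs$enhancer_id)
  for (eid in sample(eids)) {
    need <- n_pos - sum(pairs$label)
    if (need <= 0) break
    members <- which(pairs$enhancer_id == eid)
    pairs$label[members[seq_len(min(need, length(members)))]] <- 1L
  }

  # sequences: uniform background, then motif planting for positive elements
  sequences <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), chrom_lengths[[ch]], replace = TRUE),
          collapse = "")
  }, character(1))
  names(sequences) <- chroms

  if (config$seq_motif_rate > 0) {
    pos <- pairs[pairs$label == 1L, ]
    done <- character(0)
    for (j in seq_len(nrow(pos))) {
      key <- pos$enhancer_id[j]
      if (key %in% done) next
      done <- c(done, key)
      if (stats::runif(1) > config$seq_motif_rate) next
      ch <- pos$chrom[j]
      for (role in c("enh", "prom")) {
        wlen <- if (role == "enh") config$enhancer_len else config$promoter_len
        clen <- if (role == "enh") min(600L, wlen) else min(400L, wlen)
        b <- window_bounds(pos[[paste0(role, "_start")]][j],
                           pos[[paste0(role, "_end")]][j], wlen)
        c0 <- b["lo"] + (wlen - clen) %/% 2          # central crop start
        off <- c0 + sample.int(clen - nchar(MOTIF_10MER), 1)
        substr(sequences[[ch]], off + 1L, off + nchar(MOTIF_10MER)) <- MOTIF_10MER
      }
    }
  }

  # per-base tracks: baseline + smoothed noise, then planted element effects
  assays <- if (config$n_tracks == 22) ASSAYS_22
            else sprintf("track%02d", seq_len(config$n_tracks))
  baselines <- stats::runif(config$n_tracks, 0.5, 1.5)
  signal_tracks <- seq_len(max(1L, round(config$n_tracks / 3)))
  tracks <- lapply(chroms, function(ch) {
    L <- chrom_lengths[[ch]]
    m <- vapply(seq_len(config$n_tracks), function(a) {
      baselines[a] + smooth_ma(stats::rnorm(L, 0, config$noise_sd))
    }, numeric(L))
    colnames(m) <- assays
    m
  })
  names(tracks) <- chroms

  if (config$epi_effect > 0) {
    pos <- pairs[pairs$label == 1L, ]
    for (role in c("enh", "prom")) {
      wlen <- if (role == "enh") config$enhancer_len else config$promoter_len
      ids <- paste0(pos$chrom, ":", pos[[paste0(role, "_start")]])
      keep <- !duplicated(ids)
      for (j in which(keep)) {
        ch <- pos$chrom[j]
        b <- window_bounds(pos[[paste0(role, "_start")]][j],
                           pos[[paste0(role, "_end")]][j], wlen)
        idx <- seq.int(b["lo"] + 1L, b["hi"])
        tracks[[ch]][idx, signal_tracks] <-
          tracks[[ch]][idx, signal_tracks] + config$epi_effect
      }
    }
  }

  structure(list(pairs = pairs, tracks = tracks, sequences = sequences,
                 chrom_lengths = chrom_lengths, assays = assays,
                 signal_tracks = signal_tracks, config = config),
            class = "ep_dataset")
}

#' @export
print.ep_dataset <- function(x, ...) {
  cat(sprintf("<ep_dataset> %d pairs (%d positive) on %d chromosomes, %d tracks\n",
              nrow(x$pairs), sum(x$pairs$label), length(x$chrom_lengths),
              length(x$assays)))
  invisible(x)
}

#' Plant an element-memorization leak
#'
#' Adds one random per-enhancer offset (a "fingerprint", i.i.d. normal with
#' standard deviation `strength`) to all tracks across each enhancer's
#' extraction window. Every pair sharing an enhancer therefore shares the
#' offset. Because labels cluster within enhancer elements (see
#' [generate_dataset()]) while the offsets themselves carry no systematic
#' label information, a model can exploit the leak only by memorizing
#' element identity -- which inflates random-split performance and does
#' nothing under chromosome-held-out splits.
#'
#' @param dataset An `ep_dataset`.
#' @param strength Offset standard deviation (>= 0); 0 returns the dataset
#'   unchanged.
#' @return The dataset with modified tracks and `leak_strength` recorded.
#' @export
plant_leak_feature <- function(dataset, strength) {
  if (strength < 0) stop("leak strength must be >= 0")
  if (strength == 0) return(dataset)
  set.seed(dataset$config$seed + 104729L)      # deterministic given the dataset
  pr <- dataset$pairs
  ids <- unique(pr$enhancer_id)
  offs <- stats::rnorm(length(ids), 0, strength)
  names(offs) <- ids
  wlen <- dataset$config$enhancer_len
  seen <- character(0)
  for (j in seq_len(nrow(pr))) {
    eid <- pr$enhancer_id[j]
    if (eid %in% seen) next
    seen <- c(seen, eid)
    b <- window_bounds(pr$enh_start[j], pr$enh_end[j], wlen)
    idx <- seq.int(b["lo"] + 1L, b["hi"])
    dataset$tracks[[pr$chrom[j]]][idx, ] <-
      dataset$tracks[[pr$chrom[j]]][idx, ] + offs[[eid]]
  }
  dataset$leak_strength <- strength
  dataset
}

#' Write a synthetic dataset to plain-text files
#'
#' Pairs as a BEDPE-like table, tracks as one bedGraph-dialect file per
#' assay, and sequences as FASTA.
#'
#' @param dataset An `ep_dataset`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pair_table(dataset$pairs, file.path(dir, "pairs.tsv"))
  write_tracks_bedgraph(dataset, file.path(dir, "tracks"))
  write_sequences_fasta(dataset, file.path(dir, "reference.fasta"))
  invisible(dir)
}
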