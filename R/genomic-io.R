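# Window extraction and feature construction: from per-base signal tracks and
# reference sequences to the two model-ready feature formats (CNN-format
# sliding-window tensors, TargetFinder-format region means) and one-hot
# sequence matrices.
#
# Coordinates are 0-based, half-open (BED convention) throughout. Strand is
# ignored; all elements are treated as plus-strand.

#' Combine interval signal records into a per-base array
#'
#' Collapses overlapping interval measurements (bedGraph-dialect records) on
#' one chromosome into one value per base: each covered base receives the
#' mean of all interval values covering it; uncovered bases are 0.
#'
#' @param records Data frame with columns `start`, `end` (0-based half-open)
#'   and `value`.
#' @param chrom_length Chromosome length in bases.
#' @return Numeric vector of length `chrom_length`.
#' @examples
#' merge_intervals_to_per_base(data.frame(start = 0, end = 10, value = 3), 20)
#' @export
merge_intervals_to_per_base <- function(records, chrom_length) {
  if (nrow(records) == 0) return(numeric(chrom_length))
  if (any(records$start < 0)) stop("negative interval start")
  if (any(records$end > chrom_length)) stop("interval exceeds chromosome length")
  if (any(records$end <= records$start)) stop("empty or inverted interval")
  dsum <- numeric(chrom_length + 1L)
  dcnt <- numeric(chrom_length + 1L)
  s <- records$start + 1L; e <- records$end + 1L
  for (i in seq_len(nrow(records))) {
    dsum[s[i]] <- dsum[s[i]] + records$value[i]
    dsum[e[i]] <- dsum[e[i]] - records$value[i]
    dcnt[s[i]] <- dcnt[s[i]] + 1
    dcnt[e[i]] <- dcnt[e[i]] - 1
  }
  covered <- cumsum(dcnt)[seq_len(chrom_length)]
  total <- cumsum(dsum)[seq_len(chrom_length)]
  out <- numeric(chrom_length)
  nz <- covered > 0
  out[nz] <- total[nz] / covered[nz]
  out
}

window_bounds <- function(start, end, width) {
  center <- (start + end) %/% 2
  lo <- center - width %/% 2
  c(lo = lo, hi = lo + width)          # [lo, hi), 0-based
}

#' Extract a fixed-width signal window centered on an element
#'
#' Returns the signal over `[center - width/2, center + width/2)` where
#' `center = floor((start + end)/2)`; windows that would leave the
#' chromosome are a hard error (never clipped or padded), so downstream
#' feature dimensions are always exact.
#'
#' @param track Per-base signal: a numeric vector, or a matrix with one
#'   column per assay.
#' @param start,end Element coordinates (0-based half-open).
#' @param width Window width in bp (3000 for enhancers, 2000 for promoters).
#' @return A `width`-length vector, or `width x tracks` matrix.
#' @export
extract_window <- function(track, start, end, width) {
  L <- if (is.matrix(track)) nrow(track) else length(track)
  b <- window_bounds(start, end, width)
  if (b["lo"] < 0 || b["hi"] > L)
    stop(sprintf("window [%d,%d) for element [%d,%d) lies outside the chromosome (length %d)",
                 b["lo"], b["hi"], start, end, L))
  idx <- seq.int(b["lo"] + 1L, b["hi"])
  if (is.matrix(track)) track[idx, , drop = FALSE] else track[idx]
}

#' Sliding-window mean summarization
#'
#' Averages an `L x T` per-base signal block in windows of `window` bp moved
#' by `step` bp, producing `W = floor((L - window)/step) + 1` rows; with the
#' published window 50 / step 10 this maps 3000 bp to 296 windows and 2000 bp
#' to 196 windows.
#'
#' @param signal Numeric matrix (`L x T`) or vector.
#' @param window,step Window and step sizes in bp.
#' @return `W x T` matrix of window means.
#' @examples
#' nrow(sliding_window_mean(matrix(0, 3000, 22), 50, 10))  # 296
#' @export
sliding_window_mean <- function(signal, window = 50, step = 10) {
  if (is.vector(signal)) signal <- matrix(signal, ncol = 1)
  L <- nrow(signal)
  if (window > L) stop("window larger than signal length")
  if (step < 1 || window < 1) stop("window and step must be >= 1")
  W <- (L - window) %/% step + 1L
  cs <- rbind(0, apply(signal, 2, cumsum))
  starts <- (seq_len(W) - 1L) * step
  (cs[starts + window + 1L, , drop = FALSE] - cs[starts + 1L, , drop = FALSE]) / window
}

#' Region mean (TargetFinder-format summary)
#'
#' Per-track arithmetic mean over the whole window; concatenating the 22
#' enhancer means and 22 promoter means yields the 44-dimensional
#' TargetFinder-format feature vector.
#'
#' @param signal `L x T` matrix (or vector).
#' @return Length-`T` vector of means.
#' @export
region_mean <- function(signal) {
  if (is.vector(signal)) signal <- matrix(signal, ncol = 1)
  if (nrow(signal) == 0) stop("empty signal block")
  colMeans(signal)
}

#' One-hot encode a DNA sequence
#'
#' Channel order A, C, G, T; `N` encodes as an all-zero row; any other
#' character is an error. Case-insensitive.
#'
#' @param seq A single sequence string.
#' @return `nchar(seq) x 4` 0/1 matrix with columns A, C, G, T.
#' @examples
#' one_hot_encode("ACGT")  # identity
#' @export
one_hot_encode <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  code <- match(chars, c("A", "C", "G", "T", "N"))
  if (anyNA(code)) stop("sequence contains characters outside A/C/G/T/N")
  out <- matrix(0L, length(chars), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  keep <- code <= 4
  out[cbind(which(keep), code[keep])] <- 1L
  out
}

#' Central crop of a one-hot matrix
#'
#' Returns the central `target` rows (offset `floor((L - target)/2)`), the
#' preprocessing used for the attention and residual sequence models
#' (600 bp enhancer / 400 bp promoter crops).
#'
#' @param onehot `L x 4` matrix.
#' @param target Crop length (<= L).
#' @return `target x 4` matrix.
#' @export
central_crop <- function(onehot, target) {
  L <- nrow(onehot)
  if (target > L) stop("crop target larger than input")
  off <- (L - target) %/% 2
  onehot[seq.int(off + 1L, off + target), , drop = FALSE]
}

#' Match an interval's reference sequence against candidate sequences
#'
#' Extracts the reference substring for the interval and returns the index of
#' the unique exactly-matching candidate, `NA` if none matches, and an error
#' if several do (ambiguous match).
#'
#' @param chrom,start,end Interval (0-based half-open).
#' @param reference Named character vector of chromosome sequences.
#' @param candidates Character vector of candidate sequences.
#' @return Integer index into `candidates`, or `NA_integer_`.
#' @export
match_sequence <- function(chrom, start, end, reference, candidates) {
  if (!chrom %in% names(reference)) stop("chromosome ", chrom, " not in reference")
  ref <- substr(reference[[chrom]], start + 1L, end)
  if (nchar(ref) != end - start) stop("reference does not cover the interval")
  if (length(candidates) == 0) return(NA_integer_)
  hits <- which(candidates == ref)
  if (length(hits) > 1) stop("ambiguous match: ", length(hits), " candidates equal the reference substring")
  if (length(hits) == 0) NA_integer_ else hits[1]
}

## ---- dataset-level featurization -----------------------------------------

#' Build model-ready features for every pair of a dataset
#'
#' @param dataset An `ep_dataset` from [generate_dataset()] (or the same
#'   structure assembled from real inputs).
#' @param format One of `"epi_mean"` (TargetFinder-format `n x 44` matrix),
#'   `"epi_cnn"` (sliding-window tensors, `n x 296 x 22` enhancer and
#'   `n x 196 x 22` promoter), `"sequence"` (full one-hot, `n x 3000 x 4` /
#'   `n x 2000 x 4`) or `"sequence_crop"` (central crops, `n x 600 x 4` /
#'   `n x 400 x 4`).
#' @param window,step Sliding-window parameters for `"epi_cnn"`.
#' @param crop Crop lengths (enhancer, promoter) for `"sequence_crop"`.
#' @return For `"epi_mean"`, a matrix; otherwise a list with `enhancer` and
#'   `promoter` arrays. All carry the labels as attribute `"labels"`.
#' @export
featurize_pairs <- function(dataset,
                            format = c("epi_mean", "epi_cnn", "sequence", "sequence_crop"),
                            window = 50, step = 10, crop = c(600, 400)) {
  format <- match.arg(format)
  pr <- dataset$pairs
  n <- nrow(pr)
  e_len <- dataset$config$enhancer_len
  p_len <- dataset$config$promoter_len
  if (format %in% c("epi_mean", "epi_cnn")) {
    Tn <- ncol(dataset$tracks[[1]])
    if (format == "epi_mean") {
      out <- matrix(NA_real_, n, 2 * Tn)
      colnames(out) <- c(paste0(dataset$assays, "_enh"), paste0(dataset$assays, "_prom"))
    } else {
      We <- (e_len - window) %/% step + 1L
      Wp <- (p_len - window) %/% step + 1L
      enh <- array(NA_real_, c(n, We, Tn))
      prom <- array(NA_real_, c(n, Wp, Tn))
    }
    for (i in seq_len(n)) {
      trk <- dataset$tracks[[pr$chrom[i]]]
      we <- extract_window(trk, pr$enh_start[i], pr$enh_end[i], e_len)
      wp <- extract_window(trk, pr$prom_start[i], pr$prom_end[i], p_len)
      if (format == "epi_mean") {
        out[i, ] <- c(region_mean(we), region_mean(wp))
      } else {
        enh[i, , ] <- sliding_window_mean(we, window, step)
        prom[i, , ] <- sliding_window_mean(wp, window, step)
      }
    }
    res <- if (format == "epi_mean") out else list(enhancer = enh, promoter = prom)
  } else {
    le <- if (format == "sequence") e_len else crop[1]
    lp <- if (format == "sequence") p_len else crop[2]
    enh <- array(0, c(n, le, 4))
    prom <- array(0, c(n, lp, 4))
    for (i in seq_len(n)) {
      sq <- dataset$sequences[[pr$chrom[i]]]
      be <- window_bounds(pr$enh_start[i], pr$enh_end[i], e_len)
      bp <- window_bounds(pr$prom_start[i], pr$prom_end[i], p_len)
      oe <- one_hot_encode(substr(sq, be["lo"] + 1L, be["hi"]))
      op <- one_hot_encode(substr(sq, bp["lo"] + 1L, bp["hi"]))
      if (format == "sequence_crop") {
        oe <- central_crop(oe, crop[1]); op <- central_crop(op, crop[2])
      }
      enh[i, , ] <- oe
      prom[i, , ] <- op
    }
    res <- list(enhancer = enh, promoter = prom)
  }
  attr(res, "labels") <- pr$label
  res
}

## ---- plain-text readers and writers --------------------------------------

#' Write / read a BEDPE-like pair table
#'
#' Tab-separated columns: chrom, enh_start, enh_end, chrom, prom_start,
#' prom_end, label, enhancer_id, promoter_id.
#'
#' @param pairs Pair data frame (`dataset$pairs`).
#' @param path Output file.
#' @return `write_pair_table` the path, invisibly; `read_pair_table` the
#'   pair data frame.
#' @export
write_pair_table <- function(pairs, path) {
  out <- data.frame(chrom1 = pairs$chrom, enh_start = pairs$enh_start,
                    enh_end = pairs$enh_end, chrom2 = pairs$chrom,
                    prom_start = pairs$prom_start, prom_end = pairs$prom_end,
                    label = pairs$label, enhancer_id = pairs$enhancer_id,
                    promoter_id = pairs$promoter_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_table
#' @export
read_pair_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (any(df$chrom1 != df$chrom2))
    stop("inter-chromosomal pair(s) in table; EPIs are intra-chromosomal")
  data.frame(chrom = df$chrom1, enh_start = df$enh_start, enh_end = df$enh_end,
             prom_start = df$prom_start, prom_end = df$prom_end,
             label = df$label, enhancer_id = df$enhancer_id,
             promoter_id = df$promoter_id, stringsAsFactors = FALSE)
}

#' Write per-base tracks as bedGraph-dialect files (one per assay)
#'
#' Consecutive equal values are run-length collapsed into intervals
#' (chrom, start, end, value); zero runs are omitted, matching the
#' uncovered-base convention of [merge_intervals_to_per_base()].
#'
#' @param dataset An `ep_dataset`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_tracks_bedgraph <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (a in seq_along(dataset$assays)) {
    path <- file.path(dir, paste0(dataset$assays[a], ".bedGraph"))
    rows <- list()
    for (chrom in names(dataset$tracks)) {
      v <- dataset$tracks[[chrom]][, a]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values != 0
      if (any(keep)) {
        rows[[chrom]] <- data.frame(chrom = chrom, start = starts[keep],
                                    end = ends[keep], value = r$values[keep])
      }
    }
    df <- do.call(rbind, rows)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a bedGraph-dialect interval-signal file
#'
#' @param path File with tab-separated chrom, start, end, value records.
#' @return Data frame with those columns.
#' @export
read_track_bedgraph <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"),
                          stringsAsFactors = FALSE)
  df
}

#' Rebuild per-base track matrices from bedGraph-dialect files
#'
#' @param dir Directory written by [write_tracks_bedgraph()].
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param assays Assay names (determines file names and column order).
#' @return Named list of `length x assays` matrices.
#' @export
tracks_from_bedgraph <- function(dir, chrom_lengths, assays) {
  tracks <- lapply(chrom_lengths, function(L) matrix(0, L, length(assays)))
  for (a in seq_along(assays)) {
    df <- read_track_bedgraph(file.path(dir, paste0(assays[a], ".bedGraph")))
    for (chrom in unique(df$chrom)) {
      sub <- df[df$chrom == chrom, ]
      tracks[[chrom]][, a] <-
        merge_intervals_to_per_base(sub, chrom_lengths[[chrom]])
    }
  }
  for (ch in names(tracks)) colnames(tracks[[ch]]) <- assays
  tracks
}

#' Write chromosome sequences as FASTA
#'
#' @param dataset An `ep_dataset` (or any named character vector via
#'   `sequences`).
#' @param path Output FASTA file.
#' @return The path, invisibly.
#' @export
write_sequences_fasta <- function(dataset, path) {
  seqs <- if (is.character(dataset)) dataset else dataset$sequences
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::DNAStringSet(unlist(seqs))
    Biostrings::writeXStringSet(ss, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (nm in names(seqs)) {
      writeLines(paste0(">", nm), con)
      writeLines(substring(seqs[[nm]], seq(1, nchar(seqs[[nm]]), 70),
                           pmin(seq(1, nchar(seqs[[nm]]), 70) + 69, nchar(seqs[[nm]]))), con)
    }
  }
  invisible(path)
}

#' Read chromosome sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_sequences_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readDNAStringSet(path)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))
    return(out)
  }
  lines <- readLines(path)
  heads <- grepl("^>", lines)
  idx <- cumsum(heads)
  nms <- sub("^>", "", sub("\\s.*$", "", lines[heads]))
  out <- vapply(split(lines[!heads], idx[!heads]), paste0, character(1), collapse = "")
  names(out) <- nms
  out
}

#' Optional BigWig reader behind the per-base-array contract
#'
#' Thin adapter over `rtracklayer::import.bw()`: returns one value per base
#' for a chromosome, 0 where uncovered. The core pipeline never requires
#' BigWig input; this exists for real-data use.
#'
#' @param path BigWig file.
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length.
#' @return Numeric per-base vector.
#' @export
read_track_bigwig <- function(path, chrom, chrom_length) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for BigWig input")
  gr <- rtracklayer::import.bw(path, which = GenomicRanges::GRanges(
    chrom, IRanges::IRanges(1, chrom_length)))
  df <- data.frame(start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr), value = gr$score)
  merge_intervals_to_per_base(df, chrom_length)
}
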