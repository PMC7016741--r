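# Chromosome-held-out split plans (leakage-free) and the known-biased random
# split kept only for the leakage demonstration.
#
# Chromosomes 8 and 9 are always the validation set; each remaining
# chromosome serves in turn as the test set, with all others as training
# data. Pairs are assigned by their (shared) chromosome, so elements reused
# across pairs can never span partitions.

# natural chromosome order: chr1 < chr2 < ... < chr22 < chrX < chrY < others
chrom_order <- function(chroms) {
  key <- sub("^chr", "", chroms)
  num <- suppressWarnings(as.integer(key))
  rank <- ifelse(!is.na(num), num,
                 ifelse(key == "X", 100L, ifelse(key == "Y", 101L, 102L)))
  chroms[order(rank, key)]
}

#' Build chromosome-held-out split plans
#'
#' One plan per non-validation chromosome, in natural chromosome order:
#' that chromosome is the test set, chr8 and chr9 are always validation, and
#' everything else is training. With the default 23-chromosome universe this
#' yields 21 plans.
#'
#' @param chromosomes Character vector of chromosome names; must contain the
#'   validation chromosomes and at least two others (otherwise some plan
#'   would have an empty training partition).
#' @param validation_chroms The fixed validation chromosomes.
#' @return List of `split_plan`s, each with `test_chrom`,
#'   `validation_chroms`, `train_chroms` and `universe`.
#' @examples
#' length(make_split_plans(c(paste0("chr", 1:22), "chrX")))  # 21
#' @export
make_split_plans <- function(chromosomes, validation_chroms = c("chr8", "chr9")) {
  chromosomes <- unique(chromosomes)
  if (!all(validation_chroms %in% chromosomes))
    stop("chromosome universe must contain the validation chromosomes (",
         paste(validation_chroms, collapse = ", "), ")")
  rest <- chrom_order(setdiff(chromosomes, validation_chroms))
  if (length(rest) < 1) stop("no candidate test chromosomes")
  if (length(rest) < 2)
    stop("empty training partition: need at least two non-validation chromosomes")
  lapply(rest, function(tc) {
    structure(list(test_chrom = tc,
                   validation_chroms = validation_chroms,
                   train_chroms = setdiff(rest, tc),
                   universe = c(rest, validation_chroms)),
              class = "split_plan")
  })
}

#' Partition pairs by a chromosome-held-out plan
#'
#' Pairs are assigned by their enhancer chromosome (identical to the
#' promoter's, since interactions are intra-chromosomal). The three index
#' sets are disjoint and exhaustive; shared elements can therefore never
#' appear in more than one partition.
#'
#' @param pairs Pair data frame with a `chrom` column.
#' @param plan A `split_plan` from [make_split_plans()].
#' @return List of integer index vectors `train`, `validation`, `test`.
#' @export
assign_pairs <- function(pairs, plan) {
  unknown <- setdiff(unique(pairs$chrom), plan$universe)
  if (length(unknown) > 0)
    stop("pair(s) on chromosome(s) outside the plan universe: ",
         paste(unknown, collapse = ", "))
  list(train = which(pairs$chrom %in% plan$train_chroms),
       validation = which(pairs$chrom %in% plan$validation_chroms),
       test = which(pairs$chrom == plan$test_chrom))
}

#' Uniform random split (the known-biased scheme)
#'
#' Randomly partitions pair indices into train/validation/test with the
#' given fractions. Provided only for the leakage demonstration: with
#' element reuse, random splitting places shared enhancers on both sides of
#' the train/test divide, so the partitions are not independent.
#'
#' @param n_pairs Number of pairs (or a pair data frame).
#' @param fractions Positive train/validation/test fractions summing to 1.
#' @param seed Integer seed.
#' @return List of integer index vectors `train`, `validation`, `test`.
#' @export
random_split <- function(n_pairs, fractions = c(0.8, 0.1, 0.1), seed = 1) {
  if (is.data.frame(n_pairs)) n_pairs <- nrow(n_pairs)
  if (any(fractions <= 0)) stop("all fractions must be positive")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  set.seed(seed)
  idx <- sample(n_pairs)
  n_tr <- floor(n_pairs * fractions[1])
  n_va <- floor(n_pairs * fractions[2])
  list(train = sort(idx[seq_len(n_tr)]),
       validation = sort(idx[n_tr + seq_len(n_va)]),
       test = sort(idx[(n_tr + n_va + 1):n_pairs]))
}

#' Serialize a split plan (or plans) as JSON
#'
#' @param plans A `split_plan` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_split_plans <- function(plans, path) {
  if (inherits(plans, "split_plan")) plans <- list(plans)
  jsonlite::write_json(lapply(plans, unclass), path, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}
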