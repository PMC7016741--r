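# Shared fixtures: one small synthetic dataset, generated once per test run.

small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(synthetic_config(
        n_pairs = 120, imbalance_ratio = 20, epi_effect = 1, noise_sd = 0.5,
        duplication_factor = 2, seed = 7))
    }
    cache
  }
})

# naive brute-force per-base accumulation oracle for interval merging
brute_force_per_base <- function(records, chrom_length) {
  sums <- numeric(chrom_length)
  cnts <- numeric(chrom_length)
  for (i in seq_len(nrow(records))) {
    idx <- seq.int(records$start[i] + 1L, records$end[i])
    sums[idx] <- sums[idx] + records$value[i]
    cnts[idx] <- cnts[idx] + 1
  }
  ifelse(cnts > 0, sums / pmax(cnts, 1), 0)
}

# exhaustive cross-class pair-counting AUROC oracle (ties count 1/2)
brute_force_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
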