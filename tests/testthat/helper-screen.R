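# Small shared fixtures built in code.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_genes = 5L, guides_per_gene = 4L, n_pair_constructs = 0L,
                   n_controls = 20L, reads_per_guide_mean = 100,
                   n_replicates = 2L, seed = 42L)
  do.call(screen_sim_config, utils::modifyList(defaults, args))
}

# Independent brute-force two-sided Fisher p via combination counting
# (lchoose), summing table probabilities not exceeding the observed one
# with the conventional relative slack.
brute_fisher_p <- function(both, a_only, b_only, neither) {
  r <- both + a_only
  c <- both + b_only
  n <- both + a_only + b_only + neither
  x <- max(0, r + c - n):min(r, c)
  lp <- lchoose(r, x) + lchoose(n - r, c - x) - lchoose(n, c)
  probs <- exp(lp)
  obs <- probs[x == both]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# All-pairs half-open interval overlap check.
brute_bound <- function(introns, peaks, min_overlap = 1L) {
  vapply(seq_len(nrow(introns)), function(i) {
    any(peaks$chrom == introns$chrom[i] &
          pmin(peaks$end, introns$end[i]) -
          pmax(peaks$start, introns$start[i]) >= min_overlap)
  }, logical(1))
}
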