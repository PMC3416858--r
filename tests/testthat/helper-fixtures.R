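# Small reusable fixtures, built in code at test time.

small_cfg <- function(seed = 42, ...) {
  args <- list(seed = seed, n_nano = 12L, nano_len_mean = 1500,
               nano_len_sd = 300, reads_per_nano_mean = 200)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(generator_config, args)
}

# telomere-trimmed interior of a MacroGene (mirrors the package-internal
# definition, restated so tests do not reach into unexported functions)
macro_interior_for_test <- function(gene) {
  substr(gene$sequence, gene$tel5_len + 1L,
         nchar(gene$sequence) - gene$tel3_len)
}

# distinct set straight from sequences with given counts
distinct_from <- function(seqs, counts = NULL) {
  counts <- if (is.null(counts)) rep(1L, length(seqs)) else counts
  build_distinct_set(rep(seqs, counts))
}

# hits table built from a pool's ground truth (bypasses alignment), for
# statistics tests that are about the estimators rather than the aligner
truth_hits <- function(pool) {
  data.frame(seq = pool$sequence, count = 1L, record_id = pool$gene_id,
             start = ifelse(pool$strand == "+", pool$start,
                            pool$start - pool$length + 1L),
             strand = pool$strand, mismatches = 0L,
             five_prime = pool$start, stringsAsFactors = FALSE)
}
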