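# Independent brute-force alignment oracle: scans every position of the
# reference on both strands and counts substitutions directly. Kept free of
# any package alignment code so it can certify the seed-and-extend path.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

oracle_align <- function(read, ref, max_mm) {
  refc <- strsplit(ref, "")[[1]]
  L <- nchar(read)
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") read else oracle_revcomp(read)
    qc <- strsplit(q, "")[[1]]
    if (L > length(refc)) next
    for (start in 0:(length(refc) - L)) {
      win <- refc[start + seq_len(L)]
      if (any(!win %in% c("A", "C", "G", "T"))) next
      mm <- sum(win != qc)
      if (mm <= max_mm) {
        out[[length(out) + 1L]] <- data.frame(
          start = start, strand = strand, mismatches = mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) {
    df <- do.call(rbind, out)
    df[order(df$start, df$strand), , drop = FALSE]
  } else {
    data.frame(start = integer(0), strand = character(0),
               mismatches = integer(0), stringsAsFactors = FALSE)
  }
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(x, k) {
  s <- strsplit(x, "")[[1]]
  at <- sample(length(s), k)
  for (p in at) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  paste(s, collapse = "")
}
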