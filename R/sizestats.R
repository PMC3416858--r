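## Size-class statistics: length histograms with a mapped/unmapped split,
## per-position nucleotide frequency matrices in RNA space, and extraction
## of the abundant subset of a library.

#' Length histogram of distinct reads with mapped split
#'
#' One count per distinct sequence; a sequence is "mapped" when it has at
#' least one alignment site on the macronuclear assembly (chr1 or chr2;
#' chrM does not count).
#'
#' @param distinct a `DistinctReadSet`.
#' @param hits hit table from [run_two_pass()] (with `target` column) or
#'   [align_read_all_sites()]; alternatively a character vector of mapped
#'   sequences.
#' @param range lengths to tabulate (default 18-30 nt).
#' @return data.frame `length`, `distinct`, `mapped_distinct`.
#' @export
length_histogram <- function(distinct, hits, range = 18:30) {
  mapped_seqs <- if (is.character(hits)) {
    unique(hits)
  } else if (nrow(hits) == 0L) {
    character(0)
  } else if ("target" %in% names(hits)) {
    unique(hits$seq[hits$target %in% c("chr1", "chr2")])
  } else {
    unique(hits$seq)
  }
  len <- nchar(distinct$seq)
  is_mapped <- distinct$seq %in% mapped_seqs
  data.frame(
    length = range,
    distinct = vapply(range, function(L) sum(len == L), 0L),
    mapped_distinct = vapply(range, function(L) sum(len == L & is_mapped),
                             0L))
}

#' Per-position nucleotide frequency matrix for one size class
#'
#' Frequencies are reported in the RNA alphabet (T counted as U). The
#' default basis is distinct sequences; `weighted = TRUE` weights each
#' sequence by its occurrence count instead.
#'
#' @param distinct a `DistinctReadSet`.
#' @param L read length of the size class.
#' @param weighted weight sequences by their counts.
#' @return matrix with `L` rows (positions) and columns `U`, `A`, `C`,
#'   `G`; every row sums to 1.
#' @export
position_freq <- function(distinct, L, weighted = FALSE) {
  sel <- nchar(distinct$seq) == L
  if (!any(sel)) stop("no sequences of length ", L)
  seqs <- distinct$seq[sel]
  w <- if (weighted) distinct$count[sel] else rep(1L, length(seqs))
  mat <- matrix(0, nrow = L, ncol = 4L,
                dimnames = list(NULL, c("U", "A", "C", "G")))
  chars <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs),
                  byrow = TRUE)
  for (j in seq_len(L)) {
    tab <- tapply(w, factor(chars[, j], levels = c("T", "A", "C", "G")),
                  sum)
    tab[is.na(tab)] <- 0
    mat[j, ] <- tab / sum(tab)
  }
  mat
}

#' Extract the abundant subset of a read set
#'
#' Sequences observed at least `min_count` (and at most `max_count`) times.
#'
#' @param distinct a `DistinctReadSet`.
#' @param min_count inclusive lower bound on the occurrence count.
#' @param max_count inclusive upper bound (default unbounded).
#' @return a `DistinctReadSet`.
#' @export
abundant_subset <- function(distinct, min_count = 10L, max_count = Inf) {
  sel <- distinct$count >= min_count & distinct$count <= max_count
  as_distinct_set(distinct[sel, , drop = FALSE],
                  library = attr(distinct, "library"))
}
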