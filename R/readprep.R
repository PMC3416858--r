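## Paired-end read preparation: adapter trimming and bidirectional-identity
## collapse into a deduplicated read set. Inserts are shorter than the
## sequencing read length, so both mates cover the whole molecule and a
## pair is kept only when the two trimmed inserts are exact complements.

#' Read-preparation configuration
#'
#' @param adapter3 3' adapter sequence searched for in both mates.
#' @param min_len,max_len inclusive length window for kept inserts (nt).
#' @param min_adapter_overlap minimum number of exact adapter bases required
#'   to call an adapter match.
#' @return object of class `PrepConfig`.
#' @export
prep_config <- function(adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                        min_len = 16L, max_len = 45L,
                        min_adapter_overlap = 6L) {
  stopifnot(min_len >= 1L, min_len <= max_len, min_adapter_overlap >= 1L)
  stop_if_not_dna(adapter3, "adapter3")
  out <- list(adapter3 = adapter3, min_len = as.integer(min_len),
              max_len = as.integer(max_len),
              min_adapter_overlap = as.integer(min_adapter_overlap))
  class(out) <- "PrepConfig"
  out
}

#' Trim the 3' adapter from reads
#'
#' Returns, for each read, the longest prefix preceding a position where the
#' remainder of the read matches a prefix of the adapter exactly over at
#' least `min_adapter_overlap` bases. Reads with no adapter match are
#' rejected (`NA`): their insert extends beyond the read and cannot be used
#' for the identity collapse. Reads containing characters outside
#' {A,C,G,T,N} are rejected.
#'
#' @param reads character vector of raw reads.
#' @param cfg a [prep_config()].
#' @return character vector of inserts, `NA` where rejected.
#' @export
trim_adapter <- function(reads, cfg) {
  if (length(reads) == 0L) return(character(0))
  out <- rep(NA_character_, length(reads))
  ok <- !grepl("[^ACGTN]", reads)
  if (any(ok)) {
    out[ok] <- cpp_trim_adapter(reads[ok], cfg$adapter3,
                                cfg$min_adapter_overlap)
  }
  out
}

#' Collapse mate pairs by bidirectional identity
#'
#' A pair is kept iff the trimmed mate-2 insert, after reverse-complement
#' normalisation, is byte-identical to the mate-1 insert (which forces
#' equal length). The operation is symmetric in mate order.
#'
#' @param insert1,insert2 character vectors of trimmed inserts (`NA` for
#'   mates that failed adapter trimming).
#' @return character vector: the consensus insert where kept, `NA` where
#'   rejected.
#' @export
collapse_pair <- function(insert1, insert2) {
  stopifnot(length(insert1) == length(insert2))
  out <- rep(NA_character_, length(insert1))
  both <- !is.na(insert1) & !is.na(insert2) & nzchar(insert1) &
    nzchar(insert2)
  if (any(both)) {
    match <- insert1[both] == revcomp(insert2[both])
    out[both][match] <- insert1[both][match]
  }
  out
}

#' Build a deduplicated read set
#'
#' Applies the length window, restricts to the A/C/G/T alphabet, and
#' collapses exact duplicate sequences, retaining occurrence counts.
#'
#' @param seqs character vector of kept insert sequences.
#' @param cfg a [prep_config()].
#' @param library library label stored with the set.
#' @return object of class `DistinctReadSet`: a data.frame with columns
#'   `seq`, `count` and attributes `total_reads`, `distinct_reads`,
#'   `library`.
#' @export
build_distinct_set <- function(seqs, cfg = prep_config(), library = NA) {
  n <- nchar(seqs)
  keep <- n >= cfg$min_len & n <= cfg$max_len & !grepl("[^ACGT]", seqs)
  seqs <- seqs[keep]
  if (length(seqs)) {
    tab <- table(seqs)
    df <- data.frame(seq = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$seq), , drop = FALSE]
    rownames(df) <- NULL
  } else {
    df <- data.frame(seq = character(0), count = integer(0),
                     stringsAsFactors = FALSE)
  }
  attr(df, "total_reads") <- sum(df$count)
  attr(df, "distinct_reads") <- nrow(df)
  attr(df, "library") <- library
  class(df) <- c("DistinctReadSet", "data.frame")
  df
}

#' @export
print.DistinctReadSet <- function(x, ...) {
  cat("DistinctReadSet:", attr(x, "distinct_reads"), "distinct /",
      attr(x, "total_reads"), "total reads")
  if (!is.na(attr(x, "library"))) cat(" [", attr(x, "library"), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Total and distinct read counts of a read set
#' @param x a `DistinctReadSet`.
#' @return integer scalar.
#' @export
read_total <- function(x) attr(x, "total_reads")

#' @rdname read_total
#' @export
distinct_total <- function(x) attr(x, "distinct_reads")

## rebuild attributes after subsetting the underlying data.frame
as_distinct_set <- function(df, library = NA) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  attr(df, "total_reads") <- sum(df$count)
  attr(df, "distinct_reads") <- nrow(df)
  attr(df, "library") <- library
  class(df) <- c("DistinctReadSet", "data.frame")
  df
}

#' Prepare a paired-end FASTQ library
#'
#' Runs adapter trimming on both mates, the bidirectional-identity
#' collapse, and distinct-set construction. Every input pair lands in
#' exactly one terminal category.
#'
#' @param fastq1,fastq2 FASTQ paths (gzip allowed).
#' @param cfg a [prep_config()].
#' @param library library label.
#' @return list with elements `distinct` (a `DistinctReadSet`), `kept`
#'   (character vector of kept insert sequences, one per kept pair) and
#'   `stats` (one-row data.frame: `total_pairs`, `kept`,
#'   `rejected_adapter`, `rejected_identity`, `rejected_length`,
#'   `pct_identical`).
#' @export
prep_fastq_pair <- function(fastq1, fastq2, cfg = prep_config(),
                            library = NA) {
  r1 <- read_fastq(fastq1)
  r2 <- read_fastq(fastq2)
  if (nrow(r1) != nrow(r2)) stop("mate files differ in record count")
  ins1 <- trim_adapter(r1$seq, cfg)
  ins2 <- trim_adapter(r2$seq, cfg)
  no_adapter <- is.na(ins1) | is.na(ins2)
  consensus <- collapse_pair(ins1, ins2)
  identity_fail <- !no_adapter & is.na(consensus)
  n <- nchar(consensus)
  len_fail <- !is.na(consensus) &
    (n < cfg$min_len | n > cfg$max_len | grepl("[^ACGT]", consensus))
  kept <- consensus[!is.na(consensus) & !len_fail]
  distinct <- build_distinct_set(kept, cfg, library = library)
  stats <- data.frame(
    total_pairs = nrow(r1),
    kept = length(kept),
    rejected_adapter = sum(no_adapter),
    rejected_identity = sum(identity_fail),
    rejected_length = sum(len_fail),
    pct_identical = if (nrow(r1)) 100 * length(kept) / nrow(r1) else NA_real_)
  list(distinct = distinct, kept = kept, stats = stats)
}

#' Write a distinct read set as FASTA with counts in headers
#' @param x a `DistinctReadSet`.
#' @param path output FASTA.
#' @return `path`, invisibly.
#' @export
write_distinct_fasta <- function(x, path) {
  seqs <- x$seq
  names(seqs) <- sprintf("seq%06d count=%d", seq_len(nrow(x)), x$count)
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read a distinct read set written by [write_distinct_fasta()]
#' @param path FASTA path.
#' @param library library label.
#' @return a `DistinctReadSet`.
#' @export
read_distinct_fasta <- function(path, library = NA) {
  dss <- Biostrings::readDNAStringSet(path)
  counts <- suppressWarnings(
    as.integer(sub("^.*count=(\\d+).*$", "\\1", names(dss))))
  counts[is.na(counts)] <- 1L
  df <- data.frame(seq = as.character(dss), count = counts,
                   stringsAsFactors = FALSE)
  as_distinct_set(df, library = library)
}
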