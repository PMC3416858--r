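## Non-coding RNA filter: a decoy reference (rRNA/tRNA/snRNA/telomerase RNA
## plus a telomeric repeat decoy) against which reads are aligned with a
## lenient mismatch policy before genome mapping.

#' Build a non-coding RNA filter set
#'
#' Appends a telomeric decoy, equal to five concatenated copies of the
#' telomere unit (40 nt for `GGGGTTTT`), to the supplied ncRNA decoys, so
#' telomere-derived small RNAs are removed before genome alignment.
#'
#' @param ncrna either a FASTA path, a named character vector of sequences,
#'   or `NULL` (a warning is raised and only the telomeric decoy is used).
#' @param telomere_unit telomeric repeat unit.
#' @param max_mismatches lenient mismatch budget for filter alignment
#'   (default 3: up to three substitutions anywhere, no indels).
#' @return an object of class `FilterSet` with fields `seqs` and
#'   `max_mismatches`.
#' @export
build_filter_set <- function(ncrna = NULL, telomere_unit = "GGGGTTTT",
                             max_mismatches = 3L) {
  seqs <- if (is.null(ncrna)) {
    character(0)
  } else if (length(ncrna) == 1L && file.exists(ncrna)) {
    read_fasta(ncrna)
  } else {
    ncrna
  }
  if (length(seqs) == 0L) {
    warning("no ncRNA decoys supplied; filter contains only the telomeric decoy")
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence ids in ncRNA input")
  }
  decoy <- strrep(telomere_unit, 5L)
  if ("telomeric_repeat" %in% names(seqs)) {
    stop("reserved id 'telomeric_repeat' present in ncRNA input")
  }
  seqs <- c(seqs, telomeric_repeat = decoy)
  out <- list(seqs = seqs, max_mismatches = as.integer(max_mismatches),
              telomere_unit = telomere_unit)
  class(out) <- "FilterSet"
  out
}

#' @export
print.FilterSet <- function(x, ...) {
  cat("FilterSet:", length(x$seqs), "sequences (incl. telomeric decoy of",
      nchar(x$seqs[["telomeric_repeat"]]), "nt), max mismatches",
      x$max_mismatches, "\n")
  invisible(x)
}

#' Partition a read set into ncRNA matches and survivors
#'
#' A read is an ncRNA match iff it aligns to any filter sequence, on either
#' strand, with at most `max_mismatches` substitutions (no indels). The
#' partition is exhaustive and exclusive on both distinct and total counts.
#'
#' @param reads a `DistinctReadSet`.
#' @param fs a `FilterSet`.
#' @return list with `ncrna` and `surviving` (`DistinctReadSet`s) and
#'   `stats`, a one-row data.frame with the read-count bookkeeping columns
#'   `bidirectional_identical`, `ncrna`, `ncrna_pct`, `not_ncrna`,
#'   `not_ncrna_pct` (total-read basis) plus distinct-read counterparts.
#' @export
partition_reads <- function(reads, fs) {
  stopifnot(inherits(reads, "DistinctReadSet"), inherits(fs, "FilterSet"))
  lib <- attr(reads, "library")
  if (nrow(reads) == 0L) {
    empty <- as_distinct_set(reads[0L, ], library = lib)
    return(list(ncrna = empty, surviving = empty,
                stats = partition_stats(reads, empty, empty)))
  }
  ## concatenate the filter with N spacers; the aligner never reports a
  ## site overlapping an N, so hits cannot bridge two decoys
  ref <- paste(fs$seqs, collapse = strrep("N", 60L))
  hits <- cpp_align_all(reads$seq, ref, fs$max_mismatches)
  matched <- logical(nrow(reads))
  if (nrow(hits) > 0L) matched[unique(hits$read)] <- TRUE
  ncrna <- as_distinct_set(reads[matched, , drop = FALSE], library = lib)
  surviving <- as_distinct_set(reads[!matched, , drop = FALSE],
                               library = lib)
  list(ncrna = ncrna, surviving = surviving,
       stats = partition_stats(reads, ncrna, surviving))
}

partition_stats <- function(reads, ncrna, surviving) {
  tot <- read_total(reads)
  data.frame(
    bidirectional_identical = tot,
    ncrna = read_total(ncrna),
    ncrna_pct = if (tot) 100 * read_total(ncrna) / tot else NA_real_,
    not_ncrna = read_total(surviving),
    not_ncrna_pct = if (tot) 100 * read_total(surviving) / tot else NA_real_,
    distinct = distinct_total(reads),
    ncrna_distinct = distinct_total(ncrna),
    not_ncrna_distinct = distinct_total(surviving))
}
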