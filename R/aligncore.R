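## Short-read alignment surface: exhaustive bounded-mismatch enumeration on
## both strands (C++ seed-and-extend core), mapping-multiplicity
## classification, two-pass chr1(+chrM) -> chr2 orchestration, and SAM /
## bedGraph track export.

#' Alignment policy
#'
#' @param max_mismatches maximum substitutions allowed (no indels). The
#'   stringent genome policy is 1; the lenient ncRNA-filter policy is 3.
#' @param multi_cap number of sites at or beyond which a read is classed
#'   as high-multiplicity ("&gt;= 10 map sites").
#' @param report_mode `"all_sites"` retains every placement (visualisation,
#'   Venn classification); `"random_one"` retains a single random placement
#'   per read (positional statistics).
#' @return object of class `AlignPolicy`.
#' @export
align_policy <- function(max_mismatches = 1L, multi_cap = 10L,
                         report_mode = c("all_sites", "random_one")) {
  stopifnot(max_mismatches >= 0L, multi_cap >= 2L)
  out <- list(max_mismatches = as.integer(max_mismatches),
              multi_cap = as.integer(multi_cap),
              report_mode = match.arg(report_mode))
  class(out) <- "AlignPolicy"
  out
}

ref_sequence <- function(ref) {
  if (inherits(ref, "ConcatReference")) ref$sequence else ref
}

#' Enumerate all alignment sites of reads on a reference
#'
#' Complete enumeration of substitution-only placements on both strands
#' with at most `policy$max_mismatches` mismatches. Placements overlapping
#' any non-ACGT reference base (the N spacers) are excluded, so a hit can
#' never bridge two concatenated records.
#'
#' @param reads character vector of read sequences (A/C/G/T, length >= 16),
#'   or a `DistinctReadSet`.
#' @param ref a `ConcatReference` or a plain reference string.
#' @param policy an [align_policy()].
#' @return data.frame with columns `seq`, `count` (1 when counts are
#'   unavailable), `record_id`, `start` (0-based local), `strand`,
#'   `mismatches`, `five_prime` (local 0-based coordinate of the read's 5'
#'   end on its own strand), sorted by (record_id, start, strand).
#' @export
align_read_all_sites <- function(reads, ref, policy = align_policy()) {
  counts <- NULL
  if (inherits(reads, "DistinctReadSet")) {
    counts <- reads$count
    reads <- reads$seq
  }
  if (length(reads) == 0L) return(empty_hits())
  if (any(nchar(reads) < 16L)) {
    stop("reads shorter than 16 nt are not supported by the aligner")
  }
  stop_if_not_dna(reads, "read")
  counts <- counts %||% rep(1L, length(reads))
  raw <- cpp_align_all(reads, ref_sequence(ref), policy$max_mismatches)
  if (nrow(raw) == 0L) return(empty_hits())
  len <- nchar(reads)[raw$read]
  if (inherits(ref, "ConcatReference")) {
    loc <- global_to_local(ref, raw$start)
    record_id <- loc$record_id
    start <- loc$local
  } else {
    record_id <- "ref"
    start <- raw$start
  }
  hits <- data.frame(seq = reads[raw$read],
                     count = counts[raw$read],
                     record_id = record_id,
                     start = as.integer(start),
                     strand = raw$strand,
                     mismatches = raw$mismatches,
                     five_prime = as.integer(
                       ifelse(raw$strand == "+", start, start + len - 1L)),
                     stringsAsFactors = FALSE)
  hits <- hits[order(hits$record_id, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(seq = character(0), count = integer(0),
             record_id = character(0), start = integer(0),
             strand = character(0), mismatches = integer(0),
             five_prime = integer(0), stringsAsFactors = FALSE)
}

## uniform draw of one hit per read over the deterministically sorted list
pick_random_one <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  idx <- split(seq_len(nrow(hits)), hits$seq)
  keep <- vapply(idx, function(i) {
    if (length(i) == 1L) i else i[sample.int(length(i), 1L)]
  }, 1L)
  out <- hits[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

classify_multiplicity <- function(n_sites, multi_cap) {
  cut(n_sites, breaks = c(0.5, 1.5, multi_cap - 0.5, Inf),
      labels = c("unique", "multi_2to9", "multi_ge10"))
}

#' Two-pass alignment of a read set against the macronuclear reference
#'
#' Pass 1 aligns all reads to the complete-nanochromosome reference (chr1)
#' and, when provided, the mitochondrial genome (chrM), with multiplicity
#' counted jointly over both; only reads unmapped in pass 1 proceed to the
#' partial-contig reference (chr2). In `random_one` mode a single placement
#' per read is drawn uniformly (seeded) over the sorted site list.
#'
#' @param reads a `DistinctReadSet`.
#' @param chr1 `ConcatReference` of complete nanochromosomes.
#' @param chr2 `ConcatReference` of partial contigs, or `NULL`.
#' @param chrM optional mitochondrial `ConcatReference` or sequence string.
#' @param policy an [align_policy()].
#' @param seed seed for the `random_one` draw.
#' @return list with `hits` (columns as [align_read_all_sites()] plus
#'   `target` in {"chr1","chrM","chr2"}), `summary` (one-row data.frame
#'   with distinct- and total-basis counts of `unmapped`, `unique`,
#'   `multi_2to9`, `multi_ge10` and `mapped_pct`), and `read_class`
#'   (per distinct read category).
#' @export
run_two_pass <- function(reads, chr1, chr2 = NULL, chrM = NULL,
                         policy = align_policy(), seed = 1L) {
  stopifnot(inherits(reads, "DistinctReadSet"))
  h1 <- align_read_all_sites(reads, chr1, policy)
  h1$target <- rep("chr1", nrow(h1))
  hM <- empty_hits()
  if (!is.null(chrM)) hM <- align_read_all_sites(reads, chrM, policy)
  hM$target <- rep("chrM", nrow(hM))
  pass1 <- rbind(h1, hM)
  mapped1 <- unique(pass1$seq)
  rest <- reads[!(reads$seq %in% mapped1), , drop = FALSE]
  pass2 <- empty_hits()
  if (!is.null(chr2) && nrow(rest) > 0L) {
    pass2 <- align_read_all_sites(as_distinct_set(rest), chr2, policy)
  }
  pass2$target <- rep("chr2", nrow(pass2))
  hits <- rbind(pass1, pass2)

  sites <- table(hits$seq)
  n_sites <- as.integer(sites[reads$seq])
  n_sites[is.na(n_sites)] <- 0L
  cls <- rep("unmapped", nrow(reads))
  mapped <- n_sites > 0L
  cls[mapped] <- as.character(
    classify_multiplicity(n_sites[mapped], policy$multi_cap))
  read_class <- data.frame(seq = reads$seq, count = reads$count,
                           n_sites = n_sites, class = cls,
                           stringsAsFactors = FALSE)

  if (policy$report_mode == "random_one") {
    hits <- withr::with_seed(seed, pick_random_one(hits))
  }

  agg <- function(sel, basis) {
    if (basis == "distinct") sum(sel) else sum(reads$count[sel])
  }
  summary <- data.frame(
    input_distinct = nrow(reads),
    input_total = read_total(reads),
    unmapped_distinct = agg(cls == "unmapped", "distinct"),
    unique_distinct = agg(cls == "unique", "distinct"),
    multi_2to9_distinct = agg(cls == "multi_2to9", "distinct"),
    multi_ge10_distinct = agg(cls == "multi_ge10", "distinct"),
    unmapped_total = agg(cls == "unmapped", "total"),
    unique_total = agg(cls == "unique", "total"),
    multi_2to9_total = agg(cls == "multi_2to9", "total"),
    multi_ge10_total = agg(cls == "multi_ge10", "total"))
  summary$mapped_pct <- if (summary$input_total) {
    100 * (summary$input_total - summary$unmapped_total) /
      summary$input_total
  } else NA_real_
  list(hits = hits, summary = summary, read_class = read_class)
}

#' Export alignments as SAM and per-strand bedGraph tracks
#'
#' SAM uses 1-based POS, FLAG bit 0x10 for minus-strand hits, an NM tag
#' with the mismatch count, and reference-strand SEQ. The bedGraph tracks
#' count read 5' ends per strand (one unit per hit).
#'
#' @param hits hit table from [align_read_all_sites()] / [run_two_pass()].
#' @param ref the `ConcatReference` the hits refer to (for `@SQ` headers
#'   and record lengths).
#' @param sam_path output SAM path, or `NULL` to skip.
#' @param bedgraph_prefix prefix for `<prefix>.plus.bedGraph` and
#'   `<prefix>.minus.bedGraph`, or `NULL` to skip.
#' @return invisible list of written paths.
#' @export
export_tracks <- function(hits, ref, sam_path = NULL,
                          bedgraph_prefix = NULL) {
  paths <- list()
  if (!is.null(sam_path)) {
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", ref$records$id,
                     ref$records$length))
    body <- character(0)
    if (nrow(hits) > 0L) {
      minus <- hits$strand == "-"
      seq_out <- hits$seq
      if (any(minus)) seq_out[minus] <- revcomp(seq_out[minus])
      body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                      sprintf("hit%06d", seq_len(nrow(hits))),
                      ifelse(minus, 16L, 0L),
                      hits$record_id, hits$start + 1L,
                      nchar(hits$seq), seq_out, hits$mismatches)
    }
    writeLines(c(hdr, body), sam_path)
    paths$sam <- sam_path
  }
  if (!is.null(bedgraph_prefix)) {
    for (s in c("+", "-")) {
      sel <- hits[hits$strand == s, , drop = FALSE]
      path <- paste0(bedgraph_prefix, if (s == "+") ".plus" else ".minus",
                     ".bedGraph")
      if (nrow(sel)) {
        key <- paste(sel$record_id, sel$five_prime)
        tab <- table(key)
        parts <- strsplit(names(tab), " ", fixed = TRUE)
        df <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                         start = as.integer(vapply(parts, `[`, "", 2L)),
                         stringsAsFactors = FALSE)
        df$end <- df$start + 1L
        df$value <- as.integer(tab)
        df <- df[order(df$chrom, df$start), , drop = FALSE]
        writeLines(sprintf("%s\t%d\t%d\t%d", df$chrom, df$start, df$end,
                           df$value), path)
      } else {
        writeLines(character(0), path)
      }
      paths[[if (s == "+") "bedgraph_plus" else "bedgraph_minus"]] <- path
    }
  }
  invisible(paths)
}
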