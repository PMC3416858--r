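## Concatenated macronuclear reference: nanochromosome records joined with
## 50-N spacers into one long sequence per chromosome file, with an exact
## offsets table and end-anchored telomere annotation. Coordinates are
## 0-based half-open internally; 1-based only in SAM export.

#' Build a concatenated reference from nanochromosome records
#'
#' @param records named character vector of sequences, or a FASTA path.
#' @param spacer_len number of N characters inserted between records.
#' @return object of class `ConcatReference` with fields `sequence` (one
#'   string), `records` (data.frame `id`, `length`, `offset`) and
#'   `spacer_len`.
#' @export
build_concat <- function(records, spacer_len = 50L) {
  if (length(records) == 1L && is.null(names(records)) &&
      file.exists(records)) {
    records <- read_fasta(records)
  }
  stopifnot(length(records) >= 1L, !is.null(names(records)))
  if (anyDuplicated(names(records))) stop("duplicate record ids")
  if (any(grepl("N", records, fixed = TRUE))) {
    stop("records must not contain N")
  }
  stop_if_not_dna(records)
  len <- nchar(records)
  offset <- cumsum(c(0L, utils::head(len + spacer_len, -1L)))
  seq <- paste(records, collapse = strrep("N", spacer_len))
  out <- list(sequence = seq,
              records = data.frame(id = names(records),
                                   length = unname(len),
                                   offset = unname(offset),
                                   stringsAsFactors = FALSE),
              spacer_len = as.integer(spacer_len))
  class(out) <- "ConcatReference"
  out
}

#' @export
print.ConcatReference <- function(x, ...) {
  cat("ConcatReference:", nrow(x$records), "records,",
      nchar(x$sequence), "nt total,", x$spacer_len, "N spacer\n")
  invisible(x)
}

#' Map global concatenated coordinates to per-record coordinates
#'
#' @param ref a `ConcatReference`.
#' @param gpos vector of 0-based global positions.
#' @return data.frame with `record_id` (`NA` for spacer positions) and
#'   `local` (0-based position within the record, `NA` for spacers).
#' @export
global_to_local <- function(ref, gpos) {
  total <- nchar(ref$sequence)
  if (any(gpos < 0L | gpos >= total)) stop("global position out of range")
  k <- findInterval(gpos, ref$records$offset)
  local <- gpos - ref$records$offset[k]
  in_record <- local < ref$records$length[k]
  data.frame(record_id = ifelse(in_record, ref$records$id[k], NA_character_),
             local = ifelse(in_record, local, NA_integer_),
             stringsAsFactors = FALSE)
}

#' Map per-record coordinates to global concatenated coordinates
#' @param ref a `ConcatReference`.
#' @param record_id vector of record ids.
#' @param local vector of 0-based local positions.
#' @return integer vector of 0-based global positions.
#' @export
local_to_global <- function(ref, record_id, local) {
  k <- match(record_id, ref$records$id)
  if (anyNA(k)) stop("unknown record id")
  if (any(local < 0L | local >= ref$records$length[k])) {
    stop("local position out of range")
  }
  ref$records$offset[k] + as.integer(local)
}

## longest end-anchored run of the cyclic repeat of `pat`, any phase
prefix_run <- function(seq, pat) {
  u <- nchar(pat)
  m <- min(nchar(seq), 10L * u + 200L)
  if (m == 0L) return(0L)
  target <- charToRaw(substr(seq, 1L, m))
  ext <- strrep(pat, ceiling(m / u) + 2L)
  best <- 0L
  for (p in seq_len(u)) {
    ref <- charToRaw(substr(ext, p, p + m - 1L))
    d <- which(target != ref)
    run <- if (length(d)) d[1L] - 1L else m
    if (run > best) best <- run
  }
  best
}

reverse_chars <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""), "")
}

#' Annotate terminal telomeric repeats of a nanochromosome record
#'
#' Measures the maximal end-anchored runs (in any phase, allowing a partial
#' terminal repeat) of the telomere unit or its reverse complement at each
#' end. Records failing `min_run` at either end are flagged as partial
#' contigs.
#'
#' @param seq record sequence.
#' @param unit telomere repeat unit.
#' @param min_run minimum run length (nt) for an end to count as telomeric.
#' @return list with `tel5`, `tel3` (run lengths in nt) and `complete`
#'   (both ends at or above `min_run`).
#' @export
locate_telomeres <- function(seq, unit = "GGGGTTTT", min_run = 12L) {
  rc <- revcomp(unit)
  tel5 <- max(prefix_run(seq, unit), prefix_run(seq, rc))
  rseq <- reverse_chars(seq)
  runit <- reverse_chars(unit)
  rrc <- reverse_chars(rc)
  tel3 <- max(prefix_run(rseq, runit), prefix_run(rseq, rrc))
  list(tel5 = tel5, tel3 = tel3,
       complete = tel5 >= min_run && tel3 >= min_run)
}

#' Annotate telomeres for a set of records
#' @param records named character vector of sequences.
#' @param unit telomere repeat unit.
#' @param min_run minimum run length for a telomeric end.
#' @return data.frame `id`, `length`, `tel5`, `tel3`, `complete`.
#' @export
annotate_telomeres <- function(records, unit = "GGGGTTTT", min_run = 12L) {
  ann <- lapply(records, locate_telomeres, unit = unit, min_run = min_run)
  data.frame(id = names(records), length = unname(nchar(records)),
             tel5 = vapply(ann, `[[`, 0L, "tel5"),
             tel3 = vapply(ann, `[[`, 0L, "tel3"),
             complete = vapply(ann, `[[`, NA, "complete"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Split records into complete and partial reference files
#'
#' Records with telomeres detected at both ends form the complete
#' collection (chr1); the remainder form the partial-contig collection
#' (chr2). Each collection is concatenated with N spacers.
#'
#' @param records named character vector of sequences, or a FASTA path.
#' @param unit telomere repeat unit.
#' @param min_run minimum telomeric run per end.
#' @param spacer_len spacer length between records.
#' @return list with `chr1`, `chr2` (`ConcatReference` or `NULL` when a
#'   class is empty) and `annotation` (see [annotate_telomeres()]).
#' @export
split_reference <- function(records, unit = "GGGGTTTT", min_run = 12L,
                            spacer_len = 50L) {
  if (length(records) == 1L && is.null(names(records)) &&
      file.exists(records)) {
    records <- read_fasta(records)
  }
  ann <- annotate_telomeres(records, unit, min_run)
  complete <- records[ann$complete]
  partial <- records[!ann$complete]
  list(chr1 = if (length(complete)) build_concat(complete, spacer_len),
       chr2 = if (length(partial)) build_concat(partial, spacer_len),
       annotation = ann)
}

#' Write the offsets/annotation table of a reference
#' @param ref a `ConcatReference`.
#' @param path output TSV.
#' @param annotation optional telomere annotation to merge in.
#' @return `path`, invisibly.
#' @export
write_offsets <- function(ref, path, annotation = NULL) {
  df <- ref$records
  if (!is.null(annotation)) {
    df <- merge(df, annotation[, c("id", "tel5", "tel3", "complete")],
                by = "id", sort = FALSE)
  }
  write_tsv(df, path)
}

#' Rebuild a concatenated sequence from records and an offsets table
#'
#' Inverse of [build_concat()]: placing each record at its tabulated offset
#' with N fill reproduces the concatenated sequence byte-for-byte.
#'
#' @param records named character vector of record sequences.
#' @param offsets data.frame with `id`, `length`, `offset`.
#' @param spacer_len spacer length.
#' @return character scalar.
#' @export
rebuild_concat <- function(records, offsets, spacer_len = 50L) {
  offsets <- offsets[order(offsets$offset), , drop = FALSE]
  total <- offsets$offset[nrow(offsets)] + offsets$length[nrow(offsets)]
  chars <- rep("N", total)
  for (i in seq_len(nrow(offsets))) {
    s <- strsplit(records[[offsets$id[i]]], "")[[1]]
    chars[offsets$offset[i] + seq_along(s)] <- s
  }
  paste(chars, collapse = "")
}
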