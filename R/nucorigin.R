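## Micronuclear-vs-macronuclear origin classification: distinct 26-28 nt
## reads are aligned to the trimmed micronuclear and macronuclear versions
## of a gene (both strands, all placements retained) and tallied as a Venn
## diagram. A read found only in the micronuclear version must overlap IES
## sequence; a read found only in the macronuclear version must span an
## MDS/MDS junction beyond the pointer on both sides.

#' Construct a micronuclear/macronuclear gene pair
#'
#' The sequences are expected to be trimmed so that all macronuclear
#' sequence is contained within the micronuclear clone: length differences
#' are then due only to IESs and duplicated pointers.
#'
#' @param name gene name.
#' @param micro,macro micronuclear / macronuclear sequences (character) or
#'   single-record FASTA paths.
#' @param n_mds number of MDSs (annotation only, may be `NA`).
#' @param scrambled logical flag (annotation only, may be `NA`).
#' @param decomposition optional MDS decomposition: a list with elements
#'   `mds_list`, `ies_seqs`, `pointer_lens` as produced by
#'   [gen_micro_locus()].
#' @return object of class `GenePair`.
#' @export
gene_pair <- function(name, micro, macro, n_mds = NA, scrambled = NA,
                      decomposition = NULL) {
  grab <- function(x) {
    if (length(x) == 1L && !grepl("^[ACGTN]+$", x) && file.exists(x)) {
      unname(read_fasta(x)[1L])
    } else x
  }
  micro <- grab(micro); macro <- grab(macro)
  stop_if_not_dna(c(micro, macro), "gene pair sequence")
  out <- list(name = name, micro = micro, macro = macro,
              n_mds = n_mds, scrambled = scrambled,
              decomposition = decomposition)
  class(out) <- "GenePair"
  out
}

#' Gene pair from a synthetic nanochromosome and its micronuclear locus
#'
#' The macronuclear side is the telomere-trimmed interior, so that all
#' macronuclear sequence is contained within the micronuclear sequence.
#'
#' @param gene a `MacroGene`.
#' @param locus the matching `MicroLocus`.
#' @return a `GenePair` carrying the full decomposition.
#' @export
as_gene_pair <- function(gene, locus) {
  stopifnot(identical(gene$id, locus$gene_id))
  gene_pair(gene$id, micro = locus$micro_sequence,
            macro = macro_interior(gene),
            n_mds = nrow(locus$mds_list), scrambled = locus$scrambled,
            decomposition = locus)
}

#' Validate a micronuclear/macronuclear gene pair
#'
#' With a decomposition, checks the length identity
#' `micro = macro + sum(IES) + sum(pointer)` and that IES removal, pointer
#' deduplication and unscrambling reproduce the macronuclear sequence
#' exactly. Without one, reports whether the macronuclear sequence is
#' globally consistent with the micronuclear clone (report-only anchors:
#' shared terminal sequence).
#'
#' @param pair a `GenePair`.
#' @return list with `ok` (logical) and `messages` (character).
#' @export
validate_gene_pair <- function(pair) {
  msgs <- character(0)
  ok <- TRUE
  dec <- pair$decomposition
  if (!is.null(dec)) {
    expected <- nchar(pair$macro) + sum(nchar(dec$ies_seqs)) +
      sum(dec$pointer_lens)
    if (nchar(pair$micro) != expected) {
      ok <- FALSE
      msgs <- c(msgs, sprintf(
        "micro length %d != macro + IES + pointer = %d",
        nchar(pair$micro), expected))
    }
    rec <- tryCatch(reconstruct_macro(dec), error = function(e) e)
    if (inherits(rec, "error")) {
      ok <- FALSE
      msgs <- c(msgs, paste("reassembly failed:", conditionMessage(rec)))
    } else if (!identical(rec, pair$macro)) {
      d <- which(strsplit(rec, "")[[1]] != strsplit(pair$macro, "")[[1]])
      ok <- FALSE
      msgs <- c(msgs, sprintf(
        "reassembly mismatch at macro position %d",
        if (length(d)) d[1L] else nchar(pair$macro) + 1L))
    }
  } else {
    if (nchar(pair$micro) < nchar(pair$macro)) {
      ok <- FALSE
      msgs <- c(msgs, "micro shorter than macro: pair cannot be trimmed correctly")
    }
    msgs <- c(msgs, "no decomposition supplied: report-only length check")
  }
  list(ok = ok, messages = msgs)
}

#' Venn classification of 26-28 nt reads against a gene pair
#'
#' Each distinct read in the 26-28 nt band is aligned (both strands, all
#' placements, substitution-only) to the micronuclear and macronuclear
#' sequences; membership booleans are combined into Venn counts on the
#' distinct-read basis.
#'
#' @param reads a `DistinctReadSet` or character vector of sequences.
#' @param pair a `GenePair`.
#' @param max_mismatches mismatch budget (default 0 for determinism).
#' @param lengths length band retained (default 26-28 nt).
#' @return one-row data.frame of class `VennCounts` with columns `Gene`,
#'   `MicroLength`, `MacroLength`, `MDSs`, `Scrambled`, `MicroCount`,
#'   `MacroCount`, `UnionCount`, `XsectCount`, `XsectPct`,
#'   `OnlyMicroCount`, `OnlyMicroPct`, `OnlyMacroCount`, `OnlyMacroPct`.
#' @export
classify_venn <- function(reads, pair, max_mismatches = 0L,
                          lengths = 26:28) {
  seqs <- if (inherits(reads, "DistinctReadSet")) reads$seq else reads
  seqs <- unique(seqs[nchar(seqs) %in% lengths])
  in_micro <- in_macro <- logical(length(seqs))
  if (length(seqs)) {
    pol <- align_policy(max_mismatches = max_mismatches)
    hm <- align_read_all_sites(seqs, pair$micro, pol)
    hM <- align_read_all_sites(seqs, pair$macro, pol)
    in_micro <- seqs %in% hm$seq
    in_macro <- seqs %in% hM$seq
  }
  xsect <- sum(in_micro & in_macro)
  only_mic <- sum(in_micro & !in_macro)
  only_mac <- sum(!in_micro & in_macro)
  union <- xsect + only_mic + only_mac
  pct <- function(x) if (union) 100 * x / union else 0
  out <- data.frame(Gene = pair$name,
                    MicroLength = nchar(pair$micro),
                    MacroLength = nchar(pair$macro),
                    MDSs = pair$n_mds, Scrambled = pair$scrambled,
                    MicroCount = xsect + only_mic,
                    MacroCount = xsect + only_mac,
                    UnionCount = union, XsectCount = xsect,
                    XsectPct = pct(xsect),
                    OnlyMicroCount = only_mic, OnlyMicroPct = pct(only_mic),
                    OnlyMacroCount = only_mac, OnlyMacroPct = pct(only_mac),
                    stringsAsFactors = FALSE)
  class(out) <- c("VennCounts", "data.frame")
  out
}

#' Venn classification pooled over several libraries
#'
#' In `"sum"` mode (the conventional per-gene tabulation) each library is
#' classified separately and the per-library
#' distinct counts are added. In `"union"` mode the distinct sequences of
#' all libraries are pooled first and classified once.
#'
#' @param reads_list list of `DistinctReadSet`s (or character vectors), one
#'   per library.
#' @param pair a `GenePair`.
#' @param mode `"sum"` or `"union"`.
#' @param ... passed to [classify_venn()].
#' @return a `VennCounts` row.
#' @export
pool_venn <- function(reads_list, pair, mode = c("sum", "union"), ...) {
  mode <- match.arg(mode)
  if (mode == "union") {
    seqs <- unique(unlist(lapply(reads_list, function(r) {
      if (inherits(r, "DistinctReadSet")) r$seq else r
    })))
    return(classify_venn(seqs, pair, ...))
  }
  rows <- lapply(reads_list, classify_venn, pair = pair, ...)
  out <- rows[[1L]]
  countcols <- c("MicroCount", "MacroCount", "UnionCount", "XsectCount",
                 "OnlyMicroCount", "OnlyMacroCount")
  for (cc in countcols) {
    out[[cc]] <- sum(vapply(rows, function(r) r[[cc]], 0L))
  }
  u <- out$UnionCount
  pct <- function(x) if (u) 100 * x / u else 0
  out$XsectPct <- pct(out$XsectCount)
  out$OnlyMicroPct <- pct(out$OnlyMicroCount)
  out$OnlyMacroPct <- pct(out$OnlyMacroCount)
  out
}

#' Combine per-gene Venn rows into one table
#'
#' @param venn_list list of `VennCounts` rows.
#' @param digits decimal places used for the percentage columns.
#' @return data.frame with one row per gene, with rounded percentage
#'   columns.
#' @export
tabulate_venn <- function(venn_list, digits = 2L) {
  stopifnot(length(venn_list) >= 1L)
  df <- do.call(rbind, venn_list)
  for (cc in c("XsectPct", "OnlyMicroPct", "OnlyMacroPct")) {
    df[[cc]] <- round(df[[cc]], digits)
  }
  rownames(df) <- NULL
  df
}
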