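#' @useDynLib macrna27, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rgamma rlnorm rnorm rpois runif quantile cor
#' @importFrom utils write.table read.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors, delegating to
#' [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## fast scalar revcomp without DNAStringSet overhead (hot inner loops)
revcomp1 <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a named character vector of sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Light FASTQ reader tolerant of empty files and of ground-truth tags kept
#' in the description line. Gzip input is handled transparently.
#'
#' @param path FASTQ file (optionally gzipped).
#' @return data.frame with columns `name`, `comment`, `seq`.
#' @export
read_fastq <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L) {
    return(data.frame(name = character(0), comment = character(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: number of lines not a multiple of 4: ", path)
  }
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  seq <- lines[seq(2L, length(lines), by = 4L)]
  hdr <- sub("^@", "", hdr)
  has_comment <- grepl(" ", hdr, fixed = TRUE)
  name <- sub(" .*$", "", hdr)
  comment <- ifelse(has_comment, sub("^[^ ]+ ", "", hdr), "")
  data.frame(name = name, comment = comment, seq = seq,
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTQ with constant quality
#' @param name,comment,seq parallel character vectors.
#' @param path output path; `.gz` suffix enables compression.
#' @param qual_char quality character applied to every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(name, comment, seq, path, qual_char = "I") {
  hdr <- ifelse(nzchar(comment), paste0("@", name, " ", comment),
                paste0("@", name))
  qual <- vapply(nchar(seq), function(n) strrep(qual_char, n), "")
  out <- as.vector(rbind(hdr, seq, "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stop_if_not_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(what, " contains characters outside {A,C,G,T}: first offender ",
         x[which(bad)[1L]])
  }
  invisible(TRUE)
}
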