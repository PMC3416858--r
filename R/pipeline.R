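## End-to-end orchestration: paired FASTQ -> bidirectional-identity
## collapse -> ncRNA filter -> reference split/concatenation -> two-pass
## alignment -> size, strand, coverage and telomere statistics, with
## per-stage read conservation checks and a JSON run manifest.

#' Pipeline run configuration
#'
#' @param fastq1,fastq2 paired FASTQ paths.
#' @param genome_fasta FASTA of nanochromosome records; complete and
#'   partial records are separated by telomere annotation.
#' @param ncrna_fasta FASTA of ncRNA decoys (optional; the telomeric decoy
#'   is always included).
#' @param chrm_fasta optional mitochondrial genome FASTA.
#' @param out_dir output directory.
#' @param seed seed for the random-placement draw; recorded in the
#'   manifest.
#' @param prep a [prep_config()].
#' @param filter_mismatches lenient mismatch budget of the ncRNA filter.
#' @param policy an [align_policy()] for genome mapping.
#' @param envelope an [envelope_config()].
#' @param profile a [profile_config()].
#' @param telomere_unit telomeric repeat unit.
#' @param library library label.
#' @return object of class `RunConfig`.
#' @export
run_config <- function(fastq1, fastq2, genome_fasta, ncrna_fasta = NULL,
                       chrm_fasta = NULL, out_dir = tempfile("macrna27_"),
                       seed = 1L, prep = prep_config(),
                       filter_mismatches = 3L,
                       policy = align_policy(max_mismatches = 1L,
                                             report_mode = "random_one"),
                       envelope = envelope_config(),
                       profile = profile_config(),
                       telomere_unit = "GGGGTTTT",
                       library = "lib1") {
  paths <- c(fastq1 = fastq1, fastq2 = fastq2, genome_fasta = genome_fasta)
  if (!is.null(ncrna_fasta)) paths <- c(paths, ncrna_fasta = ncrna_fasta)
  if (!is.null(chrm_fasta)) paths <- c(paths, chrm_fasta = chrm_fasta)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input file(s) not found: ",
         paste(names(missing), missing, sep = "=", collapse = ", "))
  }
  out <- list(fastq1 = fastq1, fastq2 = fastq2,
              genome_fasta = genome_fasta, ncrna_fasta = ncrna_fasta,
              chrm_fasta = chrm_fasta, out_dir = out_dir,
              seed = as.integer(seed), prep = prep,
              filter_mismatches = as.integer(filter_mismatches),
              policy = policy, envelope = envelope, profile = profile,
              telomere_unit = telomere_unit, library = library)
  class(out) <- "RunConfig"
  out
}

#' Run the full small RNA pipeline
#'
#' Stage order: bidirectional-identity collapse, ncRNA filter, reference
#' construction (complete records -> chr1, partial -> chr2), two-pass
#' alignment (chr1 + chrM, then chr2), then length histogram, position
#' frequency matrix, strand-count table with envelope statistics,
#' coverage CV, and telomere-proximal profiles. Read conservation is
#' checked after every partitioning stage and a violation aborts the run.
#'
#' @param cfg a [run_config()].
#' @param write_outputs write TSV/SAM/bedGraph outputs under
#'   `cfg$out_dir`.
#' @return invisible list with every stage result (`prep`, `partition`,
#'   `reference`, `mapping`, `histogram`, `posfreq`, `strand_rows`,
#'   `envelope_stats`, `cv`, `profile`, `depletion`, `manifest`).
#' @export
run_pipeline <- function(cfg, write_outputs = TRUE) {
  stopifnot(inherits(cfg, "RunConfig"))
  if (write_outputs) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  }

  prep <- prep_fastq_pair(cfg$fastq1, cfg$fastq2, cfg$prep,
                          library = cfg$library)
  st <- prep$stats
  if (st$kept + st$rejected_adapter + st$rejected_identity +
      st$rejected_length != st$total_pairs) {
    stop("read conservation violated at the prep stage")
  }

  fs <- build_filter_set(cfg$ncrna_fasta, cfg$telomere_unit,
                         cfg$filter_mismatches)
  part <- partition_reads(prep$distinct, fs)
  if (read_total(part$ncrna) + read_total(part$surviving) !=
      read_total(prep$distinct) ||
      distinct_total(part$ncrna) + distinct_total(part$surviving) !=
      distinct_total(prep$distinct)) {
    stop("read conservation violated at the ncRNA filter stage")
  }

  refs <- split_reference(cfg$genome_fasta, cfg$telomere_unit)
  if (is.null(refs$chr1)) stop("no complete nanochromosomes in the reference")
  chrm <- if (!is.null(cfg$chrm_fasta)) build_concat(cfg$chrm_fasta)

  map <- run_two_pass(part$surviving, refs$chr1, refs$chr2, chrm,
                      cfg$policy, seed = cfg$seed)
  ms <- map$summary
  if (ms$unmapped_distinct + ms$unique_distinct + ms$multi_2to9_distinct +
      ms$multi_ge10_distinct != ms$input_distinct) {
    stop("read conservation violated at the mapping stage")
  }

  hist <- length_histogram(part$surviving, map$hits)
  modal_len <- hist$length[which.max(hist$mapped_distinct)]
  posfreq <- tryCatch(position_freq(part$surviving, modal_len),
                      error = function(e) NULL)

  chr1_hits <- map$hits[map$hits$target == "chr1", , drop = FALSE]
  rows <- strand_count_table(chr1_hits, cfg$envelope)
  envelope_stats <- NULL
  if (nrow(rows) >= 2L) {
    inside <- envelope_membership(rows$plus_total, rows$minus_total,
                                  cfg$envelope)
    envelope_stats <- data.frame(
      n_records = nrow(rows),
      pearson_total = pearson_r(rows, "total"),
      pearson_distinct = pearson_r(rows, "distinct"),
      inside_fraction = mean(inside),
      empirical_band = if (nrow(rows) >= 20L) {
        empirical_band(rows, cfg$envelope)
      } else NA_real_)
  }
  cv <- coverage_cv_table(chr1_hits, refs$chr1$records)
  ann1 <- refs$annotation[refs$annotation$complete, , drop = FALSE]
  profile <- tryCatch(
    telomere_end_profile(chr1_hits, ann1, cfg$profile, strand = "+"),
    error = function(e) NULL)
  depletion <- tryCatch(
    depletion_fold(chr1_hits, ann1, cfg$profile),
    error = function(e) NULL)

  manifest <- list(
    package = "macrna27",
    version = as.character(utils::packageVersion("macrna27")),
    seed = cfg$seed, library = cfg$library,
    inputs = list(fastq1 = cfg$fastq1, fastq2 = cfg$fastq2,
                  genome = cfg$genome_fasta,
                  ncrna = cfg$ncrna_fasta %||% NA,
                  chrm = cfg$chrm_fasta %||% NA),
    policy = unclass(cfg$policy),
    filter_mismatches = cfg$filter_mismatches,
    conservation = list(prep = TRUE, filter = TRUE, mapping = TRUE),
    counts = list(total_pairs = st$total_pairs, kept = st$kept,
                  ncrna = read_total(part$ncrna),
                  surviving = read_total(part$surviving),
                  mapped_pct = ms$mapped_pct))

  if (write_outputs) {
    od <- cfg$out_dir
    write_tsv(st, file.path(od, "prep_summary.tsv"))
    write_tsv(part$stats, file.path(od, "ncrna_partition.tsv"))
    write_offsets(refs$chr1, file.path(od, "chr1_offsets.tsv"),
                  refs$annotation)
    if (!is.null(refs$chr2)) {
      write_offsets(refs$chr2, file.path(od, "chr2_offsets.tsv"))
    }
    write_tsv(ms, file.path(od, "mapping_summary.tsv"))
    write_tsv(hist, file.path(od, "length_histogram.tsv"))
    if (!is.null(posfreq)) {
      write_tsv(data.frame(position = seq_len(nrow(posfreq)), posfreq),
                file.path(od, sprintf("posfreq_%d.tsv", modal_len)))
    }
    write_tsv(rows, file.path(od, "strand_counts.tsv"))
    if (!is.null(envelope_stats)) {
      write_tsv(envelope_stats, file.path(od, "envelope.tsv"))
    }
    write_tsv(cv, file.path(od, "coverage_cv.tsv"))
    if (!is.null(profile)) {
      write_tsv(profile, file.path(od, "end_profile.tsv"))
    }
    if (!is.null(depletion)) {
      write_tsv(depletion, file.path(od, "depletion.tsv"))
    }
    export_tracks(chr1_hits, refs$chr1,
                  sam_path = file.path(od, "chr1_hits.sam"),
                  bedgraph_prefix = file.path(od, "chr1"))
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  invisible(list(prep = prep, filter = fs, partition = part,
                 reference = refs, mapping = map, histogram = hist,
                 modal_mapped_length = modal_len, posfreq = posfreq,
                 strand_rows = rows, envelope_stats = envelope_stats,
                 cv = cv, profile = profile, depletion = depletion,
                 manifest = manifest))
}
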