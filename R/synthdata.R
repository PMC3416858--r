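## Synthetic data generator emulating ciliate nuclear dimorphism:
## macronuclear nanochromosomes with telomeres at both ends, micronuclear
## precursor loci with IESs flanked by duplicated pointers (optionally
## scrambled / inverted), bidirectional small RNA production with length
## classes, 5'-U bias, gamma-distributed per-position hotspots, subtelomeric
## depletion, ncRNA contamination, and paired-end FASTQ emission.

#' Configuration for the synthetic data generator
#'
#' Holds every tunable of the simulator. Defaults reflect the biology of
#' *Oxytricha trifallax*: nanochromosomes of mean length ~2,200 nt with
#' `GGGGTTTT` telomeric repeats (~20 nt per end), mating-type small RNA
#' length classes 26:27:28 weighted 0.1:0.8:0.1, a 5'-U probability of
#' 0.97, equal production from both strands, strongly non-uniform
#' per-position production rates (gamma shape 0.05), and an 8-fold
#' depleted zone over the 30 positions interior to each telomere.
#'
#' @param seed integer seed; all randomness in a bundle flows from it.
#' @param n_nano number of nanochromosomes to simulate.
#' @param nano_len_mean,nano_len_sd nanochromosome length distribution (nt);
#'   lengths are clipped from below so every gene can host telomeres,
#'   depletion zones, and reads.
#' @param telomere_unit telomeric repeat unit on the 3' end of the plus
#'   strand (default `GGGGTTTT`).
#' @param telomere_len telomere length per end in nt (partial terminal
#'   repeats allowed).
#' @param gc interior GC fraction.
#' @param mode `"mating"` (length classes 26-28) or `"vegetative"` (20-22).
#' @param class_weights named numeric vector mapping read length to weight;
#'   defaults depend on `mode`.
#' @param reads_per_nano_mean mean number of reads per nanochromosome.
#' @param strand_p probability that a read is produced from the plus strand.
#' @param hotspot_shape gamma shape for per-position production rates;
#'   smaller values give spikier hotspots.
#' @param deplete_zone width (nt) of the depleted zone immediately interior
#'   to each telomere.
#' @param deplete_factor fold-reduction of production rate in the zone.
#' @param u5_bias probability that a read's 5' base is U (T in DNA space),
#'   achieved by reweighting candidate start positions, never by mutating
#'   the emitted sequence.
#' @param n_ncrna_decoys number of synthetic non-coding RNA decoy sequences.
#' @param ncrna_contam_frac fraction of the final pool drawn from decoys.
#' @param pair_error_rate per-base probability that read 2 disagrees with
#'   read 1 over the insert.
#' @param adapter3 3' sequencing adapter appended to inserts.
#' @param gene_abundance_sdlog sdlog of the per-gene lognormal abundance
#'   factor; nanochromosome copy number and transcription vary over orders
#'   of magnitude, which is what makes the between-strand scatter of real
#'   libraries span several decades.
#' @return an object of class `GeneratorConfig`.
#' @export
generator_config <- function(seed = 1L,
                             n_nano = 50L,
                             nano_len_mean = 2200,
                             nano_len_sd = 800,
                             telomere_unit = "GGGGTTTT",
                             telomere_len = 20L,
                             gc = 0.5,
                             mode = c("mating", "vegetative"),
                             class_weights = NULL,
                             reads_per_nano_mean = 500,
                             strand_p = 0.5,
                             hotspot_shape = 0.05,
                             deplete_zone = 30L,
                             deplete_factor = 8,
                             u5_bias = 0.97,
                             n_ncrna_decoys = 5L,
                             ncrna_contam_frac = 0.2,
                             pair_error_rate = 0,
                             adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                             gene_abundance_sdlog = 1) {
  mode <- match.arg(mode)
  if (is.null(class_weights)) {
    class_weights <- if (mode == "mating") {
      c("26" = 0.1, "27" = 0.8, "28" = 0.1)
    } else {
      c("20" = 0.3, "21" = 0.4, "22" = 0.3)
    }
  }
  stopifnot(is.numeric(class_weights), !is.null(names(class_weights)),
            all(class_weights >= 0), sum(class_weights) > 0)
  probs <- c(strand_p = strand_p, u5_bias = u5_bias,
             ncrna_contam_frac = ncrna_contam_frac,
             pair_error_rate = pair_error_rate, gc = gc)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  }
  if (telomere_len < 1) stop("telomere_len must be positive")
  stop_if_not_dna(telomere_unit, "telomere_unit")
  stop_if_not_dna(adapter3, "adapter3")
  min_len <- 2L * telomere_len + 2L * deplete_zone + 100L
  if (nano_len_mean < 500 || nano_len_mean < min_len) {
    stop("nano_len_mean admits sequences shorter than the minimum (",
         max(500L, min_len), " nt)")
  }
  cfg <- list(seed = as.integer(seed), n_nano = as.integer(n_nano),
              nano_len_mean = nano_len_mean, nano_len_sd = nano_len_sd,
              telomere_unit = telomere_unit,
              telomere_len = as.integer(telomere_len),
              gc = gc, mode = mode, class_weights = class_weights,
              reads_per_nano_mean = reads_per_nano_mean,
              strand_p = strand_p, hotspot_shape = hotspot_shape,
              deplete_zone = as.integer(deplete_zone),
              deplete_factor = deplete_factor, u5_bias = u5_bias,
              n_ncrna_decoys = as.integer(n_ncrna_decoys),
              ncrna_contam_frac = ncrna_contam_frac,
              pair_error_rate = pair_error_rate, adapter3 = adapter3,
              gene_abundance_sdlog = gene_abundance_sdlog,
              min_nano_len = max(500L, min_len))
  class(cfg) <- "GeneratorConfig"
  cfg
}

#' @export
print.GeneratorConfig <- function(x, ...) {
  cat("GeneratorConfig (", x$mode, " mode)\n", sep = "")
  cat("  nanochromosomes:", x$n_nano, "of mean length", x$nano_len_mean,
      "nt (telomere", x$telomere_len, "nt per end)\n")
  cat("  length classes:", paste(names(x$class_weights),
                                 x$class_weights, sep = ":",
                                 collapse = ", "), "\n")
  cat("  strand_p", x$strand_p, "| u5_bias", x$u5_bias,
      "| hotspot_shape", x$hotspot_shape,
      "| deplete", x$deplete_zone, "nt /", x$deplete_factor, "fold\n")
  invisible(x)
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## all distinct k-mers read around the cyclic repeat of a unit
cyclic_kmers <- function(unit, k = 12L) {
  rep_str <- strrep(unit, ceiling(k / nchar(unit)) + 1L)
  unique(vapply(seq_len(nchar(unit)),
                function(p) substr(rep_str, p, p + k - 1L), ""))
}

interior_has_telomere_run <- function(interior, unit, min_run = 12L) {
  pats <- c(cyclic_kmers(unit, min_run), cyclic_kmers(revcomp(unit), min_run))
  any(vapply(pats, function(p) grepl(p, interior, fixed = TRUE), logical(1)))
}

#' Generate one macronuclear nanochromosome
#'
#' The plus strand begins with `telomere_len` nt of the reverse-complement
#' telomeric repeat (`CCCCAAAA`-phase for the default unit) and ends with
#' `telomere_len` nt of the unit itself; the interior is random sequence at
#' the configured GC content and is guaranteed free of telomere-unit runs
#' of 12 nt or more.
#'
#' @param cfg a [generator_config()].
#' @param id sequence identifier.
#' @return an object of class `MacroGene` with fields `id`, `sequence`,
#'   `tel5_len`, `tel3_len`.
#' @export
gen_macro_gene <- function(cfg, id = "nano00001") {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  len <- max(cfg$min_nano_len,
             round(rnorm(1, cfg$nano_len_mean, cfg$nano_len_sd)))
  tl <- cfg$telomere_len
  unit <- cfg$telomere_unit
  rc_unit <- revcomp(unit)
  reps <- ceiling(tl / nchar(unit)) + 1L
  ## right-anchored run of the rc unit, so the 5' end reads CCCC... for the
  ## default GGGGTTTT unit, matching the C4A4 5' telomere of Oxytricha
  tel5 <- substr(strrep(rc_unit, reps),
                 nchar(rc_unit) * reps - tl + 1L, nchar(rc_unit) * reps)
  tel3 <- substr(strrep(unit, reps), 1L, tl)
  interior_len <- len - 2L * tl
  repeat {
    interior <- random_dna(interior_len, cfg$gc)
    if (!interior_has_telomere_run(interior, unit)) break
  }
  out <- list(id = id, sequence = paste0(tel5, interior, tel3),
              tel5_len = tl, tel3_len = tl)
  class(out) <- "MacroGene"
  out
}

#' Generate a set of nanochromosomes
#' @param cfg a [generator_config()]. The seed is applied before sampling.
#' @return list of `MacroGene` objects named by id.
#' @export
gen_macro_genes <- function(cfg) {
  genes <- lapply(seq_len(cfg$n_nano), function(i) {
    gen_macro_gene(cfg, sprintf("nano%05d", i))
  })
  names(genes) <- vapply(genes, `[[`, "", "id")
  genes
}

macro_interior <- function(gene) {
  substr(gene$sequence, gene$tel5_len + 1L,
         nchar(gene$sequence) - gene$tel3_len)
}

#' Generate a micronuclear precursor locus for a nanochromosome
#'
#' Decomposes the macronuclear interior into `n_mds` macronuclear-destined
#' sequences (MDSs) whose consecutive pairs overlap by a pointer of 2-20 nt
#' (the pointer is the actual macro subsequence at the junction, so it is
#' present twice in the micronuclear version and once in the macronuclear
#' version), inserts a random IES between consecutive MDSs in micronuclear
#' order, and optionally scrambles the MDS order and inverts MDSs. IES
#' boundary bases are re-drawn when they would extend a pointer and make
#' the junction ambiguous.
#'
#' @param gene a `MacroGene`.
#' @param n_mds number of MDSs (1 gives the degenerate identity locus).
#' @param scrambled if `TRUE`, the micronuclear MDS order is a non-identity
#'   permutation and one MDS is strand-inverted.
#' @param pointer_range inclusive range of pointer lengths.
#' @param ies_range inclusive range of IES lengths.
#' @param min_mds minimum MDS length (nt).
#' @return an object of class `MicroLocus`.
#' @export
gen_micro_locus <- function(gene, n_mds, scrambled = FALSE,
                            pointer_range = c(2L, 20L),
                            ies_range = c(20L, 80L),
                            min_mds = 40L) {
  stopifnot(inherits(gene, "MacroGene"), n_mds >= 1L)
  interior <- macro_interior(gene)
  lm <- nchar(interior)
  n_j <- n_mds - 1L
  gap <- min_mds + pointer_range[2L]
  if (lm < n_mds * gap) {
    stop("macro interior too short for ", n_mds, " MDSs with distinct pointers")
  }
  if (n_j > 0L) {
    ## junction coordinates c_j (0-based on the interior): MDS_j covers
    ## [a_j, b_j) with b_j = c_j + pl_j and a_{j+1} = c_j, so consecutive
    ## MDSs share the pointer interior[c_j, c_j + pl_j)
    slack <- lm - n_mds * gap
    extra <- if (n_j + 1L > 1L) {
      as.vector(stats::rmultinom(1, slack, rep(1, n_j + 1L)))
    } else slack
    cj <- cumsum(gap + extra[seq_len(n_j)])
    pl <- sample(seq(pointer_range[1L], pointer_range[2L]), n_j,
                 replace = TRUE)
    pointer_seqs <- substr(rep(interior, n_j), cj + 1L, cj + pl)
  } else {
    cj <- integer(0); pl <- integer(0); pointer_seqs <- character(0)
  }
  a <- c(0L, cj)
  b <- c(cj + pl, lm)
  macro_order <- seq_len(n_mds)
  if (scrambled && n_mds >= 2L) {
    repeat {
      micro_order <- sample(macro_order)
      if (!all(micro_order == macro_order)) break
    }
    strand <- rep("+", n_mds)
    strand[sample(n_mds, 1L)] <- "-"
  } else {
    micro_order <- macro_order
    strand <- rep("+", n_mds)
  }
  ## micro_order[k] = which MDS occupies micronuclear slot k
  mds <- data.frame(mds = macro_order, start = a, end = b,
                    micro_slot = match(macro_order, micro_order),
                    strand = strand, stringsAsFactors = FALSE)

  ies <- character(0)
  if (n_j > 0L) {
    ies <- vapply(seq_len(n_j), function(j) {
      s <- random_dna(sample(seq(ies_range[1L], ies_range[2L]), 1L), 0.5)
      s
    }, "")
  }
  pieces <- vapply(micro_order, function(m) {
    p <- substr(interior, a[m] + 1L, b[m])
    if (strand[m] == "-") revcomp1(p) else p
  }, "")
  ## disambiguate IES boundaries against the flanking micro sequence so
  ## pointers cannot be extended across an IES junction
  if (n_j > 0L) {
    alt <- function(ban) sample(setdiff(c("A", "C", "G", "T"), ban), 1L)
    for (j in seq_len(n_j)) {
      left <- pieces[j]         # micro slot j, ends with a pointer copy
      right <- pieces[j + 1L]   # micro slot j+1, begins with a pointer copy
      lst <- substr(left, nchar(left), nchar(left))
      rst <- substr(right, 1L, 1L)
      if (substr(ies[j], 1L, 1L) == rst) {
        substr(ies[j], 1L, 1L) <- alt(rst)
      }
      if (substr(ies[j], nchar(ies[j]), nchar(ies[j])) == lst) {
        substr(ies[j], nchar(ies[j]), nchar(ies[j])) <- alt(lst)
      }
    }
  }
  micro <- pieces[1L]
  if (n_j > 0L) {
    for (j in seq_len(n_j)) micro <- paste0(micro, ies[j], pieces[j + 1L])
  }
  out <- list(gene_id = gene$id, mds_list = mds, ies_seqs = ies,
              pointer_lens = pl, pointer_seqs = pointer_seqs,
              micro_sequence = micro, scrambled = scrambled)
  class(out) <- "MicroLocus"
  out
}

#' Reconstruct the macronuclear interior from a micronuclear locus
#'
#' Applies IES removal, pointer deduplication, and unscrambling (reordering
#' and strand restoration) to the micronuclear sequence, using the MDS
#' decomposition carried by the locus. Exact reconstruction of the
#' macronuclear interior is the round-trip invariant of the generator.
#'
#' @param locus a `MicroLocus`.
#' @return the reconstructed macronuclear interior (character scalar).
#' @export
reconstruct_macro <- function(locus) {
  stopifnot(inherits(locus, "MicroLocus"))
  mds <- locus$mds_list
  n <- nrow(mds)
  piece_len <- mds$end - mds$start
  ies_len <- nchar(locus$ies_seqs)
  ## micro slot boundaries
  slot_of <- mds$micro_slot
  len_in_slot <- piece_len[order(slot_of)]
  starts <- cumsum(c(0L, utils::head(len_in_slot, -1L) + ies_len))
  pieces_micro <- substr(rep(locus$micro_sequence, n),
                         starts + 1L, starts + len_in_slot)
  ## map back to macro order, restoring strand
  pieces_macro <- character(n)
  ord <- order(slot_of)             # ord[k] = MDS index in slot k
  for (k in seq_len(n)) {
    m <- ord[k]
    p <- pieces_micro[k]
    if (mds$strand[m] == "-") p <- revcomp1(p)
    pieces_macro[m] <- p
  }
  out <- pieces_macro[1L]
  if (n > 1L) {
    for (j in 2L:n) {
      pl <- locus$pointer_lens[j - 1L]
      overlap_prev <- substr(out, nchar(out) - pl + 1L, nchar(out))
      overlap_next <- substr(pieces_macro[j], 1L, pl)
      if (overlap_prev != overlap_next) {
        stop("pointer mismatch at junction ", j - 1L,
             ": reconstruction failed")
      }
      out <- paste0(out, substr(pieces_macro[j], pl + 1L,
                                nchar(pieces_macro[j])))
    }
  }
  out
}

#' Generate synthetic non-coding RNA decoy sequences
#' @param cfg a [generator_config()].
#' @param len_range length range of the decoys.
#' @return named character vector (`ncrna_001`, ...).
#' @export
gen_ncrna_decoys <- function(cfg, len_range = c(80L, 1500L)) {
  n <- cfg$n_ncrna_decoys
  if (n == 0L) return(character(0))
  lens <- sample(seq(len_range[1L], len_range[2L]), n, replace = TRUE)
  out <- vapply(lens, random_dna, "", gc = cfg$gc)
  names(out) <- sprintf("ncrna_%03d", seq_len(n))
  out
}

## per-position production rate vector for one gene and strand.
## Telomere positions produce nothing (telomeric RNAs reach the pipeline
## only through the ncRNA decoy channel); the deplete_zone positions
## immediately interior to each telomere are divided by deplete_factor;
## start positions are reweighted so the expected fraction of reads whose
## 5' base is U equals u5_bias.
position_rates <- function(gene, strand, cfg) {
  lg <- nchar(gene$sequence)
  rate <- rgamma(lg, shape = cfg$hotspot_shape, rate = 1)
  t5 <- gene$tel5_len; t3 <- gene$tel3_len
  rate[seq_len(t5)] <- 0
  rate[seq(lg - t3 + 1L, lg)] <- 0
  z <- cfg$deplete_zone
  if (z > 0L) {
    zone <- c(seq(t5 + 1L, min(lg, t5 + z)),
              seq(max(1L, lg - t3 - z + 1L), lg - t3))
    rate[zone] <- rate[zone] / cfg$deplete_factor
  }
  base <- strsplit(gene$sequence, "")[[1]]
  is_u_start <- if (strand == "+") base == "T" else base == "A"
  mt <- sum(rate[is_u_start]); mn <- sum(rate[!is_u_start])
  if (mt > 0) rate[is_u_start] <- rate[is_u_start] * cfg$u5_bias / mt
  if (mn > 0) rate[!is_u_start] <- rate[!is_u_start] * (1 - cfg$u5_bias) / mn
  rate
}

#' Generate a small RNA pool with ground-truth origin labels
#'
#' Draws reads from the nanochromosomes (both strands, gamma-hotspot
#' per-position rates with subtelomeric depletion and 5'-U reweighting),
#' optionally from IES-overlapping windows of micronuclear loci, and from
#' ncRNA decoys. Every macro-origin sequence is an exact substring of its
#' gene (plus strand) or the reverse complement of one (minus strand).
#'
#' @param genes list of `MacroGene` objects.
#' @param cfg a [generator_config()].
#' @param decoys named character vector of ncRNA decoys (or `NULL` for no
#'   contamination).
#' @param loci optional list of `MicroLocus` objects used when
#'   `micro_only_frac > 0`.
#' @param micro_only_frac fraction of reads drawn from IES-overlapping
#'   windows of the micronuclear loci.
#' @return a data.frame of class `SmallRNAPool` with columns `sequence`,
#'   `gene_id`, `strand`, `start` (0-based genome coordinate of the read's
#'   5' end on its own strand), `length`, `origin`.
#' @export
gen_small_rna_pool <- function(genes, cfg, decoys = NULL, loci = NULL,
                               micro_only_frac = 0) {
  stopifnot(length(genes) > 0L)
  lens <- as.integer(names(cfg$class_weights))
  wts <- as.numeric(cfg$class_weights)
  mean_adj <- cfg$reads_per_nano_mean /
    exp(cfg$gene_abundance_sdlog^2 / 2)
  parts <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    lg <- nchar(g$sequence)
    n_g <- rpois(1, mean_adj * rlnorm(1, 0, cfg$gene_abundance_sdlog))
    if (n_g == 0L) next
    if (lg < min(lens)) {
      warning("gene ", g$id, " too short for any read; skipped")
      next
    }
    rate <- list("+" = position_rates(g, "+", cfg),
                 "-" = position_rates(g, "-", cfg))
    strand <- ifelse(runif(n_g) < cfg$strand_p, "+", "-")
    rl <- lens[sample.int(length(lens), n_g, replace = TRUE, prob = wts)]
    start <- integer(n_g)
    seqs <- character(n_g)
    for (s in c("+", "-")) {
      for (L in lens) {
        sel <- which(strand == s & rl == L)
        if (!length(sel)) next
        r <- rate[[s]]
        if (s == "+") {
          valid <- seq_len(lg - L + 1L)
        } else {
          valid <- seq(L, lg)
        }
        p <- r[valid]
        if (sum(p) <= 0) p <- rep(1, length(valid))
        pos <- valid[sample.int(length(valid), length(sel),
                                replace = TRUE, prob = p)]
        start[sel] <- pos - 1L
        if (s == "+") {
          seqs[sel] <- substr(rep(g$sequence, length(sel)), pos, pos + L - 1L)
        } else {
          seqs[sel] <- revcomp(substr(rep(g$sequence, length(sel)),
                                      pos - L + 1L, pos))
        }
      }
    }
    parts[[gi]] <- data.frame(sequence = seqs, gene_id = g$id,
                              strand = strand, start = start, length = rl,
                              origin = "macro", stringsAsFactors = FALSE)
  }
  pool <- do.call(rbind, parts)
  if (is.null(pool)) {
    pool <- data.frame(sequence = character(0), gene_id = character(0),
                       strand = character(0), start = integer(0),
                       length = integer(0), origin = character(0),
                       stringsAsFactors = FALSE)
  }
  n_macro <- nrow(pool)

  if (micro_only_frac > 0 && length(loci) > 0L && n_macro > 0L) {
    n_mic <- round(n_macro * micro_only_frac / (1 - micro_only_frac))
    usable <- Filter(function(l) length(l$ies_seqs) > 0L, loci)
    if (n_mic > 0L && length(usable) > 0L) {
      rows <- lapply(seq_len(n_mic), function(i) {
        loc <- usable[[sample.int(length(usable), 1L)]]
        micro <- loc$micro_sequence
        ## IES positions in micro coordinates
        mds <- loc$mds_list
        piece_len <- (mds$end - mds$start)[order(mds$micro_slot)]
        ies_len <- nchar(loc$ies_seqs)
        ies_start <- cumsum(piece_len + c(0L, ies_len[-length(ies_len)]))[
          seq_along(ies_len)]          # 0-based start of each IES
        j <- sample.int(length(ies_len), 1L)
        L <- lens[sample.int(length(lens), 1L, prob = wts)]
        center <- ies_start[j] + sample.int(ies_len[j], 1L)
        st <- min(max(1L, center - sample.int(L, 1L) + 1L),
                  nchar(micro) - L + 1L)
        sq <- substr(micro, st, st + L - 1L)
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") sq <- revcomp1(sq)
        data.frame(sequence = sq, gene_id = loc$gene_id, strand = strand,
                   start = if (strand == "+") st - 1L else st + L - 2L,
                   length = L, origin = "micro_only",
                   stringsAsFactors = FALSE)
      })
      pool <- rbind(pool, do.call(rbind, rows))
    }
  }

  if (!is.null(decoys) && length(decoys) > 0L &&
      cfg$ncrna_contam_frac > 0 && n_macro > 0L) {
    n_nc <- round(nrow(pool) * cfg$ncrna_contam_frac /
                    (1 - cfg$ncrna_contam_frac))
    if (n_nc > 0L) {
      dlen <- nchar(decoys)
      di <- sample.int(length(decoys), n_nc, replace = TRUE,
                       prob = dlen / sum(dlen))
      L <- lens[sample.int(length(lens), n_nc, replace = TRUE, prob = wts)]
      L <- pmin(L, dlen[di])
      st <- vapply(seq_len(n_nc), function(i) {
        sample.int(dlen[di[i]] - L[i] + 1L, 1L)
      }, 1L)
      sq <- substr(decoys[di], st, st + L - 1L)
      strand <- sample(c("+", "-"), n_nc, replace = TRUE)
      sq[strand == "-"] <- revcomp(sq[strand == "-"])
      pool <- rbind(pool, data.frame(
        sequence = unname(sq), gene_id = names(decoys)[di], strand = strand,
        start = ifelse(strand == "+", st - 1L, st + L - 2L),
        length = L, origin = "ncrna", stringsAsFactors = FALSE))
    }
  }
  rownames(pool) <- NULL
  class(pool) <- c("SmallRNAPool", "data.frame")
  pool
}

#' Emit a small RNA pool as paired-end FASTQ
#'
#' Read 1 is the insert followed by the 3' adapter, padded to `read_len`;
#' read 2 is the reverse complement of the insert (with per-base
#' disagreement at `pair_error_rate`) followed by the adapter and padding.
#' Record comments carry ground-truth tags
#' (`gene=... strand=... start=... len=... origin=...`).
#'
#' @param pool a `SmallRNAPool` (may be empty).
#' @param cfg a [generator_config()].
#' @param path1,path2 output FASTQ paths (`.gz` enables compression).
#' @param read_len sequencing read length.
#' @return `c(path1, path2)`, invisibly.
#' @export
emit_paired_fastq <- function(pool, cfg, path1, path2, read_len = 100L) {
  n <- nrow(pool)
  pad <- strrep("A", read_len)
  if (n > 0L) {
    name <- sprintf("r%07d", seq_len(n))
    comment <- sprintf("gene=%s strand=%s start=%d len=%d origin=%s",
                       pool$gene_id, pool$strand, pool$start, pool$length,
                       pool$origin)
    r1 <- substr(paste0(pool$sequence, cfg$adapter3, pad), 1L, read_len)
    ins2 <- revcomp(pool$sequence)
    e <- cfg$pair_error_rate
    if (e > 0) {
      ## per-base disagreement of mate 2 over the insert
      nerr <- rbinom(n, nchar(ins2), e)
      idx <- which(nerr > 0L)
      for (i in idx) {
        s <- strsplit(ins2[i], "")[[1]]
        at <- sample.int(length(s), nerr[i])
        for (p in at) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
        ins2[i] <- paste(s, collapse = "")
      }
    }
    r2 <- substr(paste0(ins2, cfg$adapter3, pad), 1L, read_len)
    write_fastq(name, comment, r1, path1)
    write_fastq(name, comment, r2, path2)
  } else {
    write_fastq(character(0), character(0), character(0), path1)
    write_fastq(character(0), character(0), character(0), path2)
  }
  invisible(c(path1, path2))
}

#' Write the ground-truth table for a pool
#' @param pool a `SmallRNAPool`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(pool, path) {
  df <- data.frame(read_id = sprintf("r%07d", seq_len(nrow(pool))),
                   gene_id = pool$gene_id, strand = pool$strand,
                   start = pool$start, class = pool$length,
                   origin = pool$origin, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Simulate a complete fixture bundle
#'
#' Seeds the generator once and writes a genome FASTA, ncRNA decoy FASTA,
#' optional micronuclear locus FASTA + decomposition JSON, paired FASTQ,
#' ground-truth TSV, and a JSON echo of the configuration. Bundles are
#' bit-reproducible given `(seed, cfg)`.
#'
#' @param cfg a [generator_config()].
#' @param out_dir output directory (created if absent).
#' @param n_loci number of genes for which to also generate micronuclear
#'   precursor loci.
#' @param n_mds MDSs per generated locus.
#' @param scrambled logical, recycled over loci.
#' @param gzip compress the FASTQ output.
#' @return list with the generated objects and file paths.
#' @export
simulate_bundle <- function(cfg, out_dir, n_loci = 0L, n_mds = 5L,
                            scrambled = FALSE, gzip = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(cfg$seed, {
    genes <- gen_macro_genes(cfg)
    decoys <- gen_ncrna_decoys(cfg)
    loci <- NULL
    if (n_loci > 0L) {
      scrambled <- rep_len(scrambled, n_loci)
      loci <- lapply(seq_len(n_loci), function(i) {
        gen_micro_locus(genes[[i]], n_mds = n_mds, scrambled = scrambled[i])
      })
      names(loci) <- vapply(loci, `[[`, "", "gene_id")
    }
    pool <- gen_small_rna_pool(genes, cfg, decoys = decoys)
    ext <- if (gzip) ".fastq.gz" else ".fastq"
    paths <- list(
      genome = file.path(out_dir, "genome.fasta"),
      ncrna = file.path(out_dir, "ncrna.fasta"),
      fastq1 = file.path(out_dir, paste0("reads_R1", ext)),
      fastq2 = file.path(out_dir, paste0("reads_R2", ext)),
      truth = file.path(out_dir, "truth.tsv"),
      config = file.path(out_dir, "config.json"))
    write_fasta(vapply(genes, `[[`, "", "sequence"), paths$genome)
    if (length(decoys)) write_fasta(decoys, paths$ncrna)
    emit_paired_fastq(pool, cfg, paths$fastq1, paths$fastq2)
    write_truth_table(pool, paths$truth)
    jsonlite::write_json(unclass(cfg), paths$config, auto_unbox = TRUE)
    if (!is.null(loci)) {
      paths$micro <- file.path(out_dir, "micro_loci.fasta")
      write_fasta(vapply(loci, `[[`, "", "micro_sequence"), paths$micro)
    }
    list(genes = genes, decoys = decoys, loci = loci, pool = pool,
         paths = paths, cfg = cfg)
  })
}
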