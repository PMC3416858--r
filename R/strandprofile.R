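## Strand-balance, coverage-uniformity and telomere-proximal statistics.
##
## The strand-balance statistic models each read as falling on the plus
## strand with probability 1/2: with n = plus + minus reads on a
## nanochromosome, plus - minus has mean 0 and standard deviation sqrt(n),
## so the 2-SD envelope is |plus - minus| <= 2 sqrt(plus + minus) and about
## 95% of balanced nanochromosomes fall inside it.

#' Envelope configuration
#' @param k_sd standard-deviation multiplier of the binomial envelope.
#' @param min_per_strand minimum reads per strand for a nanochromosome to
#'   enter the strand-count table.
#' @param band_quantile quantile used for the empirical band.
#' @return object of class `EnvelopeConfig`.
#' @export
envelope_config <- function(k_sd = 2, min_per_strand = 10L,
                            band_quantile = 0.95) {
  stopifnot(k_sd > 0)
  out <- list(k_sd = k_sd, min_per_strand = as.integer(min_per_strand),
              band_quantile = band_quantile)
  class(out) <- "EnvelopeConfig"
  out
}

#' Profile configuration for telomere-proximal density
#' @param window window length anchored at each record end (nt).
#' @param bin bin width (nt); `window` must be divisible by `bin`.
#' @param zone width of the subtelomeric depletion zone (nt).
#' @param min_record_len minimum record length entering the profile.
#' @param read_len_shade read length marked on the 3'-end plus-strand
#'   profile (5' ends sit one read length interior to the record end).
#' @return object of class `ProfileConfig`.
#' @export
profile_config <- function(window = 500L, bin = 25L, zone = 30L,
                           min_record_len = 500L, read_len_shade = 27L) {
  stopifnot(window %% bin == 0L)
  out <- list(window = as.integer(window), bin = as.integer(bin),
              zone = as.integer(zone),
              min_record_len = as.integer(min_record_len),
              read_len_shade = as.integer(read_len_shade))
  class(out) <- "ProfileConfig"
  out
}

#' Per-nanochromosome strand read counts
#'
#' Counts 26-28 nt reads per strand of each record, on both the total
#' (count-weighted) and distinct bases, keeping records with at least
#' `min_per_strand` total reads on each strand.
#'
#' @param hits hit table (one placement per read, e.g. `random_one` mode)
#'   carrying `count`; filtered to the requested lengths internally.
#' @param cfg an [envelope_config()].
#' @param lengths read-length band (default 26-28 nt).
#' @return data.frame `record_id`, `plus_total`, `minus_total`,
#'   `plus_distinct`, `minus_distinct`.
#' @export
strand_count_table <- function(hits, cfg = envelope_config(),
                               lengths = 26:28) {
  h <- hits[nchar(hits$seq) %in% lengths, , drop = FALSE]
  ids <- unique(h$record_id)
  agg <- function(id, s, basis) {
    sel <- h$record_id == id & h$strand == s
    if (basis == "total") sum(h$count[sel]) else sum(sel)
  }
  rows <- lapply(ids, function(id) {
    data.frame(record_id = id,
               plus_total = agg(id, "+", "total"),
               minus_total = agg(id, "-", "total"),
               plus_distinct = agg(id, "+", "distinct"),
               minus_distinct = agg(id, "-", "distinct"),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(record_id = character(0), plus_total = integer(0),
               minus_total = integer(0), plus_distinct = integer(0),
               minus_distinct = integer(0), stringsAsFactors = FALSE)
  }
  keep <- out$plus_total >= cfg$min_per_strand &
    out$minus_total >= cfg$min_per_strand
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

strand_pair <- function(rows, basis = c("total", "distinct")) {
  basis <- match.arg(basis)
  if (basis == "total") {
    list(p = rows$plus_total, m = rows$minus_total)
  } else {
    list(p = rows$plus_distinct, m = rows$minus_distinct)
  }
}

#' Pearson correlation between plus- and minus-strand counts
#' @param rows output of [strand_count_table()].
#' @param basis `"total"` or `"distinct"`.
#' @return correlation coefficient, or `NA` with a warning when a strand
#'   has zero variance.
#' @export
pearson_r <- function(rows, basis = c("total", "distinct")) {
  if (nrow(rows) < 2L) stop("need at least two records")
  v <- strand_pair(rows, basis)
  if (stats::sd(v$p) == 0 || stats::sd(v$m) == 0) {
    warning("zero variance on a strand; correlation undefined")
    return(NA_real_)
  }
  cor(v$p, v$m)
}

#' Binomial envelope membership
#'
#' A record is inside the envelope iff
#' `|plus - minus| <= k_sd * sqrt(plus + minus)`; the boundary counts as
#' inside, and a record with zero reads is inside by convention.
#'
#' @param plus,minus numeric vectors of per-record strand counts.
#' @param cfg an [envelope_config()].
#' @return logical vector.
#' @export
envelope_membership <- function(plus, minus, cfg = envelope_config()) {
  n <- plus + minus
  inside <- abs(plus - minus) <= cfg$k_sd * sqrt(n)
  inside[n == 0] <- TRUE
  inside
}

#' Empirical envelope scale factor
#'
#' The `band_quantile` of `|plus - minus| / sqrt(plus + minus)` over the
#' rows: the envelope drawn with this multiplier contains that fraction of
#' the data (up to discreteness). Under the balanced binomial null the
#' factor approaches the matching normal quantile (1.96 for 95%).
#'
#' @param rows output of [strand_count_table()].
#' @param cfg an [envelope_config()].
#' @param basis `"total"` or `"distinct"`.
#' @return numeric scale factor.
#' @export
empirical_band <- function(rows, cfg = envelope_config(),
                           basis = c("total", "distinct")) {
  if (nrow(rows) < 20L) stop("need at least 20 records for the band")
  v <- strand_pair(rows, basis)
  n <- v$p + v$m
  z <- abs(v$p - v$m)[n > 0] / sqrt(n[n > 0])
  unname(quantile(z, cfg$band_quantile))
}

#' Coverage coefficient of variation of a record
#'
#' Tallies read 5' ends per position over every position of the record
#' (both strands pooled by default, each read counted at the 5' position on
#' its own strand) and returns population standard deviation over mean.
#' Uniform coverage gives 0; all reads stacked on a single position of an
#' L-position record give `sqrt(L - 1)`; the statistic is invariant to
#' scaling all counts.
#'
#' @param five_prime integer vector of 0-based 5'-end positions.
#' @param record_length record length (number of positions).
#' @param weights optional per-hit weights (occurrence counts).
#' @return numeric CV, `NA` when there are no hits.
#' @export
coverage_cv <- function(five_prime, record_length, weights = NULL) {
  if (length(five_prime) == 0L) return(NA_real_)
  weights <- weights %||% rep(1, length(five_prime))
  cov <- numeric(record_length)
  tab <- tapply(weights, factor(five_prime + 1L,
                                levels = seq_len(record_length)), sum)
  cov[] <- ifelse(is.na(tab), 0, tab)
  mu <- mean(cov)
  if (mu == 0) return(NA_real_)
  sqrt(mean((cov - mu)^2)) / mu
}

#' Coverage CV for every record in a hit table
#' @param hits hit table (single placement per read), filtered internally
#'   to `lengths`.
#' @param records data.frame with `id` and `length` columns (e.g.
#'   `ref$records`).
#' @param lengths read-length band.
#' @param weighted use occurrence counts as weights.
#' @return data.frame `record_id`, `n_reads`, `cv`.
#' @export
coverage_cv_table <- function(hits, records, lengths = 26:28,
                              weighted = TRUE) {
  h <- hits[nchar(hits$seq) %in% lengths, , drop = FALSE]
  ids <- intersect(records$id, unique(h$record_id))
  rows <- lapply(ids, function(id) {
    sel <- h$record_id == id
    L <- records$length[match(id, records$id)]
    w <- if (weighted) h$count[sel] else NULL
    data.frame(record_id = id, n_reads = sum(sel),
               cv = coverage_cv(h$five_prime[sel], L, w),
               stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows) else {
    data.frame(record_id = character(0), n_reads = integer(0),
               cv = numeric(0), stringsAsFactors = FALSE)
  }
}

## per-record window of 5'-end counts measured from one end.
## end = "5p": window position i (1..window) is record position i.
## end = "3p": window position i is record position L - i + 1, so position
## 1 sits at the record's 3' terminus.
end_window_counts <- function(five_prime, weights, record_len, end,
                              window) {
  idx <- if (end == "5p") five_prime + 1L else record_len - five_prime
  sel <- idx >= 1L & idx <= window
  cov <- numeric(window)
  if (any(sel)) {
    tab <- tapply(weights[sel], factor(idx[sel], levels = seq_len(window)),
                  sum)
    cov[] <- ifelse(is.na(tab), 0, tab)
  }
  cov
}

#' Telomere-proximal density profile
#'
#' For each record of at least `min_record_len` nt, counts read 5' ends of
#' the requested strand in the `window` positions anchored at each record
#' end, normalises the window by its own mean density (so a uniform layout
#' gives 1.0 everywhere), and averages across records. Records with zero
#' reads in a window are skipped for that window.
#'
#' @param hits hit table (single placement per read).
#' @param annotation telomere annotation (`id`, `length`, `tel5`, `tel3`,
#'   `complete`) as from [annotate_telomeres()].
#' @param cfg a [profile_config()].
#' @param strand `"+"`, `"-"`, or `"both"`.
#' @param lengths read-length band.
#' @param per_position return single-position resolution instead of bins.
#' @param weighted use occurrence counts as weights.
#' @return data.frame: with bins, columns `end` ("5p"/"3p"), `bin`,
#'   `bin_start`, `bin_end` (0-based position range from the record end),
#'   `rel_density`, `n_records`, plus attributes `telomere_mean` (mean
#'   annotated telomere length) and `read_len_shade`; with
#'   `per_position = TRUE`, columns `end`, `pos` (1-based from the record
#'   end), `rel_density`, `n_records`.
#' @export
telomere_end_profile <- function(hits, annotation, cfg = profile_config(),
                                 strand = c("+", "-", "both"),
                                 lengths = 26:28, per_position = FALSE,
                                 weighted = TRUE) {
  strand <- match.arg(strand)
  h <- hits[nchar(hits$seq) %in% lengths, , drop = FALSE]
  if (strand != "both") h <- h[h$strand == strand, , drop = FALSE]
  ann <- annotation[annotation$complete &
                      annotation$length >= cfg$min_record_len, ,
                    drop = FALSE]
  if (nrow(ann) == 0L) stop("no qualifying records for the end profile")
  acc <- list(`5p` = numeric(cfg$window), `3p` = numeric(cfg$window))
  nrec <- c(`5p` = 0L, `3p` = 0L)
  for (i in seq_len(nrow(ann))) {
    id <- ann$id[i]
    sel <- h$record_id == id
    fp <- h$five_prime[sel]
    w <- if (weighted) h$count[sel] else rep(1, sum(sel))
    for (end in c("5p", "3p")) {
      cov <- end_window_counts(fp, w, ann$length[i], end, cfg$window)
      tot <- sum(cov)
      if (tot == 0) next
      acc[[end]] <- acc[[end]] + cov / (tot / cfg$window)
      nrec[end] <- nrec[end] + 1L
    }
  }
  if (all(nrec == 0L)) stop("no reads fall in any end window")
  out <- do.call(rbind, lapply(c("5p", "3p"), function(end) {
    if (nrec[end] == 0L) return(NULL)
    rel <- acc[[end]] / nrec[end]
    if (per_position) {
      data.frame(end = end, pos = seq_len(cfg$window),
                 rel_density = unname(rel),
                 n_records = unname(nrec[end]), stringsAsFactors = FALSE)
    } else {
      nb <- cfg$window %/% cfg$bin
      grp <- rep(seq_len(nb), each = cfg$bin)
      data.frame(end = end, bin = seq_len(nb),
                 bin_start = (seq_len(nb) - 1L) * cfg$bin,
                 bin_end = seq_len(nb) * cfg$bin,
                 rel_density = as.numeric(tapply(rel, grp, mean)),
                 n_records = unname(nrec[end]), stringsAsFactors = FALSE)
    }
  }))
  attr(out, "telomere_mean") <- mean(c(ann$tel5, ann$tel3))
  attr(out, "read_len_shade") <- cfg$read_len_shade
  rownames(out) <- NULL
  out
}

#' Subtelomeric depletion fold
#'
#' Ratio of the mean relative 5'-end density over the rest of the
#' end-anchored window (positions interior to both the annotated telomere
#' and the `zone`) to the mean over the `zone` positions immediately
#' interior to the telomere at that end, averaged over the per-record
#' normalised profiles. A fold of 8 means the zone has 8-fold lower
#' density than the rest of the record.
#'
#' @param hits hit table (single placement per read).
#' @param annotation telomere annotation.
#' @param cfg a [profile_config()].
#' @param strand `"+"`, `"-"`, or `"both"`.
#' @param lengths read-length band.
#' @param weighted use occurrence counts as weights.
#' @return data.frame `end` ("5p", "3p", "pooled"), `window_mean`,
#'   `zone_mean`, `fold` (`Inf` with the `infinite` flag set when the zone
#'   has zero density).
#' @export
depletion_fold <- function(hits, annotation, cfg = profile_config(),
                           strand = "both", lengths = 26:28,
                           weighted = TRUE) {
  h <- hits[nchar(hits$seq) %in% lengths, , drop = FALSE]
  if (strand != "both") h <- h[h$strand == strand, , drop = FALSE]
  ann <- annotation[annotation$complete &
                      annotation$length >= cfg$min_record_len, ,
                    drop = FALSE]
  if (nrow(ann) == 0L) stop("no qualifying records")
  sums <- list(`5p` = c(win = 0, zone = 0, nwin = 0, nzone = 0),
               `3p` = c(win = 0, zone = 0, nwin = 0, nzone = 0))
  for (i in seq_len(nrow(ann))) {
    sel <- h$record_id == ann$id[i]
    fp <- h$five_prime[sel]
    w <- if (weighted) h$count[sel] else rep(1, sum(sel))
    for (end in c("5p", "3p")) {
      cov <- end_window_counts(fp, w, ann$length[i], end, cfg$window)
      tot <- sum(cov)
      if (tot == 0) next
      rel <- cov / (tot / cfg$window)
      tel <- if (end == "5p") ann$tel5[i] else ann$tel3[i]
      if (tel + cfg$zone >= cfg$window) next
      zone_idx <- seq(tel + 1L, tel + cfg$zone)
      rest_idx <- seq(tel + cfg$zone + 1L, cfg$window)
      sums[[end]]["win"] <- sums[[end]]["win"] + mean(rel[rest_idx])
      sums[[end]]["zone"] <- sums[[end]]["zone"] + mean(rel[zone_idx])
      sums[[end]]["nwin"] <- sums[[end]]["nwin"] + 1
      sums[[end]]["nzone"] <- sums[[end]]["nzone"] + 1
    }
  }
  row_for <- function(win, zone) {
    fold <- if (is.na(zone)) NA_real_ else if (zone == 0) Inf else
      win / zone
    data.frame(window_mean = unname(win), zone_mean = unname(zone),
               fold = unname(fold))
  }
  res <- lapply(c("5p", "3p"), function(end) {
    s <- sums[[end]]
    if (s[["nwin"]] == 0) return(row_for(NA_real_, NA_real_))
    row_for(s[["win"]] / s[["nwin"]], s[["zone"]] / s[["nzone"]])
  })
  pooled_n <- sums$`5p`[["nwin"]] + sums$`3p`[["nwin"]]
  pooled <- row_for((sums$`5p`[["win"]] + sums$`3p`[["win"]]) / pooled_n,
                    (sums$`5p`[["zone"]] + sums$`3p`[["zone"]]) / pooled_n)
  out <- cbind(data.frame(end = c("5p", "3p", "pooled"),
                          stringsAsFactors = FALSE),
               rbind(res[[1L]], res[[2L]], pooled))
  rownames(out) <- NULL
  attr(out, "infinite") <- any(is.infinite(out$fold))
  out
}
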