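## hit table builder for statistics tests: one row per (seq, placement)
hits_of <- function(record_id, strand, five_prime, count = 1L, len = 27L) {
  n <- max(length(record_id), length(strand), length(five_prime),
           length(count))
  data.frame(seq = vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), ""),
    count = rep_len(count, n), record_id = rep_len(record_id, n),
    start = rep_len(five_prime, n), strand = rep_len(strand, n),
    mismatches = 0L, five_prime = rep_len(five_prime, n),
    stringsAsFactors = FALSE)
}

test_that("envelope membership includes the boundary and excludes beyond", {
  cfg <- envelope_config()
  ## (60, 40): |20| = 2 * sqrt(100) -> boundary, inside
  expect_true(envelope_membership(60, 40, cfg))
  ## (65, 35): |30| > 2 * sqrt(100) -> outside
  expect_false(envelope_membership(65, 35, cfg))
  ## zero-total records count as inside by convention
  expect_true(envelope_membership(0, 0, cfg))
  ## vectorised
  expect_identical(envelope_membership(c(60, 65, 50), c(40, 35, 50)),
                   c(TRUE, FALSE, TRUE))
  ## a wider multiplier relaxes the envelope
  expect_true(envelope_membership(65, 35, envelope_config(k_sd = 3)))
})

test_that("the balanced binomial null gives ~95% inside and a ~1.96 band", {
  withr::with_seed(601, {
    tot <- sample(20:2000, 5000, replace = TRUE)
    plus <- rbinom(5000, tot, 0.5)
  })
  minus <- tot - plus
  inside <- envelope_membership(plus, minus)
  expect_gt(mean(inside), 0.94)
  expect_lt(mean(inside), 0.97)
  rows <- data.frame(record_id = sprintf("r%d", 1:5000),
                     plus_total = plus, minus_total = minus,
                     plus_distinct = plus, minus_distinct = minus,
                     stringsAsFactors = FALSE)
  band <- empirical_band(rows)
  expect_gt(band, 1.8)
  expect_lt(band, 2.1)
  expect_error(empirical_band(rows[1:10, ]), "at least 20")
})

test_that("strand_count_table tallies both bases and applies the floor", {
  withr::with_seed(603, {
    h <- rbind(
      hits_of("g1", "+", 1:12, count = 2L),     # 12 distinct, 24 total
      hits_of("g1", "-", 1:11, count = 1L),     # 11 distinct, 11 total
      hits_of("g2", "+", 1:30, count = 1L),
      hits_of("g2", "-", 1:5, count = 1L))      # minus below the floor
  })
  rows <- strand_count_table(h)
  expect_identical(rows$record_id, "g1")
  expect_identical(rows$plus_total, 24L)
  expect_identical(rows$minus_total, 11L)
  expect_identical(rows$plus_distinct, 12L)
  expect_identical(rows$minus_distinct, 11L)
  ## the length band filters non-26-28-nt hits
  withr::with_seed(604, h25 <- hits_of("g3", "+", 1:40, len = 25L))
  expect_identical(nrow(strand_count_table(rbind(h, h25))), 1L)
})

test_that("pearson_r needs two rows and flags zero variance", {
  rows <- data.frame(record_id = c("a", "b", "c"),
                     plus_total = c(10L, 20L, 40L),
                     minus_total = c(11L, 19L, 42L),
                     plus_distinct = c(5L, 5L, 5L),
                     minus_distinct = c(4L, 9L, 20L))
  expect_gt(pearson_r(rows, "total"), 0.99)
  expect_warning(r <- pearson_r(rows, "distinct"), "zero variance")
  expect_true(is.na(r))
  expect_error(pearson_r(rows[1, ]), "at least two")
})

test_that("coverage CV obeys its closed forms and scale invariance", {
  L <- 400L
  ## uniform coverage: one read at every position
  expect_equal(coverage_cv(0:(L - 1L), L), 0)
  ## single spike on an L-position record
  expect_equal(coverage_cv(rep(7L, 13L), L), sqrt(L - 1))
  expect_equal(coverage_cv(7L, L, weights = 1000), sqrt(L - 1))
  ## scale invariance
  withr::with_seed(607, fp <- sample(0:(L - 1L), 200, replace = TRUE))
  expect_equal(coverage_cv(fp, L, weights = rep(1, 200)),
               coverage_cv(fp, L, weights = rep(17, 200)))
  ## no hits
  expect_true(is.na(coverage_cv(integer(0), L)))
})

test_that("coverage_cv_table computes per-record CVs on the length band", {
  withr::with_seed(611, {
    h <- rbind(hits_of("g1", "+", 0:99),
               hits_of("g2", "+", rep(50L, 20L)))
  })
  recs <- data.frame(id = c("g1", "g2"), length = c(100L, 300L),
                     stringsAsFactors = FALSE)
  tab <- coverage_cv_table(h, recs)
  expect_equal(tab$cv[tab$record_id == "g1"], 0)
  expect_equal(tab$cv[tab$record_id == "g2"], sqrt(299))
  expect_identical(tab$n_reads, c(100L, 20L))
})

test_that("a uniform layout gives a flat unit profile at both ends", {
  cfg <- profile_config(window = 100L, bin = 10L, min_record_len = 100L)
  withr::with_seed(613, h <- hits_of("g1", "+", 0:599))
  ann <- data.frame(id = "g1", length = 600L, tel5 = 20L, tel3 = 20L,
                    complete = TRUE, stringsAsFactors = FALSE)
  prof <- telomere_end_profile(h, ann, cfg)
  expect_identical(sort(unique(prof$end)), c("3p", "5p"))
  expect_equal(prof$rel_density, rep(1, 20), tolerance = 1e-12)
  pp <- telomere_end_profile(h, ann, cfg, per_position = TRUE)
  expect_equal(pp$rel_density, rep(1, 200), tolerance = 1e-12)
  expect_equal(attr(prof, "telomere_mean"), 20)
})

test_that("mirrored layouts give identical 5' and 3' profiles", {
  cfg <- profile_config(window = 100L, bin = 20L, min_record_len = 100L)
  L <- 600L
  fp <- c(30:59, (L - 60L):(L - 31L))     # symmetric blocks at both ends
  withr::with_seed(617, h <- hits_of("g1", "+", fp))
  ann <- data.frame(id = "g1", length = L, tel5 = 20L, tel3 = 20L,
                    complete = TRUE, stringsAsFactors = FALSE)
  prof <- telomere_end_profile(h, ann, cfg)
  p5 <- prof$rel_density[prof$end == "5p"]
  p3 <- prof$rel_density[prof$end == "3p"]
  expect_equal(p5, p3)
})

test_that("depletion_fold matches the deterministic coverage construction", {
  ## 600-nt record: telomeres (20 nt) empty, 30-nt zones at rate 1, the
  ## rest at rate 8 -- an exact 8-fold depletion by construction
  L <- 600L
  zone5 <- 20:49; zone3 <- (L - 50L):(L - 21L)
  interior <- setdiff(50:(L - 51L), integer(0))
  fp <- c(rep(zone5, 1L), rep(zone3, 1L), rep(interior, 8L))
  withr::with_seed(619, h <- hits_of("g1", "+", fp))
  ann <- data.frame(id = "g1", length = L, tel5 = 20L, tel3 = 20L,
                    complete = TRUE, stringsAsFactors = FALSE)
  cfg <- profile_config(window = 500L, bin = 25L, zone = 30L,
                        min_record_len = 500L)
  dep <- depletion_fold(h, ann, cfg)
  expect_identical(dep$end, c("5p", "3p", "pooled"))
  ## window composition: 20 empty + 30 at 1 + 450 at 8 = 3630 per 500;
  ## the rest-of-window mean is 8 units, the zone mean 1 unit
  expect_equal(dep$window_mean, rep(8 * 500 / 3630, 3), tolerance = 1e-12)
  expect_equal(dep$zone_mean, rep(500 / 3630, 3), tolerance = 1e-12)
  ## the estimator recovers the constructed 8-fold depletion exactly
  expect_equal(dep$fold, rep(8, 3), tolerance = 1e-12)
  expect_false(attr(dep, "infinite"))
  ## an empty zone flags an infinite fold
  h_int <- h[!(h$five_prime %in% c(zone5, zone3)), , drop = FALSE]
  dep2 <- depletion_fold(h_int, ann, cfg)
  expect_true(attr(dep2, "infinite"))
})

test_that("profiles require qualifying records and reads", {
  cfg <- profile_config(window = 100L, bin = 10L, min_record_len = 500L)
  ann <- data.frame(id = "g1", length = 300L, tel5 = 20L, tel3 = 20L,
                    complete = TRUE, stringsAsFactors = FALSE)
  withr::with_seed(623, h <- hits_of("g1", "+", 0:99))
  expect_error(telomere_end_profile(h, ann, cfg), "no qualifying")
  expect_error(depletion_fold(h, ann, cfg), "no qualifying")
  ann$length <- 600L
  expect_error(telomere_end_profile(h[0, ], ann, cfg), "no reads")
})
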