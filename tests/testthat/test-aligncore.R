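test_that("align_policy validates and defaults match the two use cases", {
  pol <- align_policy()
  expect_identical(pol$max_mismatches, 1L)
  expect_identical(pol$multi_cap, 10L)
  expect_identical(pol$report_mode, "all_sites")
  expect_error(align_policy(max_mismatches = -1))
  expect_error(align_policy(multi_cap = 1))
  expect_error(align_policy(report_mode = "best"))
})

test_that("exact hits are found with correct coordinates on both strands", {
  withr::with_seed(301, ref <- random_seq(500))
  read <- substr(ref, 101, 127)
  h <- align_read_all_sites(read, ref, align_policy(max_mismatches = 0L))
  expect_identical(h$start, 100L)
  expect_identical(h$strand, "+")
  expect_identical(h$mismatches, 0L)
  expect_identical(h$five_prime, 100L)
  hr <- align_read_all_sites(revcomp(read), ref,
                             align_policy(max_mismatches = 0L))
  expect_identical(hr$start, 100L)
  expect_identical(hr$strand, "-")
  expect_identical(hr$five_prime, 126L)
})

test_that("the aligner matches the brute-force oracle on random instances", {
  withr::with_seed(303, {
    for (i in 1:60) {
      ref <- random_seq(sample(200:500, 1))
      k <- sample(0:3, 1)
      L <- sample(16:30, 1)
      read <- if (i %% 3 == 0) {
        random_seq(L)                                # mostly no hits
      } else {
        pos <- sample(nchar(ref) - L + 1, 1)
        planted <- substr(ref, pos, pos + L - 1)
        if (i %% 2 == 0) planted <- revcomp(planted)
        mutate_seq(planted, sample(0:k, 1))
      }
      got <- align_read_all_sites(read, ref,
                                  align_policy(max_mismatches = k))
      want <- oracle_align(read, ref, k)
      expect_identical(nrow(got), nrow(want))
      if (nrow(want)) {
        got <- got[order(got$start, got$strand), ]
        expect_identical(got$start, want$start)
        expect_identical(got$strand, want$strand)
        expect_identical(got$mismatches, want$mismatches)
      }
    }
  })
})

test_that("hits never overlap the N spacers of a concatenated reference", {
  withr::with_seed(307, {
    a <- random_seq(120)
    b <- random_seq(140)
  })
  ref <- build_concat(c(a = a, b = b))
  ## a read spanning the a/b junction in spacer-free concatenation
  bridging <- paste0(substr(a, 108, 120), substr(b, 1, 14))
  h <- align_read_all_sites(bridging, ref, align_policy(max_mismatches = 1L))
  expect_identical(nrow(h), 0L)
  ## interior reads are reported in local coordinates
  h2 <- align_read_all_sites(substr(b, 21, 47), ref,
                             align_policy(max_mismatches = 0L))
  expect_identical(h2$record_id, "b")
  expect_identical(h2$start, 20L)
})

test_that("reads below 16 nt and non-DNA reads are rejected", {
  withr::with_seed(309, ref <- random_seq(200))
  expect_error(align_read_all_sites("ACGTACGTACGTACG", ref),
               "16 nt")
  expect_error(align_read_all_sites("ACGNACGTACGTACGTACGTACGTACG", ref),
               "outside")
})

test_that("multiplicity classes split at unique / 2-9 / >= 10 sites", {
  withr::with_seed(311, {
    u <- random_seq(27)
    m3 <- random_seq(27)
    m10 <- random_seq(27)
    fill <- function(n) paste(vapply(seq_len(n), function(i)
      random_seq(40), ""), collapse = "")
    ref_str <- paste0(fill(1), u, fill(1),
                      paste(rep(c(m3, fill(1)), 3), collapse = ""),
                      paste(rep(c(m10, fill(1)), 10), collapse = ""))
  })
  ds <- distinct_from(c(u, m3, m10), c(5L, 2L, 1L))
  chr1 <- build_concat(c(x = ref_str))
  res <- run_two_pass(ds, chr1, policy = align_policy(max_mismatches = 0L))
  rc <- res$read_class
  expect_identical(rc$class[match(u, rc$seq)], "unique")
  expect_identical(rc$n_sites[match(u, rc$seq)], 1L)
  expect_identical(rc$class[match(m3, rc$seq)], "multi_2to9")
  expect_identical(rc$n_sites[match(m3, rc$seq)], 3L)
  expect_identical(rc$class[match(m10, rc$seq)], "multi_ge10")
  expect_identical(rc$n_sites[match(m10, rc$seq)], 10L)
  s <- res$summary
  expect_identical(s$unique_distinct + s$multi_2to9_distinct +
                     s$multi_ge10_distinct + s$unmapped_distinct,
                   s$input_distinct)
  expect_identical(s$unique_total, 5L)
  expect_identical(s$multi_2to9_total, 2L)
  expect_identical(s$multi_ge10_total, 1L)
  expect_equal(s$mapped_pct, 100)
})

test_that("two passes give chr1 precedence and chr2 mops up the rest", {
  withr::with_seed(313, {
    shared <- random_seq(27)
    only2 <- random_seq(27)
    neither <- random_seq(27)
    c1 <- paste0(random_seq(60), shared, random_seq(60))
    c2 <- paste0(random_seq(50), shared, random_seq(20), only2,
                 random_seq(50))
  })
  ds <- distinct_from(c(shared, only2, neither))
  res <- run_two_pass(ds, build_concat(c(g1 = c1)),
                      build_concat(c(p1 = c2)),
                      policy = align_policy(max_mismatches = 0L))
  h <- res$hits
  ## the shared read maps in pass 1 only; chr2 is never searched for it
  expect_identical(unique(h$target[h$seq == shared]), "chr1")
  expect_identical(unique(h$target[h$seq == only2]), "chr2")
  expect_false(neither %in% h$seq)
  expect_identical(
    res$read_class$class[match(neither, res$read_class$seq)], "unmapped")
})

test_that("random_one mode is deterministic given the seed", {
  withr::with_seed(317, {
    multi <- random_seq(27)
    ref_str <- paste(rep(c(multi, random_seq(45)), 6), collapse = "")
  })
  chr1 <- build_concat(c(x = ref_str))
  ds <- distinct_from(multi)
  pol <- align_policy(max_mismatches = 0L, report_mode = "random_one")
  r1 <- run_two_pass(ds, chr1, policy = pol, seed = 5L)
  r2 <- run_two_pass(ds, chr1, policy = pol, seed = 5L)
  expect_identical(r1$hits, r2$hits)
  expect_identical(nrow(r1$hits), 1L)
  ## classification still counts every site
  expect_identical(r1$read_class$n_sites, 6L)
  ## over many seeds the draw visits more than one site
  starts <- vapply(1:30, function(s) {
    run_two_pass(ds, chr1, policy = pol, seed = s)$hits$start
  }, 1L)
  expect_gt(length(unique(starts)), 1L)
})

test_that("SAM export uses 1-based positions, 0x10 and reference-strand SEQ", {
  withr::with_seed(331, ref_rec <- random_seq(160))
  ref <- build_concat(c(rec1 = ref_rec))
  fwd <- substr(ref_rec, 21, 47)
  rev <- revcomp(substr(ref_rec, 61, 87))
  h <- align_read_all_sites(c(fwd, rev), ref,
                            align_policy(max_mismatches = 0L))
  d <- withr::local_tempdir()
  sam <- file.path(d, "out.sam")
  export_tracks(h, ref, sam_path = sam, bedgraph_prefix = file.path(d, "t"))
  lines <- readLines(sam)
  expect_identical(lines[1], "@HD\tVN:1.6\tSO:unsorted")
  expect_identical(lines[2], "@SQ\tSN:rec1\tLN:160")
  body <- do.call(rbind, strsplit(lines[-(1:2)], "\t"))
  expect_identical(nrow(body), 2L)
  expect_identical(sort(as.integer(body[, 2])), c(0L, 16L))
  plus_row <- body[body[, 2] == "0", ]
  minus_row <- body[body[, 2] == "16", ]
  expect_identical(as.integer(plus_row[4]), 21L)
  expect_identical(as.integer(minus_row[4]), 61L)
  expect_identical(plus_row[6], "27M")
  expect_identical(plus_row[10], fwd)
  ## minus-strand SEQ is reported on the reference strand
  expect_identical(minus_row[10], revcomp(rev))
  expect_identical(plus_row[12], "NM:i:0")

  plus_bg <- read.table(file.path(d, "t.plus.bedGraph"), sep = "\t")
  minus_bg <- read.table(file.path(d, "t.minus.bedGraph"), sep = "\t")
  expect_identical(plus_bg$V2, 20L)    # 5' end of the plus hit
  expect_identical(plus_bg$V3, 21L)
  expect_identical(plus_bg$V4, 1L)
  expect_identical(minus_bg$V2, 86L)   # 5' end of the minus hit
})

test_that("hit counts propagate from the distinct set", {
  withr::with_seed(337, ref_rec <- random_seq(150))
  read <- substr(ref_rec, 31, 57)
  ds <- distinct_from(read, 9L)
  h <- align_read_all_sites(ds, build_concat(c(r = ref_rec)),
                            align_policy(max_mismatches = 0L))
  expect_identical(h$count, 9L)
})
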