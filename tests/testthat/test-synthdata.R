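test_that("generator_config validates its inputs", {
  cfg <- generator_config()
  expect_s3_class(cfg, "GeneratorConfig")
  expect_identical(cfg$telomere_unit, "GGGGTTTT")
  expect_identical(cfg$telomere_len, 20L)
  expect_equal(cfg$class_weights, c("26" = 0.1, "27" = 0.8, "28" = 0.1))
  expect_equal(cfg$u5_bias, 0.97)
  expect_equal(cfg$deplete_zone, 30L)
  expect_equal(cfg$deplete_factor, 8)
  expect_error(generator_config(strand_p = 1.2), "probabilities")
  expect_error(generator_config(u5_bias = -0.1), "probabilities")
  expect_error(generator_config(telomere_len = 0), "telomere_len")
  expect_error(generator_config(telomere_unit = "GGXG"), "telomere_unit")
  expect_error(generator_config(nano_len_mean = 80), "minimum")
  veg <- generator_config(mode = "vegetative")
  expect_equal(names(veg$class_weights), c("20", "21", "22"))
})

test_that("nanochromosomes carry telomeres in the expected orientation", {
  cfg <- small_cfg(seed = 7)
  withr::with_seed(7, {
    g <- gen_macro_gene(cfg, "nanoA")
  })
  L <- nchar(g$sequence)
  expect_gte(L, cfg$min_nano_len)
  ## 5' end is the reverse-complement repeat phase (C4A4...), 3' end G4T4...
  expect_identical(substr(g$sequence, 1L, 8L), "CCCCAAAA")
  expect_identical(substr(g$sequence, L - 19L, L - 12L), "GGGGTTTT")
  expect_identical(substr(g$sequence, L - 3L, L), "GGGG")
  ## interior is free of 12-nt telomere-unit runs (either strand)
  interior <- substr(g$sequence, 21L, L - 20L)
  expect_false(grepl("GGGGTTTTGGGG", interior, fixed = TRUE))
  expect_false(grepl("CCCCAAAACCCC", interior, fixed = TRUE))
})

test_that("gen_macro_genes is deterministic under an outer seed", {
  cfg <- small_cfg(seed = 11)
  a <- withr::with_seed(11, gen_macro_genes(cfg))
  b <- withr::with_seed(11, gen_macro_genes(cfg))
  expect_identical(a, b)
  expect_identical(names(a), sprintf("nano%05d", 1:12))
})

test_that("micronuclear loci satisfy the length identity", {
  cfg <- small_cfg(seed = 3)
  withr::with_seed(3, {
    g <- gen_macro_gene(cfg, "nanoB")
    for (n_mds in c(1L, 2L, 5L)) {
      loc <- gen_micro_locus(g, n_mds)
      expect_identical(
        nchar(loc$micro_sequence),
        nchar(macro_interior_for_test(g)) + sum(nchar(loc$ies_seqs)) +
          sum(loc$pointer_lens))
      expect_length(loc$ies_seqs, n_mds - 1L)
      expect_length(loc$pointer_lens, n_mds - 1L)
      if (n_mds > 1L) {
        expect_true(all(loc$pointer_lens >= 2L & loc$pointer_lens <= 20L))
        expect_true(all(nchar(loc$ies_seqs) >= 20L &
                          nchar(loc$ies_seqs) <= 80L))
      }
    }
  })
})

test_that("reconstruct_macro round-trips unscrambled and scrambled loci", {
  cfg <- small_cfg(seed = 5)
  withr::with_seed(5, {
    for (rep in 1:10) {
      g <- gen_macro_gene(cfg, sprintf("nano%02d", rep))
      macro <- macro_interior_for_test(g)
      for (n_mds in c(1L, 2L, 3L, 6L)) {
        loc <- gen_micro_locus(g, n_mds, scrambled = FALSE)
        expect_identical(reconstruct_macro(loc), macro)
      }
      for (n_mds in c(2L, 4L, 6L)) {
        loc <- gen_micro_locus(g, n_mds, scrambled = TRUE)
        expect_true(loc$scrambled)
        expect_false(all(order(loc$mds_list$micro_slot) ==
                           seq_len(n_mds)))
        expect_identical(sum(loc$mds_list$strand == "-"), 1L)
        expect_identical(reconstruct_macro(loc), macro)
      }
    }
  })
})

test_that("scrambled micronuclear sequence differs from the unscrambled one", {
  cfg <- small_cfg(seed = 9)
  withr::with_seed(9, {
    g <- gen_macro_gene(cfg, "nanoC")
    plain <- gen_micro_locus(g, 4L, scrambled = FALSE)
    scr <- gen_micro_locus(g, 4L, scrambled = TRUE)
    expect_false(identical(plain$micro_sequence, scr$micro_sequence))
  })
})

test_that("pool sequences are exact substrings at their stated coordinates", {
  cfg <- small_cfg(seed = 21)
  withr::with_seed(21, {
    genes <- gen_macro_genes(cfg)
    pool <- gen_small_rna_pool(genes, cfg)
  })
  macro <- pool[pool$origin == "macro", ]
  expect_gt(nrow(macro), 100L)
  expect_true(all(macro$length %in% c(26L, 27L, 28L)))
  for (i in sample(nrow(macro), 200L)) {
    gseq <- genes[[macro$gene_id[i]]]$sequence
    st <- macro$start[i]; L <- macro$length[i]
    expected <- if (macro$strand[i] == "+") {
      substr(gseq, st + 1L, st + L)
    } else {
      revcomp(substr(gseq, st - L + 2L, st + 1L))
    }
    expect_identical(macro$sequence[i], expected)
  }
})

test_that("telomere positions produce no reads and classes follow the weights", {
  cfg <- small_cfg(seed = 13, n_ncrna_decoys = 0L, ncrna_contam_frac = 0)
  withr::with_seed(13, {
    genes <- gen_macro_genes(cfg)
    pool <- gen_small_rna_pool(genes, cfg)
  })
  glen <- nchar(vapply(genes, `[[`, "", "sequence"))[pool$gene_id]
  ## the 5' end never falls inside a telomere
  expect_true(all(pool$start >= cfg$telomere_len))
  expect_true(all(pool$start < glen - cfg$telomere_len))
  ## 27-mers dominate under the 0.1/0.8/0.1 weights
  frac27 <- mean(pool$length == 27L)
  expect_gt(frac27, 0.7)
  expect_lt(frac27, 0.9)
})

test_that("u5_bias = 1 forces a U (T) 5' base on every macro read", {
  cfg <- small_cfg(seed = 17, u5_bias = 1, n_ncrna_decoys = 0L,
                   ncrna_contam_frac = 0)
  withr::with_seed(17, {
    genes <- gen_macro_genes(cfg)
    pool <- gen_small_rna_pool(genes, cfg)
  })
  expect_true(all(substr(pool$sequence, 1L, 1L) == "T"))
})

test_that("strand_p = 1 produces plus-strand reads only", {
  cfg <- small_cfg(seed = 19, strand_p = 1, n_ncrna_decoys = 0L,
                   ncrna_contam_frac = 0)
  withr::with_seed(19, {
    genes <- gen_macro_genes(cfg)
    pool <- gen_small_rna_pool(genes, cfg)
  })
  expect_true(all(pool$strand == "+"))
})

test_that("ncRNA contamination approaches the configured fraction", {
  cfg <- small_cfg(seed = 23, ncrna_contam_frac = 0.2)
  withr::with_seed(23, {
    genes <- gen_macro_genes(cfg)
    decoys <- gen_ncrna_decoys(cfg)
    pool <- gen_small_rna_pool(genes, cfg, decoys = decoys)
  })
  frac <- mean(pool$origin == "ncrna")
  expect_gt(frac, 0.15)
  expect_lt(frac, 0.25)
  nc <- pool[pool$origin == "ncrna", ]
  for (i in sample(nrow(nc), min(50L, nrow(nc)))) {
    d <- decoys[[nc$gene_id[i]]]
    st <- nc$start[i]; L <- nc$length[i]
    expected <- if (nc$strand[i] == "+") {
      substr(d, st + 1L, st + L)
    } else {
      revcomp(substr(d, st - L + 2L, st + 1L))
    }
    expect_identical(nc$sequence[i], expected)
  }
})

test_that("simulate_bundle is bit-reproducible for a fixed config", {
  cfg <- small_cfg(seed = 31, n_nano = 4L, reads_per_nano_mean = 50)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- simulate_bundle(cfg, d1, n_loci = 2L, n_mds = 3L)
  b2 <- simulate_bundle(cfg, d2, n_loci = 2L, n_mds = 3L)
  expect_identical(b1$pool, b2$pool)
  expect_identical(b1$genes, b2$genes)
  expect_identical(readLines(b1$paths$fastq1), readLines(b2$paths$fastq1))
  expect_identical(readLines(b1$paths$genome), readLines(b2$paths$genome))
  expect_true(all(file.exists(unlist(b1$paths))))
})

test_that("emitted FASTQ embeds the insert followed by the adapter", {
  cfg <- small_cfg(seed = 37, n_nano = 3L, reads_per_nano_mean = 30)
  d <- withr::local_tempdir()
  b <- simulate_bundle(cfg, d)
  r1 <- read_fastq(b$paths$fastq1)
  r2 <- read_fastq(b$paths$fastq2)
  expect_identical(nrow(r1), nrow(b$pool))
  expect_true(all(nchar(r1$seq) == 100L))
  i <- 1L
  ins <- b$pool$sequence[i]
  expect_identical(substr(r1$seq[i], 1L, nchar(ins)), ins)
  expect_identical(substr(r1$seq[i], nchar(ins) + 1L, nchar(ins) + 21L),
                   cfg$adapter3)
  expect_identical(substr(r2$seq[i], 1L, nchar(ins)), revcomp(ins))
})
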