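---
title: "Methods: the macrna27 small RNA pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the macrna27 small RNA pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

`macrna27` analyses mating-induced ~27 nt small RNAs produced from the
macronuclear nanochromosomes of the ciliate *Oxytricha trifallax*. This
vignette walks through the method of every stage and the statistical
conventions, using the built-in synthetic data generator so that the
whole document runs offline in seconds.

```{r load}
library(macrna27)
```

## The biological model and the synthetic generator

*Oxytricha* has two nuclei: a silent germline micronucleus and a somatic
macronucleus whose genome is shattered into ~16,000 gene-sized
"nanochromosomes" (mean ~2.2 kb) capped by `GGGGTTTT`-repeat telomeres of
about 20 nt per end. During development, internally eliminated sequences
(IESs) are excised from micronuclear precursors and the retained segments
(MDSs) are stitched together at short duplicated "pointer" repeats;
in scrambled genes the MDSs are additionally reordered or inverted.

`generator_config()` encodes the biological reference conditions as defaults: telomere
unit and length, mating length classes 26:27:28 weighted 0.1:0.8:0.1,
balanced strand production (`strand_p = 0.5`), a 5′-U probability of
0.97, strongly non-uniform per-position production (gamma hotspots,
shape 0.05), an 8-fold depleted 30-nt zone interior to each telomere,
and 20% ncRNA contamination.

```{r config}
cfg <- generator_config(seed = 42, n_nano = 12, nano_len_mean = 1500,
                        nano_len_sd = 300, reads_per_nano_mean = 300)
cfg
```

Two design points deserve emphasis:

* **5′-U bias by position reweighting.** Candidate 5′-end positions are
  reweighted so that the expected fraction of reads starting on a U is
  exactly `u5_bias` per gene and strand; read sequences are never
  mutated. The bias is therefore recovered on the count-weighted basis
  (each read counted once); the distinct-sequence basis underestimates
  it when production is spiky.
* **Per-gene abundance spread.** Gene read counts are
  Poisson–lognormal (`gene_abundance_sdlog = 1`). Without the lognormal
  factor, all genes would have near-identical totals and the plus/minus
  scatter could not span the decades seen in real libraries, making the
  between-strand Pearson correlation uninformative.

`simulate_bundle()` seeds all randomness once and writes a genome FASTA,
ncRNA decoys, paired FASTQ with ground-truth tags, and a truth table:

```{r bundle}
dir <- tempfile("bundle_")
b <- simulate_bundle(cfg, dir)
head(b$pool, 3)
```

## Read preparation: bidirectional-identity collapse

Inserts (26–28 nt) are far shorter than the sequencing read, so each
mate contains the complete molecule followed by the 3′ adapter. A pair
is kept only when the trimmed mate-2 insert is the exact reverse
complement of the trimmed mate-1 insert — the "bidirectionally
identical" criterion, which functions as an error filter: with per-base
disagreement rate $e$, a pair of an $L$-mer survives with probability
$(1-e)^L$. Kept inserts in the 16–45 nt window are collapsed into a
distinct-read set with occurrence counts.

```{r prep}
prep <- prep_fastq_pair(b$paths$fastq1, b$paths$fastq2)
prep$stats
prep$distinct
```

## ncRNA filtering

Reads are matched (both strands, up to 3 substitutions, no indels)
against a decoy set of non-coding RNAs to which a 40-nt telomeric decoy
— five copies of `GGGGTTTT` — is always appended, removing
telomere-derived reads before genome mapping. The partition is
exhaustive and exclusive on both the total and the distinct basis.

```{r filter}
fs <- build_filter_set(b$paths$ncrna)
part <- partition_reads(prep$distinct, fs)
part$stats[, c("ncrna", "ncrna_pct", "not_ncrna", "not_ncrna_pct")]
```

## Reference construction

Nanochromosome records are classified by end-anchored telomere runs
(either unit orientation, partial terminal repeats allowed, minimum run
12 nt): records telomeric at both ends form the complete collection
("chr1"), the remainder the partial collection ("chr2"). Each
collection is concatenated into a single sequence with 50-N spacers and
an exact offsets table; placing each record at its offset with N fill
reproduces the concatenation byte-for-byte. All coordinates are 0-based
internally and 1-based only in SAM export.

```{r refs}
refs <- split_reference(b$paths$genome)
refs$chr1
head(refs$chr1$records, 3)
```

## Alignment

The aligner enumerates **all** placements of each read on both strands
with at most *k* substitutions (no indels) — the quality-free surrogate
for Bowtie `-n 1 -e 60` (k = 1) and `-n 3 -e 150` (k = 3). Candidate
generation is pigeonhole seeding: the read is split into k+1 disjoint
seeds, at least one of which must match exactly at any admissible site;
every candidate is then verified by direct comparison. Placements
overlapping any non-ACGT base are rejected, so hits never bridge two
records across a spacer. The test suite certifies the implementation
against a brute-force scan on randomized instances.

Mapping is two-pass: pass 1 against chr1 (plus the mitochondrial genome
when given, with multiplicity counted jointly), pass 2 maps the
leftovers to chr2. Reads are classed as unique, 2–9 sites, or ≥ 10
sites on the full site set; for positional statistics one placement per
read is then drawn uniformly under a recorded seed (`random_one`), so
runs are exactly reproducible.

```{r map}
map <- run_two_pass(part$surviving, refs$chr1, refs$chr2,
                    policy = align_policy(max_mismatches = 1,
                                          report_mode = "random_one"),
                    seed = 1)
map$summary[, c("unique_distinct", "multi_2to9_distinct",
                "multi_ge10_distinct", "unmapped_distinct", "mapped_pct")]
```

## Size classes and nucleotide composition

The length histogram counts distinct reads with a mapped/unmapped
split; the per-position nucleotide matrix is reported in RNA space
(T counted as U), on the distinct basis by default or count-weighted.

```{r sizes}
hist <- length_histogram(part$surviving, map$hits)
hist[hist$length %in% 25:29, ]
pf <- position_freq(part$surviving, 27, weighted = TRUE)
round(pf[1:3, ], 3)
```

## Micronuclear versus macronuclear origin

For a gene with known micronuclear and macronuclear versions (trimmed so
the macro sequence is contained in the micro clone), distinct 26–28 nt
reads are aligned to both versions and tallied as a Venn diagram:
reads overlapping an IES can only match the micronuclear version;
reads spanning an MDS/MDS junction beyond the pointer on both sides can
only match the macronuclear version; reads inside a single MDS match
both. For unscrambled genes, macro-derived reads therefore give
`OnlyMicroCount = 0`.

```{r venn}
g <- b$genes[[1]]
loc <- gen_micro_locus(g, n_mds = 4)
pair <- as_gene_pair(g, loc)
validate_gene_pair(pair)$ok
reads27 <- part$surviving$seq[nchar(part$surviving$seq) == 27]
classify_venn(reads27, pair)[, c("Gene", "UnionCount", "XsectCount",
                                 "OnlyMicroCount", "OnlyMacroCount")]
```

## Strand balance and the binomial envelope

If every read falls on the plus strand independently with probability
½, then for a record with $n = p + m$ reads, $p - m$ has standard
deviation $\sqrt{n}$, so about 95% of balanced records satisfy
$|p - m| \le 2\sqrt{p + m}$. `strand_count_table()` tallies 26–28 nt
reads per strand (records with ≥ 10 reads per strand),
`envelope_membership()` tests the bound (boundary counts as inside),
`pearson_r()` gives the plus/minus correlation on the total or distinct
basis, and `empirical_band()` reports the observed 95%-quantile
multiplier (≈ 1.96 under the null).

```{r strand}
rows <- strand_count_table(map$hits[map$hits$target == "chr1", ])
c(pearson = pearson_r(rows, "total"),
  inside = mean(envelope_membership(rows$plus_total, rows$minus_total)))
```

## Coverage uniformity and telomere-proximal depletion

`coverage_cv()` is the population coefficient of variation of the
per-position 5′-end count over a record: 0 for uniform coverage and
$\sqrt{L-1}$ for a single spike on an $L$-position record.
`telomere_end_profile()` counts 5′ ends in a window anchored at each
record end, normalises each record's window by its own mean (uniform
coverage → 1.0 everywhere) and averages across records.
`depletion_fold()` compares the 30-nt zone immediately interior to the
annotated telomere with the rest of the window; a fold of 8 means the
zone has 8-fold lower density than the rest of the record. This
rest-of-window convention makes the estimator unbiased: on simulated
data it recovers the generator's depletion factor within sampling noise.

```{r depletion}
ann <- refs$annotation[refs$annotation$complete, ]
depletion_fold(map$hits[map$hits$target == "chr1", ], ann,
               profile_config(window = 400, min_record_len = 400))
```

## The orchestrated pipeline

`run_pipeline()` chains all stages, enforces read conservation after
every partitioning step (any violation aborts the run), and writes TSV
summaries, SAM and per-strand bedGraph tracks, and a JSON manifest
recording the seed and stage counts, making whole runs byte-reproducible.

```{r pipeline}
out <- file.path(dir, "out")
rcfg <- run_config(b$paths$fastq1, b$paths$fastq2, b$paths$genome,
                   ncrna_fasta = b$paths$ncrna, out_dir = out, seed = 1)
res <- run_pipeline(rcfg)
res$modal_mapped_length
list.files(out)
```

```{r cleanup, include = FALSE}
unlink(dir, recursive = TRUE)
```
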