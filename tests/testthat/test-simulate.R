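test_that("make_hhr emits valid, deterministic motifs", {
  set.seed(1); a <- make_hhr(DESC, "III")
  set.seed(1); b <- make_hhr(DESC, "III")
  expect_identical(a, b)
  # the motif satisfies the descriptor when scanned in isolation
  g <- as_genome(c(m = a$seq))
  hits <- scan_genome(g, DESC)
  expect_true(any(hits$bona_fide & hits$cleavage_pos == a$cut))
  expect_lte(nchar(a$seq), 150L)
  expect_error(make_hhr(DESC, "IV"))
})

test_that("type II motifs are detectable but never bona fide", {
  d2 <- hhr_descriptor(topologies = c("II"))
  set.seed(9)
  h <- make_hhr(d2, "II")
  g <- plant_in_background(h$seq, 600, 200)
  hits <- scan_genome(g, d2)
  at <- hits[hits$cleavage_pos == 200 + h$cut, , drop = FALSE]
  expect_equal(at$topology, "II")
  expect_false(any(at$bona_fide))
})

test_that("make_retrozyme builds the documented element anatomy", {
  # zero divergence: the two LTR substrings are identical
  spec0 <- synthetic_spec(ltr_divergence = 0, seed = 2L)
  set.seed(2)
  rz <- make_retrozyme(spec0)
  s <- rz$seq; tr <- rz$truth
  ltr1 <- substr(s, tr$ltr1[1] + 1, tr$ltr1[2])
  ltr2 <- substr(s, tr$ltr2[1] + 1, tr$ltr2[2])
  expect_equal(ltr1, ltr2)
  expect_equal(nchar(ltr1), 330L)
  # TSD copies identical and WWRR-consistent
  k <- tr$tsd_len
  expect_equal(substr(s, 1, k), substr(s, nchar(s) - k + 1, nchar(s)))
  ch <- strsplit(tr$tsd, "")[[1]]
  expect_true(all(ch[1:2] %in% c("A", "T")) && all(ch[3:4] %in% c("A", "G")))
  # fixed monomer length flows into the cleavage distance
  spec753 <- synthetic_spec(monomer_length = 753L, seed = 3L)
  set.seed(3)
  rz753 <- make_retrozyme(spec753)
  expect_equal(rz753$truth$cut2 - rz753$truth$cut1, 753L)
})

test_that("build_genome bookkeeping, determinism and truth self-consistency", {
  spec <- synthetic_spec(genome_length = 200000L, n_contigs = 2L,
                         n_full = 3L, n_solo = 1L, n_multimer = 1L,
                         n_decoys = 4L, seed = 23L)
  sim1 <- build_genome(spec)
  sim2 <- build_genome(spec)
  expect_identical(sim1$genome, sim2$genome)
  expect_identical(sim1$truth, sim2$truth)
  expect_equal(nrow(sim1$truth), 9L)
  expect_equal(sum(sim1$truth$kind %in% c("full", "solo", "multimer")), 5L)
  expect_equal(sum(grepl("^decoy", sim1$truth$kind)), 4L)

  # planted LTR copies are recoverable from the genome at high identity
  tr <- sim1$truth[sim1$truth$kind == "full", ]
  for (i in seq_len(nrow(tr))) {
    l1 <- fetch(sim1$genome, tr$contig[i], tr$ltr1_start[i], tr$ltr1_end[i])
    l2 <- fetch(sim1$genome, tr$contig[i], tr$ltr2_start[i], tr$ltr2_end[i])
    expect_equal(nchar(l1), 330L)
    ident <- mean(strsplit(l1, "")[[1]] == strsplit(l2, "")[[1]])
    expect_gte(ident, 0.95)
  }
  # the monomer length in the truth equals the cleavage distance
  expect_equal(tr$monomer_len, tr$cleavage2 - tr$cleavage1)
})

test_that("background composition matches the requested GC content", {
  spec <- synthetic_spec(genome_length = 1000000L, n_contigs = 1L,
                         n_full = 0L, n_solo = 0L, n_multimer = 0L,
                         n_decoys = 0L, seed = 31L)
  sim <- build_genome(spec)
  gc <- mean(strsplit(sim$genome[[1]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.4), 0.02)
})

test_that("write_synthetic emits readable FASTA and truth files", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(genome_length = 60000L, n_contigs = 1L,
                         n_full = 1L, n_solo = 0L, n_multimer = 0L,
                         n_decoys = 0L, seed = 41L)
  sim <- build_genome(spec)
  write_synthetic(sim, dir)
  g <- read_fasta(file.path(dir, "genome.fasta"))
  expect_identical(unclass(g), unclass(sim$genome))
  truth <- read.table(file.path(dir, "truth.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
  expect_equal(nrow(truth), 1L)
  gff <- read_gff3(file.path(dir, "truth.gff3"))
  expect_equal(gff$start, truth$start)
})
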