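test_that("read_fasta normalizes and validates records", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT"), fa)
  g <- read_fasta(fa)
  expect_equal(unclass(g), c(a = "ACGT"))

  writeLines(c(">a desc text", "acgu"), fa)
  expect_equal(read_fasta(fa)[["a"]], "ACGT")

  writeLines(c(">amb", "ACRYSWKMBDHVNGT"), fa)
  expect_equal(read_fasta(fa)[["amb"]], "ACNNNNNNNNNNNGT")

  writeLines(character(0), fa)
  expect_error(read_fasta(fa), "empty")

  writeLines(c(">a", "ACGT", ">a", "GGCC"), fa)
  expect_error(read_fasta(fa), "duplicate")

  writeLines(c(">bad", "ACXGT"), fa)
  expect_error(read_fasta(fa), "bad")
})

test_that("FASTA round trip preserves sequence content", {
  set.seed(5)
  seqs <- setNames(vapply(c(50, 137, 301), random_dna_str, character(1)),
                   c("r1", "r2", "r3"))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(as_genome(seqs), fa)
  expect_equal(unclass(read_fasta(fa)), seqs)
})

test_that("fetch follows the 0-based half-open, minus-revcomp convention", {
  g <- as_genome(c(a = "ACGT", b = "AACC"))
  expect_equal(fetch(g, "a", 0, 4, "+"), "ACGT")
  expect_equal(fetch(g, "a", 0, 4, "-"), "ACGT")  # palindrome
  expect_equal(fetch(g, "b", 1, 3, "-"), "GT")  # revcomp of "AC"
  expect_equal(fetch(g, "b", 2, 4, "-"), "GG")  # revcomp of "CC"
  expect_error(fetch(g, "b", 2, 5), "out of bounds")
  expect_error(fetch(g, "zz", 0, 1), "unknown contig")
})

test_that("fetch(+) is the reverse complement of fetch(-) everywhere", {
  set.seed(9)
  g <- as_genome(c(x = random_dna_str(200)))
  for (r in 1:25) {
    s <- sample(0:190, 1); e <- s + sample(1:10, 1)
    expect_equal(fetch(g, "x", s, e, "+"), revcomp(fetch(g, "x", s, e, "-")))
  }
})

test_that("GFF3 writer uses 1-based inclusive coordinates and round-trips", {
  feats <- data.frame(contig = "c", start = 99L, end = 153L, strand = "+",
                      type = "hammerhead_ribozyme", score = 21,
                      id = "h1", parent = NA_character_,
                      stringsAsFactors = FALSE)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(feats, gff)
  lines <- readLines(gff)
  expect_equal(lines[1], "##gff-version 3")
  cols <- strsplit(lines[2], "\t")[[1]]
  expect_equal(as.integer(cols[4]), 100L)
  expect_equal(as.integer(cols[5]), 153L)

  back <- read_gff3(gff)
  expect_equal(back$start, 99L)
  expect_equal(back$end, 153L)

  # empty feature list -> header-only file
  write_gff3(feats[0, ], gff)
  expect_equal(readLines(gff), "##gff-version 3")
})

test_that("element GFF3 links LTR children to their retrozyme parent", {
  el <- data.frame(
    id = "rz_0001", contig = "c", start = 100L, end = 1100L, strand = "+",
    class = "full_retrozyme", n_units = 1L, topology = "III",
    ltr1_start = 100L, ltr1_end = 430L, ltr2_start = 770L, ltr2_end = 1100L,
    ltr_identity = 0.99, ltr_aln_len = 330L, cleavage1 = 150L,
    cleavage2 = 820L, monomer_len = 670L, tsd = "TAGG", tsd_len = 4L,
    tsd_wwrr = TRUE, pbs_start = 430L, pbs_end = 455L, pbs_mismatches = 0L,
    ppt_start = 745L, ppt_end = 770L, ppt_mismatches = 0L,
    hhr_ids = "hhr_00001,hhr_00002", stringsAsFactors = FALSE)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(elements_to_features(el), gff)
  back <- read_gff3(gff)
  ltrs <- back[back$type == "LTR", ]
  expect_equal(nrow(ltrs), 2L)
  expect_true(all(vapply(ltrs$attributes, function(a)
    identical(a$Parent, "rz_0001"), logical(1))))
  expect_equal(sort(back$type),
               sort(c("retrozyme", "LTR", "LTR", "TSD", "TSD", "PBS", "PPT")))

  # independent parser agrees on the coordinate conversion
  skip_if_not_installed("rtracklayer")
  gr <- rtracklayer::import(gff)
  rz <- gr[gr$type == "retrozyme"]
  expect_equal(BiocGenerics::start(rz), 101L)  # 1-based inclusive
  expect_equal(BiocGenerics::end(rz), 1100L)
})

test_that("BED6 output is 0-based half-open", {
  feats <- data.frame(contig = "c", start = 99L, end = 153L, strand = "-",
                      id = "h1", score = 5, stringsAsFactors = FALSE)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed6(feats, bed)
  cols <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(cols, c("c", "99", "153", "h1", "5", "-"))
})
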