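fake_hit <- function(contig, cut, strand = "+", topo = "III", bona = TRUE,
                     id = "h") {
  data.frame(contig = contig, start = cut - 10L, end = cut + 40L,
             strand = strand, topology = topo, score = 20,
             cleavage_pos = cut, tertiary_pairs = 3L, bona_fide = bona,
             id = id, stringsAsFactors = FALSE)
}

test_that("pair_hhrs groups tandem hits by cleavage spacing", {
  h <- rbind(fake_hit("c", 1000L, id = "a"), fake_hit("c", 1750L, id = "b"))
  runs <- pair_hhrs(h)
  expect_length(runs, 1L)
  expect_equal(runs[[1]]$id, c("a", "b"))

  # opposite strands never pair
  h2 <- rbind(fake_hit("c", 1000L, id = "a"),
              fake_hit("c", 1750L, strand = "-", id = "b"))
  runs2 <- pair_hhrs(h2)
  expect_length(runs2, 0L)
  expect_equal(nrow(attr(runs2, "singles")), 2L)

  # three hits at 800/800 -> one run of 3 (two monomer units)
  h3 <- rbind(fake_hit("c", 1000L, id = "a"), fake_hit("c", 1800L, id = "b"),
              fake_hit("c", 2600L, id = "c"))
  runs3 <- pair_hhrs(h3)
  expect_length(runs3, 1L)
  expect_equal(nrow(runs3[[1]]), 3L)

  # spacing outside [400, 1100] breaks the chain
  h4 <- rbind(fake_hit("c", 1000L, id = "a"), fake_hit("c", 1200L, id = "b"))
  expect_length(pair_hhrs(h4), 0L)
  # non bona fide hits never enter runs
  h5 <- rbind(fake_hit("c", 1000L, id = "a"),
              fake_hit("c", 1750L, bona = FALSE, id = "b"))
  expect_length(pair_hhrs(h5), 0L)
})

test_that("delimit_ltrs recovers planted LTR boundaries", {
  # no divergence: boundaries essentially exact
  spec0 <- synthetic_spec(ltr_divergence = 0, seed = 3L)
  set.seed(3)
  rz <- make_retrozyme(spec0)
  set.seed(4)
  g <- plant_in_background(rz$seq, 4000, 1500)
  tr <- rz$truth
  del <- delimit_ltrs(g, "chr", 1500 + tr$cut1, 1500 + tr$cut2)
  expect_false(is.null(del))
  expect_equal(del$identity, 1.0)
  expect_lte(abs((del$ltr1[2] - del$ltr1[1]) - 330L), 5L)
  expect_lte(abs((del$ltr2[2] - del$ltr2[1]) - 330L), 5L)
  expect_lte(abs(del$ltr1[1] - (1500 + tr$ltr1[1])), 5L)
  expect_lte(abs(del$ltr2[2] - (1500 + tr$ltr2[2])), 5L)

  # 2% divergence: high identity, boundaries within +/-15
  spec2 <- synthetic_spec(ltr_divergence = 0.02, seed = 5L)
  set.seed(5)
  rz2 <- make_retrozyme(spec2)
  set.seed(6)
  g2 <- plant_in_background(rz2$seq, 4000, 1200)
  tr2 <- rz2$truth
  del2 <- delimit_ltrs(g2, "chr", 1200 + tr2$cut1, 1200 + tr2$cut2)
  expect_false(is.null(del2))
  expect_gte(del2$identity, 0.95)
  expect_lte(abs(del2$ltr1[1] - (1200 + tr2$ltr1[1])), 15L)
  expect_lte(abs(del2$ltr1[2] - (1200 + tr2$ltr1[2])), 15L)
  expect_lte(abs(del2$ltr2[1] - (1200 + tr2$ltr2[1])), 15L)
  expect_lte(abs(del2$ltr2[2] - (1200 + tr2$ltr2[2])), 15L)

  # two stray motifs in unrelated flanks: no homologous block
  set.seed(7)
  m1 <- make_hhr(DESC, "III"); m2 <- make_hhr(DESC, "III")
  stray <- paste0(random_dna_str(400), m1$seq, random_dna_str(700),
                  m2$seq, random_dna_str(400))
  gs <- as_genome(c(chr = stray))
  c1 <- 400 + m1$cut
  c2 <- 400 + nchar(m1$seq) + 700 + m2$cut
  expect_null(delimit_ltrs(gs, "chr", c1, c2))
})

test_that("find_tsd honors exact duplication, sliding and WWRR annotation", {
  core <- random_dna_str(400)
  build <- function(tsd) {
    as_genome(c(chr = paste0(strrep("C", 60), tsd, core, tsd,
                             strrep("G", 60))))
  }
  g <- build("TAGG")
  tsd <- find_tsd(g, "chr", 64L, 64L + 400L)
  expect_equal(tsd$left, "TAGG")
  expect_equal(tsd$len, 4L)
  expect_true(tsd$wwrr)

  # boundaries off by a few nt are recovered by sliding
  tsd_slid <- find_tsd(g, "chr", 61L, 64L + 403L)
  expect_equal(tsd_slid$left, "TAGG")
  expect_equal(tsd_slid$start, 64L)
  expect_equal(tsd_slid$end, 464L)

  # CCGG duplicates but fails the WWRR consensus
  g2 <- build("CCGG")
  tsd2 <- find_tsd(g2, "chr", 64L, 64L + 400L)
  expect_equal(tsd2$left, "CCGG")
  expect_false(tsd2$wwrr)

  # boundaries that cannot alias under sliding share no k-mer: absent
  core3 <- paste0(strrep("A", 14), substr(core, 15, 386), strrep("T", 14))
  g3 <- as_genome(c(chr = paste0(strrep("C", 60), core3, strrep("G", 60))))
  expect_null(find_tsd(g3, "chr", 60L, 60L + 400L))

  # minus-strand elements check WWRR on the element strand
  g4 <- as_genome(c(chr = paste0(strrep("C", 60), "CCTA",
                                 revcomp(core), "CCTA", strrep("G", 60))))
  tsd4 <- find_tsd(g4, "chr", 64L, 64L + 400L, strand = "-")
  expect_equal(tsd4$left, "CCTA")
  expect_true(tsd4$wwrr)  # revcomp(CCTA) = TAGG
})

test_that("PPT detector finds the longest tolerant purine run", {
  run <- find_ppt_run("CCTTGAGAGAGGGGAATTCC")
  expect_false(is.null(run))
  expect_gte(run$len, 8L)
  expect_null(find_ppt_run("CTCTCTCTCTCTCTCT"))
  # a run of 8 pure purines at the threshold
  expect_equal(find_ppt_run("TTAGGAAGAGTT")$len, 8L)
})

test_that("junction boxes are found with their mismatch counts", {
  parts <- default_box_parts()
  boxes <- box_consensus()
  set.seed(21)
  rz <- make_retrozyme(synthetic_spec(ltr_divergence = 0, seed = 21L))
  g <- plant_in_background(rz$seq, 3000, 800)
  tr <- rz$truth
  ltr1 <- 800 + tr$ltr1; ltr2 <- 800 + tr$ltr2
  bx <- find_boxes(g, "chr", ltr1, ltr2, "+", boxes)
  expect_equal(bx$pbs$mismatches, 0L)
  expect_equal(bx$ppt$mismatches, 0L)
  # box3 straddles the 5' LTR 3' junction
  expect_equal(bx$pbs$end - bx$pbs$start, nchar(boxes$box3))
  expect_lte(abs(bx$pbs$start - (ltr1[2] - nchar(parts$ltr3))), 2L)
  expect_false(is.null(bx$ppt_run))

  # four substitutions in the genomic box3 are tolerated and counted
  s <- g[[1]]
  b3_at <- bx$pbs$start
  for (k in c(2L, 9L, 15L, 22L)) {
    base <- substr(s, b3_at + k, b3_at + k)
    substr(s, b3_at + k, b3_at + k) <-
      setdiff(c("A", "C", "G", "T"), base)[1]
  }
  g2 <- as_genome(setNames(s, "chr"))
  bx2 <- find_boxes(g2, "chr", ltr1, ltr2, "+", boxes)
  expect_equal(bx2$pbs$mismatches, 4L)
})

test_that("annotation classifies every bona fide hit exactly once", {
  sim <- build_genome(small_spec())
  hits <- scan_genome(sim$genome, DESC)
  elements <- annotate_retrozymes(sim$genome, hits)
  assigned <- unlist(strsplit(elements$hhr_ids, ","))
  bona <- hits$id[hits$bona_fide]
  expect_setequal(assigned, bona)
  expect_equal(anyDuplicated(assigned), 0L)
  expect_true(all(elements$class %in%
    c("full_retrozyme", "multimeric_retrozyme", "solo_LTR", "orphan_HHR")))
  # annotator is pure: same inputs -> identical output
  expect_identical(elements, annotate_retrozymes(sim$genome, hits))
})

test_that("monomer extraction is an exact cleavage-to-cleavage slice", {
  spec <- synthetic_spec(monomer_length = 753L, seed = 19L)
  set.seed(19)
  rz <- make_retrozyme(spec)
  expect_equal(rz$truth$cut2 - rz$truth$cut1, 753L)
  g <- plant_in_background(rz$seq, 3000, 900)
  el <- data.frame(contig = "chr", strand = "+",
                   cleavage1 = 900 + rz$truth$cut1,
                   cleavage2 = 900 + rz$truth$cut2)
  mono <- extract_monomer(g, el)
  expect_equal(mono$length, 753L)
  expect_equal(nchar(mono$seq), 753L)
  expect_false(grepl("T", mono$seq))  # RNA alphabet

  # minus strand: the monomer is the revcomp of the plus-strand slice
  el_minus <- el; el_minus$strand <- "-"
  mono_minus <- extract_monomer(g, el_minus)
  expect_equal(mono_minus$seq,
               dna_to_rna(revcomp(fetch(g, "chr", el$cleavage1,
                                        el$cleavage2, "+"))))

  el_bad <- el; el_bad$cleavage2 <- el$cleavage1 - 10L
  expect_error(extract_monomer(g, el_bad), "inverted")
})
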