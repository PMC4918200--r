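test_that("descriptor reports its constrained core positions", {
  expect_equal(core_positions(DESC), 15L)
  # the count tracks the configured strings
  d2 <- hhr_descriptor(core_seg_A = "CTGANGA", core_seg_B = "GAAAC")
  expect_equal(core_positions(d2), 16L)
  expect_error(hhr_descriptor(topologies = "IV"), "topologies")
})

test_that("scanning degenerate cases behaves per contract", {
  polyA <- as_genome(c(a = strrep("A", 1000)))
  expect_equal(nrow(scan_genome(polyA, DESC)), 0L)
  short <- as_genome(c(a = "ACG"))
  expect_equal(nrow(scan_genome(short, DESC)), 0L)
  d <- DESC; d$topologies <- character(0)
  expect_error(scan_genome(polyA, d), "empty")
})

test_that("a planted motif is recovered with its exact layout, both strands", {
  set.seed(1)
  h <- make_hhr(DESC, "III")
  set.seed(2)
  g <- plant_in_background(h$seq, 2000, 100)
  hits <- scan_genome(g, DESC)
  hits <- hits[hits$bona_fide, ]
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$topology, "III")
  expect_equal(hits$strand, "+")
  expect_equal(hits$cleavage_pos, 100L + h$cut)
  expect_gte(hits$tertiary_pairs, DESC$min_tertiary_pairs)

  # reverse complement of the record: mirrored location, same cut
  L <- nchar(g[[1]])
  grc <- as_genome(c(chr = revcomp(g[[1]])))
  hits2 <- scan_genome(grc, DESC)
  hits2 <- hits2[hits2$bona_fide, ]
  expect_equal(nrow(hits2), 1L)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$start, L - hits$end)
  expect_equal(hits2$end, L - hits$start)
  expect_equal(hits2$cleavage_pos, L - hits$cleavage_pos)
})

test_that("scanning is deterministic and its hits re-validate (soundness)", {
  set.seed(31)
  motifs <- replicate(4, make_hhr(DESC, sample(c("I", "III"), 1))$seq)
  g <- as_genome(c(c1 = paste0(random_dna_str(300), motifs[1],
                               random_dna_str(300), motifs[2],
                               random_dna_str(300)),
                   c2 = paste0(random_dna_str(200), motifs[3],
                               random_dna_str(400), motifs[4],
                               random_dna_str(100))))
  h1 <- scan_genome(g, DESC)
  h2 <- scan_genome(g, DESC)
  expect_identical(h1, h2)
  expect_gte(nrow(h1), 4L)
  expect_true(all(validate_hits(h1, g, DESC)))
  # sorted by (contig, start, strand)
  expect_identical(order(h1$contig, h1$start, h1$strand), seq_len(nrow(h1)))
})

test_that("a single substitution in any concrete core position kills the hit", {
  set.seed(77)
  h <- make_hhr(DESC, "III")
  g0 <- plant_in_background(h$seq, 600, 200)
  base_hits <- scan_genome(g0, DESC)
  expect_true(any(base_hits$bona_fide &
                    base_hits$cleavage_pos == 200 + h$cut))
  tab <- core_mutation_table(h, DESC)
  expect_gte(nrow(tab), 13L)  # concrete positions of the 15-nt core
  for (r in seq_len(nrow(tab))) {
    mut <- mutate_at(h$seq, tab$pos[r], tab$sub[r])
    gm <- as_genome(setNames(
      paste0(substr(g0[[1]], 1, 200), mut,
             substr(g0[[1]], 201 + nchar(h$seq), nchar(g0[[1]]))), "chr"))
    hm <- scan_genome(gm, DESC)
    overlapping <- hm[hm$bona_fide & hm$start < 200 + nchar(mut) &
                        hm$end > 200, , drop = FALSE]
    expect_equal(nrow(overlapping), 0L,
                 info = sprintf("core pos %d -> %s still detected",
                                tab$pos[r], tab$sub[r]))
  }
})

test_that("tertiary loop-loop run is the longest contiguous complementary run", {
  # hand-built: GCTA read against TAGC antiparallel gives a 4-run
  expect_equal(retrozyme:::tertiary_run("GCTA", "TAGC"), 4L)
  expect_equal(retrozyme:::tertiary_run("AAAA", "CCCC"), 0L)
  # wobble counts only when allowed
  expect_equal(retrozyme:::tertiary_run("GG", "TT", allow_wobble = FALSE), 0L)
  expect_equal(retrozyme:::tertiary_run("GG", "TT", allow_wobble = TRUE), 2L)
  # brute-force cross-check on random loop pairs
  set.seed(12)
  brute <- function(l1, l2) {
    a <- strsplit(l1, "")[[1]]; b <- strsplit(l2, "")[[1]]
    ok <- function(x, y) paste0(x, y) %in% c("AT", "TA", "GC", "CG")
    best <- 0
    for (i in seq_along(a)) for (j in seq_along(b)) {
      k <- 0
      while (i + k <= length(a) && j - k >= 1 && ok(a[i + k], b[j - k])) {
        k <- k + 1
      }
      best <- max(best, k)
    }
    best
  }
  for (t in 1:20) {
    l1 <- random_dna_str(sample(3:10, 1)); l2 <- random_dna_str(sample(3:10, 1))
    expect_equal(retrozyme:::tertiary_run(l1, l2), brute(l1, l2))
  }
})

test_that("destroying loop2 complementarity revokes bona fide status", {
  # pick a seeded motif whose loop1 cannot pair with a homopolymer fill
  set.seed(41)
  repeat {
    h <- make_hhr(DESC, "III")
    lay <- h$layout
    loop1_at <- h$cut + lay$h1  # 0-based offset of loop1
    loop1 <- substr(h$seq, loop1_at + 1L, loop1_at + lay$loop1)
    if (!grepl("TT", loop1)) break
  }
  loop2_at <- lay$coreA_at - 1L + nchar(DESC$core_seg_A) + lay$h2
  broken <- h$seq
  substr(broken, loop2_at + 1L, loop2_at + lay$loop2) <-
    strrep("A", lay$loop2)
  g <- plant_in_background(h$seq, 800, 300)
  gb <- as_genome(setNames(
    paste0(substr(g[[1]], 1, 300), broken,
           substr(g[[1]], 301 + nchar(h$seq), nchar(g[[1]]))), "chr"))
  hb <- scan_genome(gb, DESC)
  at_locus <- hb[hb$cleavage_pos == 300 + h$cut, , drop = FALSE]
  expect_equal(nrow(at_locus), 1L)
  expect_false(at_locus$bona_fide)
  expect_lt(at_locus$tertiary_pairs, DESC$min_tertiary_pairs)
  # check_tertiary recomputes the same verdict
  expect_identical(check_tertiary(hb, DESC)$bona_fide, hb$bona_fide)
})

test_that("find_degenerate_copies applies the identity threshold exactly", {
  set.seed(8)
  seed_seq <- random_dna_str(90)
  mutate_n <- function(s, n) {
    retrozyme:::mutate_positions(s, sample(nchar(s), n))
  }
  copy_ok <- mutate_n(seed_seq, 8)    # 82/90 = 91.1% identity
  copy_bad <- mutate_n(seed_seq, 12)  # 78/90 = 86.7% identity
  g <- as_genome(c(chr = paste0(random_dna_str(500), seed_seq,
                                random_dna_str(500), copy_ok,
                                random_dna_str(500), copy_bad,
                                random_dna_str(500))))
  found <- find_degenerate_copies(seed_seq, g, exclude = list(
    contig = "chr", start = 500L, end = 590L))
  expect_equal(nrow(found), 1L)
  expect_lt(abs(found$start - 1090L), 3L)

  # a genome holding only the seed itself: self excluded -> empty
  g2 <- as_genome(c(chr = paste0(random_dna_str(100), seed_seq,
                                 random_dna_str(100))))
  none <- find_degenerate_copies(seed_seq, g2, exclude = list(
    contig = "chr", start = 100L, end = 190L))
  expect_equal(nrow(none), 0L)

  expect_error(find_degenerate_copies("ACGT", g, window = 90L), "window")
})

test_that("degenerate copies are found on the minus strand too", {
  set.seed(13)
  seed_seq <- random_dna_str(90)
  copy <- retrozyme:::mutate_positions(seed_seq, sample(90, 5))
  g <- as_genome(c(chr = paste0(random_dna_str(300), revcomp(copy),
                                random_dna_str(300))))
  found <- find_degenerate_copies(seed_seq, g)
  expect_equal(nrow(found), 1L)
  expect_equal(found$strand, "-")
  expect_lt(abs(found$start - 300L), 3L)
})
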