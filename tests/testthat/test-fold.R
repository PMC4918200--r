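test_that("base cases fold as expected", {
  f0 <- fold_rna("AAAA")
  expect_equal(nrow(f0$pairs), 0L)
  expect_equal(f0$fraction_paired, 0)
  expect_equal(f0$dotbracket, "....")

  f <- fold_rna("GGGGAAAACCCC")
  expect_equal(nrow(f$pairs), 4L)
  expect_equal(f$fraction_paired, 8 / 12)
  expect_equal(f$score, 12)
  # the independent recursion agrees
  expect_equal(oracle_fold_score("GGGGAAAACCCC"), 12)

  expect_error(fold_rna("ACGX"), "invalid")
  expect_error(fold_rna(""), "empty")
})

test_that("DP optimum equals the exhaustive oracle on random sequences", {
  set.seed(100)
  for (t in 1:40) {
    s <- random_rna(sample(5:25, 1))
    expect_equal(fold_rna(s)$score, oracle_fold_score(s), info = s)
  }
})

test_that("returned structures satisfy the nesting and pairing invariants", {
  set.seed(101)
  for (t in 1:15) {
    s <- random_rna(sample(20:80, 1))
    f <- fold_rna(s)
    p <- f$pairs
    if (nrow(p) == 0) next
    ch <- strsplit(chartr("T", "U", s), "")[[1]]
    # allowed pairs and minimum loop
    for (r in seq_len(nrow(p))) {
      expect_true(paste0(ch[p[r, 1] + 1], ch[p[r, 2] + 1]) %in%
                    c("AU", "UA", "GC", "CG", "GU", "UG"))
      expect_gt(p[r, 2] - p[r, 1], 3L)
    }
    # no base in two pairs; no crossing pairs
    expect_equal(anyDuplicated(c(p[, 1], p[, 2])), 0L)
    if (nrow(p) > 1) {
      for (a in 1:(nrow(p) - 1)) for (b in (a + 1):nrow(p)) {
        i <- p[a, 1]; j <- p[a, 2]; k <- p[b, 1]; l <- p[b, 2]
        crossing <- (i < k & k < j & j < l) | (k < i & i < l & l < j)
        expect_false(crossing)
      }
    }
    expect_equal(f$n_paired, 2 * nrow(p))
    # dotbracket consistency
    expect_equal(unname(table(strsplit(f$dotbracket, "")[[1]])["("]),
                 nrow(p))
  }
})

test_that("appending the reverse complement never lowers fraction paired", {
  rc_rna <- function(s) {
    paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
  }
  set.seed(102)
  for (t in 1:10) {
    s <- random_rna(sample(10:40, 1))
    expect_gte(fold_rna(paste0(s, rc_rna(s)))$fraction_paired,
               fold_rna(s)$fraction_paired)
  }
})

test_that("folding is revcomp-symmetric under Watson-Crick pairing", {
  # Watson-Crick pairs map onto Watson-Crick pairs under reverse
  # complementation, so the optimal score is invariant; the number of
  # pairs is additionally invariant when every pair has unit weight
  # (with unequal weights, co-optimal structures can differ in pair
  # count, and a G:U pair maps onto unpairable A:C)
  wc <- c(GC = 3, AU = 2, GU = 0)
  unit <- c(GC = 1, AU = 1, GU = 0)
  rc_rna <- function(s) {
    paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
  }
  set.seed(103)
  for (t in 1:10) {
    s <- random_rna(30)
    expect_equal(fold_rna(s, weights = wc)$score,
                 fold_rna(rc_rna(s), weights = wc)$score)
    expect_equal(fold_rna(s, weights = unit)$fraction_paired,
                 fold_rna(rc_rna(s), weights = unit)$fraction_paired)
  }
})

test_that("a designed hairpin pairs its full stem and outfolds its shuffles", {
  set.seed(2)
  stem <- paste(sample(c("G", "C"), 20, replace = TRUE), collapse = "")
  rc <- paste(rev(strsplit(chartr("GC", "CG", stem), "")[[1]]), collapse = "")
  hp <- paste0(stem, "AAAA", rc)
  f <- fold_rna(hp)
  expect_equal(f$fraction_paired, 40 / 44)
  expect_equal(f$score, 60)  # 20 GC pairs
  shuffled <- replicate(20, {
    fold_rna(paste(sample(strsplit(hp, "")[[1]]), collapse =
                     ""))$fraction_paired
  })
  expect_lt(mean(shuffled), f$fraction_paired)
})

test_that("fraction_paired_report handles files and empty input", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">m1", "GGGGAAAACCCC", ">m2", "AAAA"), fa)
  tab <- fraction_paired_report(fa)
  expect_equal(tab$id, c("m1", "m2"))
  expect_equal(tab$fraction_paired, c(8 / 12, 0))
  expect_equal(nrow(fraction_paired_report(character(0))), 0L)
})

test_that("hhr_blocked measures pairing out of the motif span", {
  # motif fully paired against a distal complement: everything blocked
  set.seed(104)
  m <- random_rna(30)
  rc <- paste(rev(strsplit(chartr("ACGU", "UGCA", m), "")[[1]]), collapse = "")
  f <- fold_rna(paste0(m, "AAAA", rc))
  expect_gt(hhr_blocked(f, c(0L, 30L)), 0.5)
  # whole-sequence span: no partner can be outside
  expect_equal(hhr_blocked(f, c(0L, f$length)), 0)
  # a structure with no pairs at all
  expect_equal(hhr_blocked(fold_rna("AAAAAAAA"), c(0L, 4L)), 0)
  expect_error(hhr_blocked(f, c(-1L, 10L)), "bounds")
})

test_that("dot-bracket output round-trips through its own format", {
  seqs <- c(h1 = "GGGGAAAACCCC")
  folds <- list(h1 = fold_rna(seqs[["h1"]]))
  db <- withr::local_tempfile(fileext = ".db")
  write_dotbracket(folds, seqs, db)
  lines <- readLines(db)
  expect_equal(lines[1], ">h1")
  expect_equal(nchar(lines[3]), nchar(lines[2]))
  expect_equal(lines[3], folds$h1$dotbracket)
})
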