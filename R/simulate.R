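#' Specification of a synthetic benchmark genome
#'
#' The defaults reproduce the package's reference benchmark: a 5-Mb
#' background carrying 20 full retrozymes, 5 solo LTRs, 2 multimeric
#' elements and 10 decoys, with 330-bp LTRs, 300-600 bp internal
#' regions (monomers of ~650-950 nt), 1% LTR-LTR divergence, 4-bp WWRR
#' target-site duplications and type III hammerheads -- the element
#' anatomy reported for plant retrozymes.
#'
#' @param genome_length total background length in nt.
#' @param n_contigs number of chromosomes the length is split over.
#' @param gc_content background GC fraction (default 0.4).
#' @param n_full,n_solo,n_multimer,n_decoys element counts.
#' @param multimer_units number of tandem HHRs in a multimeric element
#'   (default 3, i.e. two monomer units).
#' @param ltr_length LTR length in nt (default 330).
#' @param internal_length range of the internal-region length.
#' @param monomer_length optional fixed cleavage-to-cleavage monomer
#'   length; when set, the internal length is derived from it.
#' @param ltr_divergence substitution rate between the two LTR copies
#'   (applied outside the ribozyme footprint; default 0.01).
#' @param tsd_length TSD length (4 gives WWRR-consensus sampling).
#' @param topology hammerhead topology of planted motifs.
#' @param minus_strand_prob probability an element is planted on the
#'   minus strand (default 0.5).
#' @param seed integer seed; all randomness flows from it.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(genome_length = 5e6L, n_contigs = 2L,
                           gc_content = 0.4,
                           n_full = 20L, n_solo = 5L, n_multimer = 2L,
                           n_decoys = 10L, multimer_units = 3L,
                           ltr_length = 330L,
                           internal_length = c(300L, 600L),
                           monomer_length = NULL,
                           ltr_divergence = 0.01,
                           tsd_length = 4L, topology = "III",
                           minus_strand_prob = 0.5, seed = 7L) {
  stopifnot(genome_length > 0, n_contigs >= 1L, gc_content > 0,
            gc_content < 1, n_full >= 0L, n_solo >= 0L, n_multimer >= 0L,
            n_decoys >= 0L, multimer_units >= 3L)
  structure(as.list(environment()), class = "synthetic_spec")
}

sample_iupac <- function(pattern) {
  paste(vapply(strsplit(pattern, "")[[1]],
               function(ch) {
                 s <- IUPAC_SETS[[ch]]
                 if (length(s) == 1L) s else s[sample.int(length(s), 1L)]
               }, character(1)), collapse = "")
}

random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A")

## substitute characters at given 1-based positions with a different base
mutate_positions <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

## apply a substitution rate outside protected 1-based positions
mutate_rate <- function(seq, rate, protect = integer(0)) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  eligible <- setdiff(seq_len(n), protect)
  k <- rbinom(1L, length(eligible), rate)
  if (k == 0L) return(seq)
  mutate_positions(seq, sample(eligible, k))
}

#' Generate one hammerhead ribozyme motif
#'
#' Samples helix lengths and loops uniformly inside the descriptor's
#' ranges, enforces Watson-Crick arms (occasionally one G:T wobble per
#' helix), instantiates the degenerate core segments, and plants a
#' complementary loop1-loop2 run of at least `desc$min_tertiary_pairs`
#' so the motif passes the bona fide filter.  Uses the current RNG
#' state; seed upstream for reproducibility.
#'
#' @param desc an [hhr_descriptor()].
#' @param topology `"I"`, `"II"` or `"III"`.
#' @param wobble_prob probability that a helix carries one wobble pair.
#' @return list with `seq` (DNA), `cut` (0-based between-base offset of
#'   the self-cleavage site within `seq`) and `layout` (helix/loop
#'   lengths and segment positions).
#' @export
make_hhr <- function(desc = hhr_descriptor(), topology = "III",
                     wobble_prob = 0.25) {
  stopifnot(topology %in% c("I", "II", "III"))
  rint <- function(r) sample(r[1]:r[2], 1L)
  L1 <- rint(desc$helix1); L2 <- rint(desc$helix2); L3 <- rint(desc$helix3)
  lp <- function() sample(desc$loop[1]:min(desc$loop[2], 12L), 1L)
  coreA <- sample_iupac(desc$core_seg_A)
  coreB <- sample_iupac(desc$core_seg_B)
  ctx <- sample_iupac(desc$cleavage_context)
  cutadj <- sample_iupac(desc$cut_adjacent)

  make_arms <- function(L, first_char = NULL) {
    a1 <- strsplit(random_dna(L, 0.5), "")[[1]]
    if (!is.null(first_char)) a1[L] <- DNA_COMP[[first_char]]
    a2 <- rev(DNA_COMP[a1])
    ## optional single wobble, never on a constrained terminal pair
    if (runif(1) < wobble_prob) {
      cand <- which(a1 %in% c("G", "T"))
      if (!is.null(first_char)) cand <- setdiff(cand, L)
      if (length(cand)) {
        p <- cand[sample.int(length(cand), 1L)]
        a2[L + 1L - p] <- if (a1[p] == "G") "T" else "G"
      }
    }
    list(a = paste(a1, collapse = ""), b = paste(a2, collapse = ""))
  }
  ## helix I: first base of the downstream arm is the invariant
  ## cut-adjacent residue
  h1 <- local({
    arms <- make_arms(L1, first_char = cutadj)
    ## arms$b starts at ... we need H1b[1] == cutadj: build directly
    b <- strsplit(random_dna(L1, 0.5), "")[[1]]
    b[1L] <- cutadj
    a <- rev(DNA_COMP[b])
    if (runif(1) < wobble_prob) {
      cand <- setdiff(which(b %in% c("G", "T")), 1L)
      if (length(cand)) {
        p <- cand[sample.int(length(cand), 1L)]
        a[L1 + 1L - p] <- if (b[p] == "G") "T" else "G"
      }
    }
    list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
  })
  h2 <- make_arms(L2)
  h3 <- make_arms(L3)

  ## loops are built so that the planted helix cannot be extended by a
  ## chance pair across the loop ends (ends pinned to A, which pairs
  ## with nothing here): the planted layout is then the unique
  ## maximum-scoring assembly at its locus
  loop_of <- function(n) {
    ch <- strsplit(random_dna(n, 0.5), "")[[1]]
    ch[1L] <- "A"; ch[n] <- "A"
    paste(ch, collapse = "")
  }

  plant_run <- function(donor, loop2, t, d_lo = 1L,
                        d_hi = nchar(donor) - t + 1L) {
    ## plant into loop2 (away from its pinned ends) the antiparallel
    ## complement of a donor segment chosen within [d_lo, d_hi]
    t <- min(t, nchar(donor), nchar(loop2) - 2L)
    dch <- strsplit(donor, "")[[1]]
    ir <- d_lo:max(d_lo, d_hi)
    i <- ir[sample.int(length(ir), 1L)]
    l2 <- strsplit(loop2, "")[[1]]
    jr <- (t + 1L):(nchar(loop2) - 1L)
    j <- jr[sample.int(length(jr), 1L)]
    for (k in 0:(t - 1L)) l2[j - k] <- DNA_COMP[[dch[i + k]]]
    paste(l2, collapse = "")
  }

  if (topology == "III") {
    t_run <- min(desc$min_tertiary_pairs + sample(0:2, 1L), 4L)
    lp1 <- max(lp(), t_run + 2L)
    lp2 <- max(lp(), t_run + 2L)
    loop1 <- loop_of(lp1)
    loop2 <- plant_run(loop1, loop_of(lp2), t_run,
                       d_lo = 2L, d_hi = lp1 - t_run)
    seq <- paste0(h3$b, ctx, h1$b, loop1, h1$a, coreA,
                  h2$a, loop2, h2$b, coreB, h3$a)
    cut <- L3 + nchar(ctx)
    layout <- list(topology = "III", h1 = L1, h2 = L2, h3 = L3,
                   loop1 = lp1, loop2 = lp2, loop3 = NA_integer_,
                   coreA_at = L3 + nchar(ctx) + 2L * L1 + lp1 + 1L)
  } else if (topology == "I") {
    ## the run is planted against the terminal bases of the distal
    ## helix-I arm so it stays inside the tertiary window even if the
    ## open helix gains chance pairs from the flanking sequence
    t_run <- desc$min_tertiary_pairs
    lp2 <- max(lp(), t_run + 2L)
    lp3 <- lp()
    donor <- substr(h1$b, L1 - t_run + 1L, L1)
    loop2 <- plant_run(donor, loop_of(lp2), t_run)
    seq <- paste0(h1$a, coreA, h2$a, loop2, h2$b, coreB,
                  h3$a, loop_of(lp3), h3$b, ctx, h1$b)
    cut <- nchar(seq) - L1
    layout <- list(topology = "I", h1 = L1, h2 = L2, h3 = L3,
                   loop1 = NA_integer_, loop2 = lp2, loop3 = lp3,
                   coreA_at = L1 + 1L)
  } else {
    t_run <- min(desc$min_tertiary_pairs + sample(0:2, 1L), 4L)
    lp1 <- lp(); lp3 <- lp()
    loop1 <- loop_of(lp1)
    seq <- paste0(h2$b, coreB, h3$a, loop_of(lp3), h3$b, ctx, h1$b,
                  loop1, h1$a, coreA, h2$a)
    cut <- L2 + nchar(coreB) + 2L * L3 + lp3 + nchar(ctx)
    layout <- list(topology = "II", h1 = L1, h2 = L2, h3 = L3,
                   loop1 = lp1, loop2 = NA_integer_, loop3 = lp3,
                   coreA_at = nchar(seq) - L2 - nchar(coreA) + 1L)
  }
  list(seq = seq, cut = cut, layout = layout)
}

## 1-based positions of descriptor-constrained (core) characters within
## a motif produced by make_hhr, with the concrete base required
core_footprint <- function(hhr, desc) {
  lay <- hhr$layout
  lenA <- nchar(desc$core_seg_A)
  ## coreA span plus cleavage context and cut-adjacent base
  pos <- lay$coreA_at:(lay$coreA_at + lenA - 1L)
  ctx_len <- nchar(desc$cleavage_context)
  cut <- hhr$cut
  c(pos, (cut - ctx_len + 1L):cut, cut + 1L)
}

## Ground truth must be unambiguous: a planted element is accepted only
## if scanning it recovers a bona fide hit at exactly each planted
## cleavage offset (rarely, ~0.5% of draws, a chance second motif
## interpretation outscores the planted one; those loci are resampled).
verify_planted <- function(seq, cuts, desc) {
  hits <- scan_genome(as_genome(c(el = seq)), desc)
  all(vapply(cuts, function(cu)
    any(hits$bona_fide & hits$strand == "+" & hits$cleavage_pos == cu),
    logical(1)))
}

with_retry <- function(build, cuts_of, desc, max_try = 50L) {
  for (t in seq_len(max_try)) {
    out <- build()
    if (verify_planted(out$seq, cuts_of(out), desc)) return(out)
  }
  stop("could not generate an unambiguous planted element in ",
       max_try, " tries")
}

## an LTR: conserved 5' end + pad + HHR + pad + conserved 3' end
make_ltr <- function(desc, spec, parts, topology) {
  hhr <- make_hhr(desc, topology)
  len5 <- nchar(parts$ltr5); len3 <- nchar(parts$ltr3)
  rem <- spec$ltr_length - len5 - len3 - nchar(hhr$seq)
  if (rem < 0L) stop("ltr_length too short for the motif and boxes")
  pre <- sample.int(rem + 1L, 1L) - 1L
  seq <- paste0(parts$ltr5, random_dna(pre, spec$gc_content), hhr$seq,
                random_dna(rem - pre, spec$gc_content), parts$ltr3)
  list(seq = seq, cut = len5 + pre + hhr$cut,
       motif_start = len5 + pre, motif_len = nchar(hhr$seq), hhr = hhr)
}

sample_tsd <- function(len) {
  if (len == 4L) {
    paste0(sample(c("A", "T"), 1L), sample(c("A", "T"), 1L),
           sample(c("A", "G"), 1L), sample(c("A", "G"), 1L))
  } else random_dna(len, 0.5)
}

#' Default conserved box parts used by the generator
#'
#' The four sequence blocks whose concatenations form the two junction
#' boxes: `box5 = ppt + ltr5` and `box3 = ltr3 + pbs` (see
#' [box_consensus()]).
#'
#' @return named list with `ppt`, `ltr5`, `ltr3`, `pbs`.
#' @export
default_box_parts <- function() {
  list(ppt = DEFAULT_PPT, ltr5 = DEFAULT_LTR5,
       ltr3 = DEFAULT_LTR3, pbs = DEFAULT_PBS)
}

#' Generate one full retrozyme element
#'
#' Layout (element strand): `TSD | LTR1(5' box end .. HHR .. 3' box
#' start) | PBS | internal | PPT | LTR2 (diverged copy of LTR1) | TSD`.
#' The two cleavage sites sit at the same offset of the two LTR copies,
#' so the monomer length is exactly `ltr_length + PBS + internal + PPT`.
#' LTR divergence is applied outside the ribozyme footprint (purifying
#' selection keeps the second hammerhead active).
#'
#' @param spec a [synthetic_spec()].
#' @param desc an [hhr_descriptor()].
#' @param parts conserved box parts (`ppt`, `ltr5`, `ltr3`, `pbs`).
#' @return list with `seq` (TSD-inclusive, element strand), and a
#'   `truth` list of element-strand offsets (`tsd_len`, `cut1`, `cut2`,
#'   `ltr1`, `ltr2`, `monomer_len`, `tsd`).
#' @export
make_retrozyme <- function(spec = synthetic_spec(), desc = hhr_descriptor(),
                           parts = default_box_parts()) {
  with_retry(function() make_retrozyme_once(spec, desc, parts),
             function(o) c(o$truth$cut1, o$truth$cut2), desc)
}

make_retrozyme_once <- function(spec, desc, parts) {
  ltr <- make_ltr(desc, spec, parts, spec$topology)
  aux <- nchar(parts$pbs) + nchar(parts$ppt)
  internal_len <- if (!is.null(spec$monomer_length)) {
    spec$monomer_length - spec$ltr_length - aux
  } else sample(spec$internal_length[1]:spec$internal_length[2], 1L)
  if (internal_len < 0L) stop("monomer_length too short for LTR + boxes")
  protect <- (ltr$motif_start + 1L):(ltr$motif_start + ltr$motif_len)
  ltr2 <- mutate_rate(ltr$seq, spec$ltr_divergence, protect)
  tsd <- sample_tsd(spec$tsd_length)
  internal <- random_dna(internal_len, spec$gc_content)
  core <- paste0(ltr$seq, parts$pbs, internal, parts$ppt, ltr2)
  seq <- paste0(tsd, core, tsd)
  k <- spec$tsd_length
  cut1 <- k + ltr$cut
  cut2 <- k + spec$ltr_length + nchar(parts$pbs) + internal_len +
    nchar(parts$ppt) + ltr$cut
  list(seq = seq, truth = list(
    tsd_len = k, tsd = tsd, cut1 = cut1, cut2 = cut2,
    ltr1 = c(k, k + spec$ltr_length),
    ltr2 = c(nchar(seq) - k - spec$ltr_length, nchar(seq) - k),
    monomer_len = cut2 - cut1, internal_len = internal_len,
    motif1 = c(k + ltr$motif_start, k + ltr$motif_start + ltr$motif_len)))
}

## a solo LTR: the circular-template cDNA layout PPT | LTR | PBS
make_solo_ltr <- function(spec, desc, parts) {
  with_retry(function() make_solo_ltr_once(spec, desc, parts),
             function(o) o$truth$cut1, desc)
}

make_solo_ltr_once <- function(spec, desc, parts) {
  ltr <- make_ltr(desc, spec, parts, spec$topology)
  tsd <- sample_tsd(spec$tsd_length)
  core <- paste0(parts$ppt, ltr$seq, parts$pbs)
  seq <- paste0(tsd, core, tsd)
  k <- spec$tsd_length
  list(seq = seq, truth = list(
    tsd_len = k, tsd = tsd,
    cut1 = k + nchar(parts$ppt) + ltr$cut, cut2 = NA_integer_,
    ltr1 = c(k + nchar(parts$ppt), k + nchar(parts$ppt) + spec$ltr_length),
    ltr2 = c(NA_integer_, NA_integer_),
    monomer_len = NA_integer_, internal_len = NA_integer_,
    motif1 = c(k + nchar(parts$ppt) + ltr$motif_start,
               k + nchar(parts$ppt) + ltr$motif_start + ltr$motif_len)))
}

## a tandem multimer with `units` HHR-bearing LTRs
make_multimer <- function(spec, desc, parts, units = 3L) {
  with_retry(function() make_multimer_once(spec, desc, parts, units),
             function(o) o$truth$cuts, desc)
}

make_multimer_once <- function(spec, desc, parts, units) {
  ltr <- make_ltr(desc, spec, parts, spec$topology)
  internal_len <- sample(spec$internal_length[1]:spec$internal_length[2], 1L)
  internal <- random_dna(internal_len, spec$gc_content)
  protect <- (ltr$motif_start + 1L):(ltr$motif_start + ltr$motif_len)
  pieces <- ltr$seq
  for (u in 2:units) {
    pieces <- c(pieces,
                paste0(parts$pbs,
                       mutate_rate(internal, spec$ltr_divergence),
                       parts$ppt,
                       mutate_rate(ltr$seq, spec$ltr_divergence, protect)))
  }
  tsd <- sample_tsd(spec$tsd_length)
  seq <- paste0(tsd, paste(pieces, collapse = ""), tsd)
  k <- spec$tsd_length
  unit_len <- spec$ltr_length + nchar(parts$pbs) + internal_len +
    nchar(parts$ppt)
  cuts <- k + ltr$cut + (0:(units - 1L)) * unit_len
  list(seq = seq, truth = list(
    tsd_len = k, tsd = tsd, cut1 = cuts[1], cut2 = cuts[units],
    cuts = cuts,
    ltr1 = c(k, k + spec$ltr_length),
    ltr2 = c(nchar(seq) - k - spec$ltr_length, nchar(seq) - k),
    monomer_len = unit_len, internal_len = internal_len,
    motif1 = c(k + ltr$motif_start, k + ltr$motif_start + ltr$motif_len)))
}

## decoy builders ----------------------------------------------------

## decoys that must stay invisible are verified to contain no bona
## fide motif at all (chance motifs in random sequence are resampled)
verify_none <- function(seq, desc) {
  hits <- scan_genome(as_genome(c(el = seq)), desc)
  nrow(hits) == 0L || !any(hits$bona_fide)
}

with_retry_none <- function(build, desc, max_try = 50L) {
  for (t in seq_len(max_try)) {
    out <- build()
    if (verify_none(out$seq, desc)) return(out)
  }
  stop("could not generate a motif-free decoy in ", max_try, " tries")
}

## full-element shape whose two motifs each carry one core substitution
make_decoy_core_mut <- function(spec, desc, parts) {
  with_retry_none(function() make_decoy_core_mut_once(spec, desc, parts),
                  desc)
}

make_decoy_core_mut_once <- function(spec, desc, parts) {
  rz <- make_retrozyme(spec, desc, parts)
  ch <- strsplit(rz$seq, "")[[1]]
  for (cut_at in c(rz$truth$cut1, rz$truth$cut2)) {
    ## mutate the first concrete core_seg_A base (the C of CTGA); its
    ## offset from the cut is constant across the two LTR copies only
    ## for the planted layout, so locate it by pattern in the motif
    motif_lo <- rz$truth$motif1[1]
    delta <- cut_at - rz$truth$cut1
    lo <- motif_lo + delta
    hi <- lo + (rz$truth$motif1[2] - rz$truth$motif1[1])
    window <- substr(rz$seq, lo + 1L, hi)
    m <- regexpr(seed_word(desc$core_seg_A)$word, window, fixed = TRUE)
    p <- lo + as.integer(m)  # 1-based position of the core C
    ch[p] <- "A"
  }
  list(seq = paste(ch, collapse = ""))
}

make_decoy_lone_hhr <- function(spec, desc) {
  build <- function() {
    hhr <- make_hhr(desc, spec$topology)
    pad <- function() random_dna(40L, spec$gc_content)
    s <- paste0(pad(), hhr$seq, pad())
    list(seq = s, cut = 40L + hhr$cut,
         motif = c(40L, 40L + nchar(hhr$seq)))
  }
  with_retry(build, function(o) o$cut, desc)
}

make_decoy_shuffled_monomer <- function(spec, desc, parts) {
  with_retry_none(function() {
    rz <- make_retrozyme(spec, desc, parts)
    mono <- substr(rz$seq, rz$truth$cut1 + 1L, rz$truth$cut2)
    list(seq = paste(sample(strsplit(mono, "")[[1]]), collapse = ""))
  }, desc)
}

make_decoy_ltr_pair <- function(spec, desc) {
  with_retry_none(function() {
    rep_seq <- random_dna(spec$ltr_length, spec$gc_content)
    internal <- random_dna(400L, spec$gc_content)
    list(seq = paste0(rep_seq, internal,
                      mutate_rate(rep_seq, spec$ltr_divergence)))
  }, desc)
}

#' Build a synthetic genome with planted retrozymes and ground truth
#'
#' Plants full elements, solo LTRs, tandem multimers and four kinds of
#' decoy (core-mutated elements, shuffled monomers, bare motifs, LTR
#' pairs without ribozymes) at uniform non-overlapping positions in an
#' i.i.d. background, on either strand.  All randomness flows from
#' `spec$seed`: the same spec yields byte-identical output.
#'
#' @param spec a [synthetic_spec()].
#' @param desc an [hhr_descriptor()].
#' @param parts conserved box parts (see [default_box_parts()]); the
#'   generator embeds whatever is configured so annotation against the
#'   matching [box_consensus()] is self-consistent.
#' @return list with `genome` (a `genome` object) and `truth` (data
#'   frame of planted features; `expected_class` gives the class a
#'   correct annotator assigns, `NA` for invisible decoys).
#' @export
build_genome <- function(spec = synthetic_spec(), desc = hhr_descriptor(),
                         parts = default_box_parts()) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)
  contig_len <- rep(spec$genome_length %/% spec$n_contigs, spec$n_contigs)
  contig_len[spec$n_contigs] <- spec$genome_length -
    sum(contig_len[-spec$n_contigs])
  contigs <- setNames(
    vapply(contig_len, random_dna, character(1), gc = spec$gc_content),
    sprintf("chr%02d", seq_len(spec$n_contigs)))

  plan <- c(rep("full", spec$n_full), rep("solo", spec$n_solo),
            rep("multimer", spec$n_multimer),
            rep_len(c("decoy_core_mut", "decoy_shuffled_monomer",
                      "decoy_lone_hhr", "decoy_ltr_pair_no_hhr"),
                    spec$n_decoys))

  placed <- lapply(names(contigs), function(x) NULL)
  names(placed) <- names(contigs)
  truth_rows <- list()

  for (kind in plan) {
    made <- switch(kind,
      full = make_retrozyme(spec, desc, parts),
      solo = make_solo_ltr(spec, desc, parts),
      multimer = make_multimer(spec, desc, parts, spec$multimer_units),
      decoy_core_mut = make_decoy_core_mut(spec, desc, parts),
      decoy_shuffled_monomer = make_decoy_shuffled_monomer(spec, desc, parts),
      decoy_lone_hhr = make_decoy_lone_hhr(spec, desc),
      decoy_ltr_pair_no_hhr = make_decoy_ltr_pair(spec, desc))
    strand <- if (runif(1) < spec$minus_strand_prob) "-" else "+"
    planted_seq <- if (strand == "-") revcomp(made$seq) else made$seq
    L <- nchar(planted_seq)

    pos <- NULL
    for (try in seq_len(1000L)) {
      ct <- sample(names(contigs), 1L)
      if (contig_len[[match(ct, names(contigs))]] < L + 2L) next
      p <- sample.int(nchar(contigs[[ct]]) - L - 1L, 1L)
      iv <- placed[[ct]]
      if (!is.null(iv) && any(p < iv[, 2] + 50L & p + L > iv[, 1] - 50L)) next
      pos <- list(contig = ct, at = p)
      break
    }
    if (is.null(pos)) {
      stop("could not place element without overlap after 1000 tries; ",
           "increase genome_length")
    }
    ct <- pos$contig; p <- pos$at  # 0-based insertion offset
    substr(contigs[[ct]], p + 1L, p + L) <- planted_seq
    placed[[ct]] <- rbind(placed[[ct]], c(p, p + L))

    ## element-strand offsets -> plus-strand genome coordinates
    o2p <- function(x) if (strand == "+") p + x else p + L - x
    iv2p <- function(iv) if (strand == "+") p + iv else p + L - rev(iv)
    tr <- made$truth
    row <- data.frame(
      kind = kind, contig = ct, strand = strand,
      start = NA_integer_, end = NA_integer_,
      expected_class = NA_character_,
      ltr1_start = NA_integer_, ltr1_end = NA_integer_,
      ltr2_start = NA_integer_, ltr2_end = NA_integer_,
      cleavage1 = NA_integer_, cleavage2 = NA_integer_,
      monomer_len = NA_integer_, tsd = NA_character_,
      n_units = NA_integer_, stringsAsFactors = FALSE)
    if (kind %in% c("full", "solo", "multimer")) {
      k <- tr$tsd_len
      span <- sort(c(o2p(k), o2p(L - k)))
      row$start <- span[1]; row$end <- span[2]
      row$expected_class <- switch(kind, full = "full_retrozyme",
                                   solo = "solo_LTR",
                                   multimer = "multimeric_retrozyme")
      l1 <- iv2p(tr$ltr1)
      row$ltr1_start <- l1[1]; row$ltr1_end <- l1[2]
      if (!is.na(tr$ltr2[1])) {
        l2 <- iv2p(tr$ltr2)
        if (l2[1] < l1[1]) { tmp <- l1; l1 <- l2; l2 <- tmp }
        row$ltr1_start <- l1[1]; row$ltr1_end <- l1[2]
        row$ltr2_start <- l2[1]; row$ltr2_end <- l2[2]
      }
      cuts <- sort(o2p(c(tr$cut1, tr$cut2)))
      row$cleavage1 <- cuts[1]
      if (!is.na(tr$cut2)) row$cleavage2 <- cuts[2]
      row$monomer_len <- tr$monomer_len
      row$tsd <- tr$tsd
      row$n_units <- switch(kind, full = 1L, solo = 0L,
                            multimer = spec$multimer_units - 1L)
    } else if (kind == "decoy_lone_hhr") {
      mv <- sort(c(o2p(made$motif[1]), o2p(made$motif[2])))
      row$start <- mv[1]; row$end <- mv[2]
      row$cleavage1 <- o2p(made$cut)
      row$expected_class <- "orphan_HHR"
    } else {
      row$start <- p; row$end <- p + L
    }
    truth_rows[[length(truth_rows) + 1L]] <- row
  }

  truth <- if (length(truth_rows)) {
    do.call(rbind, truth_rows)
  } else {
    data.frame(kind = character(0), contig = character(0),
               strand = character(0), start = integer(0), end = integer(0),
               expected_class = character(0), ltr1_start = integer(0),
               ltr1_end = integer(0), ltr2_start = integer(0),
               ltr2_end = integer(0), cleavage1 = integer(0),
               cleavage2 = integer(0), monomer_len = integer(0),
               tsd = character(0), n_units = integer(0),
               stringsAsFactors = FALSE)
  }
  truth$id <- sprintf("truth_%03d", seq_len(nrow(truth)))
  list(genome = as_genome(contigs), truth = truth)
}

#' Write a synthetic genome and its truth tables to an output directory
#'
#' @param sim result of [build_genome()].
#' @param dir output directory (created if needed).
#' @return paths of the files written, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fasta")
  tsv <- file.path(dir, "truth.tsv")
  gff <- file.path(dir, "truth.gff3")
  write_fasta(sim$genome, fa)
  write.table(sim$truth, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  feats <- data.frame(
    contig = sim$truth$contig, start = sim$truth$start,
    end = sim$truth$end, strand = sim$truth$strand,
    type = ifelse(is.na(sim$truth$expected_class), "decoy",
                  sim$truth$expected_class),
    id = sim$truth$id, stringsAsFactors = FALSE)
  write_gff3(feats, gff)
  invisible(c(fa, tsv, gff))
}
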