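## Longest run of concrete (non-degenerate) letters in a core segment,
## used as the exact seed word for scanning.
seed_word <- function(core) {
  chars <- strsplit(core, "")[[1]]
  concrete <- chars %in% c("A", "C", "G", "T")
  best <- c(0L, 0L)  # offset, length
  i <- 1L
  while (i <= length(chars)) {
    if (concrete[i]) {
      j <- i
      while (j < length(chars) && concrete[j + 1L]) j <- j + 1L
      if (j - i + 1L > best[2]) best <- c(i - 1L, j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  list(word = substr(core, best[1] + 1L, best[1] + best[2]),
       offset = best[1])
}

## Longest contiguous antiparallel complementary run between two loop
## sequences: l1[i+k] pairs l2[j-k] for k = 0..run-1.
tertiary_run <- function(loop1, loop2, allow_wobble = FALSE) {
  if (is.na(loop1) || is.na(loop2) || !nzchar(loop1) || !nzchar(loop2))
    return(0L)
  ok_pairs <- c("AT", "TA", "GC", "CG")
  if (allow_wobble) ok_pairs <- c(ok_pairs, "GT", "TG")
  a <- strsplit(loop1, "")[[1]]
  b <- strsplit(loop2, "")[[1]]
  n1 <- length(a); n2 <- length(b)
  best <- 0L
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      k <- 0L
      while (i + k <= n1 && j - k >= 1L &&
             paste0(a[i + k], b[j - k]) %in% ok_pairs) {
        k <- k + 1L
      }
      if (k > best) best <- k
    }
  }
  best
}

## enumerate valid helix II + core_seg_B junctions downstream of coreA
## at 1-based position sA; returns a list of candidate records
enumerate_helix2 <- function(seq, sA, desc) {
  n <- nchar(seq)
  lenA <- nchar(desc$core_seg_A)
  lenB <- nchar(desc$core_seg_B)
  out <- list()
  for (L2 in desc$helix2[1]:desc$helix2[2]) {
    h2a_start <- sA + lenA
    if (h2a_start + L2 - 1L > n) break
    h2a <- substr(seq, h2a_start, h2a_start + L2 - 1L)
    for (lp2 in desc$loop[1]:desc$loop[2]) {
      h2b_start <- h2a_start + L2 + lp2
      coreB_start <- h2b_start + L2
      if (coreB_start + lenB - 1L > n) break
      if (!match_compiled(desc$cp_B, seq, coreB_start, n)) next
      h2b <- substr(seq, h2b_start, h2b_start + L2 - 1L)
      hs <- helix_score(h2a, h2b, desc$max_wobbles)
      if (is.null(hs)) next
      out[[length(out) + 1L]] <- list(
        L2 = L2, lp2 = lp2,
        loop2 = substr(seq, h2a_start + L2, h2b_start - 1L),
        score2 = hs$score, wob2 = hs$wobbles,
        after_coreB = coreB_start + lenB)
    }
  }
  out
}

## Candidate assembly at one coreA seed for one topology.  All positions
## are 1-based inclusive in the oriented sequence; returns a list of
## candidate hit records (possibly empty).
assemble_at_seed <- function(seq, sA, topology, desc, h2cands) {
  n <- nchar(seq)
  lenA <- nchar(desc$core_seg_A)
  ctx_len <- nchar(desc$cleavage_context)
  cands <- list()
  emit <- function(start, end, L1, L2, L3, lp1, lp2, lp3,
                   loop1, loop2, loop3, cut_local, score, wobbles) {
    cands[[length(cands) + 1L]] <<- list(
      start = start, end = end, topology = topology,
      h1 = L1, h2 = L2, h3 = L3,
      loop1_len = lp1, loop2_len = lp2, loop3_len = lp3,
      loop1_seq = loop1, loop2_seq = loop2, loop3_seq = loop3,
      cut_local = cut_local, score = score, wobbles = wobbles)
  }

  if (topology == "I") {
    ## H1a coreA H2a loop2 H2b coreB H3a loop3 H3b NTH | H1b
    for (hc in h2cands) {
      q <- hc$after_coreB  # start of H3a
      for (L3 in desc$helix3[1]:desc$helix3[2]) {
        if (q + L3 - 1L > n) break
        h3a <- substr(seq, q, q + L3 - 1L)
        for (lp3 in desc$loop[1]:desc$loop[2]) {
          h3b_start <- q + L3 + lp3
          ctx_start <- h3b_start + L3
          if (ctx_start + ctx_len > n) break
          if (!match_compiled(desc$cp_ctx, seq, ctx_start, n)) next
          h3b <- substr(seq, h3b_start, h3b_start + L3 - 1L)
          hs3 <- helix_score(h3a, h3b, desc$max_wobbles)
          if (is.null(hs3)) next
          h1b_start <- ctx_start + ctx_len
          if (!match_compiled(desc$cp_cut, seq, h1b_start, n)) next
          for (L1 in desc$helix1[1]:desc$helix1[2]) {
            h1a_start <- sA - L1
            if (h1a_start < 1L || h1b_start + L1 - 1L > n) next
            h1a <- substr(seq, h1a_start, sA - 1L)
            h1b <- substr(seq, h1b_start, h1b_start + L1 - 1L)
            hs1 <- helix_score(h1a, h1b, desc$max_wobbles)
            if (is.null(hs1)) next
            wtail <- min(desc$tertiary_window, L1)
            pseudo1 <- substr(seq, h1b_start + L1 - wtail,
                              h1b_start + L1 - 1L)
            emit(start = h1a_start, end = h1b_start + L1 - 1L,
                 L1 = L1, L2 = hc$L2, L3 = L3,
                 lp1 = NA_integer_, lp2 = hc$lp2, lp3 = lp3,
                 loop1 = pseudo1, loop2 = hc$loop2,
                 loop3 = substr(seq, q + L3, h3b_start - 1L),
                 cut_local = h1b_start - 1L,
                 score = hs1$score + hc$score2 + hs3$score,
                 wobbles = hs1$wobbles + hc$wob2 + hs3$wobbles)
          }
        }
      }
    }
  } else if (topology == "III") {
    ## H3b NTH | H1b loop1 H1a coreA H2a loop2 H2b coreB H3a
    if (length(h2cands) == 0L) return(cands)
    for (L1 in desc$helix1[1]:desc$helix1[2]) {
      h1a_start <- sA - L1
      if (h1a_start < 1L) next
      h1a <- substr(seq, h1a_start, sA - 1L)
      for (lp1 in desc$loop[1]:desc$loop[2]) {
        h1b_start <- h1a_start - lp1 - L1
        if (h1b_start < 1L) break
        if (!match_compiled(desc$cp_cut, seq, h1b_start, n)) next
        h1b <- substr(seq, h1b_start, h1b_start + L1 - 1L)
        hs1 <- helix_score(h1b, h1a, desc$max_wobbles)
        if (is.null(hs1)) next
        ctx_start <- h1b_start - ctx_len
        if (ctx_start < 1L) next
        if (!match_compiled(desc$cp_ctx, seq, ctx_start, n)) next
        loop1 <- substr(seq, h1b_start + L1, h1a_start - 1L)
        for (L3 in desc$helix3[1]:desc$helix3[2]) {
          h3b_start <- ctx_start - L3
          if (h3b_start < 1L) next
          h3b <- substr(seq, h3b_start, ctx_start - 1L)
          for (hc in h2cands) {
            q <- hc$after_coreB
            if (q + L3 - 1L > n) next
            h3a <- substr(seq, q, q + L3 - 1L)
            hs3 <- helix_score(h3b, h3a, desc$max_wobbles)
            if (is.null(hs3)) next
            emit(start = h3b_start, end = q + L3 - 1L,
                 L1 = L1, L2 = hc$L2, L3 = L3,
                 lp1 = lp1, lp2 = hc$lp2, lp3 = NA_integer_,
                 loop1 = loop1, loop2 = hc$loop2, loop3 = NA_character_,
                 cut_local = h1b_start - 1L,
                 score = hs1$score + hc$score2 + hs3$score,
                 wobbles = hs1$wobbles + hc$wob2 + hs3$wobbles)
          }
        }
      }
    }
  } else if (topology == "II") {
    ## H2b coreB H3a loop3 H3b NTH | H1b loop1 H1a coreA H2a
    lenB <- nchar(desc$core_seg_B)
    for (L1 in desc$helix1[1]:desc$helix1[2]) {
      h1a_start <- sA - L1
      if (h1a_start < 1L) next
      h1a <- substr(seq, h1a_start, sA - 1L)
      for (lp1 in desc$loop[1]:desc$loop[2]) {
        h1b_start <- h1a_start - lp1 - L1
        if (h1b_start < 1L) break
        if (!match_compiled(desc$cp_cut, seq, h1b_start, n)) next
        h1b <- substr(seq, h1b_start, h1b_start + L1 - 1L)
        hs1 <- helix_score(h1b, h1a, desc$max_wobbles)
        if (is.null(hs1)) next
        ctx_start <- h1b_start - ctx_len
        if (ctx_start < 1L) next
        if (!match_compiled(desc$cp_ctx, seq, ctx_start, n)) next
        loop1 <- substr(seq, h1b_start + L1, h1a_start - 1L)
        for (L3 in desc$helix3[1]:desc$helix3[2]) {
          h3b_start <- ctx_start - L3
          if (h3b_start < 1L) next
          h3b <- substr(seq, h3b_start, ctx_start - 1L)
          for (lp3 in desc$loop[1]:desc$loop[2]) {
            h3a_start <- h3b_start - lp3 - L3
            coreB_start <- h3a_start - lenB
            if (coreB_start < 1L) break
            if (!match_compiled(desc$cp_B, seq, coreB_start, n)) next
            h3a <- substr(seq, h3a_start, h3a_start + L3 - 1L)
            hs3 <- helix_score(h3a, h3b, desc$max_wobbles)
            if (is.null(hs3)) next
            loop3 <- substr(seq, h3a_start + L3, h3b_start - 1L)
            for (L2 in desc$helix2[1]:desc$helix2[2]) {
              h2b_start <- coreB_start - L2
              h2a_start <- sA + lenA
              if (h2b_start < 1L || h2a_start + L2 - 1L > n) next
              h2b <- substr(seq, h2b_start, coreB_start - 1L)
              h2a <- substr(seq, h2a_start, h2a_start + L2 - 1L)
              hs2 <- helix_score(h2b, h2a, desc$max_wobbles)
              if (is.null(hs2)) next
              emit(start = h2b_start, end = h2a_start + L2 - 1L,
                   L1 = L1, L2 = L2, L3 = L3,
                   lp1 = lp1, lp2 = NA_integer_, lp3 = lp3,
                   loop1 = loop1, loop2 = NA_character_, loop3 = loop3,
                   cut_local = h1b_start - 1L,
                   score = hs1$score + hs2$score + hs3$score,
                   wobbles = hs1$wobbles + hs2$wobbles + hs3$wobbles)
            }
          }
        }
      }
    }
  }
  cands
}

## scan one oriented sequence; returns candidates with 1-based local
## coordinates (columns start, end) and 0-based between-base cut_local
scan_strand <- function(seq, desc) {
  sw <- seed_word(desc$core_seg_A)
  if (nchar(seq) < nchar(sw$word)) return(list())
  m <- Biostrings::matchPattern(sw$word, Biostrings::DNAString(seq))
  starts <- BiocGenerics::start(m) - sw$offset
  starts <- starts[starts >= 1L]
  cands <- list()
  for (sA in starts) {
    if (!match_compiled(desc$cp_A, seq, sA)) next
    h2cands <- if (any(c("I", "III") %in% desc$topologies))
      enumerate_helix2(seq, sA, desc) else list()
    for (topo in desc$topologies) {
      cc <- assemble_at_seed(seq, sA, topo, desc, h2cands)
      if (length(cc)) cands <- c(cands, cc)
    }
  }
  cands
}

#' Scan a genome for hammerhead ribozyme motifs
#'
#' Seeds on exact occurrences of the least-degenerate core word (under
#' the defaults, `CTGA` of `core_seg_A`), attempts junction assembly
#' within the descriptor's length ranges on both strands and in every
#' requested topology, applies the loop1-loop2 tertiary filter, and
#' resolves overlaps greedily by descending helix-stability score, then
#' leftmost.  Output is sorted by (contig, start, strand).
#'
#' @param genome a `genome` object (see [read_fasta()], [as_genome()]).
#' @param desc an [hhr_descriptor()].
#' @return data frame of hits; coordinates 0-based half-open on the plus
#'   strand; `cleavage_pos` is the plus-strand between-base index of the
#'   self-cleavage site; `cut_local` the same index within the oriented
#'   motif; helix and loop layout columns refer to the oriented motif.
#' @export
scan_genome <- function(genome, desc = hhr_descriptor()) {
  stopifnot(inherits(desc, "hhr_descriptor"))
  if (length(desc$topologies) == 0L) stop("descriptor topology set is empty")
  rows <- list()
  for (contig in names(genome)) {
    plus <- genome[[contig]]
    n <- nchar(plus)
    for (strand in c("+", "-")) {
      oriented <- if (strand == "+") plus else revcomp(plus)
      for (cand in scan_strand(oriented, desc)) {
        if (strand == "+") {
          g_start <- cand$start - 1L
          g_end <- cand$end
          g_cut <- cand$cut_local
        } else {
          g_start <- n - cand$end
          g_end <- n - cand$start + 1L
          g_cut <- n - cand$cut_local
        }
        rows[[length(rows) + 1L]] <- data.frame(
          contig = contig, start = g_start, end = g_end, strand = strand,
          topology = cand$topology, score = cand$score,
          wobbles = cand$wobbles,
          cleavage_pos = g_cut,
          cut_motif = cand$cut_local - (cand$start - 1L),
          h1 = cand$h1, h2 = cand$h2, h3 = cand$h3,
          loop1_len = cand$loop1_len, loop2_len = cand$loop2_len,
          loop3_len = cand$loop3_len,
          loop1_seq = cand$loop1_seq, loop2_seq = cand$loop2_seq,
          loop3_seq = cand$loop3_seq,
          motif_seq = substr(oriented, cand$start, cand$end),
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else empty_hits()
  if (nrow(hits)) {
    tp <- mapply(tertiary_run, hits$loop1_seq, hits$loop2_seq,
                 MoreArgs = list(allow_wobble = desc$tertiary_wobble))
    hits$tertiary_pairs <- as.integer(tp)
    hits$bona_fide <- hits$topology != "II" &
      hits$tertiary_pairs >= desc$min_tertiary_pairs
    hits <- resolve_overlaps(hits)
    ord <- order(hits$contig, hits$start, hits$strand)
    hits <- hits[ord, , drop = FALSE]
    rownames(hits) <- NULL
    hits$id <- sprintf("hhr_%05d", seq_len(nrow(hits)))
  }
  hits
}

empty_hits <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             strand = character(0), topology = character(0),
             score = numeric(0), wobbles = integer(0),
             cleavage_pos = integer(0), cut_motif = integer(0),
             h1 = integer(0), h2 = integer(0), h3 = integer(0),
             loop1_len = integer(0), loop2_len = integer(0),
             loop3_len = integer(0), loop1_seq = character(0),
             loop2_seq = character(0), loop3_seq = character(0),
             motif_seq = character(0), tertiary_pairs = integer(0),
             bona_fide = logical(0), id = character(0),
             stringsAsFactors = FALSE)
}

## greedy non-overlap resolution: keep by descending score, then
## leftmost start, then "+" before "-"; overlap is strand-agnostic
resolve_overlaps <- function(hits) {
  ord <- order(-hits$score, hits$start, hits$strand)
  keep <- logical(nrow(hits))
  taken <- list()
  for (i in ord) {
    ctg <- hits$contig[i]
    iv <- taken[[ctg]]
    if (!is.null(iv) &&
        any(hits$start[i] < iv[, 2] & hits$end[i] > iv[, 1])) next
    keep[i] <- TRUE
    taken[[ctg]] <- rbind(iv, c(hits$start[i], hits$end[i]))
  }
  hits[keep, , drop = FALSE]
}

#' Re-apply the tertiary-interaction ("bona fide") filter
#'
#' Recomputes `tertiary_pairs` (the longest contiguous antiparallel
#' complementary run between loop 1 -- or, for type I, the terminal
#' window of the distal helix-I arm -- and loop 2) and the `bona_fide`
#' flag for a table of hits.  Type II hits report the loop1-loop3 run
#' but are never bona fide: the biological interaction is between the
#' loops of helices I and II, and type II has no loop 2.
#'
#' @param hits data frame from [scan_genome()].
#' @param desc an [hhr_descriptor()].
#' @return `hits` with refreshed `tertiary_pairs` and `bona_fide`.
#' @export
check_tertiary <- function(hits, desc = hhr_descriptor()) {
  if (nrow(hits) == 0L) return(hits)
  other <- ifelse(hits$topology == "II", hits$loop3_seq, hits$loop2_seq)
  tp <- mapply(tertiary_run, hits$loop1_seq, other,
               MoreArgs = list(allow_wobble = desc$tertiary_wobble))
  hits$tertiary_pairs <- as.integer(tp)
  hits$bona_fide <- hits$topology != "II" &
    hits$tertiary_pairs >= desc$min_tertiary_pairs
  hits
}

#' Find degenerate copies of a seed sequence by identity search
#'
#' Reports all genomic windows (both strands) whose global identity to
#' the central `window` nt of the seed is at least `min_identity` under
#' an ungapped-or-lightly-gapped alignment (at most `max_gaps` gapped
#' columns).  Overlapping windows are merged per strand; the seed's own
#' location can be excluded.
#'
#' @param seed_seq seed sequence (length >= `window`).
#' @param genome a `genome` object.
#' @param min_identity minimum fraction of matching positions over the
#'   `window` (default 0.90).
#' @param window comparison length in nt (default 90).
#' @param max_gaps maximum gapped columns tolerated (default 2).
#' @param exclude optional list/data frame row with `contig`, `start`,
#'   `end`: any overlapping copy is dropped (self-exclusion).
#' @return data frame with columns `contig`, `start`, `end`, `strand`
#'   (0-based half-open, plus-strand coordinates).
#' @export
find_degenerate_copies <- function(seed_seq, genome, min_identity = 0.90,
                                   window = 90L, max_gaps = 2L,
                                   exclude = NULL) {
  seed_seq <- chartr("U", "T", toupper(seed_seq))
  if (window > nchar(seed_seq))
    stop("window (", window, ") exceeds seed length (", nchar(seed_seq), ")")
  off <- (nchar(seed_seq) - window) %/% 2L
  query <- substr(seed_seq, off + 1L, off + window)
  max_edits <- floor((1 - min_identity) * window)
  qd <- Biostrings::DNAString(query)
  rows <- list()
  for (contig in names(genome)) {
    plus <- genome[[contig]]
    n <- nchar(plus)
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") plus else revcomp(plus)
      m <- Biostrings::matchPattern(qd, Biostrings::DNAString(subj),
                                    max.mismatch = max_edits,
                                    with.indels = TRUE)
      if (length(m) == 0L) next
      st <- BiocGenerics::start(m); en <- BiocGenerics::end(m)
      for (k in seq_along(m)) {
        cand <- substr(subj, st[k], en[k])
        pa <- Biostrings::pairwiseAlignment(
          qd, Biostrings::DNAString(cand), type = "global",
          substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
            match = 1, mismatch = -1),
          gapOpening = 2, gapExtension = 1)
        ident <- Biostrings::nmatch(pa) / window
        ind <- Biostrings::nindel(pa)
        gaps <- sum(Biostrings::insertion(ind)[, 2]) +
          sum(Biostrings::deletion(ind)[, 2])
        if (ident < min_identity || gaps > max_gaps) next
        if (strand == "+") {
          g <- c(st[k] - 1L, en[k])
        } else {
          g <- c(n - en[k], n - st[k] + 1L)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          contig = contig, start = g[1], end = g[2], strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  out <- do.call(rbind, rows)
  out <- merge_intervals(out)
  if (!is.null(exclude)) {
    drop <- out$contig == exclude$contig &
      out$start < exclude$end & out$end > exclude$start
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

## merge overlapping intervals per contig+strand
merge_intervals <- function(df) {
  pieces <- split(df, paste(df$contig, df$strand))
  merged <- lapply(pieces, function(p) {
    p <- p[order(p$start), , drop = FALSE]
    out <- p[1, , drop = FALSE]
    for (i in seq_len(nrow(p))[-1]) {
      j <- nrow(out)
      if (p$start[i] <= out$end[j]) {
        out$end[j] <- max(out$end[j], p$end[i])
      } else {
        out <- rbind(out, p[i, , drop = FALSE])
      }
    }
    out
  })
  out <- do.call(rbind, merged)
  out[order(out$contig, out$start, out$strand), , drop = FALSE]
}

#' Validate a hit table against its descriptor (soundness check)
#'
#' Re-derives every reported hit from the genome sequence and checks the
#' motif layout: core segments match the degenerate patterns, each
#' helix's arms pair under the allowed pairs within the wobble budget,
#' and the cleavage context sits immediately 5' of the cut.
#'
#' @param hits data frame from [scan_genome()].
#' @param genome the scanned `genome`.
#' @param desc the [hhr_descriptor()] used.
#' @return logical vector, one element per hit.
#' @export
validate_hits <- function(hits, genome, desc = hhr_descriptor()) {
  ok <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    seq <- fetch(genome, h$contig, h$start, h$end, h$strand)
    ok[i] <- validate_layout(seq, h, desc)
  }
  ok
}

validate_layout <- function(seq, h, desc) {
  lenA <- nchar(desc$core_seg_A); lenB <- nchar(desc$core_seg_B)
  ctx <- nchar(desc$cleavage_context)
  L1 <- h$h1; L2 <- h$h2; L3 <- h$h3
  seg <- function(a, len) substr(seq, a, a + len - 1L)
  chk_pair <- function(a, b) !is.null(helix_score(a, b, desc$max_wobbles))
  if (h$topology == "I") {
    p <- 1L
    h1a <- seg(p, L1); p <- p + L1
    if (!matches_at(seq, p, desc$core_seg_A)) return(FALSE); p <- p + lenA
    h2a <- seg(p, L2); p <- p + L2 + h$loop2_len
    h2b <- seg(p, L2); p <- p + L2
    if (!matches_at(seq, p, desc$core_seg_B)) return(FALSE); p <- p + lenB
    h3a <- seg(p, L3); p <- p + L3 + h$loop3_len
    h3b <- seg(p, L3); p <- p + L3
    if (!matches_at(seq, p, desc$cleavage_context)) return(FALSE); p <- p + ctx
    if (!matches_at(seq, p, desc$cut_adjacent)) return(FALSE)
    if (h$cut_motif != p - 1L) return(FALSE)
    h1b <- seg(p, L1)
    chk_pair(h1a, h1b) && chk_pair(h2a, h2b) && chk_pair(h3a, h3b) &&
      p + L1 - 1L == nchar(seq)
  } else if (h$topology == "III") {
    p <- 1L
    h3b <- seg(p, L3); p <- p + L3
    if (!matches_at(seq, p, desc$cleavage_context)) return(FALSE); p <- p + ctx
    if (!matches_at(seq, p, desc$cut_adjacent)) return(FALSE)
    if (h$cut_motif != p - 1L) return(FALSE)
    h1b <- seg(p, L1); p <- p + L1 + h$loop1_len
    h1a <- seg(p, L1); p <- p + L1
    if (!matches_at(seq, p, desc$core_seg_A)) return(FALSE); p <- p + lenA
    h2a <- seg(p, L2); p <- p + L2 + h$loop2_len
    h2b <- seg(p, L2); p <- p + L2
    if (!matches_at(seq, p, desc$core_seg_B)) return(FALSE); p <- p + lenB
    h3a <- seg(p, L3)
    chk_pair(h1b, h1a) && chk_pair(h2a, h2b) && chk_pair(h3b, h3a) &&
      p + L3 - 1L == nchar(seq)
  } else {
    p <- 1L
    h2b <- seg(p, L2); p <- p + L2
    if (!matches_at(seq, p, desc$core_seg_B)) return(FALSE); p <- p + lenB
    h3a <- seg(p, L3); p <- p + L3 + h$loop3_len
    h3b <- seg(p, L3); p <- p + L3
    if (!matches_at(seq, p, desc$cleavage_context)) return(FALSE); p <- p + ctx
    if (!matches_at(seq, p, desc$cut_adjacent)) return(FALSE)
    if (h$cut_motif != p - 1L) return(FALSE)
    h1b <- seg(p, L1); p <- p + L1 + h$loop1_len
    h1a <- seg(p, L1); p <- p + L1
    if (!matches_at(seq, p, desc$core_seg_A)) return(FALSE); p <- p + lenA
    h2a <- seg(p, L2)
    chk_pair(h1b, h1a) && chk_pair(h2b, h2a) && chk_pair(h3a, h3b) &&
      p + L2 - 1L == nchar(seq)
  }
}

#' Convert hits to a GFF3-ready feature frame
#'
#' @param hits data frame from [scan_genome()].
#' @return data frame accepted by [write_gff3()] with feature type
#'   `hammerhead_ribozyme` and attributes topology, bona_fide,
#'   tertiary_pairs, cleavage_pos and score.
#' @export
hits_to_features <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      type = character(0)))
  }
  data.frame(
    contig = hits$contig, start = hits$start, end = hits$end,
    strand = hits$strand, type = "hammerhead_ribozyme",
    score = hits$score, id = hits$id, parent = NA_character_,
    attributes = I(lapply(seq_len(nrow(hits)), function(i) {
      c(topology = hits$topology[i],
        bona_fide = tolower(as.character(hits$bona_fide[i])),
        tertiary_pairs = hits$tertiary_pairs[i],
        cleavage_pos = hits$cleavage_pos[i])
    })),
    stringsAsFactors = FALSE)
}
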