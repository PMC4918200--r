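DEFAULT_PPT  <- "AAGAGGGGGAGA"   # polypurine tract (12 nt)
DEFAULT_LTR5 <- "TGTTAGGCACGCT"  # conserved LTR 5' end (13 nt, starts TG)
DEFAULT_LTR3 <- "GGTTCGGATGTCA"  # conserved LTR 3' end (13 nt, ends CA)
DEFAULT_PBS  <- "TGGTATCAGAGC"   # primer binding site, tRNA-Met 3' complement

#' Consensus strings for the conserved retrozyme junction boxes
#'
#' The 3' box spans the LTR 3' end plus the primer binding site (PBS);
#' the 5' box spans the polypurine tract (PPT) plus the LTR 5' end.
#' These are the two ~25-nt domains retrozymes share with Ty3-gypsy
#' retrotransposons.  The defaults are working placeholders (a canonical
#' tRNA-Met PBS, TG...CA LTR termini, a purine-rich PPT); the synthetic
#' generator embeds whatever is configured here, so annotation and
#' simulation stay self-consistent.
#'
#' @param box3 degenerate string, LTR 3' end + PBS.
#' @param box5 degenerate string, PPT + LTR 5' end.
#' @param max_mismatches maximum mismatches for a box match (default 6).
#' @param search_window search slack around the expected junction in nt
#'   (default 40).
#' @return object of class `box_consensus`.
#' @export
box_consensus <- function(box3 = paste0(DEFAULT_LTR3, DEFAULT_PBS),
                          box5 = paste0(DEFAULT_PPT, DEFAULT_LTR5),
                          max_mismatches = 6L, search_window = 40L) {
  box3 <- chartr("U", "T", toupper(box3))
  box5 <- chartr("U", "T", toupper(box5))
  stopifnot(nchar(box3) >= 15L, nchar(box3) <= 40L,
            nchar(box5) >= 15L, nchar(box5) <= 40L,
            max_mismatches < min(nchar(box3), nchar(box5)))
  structure(list(box3 = box3, box5 = box5,
                 max_mismatches = as.integer(max_mismatches),
                 search_window = as.integer(search_window)),
            class = "box_consensus")
}

#' Annotation tuning parameters
#'
#' @param min_spacing,max_spacing allowed cleavage-to-cleavage distance
#'   between consecutive tandem HHRs (defaults 400 and 1100 nt).
#' @param min_ltr_len minimum homologous-block length to call an LTR
#'   pair (default 200 nt).
#' @param min_ltr_identity minimum LTR-LTR identity (default 0.70).
#' @param ltr_window how far around each cleavage site the banded
#'   alignment looks (default 600 nt).
#' @param band half-width of the alignment band (default 10).
#' @param roll,roll_min rolling-identity guard: window length and
#'   minimum identity used when trimming block ends (defaults 20, 0.6).
#' @param monomer_bounds monomer length bounds for a full element
#'   (default 500-1200 nt, slightly wider than the 600-1000 nt of
#'   natural retrozyme RNAs to tolerate boundary noise).
#' @param tsd_lens TSD lengths tried, in preference order (default 6,5,4).
#' @param flank_window maximum boundary slide when searching the TSD
#'   (default 12 nt).
#' @param solo_context allowed box5..box3 span of a solo LTR
#'   (default 250-450 nt).
#' @param solo_search how far from an unpaired HHR the solo-LTR boxes
#'   are searched (default 450 nt).
#' @return list of class `annotate_params`.
#' @export
annotate_params <- function(min_spacing = 400L, max_spacing = 1100L,
                            min_ltr_len = 200L, min_ltr_identity = 0.70,
                            ltr_window = 600L, band = 10L,
                            roll = 20L, roll_min = 0.6,
                            monomer_bounds = c(500L, 1200L),
                            tsd_lens = c(6L, 5L, 4L),
                            flank_window = 12L,
                            solo_context = c(250L, 450L),
                            solo_search = 450L) {
  structure(as.list(environment()), class = "annotate_params")
}

#' Group tandem HHR hits into candidate runs
#'
#' Maximal same-contig, same-strand, same-topology runs of two or more
#' bona fide hits whose consecutive cleavage-to-cleavage distances fall
#' inside the spacing bounds.  A run of k hits spans k-1 monomer units.
#'
#' @param hits data frame from [scan_genome()].
#' @param min_spacing,max_spacing cleavage-distance bounds in nt.
#' @return list of data frames (subsets of `hits`, sorted by cleavage
#'   position); singleton bona fide hits are returned as attribute
#'   `singles`.
#' @export
pair_hhrs <- function(hits, min_spacing = 400L, max_spacing = 1100L) {
  bf <- hits[hits$bona_fide, , drop = FALSE]
  runs <- list()
  singles <- bf[0, , drop = FALSE]
  if (nrow(bf)) {
    groups <- split(bf, paste(bf$contig, bf$strand, bf$topology))
    for (g in groups) {
      g <- g[order(g$cleavage_pos), , drop = FALSE]
      i <- 1L
      while (i <= nrow(g)) {
        j <- i
        while (j < nrow(g) &&
               (g$cleavage_pos[j + 1L] - g$cleavage_pos[j]) >= min_spacing &&
               (g$cleavage_pos[j + 1L] - g$cleavage_pos[j]) <= max_spacing) {
          j <- j + 1L
        }
        if (j > i) {
          runs[[length(runs) + 1L]] <- g[i:j, , drop = FALSE]
        } else {
          singles <- rbind(singles, g[i, , drop = FALSE])
        }
        i <- j + 1L
      }
    }
  }
  ord <- order(vapply(runs, function(r) r$start[1], numeric(1)))
  runs <- runs[ord]
  attr(runs, "singles") <- singles
  runs
}

## banded global alignment of two equal-anchor windows (diagonal 0),
## returning per-column records of the optimal path
banded_align <- function(s1, s2, band = 10L,
                         match = 1L, mismatch = -1L, gap = -2L) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n1 <- length(a); n2 <- length(b)
  w <- 2L * band + 1L
  NEG <- -1e9
  M <- matrix(NEG, nrow = n1 + 1L, ncol = w)
  P <- matrix(0L, nrow = n1 + 1L, ncol = w)  # 1 diag, 2 up, 3 left
  kof <- function(i, j) j - i + band + 1L
  for (j in 0:min(band, n2)) M[1L, kof(0L, j)] <- gap * j
  for (i in 1:n1) {
    jlo <- max(0L, i - band); jhi <- min(n2, i + band)
    for (j in jlo:jhi) {
      k <- kof(i, j)
      best <- NEG; op <- 0L
      if (j >= 1L && k >= 1L && k <= w) {
        sc <- M[i, k] +
          (if (a[i] == b[j] && a[i] != "N") match else mismatch)
        if (sc > best) { best <- sc; op <- 1L }
      }
      if (k + 1L <= w) {  # up: consume a[i], gap in s2
        sc <- M[i, k + 1L] + gap
        if (sc > best) { best <- sc; op <- 2L }
      }
      if (k - 1L >= 1L) {  # left: consume b[j], gap in s1
        sc <- M[i + 1L, k - 1L] + gap
        if (sc > best) { best <- sc; op <- 3L }
      }
      M[i + 1L, k] <- best
      P[i + 1L, k] <- op
    }
  }
  ## traceback from (n1, n2); requires |n1 - n2| <= band
  i <- n1; j <- n2
  ops <- integer(0); iis <- integer(0); jjs <- integer(0)
  while (i > 0L || j > 0L) {
    k <- kof(i, j)
    op <- if (i == 0L) 3L else if (j == 0L) 2L else P[i + 1L, k]
    if (op == 0L) op <- if (i > 0L) 2L else 3L
    if (op == 1L) {
      ops <- c(op, ops); iis <- c(i, iis); jjs <- c(j, jjs)
      i <- i - 1L; j <- j - 1L
    } else if (op == 2L) {
      ops <- c(op, ops); iis <- c(i, iis); jjs <- c(j, jjs)
      i <- i - 1L
    } else {
      ops <- c(3L, ops); iis <- c(i, iis); jjs <- c(j, jjs)
      j <- j - 1L
    }
  }
  m <- ifelse(ops == 1L & a[pmax(iis, 1L)] == b[pmax(jjs, 1L)] &
                a[pmax(iis, 1L)] != "N", 1L, 0L)
  colscore <- ifelse(ops == 1L, ifelse(m == 1L, match, mismatch), gap)
  list(i = iis, j = jjs, op = ops, m = m, colscore = colscore)
}

#' Delimit the direct-repeat LTR pair around two tandem cleavage sites
#'
#' Anchors the two motif regions offset-aligned at their cleavage
#' positions, aligns flanking windows with a banded alignment (band
#' +/-10; match +1, mismatch -1, gap -2), and reports the
#' maximum-scoring aligned block containing the anchor, with its ends
#' guarded by a rolling 20-nt identity >= 0.6 trim.  Returns `NULL`
#' (absence is a value) when the block is shorter than `min_ltr_len` or
#' its identity is below `min_ltr_identity`.
#'
#' @param genome a `genome` object.
#' @param contig contig id.
#' @param cut1,cut2 the two cleavage positions (plus-strand between-base
#'   indices, `cut1 < cut2`).
#' @param params an [annotate_params()] list.
#' @return list with `ltr1`, `ltr2` (0-based half-open plus-strand
#'   intervals), `identity`, `aln_len`; or `NULL`.
#' @export
delimit_ltrs <- function(genome, contig, cut1, cut2,
                         params = annotate_params()) {
  stopifnot(cut1 < cut2)
  len <- nchar(genome[[contig]])
  WL <- min(params$ltr_window, cut1)
  WR <- min(params$ltr_window, len - cut2)
  if (WL + WR < params$min_ltr_len) return(NULL)
  w1s <- cut1 - WL; w2s <- cut2 - WL
  s1 <- fetch(genome, contig, w1s, cut1 + WR)
  s2 <- fetch(genome, contig, w2s, cut2 + WR)
  al <- banded_align(s1, s2, band = params$band)
  C <- length(al$m)
  if (C < params$roll) return(NULL)
  anchor <- which(al$i == WL + 1L)[1]
  if (is.na(anchor)) anchor <- which.min(abs(al$i - (WL + 1L)))
  ## maximum-scoring block containing the anchor column; a small score
  ## slack trims chance net-positive extensions past the repeat boundary
  slack <- 2L
  pre <- cumsum(al$colscore)
  left_pre <- c(0, pre)[seq_len(anchor)]     # prefix values before col l
  lmin <- min(left_pre)
  lstar <- max(which(left_pre <= lmin + slack))
  right_pre <- pre[anchor:C]
  rmax <- max(right_pre)
  rstar <- (anchor:C)[which(right_pre >= rmax - slack)[1]]
  l <- lstar; r <- rstar
  if (l > r) return(NULL)
  ## rolling-identity guard: shrink ends while the terminal window of
  ## `roll` columns falls below roll_min identity
  roll <- params$roll
  repeat {
    if (r - l + 1L < roll) break
    if (mean(al$m[l:(l + roll - 1L)]) < params$roll_min) { l <- l + 1L; next }
    if (mean(al$m[(r - roll + 1L):r]) < params$roll_min) { r <- r - 1L; next }
    break
  }
  ## trim terminal non-match columns
  while (l <= r && al$m[l] == 0L) l <- l + 1L
  while (r >= l && al$m[r] == 0L) r <- r - 1L
  if (l > r) return(NULL)
  block <- l:r
  aln_len <- length(block)
  identity <- mean(al$m[block])
  if (aln_len < params$min_ltr_len || identity < params$min_ltr_identity) {
    return(NULL)
  }
  ii <- al$i[block][al$op[block] != 3L]
  jj <- al$j[block][al$op[block] != 2L]
  if (length(ii) == 0L || length(jj) == 0L) return(NULL)
  list(ltr1 = c(w1s + min(ii) - 1L, w1s + max(ii)),
       ltr2 = c(w2s + min(jj) - 1L, w2s + max(jj)),
       identity = identity, aln_len = aln_len)
}

#' Find the target-site duplication flanking an element
#'
#' Looks for an exact duplication whose left copy ends at the element
#' start and whose right copy begins at the element end, allowing the
#' boundaries to slide by at most `flank_window` nt (smallest slide
#' first, then longest duplication, then leftmost).  A 4-nt TSD is
#' additionally checked against the WWRR consensus (W = A/T, R = A/G) on
#' the element's strand.
#'
#' @param genome a `genome` object.
#' @param contig contig id.
#' @param start,end element span (0-based half-open, TSD-exclusive).
#' @param strand element strand (used only for the WWRR check).
#' @param lens duplication lengths tried, longest preferred (default 6,5,4).
#' @param flank_window maximum boundary slide (default 12).
#' @return list with `left`, `right` (the two copies), `len`, `wwrr`,
#'   `start`, `end` (the slid boundaries); or `NULL`.
#' @export
find_tsd <- function(genome, contig, start, end, strand = "+",
                     lens = c(6L, 5L, 4L), flank_window = 12L) {
  seqlen <- nchar(genome[[contig]])
  lens <- sort(as.integer(lens), decreasing = TRUE)
  for (d in 0:flank_window) {
    combos <- expand.grid(sL = -d:d, sR = -d:d)
    combos <- combos[pmax(abs(combos$sL), abs(combos$sR)) == d, , drop = FALSE]
    combos <- combos[order(abs(combos$sL) + abs(combos$sR),
                           combos$sL, combos$sR), , drop = FALSE]
    for (k in lens) {
      for (r in seq_len(nrow(combos))) {
        sL <- combos$sL[r]; sR <- combos$sR[r]
        a <- start + sL; b <- end + sR
        if (a - k < 0L || b + k > seqlen || a >= b) next
        left <- fetch(genome, contig, a - k, a)
        right <- fetch(genome, contig, b, b + k)
        if (left == right && !grepl("N", left)) {
          tsd_oriented <- if (strand == "-") revcomp(left) else left
          wwrr <- if (k == 4L) {
            ch <- strsplit(tsd_oriented, "")[[1]]
            all(ch[1:2] %in% c("A", "T")) && all(ch[3:4] %in% c("A", "G"))
          } else NA
          return(list(left = left, right = right, len = k, wwrr = wwrr,
                      start = a, end = b))
        }
      }
    }
  }
  NULL
}

## best (fewest-mismatch) degenerate-box match with start in
## [lo, hi] (1-based, oriented sequence); ties broken leftmost
best_box_match <- function(seq, box, lo, hi, max_mm) {
  L <- nchar(box)
  best <- NULL
  for (p in max(1L, lo):min(hi, nchar(seq) - L + 1L)) {
    mm <- iupac_mismatches(box, substr(seq, p, p + L - 1L))
    if (mm <= max_mm && (is.null(best) || mm < best$mm)) {
      best <- list(pos = p, mm = mm)
      if (mm == 0L) break
    }
  }
  best
}

#' Longest polypurine run in a window
#'
#' Longest run of purines (A/G) with at most one pyrimidine, of length
#' at least `min_len`.
#'
#' @param seq window sequence (oriented 5'->3').
#' @param min_len minimum run length (default 8).
#' @param max_pyrimidines tolerated interruptions (default 1).
#' @return list with `start`, `end` (1-based inclusive within `seq`) and
#'   `len`; or `NULL`.
#' @export
find_ppt_run <- function(seq, min_len = 8L, max_pyrimidines = 1L) {
  ch <- strsplit(seq, "")[[1]]
  pur <- ch %in% c("A", "G")
  n <- length(ch)
  best <- NULL
  for (i in seq_len(n)) {
    if (!pur[i]) next  # runs start on a purine
    bad <- 0L; j <- i - 1L
    while (j < n) {
      if (!pur[j + 1L]) {
        if (bad + 1L > max_pyrimidines) break
        bad <- bad + 1L
      }
      j <- j + 1L
    }
    while (j >= i && !pur[j]) j <- j - 1L  # never end on a pyrimidine
    if (j >= i && (is.null(best) || (j - i + 1L) > best$len)) {
      best <- list(start = i, end = j, len = j - i + 1L)
    }
  }
  if (!is.null(best) && best$len >= min_len) best else NULL
}

## map an oriented interval [a,b) (0-based within the contig read on
## `strand`) back to plus-strand coordinates
oriented_to_plus <- function(a, b, strand, contig_len) {
  if (strand == "+") c(a, b) else c(contig_len - b, contig_len - a)
}

## oriented coordinate of a plus-strand between-base position
plus_to_oriented_pos <- function(p, strand, contig_len) {
  if (strand == "+") p else contig_len - p
}

#' Locate the conserved junction boxes of an element
#'
#' The 3' box (LTR 3' end + PBS) is searched around the 3' junction of
#' the element's 5' LTR; the 5' box (PPT + LTR 5' end) around the 5'
#' junction of the 3' LTR.  Positions are matched on the element's
#' strand with at most `max_mismatches` mismatches; additionally the
#' longest purine run within 40 nt upstream of the 3' LTR is reported
#' as a standalone PPT detection.
#'
#' @param genome a `genome` object.
#' @param contig contig id.
#' @param ltr1,ltr2 plus-strand 0-based half-open intervals of the two
#'   LTR copies (`ltr1` upstream on the plus strand).
#' @param strand element strand.
#' @param boxes a [box_consensus()].
#' @return list with `pbs` and `ppt` entries (each `NULL` or a list with
#'   plus-strand `start`, `end`, `mismatches`), plus `ppt_run`.
#' @export
find_boxes <- function(genome, contig, ltr1, ltr2, strand = "+",
                       boxes = box_consensus()) {
  n <- nchar(genome[[contig]])
  oriented <- if (strand == "+") genome[[contig]] else revcomp(genome[[contig]])
  if (strand == "+") {
    five_ltr <- ltr1; three_ltr <- ltr2
    j3 <- five_ltr[2]; j5 <- three_ltr[1]
  } else {
    five_ltr <- ltr2; three_ltr <- ltr1
    j3 <- n - five_ltr[1]; j5 <- n - three_ltr[2]
  }
  sw <- boxes$search_window
  out <- list(pbs = NULL, ppt = NULL, ppt_run = NULL)
  if (nzchar(boxes$box3)) {
    L3 <- nchar(boxes$box3)
    m <- best_box_match(oriented, boxes$box3, j3 - L3 - sw + 1L, j3 + sw + 1L,
                        boxes$max_mismatches)
    if (!is.null(m)) {
      iv <- oriented_to_plus(m$pos - 1L, m$pos - 1L + L3, strand, n)
      out$pbs <- list(start = iv[1], end = iv[2], mismatches = m$mm)
    }
  } else warning("box3 consensus unset; skipping 3' box search")
  if (nzchar(boxes$box5)) {
    L5 <- nchar(boxes$box5)
    m <- best_box_match(oriented, boxes$box5, j5 - L5 - sw + 1L, j5 + sw + 1L,
                        boxes$max_mismatches)
    if (!is.null(m)) {
      iv <- oriented_to_plus(m$pos - 1L, m$pos - 1L + L5, strand, n)
      out$ppt <- list(start = iv[1], end = iv[2], mismatches = m$mm)
    }
  } else warning("box5 consensus unset; skipping 5' box search")
  wlo <- max(0L, j5 - 40L)
  if (j5 > wlo) {
    run <- find_ppt_run(substr(oriented, wlo + 1L, j5))
    if (!is.null(run)) {
      iv <- oriented_to_plus(wlo + run$start - 1L, wlo + run$end, strand, n)
      out$ppt_run <- list(start = iv[1], end = iv[2], len = run$len)
    }
  }
  out
}

empty_elements <- function() {
  data.frame(id = character(0), contig = character(0), start = integer(0),
             end = integer(0), strand = character(0), class = character(0),
             n_units = integer(0), topology = character(0),
             ltr1_start = integer(0), ltr1_end = integer(0),
             ltr2_start = integer(0), ltr2_end = integer(0),
             ltr_identity = numeric(0), ltr_aln_len = integer(0),
             cleavage1 = integer(0), cleavage2 = integer(0),
             monomer_len = integer(0),
             tsd = character(0), tsd_len = integer(0), tsd_wwrr = logical(0),
             pbs_start = integer(0), pbs_end = integer(0),
             pbs_mismatches = integer(0),
             ppt_start = integer(0), ppt_end = integer(0),
             ppt_mismatches = integer(0),
             hhr_ids = character(0), stringsAsFactors = FALSE)
}

#' Assemble HHR hits into annotated retrozyme elements
#'
#' Runs the full annotation cascade: tandem pairing of bona fide hits,
#' LTR delimitation, TSD search, junction-box matching, classification
#' (`full_retrozyme`, `multimeric_retrozyme`, `solo_LTR`, `orphan_HHR`)
#' and monomer bookkeeping.  Every bona fide hit is assigned to exactly
#' one class.
#'
#' @param genome a `genome` object.
#' @param hits data frame from [scan_genome()].
#' @param boxes a [box_consensus()].
#' @param params an [annotate_params()].
#' @return data frame of elements (one row each; solo LTRs and orphan
#'   HHRs included), with 0-based half-open plus-strand coordinates.
#' @export
annotate_retrozymes <- function(genome, hits, boxes = box_consensus(),
                                params = annotate_params()) {
  runs <- pair_hhrs(hits, params$min_spacing, params$max_spacing)
  singles <- attr(runs, "singles")
  rows <- list()
  demoted <- hits[0, , drop = FALSE]

  for (run in runs) {
    k <- nrow(run)
    cuts <- sort(run$cleavage_pos)
    contig <- run$contig[1]; strand <- run$strand[1]
    del <- delimit_ltrs(genome, contig, cuts[1], cuts[k], params)
    monomers <- diff(cuts)
    if (k == 2L) {
      ok <- !is.null(del) &&
        monomers[1] >= params$monomer_bounds[1] &&
        monomers[1] <= params$monomer_bounds[2]
      if (!ok) { demoted <- rbind(demoted, run); next }
      cls <- "full_retrozyme"; n_units <- 1L
    } else {
      cls <- "multimeric_retrozyme"; n_units <- k - 1L
    }
    if (!is.null(del)) {
      e_start <- del$ltr1[1]; e_end <- del$ltr2[2]
      tsd <- find_tsd(genome, contig, e_start, e_end, strand,
                      params$tsd_lens, params$flank_window)
      bx <- find_boxes(genome, contig, del$ltr1, del$ltr2, strand, boxes)
    } else {
      e_start <- min(run$start); e_end <- max(run$end)
      tsd <- NULL; bx <- list(pbs = NULL, ppt = NULL)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      id = NA_character_, contig = contig,
      start = if (!is.null(tsd)) tsd$start else e_start,
      end = if (!is.null(tsd)) tsd$end else e_end,
      strand = strand, class = cls, n_units = n_units,
      topology = run$topology[1],
      ltr1_start = if (!is.null(del)) del$ltr1[1] else NA_integer_,
      ltr1_end = if (!is.null(del)) del$ltr1[2] else NA_integer_,
      ltr2_start = if (!is.null(del)) del$ltr2[1] else NA_integer_,
      ltr2_end = if (!is.null(del)) del$ltr2[2] else NA_integer_,
      ltr_identity = if (!is.null(del)) del$identity else NA_real_,
      ltr_aln_len = if (!is.null(del)) del$aln_len else NA_integer_,
      cleavage1 = cuts[1], cleavage2 = cuts[k],
      monomer_len = if (k == 2L) monomers[1] else cuts[k] - cuts[1],
      tsd = if (!is.null(tsd)) tsd$left else NA_character_,
      tsd_len = if (!is.null(tsd)) tsd$len else NA_integer_,
      tsd_wwrr = if (!is.null(tsd) && !is.na(tsd$wwrr)) tsd$wwrr else NA,
      pbs_start = if (!is.null(bx$pbs)) bx$pbs$start else NA_integer_,
      pbs_end = if (!is.null(bx$pbs)) bx$pbs$end else NA_integer_,
      pbs_mismatches = if (!is.null(bx$pbs)) bx$pbs$mismatches else NA_integer_,
      ppt_start = if (!is.null(bx$ppt)) bx$ppt$start else NA_integer_,
      ppt_end = if (!is.null(bx$ppt)) bx$ppt$end else NA_integer_,
      ppt_mismatches = if (!is.null(bx$ppt)) bx$ppt$mismatches else NA_integer_,
      hhr_ids = paste(run$id, collapse = ","),
      stringsAsFactors = FALSE)
  }

  singles <- rbind(singles, demoted)
  for (i in seq_len(nrow(singles))) {
    h <- singles[i, ]
    n <- nchar(genome[[h$contig]])
    oriented <- if (h$strand == "+") genome[[h$contig]] else
      revcomp(genome[[h$contig]])
    if (h$strand == "+") {
      o_start <- h$start; o_end <- h$end
    } else {
      o_start <- n - h$end; o_end <- n - h$start
    }
    L5 <- nchar(boxes$box5); L3 <- nchar(boxes$box3)
    m5 <- best_box_match(oriented, boxes$box5,
                         o_start - params$solo_search + 1L, o_start + 1L,
                         boxes$max_mismatches)
    m3 <- best_box_match(oriented, boxes$box3, o_end + 1L - L3,
                         o_end + params$solo_search - L3 + 1L,
                         boxes$max_mismatches)
    is_solo <- FALSE
    if (!is.null(m5) && !is.null(m3)) {
      span <- (m3$pos + L3 - 1L) - (m5$pos - 1L)
      is_solo <- span >= params$solo_context[1] &&
        span <= params$solo_context[2]
    }
    if (is_solo) {
      iv <- oriented_to_plus(m5$pos - 1L, m3$pos + L3 - 1L, h$strand, n)
      tsd <- find_tsd(genome, h$contig, iv[1], iv[2], h$strand,
                      params$tsd_lens, params$flank_window)
      rows[[length(rows) + 1L]] <- element_row(
        contig = h$contig, start = iv[1], end = iv[2], strand = h$strand,
        class = "solo_LTR", topology = h$topology, hhr_ids = h$id,
        cleavage1 = h$cleavage_pos, tsd = tsd,
        pbs_mm = m3$mm, ppt_mm = m5$mm)
    } else {
      rows[[length(rows) + 1L]] <- element_row(
        contig = h$contig, start = h$start, end = h$end, strand = h$strand,
        class = "orphan_HHR", topology = h$topology, hhr_ids = h$id,
        cleavage1 = h$cleavage_pos)
    }
  }

  if (length(rows) == 0L) return(empty_elements())
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out$id <- sprintf("rz_%04d", seq_len(nrow(out)))
  out
}

## uniform element-row builder for solo/orphan rows
element_row <- function(contig, start, end, strand, class, topology,
                        hhr_ids, cleavage1 = NA_integer_, tsd = NULL,
                        pbs_mm = NA_integer_, ppt_mm = NA_integer_) {
  data.frame(
    id = NA_character_, contig = contig,
    start = if (!is.null(tsd)) tsd$start else start,
    end = if (!is.null(tsd)) tsd$end else end,
    strand = strand, class = class, n_units = 0L, topology = topology,
    ltr1_start = NA_integer_, ltr1_end = NA_integer_,
    ltr2_start = NA_integer_, ltr2_end = NA_integer_,
    ltr_identity = NA_real_, ltr_aln_len = NA_integer_,
    cleavage1 = cleavage1, cleavage2 = NA_integer_,
    monomer_len = NA_integer_,
    tsd = if (!is.null(tsd)) tsd$left else NA_character_,
    tsd_len = if (!is.null(tsd)) tsd$len else NA_integer_,
    tsd_wwrr = if (!is.null(tsd) && !is.na(tsd$wwrr)) tsd$wwrr else NA,
    pbs_start = NA_integer_, pbs_end = NA_integer_, pbs_mismatches = pbs_mm,
    ppt_start = NA_integer_, ppt_end = NA_integer_, ppt_mismatches = ppt_mm,
    hhr_ids = hhr_ids, stringsAsFactors = FALSE)
}

#' Extract the cleavage-to-cleavage monomer RNA of an element
#'
#' The monomer is the plus-strand slice `[cleavage1, cleavage2)`,
#' reverse-complemented for minus-strand elements, returned in the RNA
#' alphabet.  Its length always equals `cleavage2 - cleavage1`.
#'
#' @param genome a `genome` object.
#' @param element one row of the [annotate_retrozymes()] table.
#' @return list with `seq` (RNA) and `length`.
#' @export
extract_monomer <- function(genome, element) {
  c1 <- element$cleavage1; c2 <- element$cleavage2
  if (is.na(c1) || is.na(c2)) stop("element has no cleavage pair")
  if (c1 >= c2) stop("inverted cleavage positions: ", c1, " >= ", c2)
  s <- fetch(genome, element$contig, c1, c2, element$strand)
  list(seq = dna_to_rna(s), length = c2 - c1)
}

#' Extract all monomers of full/multimeric elements
#'
#' Full elements yield one monomer from their recorded cleavage pair.
#' For multimeric elements every consecutive cleavage-to-cleavage unit
#' is a monomer; the per-unit cuts are recovered from the hit table
#' when it is supplied, otherwise the first-to-last span is returned
#' as a single record.
#'
#' @param genome a `genome` object.
#' @param elements the [annotate_retrozymes()] table.
#' @param hits optional hit table, used to split multimeric elements
#'   into their per-unit monomers.
#' @return named character vector of RNA monomers; names carry element
#'   id and class.
#' @export
extract_monomers <- function(genome, elements, hits = NULL) {
  out <- character(0)
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    if (!e$class %in% c("full_retrozyme", "multimeric_retrozyme")) next
    if (e$class == "multimeric_retrozyme" && !is.null(hits)) {
      ids <- strsplit(e$hhr_ids, ",")[[1]]
      cuts <- sort(hits$cleavage_pos[match(ids, hits$id)])
      for (u in seq_len(length(cuts) - 1L)) {
        s <- fetch(genome, e$contig, cuts[u], cuts[u + 1L], e$strand)
        out[paste0(e$id, "_unit", u, "|", e$class)] <- dna_to_rna(s)
      }
    } else {
      mono <- extract_monomer(genome, e)
      out[paste0(e$id, "|", e$class)] <- mono$seq
    }
  }
  out
}

#' Per-contig census of hits and elements
#'
#' @param hits hit table.
#' @param elements element table.
#' @return data frame, one row per contig.
#' @export
census_report <- function(hits, elements) {
  contigs <- sort(unique(c(hits$contig, elements$contig)))
  do.call(rbind, lapply(contigs, function(ct) {
    h <- hits[hits$contig == ct, , drop = FALSE]
    e <- elements[elements$contig == ct, , drop = FALSE]
    ml <- e$monomer_len[e$class == "full_retrozyme"]
    data.frame(contig = ct, n_hhrs = nrow(h),
               n_bona_fide = sum(h$bona_fide),
               n_full = sum(e$class == "full_retrozyme"),
               n_solo = sum(e$class == "solo_LTR"),
               n_multimer = sum(e$class == "multimeric_retrozyme"),
               n_orphan = sum(e$class == "orphan_HHR"),
               monomer_min = if (length(ml)) min(ml) else NA_integer_,
               monomer_median = if (length(ml)) median(ml) else NA_real_,
               monomer_max = if (length(ml)) max(ml) else NA_integer_,
               stringsAsFactors = FALSE)
  }))
}

#' Convert an element table to GFF3-ready features
#'
#' Emits one `retrozyme` parent feature per element with `LTR`, `TSD`,
#' `PBS` and `PPT` children linked by `Parent`.
#'
#' @param elements the [annotate_retrozymes()] table.
#' @return data frame accepted by [write_gff3()].
#' @export
elements_to_features <- function(elements) {
  rows <- list()
  add <- function(contig, start, end, strand, type, id, parent, attrs) {
    rows[[length(rows) + 1L]] <<- data.frame(
      contig = contig, start = start, end = end, strand = strand,
      type = type, score = NA_real_, id = id, parent = parent,
      attributes = I(list(attrs)), stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    add(e$contig, e$start, e$end, e$strand, "retrozyme", e$id,
        NA_character_,
        c(class = e$class, n_units = e$n_units, topology = e$topology,
          monomer_len = e$monomer_len, ltr_identity = e$ltr_identity,
          hhr_ids = e$hhr_ids))
    if (!is.na(e$ltr1_start)) {
      add(e$contig, e$ltr1_start, e$ltr1_end, e$strand, "LTR",
          paste0(e$id, "_LTR1"), e$id, c(which = "1"))
      add(e$contig, e$ltr2_start, e$ltr2_end, e$strand, "LTR",
          paste0(e$id, "_LTR2"), e$id, c(which = "2"))
    }
    if (!is.na(e$tsd_len)) {
      add(e$contig, e$start - e$tsd_len, e$start, e$strand, "TSD",
          paste0(e$id, "_TSD1"), e$id, c(seq = e$tsd))
      add(e$contig, e$end, e$end + e$tsd_len, e$strand, "TSD",
          paste0(e$id, "_TSD2"), e$id, c(seq = e$tsd))
    }
    if (!is.na(e$pbs_start)) {
      add(e$contig, e$pbs_start, e$pbs_end, e$strand, "PBS",
          paste0(e$id, "_PBS"), e$id, c(mismatches = e$pbs_mismatches))
    }
    if (!is.na(e$ppt_start)) {
      add(e$contig, e$ppt_start, e$ppt_end, e$strand, "PPT",
          paste0(e$id, "_PPT"), e$id, c(mismatches = e$ppt_mismatches))
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      type = character(0)))
  }
  do.call(rbind, rows)
}
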