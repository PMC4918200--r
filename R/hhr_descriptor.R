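IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

#' Parametric descriptor of the hammerhead ribozyme motif
#'
#' The hammerhead is modelled as a cycle
#' `[helix I]-core_seg_A-[helix II+loop2]-core_seg_B-[helix III+loop3]-
#' cleavage_context | cut-[back to helix I]`; a genomic motif linearizes
#' the cycle by opening exactly one helix, and the opened helix names the
#' topology (type I, II or III).  The catalytic core comprises the two
#' core segments, the cleavage context immediately 5' of the scissile
#' bond, and one invariant residue immediately 3' of it (the first base
#' of helix I); under the defaults that is 15 constrained positions.
#'
#' @param core_seg_A degenerate core segment between helix I and helix II
#'   (DNA alphabet; default `"CTGANGA"`, i.e. CUGANGA in RNA).
#' @param core_seg_B degenerate core segment between helix II and helix
#'   III (default `"GAAA"`).
#' @param cleavage_context degenerate triplet immediately 5' of the cut
#'   (default `"NTH"`, i.e. NUH).
#' @param cut_adjacent invariant residue immediately 3' of the cut
#'   (default `"C"`; it forms the first, C:G, pair of helix I).
#' @param helix1,helix2,helix3 length-2 integer vectors giving the
#'   allowed base-pair range of each helix (defaults 3-7, 3-6, 2-5).
#' @param loop length-2 integer vector, allowed loop lengths for closed
#'   helices (default 3-20).
#' @param max_wobbles maximum number of G:T (G.U) wobble pairs allowed
#'   per helix (default 1); all other pairs must be Watson-Crick.
#' @param topologies subset of `c("I","II","III")` to scan (default
#'   types I and III, the forms described in plants).
#' @param min_tertiary_pairs minimum length of the loop1-loop2
#'   complementary run for a hit to be flagged bona fide (default 2).
#' @param tertiary_window for type I motifs (open helix I has no loop 1),
#'   the number of terminal nucleotides of the distal helix-I arm used in
#'   place of loop 1 (default 6).
#' @param tertiary_wobble whether G:T counts as complementary in the
#'   loop-loop run (default `FALSE`; the kissing interaction is
#'   Watson-Crick in known plant hammerheads).
#' @return object of class `hhr_descriptor`.
#' @examples
#' d <- hhr_descriptor()
#' core_positions(d)  # 15
#' @export
hhr_descriptor <- function(core_seg_A = "CTGANGA",
                           core_seg_B = "GAAA",
                           cleavage_context = "NTH",
                           cut_adjacent = "C",
                           helix1 = c(3L, 7L),
                           helix2 = c(3L, 6L),
                           helix3 = c(2L, 5L),
                           loop = c(3L, 20L),
                           max_wobbles = 1L,
                           topologies = c("I", "III"),
                           min_tertiary_pairs = 2L,
                           tertiary_window = 6L,
                           tertiary_wobble = FALSE) {
  norm <- function(x) chartr("U", "T", toupper(x))
  core_seg_A <- norm(core_seg_A); core_seg_B <- norm(core_seg_B)
  cleavage_context <- norm(cleavage_context)
  cut_adjacent <- norm(cut_adjacent)
  for (s in c(core_seg_A, core_seg_B, cleavage_context, cut_adjacent)) {
    if (grepl(sprintf("[^%s]", paste(names(IUPAC_SETS), collapse = "")), s))
      stop("core segments must be IUPAC codes, got: ", s)
  }
  stopifnot(length(helix1) == 2L, length(helix2) == 2L, length(helix3) == 2L,
            helix1[1] >= 1L, helix2[1] >= 1L, helix3[1] >= 1L,
            helix1[1] <= helix1[2], helix2[1] <= helix2[2],
            helix3[1] <= helix3[2],
            length(loop) == 2L, loop[1] >= 3L, loop[1] <= loop[2])
  if (!all(topologies %in% c("I", "II", "III")))
    stop("topologies must be a subset of I, II, III")
  structure(list(
    core_seg_A = core_seg_A, core_seg_B = core_seg_B,
    cleavage_context = cleavage_context, cut_adjacent = cut_adjacent,
    cp_A = compile_pattern(core_seg_A), cp_B = compile_pattern(core_seg_B),
    cp_ctx = compile_pattern(cleavage_context),
    cp_cut = compile_pattern(cut_adjacent),
    helix1 = as.integer(helix1), helix2 = as.integer(helix2),
    helix3 = as.integer(helix3), loop = as.integer(loop),
    max_wobbles = as.integer(max_wobbles),
    topologies = topologies,
    min_tertiary_pairs = as.integer(min_tertiary_pairs),
    tertiary_window = as.integer(tertiary_window),
    tertiary_wobble = isTRUE(tertiary_wobble)
  ), class = "hhr_descriptor")
}

#' Number of constrained catalytic-core positions of a descriptor
#'
#' @param desc an [hhr_descriptor()].
#' @return integer count (15 under the defaults).
#' @export
core_positions <- function(desc) {
  stopifnot(inherits(desc, "hhr_descriptor"))
  nchar(desc$core_seg_A) + nchar(desc$core_seg_B) +
    nchar(desc$cleavage_context) + nchar(desc$cut_adjacent)
}

#' @export
print.hhr_descriptor <- function(x, ...) {
  cat("HHR descriptor\n")
  cat("  core:", x$core_seg_A, "/", x$core_seg_B,
      "/ context", x$cleavage_context, "| cut |", x$cut_adjacent,
      sprintf(" (%d constrained positions)\n", core_positions(x)))
  cat(sprintf("  helices I %d-%d, II %d-%d, III %d-%d bp; loops %d-%d nt; <=%d wobble(s)/helix\n",
              x$helix1[1], x$helix1[2], x$helix2[1], x$helix2[2],
              x$helix3[1], x$helix3[2], x$loop[1], x$loop[2], x$max_wobbles))
  cat("  topologies:", paste(x$topologies, collapse = ", "),
      "; bona fide: loop1-loop2 run >=", x$min_tertiary_pairs, "\n")
  invisible(x)
}

## precompiled degenerate pattern for the scanner's hot path: concrete
## patterns reduce to substring equality, degenerate ones to per-column
## set membership
compile_pattern <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  list(pattern = pattern, len = nchar(pattern),
       concrete = all(chars %in% c("A", "C", "G", "T")),
       sets = lapply(chars, function(ch)
         setdiff(IUPAC_SETS[[ch]], "N")))
}

match_compiled <- function(cp, seq, pos, n = nchar(seq)) {
  if (pos < 1L || pos + cp$len - 1L > n) return(FALSE)
  s <- substr(seq, pos, pos + cp$len - 1L)
  if (cp$concrete) return(s == cp$pattern)
  ch <- strsplit(s, "")[[1]]
  for (i in seq_len(cp$len)) {
    if (!(ch[i] %in% cp$sets[[i]])) return(FALSE)
  }
  TRUE
}

## does subject character (concrete base or N) satisfy a degenerate
## pattern character?  subject N never matches, by convention.
iupac_char_ok <- function(pat_char, sub_char) {
  sub_char %in% IUPAC_SETS[[pat_char]] && sub_char != "N"
}

## match a degenerate pattern at 1-based position `pos` of `seq`
matches_at <- function(seq, pos, pattern) {
  k <- nchar(pattern)
  if (pos < 1L || pos + k - 1L > nchar(seq)) return(FALSE)
  sub <- strsplit(substr(seq, pos, pos + k - 1L), "")[[1]]
  pat <- strsplit(pattern, "")[[1]]
  for (i in seq_len(k)) {
    if (!iupac_char_ok(pat[i], sub[i])) return(FALSE)
  }
  TRUE
}

## count mismatches of degenerate `pattern` against `subject` (equal
## lengths); subject N always mismatches
iupac_mismatches <- function(pattern, subject) {
  pat <- strsplit(pattern, "")[[1]]
  sub <- strsplit(subject, "")[[1]]
  stopifnot(length(pat) == length(sub))
  sum(!mapply(iupac_char_ok, pat, sub))
}

PAIR_WEIGHTS <- c(AT = 2, TA = 2, GC = 3, CG = 3, GT = 1, TG = 1)

## score an antiparallel helix: a[i] pairs b[L+1-i]; returns NULL if any
## position fails to pair or the wobble budget is exceeded
helix_score <- function(a, b, max_wobbles) {
  ac <- strsplit(a, "")[[1]]
  bc <- rev(strsplit(b, "")[[1]])
  keys <- paste0(ac, bc)
  w <- PAIR_WEIGHTS[keys]
  if (anyNA(w)) return(NULL)
  n_wob <- sum(keys %in% c("GT", "TG"))
  if (n_wob > max_wobbles) return(NULL)
  list(score = sum(w), wobbles = n_wob)
}
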