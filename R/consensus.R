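#' A set of aligned sequences
#'
#' @param rows character vector of equal-length gapped sequences over
#'   `{A,C,G,U,-}` (T is accepted and read as U).
#' @param ids optional row identifiers.
#' @return object of class `aligned_set`.
#' @export
aligned_set <- function(rows, ids = NULL) {
  rows <- chartr("Tt", "Uu", toupper(rows))
  if (length(rows) < 2L) stop("an alignment needs at least 2 rows")
  if (length(unique(nchar(rows))) != 1L) stop("rows differ in length")
  if (any(grepl("[^ACGUN-]", rows))) stop("rows must be over A,C,G,U,N,-")
  if (is.null(ids)) ids <- paste0("seq", seq_along(rows))
  structure(list(rows = unname(rows), ids = ids, width = nchar(rows[1])),
            class = "aligned_set")
}

#' Per-column base frequencies of an alignment
#'
#' Gaps are excluded from the denominator, so frequencies sum to 1 over
#' the non-gap symbols of each column (all-gap columns report depth 0).
#'
#' @param aln an [aligned_set()].
#' @return data frame with columns `column`, `A`, `C`, `G`, `U`,
#'   `depth`.
#' @export
column_frequencies <- function(aln) {
  stopifnot(inherits(aln, "aligned_set"))
  mat <- do.call(rbind, strsplit(aln$rows, ""))
  out <- lapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col != "-"]
    depth <- length(col)
    f <- function(b) if (depth) sum(col == b) / depth else 0
    data.frame(column = j, A = f("A"), C = f("C"), G = f("G"), U = f("U"),
               depth = depth)
  })
  do.call(rbind, out)
}

consensus_char <- function(freq, depth, full, partial) {
  if (depth == 0L) return(".")
  bases <- c("A", "C", "G", "U")
  fr <- unlist(freq[bases])
  pur <- fr[["A"]] + fr[["G"]]
  pyr <- fr[["C"]] + fr[["U"]]
  top <- which.max(fr)
  if (fr[top] >= full) return(bases[top])
  if (pur >= full) return("R")
  if (pyr >= full) return("Y")
  if (fr[top] >= partial) return(tolower(bases[top]))
  if (pur >= partial) return("r")
  if (pyr >= partial) return("y")
  "."
}

#' Build a conservation consensus string
#'
#' Per column (gap-excluded denominators): a base conserved in every
#' sequence is written uppercase; a purine- or pyrimidine-only column at
#' full conservation is written `R`/`Y`; a base (or purine/pyrimidine
#' class) at or above the `partial` threshold is written lowercase; any
#' less conserved column is a dot.
#'
#' @param aln an [aligned_set()].
#' @param full threshold for uppercase (default 1.0).
#' @param partial threshold for lowercase (default 0.70).
#' @return consensus string, one character per column.
#' @export
build_consensus <- function(aln, full = 1.0, partial = 0.70) {
  stopifnot(0 < partial, partial < full, full <= 1)
  freqs <- column_frequencies(aln)
  chars <- vapply(seq_len(nrow(freqs)), function(j) {
    consensus_char(freqs[j, ], freqs$depth[j], full, partial)
  }, character(1))
  paste(chars, collapse = "")
}

## plain Needleman-Wunsch, match +1 / mismatch -1 / gap -2; returns the
## two gapped strings
nw_align <- function(s1, s2, match = 1L, mismatch = -1L, gap = -2L) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0L, n + 1L, m + 1L)
  M[1, ] <- gap * 0:m
  M[, 1] <- gap * 0:n
  for (i in 1:n) {
    sub <- ifelse(a[i] == b, match, mismatch)
    for (j in 1:m) {
      M[i + 1L, j + 1L] <- max(M[i, j] + sub[j], M[i, j + 1L] + gap,
                               M[i + 1L, j] + gap)
    }
  }
  g1 <- character(0); g2 <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        M[i + 1L, j + 1L] == M[i, j] + (if (a[i] == b[j]) match else mismatch)) {
      g1 <- c(a[i], g1); g2 <- c(b[j], g2); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && M[i + 1L, j + 1L] == M[i, j + 1L] + gap) {
      g1 <- c(a[i], g1); g2 <- c("-", g2); i <- i - 1L
    } else {
      g1 <- c("-", g1); g2 <- c(b[j], g2); j <- j - 1L
    }
  }
  list(s1 = paste(g1, collapse = ""), s2 = paste(g2, collapse = ""),
       score = M[n + 1L, m + 1L])
}

#' Simple center-star multiple alignment
#'
#' A deliberately small aligner (match +1, mismatch -1, gap -2) used to
#' build alignment fixtures for consensus rendering; it makes no claim
#' to progressive-alignment quality.
#'
#' @param seqs character vector of sequences (>= 2).
#' @param ids optional identifiers.
#' @return an [aligned_set()].
#' @export
center_star_align <- function(seqs, ids = NULL) {
  seqs <- chartr("Uu", "Tt", toupper(seqs))
  k <- length(seqs)
  stopifnot(k >= 2L)
  if (k == 2L) {
    ctr <- 1L
  } else {
    tot <- numeric(k)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      sc <- nw_align(seqs[i], seqs[j])$score
      tot[i] <- tot[i] + sc; tot[j] <- tot[j] + sc
    }
    ctr <- which.max(tot)
  }
  others <- setdiff(seq_len(k), ctr)
  alns <- lapply(others, function(i) nw_align(seqs[ctr], seqs[i]))
  n <- nchar(seqs[ctr])
  ## per-alignment insertion counts between center characters 0..n
  ins <- lapply(alns, function(al) {
    cc <- strsplit(al$s1, "")[[1]]
    cnt <- integer(n + 1L)
    pos <- 0L
    for (ch in cc) {
      if (ch == "-") cnt[pos + 1L] <- cnt[pos + 1L] + 1L else pos <- pos + 1L
    }
    cnt
  })
  master <- Reduce(pmax, ins, integer(n + 1L))
  pad_row <- function(al) {
    cc <- strsplit(al$s1, "")[[1]]; oo <- strsplit(al$s2, "")[[1]]
    out <- character(0)
    pos <- 0L; run <- 0L
    flush <- function(out, run, pos) {
      c(out, rep("-", master[pos + 1L] - run))
    }
    for (t in seq_along(cc)) {
      if (cc[t] == "-") {
        run <- run + 1L
        out <- c(out, oo[t])
      } else {
        out <- flush(out, run, pos)
        run <- 0L; pos <- pos + 1L
        out <- c(out, oo[t])
      }
    }
    out <- flush(out, run, pos)
    paste(out, collapse = "")
  }
  center_row <- {
    out <- character(0)
    ch <- strsplit(seqs[ctr], "")[[1]]
    for (pos in 0:n) {
      out <- c(out, rep("-", master[pos + 1L]),
               if (pos < n) ch[pos + 1L] else character(0))
    }
    paste(out, collapse = "")
  }
  rows <- character(k)
  rows[ctr] <- center_row
  for (t in seq_along(others)) rows[others[t]] <- pad_row(alns[[t]])
  if (is.null(ids)) ids <- paste0("seq", seq_len(k))
  aligned_set(rows, ids)
}
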