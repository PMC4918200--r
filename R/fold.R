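#' Fold an RNA by weighted base-pair maximization
#'
#' Computes a nested (pseudoknot-free) secondary structure maximizing
#' the weighted number of base pairs (defaults GC = 3, AU = 2, GU = 1),
#' with a minimum hairpin loop of `min_loop` unpaired bases.  This is a
#' Nussinov-style interval dynamic program, not a thermodynamic model;
#' it is exactly testable against enumeration and is used for the
#' self-complementarity (fraction-paired) statistic of monomer RNAs.
#' Among co-optimal structures the deterministic traceback (5'-most
#' base first, partners tried 3'-most first) fixes the reported one.
#'
#' @param seq RNA string over `{A,C,G,U}` (T is accepted and read as U).
#' @param weights named numeric vector with elements `GC`, `AU`, `GU`;
#'   a weight of 0 disallows that pair.
#' @param min_loop minimum number of unpaired bases in a hairpin loop
#'   (default 3).
#' @return object of class `fold_result`: list with `length`, `pairs`
#'   (two-column 0-based matrix, i < j), `dotbracket`, `n_paired`,
#'   `fraction_paired`, `score`.
#' @examples
#' fold_rna("GGGGAAAACCCC")$fraction_paired  # 8/12
#' @export
fold_rna <- function(seq, weights = c(GC = 3, AU = 2, GU = 1),
                     min_loop = 3L) {
  seq <- chartr("Tt", "Uu", toupper(seq))
  if (!nzchar(seq)) stop("empty sequence")
  if (grepl("[^ACGU]", seq)) {
    stop("invalid RNA characters: ",
         paste(unique(strsplit(gsub("[ACGU]", "", seq), "")[[1]]),
               collapse = ""))
  }
  stopifnot(all(c("GC", "AU", "GU") %in% names(weights)))
  res <- .nussinov_cpp(seq, as.integer(weights[["GC"]]),
                       as.integer(weights[["AU"]]),
                       as.integer(weights[["GU"]]), as.integer(min_loop))
  n <- nchar(seq)
  pairs <- cbind(i = res$i, j = res$j)
  db <- rep(".", n)
  if (nrow(pairs)) {
    db[pairs[, 1] + 1L] <- "("
    db[pairs[, 2] + 1L] <- ")"
  }
  structure(list(
    length = n, pairs = pairs, dotbracket = paste(db, collapse = ""),
    n_paired = 2L * nrow(pairs),
    fraction_paired = 2 * nrow(pairs) / n,
    score = res$score), class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("fold: %d nt, %d pairs (%.1f%% paired), score %d\n",
              x$length, nrow(x$pairs), 100 * x$fraction_paired, x$score))
  invisible(x)
}

#' Fraction-paired report for a set of monomer RNAs
#'
#' @param x FASTA path or named character vector of RNA sequences.
#' @param weights,min_loop passed to [fold_rna()].
#' @return data frame with columns `id`, `length`, `fraction_paired`,
#'   `score`, one row per record (empty input gives an empty table).
#' @export
fraction_paired_report <- function(x, weights = c(GC = 3, AU = 2, GU = 1),
                                   min_loop = 3L) {
  seqs <- if (is.character(x) && length(x) == 1L && file.exists(x)) {
    set <- Biostrings::readBStringSet(x)
    setNames(as.character(set),
             vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L))
  } else x
  if (length(seqs) == 0L) {
    return(data.frame(id = character(0), length = integer(0),
                      fraction_paired = numeric(0), score = numeric(0)))
  }
  rows <- lapply(names(seqs), function(id) {
    f <- fold_rna(seqs[[id]], weights, min_loop)
    data.frame(id = id, length = f$length,
               fraction_paired = f$fraction_paired, score = f$score,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fraction of motif nucleotides paired outside the motif span
#'
#' Quantifies how much of a hammerhead motif is sequestered by pairing
#' with the rest of the monomer (the "blocked" hammerhead conformation
#' of retrozyme RNAs): the fraction of nucleotides in `span` whose
#' partner lies outside `span`.
#'
#' @param fold a [fold_rna()] result for the monomer.
#' @param span 0-based half-open `c(start, end)` of the motif within
#'   the monomer.
#' @return numeric in `[0, 1]`.
#' @export
hhr_blocked <- function(fold, span) {
  stopifnot(inherits(fold, "fold_result"), length(span) == 2L)
  if (span[1] < 0 || span[2] > fold$length || span[1] >= span[2]) {
    stop("motif span out of monomer bounds")
  }
  idx <- span[1]:(span[2] - 1L)
  if (nrow(fold$pairs) == 0L) return(0)
  inside <- function(x) x >= span[1] & x < span[2]
  cnt <- sum(inside(fold$pairs[, 1]) & !inside(fold$pairs[, 2])) +
    sum(inside(fold$pairs[, 2]) & !inside(fold$pairs[, 1]))
  cnt / length(idx)
}

#' Write fold results as a dot-bracket file
#'
#' @param folds named list of [fold_rna()] results.
#' @param seqs named character vector of the folded sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dotbracket <- function(folds, seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(folds)) {
    writeLines(c(paste0(">", id), chartr("Tt", "Uu", toupper(seqs[[id]])),
                 folds[[id]]$dotbracket), con)
  }
  invisible(path)
}
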