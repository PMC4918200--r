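IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Read a genome from a FASTA file
#'
#' Sequences are uppercased, `U` is converted to `T`, and IUPAC ambiguity
#' letters other than `N` are mapped to `N` (they never match descriptor
#' positions downstream).  Any other character is an error naming the
#' offending record.
#'
#' @param path path to a FASTA file.
#' @return A named character vector of class `genome`; names are record
#'   ids (first whitespace-delimited token of each header), values are
#'   sequences over `{A,C,G,T,N}`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgu"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  seqs <- chartr(paste(IUPAC_AMBIG, collapse = ""),
                 strrep("N", length(IUPAC_AMBIG)), seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-IUPAC characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  as_genome(setNames(unname(seqs), ids))
}

#' Construct a genome object from named sequences
#'
#' @param seqs named character vector of DNA sequences.
#' @return object of class `genome` (named character vector).
#' @export
as_genome <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)),
            !anyDuplicated(names(seqs)))
  structure(seqs, class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("genome set:", length(x), "record(s),",
      format(sum(nchar(x)), big.mark = ","), "nt total\n")
  for (id in head(names(x), 10L)) {
    cat("  ", id, " (", nchar(x[[id]]), " nt)\n", sep = "")
  }
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (DNA or RNA).
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(unclass(seqs))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement of DNA sequences
#'
#' `N` maps to `N`.  Vectorized over `x`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Fetch the sequence of an interval
#'
#' Intervals are 0-based half-open in plus-strand coordinates; strand `-`
#' returns the reverse complement of the plus-strand slice.
#'
#' @param genome a `genome` object (named character vector).
#' @param contig record id.
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"` or `"-"`.
#' @return sequence string of length `end - start`.
#' @export
fetch <- function(genome, contig, start, end, strand = "+") {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  len <- nchar(genome[[contig]])
  if (!(start >= 0 && start < end && end <= len)) {
    stop("interval out of bounds for ", contig, ": [", start, ",", end,
         ") on length ", len)
  }
  s <- substr(genome[[contig]], start + 1L, end)
  if (strand == "-") revcomp(s) else s
}

#' DNA -> RNA alphabet
#' @param x character vector of DNA sequences.
#' @return same sequences with `T` replaced by `U`.
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x
}

#' Write features to GFF3
#'
#' Internal 0-based half-open intervals are converted to the 1-based
#' inclusive GFF3 convention (`start + 1`, `end`).
#'
#' @param features data frame with columns `contig`, `start`, `end`,
#'   `strand`, `type`, optionally `score`, `id`, `parent`, and an
#'   `attributes` list/character column of extra `key=value` pairs.
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, source = "retrozyme") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (is.null(features) || nrow(features) == 0L) return(invisible(path))
  n <- nrow(features)
  score <- if ("score" %in% names(features)) {
    ifelse(is.na(features$score), ".", format(features$score, trim = TRUE))
  } else rep(".", n)
  attrs <- character(n)
  for (i in seq_len(n)) {
    parts <- character(0)
    if ("id" %in% names(features) && !is.na(features$id[i])) {
      parts <- c(parts, paste0("ID=", gff3_escape(features$id[i])))
    }
    if ("parent" %in% names(features) && !is.na(features$parent[i])) {
      parts <- c(parts, paste0("Parent=", gff3_escape(features$parent[i])))
    }
    if ("attributes" %in% names(features)) {
      extra <- features$attributes[[i]]
      if (length(extra) && !all(is.na(extra))) {
        parts <- c(parts, paste0(names(extra), "=",
                                 gff3_escape(as.character(extra))))
      }
    }
    attrs[i] <- if (length(parts)) paste(parts, collapse = ";") else "."
  }
  lines <- paste(features$contig, source, features$type,
                 features$start + 1L, features$end, score,
                 features$strand, ".", attrs, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Minimal GFF3 reader
#'
#' Reads a GFF3 file back into the package's 0-based half-open interval
#' convention, with attributes expanded into a named list column.
#'
#' @param path GFF3 file.
#' @return data frame with columns `contig`, `type`, `start`, `end`,
#'   `score`, `strand`, `attributes` (list of named character vectors).
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(contig = character(0), type = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0), strand = character(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  parse_attrs <- function(a) {
    if (a == ".") return(list())
    kv <- strsplit(strsplit(a, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    vals <- vapply(kv, function(p) if (length(p) > 1) p[2] else "",
                   character(1))
    vals <- gsub("%3B", ";", gsub("%3D", "=", gsub("%2C", ",", vals)))
    vals <- gsub("%25", "%", vals)
    setNames(as.list(vals), vapply(kv, `[[`, character(1), 1L))
  }
  out <- data.frame(
    contig = vapply(f, `[[`, character(1), 1L),
    type   = vapply(f, `[[`, character(1), 3L),
    start  = as.integer(vapply(f, `[[`, character(1), 4L)) - 1L,
    end    = as.integer(vapply(f, `[[`, character(1), 5L)),
    score  = suppressWarnings(as.numeric(vapply(f, `[[`, character(1), 6L))),
    strand = vapply(f, `[[`, character(1), 7L),
    stringsAsFactors = FALSE)
  out$attributes <- lapply(f, function(p) parse_attrs(p[9]))
  out
}

#' Write features to BED6
#'
#' BED is natively 0-based half-open, matching the internal convention.
#'
#' @param features data frame with columns `contig`, `start`, `end`,
#'   `strand`, and optionally `id` (name) and `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(features, path) {
  n <- if (is.null(features)) 0L else nrow(features)
  if (n == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  name <- if ("id" %in% names(features)) features$id else rep(".", n)
  score <- if ("score" %in% names(features)) {
    ifelse(is.na(features$score), 0, features$score)
  } else rep(0, n)
  lines <- paste(features$contig, features$start, features$end,
                 name, format(score, trim = TRUE), features$strand,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
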