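# Independent oracle for the folding DP: exhaustive optimum over all
# nested structures via a memoized recursion on the *other* end of the
# interval (whether j is unpaired or paired with some k), so it shares
# neither recurrence direction nor implementation with the C++ DP.
oracle_pair_w <- function(a, b, w) {
  key <- paste0(a, b)
  if (key %in% c("GC", "CG")) return(w[["GC"]])
  if (key %in% c("AU", "UA")) return(w[["AU"]])
  if (key %in% c("GU", "UG")) return(w[["GU"]])
  0
}

oracle_fold_score <- function(seq, weights = c(GC = 3, AU = 2, GU = 1),
                              min_loop = 3L) {
  ch <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  n <- length(ch)
  memo <- matrix(NA_real_, n, n)
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0)
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- rec(i, j - 1L)           # j unpaired
    for (k in i:(j - min_loop - 1L)) {  # j paired with k
      w <- oracle_pair_w(ch[k], ch[j], weights)
      if (w == 0) next
      left <- if (k > i) rec(i, k - 1L) else 0
      inner <- rec(k + 1L, j - 1L)
      best <- max(best, left + w + inner)
    }
    memo[i, j] <<- best
    best
  }
  if (n < 2L) return(0)
  rec(1L, n)
}

# random RNA of length n from the current RNG
random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
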