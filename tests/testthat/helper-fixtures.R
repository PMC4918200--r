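# shared fixtures; everything is generated in code under fixed seeds

DESC <- hhr_descriptor()

random_dna_str <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# plant a motif sequence at a 0-based offset inside a random background
plant_in_background <- function(motif, bg_len, offset, contig = "chr") {
  bg <- random_dna_str(bg_len)
  as_genome(setNames(
    paste0(substr(bg, 1, offset), motif, substr(bg, offset + 1, bg_len)),
    contig))
}

# small, fast benchmark spec used by unit tests (the full 5-Mb
# reference benchmark lives in the acceptance suite)
small_spec <- function(seed = 11L) {
  synthetic_spec(genome_length = 300000L, n_contigs = 1L, n_full = 3L,
                 n_solo = 1L, n_multimer = 1L, n_decoys = 4L, seed = seed)
}

# the acceptance benchmark is expensive; compute once per test run
bench_cache <- new.env(parent = emptyenv())
get_benchmark <- function() {
  if (is.null(bench_cache$run)) {
    sim <- build_genome(synthetic_spec())
    hits <- scan_genome(sim$genome, DESC)
    elements <- annotate_retrozymes(sim$genome, hits)
    bench_cache$run <- list(sim = sim, hits = hits, elements = elements,
                            eval = evaluate_predictions(elements, sim$truth))
  }
  bench_cache$run
}

# 1-based motif-local positions of all concretely-constrained core
# characters of a make_hhr motif, with a disallowed substitution base
core_mutation_table <- function(hhr, desc = DESC) {
  lay <- hhr$layout
  disallowed <- function(pat_char) {
    setdiff(c("A", "C", "G", "T"), retrozyme:::IUPAC_SETS[[pat_char]])
  }
  out <- NULL
  add <- function(pos, pat_char) {
    bad <- disallowed(pat_char)
    if (length(bad)) {
      out <<- rbind(out, data.frame(pos = pos, sub = bad[1],
                                    stringsAsFactors = FALSE))
    }
  }
  pa <- strsplit(desc$core_seg_A, "")[[1]]
  for (i in seq_along(pa)) add(lay$coreA_at + i - 1L, pa[i])
  # core_seg_B position depends on the topology layout
  lenA <- nchar(desc$core_seg_A)
  coreB_at <- switch(lay$topology,
    III = lay$coreA_at + lenA + 2L * lay$h2 + lay$loop2,
    I   = lay$coreA_at + lenA + 2L * lay$h2 + lay$loop2,
    II  = NA_integer_)
  pb <- strsplit(desc$core_seg_B, "")[[1]]
  if (!is.na(coreB_at)) {
    for (i in seq_along(pb)) add(coreB_at + i - 1L, pb[i])
  }
  pc <- strsplit(desc$cleavage_context, "")[[1]]
  ctx_at <- hhr$cut - nchar(desc$cleavage_context) + 1L
  for (i in seq_along(pc)) add(ctx_at + i - 1L, pc[i])
  add(hhr$cut + 1L, desc$cut_adjacent)
  out
}

mutate_at <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}
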