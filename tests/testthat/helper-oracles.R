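# Independent oracles and small fixture builders used across the test files.
# Everything here works on strings directly and shares no code with the
# folding operator it checks.

random_dna <- function(len, seed = NULL,
                       bases = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(bases, len, replace = TRUE), collapse = "")
}

# Brute-force gapped k-mer counter: slides a window over the sequence and,
# for every dependency model, records the window projected onto the model's
# dependent positions (N at gaps). Returns a table keyed by pattern string.
oracle_gapped_counts <- function(seq, k) {
  L <- nchar(seq)
  masks <- seq(1L, 2L^k - 1L, by = 2L)
  bits <- lapply(masks, function(d) bitwAnd(d, 2L^((k - 1):0)) > 0L)
  pats <- character(0)
  for (off in seq_len(L - k + 1)) {
    win <- strsplit(substr(seq, off, off + k - 1), "")[[1]]
    if (any(win == "N")) next
    for (b in bits) {
      p <- win
      p[!b] <- "N"
      pats[length(pats) + 1] <- paste(p, collapse = "")
    }
  }
  table(pats)
}

# Uniform background model: every contiguous k-mer equally frequent.
uniform_background <- function(k) {
  words <- foldkspec:::all_kmers(k)
  structure(list(k = as.integer(k),
                 counts = stats::setNames(rep(1, length(words)), words),
                 total_windows = length(words), pseudocount = 0),
            class = "kmer_background")
}

# Strongly separable toy dataset: positives carry many exact copies of a
# contiguous motif, negatives are scrambles.
separable_dataset <- function(n_pos = 10, length = 300, seed = 42,
                              n_scrambles = 5) {
  spec <- plant_spec("TGACGT", plants_per_sequence = 10, mutation_rate = 0,
                     seed = seed)
  make_dataset(n_pos = n_pos, length = length, spec = spec,
               n_scrambles = n_scrambles, seed = seed)
}

base_counts <- function(s) {
  tab <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T", "N")))
  as.integer(tab)
}
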