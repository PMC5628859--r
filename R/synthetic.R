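#' Generate i.i.d. background DNA sequences
#'
#' @param n number of sequences (0 allowed).
#' @param length sequence length in bp.
#' @param composition probabilities over A/C/G/T (must sum to 1 within 1e-9).
#' @param seed RNG seed.
#' @param prefix id prefix (ids `<prefix>001`, ...).
#' @return A [dna_set] of unlabeled original sequences.
#' @export
generate_background <- function(n, length,
                                composition = c(A = 0.25, C = 0.25,
                                                G = 0.25, T = 0.25),
                                seed = 1L, prefix = "seq") {
  if (abs(sum(composition) - 1) > 1e-9)
    stop2("composition probabilities must sum to 1")
  if (n == 0) return(dna_set(character(), character()))
  seqs <- with_seed(seed, vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                 prob = composition), collapse = ""), character(1)))
  dna_set(sprintf("%s%03d", prefix, seq_len(n)), seqs)
}

#' Planted-motif specification
#'
#' Describes the ground-truth signal inserted into synthetic positives: a
#' consensus word over A/C/G/T/N (N = unconstrained position, left as the
#' original background base — the synthetic analogue of a gapped dependency),
#' the number of non-overlapping plants per sequence, and a per-dependent-
#' position substitution probability emulating binding-site degeneracy.
#'
#' @param consensus consensus string over A/C/G/T/N.
#' @param plants_per_sequence non-negative integer.
#' @param mutation_rate substitution probability in [0, 1) applied
#'   independently at each dependent (non-N) position.
#' @param seed RNG seed for planting.
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(consensus, plants_per_sequence = 3L,
                       mutation_rate = 0.1, seed = 1L) {
  consensus <- toupper(consensus)
  if (!grepl("^[ACGTN]+$", consensus)) stop2("consensus must be over A/C/G/T/N")
  if (!grepl("[ACGT]", consensus))
    stop2("consensus needs at least one dependent (non-N) position")
  if (mutation_rate < 0 || mutation_rate >= 1)
    stop2("mutation_rate must be in [0, 1)")
  if (plants_per_sequence < 0) stop2("plants_per_sequence must be >= 0")
  structure(list(consensus = consensus,
                 plants_per_sequence = as.integer(plants_per_sequence),
                 mutation_rate = mutation_rate, seed = as.integer(seed)),
            class = "plant_spec")
}

#' Plant motif instances into sequences
#'
#' Writes realizations of the consensus at non-overlapping uniform-random
#' offsets of each sequence. N positions keep the original background base;
#' dependent positions receive the consensus base, substituted by a different
#' uniform base with probability `mutation_rate`. The returned log records
#' every plant (sequence id, 1-based offset, realized window) and exactly
#' matches a rescan of the output.
#'
#' @param x sequences (see [dna_set]).
#' @param spec a [plant_spec].
#' @return List with `sequences` (modified [dna_set]) and `plants` (data
#'   frame: `id`, `offset`, `strand`, `word`).
#' @export
plant_motifs <- function(x, spec) {
  stopifnot(inherits(spec, "plant_spec"))
  x <- as_dna_set(x)
  k <- nchar(spec$consensus)
  pat <- strsplit(spec$consensus, "")[[1]]
  dep <- which(pat != "N")
  bases <- c("A", "C", "G", "T")
  log_id <- character(0); log_off <- integer(0); log_word <- character(0)
  seqs <- x$seq
  if (spec$plants_per_sequence > 0) for (i in seq_len(nrow(x))) {
    L <- nchar(seqs[i])
    if (L < k) stop2("sequence ", x$id[i], " shorter than the consensus")
    offs <- with_seed(derive_seed(spec$seed, x$id[i], 1L),
                      draw_nonoverlapping(L, k, spec$plants_per_sequence))
    chars <- strsplit(seqs[i], "")[[1]]
    words <- with_seed(derive_seed(spec$seed, x$id[i], 2L), {
      vapply(offs, function(off) {
        win <- chars[off:(off + k - 1)]
        win[dep] <- pat[dep]
        mut <- dep[stats::runif(length(dep)) < spec$mutation_rate]
        for (p in mut) win[p] <- sample(setdiff(bases, win[p]), 1)
        chars[off:(off + k - 1)] <<- win
        paste(win, collapse = "")
      }, character(1))
    })
    seqs[i] <- paste(chars, collapse = "")
    log_id <- c(log_id, rep(x$id[i], length(offs)))
    log_off <- c(log_off, offs)
    log_word <- c(log_word, words)
  }
  out <- x
  out$seq <- seqs
  list(sequences = out,
       plants = data.frame(id = log_id, offset = log_off,
                           strand = rep("+", length(log_id)),
                           word = log_word, stringsAsFactors = FALSE))
}

# Uniform-random non-overlapping offsets (1-based) for `n` windows of width k
# in a sequence of length L; errors when placement is impossible.
draw_nonoverlapping <- function(L, k, n, max_tries = 1000L) {
  if (n * k > L)
    stop2("cannot place ", n, " non-overlapping windows of width ", k,
          " in length ", L)
  for (try in seq_len(max_tries)) {
    offs <- sort(sample.int(L - k + 1, n))
    if (n == 1 || all(diff(offs) >= k)) return(offs)
  }
  # dense case: fall back to spaced sampling (still uniform over valid sets)
  gaps <- stats::rmultinom(1, L - n * k, rep(1, n + 1))[, 1]
  cumsum(c(1, rep(k, n - 1))) + cumsum(gaps)[seq_len(n)]
}

#' Generate a labeled synthetic dataset with planted motifs
#'
#' Emulates the study design used for regulatory-sequence classification:
#' positive sequences are i.i.d. background DNA carrying planted motif
#' instances; each positive gets `n_scrambles` composition-preserving
#' scrambled copies as matched negatives. Generator metadata (plant log,
#' parameters) is attached for ground-truth evaluation.
#'
#' @param n_pos number of positive sequences.
#' @param length positive sequence length in bp.
#' @param spec a [plant_spec] describing the planted motif.
#' @param n_scrambles scrambled negatives per positive (default 10).
#' @param composition background base probabilities.
#' @param seed RNG seed.
#' @return A [dna_set] of `n_pos * (1 + n_scrambles)` sequences with labels,
#'   plus attributes `plants` (plant log) and `params`.
#' @export
make_dataset <- function(n_pos = 100L, length = 1000L, spec,
                         n_scrambles = 10L,
                         composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                         seed = 1L) {
  stopifnot(inherits(spec, "plant_spec"))
  bg <- generate_background(n_pos, length, composition = composition,
                            seed = derive_seed(seed, "background"),
                            prefix = "pos")
  spec_run <- spec
  spec_run$seed <- derive_seed(seed, "plants", spec$seed)
  planted <- plant_motifs(bg, spec_run)
  positives <- planted$sequences
  positives$label <- 1L
  negatives <- scramble_sequences(positives, n_copies = n_scrambles,
                                  seed = derive_seed(seed, "scrambles"))
  out <- rbind(positives, negatives)
  class(out) <- c("dna_set", "data.frame")
  attr(out, "plants") <- planted$plants
  attr(out, "params") <- list(n_pos = n_pos, length = length, spec = spec,
                              n_scrambles = n_scrambles,
                              composition = composition, seed = seed)
  out
}
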