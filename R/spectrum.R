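#' Enumerate gapped k-mer dependency models
#'
#' A dependency model (gap mask) is a binary pattern over the k positions of a
#' k-mer: 1 marks a dependent (fixed) nucleotide, 0 a gap. Position 1 is the
#' most-significant bit, so decimal 5 encodes the pattern 101 ("alpha N
#' alpha"). Only odd decimals occur — the last position is always dependent,
#' since a trailing gap would duplicate a shorter mask at a shifted offset —
#' giving exactly 2^(k-1) models: decimal 1 is the monomer model N...N alpha,
#' 3 the dimer model, and 2^k - 1 the contiguous k-mer model.
#'
#' @param k word length, 1..12.
#' @return A data frame with one row per model: `m` (model index, decimal =
#'   2m - 1), `decimal`, `bits` (pattern string of 1/0), `n_dependent`
#'   (popcount), `n_features` (4^popcount).
#' @export
enumerate_models <- function(k) {
  if (length(k) != 1 || is.na(k) || k < 1 || k > 12)
    stop2("k must be a single integer in 1..12")
  k <- as.integer(k)
  decimal <- seq.int(1L, 2L^k - 1L, by = 2L)
  bits <- vapply(decimal, function(d)
    paste(as.integer(mask_bits(d, k)), collapse = ""), character(1))
  n_dep <- vapply(decimal, function(d) sum(mask_bits(d, k)), integer(1))
  data.frame(m = seq_along(decimal), decimal = decimal, bits = bits,
             n_dependent = n_dep, n_features = 4L^n_dep,
             stringsAsFactors = FALSE)
}

# Logical mask, position 1 (leftmost) = most-significant bit.
mask_bits <- function(decimal, k) {
  bitwAnd(decimal, 2L^((k - 1):0)) > 0L
}

#' Gapped k-mer feature space
#'
#' The indexed union of all gapped k-mer features across the 2^(k-1)
#' dependency models, in a fixed deterministic order: models by ascending
#' decimal, features within a model in lexicographic order of the word at the
#' dependent positions. The total dimension is N = 4 * 5^(k-1). Feature names
#' are length-k pattern strings with N at gap positions (e.g. "ANTNAA").
#'
#' The folding operator — the linear map that turns the contiguous k-spectrum
#' into every gapped feature value by summing the contiguous k-mers compatible
#' with each gapped pattern — is precomputed as a sparse 0/1 matrix
#' (4^k rows, N columns).
#'
#' @param k word length, 1..8 (the full space is materialized).
#' @return An object of class `feature_space`: list with `k`, `models` (the
#'   [enumerate_models] table), `n_features` (N), `feature_names`,
#'   `feature_model` (decimal of each feature's mask), `offsets` (0-based
#'   column offset per model) and `fold_map` (sparse matrix).
#' @export
feature_space <- function(k) {
  if (length(k) != 1 || is.na(k) || k < 1 || k > 8)
    stop2("k must be a single integer in 1..8 for full feature-space construction")
  k <- as.integer(k)
  models <- enumerate_models(k)
  n_contig <- 4L^k
  offsets <- c(0L, cumsum(models$n_features))
  N <- offsets[length(offsets)]
  # base-4 digits of every contiguous k-mer, MSB = position 1
  digits <- matrix(0L, nrow = n_contig, ncol = k)
  idx <- 0:(n_contig - 1)
  for (p in k:1) {
    digits[, p] <- idx %% 4L
    idx <- idx %/% 4L
  }
  letters4 <- c("A", "C", "G", "T")
  feature_names <- character(N)
  feature_model <- integer(N)
  rows <- integer(n_contig * nrow(models))
  cols <- integer(n_contig * nrow(models))
  pos <- 0L
  for (mi in seq_len(nrow(models))) {
    dep <- which(mask_bits(models$decimal[mi], k))
    p <- length(dep)
    nf <- 4L^p
    # projected index of each contiguous k-mer onto the dependent positions
    proj <- rep(0L, n_contig)
    for (d in dep) proj <- proj * 4L + digits[, d]
    rows[pos + seq_len(n_contig)] <- seq_len(n_contig)
    cols[pos + seq_len(n_contig)] <- offsets[mi] + proj + 1L
    pos <- pos + n_contig
    # names: pattern with N at gaps, dependent word lexicographic
    fidx <- 0:(nf - 1)
    word <- matrix("N", nrow = nf, ncol = k)
    for (d in rev(dep)) {
      word[, d] <- letters4[fidx %% 4L + 1L]
      fidx <- fidx %/% 4L
    }
    feature_names[offsets[mi] + seq_len(nf)] <-
      apply(word, 1, paste, collapse = "")
    feature_model[offsets[mi] + seq_len(nf)] <- models$decimal[mi]
  }
  fold_map <- Matrix::sparseMatrix(i = rows, j = cols, x = 1,
                                   dims = c(n_contig, N))
  structure(
    list(k = k, models = models, n_features = N,
         feature_names = feature_names, feature_model = feature_model,
         offsets = offsets, fold_map = fold_map,
         contiguous_index = (offsets[nrow(models)] + 1L):N),
    class = "feature_space"
  )
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("feature_space: k=%d, %d models, N=%d gapped k-mer features\n",
              x$k, nrow(x$models), x$n_features))
  invisible(x)
}

#' Contiguous k-mer spectrum (raw counts)
#'
#' Overlapping sliding-window counts of every contiguous k-mer, one row per
#' sequence, 4^k lexicographic columns. Windows containing N contribute to no
#' word.
#'
#' @param x sequences (see [dna_set]).
#' @param k word length.
#' @return Numeric matrix with attributes `k`, `stage = "raw_count"`,
#'   `seq_length` (per-row sequence lengths) and `index` (global feature
#'   indices of the contiguous model within [feature_space]).
#' @export
count_contiguous <- function(x, k) {
  x <- as_dna_set(x)
  len <- nchar(x$seq)
  if (any(len < k))
    stop2("sequence(s) shorter than k = ", k, ": ",
          paste(x$id[len < k], collapse = ", "))
  m <- Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(x$seq),
                                            width = k)
  m <- matrix(as.numeric(m), nrow = nrow(x), dimnames = list(x$id, colnames(m)))
  spectrum_attrs(m, k = as.integer(k), stage = "raw_count", seq_length = len,
                 index = contiguous_global_index(k))
}

# Global indices of the contiguous (all-ones) model columns.
contiguous_global_index <- function(k) {
  N <- 4L * 5L^(k - 1L)
  (N - 4L^k + 1L):N
}

spectrum_attrs <- function(m, k, stage, seq_length, index) {
  attr(m, "k") <- k
  attr(m, "stage") <- stage
  attr(m, "seq_length") <- seq_length
  attr(m, "index") <- index
  m
}

#' Background-normalized relative k-mer frequencies
#'
#' Converts raw contiguous counts to the relative-frequency mapping
#' phi_alpha = (count / (len - k + 1)) / f_bg(alpha), where f_bg is the
#' background frequency of alpha (with pseudocount; see
#' [background_frequency]). This cancels the influence of sequence length and
#' background composition. The denominator len - k + 1 counts all windows,
#' including any containing N.
#'
#' @param counts a raw-count matrix from [count_contiguous].
#' @param bg a [build_background] model with matching `k`.
#' @return Matrix at stage `"normalized"`, same shape and attributes.
#' @export
normalize_spectrum <- function(counts, bg) {
  stopifnot(inherits(bg, "kmer_background"))
  k <- attr(counts, "k")
  if (!identical(attr(counts, "stage"), "raw_count"))
    stop2("normalize_spectrum expects a raw_count spectrum")
  if (bg$k != k) stop2("background k (", bg$k, ") != spectrum k (", k, ")")
  f_bg <- background_frequency(bg)[colnames(counts)]
  if (any(f_bg == 0)) {
    offending <- colnames(counts)[f_bg == 0 & colSums(counts) > 0]
    if (length(offending))
      stop2("zero background frequency for observed k-mer(s): ",
            paste(utils::head(offending, 5), collapse = ", "))
  }
  len <- attr(counts, "seq_length")
  out <- counts / (len - k + 1)
  out <- sweep(out, 2, f_bg, "/")
  out[, f_bg == 0] <- 0   # unobserved everywhere; 0/0 -> 0
  spectrum_attrs(out, k = k, stage = "normalized", seq_length = len,
                 index = attr(counts, "index"))
}

#' Fold the contiguous spectrum onto all gapped feature sets
#'
#' Each gapped feature's value is the unweighted sum of the contiguous k-mer
#' values that agree with it at all dependent positions (e.g. for k = 3,
#' value("ANA") = value("AAA") + value("ACA") + value("AGA") + value("ATA")).
#' The contiguous-model coordinates pass through unchanged. Folding is linear,
#' so it applies equally to raw counts and normalized frequencies.
#'
#' @param contiguous a matrix from [count_contiguous] or [normalize_spectrum]
#'   covering the full contiguous model (4^k columns).
#' @param space a [feature_space] with matching `k`.
#' @return Matrix with N = 4 * 5^(k-1) columns named by feature pattern,
#'   stage preserved, `index` = 1..N.
#' @export
fold_spectrum <- function(contiguous, space) {
  stopifnot(inherits(space, "feature_space"))
  if (ncol(contiguous) != 4^space$k)
    stop2("contiguous spectrum has ", ncol(contiguous),
          " columns; expected ", 4^space$k)
  if (!is.null(attr(contiguous, "k")) && attr(contiguous, "k") != space$k)
    stop2("spectrum k and feature-space k differ")
  out <- as.matrix(contiguous %*% space$fold_map)
  dimnames(out) <- list(rownames(contiguous), space$feature_names)
  spectrum_attrs(out, k = space$k, stage = attr(contiguous, "stage") %||% "raw_count",
                 seq_length = attr(contiguous, "seq_length"),
                 index = seq_len(space$n_features))
}

#' Folded k-spectrum feature map
#'
#' The full pipeline: contiguous k-mer counting, background normalization,
#' then folding onto all 2^(k-1) gapped feature sets.
#'
#' @param x sequences (see [dna_set]).
#' @param space a [feature_space].
#' @param bg a [build_background] model; if `NULL`, built from `x` itself
#'   (pseudocount 1).
#' @return Normalized feature matrix, one row per sequence, N columns.
#' @export
featurize <- function(x, space, bg = NULL) {
  x <- as_dna_set(x)
  if (is.null(bg)) bg <- build_background(x, space$k)
  counts <- count_contiguous(x, space$k)
  fold_spectrum(normalize_spectrum(counts, bg), space)
}

#' Restrict a feature matrix to an index set
#'
#' Drops all coordinates outside `index`, keeping track of the surviving
#' global indices so that restricted vectors and models stay aligned.
#'
#' @param x a feature matrix carrying an `index` attribute.
#' @param index global feature indices to keep (subset of the matrix's own).
#' @return The restricted matrix; `attr(, "index")` gives the kept global
#'   indices in ascending order.
#' @export
restrict_spectrum <- function(x, index) {
  cur <- attr(x, "index")
  if (is.null(cur)) stop2("matrix carries no feature index")
  index <- sort(unique(as.integer(index)))
  if (length(index) && (min(index) < 1 || !all(index %in% cur)))
    stop2("index out of range of the matrix's feature index")
  keep <- match(index, cur)
  out <- x[, keep, drop = FALSE]
  spectrum_attrs(out, k = attr(x, "k"), stage = attr(x, "stage"),
                 seq_length = attr(x, "seq_length"), index = index)
}

#' Match a gapped pattern against k-mer windows
#'
#' Direct sliding-window matcher treating N as a wildcard; used for
#' verification and motif inspection, independent of the folding operator.
#'
#' @param seq a single residue string.
#' @param pattern length-k pattern over A/C/G/T/N (N = any base).
#' @return Number of windows of `seq` matching `pattern` (windows containing
#'   N in the sequence never match).
#' @export
match_gapped <- function(seq, pattern) {
  seq <- toupper(seq)
  k <- nchar(pattern)
  L <- nchar(seq)
  if (L < k) return(0L)
  pat <- strsplit(pattern, "")[[1]]
  dep <- which(pat != "N")
  chars <- strsplit(seq, "")[[1]]
  n <- 0L
  for (off in 0:(L - k)) {
    win <- chars[off + seq_len(k)]
    if (any(win == "N")) next
    if (all(win[dep] == pat[dep])) n <- n + 1L
  }
  n
}
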