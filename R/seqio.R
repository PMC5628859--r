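#' DNA sequence sets
#'
#' A `dna_set` is a plain data frame with one row per sequence and columns
#' `id` (unique identifier), `seq` (uppercase residues over A/C/G/T/N),
#' `label` (+1, -1 or `NA`), `origin` (`"original"` or `"scrambled"`) and
#' `parent` (for a scrambled sequence, the id of the original it permutes;
#' `NA` otherwise). All functions in the package that take sequences accept a
#' `dna_set`, a named character vector of residues, or a FASTA file path.
#'
#' @param id character vector of sequence identifiers (must be unique).
#' @param seq character vector of residues; lowercase input is folded to
#'   uppercase, any character outside A/C/G/T/N is rejected.
#' @param label optional class labels in \{+1, -1\}; `NA` for unlabeled.
#' @param origin `"original"` or `"scrambled"`, recycled.
#' @param parent parent sequence id, required exactly when
#'   `origin == "scrambled"`.
#' @return A data frame of class `c("dna_set", "data.frame")`.
#' @export
dna_set <- function(id, seq, label = NA_integer_, origin = "original",
                    parent = NA_character_) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  n <- length(seq)
  if (length(id) != n) stop2("`id` and `seq` lengths differ")
  if (anyDuplicated(id)) stop2("duplicated sequence ids: ",
                               paste(unique(id[duplicated(id)]), collapse = ", "))
  bad <- regexpr("[^ACGTN]", seq)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop2(sprintf("illegal residue '%s' in record '%s' at position %d",
                  substr(seq[i], bad[i], bad[i]), id[i], bad[i]))
  }
  label <- rep_len(as.integer(label), n)
  if (!all(is.na(label) | label %in% c(-1L, 1L)))
    stop2("labels must be +1, -1 or NA")
  origin <- rep_len(origin, n)
  if (!all(origin %in% c("original", "scrambled")))
    stop2("origin must be 'original' or 'scrambled'")
  parent <- rep_len(as.character(parent), n)
  if (any(origin == "scrambled" & is.na(parent)))
    stop2("scrambled sequences must carry a parent id")
  if (any(origin == "original" & !is.na(parent)))
    stop2("original sequences must not carry a parent id")
  structure(
    data.frame(id = id, seq = seq, label = label, origin = origin,
               parent = parent, stringsAsFactors = FALSE),
    class = c("dna_set", "data.frame")
  )
}

# Coerce the accepted input forms to a dna_set.
as_dna_set <- function(x) {
  if (inherits(x, "dna_set")) return(x)
  if (is.data.frame(x)) {
    return(dna_set(x$id, x$seq,
                   label = x$label %||% NA_integer_,
                   origin = x$origin %||% "original",
                   parent = x$parent %||% NA_character_))
  }
  if (is.character(x) && length(x) == 1 && file.exists(x) &&
      !grepl("^[ACGTNacgtn]+$", x)) {
    return(read_fasta(x))
  }
  if (is.character(x)) {
    ids <- names(x) %||% sprintf("seq%04d", seq_along(x))
    if (is.null(names(x)) && length(x) > 0) names(x) <- ids
    return(dna_set(ids, unname(x)))
  }
  stop2("cannot interpret input as a set of DNA sequences")
}

#' @export
print.dna_set <- function(x, ...) {
  cat(sprintf("dna_set: %d sequences (%d original, %d scrambled)\n",
              nrow(x), sum(x$origin == "original"), sum(x$origin == "scrambled")))
  if (nrow(x) > 0) {
    len <- nchar(x$seq)
    cat(sprintf("  lengths %d-%d; labels: %s\n", min(len), max(len),
                paste(names(table(x$label, useNA = "ifany")),
                      table(x$label, useNA = "ifany"),
                      sep = ":", collapse = " ")))
  }
  invisible(x)
}

#' Read DNA sequences from a FASTA file
#'
#' Record ids are taken from the header up to the first whitespace; residues
#' are uppercased and validated against the A/C/G/T/N alphabet. Both
#' single-line and wrapped FASTA dialects are accepted; an empty file yields
#' an empty set.
#'
#' @param path path to a FASTA file.
#' @return A [dna_set] with `origin = "original"` and `NA` labels.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop2("no such file: ", path)
  if (file.size(path) == 0)
    return(dna_set(character(), character()))
  ss <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop2("malformed FASTA in ", path, ": ", conditionMessage(e))
  )
  ids <- sub("\\s.*$", "", names(ss))
  dna_set(ids, as.character(ss))
}

#' Write a sequence set to FASTA
#'
#' @param x sequences (see [dna_set]).
#' @param path output file path; lines are wrapped at 80 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  x <- as_dna_set(x)
  ss <- Biostrings::BStringSet(x$seq)
  names(ss) <- x$id
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Composition-preserving sequence scrambling
#'
#' Generates negative (background) examples by uniform random permutation of
#' each sequence's residues, exactly conserving its nucleotide counts. Each
#' copy draws from an RNG substream derived from `(seed, parent id, copy
#' index)`, so any subset of the output is reproducible independently of
#' generation order.
#'
#' @param x sequences to scramble (see [dna_set]).
#' @param n_copies number of scrambled copies per input sequence (>= 1).
#' @param seed integer seed for the permutation stream.
#' @param label class label assigned to the scrambles (default -1).
#' @return A [dna_set] of `nrow(x) * n_copies` scrambled sequences with ids
#'   `<parent>_scr<j>`, `origin = "scrambled"` and `parent` set.
#' @export
scramble_sequences <- function(x, n_copies = 10L, seed = 1L, label = -1L) {
  x <- as_dna_set(x)
  if (n_copies < 1) stop2("n_copies must be >= 1")
  out_id <- character(nrow(x) * n_copies)
  out_seq <- character(nrow(x) * n_copies)
  out_par <- character(nrow(x) * n_copies)
  pos <- 0L
  for (i in seq_len(nrow(x))) {
    chars <- strsplit(x$seq[i], "", fixed = TRUE)[[1]]
    for (j in seq_len(n_copies)) {
      pos <- pos + 1L
      out_id[pos] <- sprintf("%s_scr%d", x$id[i], j)
      out_seq[pos] <- with_seed(derive_seed(seed, x$id[i], j),
                                paste(sample(chars), collapse = ""))
      out_par[pos] <- x$id[i]
    }
  }
  dna_set(out_id, out_seq, label = label, origin = "scrambled", parent = out_par)
}

#' Genomic background k-mer model
#'
#' Tallies sliding-window contiguous k-mer occurrences over a set of
#' background sequences. Windows containing N contribute to no word;
#' `total_windows` is the number of length-k windows, `sum(len - k + 1)`. A
#' Laplace pseudocount (default 1) keeps every background frequency strictly
#' positive on small backgrounds; set it to 0 to use raw genome frequencies.
#'
#' @param x background sequences (see [dna_set]).
#' @param k word length (>= 1).
#' @param pseudocount non-negative number added to every k-mer count when
#'   frequencies are formed.
#' @return An object of class `kmer_background`: a list with `k`, `counts`
#'   (named integer vector over all 4^k words, lexicographic), `total_windows`
#'   and `pseudocount`.
#' @export
build_background <- function(x, k, pseudocount = 1) {
  x <- as_dna_set(x)
  if (k < 1) stop2("k must be >= 1")
  if (pseudocount < 0) stop2("pseudocount must be non-negative")
  len <- nchar(x$seq)
  if (nrow(x) == 0 || all(len < k))
    stop2("no background sequence of length >= k = ", k)
  keep <- len >= k
  ss <- Biostrings::DNAStringSet(x$seq[keep])
  counts <- colSums(Biostrings::oligonucleotideFrequency(ss, width = k))
  structure(
    list(k = as.integer(k), counts = counts,
         total_windows = sum(len[keep] - k + 1),
         pseudocount = pseudocount),
    class = "kmer_background"
  )
}

#' Background k-mer frequencies
#'
#' `(count + pseudocount) / (total_windows + 4^k * pseudocount)` per word.
#'
#' @param bg a [build_background] model.
#' @return Named numeric vector of length 4^k.
#' @export
background_frequency <- function(bg) {
  stopifnot(inherits(bg, "kmer_background"))
  (bg$counts + bg$pseudocount) /
    (bg$total_windows + 4^bg$k * bg$pseudocount)
}

#' @export
print.kmer_background <- function(x, ...) {
  cat(sprintf("kmer_background: k=%d, %d words, %s windows, pseudocount=%g\n",
              x$k, length(x$counts), format(x$total_windows, big.mark = ","),
              x$pseudocount))
  invisible(x)
}

#' Serialize / read a background model as TSV
#'
#' Two columns (kmer, count) after a header line
#' `#k=<k> total_windows=<n> pseudocount=<p>`.
#'
#' @param bg a [build_background] model.
#' @param path file path.
#' @return `path` (write) or a `kmer_background` (read).
#' @export
write_background <- function(bg, path) {
  stopifnot(inherits(bg, "kmer_background"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#k=%d total_windows=%.0f pseudocount=%.9g",
                     bg$k, bg$total_windows, bg$pseudocount), con)
  utils::write.table(
    data.frame(kmer = names(bg$counts), count = as.integer(bg$counts)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_background
#' @export
read_background <- function(path) {
  header <- readLines(path, n = 1)
  m <- regmatches(header,
                  regexec("^#k=(\\d+) total_windows=(\\d+) pseudocount=([0-9.eE+-]+)$",
                          header))[[1]]
  if (length(m) != 4) stop2("not a background model file: ", path)
  tab <- utils::read.table(path, sep = "\t", skip = 1,
                           col.names = c("kmer", "count"),
                           colClasses = c("character", "numeric"))
  counts <- stats::setNames(tab$count, tab$kmer)
  k <- as.integer(m[2])
  want <- all_kmers(k)
  if (!identical(sort(names(counts)), sort(want)))
    stop2("background file does not cover all 4^k words")
  structure(list(k = k, counts = counts[want],
                 total_windows = as.numeric(m[3]),
                 pseudocount = as.numeric(m[4])),
            class = "kmer_background")
}

# All 4^k words over ACGT in lexicographic order (matches Biostrings).
all_kmers <- function(k) {
  if (k == 0) return("")
  Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
}
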