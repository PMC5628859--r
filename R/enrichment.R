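#' Per-sequence feature-enrichment scores
#'
#' The enrichment score of feature n in a sequence with feature vector x is
#' r(n) = w(n) x(n), the feature's contribution to the SVM decision value
#' (so sum_n r(n) + b = f(x)). Features scoring strictly above the cutoff
#' (default 0.005) are "top-enriched" and selected.
#'
#' @param model a [svm_train] fit.
#' @param X feature matrix restricted to the model's active index, one row
#'   per sequence.
#' @param cutoff enrichment cutoff; selection is strict (`r > cutoff`).
#' @return An object of class `enrichment_profiles`: list with `scores`
#'   (matrix, rows = sequences, columns = active features), `index` (global
#'   feature indices of the columns), `cutoff`, and `selected` (named list of
#'   global index vectors, one per sequence).
#' @export
enrichment_scores <- function(model, X, cutoff = 0.005) {
  stopifnot(inherits(model, "kspec_svm"))
  idx <- attr(X, "index")
  if (!is.null(idx) && !identical(as.integer(idx), as.integer(model$index)))
    stop2("feature index of X does not match the model's active index")
  scores <- sweep(X, 2, model$w, "*")
  rownames(scores) <- rownames(X)
  index <- as.integer(model$index)
  selected <- apply(scores > cutoff, 1, function(r) index[r], simplify = FALSE)
  structure(list(scores = scores, index = index, cutoff = cutoff,
                 selected = selected, b = model$b),
            class = "enrichment_profiles")
}

#' @export
print.enrichment_profiles <- function(x, ...) {
  cat(sprintf("enrichment_profiles: %d sequences x %d features, cutoff %g; %s selected per sequence (median)\n",
              nrow(x$scores), ncol(x$scores), x$cutoff,
              stats::median(lengths(x$selected))))
  invisible(x)
}

#' Gapped k-mer motif fragments
#'
#' Groups a sequence's top-enriched features by dependency model and builds
#' one motif fragment per model: a per-position nucleotide count matrix over
#' the member features (gap positions flagged), rendered like "(A/T)NT".
#' Fragments are candidate pieces of transcription-factor binding motifs and
#' can be exported for comparison against a motif database ([export_meme]).
#'
#' @param profiles an [enrichment_scores] object.
#' @param space the [feature_space] the profile indices refer to.
#' @param ids sequences to process (default all).
#' @return Named list (per sequence) of lists of `motif_fragment` objects;
#'   each has `sequence_id`, `decimal` (gap-mask), `members` (feature pattern
#'   strings), `counts` (4 x k matrix, rows A/C/G/T, NA at gaps), `render`.
#' @export
motif_fragments <- function(profiles, space, ids = NULL) {
  stopifnot(inherits(profiles, "enrichment_profiles"),
            inherits(space, "feature_space"))
  ids <- ids %||% rownames(profiles$scores)
  out <- lapply(ids, function(id) {
    sel <- profiles$selected[[id]]
    if (is.null(sel) || length(sel) == 0) return(list())
    masks <- space$feature_model[sel]
    lapply(split(sel, masks), function(members)
      build_fragment(id, space$feature_model[members[1]],
                     space$feature_names[members], space$k))
  })
  names(out) <- ids
  out
}

build_fragment <- function(sequence_id, decimal, member_patterns, k) {
  counts <- matrix(0, nrow = 4, ncol = k,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  dep <- mask_bits(decimal, k)
  for (pat in member_patterns) {
    chars <- strsplit(pat, "")[[1]]
    for (p in which(dep)) counts[chars[p], p] <- counts[chars[p], p] + 1
  }
  counts[, !dep] <- NA
  structure(
    list(sequence_id = sequence_id, decimal = as.integer(decimal),
         members = member_patterns, counts = counts, k = k,
         render = render_fragment(counts, dep)),
    class = "motif_fragment"
  )
}

render_fragment <- function(counts, dep) {
  paste(vapply(seq_len(ncol(counts)), function(p) {
    if (!dep[p]) return("N")
    nts <- rownames(counts)[counts[, p] > 0]
    if (length(nts) == 1) nts else paste0("(", paste(nts, collapse = "/"), ")")
  }, character(1)), collapse = "")
}

#' Parse a fragment rendering back to per-position nucleotide sets
#'
#' Inverse of the `(A/T)NT`-style rendering; used for round-trip checks and
#' for reading fragments from reports.
#'
#' @param render a fragment string such as `"(A/T)NT"`.
#' @return List of character vectors, one per position; `"N"` for gaps.
#' @export
parse_fragment <- function(render) {
  out <- list()
  i <- 1
  chars <- strsplit(render, "")[[1]]
  while (i <= length(chars)) {
    if (chars[i] == "(") {
      j <- i
      while (chars[j] != ")") j <- j + 1
      out[[length(out) + 1]] <- setdiff(chars[(i + 1):(j - 1)], "/")
      i <- j + 1
    } else {
      out[[length(out) + 1]] <- chars[i]
      i <- i + 1
    }
  }
  out
}

fragment_id <- function(frag) {
  sprintf("%s_m%d_n%d", frag$sequence_id, frag$decimal, length(frag$members))
}

#' @export
print.motif_fragment <- function(x, ...) {
  cat(sprintf("motif_fragment %s: %s (%d member feature%s, mask %d)\n",
              x$sequence_id, x$render, length(x$members),
              if (length(x$members) == 1) "" else "s", x$decimal))
  invisible(x)
}

#' Export motif fragments in MEME minimal format
#'
#' Writes position probability matrices (counts normalized per dependent
#' column; gap columns as uniform 0.25) suitable for external motif-comparison
#' tools. Motif names encode sequence id, gap-mask decimal and member count
#' (`<seq>_m<decimal>_n<members>`).
#'
#' @param fragments a non-empty list of `motif_fragment` objects (a nested
#'   per-sequence list as returned by [motif_fragments] is flattened).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_meme <- function(fragments, path) {
  if (length(fragments) && !inherits(fragments[[1]], "motif_fragment"))
    fragments <- unlist(fragments, recursive = FALSE)
  if (length(fragments) == 0) stop2("no motif fragments to export")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: +", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (frag in fragments) {
    prob <- frag$counts
    for (p in seq_len(ncol(prob))) {
      if (anyNA(prob[, p])) prob[, p] <- 0.25
      else prob[, p] <- prob[, p] / sum(prob[, p])
    }
    writeLines(sprintf("MOTIF %s %s", fragment_id(frag), frag$render), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d",
                       ncol(prob), length(frag$members)), con)
    writeLines(apply(prob, 2, function(col)
      paste(sprintf("%.6f", col), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a motif-comparison hit table
#'
#' Tab-separated columns: fragment id (as written by [export_meme]), database
#' motif id, p-value. Produced by an external motif-comparison tool run
#' against the exported fragments.
#'
#' @param path TSV path (a header line starting with `#` or column names
#'   `fragment_id` is skipped).
#' @return Data frame with `fragment_id`, `motif_id`, `p_value`.
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) && grepl("^fragment_id\\b", lines[1])) lines <- lines[-1]
  if (length(lines) == 0)
    return(data.frame(fragment_id = character(), motif_id = character(),
                      p_value = numeric()))
  tab <- utils::read.table(text = lines, sep = "\t",
                           col.names = c("fragment_id", "motif_id", "p_value"),
                           colClasses = c("character", "character", "numeric"))
  tab
}

#' Discover falsely-enriched features from scrambled positives
#'
#' Sequence composition alone can enrich features that do not represent
#' binding sites. To find them, each positive sequence is replaced by
#' `n_scrambles` composition-preserving scrambled copies; this expanded
#' "false positive" set (against fresh scrambles of the copies as negatives)
#' is used to train the folded-kernel SVM, and the features enriched above
#' the cutoff in each scrambled copy are recorded as false, keyed by the copy
#' and by the parent positive.
#'
#' If a motif-comparison hit table is supplied, only false features whose
#' per-copy motif fragment has a database hit with p-value below
#' `hit_p_cutoff` are retained as false: a background pattern that
#' consistently resembles a known motif is exactly the kind of spurious
#' enrichment worth removing, while patterns with no database resemblance are
#' dropped from the false set as insignificant.
#'
#' @param positives the positive sequence set (see [dna_set]).
#' @param space a [feature_space].
#' @param bg background model used for featurization; `NULL` builds one from
#'   the scrambled training data itself.
#' @param n_scrambles scrambled copies per positive (default 10).
#' @param n_neg_per_copy fresh scrambles of each copy used as negatives
#'   (default 1, giving a balanced training set).
#' @param C,tol SVM parameters (see [svm_train]).
#' @param cutoff enrichment cutoff (default 0.005, strict >).
#' @param hits optional hit table (data frame from [read_hit_table]).
#' @param hit_p_cutoff significance threshold for database hits (default 1e-3).
#' @param seed RNG seed for the scramble streams.
#' @return An object of class `feature_filter`: list with `false_features`
#'   (per scrambled-copy id, global feature indices), `false_models_by_parent`
#'   (per positive id, implicated gap-mask decimals), `cutoff`, `n_scrambles`.
#' @export
discover_false_features <- function(positives, space, bg = NULL,
                                    n_scrambles = 10L, n_neg_per_copy = 1L,
                                    C = 1, tol = 1e-3, cutoff = 0.005,
                                    hits = NULL, hit_p_cutoff = 1e-3,
                                    seed = 1L) {
  positives <- as_dna_set(positives)
  false_pos <- scramble_sequences(positives, n_copies = n_scrambles,
                                  seed = seed, label = 1L)
  negatives <- scramble_sequences(false_pos, n_copies = n_neg_per_copy,
                                  seed = derive_seed(seed, "false-negatives"),
                                  label = -1L)
  train_set <- rbind(false_pos, negatives)
  class(train_set) <- c("dna_set", "data.frame")
  X <- featurize(train_set, space, bg = bg)
  model <- svm_train(X, train_set$label, C = C, tol = tol)
  profiles <- enrichment_scores(model, X[train_set$label == 1L, , drop = FALSE],
                                cutoff = cutoff)
  false_features <- profiles$selected
  if (!is.null(hits)) {
    known <- unique(hits$fragment_id)
    frag_all <- unlist(lapply(names(false_features), function(id) {
      fr <- motif_fragments(profiles, space, ids = id)[[1]]
      vapply(fr, fragment_id, character(1))
    }))
    unknown <- setdiff(hits$fragment_id, frag_all)
    if (length(unknown))
      stop2("hit table references unknown fragment id(s): ",
            paste(utils::head(unknown, 5), collapse = ", "))
    sig <- unique(hits$fragment_id[hits$p_value < hit_p_cutoff])
    false_features <- lapply(names(false_features), function(id) {
      sel <- false_features[[id]]
      if (length(sel) == 0) return(sel)
      frs <- motif_fragments(profiles, space, ids = id)[[1]]
      sig_masks <- vapply(frs, function(f)
        if (fragment_id(f) %in% sig) f$decimal else NA_integer_, integer(1))
      sig_masks <- sig_masks[!is.na(sig_masks)]
      sel[space$feature_model[sel] %in% sig_masks]
    })
    names(false_features) <- names(profiles$selected)
  }
  parents <- false_pos$parent[match(names(false_features), false_pos$id)]
  false_models_by_parent <- lapply(split(false_features, parents), function(sets)
    sort(unique(space$feature_model[unlist(sets)])))
  structure(
    list(false_features = false_features,
         false_models_by_parent = false_models_by_parent,
         cutoff = cutoff, n_scrambles = n_scrambles,
         hits_used = !is.null(hits)),
    class = "feature_filter"
  )
}

#' @export
print.feature_filter <- function(x, ...) {
  cat(sprintf("feature_filter: %d scrambled copies over %d positives; %d false features total%s\n",
              length(x$false_features), length(x$false_models_by_parent),
              length(unique(unlist(x$false_features))),
              if (x$hits_used) " (hit-table refined)" else ""))
  invisible(x)
}

#' False-discovery feature elimination
#'
#' Zeroes each positive sequence's enrichment scores at features implicated by
#' its own scrambled copies, then pools the surviving selections into the
#' high-confidence feature index set (the constrained feature map). In
#' `by_model` mode (default) a feature is eliminated when its gap mask belongs
#' to any falsely-enriched feature of the sequence's copies; `by_feature`
#' eliminates only exact feature-index matches.
#'
#' @param profiles [enrichment_scores] of the positive sequences under the
#'   main model.
#' @param filter a [discover_false_features] filter covering every sequence in
#'   `profiles`.
#' @param space the [feature_space].
#' @param mode `"by_model"` or `"by_feature"`.
#' @return List with `profiles` (scores after elimination, reselected) and
#'   `surviving_index`: the union over positives of surviving selected
#'   indices, intersected with the full feature index.
#' @export
eliminate_features <- function(profiles, filter, space,
                               mode = c("by_model", "by_feature")) {
  mode <- match.arg(mode)
  stopifnot(inherits(profiles, "enrichment_profiles"),
            inherits(filter, "feature_filter"))
  ids <- rownames(profiles$scores)
  missing <- setdiff(ids, names(filter$false_models_by_parent))
  if (length(missing))
    stop2("no scrambled copies in the filter for sequence(s): ",
          paste(utils::head(missing, 5), collapse = ", "))
  scores <- profiles$scores
  index <- profiles$index
  for (id in ids) {
    if (mode == "by_model") {
      bad_models <- filter$false_models_by_parent[[id]]
      drop <- space$feature_model[index] %in% bad_models
    } else {
      copies <- names(filter$false_features)[
        startsWith(names(filter$false_features), paste0(id, "_scr"))]
      bad_feats <- unique(unlist(filter$false_features[copies]))
      drop <- index %in% bad_feats
    }
    scores[id, drop] <- 0
  }
  selected <- apply(scores > profiles$cutoff, 1, function(r) index[r],
                    simplify = FALSE)
  surviving <- sort(unique(unlist(selected)))
  out <- structure(list(scores = scores, index = index,
                        cutoff = profiles$cutoff, selected = selected,
                        b = profiles$b),
                   class = "enrichment_profiles")
  list(profiles = out, surviving_index = as.integer(surviving))
}

#' Write enrichment profiles as TSV
#'
#' Long format: one row per (sequence, selected feature) with its score.
#'
#' @param profiles an [enrichment_scores] object.
#' @param space the [feature_space] (for pattern names).
#' @param path output path.
#' @export
write_profiles <- function(profiles, space, path) {
  rows <- do.call(rbind, lapply(rownames(profiles$scores), function(id) {
    sel <- profiles$selected[[id]]
    if (length(sel) == 0) return(NULL)
    data.frame(sequence_id = id,
               feature = space$feature_names[sel],
               score = sprintf("%.9g",
                               profiles$scores[id, match(sel, profiles$index)]))
  }))
  if (is.null(rows))
    rows <- data.frame(sequence_id = character(), feature = character(),
                       score = character())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
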