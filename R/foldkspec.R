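#' Fit a folded k-spectrum kernel SVM to a positive sequence set
#'
#' The one-stop modelling interface. Given a set of putative regulatory
#' sequences (the positive class), the function (i) generates matched
#' negatives by composition-preserving scrambling unless negatives are
#' supplied, (ii) builds the background k-mer model (from a user-supplied
#' background, or from the union of all training sequences), (iii) maps every
#' sequence to the folded k-spectrum — background-normalized relative
#' frequencies of all 4*5^(k-1) gapped k-mers — and (iv) trains a soft-margin
#' linear SVM on those explicit features. Per-positive feature-enrichment
#' profiles are computed from the fit; with `feature_elimination = TRUE` the
#' false-discovery filter is run (scrambled positives retrained and their
#' spurious enrichments removed) and the SVM is refit on the surviving
#' high-confidence feature set.
#'
#' @param positives positive sequences: a [dna_set], named character vector,
#'   or FASTA path.
#' @param negatives optional negative sequences; default scrambles each
#'   positive `n_scrambles` times.
#' @param k word length (default 6, a sufficient and practical choice for
#'   regulatory sequence discrimination).
#' @param C SVM soft-margin cost (default 1).
#' @param kernel `"folded"` (all 2^(k-1) gapped models) or `"contiguous"`
#'   (classical k-spectrum).
#' @param n_scrambles scrambled negatives per positive (default 10).
#' @param cutoff enrichment cutoff (default 0.005, strict >).
#' @param background optional background sequences or a prebuilt
#'   [build_background] model.
#' @param pseudocount Laplace pseudocount for background frequencies.
#' @param feature_elimination run the false-discovery feature elimination and
#'   refit on the constrained map (default FALSE).
#' @param elimination_mode `"by_model"` or `"by_feature"` (see
#'   [eliminate_features]).
#' @param hits optional motif-database hit table for the filter (see
#'   [discover_false_features]).
#' @param tol SVM solver tolerance.
#' @param seed RNG seed for scramble generation.
#' @return An object of class `foldkspec`: list with the feature `space`,
#'   `background` model, trained `svm` (class `kspec_svm`), per-positive
#'   enrichment `profiles`, `filter` and `surviving_index` (when elimination
#'   ran), the training `data`, and the call. Methods: `print`, `summary`,
#'   `coef`, `predict`, `plot`.
#' @examples
#' spec <- plant_spec("GANNTC", plants_per_sequence = 3, mutation_rate = 0.1)
#' dat <- make_dataset(n_pos = 8, length = 300, spec = spec,
#'                     n_scrambles = 4, seed = 1)
#' fit <- foldkspec(dat[dat$label == 1, ], negatives = dat[dat$label == -1, ],
#'                  k = 3, seed = 1)
#' fit
#' head(sort(coef(fit), decreasing = TRUE))
#' @export
foldkspec <- function(positives, negatives = NULL, k = 6L, C = 1,
                      kernel = c("folded", "contiguous"),
                      n_scrambles = 10L, cutoff = 0.005,
                      background = NULL, pseudocount = 1,
                      feature_elimination = FALSE,
                      elimination_mode = c("by_model", "by_feature"),
                      hits = NULL, tol = 1e-3, seed = 1L) {
  kernel <- match.arg(kernel)
  elimination_mode <- match.arg(elimination_mode)
  positives <- as_dna_set(positives)
  if (nrow(positives) == 0) stop2("no positive sequences")
  positives$label <- 1L
  if (is.null(negatives)) {
    negatives <- scramble_sequences(positives, n_copies = n_scrambles,
                                    seed = seed)
  } else {
    negatives <- as_dna_set(negatives)
    negatives$label <- -1L
  }
  dataset <- rbind(positives, negatives)
  class(dataset) <- c("dna_set", "data.frame")
  space <- feature_space(k)
  bg <- if (inherits(background, "kmer_background")) background
        else build_background(if (is.null(background)) dataset
                              else as_dna_set(background),
                              k, pseudocount = pseudocount)
  X <- featurize(dataset, space, bg = bg)
  X <- restrict_to_kernel(X, space, kernel)
  model <- svm_train(X, dataset$label, C = C, tol = tol, seed = seed)
  Xpos <- restrict_rows(X, dataset$label == 1L)
  profiles <- enrichment_scores(model, Xpos, cutoff = cutoff)
  filter <- NULL
  surviving_index <- NULL
  if (feature_elimination) {
    filter <- discover_false_features(positives, space, bg = bg,
                                      n_scrambles = n_scrambles, C = C,
                                      tol = tol, cutoff = cutoff, hits = hits,
                                      seed = derive_seed(seed, "filter"))
    elim <- eliminate_features(profiles, filter, space, mode = elimination_mode)
    surviving_index <- elim$surviving_index
    if (length(surviving_index)) {
      Xh <- restrict_spectrum(X, surviving_index)
      model <- svm_train(Xh, dataset$label, C = C, tol = tol, seed = seed)
      profiles <- enrichment_scores(model, restrict_rows(Xh, dataset$label == 1L),
                                    cutoff = cutoff)
    } else {
      warning("feature elimination removed every enriched feature; keeping the unconstrained model")
    }
  }
  structure(
    list(call = match.call(), k = as.integer(k), kernel = kernel, C = C,
         cutoff = cutoff, space = space, background = bg, svm = model,
         profiles = profiles, filter = filter,
         surviving_index = surviving_index,
         feature_elimination = feature_elimination,
         data = dataset, seed = seed, tol = tol),
    class = "foldkspec"
  )
}

# row subset preserving spectrum attributes
restrict_rows <- function(X, rows) {
  out <- X[rows, , drop = FALSE]
  spectrum_attrs(out, attr(X, "k"), attr(X, "stage"),
                 attr(X, "seq_length")[rows], attr(X, "index"))
}

#' @export
print.foldkspec <- function(x, ...) {
  cat(sprintf("foldkspec: %s k-spectrum kernel SVM, k = %d\n",
              x$kernel, x$k))
  cat(sprintf("  features: %d of %d%s\n", length(x$svm$w),
              x$space$n_features,
              if (x$feature_elimination && !is.null(x$surviving_index))
                sprintf(" (feature elimination kept %d)",
                        length(x$surviving_index)) else ""))
  cat(sprintf("  training set: %d positives, %d negatives; C = %g\n",
              x$svm$n_pos, x$svm$n_neg, x$C))
  d <- decision_values(x$svm,
                       restrict_to_model_columns(x))
  acc <- mean(ifelse(d > 0, 1L, -1L) == x$data$label)
  cat(sprintf("  training accuracy: %.3f\n", acc))
  invisible(x)
}

restrict_to_model_columns <- function(x) {
  X <- featurize(x$data, x$space, bg = x$background)
  restrict_spectrum(X, x$svm$index)
}

#' @export
summary.foldkspec <- function(object, top = 10L, ...) {
  w <- sort(object$svm$w, decreasing = TRUE)
  sel_per_seq <- lengths(object$profiles$selected)
  model_of_sel <- object$space$feature_model[unlist(object$profiles$selected)]
  per_model <- sort(table(model_of_sel), decreasing = TRUE)
  structure(
    list(fit = object, top_weights = utils::head(w, top),
         selected_per_sequence = sel_per_seq,
         selected_per_model = per_model),
    class = "summary.foldkspec"
  )
}

#' @export
print.summary.foldkspec <- function(x, ...) {
  print(x$fit)
  cat("\nTop-weighted features:\n")
  print(round(x$top_weights, 6))
  cat(sprintf("\nEnriched features per positive (cutoff %g): median %g, range %d-%d\n",
              x$fit$cutoff, stats::median(x$selected_per_sequence),
              min(x$selected_per_sequence), max(x$selected_per_sequence)))
  if (length(x$selected_per_model)) {
    cat("Selected features per gapped model (mask decimal: count):\n")
    print(utils::head(x$selected_per_model, 10))
  }
  invisible(x)
}

#' @export
coef.foldkspec <- function(object, ...) object$svm$w

#' Predict classes or decision values for new sequences
#'
#' New sequences are mapped through the fitted feature space with the
#' training background model, restricted to the model's active feature set,
#' and scored with the learned (w, b).
#'
#' @param object a [foldkspec] fit.
#' @param newdata sequences (see [dna_set]); defaults to the training data.
#' @param type `"class"` (+1/-1; a decision value of exactly 0 gives -1) or
#'   `"decision"`.
#' @param ... ignored.
#' @export
predict.foldkspec <- function(object, newdata = NULL,
                              type = c("class", "decision"), ...) {
  type <- match.arg(type)
  newdata <- if (is.null(newdata)) object$data else as_dna_set(newdata)
  X <- featurize(newdata, object$space, bg = object$background)
  X <- restrict_spectrum(X, object$svm$index)
  predict(object$svm, X, type = type)
}

#' @export
plot.foldkspec <- function(x, top = 20L, ...) {
  w <- sort(x$svm$w, decreasing = TRUE)
  w <- utils::head(w, top)
  op <- graphics::par(mar = c(5, 7, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(w), horiz = TRUE, las = 1,
                    xlab = "SVM weight",
                    main = sprintf("Top %d features (%s kernel, k=%d)",
                                   length(w), x$kernel, x$k), ...)
  invisible(x)
}
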