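#' Stratified fold assignment
#'
#' Randomly partitions examples into `folds` disjoint subsets retaining
#' (approximately) equal class proportions: per-fold class counts differ from
#' exact proportionality by at most one example. When `group` is supplied
#' (e.g. the parent id linking a positive to its scrambled copies), whole
#' groups are assigned to a single fold, so matched scrambles never leak
#' across the train/test split.
#'
#' @param labels class labels in \{+1, -1\}.
#' @param folds number of folds (default 10).
#' @param seed RNG seed.
#' @param group optional grouping vector (same length as labels); `NA` means
#'   ungrouped.
#' @return Integer vector of fold ids in 1..folds, one per example.
#' @export
stratified_folds <- function(labels, folds = 10L, seed = NULL, group = NULL) {
  labels <- as.integer(labels)
  if (folds < 2) stop2("folds must be >= 2")
  if (length(unique(labels)) < 2) stop2("both classes must be present")
  fold <- integer(length(labels))
  with_seed(seed, {
    if (!is.null(group) && any(!is.na(group))) {
      grouped <- !is.na(group)
      units <- unique(group[grouped])
      if (length(units) < folds)
        stop2("fewer groups (", length(units), ") than folds (", folds, ")")
      unit_fold <- stats::setNames(
        rep_len(seq_len(folds), length(units))[sample.int(length(units))],
        units)
      fold[grouped] <- unit_fold[group[grouped]]
      for (cls in unique(labels[!grouped])) {
        i <- which(!grouped & labels == cls)
        fold[i] <- rep_len(seq_len(folds), length(i))[sample.int(length(i))]
      }
    } else {
      for (cls in unique(labels)) {
        i <- which(labels == cls)
        if (length(i) < folds)
          stop2("folds (", folds, ") exceeds size of class ", cls,
                " (", length(i), ")")
        fold[i] <- rep_len(seq_len(folds), length(i))[sample.int(length(i))]
      }
    }
  })
  fold
}

#' ROC and precision-recall curves with AUC
#'
#' Threshold sweep over the unique decision scores (ties share a threshold),
#' trapezoidal integration for both areas. The ROC curve plots false positive
#' rate FP/(FP+TN) against true positive rate TP/(TP+FN); the PR curve plots
#' precision TP/(TP+FP) against recall (= TPR).
#'
#' @param scores numeric decision values (larger = more positive).
#' @param labels class labels in \{+1, -1\}, both present.
#' @return List with `roc` (data frame fpr/tpr), `pr` (recall/precision),
#'   `auc`, `aucpr`.
#' @export
roc_pr <- function(scores, labels) {
  y <- as.integer(labels) == 1L
  if (!any(y) || all(y)) stop2("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- y[o]
  tp <- cumsum(y)
  fp <- cumsum(!y)
  last <- !duplicated(s, fromLast = TRUE)  # one point per distinct threshold
  tp <- tp[last]
  fp <- fp[last]
  P <- sum(y)
  Nn <- sum(!y)
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / Nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  rec <- c(0, tp / P)
  prec <- c((tp / (tp + fp))[1], tp / (tp + fp))
  aucpr <- sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr),
       pr = data.frame(recall = rec, precision = prec),
       auc = auc, aucpr = aucpr)
}

# Shared featurization for the CV engine: full folded matrix (the contiguous
# kernel is its restriction to the contiguous-model columns).
prepare_features <- function(dataset, k, bg = NULL, space = NULL,
                             pseudocount = 1) {
  dataset <- as_dna_set(dataset)
  space <- space %||% feature_space(k)
  bg <- bg %||% build_background(dataset, k, pseudocount = pseudocount)
  X <- featurize(dataset, space, bg = bg)
  list(dataset = dataset, space = space, bg = bg, X = X)
}

restrict_to_kernel <- function(X, space, kernel) {
  if (kernel == "contiguous") restrict_spectrum(X, space$contiguous_index)
  else X
}

#' One pass of stratified k-fold cross-validation
#'
#' Splits the dataset into stratified folds (each positive's scrambled copies
#' travel with it), trains the SVM on 9/10 of the data and scores the held-out
#' fold, so every sequence is tested exactly once. With
#' `feature_elimination = TRUE` the false-feature filter and the
#' high-confidence index set are derived from the training folds only, then
#' applied to both train and test featurization.
#'
#' @param dataset labeled sequences (positives `+1` with their scrambled
#'   negatives `-1` linked by `parent`).
#' @param k word length (default 6).
#' @param kernel `"folded"` (all gapped models) or `"contiguous"` (classical
#'   k-spectrum).
#' @param folds,C,cutoff,tol,seed as elsewhere.
#' @param feature_elimination apply the false-discovery filter inside each
#'   fold.
#' @param n_scrambles scramble multiplicity used by the filter.
#' @param prepared optional precomputed [prepare_features] result (internal
#'   reuse across repeats).
#' @return Data frame with `id`, `label`, `fold`, `decision`, `predicted`.
#' @export
run_cv_once <- function(dataset, k = 6L, kernel = c("folded", "contiguous"),
                        folds = 10L, C = 1, cutoff = 0.005, tol = 1e-3,
                        feature_elimination = FALSE, n_scrambles = 10L,
                        seed = NULL, prepared = NULL) {
  kernel <- match.arg(kernel)
  prep <- prepared %||% prepare_features(dataset, k)
  dataset <- prep$dataset
  space <- prep$space
  X <- restrict_to_kernel(prep$X, space, kernel)
  fold <- stratified_folds(dataset$label, folds = folds, seed = seed,
                           group = ifelse(is.na(dataset$parent),
                                          dataset$id, dataset$parent))
  K <- tcrossprod(X)   # linear Gram, computed once and subset per fold
  decision <- numeric(nrow(dataset))
  for (f in seq_len(folds)) {
    test <- fold == f
    Xtr <- X[!test, , drop = FALSE]
    Xte <- X[test, , drop = FALSE]
    atr <- attr(X, "index")
    Xtr <- spectrum_attrs(Xtr, attr(X, "k"), attr(X, "stage"),
                          attr(X, "seq_length")[!test], atr)
    Xte <- spectrum_attrs(Xte, attr(X, "k"), attr(X, "stage"),
                          attr(X, "seq_length")[test], atr)
    if (feature_elimination) {
      train_pos <- dataset[!test & dataset$label == 1L, , drop = FALSE]
      class(train_pos) <- c("dna_set", "data.frame")
      filt <- discover_false_features(
        train_pos, space, bg = prep$bg, n_scrambles = n_scrambles,
        C = C, tol = tol, cutoff = cutoff,
        seed = derive_seed(seed %||% 0L, "cv-filter", f))
      main <- svm_train(Xtr, dataset$label[!test], C = C, tol = tol,
                        gram = K[!test, !test])
      prof <- enrichment_scores(
        main, Xtr[dataset$label[!test] == 1L, , drop = FALSE], cutoff = cutoff)
      attr_idx <- attr(Xtr, "index")
      surv <- eliminate_features(prof, filt, space)$surviving_index
      surv <- intersect(surv, attr_idx)
      if (length(surv) == 0) surv <- attr_idx   # degenerate: keep everything
      Xtr <- restrict_spectrum(Xtr, surv)
      Xte <- restrict_spectrum(Xte, surv)
      model <- svm_train(Xtr, dataset$label[!test], C = C, tol = tol)
    } else {
      model <- svm_train(Xtr, dataset$label[!test], C = C, tol = tol,
                         gram = K[!test, !test])
    }
    decision[test] <- decision_values(model, Xte)
  }
  data.frame(id = dataset$id, label = dataset$label, fold = fold,
             decision = decision,
             predicted = ifelse(decision > 0, 1L, -1L),
             stringsAsFactors = FALSE)
}

#' Repeated cross-validation with false-negative call accounting
#'
#' Repeats [run_cv_once] with a fresh random partition each time, accumulating
#' per-sequence false-negative (positives) and false-positive (negatives)
#' call counts and per-repeat ROC/PR curves with their areas. The cumulative
#' FN count of a positive over the repeats measures how consistently the
#' classifier detects it when held out.
#'
#' @inheritParams run_cv_once
#' @param repeats number of randomized CV repetitions (default 100).
#' @param keep_curves retain per-repeat ROC/PR point sets (default TRUE).
#' @return An object of class `kspec_cv`: list with `per_sequence` (id, label,
#'   tested, fn, fp), `per_repeat` (repeat, auc, aucpr), `auc_avg`,
#'   `aucpr_avg`, `roc`/`pr` curve lists, and the configuration.
#' @export
repeat_cv <- function(dataset, k = 6L, kernel = c("folded", "contiguous"),
                      folds = 10L, repeats = 100L, C = 1, cutoff = 0.005,
                      tol = 1e-3, feature_elimination = FALSE,
                      n_scrambles = 10L, seed = 1L, keep_curves = TRUE,
                      prepared = NULL) {
  kernel <- match.arg(kernel)
  prep <- prepared %||% prepare_features(dataset, k)
  n <- nrow(prep$dataset)
  fn <- fp <- stats::setNames(integer(n), prep$dataset$id)
  per_repeat <- data.frame(repeat_ = seq_len(repeats), auc = NA_real_,
                           aucpr = NA_real_)
  roc <- pr <- if (keep_curves) vector("list", repeats) else NULL
  for (r in seq_len(repeats)) {
    res <- run_cv_once(NULL, k = k, kernel = kernel, folds = folds, C = C,
                       cutoff = cutoff, tol = tol,
                       feature_elimination = feature_elimination,
                       n_scrambles = n_scrambles,
                       seed = derive_seed(seed, "cv-repeat", r),
                       prepared = prep)
    miss <- res$predicted != res$label
    fn <- fn + (miss & res$label == 1L)
    fp <- fp + (miss & res$label == -1L)
    curves <- roc_pr(res$decision, res$label)
    per_repeat$auc[r] <- curves$auc
    per_repeat$aucpr[r] <- curves$aucpr
    if (keep_curves) {
      roc[[r]] <- curves$roc
      pr[[r]] <- curves$pr
    }
  }
  structure(
    list(per_sequence = data.frame(id = prep$dataset$id,
                                   label = prep$dataset$label,
                                   tested = repeats, fn = as.integer(fn),
                                   fp = as.integer(fp),
                                   stringsAsFactors = FALSE),
         per_repeat = per_repeat,
         auc_avg = mean(per_repeat$auc), aucpr_avg = mean(per_repeat$aucpr),
         roc = roc, pr = pr,
         config = list(k = k, kernel = kernel, folds = folds,
                       repeats = repeats, C = C, cutoff = cutoff,
                       feature_elimination = feature_elimination,
                       seed = seed)),
    class = "kspec_cv"
  )
}

#' @export
print.kspec_cv <- function(x, ...) {
  cat(sprintf("kspec_cv: %s kernel, k=%d, %d-fold x %d repeats%s\n",
              x$config$kernel, x$config$k, x$config$folds, x$config$repeats,
              if (x$config$feature_elimination) " (feature elimination)" else ""))
  cat(sprintf("  AUC_avg = %.4f, AUCPR_avg = %.4f\n", x$auc_avg, x$aucpr_avg))
  pos <- x$per_sequence[x$per_sequence$label == 1L, ]
  cat(sprintf("  positives with FN calls: %d of %d (max FN %d/%d)\n",
              sum(pos$fn > 0), nrow(pos), max(pos$fn), x$config$repeats))
  invisible(x)
}

#' @export
plot.kspec_cv <- function(x, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  curves <- if (which == "roc") x$roc else x$pr
  if (is.null(curves)) stop2("curves were not retained (keep_curves = FALSE)")
  xlab <- if (which == "roc") "False positive rate" else "Recall"
  ylab <- if (which == "roc") "True positive rate" else "Precision"
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1), xlab = xlab,
                 ylab = ylab,
                 main = sprintf("%s kernel (k=%d), %d repeats",
                                x$config$kernel, x$config$k, x$config$repeats))
  for (cv in curves)
    graphics::lines(cv[[1]], cv[[2]], col = grDevices::adjustcolor("steelblue", 0.4))
  invisible(x)
}

#' Assign positives to detection groups
#'
#' A positive is "detected" by a kernel when its cumulative FN call rate does
#' not exceed the cutoff (strictly more than `rate_cutoff * repeats` FN calls
#' means undetected, so a boundary count of exactly 10/100 still counts as
#' detected). Group 1: detected by the folded kernel only; Group 2: by
#' neither; Group 3: by both; Group 0: detected by the contiguous kernel only
#' (expected empty, since the contiguous features are a subset of the folded
#' ones).
#'
#' @param fn_folded,fn_contiguous named FN counts per positive id (same ids).
#' @param repeats number of CV repetitions the counts accumulate over.
#' @param rate_cutoff FN call-rate cutoff (default 0.10).
#' @return An object of class `group_assignment`: list of id vectors
#'   `group1`, `group2`, `group3`, `group0` partitioning the positives.
#' @export
assign_groups <- function(fn_folded, fn_contiguous, repeats,
                          rate_cutoff = 0.10) {
  if (!setequal(names(fn_folded), names(fn_contiguous)))
    stop2("FN tables cover different sequence ids")
  ids <- names(fn_folded)
  fc <- fn_contiguous[ids]
  detected_f <- !(fn_folded > rate_cutoff * repeats)
  detected_c <- !(fc > rate_cutoff * repeats)
  structure(
    list(group1 = ids[detected_f & !detected_c],
         group2 = ids[!detected_f & !detected_c],
         group3 = ids[detected_f & detected_c],
         group0 = ids[!detected_f & detected_c],
         repeats = repeats, rate_cutoff = rate_cutoff),
    class = "group_assignment"
  )
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("group_assignment (FN > %g%% of %d repeats = undetected):\n",
              100 * x$rate_cutoff, x$repeats))
  cat(sprintf("  Group 1 (folded only):      %d\n", length(x$group1)))
  cat(sprintf("  Group 2 (neither):          %d\n", length(x$group2)))
  cat(sprintf("  Group 3 (both):             %d\n", length(x$group3)))
  cat(sprintf("  Group 0 (contiguous only):  %d\n", length(x$group0)))
  invisible(x)
}

#' Serialize a cross-validation result
#'
#' Writes per-sequence FN/FP counts, per-repeat AUC/AUCPR, and (if retained)
#' ROC/PR point sets as TSV files sharing a path prefix.
#'
#' @param cv a [repeat_cv] result.
#' @param prefix output path prefix (files `<prefix>_per_sequence.tsv`,
#'   `<prefix>_per_repeat.tsv`, `<prefix>_roc.tsv`, `<prefix>_pr.tsv`).
#' @export
write_cv_result <- function(cv, prefix) {
  stopifnot(inherits(cv, "kspec_cv"))
  utils::write.table(cv$per_sequence, paste0(prefix, "_per_sequence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(repeat_ = cv$per_repeat$repeat_,
               auc = sprintf("%.9g", cv$per_repeat$auc),
               aucpr = sprintf("%.9g", cv$per_repeat$aucpr)),
    paste0(prefix, "_per_repeat.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cv$roc)) {
    flat <- function(lst, names2) do.call(rbind, lapply(seq_along(lst), function(r)
      cbind(repeat_ = r, stats::setNames(lst[[r]], names2))))
    utils::write.table(flat(cv$roc, c("fpr", "tpr")), paste0(prefix, "_roc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(flat(cv$pr, c("recall", "precision")),
                       paste0(prefix, "_pr.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}
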