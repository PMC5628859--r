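test_that("stratified folds are disjoint, exhaustive and class-balanced", {
  labels <- c(rep(1L, 10), rep(-1L, 10))
  f <- stratified_folds(labels, folds = 10, seed = 1)
  expect_equal(sort(unique(f)), 1:10)
  for (k in 1:10) {
    expect_equal(sum(f == k & labels == 1), 1L)
    expect_equal(sum(f == k & labels == -1), 1L)
  }
  # a realistic CRM-study shape: 127 positives, 10 scrambles each
  labels2 <- c(rep(1L, 127), rep(-1L, 1270))
  f2 <- stratified_folds(labels2, folds = 10, seed = 2)
  pos_per_fold <- table(f2[labels2 == 1])
  neg_per_fold <- table(f2[labels2 == -1])
  expect_true(all(pos_per_fold %in% c(12L, 13L)))
  expect_true(all(neg_per_fold == 127L))
  # determinism
  expect_identical(stratified_folds(labels2, 10, seed = 2), f2)
  expect_false(identical(stratified_folds(labels2, 10, seed = 3), f2))
  expect_error(stratified_folds(labels, folds = 11), "exceeds")
  expect_error(stratified_folds(rep(1L, 5), folds = 2), "both classes")
})

test_that("grouped folds keep scrambles with their parent", {
  dat <- separable_dataset(n_pos = 12, length = 150, seed = 51, n_scrambles = 4)
  grp <- ifelse(is.na(dat$parent), dat$id, dat$parent)
  f <- stratified_folds(dat$label, folds = 4, seed = 5, group = grp)
  for (u in unique(grp))
    expect_equal(length(unique(f[grp == u])), 1L)
  # positives spread evenly across folds
  expect_true(all(table(f[dat$label == 1]) == 3L))
})

test_that("roc_pr handles perfect, reversed and tied rankings", {
  perfect <- roc_pr(c(2, 1, -1, -2), c(1, 1, -1, -1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$aucpr, 1)
  reversed <- roc_pr(c(-2, -1, 1, 2), c(1, 1, -1, -1))
  expect_equal(reversed$auc, 0)
  tied <- roc_pr(c(1, 1, 1, 1), c(1, 1, -1, -1))
  expect_equal(tied$auc, 0.5)
  expect_error(roc_pr(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(52)
  scores <- rnorm(60)
  labels <- ifelse(scores + rnorm(60) > 0, 1L, -1L)
  if (length(unique(labels)) < 2) labels[1] <- -labels[1]
  base <- roc_pr(scores, labels)
  for (tr in list(function(s) 3 * s + 7, function(s) exp(s),
                  function(s) s^3 + s)) {
    expect_equal(roc_pr(tr(scores), labels)$auc, base$auc)
    expect_equal(roc_pr(tr(scores), labels)$aucpr, base$aucpr)
  }
})

test_that("hand-rolled AUC agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(53)
  for (i in 1:5) {
    scores <- round(rnorm(80), 1)  # rounding forces ties
    labels <- ifelse(rnorm(80) + scores / 2 > 0, 1L, -1L)
    if (length(unique(labels)) < 2) next
    ours <- roc_pr(scores, labels)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("one CV repeat tests every sequence exactly once", {
  dat <- separable_dataset(n_pos = 10, length = 150, seed = 54, n_scrambles = 3)
  res <- run_cv_once(dat, k = 3, folds = 5, seed = 9)
  expect_equal(sort(res$id), sort(dat$id))
  expect_equal(nrow(res), nrow(dat))
  expect_false(any(duplicated(res$id)))
  expect_equal(sort(unique(res$fold)), 1:5)
})

test_that("a strongly separable fixture is classified perfectly in CV", {
  dat <- separable_dataset(n_pos = 10, length = 200, seed = 55, n_scrambles = 3)
  res <- run_cv_once(dat, k = 3, folds = 5, seed = 9)
  expect_equal(res$predicted, res$label)
  expect_equal(roc_pr(res$decision, res$label)$auc, 1)
})

test_that("randomized labels give chance-level CV accuracy", {
  set.seed(56)
  accs <- vapply(1:8, function(s) {
    bg <- generate_background(12, 150, seed = s)
    bg$label <- rep(c(1L, -1L), 6)  # arbitrary labels on pure noise
    res <- run_cv_once(bg, k = 3, folds = 4, seed = s)
    mean(res$predicted == res$label)
  }, numeric(1))
  # binomial null: mean accuracy ~ 0.5, se ~ 0.05 across 8 runs of 12
  expect_lt(abs(mean(accs) - 0.5), 3 * 0.5 / sqrt(8 * 12))
})

test_that("repeat_cv accumulates FN counts and per-repeat curves", {
  dat <- separable_dataset(n_pos = 8, length = 200, seed = 57, n_scrambles = 3)
  cv <- repeat_cv(dat, k = 3, folds = 4, repeats = 3, seed = 11)
  expect_s3_class(cv, "kspec_cv")
  expect_equal(nrow(cv$per_sequence), nrow(dat))
  expect_true(all(cv$per_sequence$tested == 3L))
  expect_true(all(cv$per_sequence$fn >= 0 & cv$per_sequence$fn <= 3L))
  expect_true(all(cv$per_sequence$fn[cv$per_sequence$label == -1L] == 0L))
  expect_equal(nrow(cv$per_repeat), 3L)
  expect_true(all(cv$per_repeat$auc >= 0 & cv$per_repeat$auc <= 1))
  expect_equal(cv$auc_avg, 1)           # separable fixture
  expect_equal(cv$aucpr_avg, 1)
  # repeats = 1 reduces to run_cv_once under the same derived seed
  cv1 <- repeat_cv(dat, k = 3, folds = 4, repeats = 1, seed = 11)
  res1 <- run_cv_once(dat, k = 3, folds = 4,
                      seed = foldkspec:::derive_seed(11, "cv-repeat", 1))
  expect_equal(cv1$per_sequence$fn[cv1$per_sequence$label == 1],
               as.integer(res1$predicted != res1$label)[res1$label == 1])
})

test_that("group assignment applies the strict >10% FN call-rate rule", {
  fnf <- c(a = 5, b = 100, c = 3, d = 10)
  fnc <- c(a = 50, b = 100, c = 1, d = 11)
  g <- assign_groups(fnf, fnc, repeats = 100)
  expect_equal(g$group1, c("a", "d"))   # d: folded 10/100 is detected, contig 11 is not
  expect_equal(g$group2, "b")
  expect_equal(g$group3, "c")
  expect_equal(g$group0, character(0))
  # partition property
  all_ids <- sort(c(g$group1, g$group2, g$group3, g$group0))
  expect_equal(all_ids, sort(names(fnf)))
  expect_error(assign_groups(fnf, fnc[1:3], 100), "different sequence ids")
})

test_that("feature elimination inside CV still tests each sequence once", {
  dat <- separable_dataset(n_pos = 8, length = 150, seed = 58, n_scrambles = 2)
  res <- run_cv_once(dat, k = 3, folds = 4, seed = 13,
                     feature_elimination = TRUE, n_scrambles = 2)
  expect_equal(sort(res$id), sort(dat$id))
  expect_false(any(duplicated(res$id)))
  # the planted contiguous signal is strong enough to survive elimination
  pos <- res$label == 1
  expect_gte(mean(res$predicted[pos] == 1), 0.75)
})

test_that("cross-validation results serialize to TSV", {
  dat <- separable_dataset(n_pos = 6, length = 150, seed = 59, n_scrambles = 2)
  cv <- repeat_cv(dat, k = 3, folds = 3, repeats = 2, seed = 17)
  prefix <- file.path(withr::local_tempdir(), "cv")
  write_cv_result(cv, prefix)
  per_seq <- utils::read.table(paste0(prefix, "_per_sequence.tsv"),
                               header = TRUE, sep = "\t")
  expect_equal(nrow(per_seq), nrow(dat))
  per_rep <- utils::read.table(paste0(prefix, "_per_repeat.tsv"),
                               header = TRUE, sep = "\t")
  expect_equal(nrow(per_rep), 2L)
  expect_true(file.exists(paste0(prefix, "_roc.tsv")))
})
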