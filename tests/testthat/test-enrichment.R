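make_model <- function(w, b = 0, index = seq_along(w)) {
  structure(list(w = w, b = b, index = as.integer(index), C = 1, tol = 1e-3,
                 n_pos = 1, n_neg = 1, n_sv = 0, seed = NULL),
            class = "kspec_svm")
}

as_X <- function(values, index, ids = sprintf("s%d", seq_len(nrow(values)))) {
  rownames(values) <- ids
  attr(values, "index") <- as.integer(index)
  values
}

test_that("enrichment scores are w(n)x(n) with strict cutoff selection", {
  # exactly representable values so the boundary case r == cutoff is exact
  m <- make_model(c(0.25, -0.2))
  X <- as_X(matrix(c(0.02, 0.1), 1), 1:2)
  pr <- enrichment_scores(m, X, cutoff = 0.25 * 0.02)
  expect_equal(unname(pr$scores[1, ]), c(0.25 * 0.02, -0.02))
  expect_equal(pr$selected[["s1"]], integer(0))  # r == cutoff is not selected

  m2 <- make_model(0.2)
  pr2 <- enrichment_scores(m2, as_X(matrix(0.05, 1), 1L))
  expect_equal(unname(pr2$scores[1, 1]), 0.01)
  expect_equal(pr2$selected[["s1"]], 1L)
})

test_that("enrichment scores sum to the decision value minus the bias", {
  set.seed(41)
  sp <- feature_space(3)
  dat <- separable_dataset(n_pos = 6, length = 200, seed = 41, n_scrambles = 2)
  X <- featurize(dat, sp)
  m <- svm_train(X, dat$label)
  pr <- enrichment_scores(m, X)
  expect_equal(unname(rowSums(pr$scores)) + m$b,
               decision_values(m, X), tolerance = 1e-10)
})

test_that("fragments group selected features by gap mask and render correctly", {
  sp <- feature_space(3)
  idx <- function(pats) match(pats, sp$feature_names)
  w <- rep(0, 100)
  w[idx(c("ANT", "TNT", "GGG"))] <- 1
  m <- make_model(w, index = 1:100)
  X <- as_X(matrix(0, 1, 100), 1:100, ids = "crm1")
  X[1, idx(c("ANT", "TNT", "GGG"))] <- 0.1
  pr <- enrichment_scores(m, X)
  frs <- motif_fragments(pr, sp)[["crm1"]]
  expect_equal(length(frs), 2L)  # one per implicated mask
  renders <- sort(unname(vapply(frs, `[[`, character(1), "render")))
  expect_equal(renders, c("(A/T)NT", "GGG"))
  frag <- frs[[which(vapply(frs, `[[`, integer(1), "decimal") == 5L)]]
  expect_equal(sort(frag$members), c("ANT", "TNT"))
  # counts: position 1 splits A/T, position 2 is a gap, position 3 is 2xT
  expect_equal(unname(frag$counts[, 1]), c(1, 0, 0, 1))
  expect_true(all(is.na(frag$counts[, 2])))
  expect_equal(unname(frag$counts[, 3]), c(0, 0, 0, 2))

  # singleton fragment renders without parentheses
  w2 <- rep(0, 100); w2[idx("ANT")] <- 1
  X2 <- as_X(matrix(0, 1, 100), 1:100, ids = "crm1")
  X2[1, idx("ANT")] <- 0.1
  fr2 <- motif_fragments(enrichment_scores(make_model(w2, index = 1:100), X2),
                         sp)[["crm1"]]
  expect_equal(fr2[[1]]$render, "ANT")
  expect_equal(unname(fr2[[1]]$counts[, 1]), c(1, 0, 0, 0))
})

test_that("fragment rendering round-trips through parse_fragment", {
  sp <- feature_space(4)
  set.seed(42)
  for (rep in 1:10) {
    mask <- sample(sp$models$decimal, 1)
    members <- sample(sp$feature_names[sp$feature_model == mask],
                      sample(1:4, 1))
    frag <- foldkspec:::build_fragment("s", mask, members, 4)
    parsed <- parse_fragment(frag$render)
    chars <- do.call(rbind, strsplit(members, ""))
    for (p in 1:4) {
      expected <- if (foldkspec:::mask_bits(mask, 4)[p])
        sort(unique(chars[, p])) else "N"
      expect_equal(sort(parsed[[p]]), expected)
    }
  }
})

test_that("MEME export writes normalized probability columns", {
  frag <- foldkspec:::build_fragment("crm1", 5L, c("ANT", "TNT"), 3)
  f <- withr::local_tempfile(fileext = ".meme")
  export_meme(list(frag), f)
  lines <- readLines(f)
  expect_true(any(grepl("^MEME version", lines)))
  mi <- grep("^MOTIF crm1_m5_n2", lines)
  expect_length(mi, 1L)
  mat <- do.call(rbind, lapply(strsplit(lines[mi + 2:4], " "), as.numeric))
  expect_equal(mat[1, ], c(0.5, 0, 0, 0.5))
  expect_equal(mat[2, ], rep(0.25, 4))
  expect_equal(mat[3, ], c(0, 0, 0, 1))
  expect_error(export_meme(list(), f), "no motif fragments")
})

test_that("false features are discovered in composition-biased positives", {
  # A-rich positives: scrambled copies stay A-rich, so A-dominated features
  # enrich in the false-positive training and are flagged.
  set.seed(43)
  pos <- dna_set(sprintf("p%d", 1:12),
                 vapply(1:12, function(i)
                   random_dna(200, bases = c("A", "A", "A", "C", "G", "T")),
                   character(1)))
  sp <- feature_space(3)
  filt <- discover_false_features(pos, sp, n_scrambles = 5, seed = 7)
  expect_s3_class(filt, "feature_filter")
  expect_equal(length(filt$false_features), 60L)
  expect_equal(sort(names(filt$false_models_by_parent)), sort(pos$id))
  false_all <- unique(unlist(filt$false_features))
  expect_gt(length(false_all), 0)
  # the most A-dominated features should be implicated somewhere
  false_names <- sp$feature_names[false_all]
  expect_true(any(grepl("^[AN]+$", false_names)))
})

test_that("a hit table marking every fragment non-significant empties the false set", {
  set.seed(44)
  pos <- dna_set(sprintf("p%d", 1:6),
                 vapply(1:6, function(i)
                   random_dna(150, bases = c("A", "A", "C", "G", "T")),
                   character(1)))
  sp <- feature_space(3)
  filt0 <- discover_false_features(pos, sp, n_scrambles = 3, seed = 7)
  ids <- unlist(lapply(names(filt0$false_features), function(id) {
    sel <- filt0$false_features[[id]]
    if (length(sel) == 0) return(NULL)
    masks <- unique(sp$feature_model[sel])
    sprintf("%s_m%d_n%d", id, masks,
            vapply(masks, function(mm) sum(sp$feature_model[sel] == mm),
                   integer(1)))
  }))
  hits <- data.frame(fragment_id = ids, motif_id = "MA0001.1", p_value = 0.5)
  filt <- discover_false_features(pos, sp, n_scrambles = 3, seed = 7,
                                  hits = hits)
  expect_equal(length(unlist(filt$false_features)), 0L)
  bad <- data.frame(fragment_id = "nonexistent_m1_n1", motif_id = "x",
                    p_value = 1e-5)
  expect_error(discover_false_features(pos, sp, n_scrambles = 3, seed = 7,
                                       hits = bad),
               "unknown fragment id")
})

test_that("elimination zeroes implicated coordinates and pools survivors", {
  sp <- feature_space(3)
  # two positives with known selections
  w <- rep(0, 100)
  idx <- function(pats) match(pats, sp$feature_names)
  sel_a <- idx(c("ANA", "AAA"))   # masks 5 and 7
  sel_b <- idx(c("TNT", "NNG"))   # masks 5 and 1
  w[c(sel_a, sel_b)] <- 1
  m <- make_model(w, index = 1:100)
  X <- as_X(matrix(0, 2, 100), 1:100, ids = c("a", "b"))
  X[1, sel_a] <- 0.1
  X[2, sel_b] <- 0.1
  pr <- enrichment_scores(m, X)

  # empty filter: profiles unchanged, survivors = union of selections
  empty_filter <- structure(
    list(false_features = stats::setNames(list(integer(0), integer(0)),
                                          c("a_scr1", "b_scr1")),
         false_models_by_parent = list(a = integer(0), b = integer(0)),
         cutoff = 0.005, n_scrambles = 1, hits_used = FALSE),
    class = "feature_filter")
  out <- eliminate_features(pr, empty_filter, sp)
  expect_equal(out$profiles$scores, pr$scores)
  expect_equal(out$surviving_index, sort(c(sel_a, sel_b)))

  # by_model: mask 7 implicated for "a" only -> AAA zeroed there
  filt <- empty_filter
  filt$false_models_by_parent$a <- 7L
  filt$false_features[["a_scr1"]] <- idx("CCC")
  out2 <- eliminate_features(pr, filt, sp)
  expect_equal(out2$profiles$selected[["a"]], idx("ANA"))
  expect_equal(out2$profiles$selected[["b"]], sort(sel_b))
  expect_equal(out2$surviving_index, sort(c(idx("ANA"), sel_b)))

  # by_feature zeroes only the exact index, in the matched parent only
  filt$false_features[["a_scr1"]] <- idx("AAA")
  out3 <- eliminate_features(pr, filt, sp, mode = "by_feature")
  expect_equal(out3$profiles$selected[["a"]], idx("ANA"))
  # by_feature survivors are a superset of by_model survivors
  expect_true(all(out2$surviving_index %in% out3$surviving_index))

  # missing parent errors
  pr_missing <- pr
  rownames(pr_missing$scores) <- c("a", "zz")
  expect_error(eliminate_features(pr_missing, filt, sp), "zz")
})

test_that("enlarging the false set never enlarges the surviving index", {
  set.seed(45)
  sp <- feature_space(3)
  dat <- separable_dataset(n_pos = 6, length = 200, seed = 46, n_scrambles = 2)
  X <- featurize(dat, sp)
  m <- svm_train(X, dat$label)
  pos_rows <- dat$label == 1L
  Xp <- X[pos_rows, , drop = FALSE]
  attr(Xp, "index") <- attr(X, "index")
  pr <- enrichment_scores(m, Xp)
  ids <- rownames(pr$scores)
  masks <- sp$models$decimal
  surv_sizes <- vapply(c(0, 2, 4, 8), function(nbad) {
    filt <- structure(
      list(false_features = stats::setNames(
             rep(list(integer(0)), length(ids)), paste0(ids, "_scr1")),
           false_models_by_parent = stats::setNames(
             rep(list(sort(utils::head(masks, nbad))), length(ids)), ids),
           cutoff = 0.005, n_scrambles = 1, hits_used = FALSE),
      class = "feature_filter")
    length(eliminate_features(pr, filt, sp)$surviving_index)
  }, numeric(1))
  expect_true(all(diff(surv_sizes) <= 0))
})
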