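#' Train a soft-margin linear SVM on explicit spectrum features
#'
#' Fits the standard soft-margin support vector classifier by solving the
#' dual quadratic program (delegated to libsvm via \pkg{e1071}) with a linear
#' kernel on the explicit folded-spectrum features, and recovers the primal
#' weight vector w = sum_i y_i alpha_i x_i and bias b. The decision value of
#' an example z is f(z) = z'w + b, the signed distance from the learned
#' boundary; its sign is the predicted class.
#'
#' No feature scaling is applied: the relative-frequency normalization of the
#' feature map already accounts for sequence length and background
#' composition (set `scale = TRUE` to standardize anyway).
#'
#' @param X feature matrix (rows = examples) carrying an `index` attribute,
#'   as produced by [featurize] / [restrict_spectrum].
#' @param y class labels in \{+1, -1\}, both classes present.
#' @param C soft-margin cost parameter (default 1).
#' @param tol solver termination tolerance.
#' @param scale standardize features before training (default FALSE).
#' @param seed stored for provenance; the solver itself is deterministic.
#' @param gram optional precomputed linear Gram matrix `tcrossprod(X)` for the
#'   training rows; triggers the factorized-Gram path (see Details).
#'
#' @details When there are more features than examples (the usual regime:
#' N = 4*5^(k-1) features vs a few hundred sequences), the dual QP depends on
#' the features only through the n x n Gram matrix K = XX'. The fit then runs
#' libsvm on the exact factorization Z = U Lambda^(1/2) of K (so ZZ' = K),
#' which costs n-length instead of N-length dot products per kernel
#' evaluation, and recovers the primal weights as w = X'(alpha * y). This is
#' the same optimization problem with the same solution, not an approximation.
#' @return An object of class `kspec_svm`: list with `w` (named weight per
#'   active feature), `b`, `index` (active global feature indices), `C`,
#'   `tol`, `n_pos`, `n_neg`, `n_sv`, `seed`.
#' @export
svm_train <- function(X, y, C = 1, tol = 1e-3, scale = FALSE, seed = NULL,
                      gram = NULL) {
  y <- as.integer(y)
  if (nrow(X) != length(y)) stop2("nrow(X) != length(y)")
  if (length(unique(y[!is.na(y)])) < 2)
    stop2("training data must contain both classes")
  if (!all(y %in% c(-1L, 1L))) stop2("labels must be +1/-1")
  index <- attr(X, "index") %||% seq_len(ncol(X))
  use_gram <- !scale && (!is.null(gram) || ncol(X) > nrow(X))
  if (use_gram) {
    K <- gram %||% tcrossprod(X)
    eig <- eigen(K, symmetric = TRUE)
    Z <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), nrow(K))
    fit <- e1071::svm(Z, factor(y, levels = c(-1, 1)),
                      type = "C-classification", kernel = "linear", cost = C,
                      scale = FALSE, tolerance = tol)
    a <- numeric(nrow(X))
    a[fit$index] <- fit$coefs   # y_i * alpha_i, in training-row order
    w <- as.numeric(crossprod(X, a))
  } else {
    fit <- e1071::svm(X, factor(y, levels = c(-1, 1)), type = "C-classification",
                      kernel = "linear", cost = C, scale = scale,
                      tolerance = tol)
    w <- as.numeric(Matrix::crossprod(fit$SV, fit$coefs))
  }
  b <- -fit$rho
  # libsvm orients the decision toward the first label it encounters;
  # normalize so that positive decision values mean class +1.
  if (fit$levels[fit$labels[1]] == "-1") {
    w <- -w
    b <- -b
  }
  if (scale) {
    # fold the standardization into (w, b) so decision() works on raw features
    ctr <- attr(fit$x.scale, "scaled:center") %||% rep(0, ncol(X))
    scl <- attr(fit$x.scale, "scaled:scale") %||% rep(1, ncol(X))
    scl[scl == 0] <- 1
    b <- b - sum(w * ctr / scl)
    w <- w / scl
  }
  names(w) <- colnames(X)
  structure(
    list(w = w, b = b, index = index, C = C, tol = tol,
         n_pos = sum(y == 1L), n_neg = sum(y == -1L),
         n_sv = nrow(fit$SV), seed = seed),
    class = "kspec_svm"
  )
}

#' Decision values of a trained spectrum SVM
#'
#' f(z) = z'w + b per row of `X`; the sign gives the class, the magnitude the
#' distance from the decision boundary (up to ||w||).
#'
#' @param model a [svm_train] fit.
#' @param X feature matrix restricted to the model's active index.
#' @return Numeric vector of decision values.
#' @export
decision_values <- function(model, X) {
  stopifnot(inherits(model, "kspec_svm"))
  idx <- attr(X, "index")
  if (!is.null(idx) && !identical(as.integer(idx), as.integer(model$index)))
    stop2("feature index of X does not match the model's active index")
  if (ncol(X) != length(model$w))
    stop2("X has ", ncol(X), " columns; model has ", length(model$w), " weights")
  as.numeric(X %*% model$w + model$b)
}

#' @export
#' @rdname decision_values
#' @param object,newdata,type standard predict arguments; `type = "class"`
#'   returns +1/-1 labels (a decision value of exactly 0 is labeled -1),
#'   `type = "decision"` the raw decision values.
#' @param ... ignored.
predict.kspec_svm <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  d <- decision_values(object, newdata)
  if (type == "decision") return(d)
  ifelse(d > 0, 1L, -1L)
}

#' @export
coef.kspec_svm <- function(object, ...) {
  c(`(bias)` = object$b, object$w)
}

#' @export
print.kspec_svm <- function(x, ...) {
  cat(sprintf("kspec_svm: %d active features, C=%g, %d SV (trained on %d+ / %d-)\n",
              length(x$w), x$C, x$n_sv, x$n_pos, x$n_neg))
  invisible(x)
}

#' Serialize / read a trained model as TSV
#'
#' One row per (feature pattern, weight) after a header line carrying b, C, k
#' and a hash of the active feature index.
#'
#' @param model a [svm_train] fit.
#' @param path file path.
#' @param k word length recorded in the header (optional).
#' @export
write_model <- function(model, path, k = NA) {
  stopifnot(inherits(model, "kspec_svm"))
  con <- file(path, "w")
  on.exit(close(con))
  idx_hash <- sum(as.numeric(model$index) * 31) %% 2147483647
  writeLines(sprintf("#b=%.9g C=%.9g k=%s index_hash=%.0f n_features=%d",
                     model$b, model$C, as.character(k), idx_hash,
                     length(model$w)), con)
  utils::write.table(
    data.frame(feature = names(model$w) %||% as.character(model$index),
               index = model$index, weight = sprintf("%.9g", model$w)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  header <- readLines(path, n = 1)
  m <- regmatches(header, regexec(
    "^#b=([0-9.eE+-]+) C=([0-9.eE+-]+) k=(\\S+) index_hash=(\\d+) n_features=(\\d+)$",
    header))[[1]]
  if (length(m) != 6) stop2("not a model file: ", path)
  tab <- utils::read.table(path, sep = "\t", skip = 1,
                           col.names = c("feature", "index", "weight"),
                           colClasses = c("character", "integer", "numeric"))
  structure(
    list(w = stats::setNames(tab$weight, tab$feature), b = as.numeric(m[2]),
         index = tab$index, C = as.numeric(m[3]), tol = NA,
         n_pos = NA, n_neg = NA, n_sv = NA, seed = NULL),
    class = "kspec_svm"
  )
}
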