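#' Write a feature matrix as TSV
#'
#' One row per sequence, a leading `id` column, then one column per feature
#' named by its gapped pattern (N at gaps). Values are printed with 9
#' significant digits, so identical runs produce byte-identical files.
#'
#' @param X feature matrix from [featurize] (or a restriction of it).
#' @param path output path.
#' @export
write_feature_matrix <- function(X, path) {
  df <- data.frame(id = rownames(X) %||% seq_len(nrow(X)),
                   apply(X, 2, function(col) sprintf("%.9g", col)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Records the configuration, seed and package version of a run as JSON, so
#' any artifact can be regenerated exactly.
#'
#' @param config named list of run parameters.
#' @param path output path (JSON).
#' @export
write_run_manifest <- function(config, path) {
  config$package <- "foldkspec"
  config$package_version <- as.character(utils::packageVersion("foldkspec"))
  config$r_version <- R.version.string
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a group-assignment table
#'
#' @param groups an [assign_groups] result.
#' @param path output TSV path (columns id, group).
#' @export
write_groups <- function(groups, path) {
  stopifnot(inherits(groups, "group_assignment"))
  df <- do.call(rbind, lapply(c(1, 2, 3, 0), function(g) {
    ids <- groups[[paste0("group", g)]]
    if (length(ids) == 0) return(NULL)
    data.frame(id = ids, group = g)
  }))
  if (is.null(df)) df <- data.frame(id = character(), group = integer())
  utils::write.table(df[order(df$id), ], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
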