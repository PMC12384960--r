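# Non-feature columns recognised in user tables.
fs_meta_cols <- c("label", "role", "query_id", "episode")

# Extract the numeric feature matrix from a data frame (every numeric
# column that is not a metadata column), preserving column order.
fs_feature_matrix <- function(data, arg = "data") {
  if (!is.data.frame(data)) abort(sprintf("`%s` must be a data frame.", arg))
  keep <- vapply(data, is.numeric, logical(1)) & !(names(data) %in% fs_meta_cols)
  if (!any(keep)) abort(sprintf("`%s` has no numeric feature columns.", arg))
  x <- as.matrix(data[keep])
  if (anyNA(x) || !all(is.finite(x))) {
    abort(sprintf("feature columns of `%s` must be finite (no NA/Inf).", arg))
  }
  x
}

# Labels as a factor with deterministically sorted levels (class index =
# position in sorted level order; ties throughout the package break to
# the smallest class index under this ordering).
fs_labels <- function(data, levels = NULL, arg = "data") {
  if (!"label" %in% names(data)) {
    abort(sprintf("`%s` must contain a `label` column.", arg))
  }
  lab <- data$label
  if (is.null(levels)) levels <- sort(unique(as.character(lab)))
  f <- factor(as.character(lab), levels = levels)
  if (anyNA(f)) abort("labels outside the model's known classes.")
  f
}
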