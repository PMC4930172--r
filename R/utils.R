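# Internal helpers shared across modules.

# Extract the numeric value matrix from an expression tibble
# (first column = feature ids, remaining columns = samples).
expr_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), ncol(expr) >= 2)
  x <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- as.character(expr[[1]])
  x
}

# Rebuild an expression tibble from a value matrix.
expr_tibble <- function(x, id_col = "feature_id") {
  if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(ncol(x)))
  out <- tibble::as_tibble(x, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(!!id_col := rownames(x)), out)
  out
}

check_scalar_number <- function(value, field, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  ok <- is.numeric(value) && length(value) == 1L && is.finite(value) &&
    (if (strict_lower) value > lower else value >= lower) && value <= upper
  if (!ok) {
    abort(sprintf("invalid configuration: field `%s` must be a finite number in %s%s, %s]",
                  field, if (strict_lower) "(" else "[", lower, upper),
          class = "ffldyn_config_error")
  }
  invisible(value)
}

check_count <- function(value, field, min = 1L) {
  ok <- is.numeric(value) && length(value) == 1L && is.finite(value) &&
    value == as.integer(value) && value >= min
  if (!ok) {
    abort(sprintf("invalid configuration: field `%s` must be an integer >= %d",
                  field, min),
          class = "ffldyn_config_error")
  }
  invisible(as.integer(value))
}

# Stable key for a typed directed edge.
edge_key <- function(source, target, label) {
  paste(source, target, label, sep = "\r")
}
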