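# Internal helpers shared across modules.

# Center/scale a numeric vector to mean 0, SD 1 (sample SD).
standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    abort("cannot standardize a constant (zero-variance) vector")
  }
  (x - mean(x)) / s
}

# Population variance (divide by n), the convention used for variance-absorbed
# proportions so that a standardized response has variance exactly 1.
pop_var <- function(x) {
  n <- length(x)
  if (n == 0L) abort("empty vector")
  mean((x - mean(x))^2)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x > 0 && x == round(x)

# Derive a per-layer seed from a base seed, keeping within 32-bit range.
layer_seed <- function(seed, layer) {
  (as.integer(seed %% 599999L) * 3511L + layer * 7919L) %% 2147483629L
}

# Columns of a wide table that are not the sample-id column.
value_columns <- function(df, id_col = "sample_id") {
  setdiff(names(df), id_col)
}

# Extract the numeric matrix behind a wide sample-by-feature tibble.
wide_matrix <- function(df, id_col = "sample_id") {
  stopifnot(id_col %in% names(df))
  m <- as.matrix(df[value_columns(df, id_col)])
  rownames(m) <- as.character(df[[id_col]])
  storage.mode(m) <- "double"
  m
}

# Rebuild a wide tibble from a matrix plus sample ids.
matrix_tibble <- function(m, sample_id, id_col = "sample_id") {
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(!!id_col := sample_id), out)
  out
}
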