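# internal input checks shared across modules

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

assert_proportion <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%g, %g].", name, lo, hi))
  }
  as.numeric(x)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  as.numeric(x)
}

# coerce dense or sparse input to a dgC sparse matrix, keeping dimnames
as_sparse <- function(x) {
  if (!inherits(x, "Matrix")) x <- Matrix::Matrix(as.matrix(x), sparse = TRUE)
  as(as(x, "generalMatrix"), "CsparseMatrix")
}

# canonical cell-cycle phase labels, in cycle order
cycle_phases <- function() c("G1/S", "S", "G2/M", "M", "M/G1")

# pairwise hamming distances between equal-length strings
hamming_matrix <- function(x, y) {
  xs <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  ys <- do.call(rbind, strsplit(y, "", fixed = TRUE))
  d <- matrix(0L, nrow = length(x), ncol = length(y))
  for (j in seq_len(ncol(xs))) {
    d <- d + outer(xs[, j], ys[, j], "!=")
  }
  d
}

# wide phase-score tibble (cell + one column per phase) -> numeric matrix
phase_matrix <- function(scores) {
  if (!is.data.frame(scores) || !"cell" %in% names(scores)) {
    abort("phase scores must be a data frame with a `cell` column.")
  }
  m <- as.matrix(scores[setdiff(names(scores), "cell")])
  rownames(m) <- scores$cell
  storage.mode(m) <- "double"
  m
}

matrix_to_phase_tbl <- function(m) {
  dplyr::bind_cols(tibble::tibble(cell = rownames(m)), tibble::as_tibble(m))
}
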