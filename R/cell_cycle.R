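#' Log-normalize a UMI count matrix
#'
#' Per-cell depth normalization followed by a log transform:
#' `value = ln(1 + count * scale_factor / cell_total)`. Cells with zero
#' total counts are dropped with a warning.
#'
#' @param counts Sparse or dense genes x cells matrix of non-negative
#'   integer counts.
#' @param scale_factor Positive pseudo-depth every cell is scaled to
#'   (default 10,000, the de-facto standard for this normalization).
#'
#' @return A `dgCMatrix` of normalized values, same shape (minus dropped
#'   cells).
#' @export
#' @examples
#' m <- Matrix::Matrix(matrix(c(10, 0, 5, 5), 2,
#'   dimnames = list(c("g1", "g2"), c("c1", "c2"))), sparse = TRUE)
#' log_normalize(m)
log_normalize <- function(counts, scale_factor = 10000) {
  scale_factor <- assert_positive(scale_factor, "scale_factor")
  counts <- as_sparse(counts)
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    abort("`counts` must contain non-negative integers.")
  }
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    warn(sprintf("dropping %d cell(s) with zero total counts.", sum(totals == 0)))
    counts <- counts[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  out <- counts %*% Matrix::Diagonal(x = scale_factor / totals)
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  as(out, "CsparseMatrix")
}

#' Score cells against phase gene sets
#'
#' The raw score of a cell for a gene set is the arithmetic mean of the
#' normalized expression of the set's genes present in the matrix. Genes
#' absent from the matrix are dropped (with a message reporting how many);
#' a set with no present genes is an error.
#'
#' @param normalized Genes x cells matrix of log-normalized expression (see
#'   [log_normalize()]).
#' @param gene_sets Named list of character vectors, one per phase.
#'
#' @return A wide tibble: `cell` plus one raw-score column per gene set,
#'   in the order given.
#' @export
score_gene_sets <- function(normalized, gene_sets) {
  if (is.null(names(gene_sets)) || anyDuplicated(names(gene_sets))) {
    abort("`gene_sets` must be a uniquely named list.")
  }
  scores <- lapply(names(gene_sets), function(nm) {
    present <- intersect(gene_sets[[nm]], rownames(normalized))
    n_drop <- length(gene_sets[[nm]]) - length(present)
    if (length(present) == 0L) {
      abort(sprintf("gene set '%s' has no genes present in the matrix.", nm))
    }
    if (n_drop > 0L) {
      inform(sprintf("gene set '%s': %d gene(s) absent from the matrix.", nm, n_drop))
    }
    unname(Matrix::colMeans(normalized[present, , drop = FALSE]))
  })
  names(scores) <- names(gene_sets)
  dplyr::bind_cols(
    tibble::tibble(cell = colnames(normalized)),
    tibble::as_tibble(scores)
  )
}

#' Doubly normalize phase scores
#'
#' First each phase is mean-centred and SD-normalized across all cells
#' (`norm1`); then each individual cell is mean-centred and SD-normalized
#' across its phases (`norm2`). The column-then-row order is mandatory.
#' Sample (n-1) standard deviations are used throughout. A phase with zero
#' spread across cells, or a cell with zero spread across phases, is a
#' degenerate input and raises an error naming it.
#'
#' @param raw Wide tibble from [score_gene_sets()] (`cell` + one column per
#'   phase).
#'
#' @return List with `norm1` and `norm2`, both wide tibbles shaped like
#'   `raw`.
#' @export
normalize_phase_scores <- function(raw) {
  m <- phase_matrix(raw)
  if (nrow(m) < 2L) abort("need at least 2 cells.")
  col_sd <- apply(m, 2L, sd)
  if (any(col_sd == 0)) {
    abort(sprintf("degenerate input: phase '%s' has identical scores across cells.",
                  colnames(m)[which(col_sd == 0)[1L]]))
  }
  norm1 <- scale(m)
  row_sd <- apply(norm1, 1L, sd)
  if (any(row_sd == 0)) {
    abort(sprintf("degenerate input: cell '%s' has identical scores across phases.",
                  rownames(m)[which(row_sd == 0)[1L]]))
  }
  norm2 <- t(scale(t(norm1)))
  dimnames(norm2) <- dimnames(m)
  list(
    norm1 = matrix_to_phase_tbl(norm1[, colnames(m), drop = FALSE]),
    norm2 = matrix_to_phase_tbl(norm2)
  )
}

#' Call on-phases, assign a phase and order cells
#'
#' A phase is "on" in a cell when its doubly-normalized score exceeds
#' `on_threshold` (default 0, i.e. above the cell's own mean). The assigned
#' phase is the argmax (ties broken toward the earlier phase in canonical
#' cycle order). Cells are ordered by their on-pattern: patterns rank by the
#' position of their first on-phase in canonical order, then by the number
#' of on-phases, then lexicographically by the pattern; cells with no phase
#' on come last; within a pattern cells sort by decreasing maximal score.
#'
#' @param norm2 Wide tibble of doubly-normalized scores (see
#'   [normalize_phase_scores()]).
#' @param on_threshold Score above which a phase counts as switched on.
#' @param phase_order Canonical phase order; defaults to the score columns'
#'   order.
#'
#' @return Tibble ordered as described, with columns `cell`, one logical
#'   column per phase, `assigned`, `pattern` and `order` (1 = first).
#' @export
call_and_order <- function(norm2, on_threshold = 0, phase_order = NULL) {
  m <- phase_matrix(norm2)
  if (any(!is.finite(m))) abort("`norm2` must be finite.")
  phase_order <- phase_order %||% colnames(m)
  if (!setequal(phase_order, colnames(m))) {
    abort("`phase_order` must be a permutation of the score columns.")
  }
  m <- m[, phase_order, drop = FALSE]

  on <- m > on_threshold
  assigned <- phase_order[max.col(m, ties.method = "first")]
  first_on <- unname(apply(on, 1L, function(r) if (any(r)) which(r)[1L] else Inf))
  n_on <- unname(rowSums(on))
  pattern_bits <- unname(apply(on, 1L, function(r) paste(as.integer(r), collapse = "")))
  pattern <- unname(apply(on, 1L, function(r) {
    if (!any(r)) "none" else paste(phase_order[r], collapse = "+")
  }))
  max_score <- unname(apply(m, 1L, max))

  out <- dplyr::bind_cols(
    tibble::tibble(cell = rownames(m)),
    tibble::as_tibble(on),
    tibble::tibble(
      assigned = assigned, pattern = pattern,
      .first_on = first_on, .n_on = n_on, .bits = pattern_bits,
      .max_score = max_score
    )
  )
  out <- dplyr::arrange(out, .data$.first_on, .data$.n_on, .data$.bits,
                        dplyr::desc(.data$.max_score))
  out$order <- seq_len(nrow(out))
  dplyr::select(out, -dplyr::starts_with("."))
}
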