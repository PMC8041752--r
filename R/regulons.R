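#' Filter genes by expression breadth
#'
#' Keeps genes with a nonzero count in at least `ceiling(min_cell_fraction *
#' n_cells)` cells — a gene detected in exactly the threshold fraction of
#' cells is kept ("at least").
#'
#' @param counts Genes x cells count matrix.
#' @param min_cell_fraction Required detection fraction, strictly between 0
#'   and 1.
#'
#' @return The filtered count matrix.
#' @export
filter_expressed_genes <- function(counts, min_cell_fraction = 0.10) {
  if (!is.numeric(min_cell_fraction) || min_cell_fraction <= 0 || min_cell_fraction >= 1) {
    abort("`min_cell_fraction` must be strictly between 0 and 1.")
  }
  counts <- as_sparse(counts)
  need <- ceiling(min_cell_fraction * ncol(counts))
  n_cells_detected <- Matrix::rowSums(counts > 0)
  keep <- n_cells_detected >= need
  if (!any(keep)) abort("no genes pass the expression filter.")
  counts[keep, , drop = FALSE]
}

#' Filter regulons to expressed TFs with enough expressed targets
#'
#' A regulon is retained when its TF gene is in the expressed gene set
#' (optional, on by default) and it has strictly more than `min_targets`
#' targets among the expressed genes; the retained regulon's targets are
#' restricted to expressed genes.
#'
#' @param regulons Tibble with columns `tf`, `target` and optionally `mode`,
#'   `network`.
#' @param expressed_genes Character vector of expressed gene identifiers.
#' @param min_targets Regulons must have more than this many expressed
#'   targets (strict inequality; default 10).
#' @param require_tf_expressed Also require the TF gene itself to be
#'   expressed.
#'
#' @return The filtered regulon tibble.
#' @export
filter_regulons <- function(regulons, expressed_genes, min_targets = 10,
                            require_tf_expressed = TRUE) {
  if (min_targets < 1) abort("`min_targets` must be >= 1.")
  out <- regulons[regulons$target %in% expressed_genes, , drop = FALSE]
  keep_tf <- dplyr::count(out, .data$tf)
  keep_tf <- keep_tf$tf[keep_tf$n > min_targets]
  if (require_tf_expressed) keep_tf <- intersect(keep_tf, expressed_genes)
  out[out$tf %in% keep_tf, , drop = FALSE]
}

#' Score regulon activity in single cells
#'
#' The activity of a TF in a cell is the mean normalized expression of the
#' regulon's targets in that cell (unsigned by default; in signed mode
#' repressed targets enter with a negative sign). Per-regulon scores are
#' then mean-centred and SD-normalized across all cells.
#'
#' @param normalized Genes x cells matrix of normalized expression.
#' @param regulons Tibble with `tf`, `target` and (for signed mode) `mode`
#'   columns; pre-filter with [filter_regulons()].
#' @param mode_handling "unsigned" (default) or "signed".
#'
#' @return Long tibble with columns `tf`, `cell`, `activity` (normalized)
#'   and `n_targets_used`.
#' @export
score_regulon_activity <- function(normalized, regulons,
                                   mode_handling = c("unsigned", "signed")) {
  mode_handling <- match.arg(mode_handling)
  cells <- colnames(normalized)
  purrr::map_dfr(split(regulons, regulons$tf), function(reg) {
    present <- reg[reg$target %in% rownames(normalized), , drop = FALSE]
    if (nrow(present) == 0L) {
      abort(sprintf("regulon '%s' has no targets in the matrix.", reg$tf[1L]))
    }
    sign <- if (mode_handling == "signed" && "mode" %in% names(present)) {
      ifelse(present$mode == "Repression", -1, 1)
    } else {
      rep(1, nrow(present))
    }
    raw <- as.numeric(sign %*% as.matrix(normalized[present$target, , drop = FALSE])) /
      nrow(present)
    s <- sd(raw)
    if (s == 0) {
      abort(sprintf("regulon '%s' has constant activity across cells.", reg$tf[1L]))
    }
    tibble::tibble(
      tf = reg$tf[1L], cell = cells,
      activity = (raw - mean(raw)) / s,
      n_targets_used = nrow(present)
    )
  })
}

#' Correlate regulon activity with phase scores
#'
#' Pearson correlation of each regulon's normalized activity with each
#' phase's across-cell normalized score. The test statistic is
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on a t distribution with n - 2
#' degrees of freedom (two-sided). A (regulon, phase) pair passes when the
#' correlation strictly exceeds `r_threshold` and the (optionally adjusted)
#' p-value is below `p_threshold`.
#'
#' @param activity Long tibble from [score_regulon_activity()] (`tf`,
#'   `cell`, `activity`).
#' @param phases_norm1 Wide tibble of across-cell normalized phase scores
#'   (`norm1` from [normalize_phase_scores()]).
#' @param r_threshold Correlation needed to pass (strict `>`), default 0.3.
#' @param p_threshold Significance level on the (adjusted) p-value, default
#'   0.01.
#' @param adjust Multiple-testing adjustment over all (regulon, phase)
#'   pairs: "none" (default), "bonferroni" or "BH".
#'
#' @return Tibble with one row per (tf, phase): `n`, `estimate`,
#'   `statistic`, `p.value`, `p.adjusted`, `pass`.
#' @export
correlate_activity_phases <- function(activity, phases_norm1,
                                      r_threshold = 0.3, p_threshold = 0.01,
                                      adjust = c("none", "bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  wide <- tidyr::pivot_wider(activity[, c("tf", "cell", "activity")],
                             names_from = "tf", values_from = "activity")
  if (!setequal(wide$cell, phases_norm1$cell)) {
    abort("activity and phase scores cover different cell sets.")
  }
  wide <- wide[match(phases_norm1$cell, wide$cell), , drop = FALSE]
  n <- nrow(wide)
  if (n < 4L) abort("need at least 4 cells.")

  A <- as.matrix(wide[-1L])
  P <- phase_matrix(phases_norm1)
  r <- cor(A, P)

  out <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(tf = rownames(r)), tibble::as_tibble(r)),
    -"tf", names_to = "phase", values_to = "estimate"
  )
  out$n <- n
  out$statistic <- out$estimate * sqrt(n - 2) / sqrt(pmax(1 - out$estimate^2, .Machine$double.eps))
  out$p.value <- 2 * pt(-abs(out$statistic), df = n - 2)
  out$p.adjusted <- p.adjust(out$p.value, method = switch(adjust,
    none = "none", bonferroni = "bonferroni", BH = "BH"
  ))
  out$pass <- out$estimate > r_threshold & out$p.adjusted < p_threshold
  out[, c("tf", "phase", "n", "estimate", "statistic", "p.value", "p.adjusted", "pass")]
}
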