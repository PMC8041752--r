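#' Per-gene expression signature z-scores
#'
#' Converts a normalized genes x cells matrix into a signature matrix of
#' per-gene z-scores across cells (sample, n-1, standard deviation).
#' Zero-variance genes cannot be scored and are removed with a message.
#'
#' @param normalized Genes x cells normalized expression matrix.
#'
#' @return A dense genes x cells matrix; every row has mean 0 and SD 1.
#' @export
signature_zscores <- function(normalized) {
  m <- as.matrix(normalized)
  if (ncol(m) < 2L) abort("need at least 2 cells.")
  sds <- apply(m, 1L, sd)
  drop <- sds == 0
  if (all(drop)) abort("all genes have zero variance.")
  if (any(drop)) {
    inform(sprintf("dropping %d zero-variance gene(s): %s%s",
                   sum(drop),
                   paste(utils::head(rownames(m)[drop], 5L), collapse = ", "),
                   if (sum(drop) > 5L) ", ..." else ""))
    m <- m[!drop, , drop = FALSE]
    sds <- sds[!drop]
  }
  (m - rowMeans(m)) / sds
}

#' Single-cell enrichment score of one regulon
#'
#' Stouffer combination of the regulon targets' signature z-scores:
#' `NES(cell) = sum(s_i * z_i) / sqrt(n)` over the targets present in the
#' signature, with `s_i = -1` for repressed targets in signed mode and `+1`
#' otherwise. Under an independent standard-normal null signature the NES is
#' itself standard normal.
#'
#' @param signature Genes x cells z-score matrix from [signature_zscores()].
#' @param regulon Tibble with `target` (and optionally `mode`) columns, or a
#'   character vector of targets.
#' @param signed Negate repressed targets' contributions.
#' @param min_targets Minimum targets that must be present (default 10).
#'
#' @return Named numeric vector of per-cell NES.
#' @export
enrichment_nes <- function(signature, regulon, signed = FALSE, min_targets = 10) {
  if (is.character(regulon)) {
    regulon <- tibble::tibble(target = regulon, mode = "Unknown")
  }
  present <- regulon[regulon$target %in% rownames(signature), , drop = FALSE]
  n <- nrow(present)
  if (n < min_targets) {
    abort(sprintf("only %d regulon target(s) present; need at least %d.", n, min_targets))
  }
  s <- if (signed && "mode" %in% names(present)) {
    ifelse(present$mode == "Repression", -1, 1)
  } else {
    rep(1, n)
  }
  nes <- as.numeric(s %*% signature[present$target, , drop = FALSE]) / sqrt(n)
  setNames(nes, colnames(signature))
}

#' Score all regulons of several source networks
#'
#' Applies [enrichment_nes()] to every regulon in every network; regulons
#' with fewer than `min_targets` present targets in a given network are
#' skipped there (a network that lacks a regulon simply does not vote for
#' it).
#'
#' @param signature Genes x cells z-score matrix.
#' @param networks Named list of regulon tibbles (`tf`, `target`, `mode`).
#' @param min_targets Per-network minimum present targets.
#' @param signed Negate repressed targets.
#'
#' @return Long tibble: `network`, `tf`, `cell`, `nes`.
#' @export
score_networks <- function(signature, networks, min_targets = 10, signed = FALSE) {
  if (is.null(names(networks)) || anyDuplicated(names(networks))) {
    abort("`networks` must be a uniquely named list.")
  }
  purrr::map_dfr(names(networks), function(nw) {
    purrr::map_dfr(split(networks[[nw]], networks[[nw]]$tf), function(reg) {
      present <- sum(reg$target %in% rownames(signature))
      if (present < min_targets) return(NULL)
      nes <- enrichment_nes(signature, reg, signed = signed, min_targets = min_targets)
      tibble::tibble(network = nw, tf = reg$tf[1L], cell = names(nes), nes = nes)
    })
  })
}

#' Integrate enrichment scores across networks (average score)
#'
#' For each regulon the integrated score in a cell is the arithmetic mean of
#' its NES over the networks that contain the regulon (networks lacking it
#' are ignored, not zero-filled). Integrated scores are then mean-centred
#' and SD-normalized per regulon across all cells, so the result plugs
#' directly into [correlate_meta()].
#'
#' @param nes Long tibble from [score_networks()] (`network`, `tf`, `cell`,
#'   `nes`).
#'
#' @return Long tibble: `tf`, `cell`, `activity` (normalized integrated
#'   score), `n_networks`.
#' @export
avg_score_integrate <- function(nes) {
  if (nrow(nes) == 0L) abort("no regulon was scored in any network.")
  out <- dplyr::summarise(
    dplyr::group_by(nes, .data$tf, .data$cell),
    activity = mean(.data$nes), n_networks = dplyr::n(), .groups = "drop_last"
  )
  out <- dplyr::mutate(out, .sd = sd(.data$activity))
  if (any(out$.sd == 0)) {
    abort(sprintf("regulon '%s' has constant integrated score across cells.",
                  out$tf[out$.sd == 0][1L]))
  }
  out <- dplyr::mutate(out,
    activity = (.data$activity - mean(.data$activity)) / .data$.sd
  )
  dplyr::select(dplyr::ungroup(out), -".sd")
}

#' Correlate integrated enrichment with phase scores
#'
#' [correlate_activity_phases()] with the multi-network defaults: pass
#' requires Pearson r strictly above 0.35 and a Bonferroni-adjusted p-value
#' below 0.05. (A Benjamini-Hochberg FDR alternative is available via
#' `adjust = "BH"`.)
#'
#' @param integrated Long tibble from [avg_score_integrate()].
#' @param phases_norm1 Wide tibble of across-cell normalized phase scores.
#' @param r_threshold Strict correlation threshold (default 0.35).
#' @param alpha Level on the adjusted p-value (default 0.05).
#' @param adjust "bonferroni" (default) or "BH".
#'
#' @return Tibble as in [correlate_activity_phases()].
#' @export
correlate_meta <- function(integrated, phases_norm1, r_threshold = 0.35,
                           alpha = 0.05, adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  correlate_activity_phases(integrated, phases_norm1,
                            r_threshold = r_threshold, p_threshold = alpha,
                            adjust = adjust)
}
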