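#' Filter guides by combined initial abundance
#'
#' The initial counts of each guide are summed across all lines and
#' replicates to form a combined reference; guides with fewer than
#' `min_combined_counts` total counts are removed ("less than" is strict, so
#' a guide at exactly the threshold is retained). A message reports how many
#' guides were dropped.
#'
#' @param counts Screen tibble with columns `sgrna`, `gene`, `line`,
#'   `replicate`, `initial`, `final` (see [simulate_crispr_screen()]).
#' @param min_combined_counts Combined-count threshold (default 400).
#'
#' @return The filtered screen tibble.
#' @export
filter_sgrnas <- function(counts, min_combined_counts = 400) {
  if (any(is.na(counts$initial))) abort("initial counts must be present for all samples.")
  combined <- dplyr::summarise(dplyr::group_by(counts, .data$sgrna),
                               combined = sum(.data$initial), .groups = "drop")
  keep <- combined$sgrna[combined$combined >= min_combined_counts]
  n_drop <- length(unique(counts$sgrna)) - length(keep)
  inform(sprintf("removed %d guide(s) with combined initial counts below %g.",
                 n_drop, min_combined_counts))
  out <- counts[counts$sgrna %in% keep, , drop = FALSE]
  if (nrow(out) == 0L) abort("no guides survive the combined-count filter.")
  out
}

#' Per-guide log2 fold changes
#'
#' Computes `lfc = log2((final' + pseudocount) / (initial' + pseudocount))`
#' per guide and sample. With `depth_normalize = TRUE` (default) every
#' sample's counts are first scaled to the median library size across all
#' initial and final samples, so abundance changes are not confounded with
#' sequencing depth.
#'
#' @param counts Screen tibble (`sgrna`, `gene`, `line`, `replicate`,
#'   `initial`, `final`).
#' @param pseudocount Added to both normalized counts (default 1).
#' @param depth_normalize Scale samples to the median library size first.
#'
#' @return The tibble with extra columns `initial_norm`, `final_norm`,
#'   `lfc`.
#' @export
sgrna_log2fc <- function(counts, pseudocount = 1, depth_normalize = TRUE) {
  if (any(counts$initial < 0) || any(counts$final < 0)) {
    abort("counts must be non-negative.")
  }
  out <- counts
  if (depth_normalize) {
    by_sample <- dplyr::group_by(out, .data$line, .data$replicate)
    sizes <- dplyr::summarise(by_sample,
                              size_initial = sum(.data$initial),
                              size_final = sum(.data$final), .groups = "drop")
    med <- median(c(sizes$size_initial, sizes$size_final))
    out <- dplyr::left_join(out, sizes, by = c("line", "replicate"))
    out$initial_norm <- out$initial * med / out$size_initial
    out$final_norm <- out$final * med / out$size_final
    out$size_initial <- out$size_final <- NULL
  } else {
    out$initial_norm <- as.numeric(out$initial)
    out$final_norm <- as.numeric(out$final)
  }
  out$lfc <- log2((out$final_norm + pseudocount) / (out$initial_norm + pseudocount))
  out
}

#' Gene-level CRISPR scores
#'
#' The CRISPR score of a gene in a line is the mean log2 fold change of all
#' its surviving guides; lines screened in replicate are scored per
#' replicate and the replicate scores averaged. Control guides (gene =
#' "CONTROL") are scored like any other "gene" and can be used as a null
#' reference.
#'
#' @param lfc Tibble from [sgrna_log2fc()].
#'
#' @return Tibble with columns `gene`, `line`, `score`, `n_sgrnas`.
#' @export
gene_crispr_score <- function(lfc) {
  if (!"lfc" %in% names(lfc)) abort("run `sgrna_log2fc()` first.")
  per_rep <- dplyr::summarise(
    dplyr::group_by(lfc, .data$gene, .data$line, .data$replicate),
    score = mean(.data$lfc), n_sgrnas = dplyr::n(), .groups = "drop"
  )
  dplyr::summarise(
    dplyr::group_by(per_rep, .data$gene, .data$line),
    score = mean(.data$score), n_sgrnas = max(.data$n_sgrnas), .groups = "drop"
  )
}

#' Rank test for gene depletion against control guides
#'
#' One-sided (depletion) test comparing each gene's guide log2 fold changes
#' with the control guides' in the same line. The default is a
#' Mann-Whitney/Wilcoxon rank-sum test (robust for a handful of guides
#' against hundreds of controls); Welch's t test is available. P-values are
#' Benjamini-Hochberg adjusted across genes within each line.
#'
#' @param lfc Tibble from [sgrna_log2fc()] containing control guides
#'   (`gene == control_label`).
#' @param method "mann_whitney" (default) or "welch".
#' @param adjust P-adjustment method across genes (default "BH").
#' @param control_label Gene label of control guides.
#' @param min_gene_sgrnas Minimum guides a gene needs (default 3).
#' @param min_controls Minimum control guides required (default 20).
#'
#' @return Tibble with `line`, `gene`, `n_sgrnas`, `statistic`, `p.value`,
#'   `p.adjusted`.
#' @export
test_gene_depletion <- function(lfc, method = c("mann_whitney", "welch"),
                                adjust = "BH", control_label = "CONTROL",
                                min_gene_sgrnas = 3, min_controls = 20) {
  method <- match.arg(method)
  if (!"lfc" %in% names(lfc)) abort("run `sgrna_log2fc()` first.")
  purrr::map_dfr(split(lfc, lfc$line), function(d) {
    ctrl <- d$lfc[d$gene == control_label]
    if (length(ctrl) < min_controls) {
      abort(sprintf("line '%s': %d control guide(s), need at least %d.",
                    d$line[1L], length(ctrl), min_controls))
    }
    genes <- setdiff(unique(d$gene), control_label)
    res <- purrr::map_dfr(genes, function(g) {
      x <- d$lfc[d$gene == g]
      if (length(x) < min_gene_sgrnas) {
        abort(sprintf("gene '%s' has %d guide(s); need at least %d.",
                      g, length(x), min_gene_sgrnas))
      }
      ht <- if (method == "mann_whitney") {
        wilcox.test(x, ctrl, alternative = "less", exact = FALSE, correct = TRUE)
      } else {
        t.test(x, ctrl, alternative = "less")
      }
      tibble::tibble(line = d$line[1L], gene = g, n_sgrnas = length(x),
                     statistic = unname(ht$statistic), p.value = ht$p.value)
    })
    res$p.adjusted <- p.adjust(res$p.value, method = adjust)
    res
  })
}

#' Flag dependent cell lines
#'
#' A line is considered dependent on a gene when its essentiality score is
#' strictly below the cutoff (default -0.5; on the scale where -1 is the
#' median of common essential genes).
#'
#' @param scores Tibble with columns `gene`, `line`, `score`.
#' @param dependent_cutoff Strict threshold (default -0.5).
#'
#' @return The tibble with a logical `dependent` column.
#' @export
classify_dependency <- function(scores, dependent_cutoff = -0.5) {
  if (any(!is.finite(scores$score))) abort("scores must be finite.")
  dplyr::mutate(scores, dependent = .data$score < dependent_cutoff)
}

#' Identify common essential genes across many lines
#'
#' Within each line, genes are ranked by depletion (rank 1 = most negative
#' score). For each gene the 90th percentile of its ranks across lines (its
#' rank in its 90th-percentile least depleting line) is computed; the cutoff
#' X is chosen empirically as the antimode (minimum density) of that
#' distribution, which separates the always-depleted genes from the rest. A
#' gene is flagged common-essential when its rank is at most X in at least
#' 90% of lines.
#'
#' @param scores Tibble with columns `gene`, `line`, `score`; at least 10
#'   lines and 50 genes are recommended (warned otherwise).
#'
#' @return Tibble with `gene`, `q90_rank`, `frac_lines_top`,
#'   `common_essential`; the chosen X is in attribute `"X"` and column `X`.
#' @export
find_common_essentials <- function(scores) {
  wide <- tidyr::pivot_wider(scores[, c("gene", "line", "score")],
                             names_from = "line", values_from = "score")
  m <- as.matrix(wide[-1L])
  rownames(m) <- wide$gene
  if (ncol(m) < 10L || nrow(m) < 50L) {
    warn("fewer than 10 lines or 50 genes; common-essential calling is unstable.")
  }
  if (any(apply(m, 2L, function(col) max(col) == min(col)))) {
    abort("degenerate input: a line has identical scores for all genes.")
  }
  ranks <- apply(m, 2L, rank, ties.method = "average")
  q90 <- apply(ranks, 1L, quantile, probs = 0.9, names = FALSE)

  dens <- density(q90, n = 512)
  y <- dens$y
  interior <- which(diff(sign(diff(y))) == 2) + 1L # local minima
  maxima <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(interior) == 0L || length(maxima) < 2L) {
    warn("rank distribution is unimodal; no common-essential cutoff found.")
    X <- NA_real_
  } else {
    top2 <- sort(maxima[order(y[maxima], decreasing = TRUE)][1:2])
    between <- interior[interior > top2[1L] & interior < top2[2L]]
    cand <- if (length(between)) between else interior
    X <- dens$x[cand[which.min(y[cand])]]
  }

  frac_top <- if (is.na(X)) rep(NA_real_, nrow(ranks)) else rowMeans(ranks <= X)
  tibble::tibble(
    gene = rownames(m),
    q90_rank = q90,
    frac_lines_top = frac_top,
    common_essential = !is.na(frac_top) & frac_top >= 0.9,
    X = X
  ) -> out
  attr(out, "X") <- X
  out
}
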