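#' Expected STAMP count under droplet loading
#'
#' A STAMP (single-cell transcriptome attached to microparticle) arises when
#' a processed bead shared its droplet with at least one cell. Under double
#' Poisson loading the expected STAMP count is `n_beads * P(>= 1 cell)`;
#' with Poisson cell occupancy `lambda` that probability is `1 - exp(-lambda)`,
#' and a fixed occupancy (e.g. 1 cell in every 20 droplets, P = 0.05) may be
#' given directly.
#'
#' @param n_beads Number of beads processed into the library.
#' @param cell_occupancy Probability a droplet holds at least one cell.
#'   Supply either this or `lambda`.
#' @param lambda Mean cells per droplet (Poisson); converted to
#'   `1 - exp(-lambda)`.
#'
#' @return Expected number of STAMPs (numeric scalar).
#' @export
#' @examples
#' expected_stamps(2000, cell_occupancy = 1 / 20) # 100
#' expected_stamps(12000, cell_occupancy = 1 / 20) # 600
expected_stamps <- function(n_beads, cell_occupancy = NULL, lambda = NULL) {
  if (!is.numeric(n_beads) || length(n_beads) != 1L || is.na(n_beads) || n_beads < 0) {
    abort("`n_beads` must be a single non-negative number.")
  }
  if (is.null(cell_occupancy) == is.null(lambda)) {
    abort("supply exactly one of `cell_occupancy` or `lambda`.")
  }
  p <- if (!is.null(cell_occupancy)) {
    assert_proportion(cell_occupancy, "cell_occupancy")
  } else {
    if (lambda < 0) abort("`lambda` must be non-negative.")
    1 - exp(-lambda)
  }
  n_beads * p
}

#' Conditional doublet rate among occupied droplets
#'
#' Under Poisson cell loading with mean `lambda` cells per droplet, the
#' fraction of cell-containing droplets that hold two or more cells is
#' `1 - lambda * exp(-lambda) / (1 - exp(-lambda))`. The limit at
#' `lambda -> 0` is 0.
#'
#' @param lambda Mean cells per droplet (non-negative; vectorised).
#'
#' @return Doublet fraction among occupied droplets.
#' @export
#' @examples
#' conditional_doublet_rate(0.1) # ~0.0492, below the 5% loading bound
conditional_doublet_rate <- function(lambda) {
  if (!is.numeric(lambda) || any(is.na(lambda)) || any(lambda < 0)) {
    abort("`lambda` must be non-negative.")
  }
  out <- ifelse(lambda == 0, 0, 1 - lambda * exp(-lambda) / (1 - exp(-lambda)))
  unname(out)
}

#' Assign a species call to each barnyard barcode
#'
#' A barcode is called species A if its species-A read share is at least
#' `purity_threshold`, species B symmetrically, and "mixed" otherwise.
#' Barcodes with zero total reads are excluded with a warning.
#'
#' @param table Barnyard tibble with columns `reads_a` and `reads_b` (e.g.
#'   from [simulate_barnyard()]).
#' @param purity_threshold Read-share purity needed for a single-species
#'   call, in (0.5, 1].
#'
#' @return The table with a `call` column in {"A", "B", "mixed"}.
#' @export
assign_species <- function(table, purity_threshold = 0.9) {
  if (!is.data.frame(table) || nrow(table) == 0L) abort("`table` must be a non-empty data frame.")
  if (!all(c("reads_a", "reads_b") %in% names(table))) {
    abort("`table` needs `reads_a` and `reads_b` columns.")
  }
  if (purity_threshold <= 0.5 || purity_threshold > 1) {
    abort("`purity_threshold` must be in (0.5, 1].")
  }
  total <- table$reads_a + table$reads_b
  if (any(total == 0L)) {
    warn(sprintf("excluding %d barcode(s) with zero total reads.", sum(total == 0L)))
    table <- table[total > 0L, , drop = FALSE]
    total <- total[total > 0L]
  }
  frac_a <- table$reads_a / total
  dplyr::mutate(table, call = dplyr::case_when(
    frac_a >= purity_threshold ~ "A",
    frac_a <= 1 - purity_threshold ~ "B",
    TRUE ~ "mixed"
  ))
}

#' Summarise a called barnyard table
#'
#' Reports the observed mixed-call fraction, the implied total doublet rate,
#' and the mean cross-species (minor) read fraction among singlet calls.
#' Only doublets pairing the two species are visible as mixed calls; with
#' species proportions p and q = 1 - p the total doublet rate is estimated
#' as `mixed_fraction / (2 p q)`. That correction is an extension of the raw
#' mixed percentage and is labelled as such in the output.
#'
#' @param table Barnyard tibble with a `call` column (see [assign_species()]).
#' @param species_prop Proportion p of species A among cells; defaults to the
#'   fraction of A among single-species calls.
#'
#' @return One-row tibble: `n_barcodes`, `n_singlets`, `mixed_fraction`,
#'   `inferred_total_doublet_rate`, `contamination` (mean minor-species read
#'   fraction among singlets).
#' @export
summarize_barnyard <- function(table, species_prop = NULL) {
  if (!"call" %in% names(table)) abort("run `assign_species()` first.")
  singlet <- table[table$call %in% c("A", "B"), , drop = FALSE]
  if (nrow(singlet) == 0L) abort("no singlet calls in `table`.")
  p <- species_prop %||% mean(singlet$call == "A")
  q <- 1 - p
  mixed_fraction <- mean(table$call == "mixed")
  total <- singlet$reads_a + singlet$reads_b
  minor <- ifelse(singlet$call == "A", singlet$reads_b, singlet$reads_a) / total
  tibble::tibble(
    n_barcodes = nrow(table),
    n_singlets = nrow(singlet),
    mixed_fraction = mixed_fraction,
    inferred_total_doublet_rate = if (p > 0 && q > 0) mixed_fraction / (2 * p * q) else NA_real_,
    contamination = mean(minor)
  )
}

#' Estimate captured STAMPs from the barcode-rank knee
#'
#' Sorts per-barcode UMI totals in decreasing order, forms the normalized
#' cumulative-fraction curve against normalized rank (with the origin
#' prepended), and returns the rank at maximal perpendicular distance from
#' the chord joining the curve's endpoints. A second-difference variant
#' (maximum negative curvature of the cumulative curve) is available for
#' sensitivity checks.
#'
#' @param umi_counts Numeric vector of per-barcode total UMI (or read)
#'   counts; order is irrelevant.
#' @param method "distance" (default, max distance to chord) or
#'   "second_diff".
#'
#' @return Estimated number of STAMPs (integer rank of the knee).
#' @export
#' @examples
#' estimate_stamps_knee(c(rep(10000, 100), rep(100, 1900)))
estimate_stamps_knee <- function(umi_counts, method = c("distance", "second_diff")) {
  method <- match.arg(method)
  x <- sort(as.numeric(umi_counts), decreasing = TRUE)
  n <- length(x)
  if (n < 10L) abort("need at least 10 barcodes.")
  if (max(x) == min(x)) abort("knee indeterminate: all barcode counts are equal.")

  cum <- c(0, cumsum(x) / sum(x))
  rank_frac <- c(0, seq_len(n) / n)

  if (method == "distance") {
    dx <- rank_frac[n + 1L] - rank_frac[1L]
    dy <- cum[n + 1L] - cum[1L]
    dist <- abs(dy * (rank_frac - rank_frac[1L]) - dx * (cum - cum[1L])) / sqrt(dx^2 + dy^2)
    if (max(dist) < 1e-9) abort("knee indeterminate: cumulative curve is linear.")
    best <- which.max(dist) - 1L # drop the prepended origin
  } else {
    d2 <- diff(cum, differences = 2L) # at interior points 1..n-1
    best <- which.min(d2)
    if (abs(min(d2)) < .Machine$double.eps * 10) {
      abort("knee indeterminate: cumulative curve is linear.")
    }
  }
  as.integer(best)
}

#' Fit capture-efficiency slopes from saturation data
#'
#' Ordinary least squares of UMIs (and, when present, genes) on total reads
#' across cells. The slope per 1000 reads is the platform's
#' unique-transcripts-per-additional-thousand-reads capture metric.
#'
#' @param saturation Tibble with columns `reads`, `umis` and optionally
#'   `genes` (see [simulate_saturation_curves()]).
#'
#' @return An object of class `saturation_fit`; see [tidy()] / [glance()]
#'   methods. Key fields: `slope_umis_per_read`, `slope_umis_per_1000`,
#'   `slope_genes_per_read`, intercepts, `n_cells`, `read_range`.
#' @export
fit_capture_slope <- function(saturation) {
  if (!all(c("reads", "umis") %in% names(saturation))) {
    abort("`saturation` needs `reads` and `umis` columns.")
  }
  if (nrow(saturation) < 3L || length(unique(saturation$reads)) < 3L) {
    abort("need at least 3 cells with distinct read counts.")
  }
  umi_fit <- lm(umis ~ reads, data = saturation)
  gene_fit <- if ("genes" %in% names(saturation)) {
    lm(genes ~ reads, data = saturation)
  }
  out <- list(
    slope_umis_per_read = unname(coef(umi_fit)[["reads"]]),
    slope_umis_per_1000 = unname(coef(umi_fit)[["reads"]]) * 1000,
    intercept_umis = unname(coef(umi_fit)[[1L]]),
    slope_genes_per_read = if (!is.null(gene_fit)) unname(coef(gene_fit)[["reads"]]) else NA_real_,
    slope_genes_per_1000 = if (!is.null(gene_fit)) unname(coef(gene_fit)[["reads"]]) * 1000 else NA_real_,
    intercept_genes = if (!is.null(gene_fit)) unname(coef(gene_fit)[[1L]]) else NA_real_,
    n_cells = nrow(saturation),
    read_range = range(saturation$reads),
    umi_fit = umi_fit,
    gene_fit = gene_fit
  )
  class(out) <- "saturation_fit"
  out
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat("Capture-efficiency fit over", x$n_cells, "cells\n")
  cat(sprintf("  UMIs : %.1f per 1000 reads (intercept %.1f)\n",
              x$slope_umis_per_1000, x$intercept_umis))
  if (!is.na(x$slope_genes_per_1000)) {
    cat(sprintf("  genes: %.1f per 1000 reads (intercept %.1f)\n",
                x$slope_genes_per_1000, x$intercept_genes))
  }
  invisible(x)
}

#' @export
tidy.saturation_fit <- function(x, ...) {
  rows <- list(tibble::tibble(
    response = "umis",
    term = c("(Intercept)", "reads"),
    estimate = unname(coef(x$umi_fit))
  ))
  if (!is.null(x$gene_fit)) {
    rows <- c(rows, list(tibble::tibble(
      response = "genes",
      term = c("(Intercept)", "reads"),
      estimate = unname(coef(x$gene_fit))
    )))
  }
  dplyr::bind_rows(rows)
}

#' @export
glance.saturation_fit <- function(x, ...) {
  tibble::tibble(
    slope_umis_per_1000 = x$slope_umis_per_1000,
    slope_genes_per_1000 = x$slope_genes_per_1000,
    n_cells = x$n_cells,
    min_reads = x$read_range[1L],
    max_reads = x$read_range[2L]
  )
}

#' Correct observed barcodes against a whitelist
#'
#' Maps each observed barcode to the unique whitelist entry within the
#' hamming-distance budget (1 for cell barcodes, 2 for UMIs). An observed
#' barcode with no entry in budget, or with two or more entries tied at the
#' minimal in-budget distance, stays unassigned. In cell mode the whitelist
#' must have pairwise minimum distance 3, which guarantees distance-1
#' corrections are unambiguous.
#'
#' @param observed Character vector of observed barcodes (equal length).
#' @param whitelist Character vector of reference barcodes (same length as
#'   the observed ones).
#' @param mode "cell" (budget 1, whitelist validated to pairwise minimum
#'   distance 3) or "umi" (budget 2, no validation).
#' @param max_hamming Override of the distance budget.
#'
#' @return Tibble with columns `observed`, `assigned` (NA when unassigned)
#'   and `distance`.
#' @export
#' @examples
#' correct_barcodes("AAAT", c("AAAA", "CCCC"))
correct_barcodes <- function(observed, whitelist, mode = c("cell", "umi"),
                             max_hamming = NULL) {
  mode <- match.arg(mode)
  budget <- max_hamming %||% switch(mode, cell = 1L, umi = 2L)
  lens <- unique(nchar(c(observed, whitelist)))
  if (length(lens) != 1L) abort("all barcodes must have equal length.")

  if (mode == "cell" && length(whitelist) > 1L) {
    wd <- hamming_matrix(whitelist, whitelist)
    diag(wd) <- NA
    if (min(wd, na.rm = TRUE) < 3L) {
      abort("whitelist violates the minimum pairwise distance of 3 required in cell mode.")
    }
  }

  d <- hamming_matrix(observed, whitelist)
  assigned <- character(length(observed))
  dist_out <- integer(length(observed))
  for (i in seq_along(observed)) {
    di <- d[i, ]
    dmin <- min(di)
    hits <- which(di == dmin)
    if (dmin <= budget && length(hits) == 1L) {
      assigned[i] <- whitelist[hits]
      dist_out[i] <- dmin
    } else {
      assigned[i] <- NA_character_
      dist_out[i] <- NA_integer_
    }
  }
  tibble::tibble(observed = observed, assigned = assigned, distance = dist_out)
}
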