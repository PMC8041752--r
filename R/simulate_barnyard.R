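#' Configuration for the mixed-species barnyard simulator
#'
#' @param n_barcodes Number of bead barcodes.
#' @param frac_human Fraction of cells from species A ("human"); the rest are
#'   species B ("mouse").
#' @param doublet_rate Probability a barcode captures two cells (drawn
#'   independently of the species mix).
#' @param contamination Expected fraction of a singlet's reads assigned to
#'   the alternative species (barcode swapping / ambient level).
#' @param reads_mean_log,reads_sd_log Lognormal parameters of per-barcode
#'   total read depth.
#' @param new_umi_rate Probability a read reports a previously unseen UMI
#'   (so expected UMIs = rate x reads at these depths).
#' @param seed Integer seed.
#'
#' @return A list of class `barnyard_sim_config`.
#' @export
barnyard_sim_config <- function(n_barcodes = 2000, frac_human = 0.75,
                                doublet_rate = 0.01, contamination = 0.0152,
                                reads_mean_log = log(10000),
                                reads_sd_log = 0.5, new_umi_rate = 0.29,
                                seed = 1L) {
  structure(list(
    n_barcodes = assert_count(n_barcodes, "n_barcodes"),
    frac_human = assert_proportion(frac_human, "frac_human"),
    doublet_rate = assert_proportion(doublet_rate, "doublet_rate"),
    contamination = assert_proportion(contamination, "contamination"),
    reads_mean_log = assert_positive(reads_mean_log, "reads_mean_log"),
    reads_sd_log = assert_proportion(reads_sd_log, "reads_sd_log", hi = Inf),
    new_umi_rate = assert_proportion(new_umi_rate, "new_umi_rate"),
    seed = assert_count(seed, "seed", min = 0L)
  ), class = "barnyard_sim_config")
}

#' Simulate a barnyard (mixed-species) barcode table with truth labels
#'
#' Each barcode is a singlet (one cell of one species, with a
#' `Binomial(contamination)` share of its reads flipped to the other
#' species) or a doublet (both species mixed with a Uniform(0.25, 0.75)
#' proportion). Per-species UMIs follow the new-UMI-per-read process: every
#' read opens a new UMI with probability `new_umi_rate`.
#'
#' @param config A [barnyard_sim_config()].
#'
#' @return A tibble with columns `barcode`, `reads_a`, `reads_b`, `umis_a`,
#'   `umis_b` and truth columns `true_type` ("singlet"/"doublet") and
#'   `true_species` ("A", "B" or "mixed"). Attribute `species` names the two
#'   species.
#' @export
#' @examples
#' bt <- simulate_barnyard(barnyard_sim_config(n_barcodes = 100, seed = 3))
#' table(bt$true_type)
simulate_barnyard <- function(config = barnyard_sim_config()) {
  stopifnot(inherits(config, "barnyard_sim_config"))
  set.seed(config$seed)
  n <- config$n_barcodes

  is_doublet <- runif(n) < config$doublet_rate
  species_a <- runif(n) < config$frac_human
  total_reads <- pmax(1L, round(rlnorm(n, config$reads_mean_log, config$reads_sd_log)))

  frac_a <- ifelse(
    is_doublet,
    runif(n, 0.25, 0.75),
    ifelse(species_a, 1 - config$contamination, config$contamination)
  )
  reads_a <- rbinom(n, total_reads, frac_a)
  reads_b <- total_reads - reads_a

  tibble::tibble(
    barcode = sprintf("BC%05d", seq_len(n)),
    reads_a = reads_a,
    reads_b = reads_b,
    umis_a = rbinom(n, reads_a, config$new_umi_rate),
    umis_b = rbinom(n, reads_b, config$new_umi_rate),
    true_type = ifelse(is_doublet, "doublet", "singlet"),
    true_species = ifelse(is_doublet, "mixed", ifelse(species_a, "A", "B"))
  ) -> out
  attr(out, "species") <- c(A = "human", B = "mouse")
  out
}

#' Simulate per-cell sequencing saturation curves
#'
#' Generates per-cell total reads (lognormal), UMIs via the new-UMI-per-read
#' Bernoulli process (`UMIs ~ Binomial(reads, new_umi_rate)`, so `E[UMIs |
#' reads] = new_umi_rate * reads`, the low-depth regime in which the
#' capture-efficiency slope equals the per-read rate), and distinct genes by
#' scattering UMIs over a gene pool.
#'
#' @param n_cells Number of cells.
#' @param new_umi_rate Probability a read yields a new UMI, in (0, 1].
#' @param reads_mean_log,reads_sd_log Lognormal read-depth parameters
#'   (default: centred near 20,000 reads per cell).
#' @param gene_pool Number of distinct genes UMIs can land on.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `cell`, `reads`, `umis`, `genes`.
#' @export
#' @examples
#' sat <- simulate_saturation_curves(50, 0.29, seed = 2)
#' fit_capture_slope(sat)
simulate_saturation_curves <- function(n_cells, new_umi_rate,
                                       reads_mean_log = log(20000),
                                       reads_sd_log = 0.4,
                                       gene_pool = 10000, seed = 1L) {
  n_cells <- assert_count(n_cells, "n_cells")
  new_umi_rate <- assert_proportion(new_umi_rate, "new_umi_rate", lo = 1e-12)
  gene_pool <- assert_count(gene_pool, "gene_pool")
  set.seed(assert_count(seed, "seed", min = 0L))

  reads <- round(rlnorm(n_cells, reads_mean_log, reads_sd_log))
  umis <- ifelse(reads > 0L, rbinom(n_cells, reads, new_umi_rate), 0L)
  if (new_umi_rate == 1) umis <- reads
  genes <- vapply(umis, function(u) {
    if (u == 0L) return(0L)
    length(unique(sample.int(gene_pool, u, replace = TRUE)))
  }, integer(1))

  tibble::tibble(
    cell = sprintf("cell%05d", seq_len(n_cells)),
    reads = as.integer(reads),
    umis = as.integer(umis),
    genes = genes
  )
}
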