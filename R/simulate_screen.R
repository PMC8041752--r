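#' Configuration for the pooled CRISPR depletion-screen simulator
#'
#' @param n_genes Number of targeted genes.
#' @param sgrnas_per_gene Guides per gene.
#' @param n_control_sgrnas Non-targeting control guides (gene = "CONTROL",
#'   true log2 fold change 0).
#' @param n_lines Number of cell lines screened.
#' @param n_essential Number of essential genes (the first `n_essential`
#'   genes) given the depleting effect.
#' @param essential_lfc True log2 fold change of essential-gene guides
#'   (negative = depletion).
#' @param count_depth Expected initial counts per guide.
#' @param low_count_fraction Fraction of guides seeded with initial counts
#'   low enough to fall below the combined-count filter.
#' @param replicates_per_line Integer vector (length 1 or `n_lines`) of
#'   replicate screens per line.
#' @param lfc_noise_sd Per-guide standard deviation of the true log2 effect.
#' @param dispersion Negative-binomial dispersion of counts.
#' @param seed Integer seed.
#'
#' @return A list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_genes = 500, sgrnas_per_gene = 7,
                              n_control_sgrnas = 953, n_lines = 4,
                              n_essential = 25, essential_lfc = -2,
                              count_depth = 500, low_count_fraction = 0.05,
                              replicates_per_line = c(2, 1, 1, 1),
                              lfc_noise_sd = 0.3, dispersion = 0.05,
                              seed = 1L) {
  n_lines <- assert_count(n_lines, "n_lines")
  if (length(replicates_per_line) == 1L) {
    replicates_per_line <- rep(replicates_per_line, n_lines)
  }
  if (length(replicates_per_line) != n_lines) {
    abort("`replicates_per_line` must have length 1 or `n_lines`.")
  }
  structure(list(
    n_genes = assert_count(n_genes, "n_genes"),
    sgrnas_per_gene = assert_count(sgrnas_per_gene, "sgrnas_per_gene"),
    n_control_sgrnas = assert_count(n_control_sgrnas, "n_control_sgrnas", min = 0L),
    n_lines = n_lines,
    n_essential = assert_count(n_essential, "n_essential", min = 0L),
    essential_lfc = as.numeric(essential_lfc),
    count_depth = assert_positive(count_depth, "count_depth"),
    low_count_fraction = assert_proportion(low_count_fraction, "low_count_fraction"),
    replicates_per_line = as.integer(replicates_per_line),
    lfc_noise_sd = assert_proportion(lfc_noise_sd, "lfc_noise_sd", hi = Inf),
    dispersion = assert_positive(dispersion, "dispersion"),
    seed = assert_count(seed, "seed", min = 0L)
  ), class = "screen_sim_config")
}

#' Simulate a pooled CRISPR depletion screen with known effects
#'
#' Initial guide abundances are negative-binomial around `count_depth`
#' (a `low_count_fraction` of guides is seeded at a much lower depth so the
#' combined-count filter has work to do). Final abundances are
#' `initial x 2^(true lfc + guide noise)` with count noise; essential genes
#' carry `essential_lfc`, every other gene and all controls carry 0.
#'
#' @param config A [screen_sim_config()].
#'
#' @return A list with `counts` (tibble: `sgrna`, `gene`, `line`,
#'   `replicate`, `initial`, `final`) and `truth` (tibble: `gene`,
#'   `true_lfc`, `essential`).
#' @export
#' @examples
#' scr <- simulate_crispr_screen(screen_sim_config(n_genes = 20, n_lines = 2,
#'   n_control_sgrnas = 30, replicates_per_line = 1, seed = 5))
#' head(scr$counts)
simulate_crispr_screen <- function(config = screen_sim_config()) {
  stopifnot(inherits(config, "screen_sim_config"))
  if (config$n_genes < 1L) abort("gene list must be non-empty.")
  set.seed(config$seed)

  genes <- sprintf("geneS%04d", seq_len(config$n_genes))
  essential <- genes[seq_len(min(config$n_essential, config$n_genes))]
  true_lfc <- setNames(numeric(config$n_genes), genes)
  true_lfc[essential] <- config$essential_lfc

  sg <- tibble::tibble(
    sgrna = sprintf("sg%05d", seq_len(config$n_genes * config$sgrnas_per_gene + config$n_control_sgrnas)),
    gene = c(rep(genes, each = config$sgrnas_per_gene),
             rep("CONTROL", config$n_control_sgrnas))
  )
  n_sg <- nrow(sg)
  sg$true_lfc <- ifelse(sg$gene == "CONTROL", 0, true_lfc[sg$gene])
  low <- runif(n_sg) < config$low_count_fraction
  depth <- ifelse(low, config$count_depth / 50, config$count_depth)

  lines <- sprintf("line%d", seq_len(config$n_lines))
  size <- 1 / config$dispersion
  out <- purrr::map_dfr(seq_len(config$n_lines), function(i) {
    purrr::map_dfr(seq_len(config$replicates_per_line[i]), function(r) {
      initial <- rnbinom(n_sg, mu = depth, size = size)
      # guide-and-sample measurement noise around the gene-level effect;
      # final counts resample the library at the shifted abundance, so with
      # no effect the initial and final draws are exchangeable
      guide_lfc <- sg$true_lfc + rnorm(n_sg, 0, config$lfc_noise_sd)
      final <- rnbinom(n_sg, mu = depth * 2^guide_lfc, size = size)
      tibble::tibble(
        sgrna = sg$sgrna, gene = sg$gene, line = lines[i],
        replicate = r, initial = initial, final = final
      )
    })
  })

  list(
    counts = out,
    truth = tibble::tibble(
      gene = genes, true_lfc = as.numeric(true_lfc),
      essential = genes %in% essential
    )
  )
}
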