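#' Configuration for the cell-cycle expression simulator
#'
#' Builds a validated configuration for [simulate_cell_cycle_dataset()]. The
#' simulator emulates an asynchronous population cycling through five phases:
#' each cell sits in one phase, the genes of that phase's marker set are
#' up-regulated, and the targets of transcription factors peaking in that
#' phase move up (activated targets) or down (repressed targets) by the same
#' fold change.
#'
#' @param n_cells Number of cells.
#' @param n_genes Total genes; must accommodate the phase marker sets, the TF
#'   genes and their targets (`5 * genes_per_phase + n_tfs * (1 +
#'   targets_per_tf)`), with the remainder flat background genes.
#' @param phases Ordered labels of the five cell-cycle phases.
#' @param genes_per_phase Marker genes per phase (sets are disjoint).
#' @param n_tfs Number of simulated transcription factors; peak phases are
#'   assigned round-robin over `phases`.
#' @param targets_per_tf Targets per TF regulon (disjoint across TFs).
#' @param activation_fraction Fraction of each regulon's targets with
#'   activating mode; the rest are repressing.
#' @param effect_size Fold change applied in a gene's active phase
#'   (multiplied for up-regulation, divided for repression; `1` = no signal).
#' @param baseline_mean Expected count of a background gene in an
#'   average-sized cell.
#' @param dispersion Negative-binomial dispersion (variance = mu + dispersion
#'   * mu^2).
#' @param dropout_extra Extra zero-inflation: each molecule is kept with
#'   probability `1 - dropout_extra` (binomial thinning).
#' @param size_factor_sdlog Standard deviation (log scale) of lognormal
#'   per-cell size factors. Set to `0` for an exchangeable-depth population,
#'   which is the condition under which score correlations have a calibrated
#'   null (see the methods vignette).
#' @param n_networks Number of regulon source networks to emit; networks
#'   beyond the first are independent subsamples of each regulon's targets,
#'   emulating partially overlapping interactomes.
#' @param target_subsample Fraction of targets retained in each derived
#'   network.
#' @param seed Integer seed; identical seeds give bit-identical output.
#'
#' @return A list of class `cycle_sim_config`.
#' @export
cycle_sim_config <- function(n_cells = 500, n_genes = 1200,
                             phases = cycle_phases(),
                             genes_per_phase = 40, n_tfs = 10,
                             targets_per_tf = 20, activation_fraction = 0.7,
                             effect_size = 3, baseline_mean = 0.5,
                             dispersion = 0.3, dropout_extra = 0.05,
                             size_factor_sdlog = 0.3, n_networks = 2,
                             target_subsample = 0.8, seed = 1L) {
  cfg <- list(
    n_cells = assert_count(n_cells, "n_cells"),
    n_genes = assert_count(n_genes, "n_genes"),
    phases = as.character(phases),
    genes_per_phase = assert_count(genes_per_phase, "genes_per_phase"),
    n_tfs = assert_count(n_tfs, "n_tfs"),
    targets_per_tf = assert_count(targets_per_tf, "targets_per_tf"),
    activation_fraction = assert_proportion(activation_fraction, "activation_fraction"),
    effect_size = assert_positive(effect_size, "effect_size"),
    baseline_mean = assert_positive(baseline_mean, "baseline_mean"),
    dispersion = assert_positive(dispersion, "dispersion"),
    dropout_extra = assert_proportion(dropout_extra, "dropout_extra"),
    size_factor_sdlog = assert_proportion(size_factor_sdlog, "size_factor_sdlog", hi = Inf),
    n_networks = assert_count(n_networks, "n_networks"),
    target_subsample = assert_proportion(target_subsample, "target_subsample", lo = 1e-6),
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (length(cfg$phases) != 5L || anyDuplicated(cfg$phases)) {
    abort("`phases` must be five distinct labels.")
  }
  needed <- 5L * cfg$genes_per_phase + cfg$n_tfs * (1L + cfg$targets_per_tf)
  if (cfg$n_genes < needed) {
    abort(sprintf("`n_genes` must be >= %d to hold phase sets, TFs and targets.", needed))
  }
  structure(cfg, class = "cycle_sim_config")
}

#' Simulate a five-phase cell-cycle scRNA-seq dataset with known truth
#'
#' Draws a sparse genes x cells UMI count matrix from a negative-binomial
#' model with lognormal cell size factors. Cells are assigned uniformly to
#' the five phases; phase marker genes, TF genes and TF targets are modulated
#' by `effect_size` in their active phase. Output includes the phase gene
#' sets, one or more regulon networks, and ground-truth tables for
#' parameter-recovery tests.
#'
#' @param config A [cycle_sim_config()].
#'
#' @return A list with elements `counts` (dgCMatrix, genes x cells),
#'   `gene_sets` (named list of 5 character vectors), `regulons` (tibble:
#'   `tf`, `target`, `mode`, `network`), `networks` (named list of regulon
#'   tibbles, one per source network), `truth` (list with `cells` and `tfs`
#'   tibbles) and the `config`.
#' @export
#' @examples
#' sim <- simulate_cell_cycle_dataset(cycle_sim_config(n_cells = 50, seed = 7))
#' dim(sim$counts)
simulate_cell_cycle_dataset <- function(config = cycle_sim_config()) {
  stopifnot(inherits(config, "cycle_sim_config"))
  n_cells <- config$n_cells
  n_genes <- config$n_genes

  set.seed(config$seed)
  phases <- config$phases
  gpp <- config$genes_per_phase

  genes <- sprintf("gene%05d", seq_len(n_genes))
  idx <- 0L
  gene_sets <- lapply(seq_along(phases), function(i) {
    genes[(i - 1L) * gpp + seq_len(gpp)]
  })
  names(gene_sets) <- phases
  idx <- 5L * gpp

  tf_genes <- sprintf("TF%03d", seq_len(config$n_tfs))
  genes[idx + seq_len(config$n_tfs)] <- tf_genes
  idx <- idx + config$n_tfs

  target_ids <- genes[idx + seq_len(config$n_tfs * config$targets_per_tf)]
  tf_peak <- phases[((seq_len(config$n_tfs) - 1L) %% 5L) + 1L]

  regulons <- tibble::tibble(
    tf = rep(tf_genes, each = config$targets_per_tf),
    target = target_ids,
    mode = ifelse(
      runif(length(target_ids)) < config$activation_fraction,
      "Activation", "Repression"
    ),
    network = "net1"
  )

  cells <- sprintf("cell%05d", seq_len(n_cells))
  cell_phase <- sample(phases, n_cells, replace = TRUE)

  # per-gene baseline means with mild biological spread
  base_mu <- config$baseline_mean * exp(rnorm(n_genes, 0, 0.25))
  names(base_mu) <- genes
  size_factor <- rlnorm(n_cells, 0, config$size_factor_sdlog)

  # log2 fold-change matrix restricted to modulated genes, per phase
  eff <- config$effect_size
  phase_mult <- matrix(1, nrow = n_genes, ncol = 5L,
                       dimnames = list(genes, phases))
  for (i in seq_along(phases)) {
    phase_mult[gene_sets[[i]], i] <- eff
  }
  for (k in seq_len(config$n_tfs)) {
    p <- tf_peak[k]
    phase_mult[tf_genes[k], p] <- eff
    reg <- regulons[regulons$tf == tf_genes[k], ]
    up <- reg$target[reg$mode == "Activation"]
    dn <- reg$target[reg$mode == "Repression"]
    phase_mult[up, p] <- phase_mult[up, p] * eff
    phase_mult[dn, p] <- phase_mult[dn, p] / eff
  }

  # expected counts genes x cells: baseline * phase multiplier * size factor
  mu <- phase_mult[, match(cell_phase, phases), drop = FALSE] * base_mu
  mu <- sweep(mu, 2L, size_factor, `*`)

  counts <- matrix(
    rnbinom(n_genes * n_cells, mu = as.vector(mu), size = 1 / config$dispersion),
    nrow = n_genes, ncol = n_cells, dimnames = list(genes, cells)
  )
  if (config$dropout_extra > 0) {
    nz <- counts > 0L
    counts[nz] <- rbinom(sum(nz), counts[nz], 1 - config$dropout_extra)
  }

  networks <- list(net1 = regulons)
  if (config$n_networks > 1L) {
    keep_n <- max(1L, round(config$target_subsample * config$targets_per_tf))
    for (k in 2L:config$n_networks) {
      nm <- paste0("net", k)
      sub <- dplyr::group_modify(
        dplyr::group_by(regulons, .data$tf),
        function(d, key) d[sort(sample(nrow(d), min(keep_n, nrow(d)))), ]
      )
      sub <- dplyr::ungroup(sub)
      sub$network <- nm
      networks[[nm]] <- sub[, c("tf", "target", "mode", "network")]
    }
  }

  list(
    counts = as_sparse(counts),
    gene_sets = gene_sets,
    regulons = regulons,
    networks = networks,
    truth = list(
      cells = tibble::tibble(cell = cells, phase = cell_phase),
      tfs = tibble::tibble(tf = tf_genes, peak_phase = tf_peak)
    ),
    config = config
  )
}
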