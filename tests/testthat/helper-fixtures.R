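# shared fixture builders; all seeded, all built in code

small_cycle_sim <- function(seed = 1, ...) {
  simulate_cell_cycle_dataset(cycle_sim_config(
    n_cells = 200, n_genes = 800, genes_per_phase = 30, n_tfs = 5,
    targets_per_tf = 15, seed = seed, ...
  ))
}

# run the phase-scoring chain on a simulation
phase_chain <- function(sim, scale_factor = 10000) {
  norm <- log_normalize(sim$counts, scale_factor = scale_factor)
  raw <- score_gene_sets(norm, sim$gene_sets)
  pn <- normalize_phase_scores(raw)
  list(norm = norm, raw = raw, norm1 = pn$norm1, norm2 = pn$norm2)
}

# fraction of TFs whose max-|r| phase matches the simulated peak phase
peak_phase_recovery <- function(cors, truth) {
  peak <- dplyr::slice_max(dplyr::group_by(cors, tf), abs(estimate),
                           n = 1, with_ties = FALSE)
  peak <- dplyr::ungroup(peak)
  mean(peak$phase[match(truth$tf, peak$tf)] == truth$peak_phase, na.rm = TRUE)
}

# guide-level lfc tibble with known distributions, for depletion-test checks
synthetic_lfc_tbl <- function(n_genes = 10, n_gene_sgrnas = 7,
                              n_controls = 953, gene_shift = 0,
                              line = "line1", seed = 1) {
  set.seed(seed)
  tibble::tibble(
    sgrna = sprintf("sg%05d", seq_len(n_genes * n_gene_sgrnas + n_controls)),
    gene = c(rep(sprintf("g%03d", seq_len(n_genes)), each = n_gene_sgrnas),
             rep("CONTROL", n_controls)),
    line = line,
    replicate = 1L,
    lfc = c(rnorm(n_genes * n_gene_sgrnas, gene_shift, 1), rnorm(n_controls, 0, 1))
  )
}
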