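#' Build a validated pipeline configuration
#'
#' Collects every stage toggle and threshold used by [run_pipeline()], with
#' the analysis defaults: species-call purity 0.9, gene detection fraction
#' 0.10, more-than-10 expressed targets per regulon, correlation thresholds
#' 0.3 (single-network, p < 0.01 unadjusted) and 0.35 (multi-network,
#' Bonferroni-adjusted p < 0.05), combined guide-count filter 400,
#' dependency cutoff -0.5, normalization scale factor 10,000. Unknown keys
#' are rejected.
#'
#' @param seed Integer seed used for every stochastic stage.
#' @param outdir Output directory.
#' @param stages Named logical list toggling `simulate`, `qc`, `phases`,
#'   `regulons`, `meta`, `crispr`; missing entries default to `TRUE`.
#' @param purity_threshold,min_cell_fraction,min_targets Thresholds (see
#'   description).
#' @param r_threshold_single,r_threshold_meta,p_threshold,alpha Correlation
#'   pass thresholds.
#' @param min_sgrna_counts,dependency_cutoff CRISPR thresholds.
#' @param scale_factor,on_threshold Normalization scale and phase-on
#'   threshold.
#' @param sim Named list of simulator configurations (`cycle`, `barnyard`,
#'   `saturation`, `screen`); defaults are filled in for missing entries.
#' @param paths Named list of input paths used when `stages$simulate` is
#'   `FALSE`: `counts` (MTX trio directory or dense TSV), `gene_sets`
#'   (GMT), `regulons` (one or more TRRUST-style TSVs).
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("cyclereg_run_"),
                            stages = list(),
                            purity_threshold = 0.9, min_cell_fraction = 0.10,
                            min_targets = 10, r_threshold_single = 0.3,
                            r_threshold_meta = 0.35, p_threshold = 0.01,
                            alpha = 0.05, min_sgrna_counts = 400,
                            dependency_cutoff = -0.5, scale_factor = 10000,
                            on_threshold = 0, sim = list(), paths = list()) {
  stage_names <- c("simulate", "qc", "phases", "regulons", "meta", "crispr")
  if (length(setdiff(names(stages), stage_names))) {
    abort(sprintf("unknown stage toggle(s): %s",
                  paste(setdiff(names(stages), stage_names), collapse = ", ")))
  }
  toggles <- setNames(rep(TRUE, length(stage_names)), stage_names)
  toggles[names(stages)] <- unlist(stages)

  sim_names <- c("cycle", "barnyard", "saturation", "screen")
  if (length(setdiff(names(sim), sim_names))) {
    abort(sprintf("unknown sim config(s): %s",
                  paste(setdiff(names(sim), sim_names), collapse = ", ")))
  }
  seed <- assert_count(seed, "seed", min = 0L)
  cfg <- list(
    seed = seed,
    outdir = outdir,
    stages = as.list(toggles),
    purity_threshold = purity_threshold,
    min_cell_fraction = min_cell_fraction,
    min_targets = min_targets,
    r_threshold_single = r_threshold_single,
    r_threshold_meta = r_threshold_meta,
    p_threshold = p_threshold,
    alpha = alpha,
    min_sgrna_counts = min_sgrna_counts,
    dependency_cutoff = dependency_cutoff,
    scale_factor = scale_factor,
    on_threshold = on_threshold,
    sim = list(
      cycle = sim$cycle %||% cycle_sim_config(seed = seed),
      barnyard = sim$barnyard %||% barnyard_sim_config(seed = seed + 1L),
      saturation = sim$saturation %||% list(n_cells = 500, new_umi_rate = 0.29,
                                            seed = seed + 2L),
      screen = sim$screen %||% screen_sim_config(seed = seed + 3L)
    ),
    paths = paths
  )
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments; unknown keys are rejected.
#'
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  if (length(setdiff(names(vals), known))) {
    abort(sprintf("unknown config key(s): %s",
                  paste(setdiff(names(vals), known), collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Executes the toggled stages in order — simulate (or load inputs), QC,
#' phase scoring, regulon activity, multi-network enrichment, CRISPR
#' depletion — writing each stage's tables as TSV (with a provenance header
#' naming the package version and configuration hash) into
#' `config$outdir`, plus `config.yml` and `run_log.txt`. Identical seeds
#' give bit-identical outputs.
#'
#' @param config A [pipeline_config()].
#'
#' @return Invisibly, a list of the in-memory stage results plus a `report`
#'   tibble of written files.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages

  # fail on missing inputs before any compute
  if (!st$simulate) {
    needed <- c("counts", "gene_sets", "regulons")
    missing_keys <- setdiff(needed, names(config$paths))
    if (length(missing_keys)) {
      abort(sprintf("stages need input path(s): %s",
                    paste(missing_keys, collapse = ", ")))
    }
    for (p in unlist(config$paths)) {
      if (!file.exists(p) && !dir.exists(p)) abort(sprintf("missing input: %s", p))
    }
  }

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_plain <- unclass(config)
  cfg_plain$sim <- lapply(cfg_plain$sim, unclass)
  # hash the analysis parameters, not the output location
  hash <- rlang::hash(cfg_plain[setdiff(names(cfg_plain), "outdir")])
  yaml::write_yaml(cfg_plain, file.path(config$outdir, "config.yml"))
  emit <- function(tbl, name) {
    path <- file.path(config$outdir, name)
    write_output_tsv(tbl, path, hash, config$seed)
    path
  }

  results <- list()
  files <- character()

  if (st$simulate) {
    sim <- simulate_cell_cycle_dataset(config$sim$cycle)
    results$sim <- sim
    counts <- sim$counts
    gene_sets <- sim$gene_sets
    networks <- sim$networks
    regulons <- sim$regulons
  } else {
    counts <- read_count_matrix(config$paths$counts)
    gene_sets <- read_gmt(config$paths$gene_sets)
    reg_paths <- config$paths$regulons
    networks <- lapply(seq_along(reg_paths), function(i) {
      read_regulons(reg_paths[[i]], network = paste0("net", i))
    })
    names(networks) <- vapply(networks, function(x) x$network[1L], "")
    regulons <- networks[[1L]]
  }

  if (st$qc) {
    bt <- simulate_barnyard(config$sim$barnyard)
    called <- assign_species(bt, purity_threshold = config$purity_threshold)
    results$barnyard <- summarize_barnyard(called)
    files <- c(files, emit(called, "barnyard_calls.tsv"),
               emit(results$barnyard, "barnyard_summary.tsv"))

    sat_cfg <- config$sim$saturation
    sat <- simulate_saturation_curves(sat_cfg$n_cells, sat_cfg$new_umi_rate,
                                      seed = sat_cfg$seed)
    fit <- fit_capture_slope(sat)
    results$saturation <- glance(fit)
    results$knee <- estimate_stamps_knee(called$umis_a + called$umis_b)
    files <- c(files, emit(results$saturation, "saturation_fit.tsv"))
  }

  norm <- NULL
  phase_norm <- NULL
  if (st$phases || st$regulons || st$meta) {
    norm <- log_normalize(counts, scale_factor = config$scale_factor)
    raw <- score_gene_sets(norm, gene_sets)
    phase_norm <- normalize_phase_scores(raw)
  }
  if (st$phases) {
    ordering <- call_and_order(phase_norm$norm2, on_threshold = config$on_threshold)
    results$phases <- ordering
    files <- c(files, emit(phase_norm$norm2, "phase_scores.tsv"),
               emit(ordering, "phase_calls.tsv"))
  }

  expressed <- NULL
  if (st$regulons || st$meta) {
    expressed <- rownames(filter_expressed_genes(counts, config$min_cell_fraction))
  }
  if (st$regulons) {
    kept <- filter_regulons(regulons, expressed, min_targets = config$min_targets)
    activity <- score_regulon_activity(norm[rownames(norm) %in% expressed, ], kept)
    results$regulon_correlations <- correlate_activity_phases(
      activity, phase_norm$norm1,
      r_threshold = config$r_threshold_single,
      p_threshold = config$p_threshold, adjust = "none"
    )
    files <- c(files, emit(results$regulon_correlations, "regulon_phase_correlations.tsv"))
  }

  if (st$meta) {
    signature <- signature_zscores(norm[rownames(norm) %in% expressed, ])
    nes <- score_networks(signature, networks, min_targets = config$min_targets)
    integrated <- avg_score_integrate(nes)
    results$meta_correlations <- correlate_meta(
      integrated, phase_norm$norm1,
      r_threshold = config$r_threshold_meta, alpha = config$alpha
    )
    files <- c(files, emit(results$meta_correlations, "meta_phase_correlations.tsv"))
  }

  if (st$crispr) {
    scr <- simulate_crispr_screen(config$sim$screen)
    lfc <- sgrna_log2fc(filter_sgrnas(scr$counts, config$min_sgrna_counts))
    scores <- gene_crispr_score(lfc)
    dep <- classify_dependency(scores[scores$gene != "CONTROL", ],
                               dependent_cutoff = config$dependency_cutoff)
    results$crispr <- dep
    files <- c(files, emit(dep, "crispr_gene_scores.tsv"))
  }

  writeLines(c(
    sprintf("cyclereg %s", as.character(utils::packageVersion("cyclereg"))),
    sprintf("seed: %d", config$seed),
    sprintf("config_hash: %s", hash),
    sprintf("stages: %s", paste(names(st)[unlist(st)], collapse = ", ")),
    sprintf("outputs: %s", paste(basename(files), collapse = ", "))
  ), file.path(config$outdir, "run_log.txt"))

  results$report <- tibble::tibble(file = c(files, file.path(config$outdir, "run_log.txt")))
  invisible(results)
}
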