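# cyclereg

Droplet scRNA-seq quality control, cell-cycle phase scoring, and regulon
activity inference — with seeded synthetic data for every step.

## What this package is for

Droplet platforms co-encapsulate barcoded beads and cells, and the first
questions about any run are statistical: how many cells should this many
beads have captured, what doublet rate does the loading density imply, how
pure are the species calls in a mixed (barnyard) experiment, and how many
unique transcripts does each extra unit of sequencing buy? Downstream, the
same single-cell profiles can be pushed further: scoring each cell against
five cell-cycle phase gene sets (G1/S, S, G2/M, M, M/G1), inferring
transcription-factor (TF) activity from the summarized expression of each
TF's target set (its *regulon*), correlating activity with the phases,
integrating enrichment scores across several regulon networks, and — for
candidate regulators — quantifying proliferation effects in pooled CRISPR
depletion screens.

cyclereg implements that chain as plain R functions that take and return
tibbles (count matrices are sparse `Matrix::dgCMatrix`, genes × cells),
so each stage pipes into the next. Because the real datasets behind such
analyses are large and external, the package ships seeded generators that
emulate their structure with known ground truth; every estimator is tested
by parameter recovery against those generators.

## The core quantities

* Expected STAMPs: `n_beads · P(≥1 cell)`; with Poisson occupancy λ,
  `P = 1 − e^{−λ}` (one cell per 20 droplets ⇒ P = 0.05).
* Conditional doublet rate among occupied droplets:
  `1 − λe^{−λ}/(1 − e^{−λ})`.
* Implied total doublet rate from a barnyard table: `mixed/(2pq)` for
  species proportions p, q.
* Capture efficiency: OLS slope of UMIs on reads, reported per 1,000 reads.
* Phase scores: mean log-normalized expression over a phase gene set,
  normalized per phase across cells, then per cell across phases; a phase
  is "on" above threshold 0, and cells are ordered by their on-pattern.
* Regulon activity: mean normalized expression of a TF's targets,
  standardized across cells; association with phases by Pearson r with
  `t = r√(n−2)/√(1−r²)` (r > 0.3, p < 0.01 single-network;
  r > 0.35, Bonferroni p < 0.05 for multi-network integration, where the
  integrated score is the mean NES over the networks containing the
  regulon).
* CRISPR score: mean log2 fold change `log2((final+1)/(initial+1))` over a
  gene's guides (combined initial counts < 400 filtered out), dependency at
  score < −0.5, common essentials by the top-X-in-≥90%-of-lines rank rule.

See `vignettes/cyclereg-methods.Rmd` for the models, parameter defaults and
design decisions.

## A worked example

```r
library(cyclereg)

# --- loading arithmetic ------------------------------------------------
expected_stamps(2000, cell_occupancy = 1/20)
#> [1] 100
conditional_doublet_rate(0.1)
#> [1] 0.04916681

# --- barnyard QC on simulated mixed-species data -----------------------
bt     <- simulate_barnyard(barnyard_sim_config(seed = 1))
called <- assign_species(bt, purity_threshold = 0.9)
summarize_barnyard(called)
#> # A tibble: 1 × 5
#>   n_barcodes n_singlets mixed_fraction inferred_total_doublet_rate contamination
#> 1       2000       1977         0.0115                      0.0294        0.0152

estimate_stamps_knee(c(rep(10000, 100), rep(100, 1900)))
#> [1] 100

sat <- simulate_saturation_curves(500, new_umi_rate = 0.29, seed = 1)
fit_capture_slope(sat)
#> Capture-efficiency fit over 500 cells
#>   UMIs : 289.5 per 1000 reads (intercept 7.1)
#>   genes: 131.4 per 1000 reads (intercept 1645.7)

# --- cell-cycle phases and TF activity on simulated data ---------------
sim    <- simulate_cell_cycle_dataset(cycle_sim_config(seed = 1))
norm   <- log_normalize(sim$counts)
scores <- normalize_phase_scores(score_gene_sets(norm, sim$gene_sets))
calls  <- call_and_order(scores$norm2)
mean(calls$assigned[match(sim$truth$cells$cell, calls$cell)] ==
     sim$truth$cells$phase)
#> [1] 0.998

expressed <- rownames(filter_expressed_genes(sim$counts, 0.10))
activity  <- score_regulon_activity(norm[rownames(norm) %in% expressed, ],
                                    filter_regulons(sim$regulons, expressed))
cors <- correlate_activity_phases(activity, scores$norm1)
dplyr::filter(cors, pass)[1:4, ]
#> # A tibble: 4 × 8
#>   tf    phase     n estimate statistic  p.value p.adjusted pass
#> 1 TF001 G1/S    500    0.623      17.8 3.75e-55   3.75e-55 TRUE
#> 2 TF002 S       500    0.644      18.8 6.57e-60   6.57e-60 TRUE
#> 3 TF003 G2/M    500    0.611      17.2 1.51e-52   1.51e-52 TRUE
#> 4 TF004 M       500    0.538      14.3 6.26e-39   6.26e-39 TRUE
```

Reading those numbers: the simulated run recovers the 1.52% cross-species
read contamination it was generated with; the knee estimator finds the 100
cell-containing barcodes; the capture slope lands at ~290 UMIs per 1,000
reads for a per-read new-UMI rate of 0.29; phase assignment matches the
simulated truth for 99.8% of cells; and each simulated TF's activity
correlates most strongly with its engineered peak phase, passing the
r > 0.3, p < 0.01 rule.

`run_pipeline(pipeline_config(seed = 1, outdir = "out"))` executes the
whole chain (simulate → QC → phases → regulons → multi-network enrichment →
CRISPR) and writes each stage's tables with a provenance header; identical
seeds give bit-identical outputs.

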