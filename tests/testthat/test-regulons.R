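test_that("expression filter keeps a gene detected in exactly the threshold fraction", {
  m <- Matrix::Matrix(0, nrow = 3, ncol = 100,
                      dimnames = list(c("at10", "at9", "at50"), sprintf("c%03d", 1:100)),
                      sparse = TRUE)
  m["at10", 1:10] <- 1
  m["at9", 1:9] <- 1
  m["at50", 1:50] <- 1
  kept <- filter_expressed_genes(m, 0.10)
  expect_identical(rownames(kept), c("at10", "at50"))
  expect_error(filter_expressed_genes(m, 0), "strictly between")
  expect_error(filter_expressed_genes(m, 1), "strictly between")
  expect_error(filter_expressed_genes(m, 0.9), "no genes pass")
})

test_that("regulon filter applies the strict more-than-min-targets rule", {
  expressed <- c("TF1", sprintf("t%02d", 1:11))
  reg <- tibble::tibble(
    tf = c(rep("TF1", 11), rep("TF2", 12), rep("TF3", 11)),
    target = c(sprintf("t%02d", 1:11), # TF1: 11 expressed targets
               c(sprintf("t%02d", 1:10), "x1", "x2"), # TF2: 10 expressed
               sprintf("t%02d", 1:11)), # TF3: 11 expressed but TF not expressed
    mode = "Activation"
  )
  kept <- filter_regulons(reg, expressed, min_targets = 10)
  expect_identical(unique(kept$tf), "TF1")
  expect_true(all(kept$target %in% expressed))
  # relaxing the TF-expression requirement readmits TF3
  kept2 <- filter_regulons(reg, expressed, min_targets = 10, require_tf_expressed = FALSE)
  expect_setequal(unique(kept2$tf), c("TF1", "TF3"))
})

test_that("regulon activity is the target mean, normalized across cells", {
  m <- Matrix::Matrix(matrix(c(1, 1, 3, 3, 2, 4), nrow = 2,
    dimnames = list(c("t1", "t2"), c("c1", "c2", "c3"))), sparse = TRUE)
  reg <- tibble::tibble(tf = "TF1", target = c("t1", "t2"), mode = "Activation")
  act <- score_regulon_activity(m, reg)
  raw <- c(1, 3, 3) # per-cell target means
  expect_equal(act$activity, (raw - mean(raw)) / sd(raw))
  expect_identical(unique(act$n_targets_used), 2L)
  # constant activity across cells is degenerate
  mc <- Matrix::Matrix(matrix(1, 2, 3,
    dimnames = list(c("t1", "t2"), c("c1", "c2", "c3"))), sparse = TRUE)
  expect_error(score_regulon_activity(mc, reg), "constant activity")
  # signed mode negates repressed targets
  regs <- tibble::tibble(tf = "TF1", target = c("t1", "t2"),
                         mode = c("Activation", "Repression"))
  acts <- score_regulon_activity(m, regs, mode_handling = "signed")
  raws <- c((1 - 1) / 2, (3 - 3) / 2, (2 - 4) / 2)
  expect_equal(acts$activity, (raws - mean(raws)) / sd(raws))
})

test_that("phase correlation reproduces the closed-form t and cor.test", {
  # the worked t-statistic: r = 0.3 over 233 cells
  r <- 0.3
  n <- 233
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  expect_equal(t_stat, 4.7800, tolerance = 1e-4)
  expect_equal(2 * pt(-t_stat, n - 2), 3.1e-6, tolerance = 0.05)

  set.seed(8)
  n_cells <- 60
  act <- tibble::tibble(
    tf = rep(c("TF1", "TF2"), each = n_cells),
    cell = rep(sprintf("c%03d", 1:n_cells), 2),
    activity = rnorm(2 * n_cells)
  )
  phases <- tibble::tibble(
    cell = sprintf("c%03d", 1:n_cells),
    p1 = rnorm(n_cells), p2 = rnorm(n_cells)
  )
  out <- correlate_activity_phases(act, phases)
  # dual route: every pair agrees with stats::cor.test
  for (i in seq_len(nrow(out))) {
    a <- act$activity[act$tf == out$tf[i]]
    p <- phases[[out$phase[i]]]
    ct <- cor.test(a, p)
    expect_equal(out$estimate[i], unname(ct$estimate))
    expect_equal(out$statistic[i], unname(ct$statistic))
    expect_equal(out$p.value[i], ct$p.value)
  }
  # a vector correlated with itself: r = 1, p ~ 0
  act_self <- tibble::tibble(tf = "TF1", cell = phases$cell, activity = phases$p1)
  self <- correlate_activity_phases(act_self, phases)
  expect_equal(self$estimate[self$phase == "p1"], 1)
  expect_lt(self$p.value[self$phase == "p1"], 1e-12)
  # correlation is invariant under affine transforms of either vector
  act_aff <- dplyr::mutate(act_self, activity = 3 * activity + 7)
  aff <- correlate_activity_phases(act_aff, phases)
  expect_equal(aff$estimate, self$estimate)
  expect_error(
    correlate_activity_phases(act_self, dplyr::mutate(phases, cell = paste0(cell, "x"))),
    "different cell sets"
  )
})

test_that("pass flags respect the strict r threshold", {
  set.seed(1)
  act <- tibble::tibble(tf = "TF1", cell = sprintf("c%d", 1:100),
                        activity = rnorm(100))
  phases <- tibble::tibble(cell = act$cell, p1 = rnorm(100))
  out <- correlate_activity_phases(act, phases, r_threshold = 0.3)
  manual <- out$estimate > 0.3 & out$p.adjusted < 0.01
  expect_identical(out$pass, manual)
  # boundary: r exactly at the threshold fails the strict inequality
  boundary <- tibble::tibble(tf = "TF1", phase = "p1", estimate = 0.35)
  expect_false(boundary$estimate > 0.35)
})

test_that("TF peak phases are recovered from structured data", {
  sim <- simulate_cell_cycle_dataset(cycle_sim_config(n_cells = 500, effect_size = 3, seed = 2))
  ch <- phase_chain(sim)
  expressed <- rownames(filter_expressed_genes(sim$counts, 0.10))
  kept <- filter_regulons(sim$regulons, expressed)
  act <- score_regulon_activity(ch$norm[rownames(ch$norm) %in% expressed, ], kept)
  cors <- correlate_activity_phases(act, ch$norm1)
  expect_gte(peak_phase_recovery(cors, sim$truth$tfs), 0.8)
  # activity correlates with the truth: cells in the peak phase score higher
  # (signed mode uses the simulated target modes, the sharpest readout)
  act_s <- score_regulon_activity(ch$norm[rownames(ch$norm) %in% expressed, ],
                                  kept, mode_handling = "signed")
  one_tf <- sim$truth$tfs$tf[1]
  a <- act_s[act_s$tf == one_tf, ]
  in_peak <- sim$truth$cells$phase[match(a$cell, sim$truth$cells$cell)] ==
    sim$truth$tfs$peak_phase[1]
  expect_gt(cor(a$activity, as.numeric(in_peak)), 0.5)
})
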