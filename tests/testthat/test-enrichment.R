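test_that("signature z-scores use the sample-SD convention and drop flat genes", {
  m <- matrix(c(1, 5, 3, 5, 2, 5), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "flat", "g2"), c("c1", "c2")))
  m["flat", ] <- 5
  expect_message(z <- signature_zscores(m), "zero-variance")
  expect_false("flat" %in% rownames(z))
  # two cells with values (1, 5): sample SD convention
  expect_equal(unname(z["g1", ]), c(1 - 3, 5 - 3) / sd(c(1, 5)))
  expect_equal(unname(rowMeans(z)), rep(0, 2))
  expect_error(signature_zscores(matrix(1, 2, 3)), "zero variance")
})

test_that("NES is the Stouffer combination of target z-scores", {
  sig <- matrix(1, nrow = 4, ncol = 2,
                dimnames = list(paste0("t", 1:4), c("c1", "c2")))
  nes <- enrichment_nes(sig, paste0("t", 1:4), min_targets = 4)
  expect_equal(unname(nes), c(2, 2)) # 4 / sqrt(4)
  nes0 <- enrichment_nes(sig * 0, paste0("t", 1:4), min_targets = 4)
  expect_equal(unname(nes0), c(0, 0))
  # signed mode flips repressed targets; NES is linear and odd in the signature
  reg <- tibble::tibble(target = paste0("t", 1:4),
                        mode = c("Activation", "Activation", "Repression", "Unknown"))
  nes_s <- enrichment_nes(sig, reg, signed = TRUE, min_targets = 4)
  expect_equal(unname(nes_s), c(1, 1)) # (1+1-1+1)/2
  expect_equal(enrichment_nes(-sig, paste0("t", 1:4), min_targets = 4), -nes)
  expect_error(enrichment_nes(sig, paste0("t", 1:3)), "need at least 10")
})

test_that("NES is standard normal under an iid normal null signature", {
  set.seed(13)
  sig <- matrix(rnorm(200 * 10000), nrow = 200, ncol = 10000,
                dimnames = list(paste0("g", 1:200), paste0("c", 1:10000)))
  nes <- enrichment_nes(sig, paste0("g", 1:20))
  expect_gt(sd(nes), 0.97)
  expect_lt(sd(nes), 1.03)
  expect_lt(abs(mean(nes)), 0.03)
})

test_that("average-score integration means over available networks only", {
  nes <- tibble::tibble(
    network = c("n1", "n2", "n1", "n1", "n2", "n2"),
    tf = c("A", "A", "A", "B", "A", "A"),
    cell = c("c1", "c1", "c2", "c1", "c2", "c3"),
    nes = c(2, 4, 1, 5, 3, 7)
  )
  # regulon B exists in one network only: identity pass-through before scaling
  nes_b <- tibble::tibble(network = "n1", tf = "B",
                          cell = c("c1", "c2", "c3"), nes = c(5, 1, 3))
  pre <- dplyr::summarise(dplyr::group_by(nes_b, tf, cell),
                          m = mean(nes), .groups = "drop")
  expect_equal(pre$m, nes_b$nes[match(pre$cell, nes_b$cell)])
  # regulon A in two networks: (2+4)/2 = 3 for c1
  intg <- avg_score_integrate(nes[nes$tf == "A", ])
  means <- c(c1 = 3, c2 = 2, c3 = 7)
  expect_equal(intg$activity,
               unname((means - mean(means)) / sd(means))[match(intg$cell, names(means))])
  # permuting network rows changes nothing
  intg2 <- avg_score_integrate(nes[nes$tf == "A", ][c(4, 2, 1, 3, 5), ])
  expect_equal(dplyr::arrange(intg, cell), dplyr::arrange(intg2, cell))
})

test_that("integration over K independent networks shrinks the null SD like 1/sqrt(K)", {
  set.seed(21)
  n_genes <- 400
  sig <- matrix(rnorm(n_genes * 4000), nrow = n_genes,
                dimnames = list(paste0("g", 1:n_genes), paste0("c", 1:4000)))
  K <- 4
  networks <- lapply(1:K, function(k) {
    tibble::tibble(tf = "TF1",
                   target = paste0("g", ((k - 1) * 20 + 1):(k * 20)),
                   mode = "Unknown")
  })
  names(networks) <- paste0("net", 1:K)
  nes <- score_networks(sig, networks)
  raw_means <- dplyr::summarise(dplyr::group_by(nes, cell),
                                m = mean(nes), .groups = "drop")
  expect_equal(sd(raw_means$m), 1 / sqrt(K), tolerance = 0.05)
})

test_that("Bonferroni-adjusted meta correlations use the strict 0.35 rule", {
  expect_equal(p.adjust(0.001, method = "bonferroni", n = 72), 0.072)
  set.seed(5)
  n <- 80
  phases <- tibble::tibble(cell = sprintf("c%03d", 1:n), p1 = rnorm(n), p2 = rnorm(n))
  intg <- tibble::tibble(tf = "TF1", cell = phases$cell, activity = phases$p1,
                         n_networks = 2L)
  out <- correlate_meta(intg, phases)
  expect_true(out$pass[out$phase == "p1"]) # identical vectors pass
  expect_equal(out$p.adjusted, pmin(1, out$p.value * 2)) # Bonferroni over 2 tests
  # r exactly 0.35 fails the strict threshold
  fake <- out
  fake$estimate <- 0.35
  expect_false(any(fake$estimate > 0.35))
})

test_that("multi-network integration recovers peak phases at least as well as single networks", {
  rec_int <- numeric(0)
  rec_single <- numeric(0)
  for (s in 1:3) {
    sim <- simulate_cell_cycle_dataset(cycle_sim_config(
      n_cells = 300, effect_size = 1.5, targets_per_tf = 12,
      n_networks = 3, target_subsample = 0.6, seed = s
    ))
    ch <- phase_chain(sim)
    expressed <- rownames(filter_expressed_genes(sim$counts, 0.10))
    sig <- signature_zscores(ch$norm[rownames(ch$norm) %in% expressed, ])
    nes <- score_networks(sig, sim$networks, min_targets = 5)
    rec_int <- c(rec_int, peak_phase_recovery(
      correlate_meta(avg_score_integrate(nes), ch$norm1), sim$truth$tfs))
    for (nw in unique(nes$network)) {
      one <- avg_score_integrate(nes[nes$network == nw, ])
      rec_single <- c(rec_single, peak_phase_recovery(
        correlate_meta(one, ch$norm1), sim$truth$tfs))
    }
  }
  expect_gte(mean(rec_int), mean(rec_single) - 0.05)
})
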