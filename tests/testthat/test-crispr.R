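test_that("guide filter applies the strict less-than rule on combined counts", {
  counts <- tibble::tibble(
    sgrna = rep(c("sgA", "sgB", "sgC"), each = 2),
    gene = rep(c("g1", "g1", "g2"), each = 2),
    line = rep(c("l1", "l2"), 3),
    replicate = 1L,
    initial = c(200L, 200L, 200L, 199L, 10L, 10L),
    final = 100L
  )
  expect_message(out <- filter_sgrnas(counts, 400), "removed 2")
  expect_identical(unique(out$sgrna), "sgA") # combined 400 retained, 399 and 20 removed
  lone <- counts[counts$sgrna == "sgC", ]
  expect_message(expect_error(filter_sgrnas(lone, 400), "no guides survive"))
})

test_that("log2 fold change matches the pseudocount formula and is antisymmetric", {
  counts <- tibble::tibble(
    sgrna = c("a", "b", "c"), gene = "g1", line = "l1", replicate = 1L,
    initial = c(100L, 50L, 0L), final = c(0L, 50L, 0L)
  )
  out <- sgrna_log2fc(counts, depth_normalize = FALSE)
  expect_equal(out$lfc, c(log2(1 / 101), 0, 0))
  expect_equal(log2(1 / 101), -6.65821, tolerance = 1e-5)
  expect_error(sgrna_log2fc(dplyr::mutate(counts, initial = -1L)), "non-negative")

  # swapping initial and final negates lfc once depths are equalized
  set.seed(2)
  tbl <- tibble::tibble(
    sgrna = sprintf("s%02d", 1:20), gene = "g", line = "l1", replicate = 1L,
    initial = rpois(20, 300), final = rpois(20, 300)
  )
  fwd <- sgrna_log2fc(tbl)
  swapped <- dplyr::rename(tbl, initial = final, final = initial)
  rev <- sgrna_log2fc(swapped)
  expect_equal(rev$lfc, -fwd$lfc)
})

test_that("gene scores average guides then replicates, order-invariantly", {
  lfc <- tibble::tibble(
    sgrna = c("a", "b", "c", "a", "b", "c"),
    gene = "g1", line = "l1", replicate = rep(1:2, each = 3),
    lfc = c(-2, -1, -3, -4, -4, -4)
  )
  out <- gene_crispr_score(lfc)
  expect_equal(out$score, mean(c(mean(c(-2, -1, -3)), -4))) # (-2 + -4)/2 = -3
  shuffled <- gene_crispr_score(lfc[sample(6), ])
  expect_equal(shuffled$score, out$score)
  # monotone: lowering one guide's lfc lowers the score
  lower <- dplyr::mutate(lfc, lfc = ifelse(dplyr::row_number() == 1, -5, lfc))
  expect_lt(gene_crispr_score(lower)$score, out$score)
})

test_that("simulated essential genes recover their engineered effect", {
  scr <- simulate_crispr_screen(screen_sim_config(seed = 9))
  lfc <- sgrna_log2fc(suppressMessages(filter_sgrnas(scr$counts)))
  gs <- gene_crispr_score(lfc)
  ess <- scr$truth$gene[scr$truth$essential]
  per_gene <- dplyr::summarise(dplyr::group_by(gs[gs$gene %in% ess, ], gene),
                               m = mean(score), .groups = "drop")
  expect_true(all(abs(per_gene$m - (-2)) < 0.5))
  # replicate averaging: line1 carries two replicates in the default design
  expect_identical(sort(unique(lfc$replicate[lfc$line == "line1"])), 1:2)
})

test_that("the depletion rank test is extreme for fully separated guides and calibrated under the null", {
  # 7 guides all below every one of 953 controls: minimal achievable statistic
  lfc <- synthetic_lfc_tbl(n_genes = 1, gene_shift = -20, seed = 3)
  out <- test_gene_depletion(lfc)
  expect_equal(out$statistic, 0) # rank-sum W at its floor
  expect_lt(out$p.value, 1e-5)

  # null: gene guides drawn from the control distribution -> uniform p
  ps <- unlist(lapply(1:8, function(s) {
    test_gene_depletion(synthetic_lfc_tbl(n_genes = 25, gene_shift = 0, seed = s))$p.value
  }))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)

  # too few guides is an error
  tiny <- synthetic_lfc_tbl(n_genes = 1, n_gene_sgrnas = 2, seed = 1)
  expect_error(test_gene_depletion(tiny), "need at least 3")
  few_ctrl <- synthetic_lfc_tbl(n_genes = 1, n_controls = 10, seed = 1)
  expect_error(test_gene_depletion(few_ctrl), "control guide")
})

test_that("dependency classification uses the strict -0.5 cutoff", {
  scores <- tibble::tibble(gene = c("a", "b", "c"), line = "l1",
                           score = c(-0.6, -0.5, -1.0))
  out <- classify_dependency(scores)
  expect_identical(out$dependent, c(TRUE, FALSE, TRUE))
  expect_error(classify_dependency(dplyr::mutate(scores, score = c(1, NA, 0))),
               "finite")
})

test_that("common essentials are exactly the engineered pan-essential genes", {
  hits <- vapply(1:5, function(s) {
    scr <- simulate_crispr_screen(screen_sim_config(
      n_lines = 10, n_essential = 10, replicates_per_line = 1, seed = s
    ))
    gs <- gene_crispr_score(sgrna_log2fc(suppressMessages(filter_sgrnas(scr$counts))))
    ce <- suppressWarnings(find_common_essentials(gs[gs$gene != "CONTROL", ]))
    setequal(ce$gene[ce$common_essential], scr$truth$gene[scr$truth$essential])
  }, logical(1))
  expect_true(all(hits))

  # a gene most depleting in every line is flagged whenever X >= 1
  set.seed(2)
  scores <- tibble::tibble(
    gene = rep(sprintf("g%02d", 1:60), 10),
    line = rep(sprintf("l%02d", 1:10), each = 60),
    score = rnorm(600, 0, 0.1)
  )
  scores$score[scores$gene == "g01"] <- -5
  ce <- suppressWarnings(find_common_essentials(scores))
  expect_gte(attr(ce, "X"), 1)
  expect_true(ce$common_essential[ce$gene == "g01"])
  # degenerate input: a line with identical scores errors
  bad <- tibble::tibble(gene = rep(sprintf("g%02d", 1:60), 10),
                        line = rep(sprintf("l%02d", 1:10), each = 60),
                        score = 0)
  expect_error(find_common_essentials(bad), "degenerate")
})
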