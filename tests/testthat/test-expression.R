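make_de <- function(genes, log2fc, padj) {
  tibble::tibble(gene_id = genes, log2fc = log2fc, padj = padj)
}

test_that("dual-contrast overexpression intersection applies inclusive thresholds", {
  de1 <- make_de(c("a", "b", "c"), c(1.0, 0.2, 2.0), c(0.01, 0.01, 0.2))
  de2 <- make_de(c("a", "b", "c"), c(1.5, 1.5, 1.5), c(0.01, 0.01, 0.01))
  got <- intersect_overexpressed(de1, de2)
  # a: 2-fold, padj 0.01 in both -> in; b: 1.15-fold in contrast 1 -> out;
  # c: padj 0.2 in contrast 1 -> out
  expect_identical(got, "a")

  # boundary inclusive: log2fc exactly log2(1.5), padj exactly 0.05
  deb <- make_de("x", log2(1.5), 0.05)
  expect_identical(intersect_overexpressed(deb, deb), "x")

  # genes absent from one table are not overexpressed, not an error
  de3 <- make_de("a", 2, 0.01)
  expect_identical(intersect_overexpressed(de1, de3), "a")
  expect_length(intersect_overexpressed(de1, make_de("zz", 2, 0.01)), 0)

  # brute-force oracle on random toy tables
  set.seed(5)
  for (i in 1:10) {
    genes <- paste0("g", 1:8)
    d1 <- make_de(genes, rnorm(8, 0.5, 1), runif(8))
    d2 <- make_de(genes, rnorm(8, 0.5, 1), runif(8))
    brute <- genes[d1$log2fc >= log2(1.5) & d1$padj <= 0.05 &
      d2$log2fc >= log2(1.5) & d2$padj <= 0.05]
    expect_identical(intersect_overexpressed(d1, d2), sort(brute))
  }
})

test_that("the combined rank metric is -log10 of the averaged percent ranks", {
  m <- combined_rank_metric(0.1, 0.3)
  expect_equal(m$avg_rank, 0.2)
  expect_equal(m$metric, -log10(0.2), tolerance = 1e-12) # ~0.699, passes 0.5

  expect_equal(combined_rank_metric(1, 1)$metric, 0) # fails the 0.5 cutoff

  # strictly decreasing in either rank
  base <- combined_rank_metric(0.5, 0.5)$metric
  expect_lt(combined_rank_metric(0.6, 0.5)$metric, base)
  expect_lt(combined_rank_metric(0.5, 0.6)$metric, base)

  # harmonic option
  h <- combined_rank_metric(0.1, 0.3, average = "harmonic")
  expect_equal(h$avg_rank, 2 / (1 / 0.1 + 1 / 0.3), tolerance = 1e-12)

  expect_error(combined_rank_metric(0, 1), "positive")
})

test_that("the quantile gate uses interpolated quantiles with inclusive passes", {
  g <- quartile_gate(c(1, 2, 3, 4), 0.75)
  expect_equal(g$threshold, 3.25)
  expect_equal(g$pass, c(FALSE, FALSE, FALSE, TRUE))

  all_equal <- quartile_gate(rep(2.5, 5), 0.75)
  expect_true(all(all_equal$pass))

  single <- quartile_gate(7, 0.75)
  expect_true(single$pass)

  empty <- quartile_gate(numeric(0))
  expect_length(empty$pass, 0)
})

test_that("candidate selection equals the brute-force application of the three gates", {
  set.seed(31)
  genes <- paste0("g", 1:20)
  de1 <- make_de(genes, rnorm(20, 1, 1), runif(20, 0, 0.3))
  de2 <- make_de(genes, rnorm(20, 1, 1), runif(20, 0, 0.3))
  peps <- tibble::tibble(
    peptide_id = sprintf("p%02d", 1:30),
    gene_id = sample(genes, 30, replace = TRUE),
    rank_Kd = 10^runif(30, -2, 0.8),
    rank_Dd = 10^runif(30, -2, 0.8)
  )
  cfg <- selection_config()
  got <- select_taa_candidates(peps, de1, de2, cfg)

  # independent brute force over the stated gates
  over <- intersect(
    genes[de1$log2fc >= log2(1.5) & de1$padj <= 0.05],
    genes[de2$log2fc >= log2(1.5) & de2$padj <= 0.05]
  )
  avg_fc <- (2^de1$log2fc[match(peps$gene_id, de1$gene_id)] +
    2^de2$log2fc[match(peps$gene_id, de2$gene_id)]) / 2
  pass_de <- peps$gene_id %in% over
  thr <- unname(quantile(avg_fc[pass_de], 0.75, type = 7))
  metric <- -log10((peps$rank_Kd + peps$rank_Dd) / 2)
  brute_sel <- pass_de & metric >= 0.5 & avg_fc >= thr
  expect_equal(got$selected, brute_sel)
  expect_equal(got$avg_fc, avg_fc, tolerance = 1e-12)

  # selected implies all three gates
  expect_true(all(got$selected == (got$pass_de & got$pass_rank & got$pass_quartile)))

  # row-order invariance
  shuffled <- select_taa_candidates(peps[sample(30), ], de1, de2, cfg)
  expect_equal(
    shuffled$selected[order(shuffled$peptide_id)],
    got$selected[order(got$peptide_id)]
  )

  # padj_max = 0 admits nothing (padj values are strictly positive here)
  none <- select_taa_candidates(peps, de1, de2, selection_config(padj_max = 1e-12))
  expect_false(any(none$selected))

  # loosening the quantile gate yields a superset
  loose <- select_taa_candidates(peps, de1, de2, selection_config(fc_quantile = 0.01))
  expect_true(all(got$selected <= loose$selected))

  # tightening any threshold never adds a candidate
  for (tighter in list(
    selection_config(fc_min = 2.5), selection_config(padj_max = 0.01),
    selection_config(rank_metric_min = 1), selection_config(fc_quantile = 0.9)
  )) {
    tight <- select_taa_candidates(peps, de1, de2, tighter)
    expect_true(all(tight$selected <= got$selected))
  }

  # peptides without a source gene are excluded and counted
  peps_na <- peps
  peps_na$gene_id[1] <- NA
  got_na <- select_taa_candidates(peps_na, de1, de2, cfg)
  expect_equal(attr(got_na, "n_excluded_no_gene"), 1L)
  expect_false("p01" %in% got_na$peptide_id)
})

test_that("planted overexpressed genes supply all selected peptides (precision 1)", {
  cfg <- sim_config(seed = 13, n_genes = 30, planted_overexpressed = 8)
  pr <- gen_proteome(cfg)
  de <- gen_de_tables(cfg, pr$gene_map)
  # binder peptides over all genes, with strong dual-allele ranks so the rank
  # gate is informative
  set.seed(14)
  peps <- tibble::tibble(
    peptide_id = sprintf("p%03d", 1:60),
    gene_id = sample(pr$gene_map$gene_id, 60, replace = TRUE),
    rank_Kd = runif(60, 0.01, 0.5),
    rank_Dd = runif(60, 0.01, 0.5)
  )
  got <- select_taa_candidates(peps, de$de1, de$de2)
  expect_gt(sum(got$selected), 0)
  expect_true(all(got$gene_id[got$selected] %in% de$planted))
})
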