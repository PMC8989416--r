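test_that("length filtering is inclusive at the bounds and conserves records", {
  peps <- tibble::tibble(
    peptide_id = paste0("p", 1:5),
    sequence = c("ACDEFG", "ACDEFGH", "ACDEFGHIK", "ACDEFGHIKLMNP", "ACDEFGHIKLMNPQ")
  ) # lengths 6, 7, 9, 13, 14
  out <- filter_by_length(peps, 7, 13)
  expect_equal(out$kept$peptide_id, c("p2", "p3", "p4"))
  expect_equal(out$removed$peptide_id, c("p1", "p5"))

  empty <- filter_by_length(peps[0, ], 7, 13)
  expect_equal(nrow(empty$kept) + nrow(empty$removed), 0)

  only9 <- filter_by_length(peps, 9, 9)
  expect_equal(only9$kept$peptide_id, "p3")

  # conservation property over random inputs
  set.seed(1)
  for (i in 1:10) {
    lens <- sample(5:20, 30, replace = TRUE)
    tab <- tibble::tibble(sequence = vapply(
      lens, function(l) paste(sample(aa_alphabet(), l, TRUE), collapse = ""),
      character(1)
    ))
    res <- filter_by_length(tab, 7, 13)
    expect_equal(nrow(res$kept) + nrow(res$removed), 30)
    expect_true(all(res$kept$length >= 7 & res$kept$length <= 13))
  }
})

test_that("length distributions report counts and percents that total the input", {
  tab <- tibble::tibble(sequence = c(
    rep("ACDEFGHIK", 4), rep("ACDEFGH", 3), rep("ACDEFGHIKLMNP", 3)
  ))
  d <- length_distribution(tab)
  expect_equal(d$count[d$length == 9], 4)
  expect_equal(d$percent[d$length == 9], 40)
  expect_equal(sum(d$count), 10)
  expect_equal(sum(d$percent), 100, tolerance = 1e-9)

  single <- length_distribution(tibble::tibble(sequence = "ACDEFGHIK"))
  expect_equal(single$percent, 100)

  # uniform lengths 7..13: each 1/7 of the total
  uni <- tibble::tibble(sequence = vapply(
    7:13, function(l) paste(rep("A", l), collapse = ""), character(1)
  ))
  du <- length_distribution(uni)
  expect_equal(du$percent, rep(100 / 7, 7), tolerance = 1e-9)
})

test_that("peptide-to-protein mapping is exact substring search", {
  proteome <- c(prot1 = "MMACDEFKK", prot2 = "QQQACDEFQQ", prot3 = "WWWWWWWWW")
  peps <- tibble::tibble(
    peptide_id = c("hit", "both", "miss"),
    sequence = c("MMACD", "ACDEF", "KKKKK")
  )
  out <- map_peptides_to_proteins(peps, proteome)
  expect_equal(out$source_proteins[[1]], "prot1")
  expect_setequal(out$source_proteins[[2]], c("prot1", "prot2"))
  expect_true(out$unmapped[3])
  expect_equal(out$n_sources, c(1L, 2L, 0L))
  expect_equal(attr(out, "n_source_proteins"), 2)
})

test_that("motif log-odds scores follow the PWM definition", {
  bg <- rep(1 / 20, 20)
  flat <- motif_model(matrix(bg, 20, 9), bg)
  expect_equal(score_peptides(flat, "SYHPALNAI"), 0, tolerance = 1e-12)

  # single position, all mass on A, uniform background
  f <- matrix(0, 20, 1)
  f[match("A", aa_alphabet()), 1] <- 1
  m1 <- motif_model(f, bg)
  expect_equal(score_peptides(m1, "A"), log2(20), tolerance = 1e-12)

  # additivity over positions
  f2 <- matrix(1 / 20, 20, 2)
  f2[, 1] <- 0
  f2[match("A", aa_alphabet()), 1] <- 1
  m2 <- motif_model(f2, bg)
  expect_equal(
    score_peptides(m2, "AC"),
    score_peptides(m1, "A") + 0,
    tolerance = 1e-12
  )

  expect_error(score_peptides(m1, "AC"), "length")
  expect_error(motif_model(matrix(0.04, 20, 9)), "sums to")
})

test_that("percentile ranks follow the count-and-divide definition", {
  bg <- rep(1 / 20, 20)
  # two positions each contributing 3.75 bits for residue A: score("AA") = 7.5
  f <- matrix((1 - 0.05 * 2^3.75) / 19, 20, 2)
  f[match("A", aa_alphabet()), ] <- 0.05 * 2^3.75
  m <- motif_model(f, bg)
  expect_equal(score_peptides(m, "AA"), 7.5, tolerance = 1e-9)

  # toy background scores 1..9: two scores >= 7.5 -> rank 100 * 3 / 10
  expect_equal(calibrate_rank(m, "AA", bg_scores = 1:9), 30)
  # above all backgrounds: the minimum attainable rank 100 / (N + 1)
  expect_equal(calibrate_rank(m, "AA", bg_scores = rep(0, 9)), 10)
  # below all backgrounds: rank 100
  expect_equal(calibrate_rank(m, "AA", bg_scores = rep(99, 9)), 100)

  # rank is monotone non-increasing in score for a fixed background sample
  set.seed(3)
  bg_scores <- rnorm(500)
  peps <- c("AA", "AC", "CC") # strictly decreasing scores under m
  ranks <- calibrate_rank(m, peps, bg_scores = bg_scores)
  s <- score_peptides(m, peps)
  expect_true(all(diff(s) < 0))
  expect_true(all(diff(ranks) >= 0))

  expect_error(calibrate_rank(m, "AA", n_bg = 10), "at least 100")
})

test_that("binder classification uses the inclusive 2% min-rank rule", {
  ranks <- tibble::tibble(
    peptide_id = rep(c("a", "b", "c"), each = 2),
    allele = rep(c("Dd", "Kd"), 3),
    rank = c(5.0, 0.4, 2.5, 3.0, 2.0, 2.0)
  )
  out <- classify_binders(ranks, threshold = 2)
  out <- out[match(c("a", "b", "c"), out$peptide_id), ]
  expect_equal(out$binder, c(TRUE, FALSE, TRUE))
  expect_equal(out$preferred_allele, c("Kd", NA, "Dd")) # tie -> first allele
  expect_true(out$rank_tie[3])

  expect_error(
    classify_binders(ranks[-1, ]),
    "lacks a rank"
  )
  ranks$rank[2] <- NA
  expect_error(classify_binders(ranks), "missing rank")
})

test_that("hypergeometric enrichment matches exact combinatorial enumeration", {
  universe <- paste0("g", 1:10)
  selected <- paste0("g", 1:4)
  sets <- list(hit = paste0("g", c(1:4, 9)), all = universe)
  out <- overrepresentation_test(selected, universe, sets)
  # C(5,4) C(5,0) / C(10,4) = 5 / 210
  expect_equal(out$p_value[out$set == "hit"], 5 / 210, tolerance = 1e-12)
  expect_equal(out$overlap[out$set == "all"], 4)
  expect_equal(out$p_value[out$set == "all"], 1)

  # oracle equivalence across random small universes
  set.seed(42)
  for (i in 1:20) {
    n_univ <- sample(4:12, 1)
    univ <- paste0("u", seq_len(n_univ))
    sel <- sample(univ, sample(1:n_univ, 1))
    st <- sample(univ, sample(1:n_univ, 1))
    got <- overrepresentation_test(sel, univ, list(s = st))
    expect_equal(
      got$p_value,
      hyper_upper_oracle(got$overlap, length(st), n_univ, length(sel)),
      tolerance = 1e-12
    )
  }

  expect_error(overrepresentation_test("x", character(0), list()), "empty")
  expect_error(overrepresentation_test("zz", universe, sets), "subset")
})

test_that("BH adjustment matches the standard step-up across sets", {
  universe <- paste0("g", 1:20)
  selected <- paste0("g", 1:6)
  sets <- purrr::map(1:5, function(i) sample(universe, 8))
  names(sets) <- paste0("s", 1:5)
  out <- overrepresentation_test(selected, universe, sets)
  expect_equal(out$p_adjust, p.adjust(out$p_value, "BH"))
})

test_that("synthetic ligandome binder calibration recovers planted structure", {
  cfg <- sim_config(seed = 21, n_peptides = 600)
  pr <- gen_proteome(cfg)
  lig <- gen_ligandome(cfg, pr$proteome, pr$gene_map)
  nine_idx <- lig$peptides$length == 9
  nine <- lig$peptides[nine_idx, ]
  truth <- lig$truth[nine_idx, ]
  motifs <- lapply(cfg$allele_motifs, allele_motif_model)
  ranks <- dplyr::bind_rows(purrr::imap(motifs, function(m, allele) {
    tibble::tibble(
      peptide_id = nine$peptide_id, allele = allele,
      rank = calibrate_rank(m, nine$sequence, n_bg = 50000, seed = 33)
    )
  }))
  cls <- classify_binders(ranks)
  cls <- cls[match(nine$peptide_id, cls$peptide_id), ]

  # peptides carrying the planted anchor signature are all called binders;
  # the overall motif-peptide binder rate tracks the anchor probability
  expect_true(all(cls$binder[truth$anchored]))
  expect_gte(mean(cls$binder[!truth$is_contaminant]), 0.85)
  # contaminant 9mers (uniform residues) are rejected
  if (any(truth$is_contaminant)) {
    expect_gte(mean(!cls$binder[truth$is_contaminant]), 0.95)
  }
  # the preferred allele recovers the generating allele
  ok <- cls$binder & !truth$is_contaminant
  expect_gte(mean(cls$preferred_allele[ok] == truth$allele[ok]), 0.9)
})
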