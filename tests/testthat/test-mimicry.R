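test_that("weighted similarity is self-normalised and centre-weighted", {
  cfg <- mimicry_config()
  p <- "SYHPALNAI"
  expect_equal(weighted_similarity(p, p, cfg), 1)

  # identity scoring matrix + Gaussian weights sigma 2 centred at position 5:
  # a single mismatch costs w_i / sum(w), so central mismatches cost more
  ident <- diag(20)
  dimnames(ident) <- list(aa_alphabet(), aa_alphabet())
  icfg <- mimicry_config(matrix = ident)
  w <- exp(-((1:9 - 5)^2) / (2 * 2^2))
  a <- "AAAAAAAAA"
  mut_at <- function(pos) {
    x <- strsplit(a, "")[[1]]
    x[pos] <- "C"
    paste(x, collapse = "")
  }
  s1 <- weighted_similarity(a, mut_at(1), icfg)
  s5 <- weighted_similarity(a, mut_at(5), icfg)
  expect_equal(s1, (sum(w) - w[1]) / sum(w), tolerance = 1e-9) # ~0.9724
  expect_equal(s5, (sum(w) - w[5]) / sum(w), tolerance = 1e-9) # ~0.7958
  expect_lt(s5, s1)

  expect_error(weighted_similarity("AAA", "AAAA", cfg), "equal length")
})

test_that("weighted similarity is symmetric and bounded on random pairs", {
  cfg <- mimicry_config()
  set.seed(9)
  for (i in 1:25) {
    a <- random_peptides(1)
    b <- random_peptides(1)
    sab <- weighted_similarity(a, b, cfg)
    sba <- weighted_similarity(b, a, cfg)
    expect_gte(sab, 0)
    expect_lte(sab, 1)
    # symmetric matrix, but self-normalisation differs unless self-scores match
    self_a <- sum(position_weights(9) * diag(blosum62())[match(strsplit(a, "")[[1]], aa_alphabet())])
    self_b <- sum(position_weights(9) * diag(blosum62())[match(strsplit(b, "")[[1]], aa_alphabet())])
    expect_equal(sab * self_a, sba * self_b, tolerance = 1e-9)
  }
})

test_that("identity fraction counts matching positions", {
  expect_equal(identity_fraction("AAAAAAAAA", "AAAAAAAAC"), 8 / 9)
  expect_equal(identity_fraction("SYHPALNAI", "SYHPALNAI"), 1)
  expect_equal(identity_fraction("AAAA", "CCCC"), 0)
  expect_error(identity_fraction("AAA", "AAAA"), "equal length")
})

test_that("database scanning is exhaustive with deterministic tie-breaks", {
  cfg <- mimicry_config()
  tumor <- c(t1 = "SYHPALNAI")
  db <- c(rec1 = "MMSYHPALNAIKK", rec2 = "SYHPALNAI")
  best <- scan_database(tumor, db, cfg)
  # verbatim occurrence: perfect score; tie broken to the lowest record id
  expect_equal(best$weighted_score, 1)
  expect_equal(best$identity_fraction, 1)
  expect_equal(best$record_id, "rec1")
  expect_equal(best$offset, 2L)
  expect_equal(best$pathogen_window, "SYHPALNAI")

  # brute-force double loop over all windows on a 3-record toy
  set.seed(21)
  tumor3 <- setNames(random_peptides(4), paste0("t", 1:4))
  db3 <- setNames(
    vapply(c(12, 9, 15), function(l) {
      paste(sample(aa_alphabet(), l, TRUE), collapse = "")
    }, character(1)),
    paste0("r", 1:3)
  )
  res <- scan_database(tumor3, db3, cfg, all_hits = TRUE)
  s <- blosum62()
  w <- position_weights(9)
  for (tp in names(tumor3)) {
    a <- strsplit(tumor3[[tp]], "")[[1]]
    self <- sum(w * s[cbind(a, a)])
    brute_best <- -Inf
    for (rid in names(db3)) {
      seqc <- db3[[rid]]
      for (off in 0:(nchar(seqc) - 9)) {
        b <- strsplit(substr(seqc, off + 1, off + 9), "")[[1]]
        brute_best <- max(brute_best, max(0, sum(w * s[cbind(a, b)]) / self))
      }
    }
    expect_equal(
      best_score <- res$best$weighted_score[res$best$peptide_id == tp],
      brute_best,
      tolerance = 1e-12
    )
  }
  # full hit list covers every window of every record
  expect_equal(
    nrow(res$hits),
    4 * sum(nchar(db3) - 9 + 1)
  )

  # empty database: empty result with a warning, not an error
  expect_warning(out <- scan_database(tumor, character(0), cfg), "empty")
  expect_equal(nrow(out), 0)
})

test_that("planted homologs are the best hits for planted tumor peptides", {
  for (muts in c(1, 2)) {
    cfg_sim <- sim_config(
      seed = 40 + muts, homolog_mutations = muts,
      n_pathogen_epitopes = 150
    )
    tumor <- setNames(random_peptides(20, seed = 50 + muts), sprintf("t%02d", 1:20))
    db <- gen_pathogen_db(cfg_sim, tumor, n_homologs = 20)
    best <- scan_database(tumor, db$db)
    merged <- dplyr::inner_join(db$pairs, best, by = "peptide_id")
    expect_gte(mean(merged$record_id.x == merged$record_id.y), 0.95)
  }
})

test_that("mimicry filtering combines score, identity and the affinity gate", {
  hits <- tibble::tibble(
    peptide_id = c("a", "b", "c", "d"),
    weighted_score = c(0.9, 0.7, 0.95, 0.85),
    identity_fraction = c(0.89, 0.95, 0.95, 0.7)
  )
  ic50 <- c(a = 30, b = 20, c = 400, d = 10)

  strong <- filter_mimics(hits, ic50, mimicry_config(affinity_mode = "strong_lt50nM"))
  expect_true(strong$selected[strong$peptide_id == "a"]) # 0.9 / 0.89 / 30 nM
  expect_false(strong$selected[strong$peptide_id == "b"]) # score 0.7 fails
  expect_false(strong$selected[strong$peptide_id == "c"]) # 400 nM fails <50
  expect_false(strong$selected[strong$peptide_id == "d"]) # identity fails

  ranged <- filter_mimics(hits, ic50, mimicry_config(affinity_mode = "range_50_500nM"))
  expect_true(ranged$selected[ranged$peptide_id == "c"])
  expect_false(ranged$selected[ranged$peptide_id == "a"])

  off <- filter_mimics(hits, config = mimicry_config(affinity_mode = "off"))
  expect_equal(
    off$selected,
    hits$weighted_score >= 0.8 & hits$identity_fraction >= 0.8
  )

  expect_error(
    filter_mimics(hits, ic50[-1], mimicry_config(affinity_mode = "strong_lt50nM")),
    "missing IC50"
  )
  expect_error(
    filter_mimics(hits, config = mimicry_config(affinity_mode = "strong_lt50nM")),
    "required"
  )
})

test_that("position weight profiles behave as documented", {
  g <- position_weights(9, "gaussian", sigma = 2)
  expect_equal(which.max(g), 5)
  expect_equal(g[5], 1)
  expect_equal(position_weights(9, "flat"), rep(1, 9))
  am <- position_weights(9, "anchor_masked")
  expect_equal(am[c(2, 9)], c(0.2, 0.2))
  expect_equal(am[1], 1)
  expect_error(mimicry_config(weights = rep(0, 9)), class = "peptivax_config_error")
})

test_that("the shipped substitution matrix matches the reference BLOSUM62", {
  s <- blosum62()
  expect_true(isSymmetric(unname(s)))
  ref_env <- new.env()
  suppressWarnings(suppressMessages(
    data("BLOSUM62", package = "Biostrings", envir = ref_env)
  ))
  ref <- ref_env$BLOSUM62[aa_alphabet(), aa_alphabet()]
  expect_equal(unname(s), unname(ref))
})
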