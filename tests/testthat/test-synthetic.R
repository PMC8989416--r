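test_that("proteome generation is deterministic under seed and validates config", {
  cfg <- sim_config(seed = 1, n_genes = 50)
  p1 <- gen_proteome(cfg)
  p2 <- gen_proteome(cfg)
  expect_identical(p1, p2)
  expect_length(p1$proteome, 50)
  expect_true(all(nchar(p1$proteome) >= 100 & nchar(p1$proteome) <= 600))

  p3 <- gen_proteome(sim_config(seed = 2, n_genes = 50))
  expect_false(identical(p1$proteome, p3$proteome))

  expect_error(sim_config(n_genes = 0), class = "peptivax_config_error")
})

test_that("ligandome generation plants motifs, contaminants and truth labels", {
  cfg <- sim_config(seed = 7, n_peptides = 1000, contaminant_fraction = 0.1)
  pr <- gen_proteome(cfg)
  lig <- gen_ligandome(cfg, pr$proteome, pr$gene_map)
  expect_equal(nrow(lig$peptides), 1000)
  expect_equal(sum(lig$truth$is_contaminant), 100)
  expect_identical(lig$peptides$peptide_id, lig$truth$peptide_id)

  # determinism
  lig2 <- gen_ligandome(cfg, pr$proteome, pr$gene_map)
  expect_identical(lig, lig2)

  # with no contaminants and no anchor forcing, every peptide is a substring
  cfg0 <- sim_config(
    seed = 3, n_peptides = 150, contaminant_fraction = 0,
    allele_motifs = list(
      Kd = list(anchors = list(`2` = "Y"), anchor_prob = 0),
      Dd = list(anchors = list(`2` = "G"), anchor_prob = 0)
    )
  )
  pr0 <- gen_proteome(cfg0)
  lig0 <- gen_ligandome(cfg0, pr0$proteome, pr0$gene_map)
  found <- vapply(
    lig0$peptides$sequence,
    function(s) any(grepl(s, pr0$proteome, fixed = TRUE)), logical(1)
  )
  expect_true(all(found))

  # anchor probability 1 with a single anchor residue forces it everywhere
  cfg1 <- sim_config(
    seed = 5, n_peptides = 300, contaminant_fraction = 0,
    allele_motifs = list(
      A = list(anchors = list(`2` = "Y"), anchor_prob = 1),
      B = list(anchors = list(`2` = "G"), anchor_prob = 1)
    )
  )
  pr1 <- gen_proteome(cfg1)
  lig1 <- gen_ligandome(cfg1, pr1$proteome, pr1$gene_map)
  nine <- lig1$truth$allele == "A" & !is.na(lig1$truth$allele)
  p2res <- substr(lig1$peptides$sequence[nine], 2, 2)
  expect_true(all(p2res == "Y"))
})

test_that("planted DE structure is recovered exactly by the threshold filter", {
  cfg <- sim_config(seed = 11, n_genes = 50, planted_overexpressed = 10)
  pr <- gen_proteome(cfg)
  de <- gen_de_tables(cfg, pr$gene_map)
  expect_length(de$planted, 10)

  # independent brute-force row filter on both tables
  brute <- function(tab) {
    tab$gene_id[tab$log2fc >= log2(1.5) & tab$padj <= 0.05]
  }
  recovered <- sort(intersect(brute(de$de1), brute(de$de2)))
  expect_identical(recovered, de$planted)

  # no planted genes -> empty intersection
  de0 <- gen_de_tables(sim_config(seed = 11, planted_overexpressed = 0), pr$gene_map)
  expect_length(intersect(brute(de0$de1), brute(de0$de2)), 0)

  expect_identical(de, gen_de_tables(cfg, pr$gene_map))
})

test_that("pathogen database plants homologs at the requested identity", {
  tumor <- setNames(random_peptides(20, seed = 2), sprintf("tp%02d", 1:20))
  cfg <- sim_config(seed = 4, homolog_mutations = 1, n_pathogen_epitopes = 50)
  db <- gen_pathogen_db(cfg, tumor, n_homologs = 5)
  expect_equal(nrow(db$pairs), 5)
  obs_ident <- mapply(
    identity_fraction, db$pairs$tumor_peptide, db$pairs$homolog_sequence
  )
  expect_true(all(abs(obs_ident - 8 / 9) < 1e-12))

  db0 <- gen_pathogen_db(
    sim_config(seed = 4, homolog_mutations = 0), tumor,
    n_homologs = 5
  )
  expect_identical(db0$pairs$tumor_peptide, db0$pairs$homolog_sequence)

  expect_identical(db, gen_pathogen_db(cfg, tumor, n_homologs = 5))
  expect_error(sim_config(homolog_mutations = 9), class = "peptivax_config_error")
})

test_that("ELISpot counts separate planted responders from background", {
  cfg <- sim_config(seed = 8)
  panel <- sprintf("pep%02d", 1:10)
  counts <- gen_elispot(cfg, panel, responders = panel[1:3])
  expect_equal(sort(unique(counts$group)), sort(c(panel, "adjuvant_only", "saline")))
  expect_equal(nrow(counts), (10 + 2) * 3)
  expect_true(all(counts$spots >= 0))
  gate <- elispot_gate(elispot_summarize(counts))
  expect_setequal(gate$group[gate$selected], panel[1:3])

  none <- gen_elispot(cfg, panel, responders = character(0))
  gate0 <- elispot_gate(elispot_summarize(none))
  expect_false(any(gate0$selected))

  expect_identical(counts, gen_elispot(cfg, panel, responders = panel[1:3]))
  expect_error(gen_elispot(cfg, panel, responders = "not_in_panel"),
    class = "peptivax_config_error"
  )
})

test_that("synthetic sensorgrams carry recoverable two-phase plateaus", {
  cfg <- sim_config(seed = 9, sensorgram_noise_sd = 0.005)
  sg <- gen_sensorgram(cfg, r_eq = 0.5, r_diss = 0.2)
  ph <- extract_phase_levels(sg)
  expect_lt(abs(ph$r_max - 0.5), 0.01)
  expect_lt(abs(ph$r_min - 0.2), 0.01)

  clean <- gen_sensorgram(sim_config(seed = 9, sensorgram_noise_sd = 0),
    r_eq = 0.5, r_diss = 0.2
  )
  ph0 <- extract_phase_levels(clean)
  expect_equal(ph0$r_max, 0.5, tolerance = 1e-6)
  expect_equal(ph0$r_min, 0.2, tolerance = 1e-6)

  expect_error(gen_sensorgram(cfg, r_eq = 0.2, r_diss = 0.5),
    class = "peptivax_config_error"
  )
})
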