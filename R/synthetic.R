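#' Simulation configuration for the synthetic-data generators
#'
#' Bundles every knob of the synthetic cohort: proteome size, ligandome size
#' and motif structure, contaminant rate, planted differential-expression
#' signal, pathogen-database homologs, ELISpot count structure, and
#' sensorgram noise. Defaults emulate the statistical structure of a mouse
#' MHC-I (H2-Kd / H2-Dd) ligandome study: a length distribution peaking at
#' 9mers, two allele motifs with anchor positions P2 and P9, overexpressed
#' tumor genes that are significant in both of two DE contrasts, and
#' overdispersed ELISpot counts with a clear responder/background separation.
#'
#' @param seed Integer seed; every generator is deterministic given the seed.
#' @param n_genes Number of genes/proteins in the synthetic proteome.
#' @param n_peptides Number of eluted peptides in the ligandome.
#' @param allele_motifs Named list of two allele motif specs, each a list with
#'   `anchors` (named list: position -> allowed anchor residues) and
#'   `anchor_prob` (probability that a generated 9mer carries the full anchor
#'   signature of its allele).
#' @param contaminant_fraction Fraction of peptides drawn as contaminants
#'   (uniform residues, lengths 7-25).
#' @param length_weights Named numeric vector of length probabilities for
#'   non-contaminant peptides (names are lengths).
#' @param background Background residue frequencies (20-vector).
#' @param planted_overexpressed Number of genes planted as overexpressed in
#'   both DE contrasts.
#' @param planted_log2fc_mean,planted_log2fc_sd Normal parameters of planted
#'   log2 fold changes.
#' @param null_log2fc_sd SD of null log2 fold changes (mean 0).
#' @param planted_padj_max Planted adjusted p-values are uniform on
#'   (0, `planted_padj_max`].
#' @param null_padj_min Null adjusted p-values are uniform on
#'   \[`null_padj_min`, 1\].
#' @param n_pathogen_epitopes Number of random pathogen epitope records.
#' @param homolog_mutations Number of substituted positions in each planted
#'   pathogen homolog (must be < 9).
#' @param elispot_responder_mean,elispot_background_mean Negative-binomial
#'   means of spot counts for responder peptides and background/controls.
#' @param elispot_dispersion Negative-binomial dispersion (variance =
#'   mean + mean^2 / dispersion).
#' @param elispot_replicates Replicates per ELISpot group.
#' @param sensorgram_noise_sd Gaussian noise SD of synthetic sensorgrams, in
#'   degrees.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 50L,
                       n_peptides = 1000L,
                       allele_motifs = default_allele_motifs(),
                       contaminant_fraction = 0.1,
                       length_weights = c(
                         `7` = 0.08, `8` = 0.14, `9` = 0.35, `10` = 0.18,
                         `11` = 0.12, `12` = 0.08, `13` = 0.05
                       ),
                       background = rep(1 / 20, 20),
                       planted_overexpressed = 10L,
                       planted_log2fc_mean = 2,
                       planted_log2fc_sd = 0.5,
                       null_log2fc_sd = 0.5,
                       planted_padj_max = 0.01,
                       null_padj_min = 0.05,
                       n_pathogen_epitopes = 200L,
                       homolog_mutations = 1L,
                       elispot_responder_mean = 200,
                       elispot_background_mean = 8,
                       elispot_dispersion = 10,
                       elispot_replicates = 3L,
                       sensorgram_noise_sd = 0.005) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    n_peptides = as.integer(n_peptides),
    allele_motifs = allele_motifs,
    contaminant_fraction = contaminant_fraction,
    length_weights = length_weights,
    background = as.numeric(background),
    planted_overexpressed = as.integer(planted_overexpressed),
    planted_log2fc_mean = planted_log2fc_mean,
    planted_log2fc_sd = planted_log2fc_sd,
    null_log2fc_sd = null_log2fc_sd,
    planted_padj_max = planted_padj_max,
    null_padj_min = null_padj_min,
    n_pathogen_epitopes = as.integer(n_pathogen_epitopes),
    homolog_mutations = as.integer(homolog_mutations),
    elispot_responder_mean = elispot_responder_mean,
    elispot_background_mean = elispot_background_mean,
    elispot_dispersion = elispot_dispersion,
    elispot_replicates = as.integer(elispot_replicates),
    sensorgram_noise_sd = sensorgram_noise_sd
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Default two-allele anchor motif specification
#'
#' H2-Kd-like: aromatic P2 (Y/F) and aliphatic P9 (I/L); H2-Dd-like: G at P2
#' and L at P9. Both use anchor probability 0.9.
#'
#' @return Named list of two allele motif specs.
#' @export
default_allele_motifs <- function() {
  list(
    Kd = list(anchors = list(`2` = c("Y", "F"), `9` = c("I", "L")), anchor_prob = 0.9),
    Dd = list(anchors = list(`2` = "G", `9` = "L"), anchor_prob = 0.9)
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1)
  if (cfg$n_genes < 1) abort("n_genes must be >= 1", class = "peptivax_config_error")
  if (cfg$n_peptides < 1) abort("n_peptides must be >= 1", class = "peptivax_config_error")
  if (cfg$contaminant_fraction < 0 || cfg$contaminant_fraction > 1) {
    abort("contaminant_fraction must be in [0, 1]", class = "peptivax_config_error")
  }
  if (cfg$planted_overexpressed > cfg$n_genes) {
    abort("planted_overexpressed cannot exceed n_genes", class = "peptivax_config_error")
  }
  if (cfg$planted_padj_max <= 0 || cfg$planted_padj_max > 1 ||
    cfg$null_padj_min < 0 || cfg$null_padj_min > 1) {
    abort("padj bounds must lie in [0, 1]", class = "peptivax_config_error")
  }
  if (cfg$homolog_mutations < 0 || cfg$homolog_mutations >= 9) {
    abort("homolog_mutations must be in [0, 9)", class = "peptivax_config_error")
  }
  if (length(cfg$allele_motifs) != 2 || is.null(names(cfg$allele_motifs))) {
    abort("allele_motifs must be a named list of two specs", class = "peptivax_config_error")
  }
  for (sp in cfg$allele_motifs) {
    if (sp$anchor_prob < 0 || sp$anchor_prob > 1) {
      abort("anchor_prob must be in [0, 1]", class = "peptivax_config_error")
    }
  }
  if (abs(sum(cfg$length_weights) - 1) > 1e-9) {
    abort("length_weights must sum to 1", class = "peptivax_config_error")
  }
  invisible(cfg)
}

#' Generate a synthetic proteome
#'
#' `n_genes` random proteins with i.i.d. residues from the configured
#' background frequencies and lengths uniform on 100-600.
#'
#' @param config A [sim_config()].
#' @return List with `proteome` (named character vector, ids `prot_###`) and
#'   `gene_map` (tibble `protein_id`, `gene_id`).
#' @export
gen_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    lens <- sample(100:600, config$n_genes, replace = TRUE)
    seqs <- random_aa_sequences(lens, config$background)
  })
  ids <- sprintf("prot_%03d", seq_len(config$n_genes))
  list(
    proteome = setNames(seqs, ids),
    gene_map = tibble::tibble(
      protein_id = ids,
      gene_id = sprintf("gene_%03d", seq_len(config$n_genes))
    )
  )
}

force_anchors <- function(sequence, anchors) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  for (pos in names(anchors)) {
    chars[as.integer(pos)] <- sample(rep(anchors[[pos]], 2), 1)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic ligandome with planted motif structure
#'
#' Non-contaminant peptides are exact substrings of proteome proteins with
#' lengths drawn from the configured distribution (mode 9). Each 9mer is
#' assigned to one of the two allele motifs; with probability `anchor_prob`
#' its full anchor signature (both P2 and P9) is written into the sequence,
#' emulating the reduced residue complexity at anchor positions that real
#' eluted ligandomes show. Contaminants are uniform-residue sequences with
#' lengths 7-25. Planted truth (allele, contaminant flag, source gene,
#' whether anchors were applied) is returned as a sidecar tibble.
#'
#' @param config A [sim_config()].
#' @param proteome Named character vector of protein sequences (from
#'   [gen_proteome()]).
#' @param gene_map Tibble mapping `protein_id` to `gene_id`.
#' @return List with `peptides` (tibble `peptide_id`, `sequence`, `length`)
#'   and `truth` (sidecar tibble with planted labels).
#' @export
gen_ligandome <- function(config, proteome, gene_map) {
  stopifnot(inherits(config, "sim_config"))
  if (length(proteome) == 0) abort("proteome is empty")
  lens_avail <- nchar(proteome)
  max_len <- max(as.integer(names(config$length_weights)))
  if (max(lens_avail) < max_len) {
    abort("proteome proteins are shorter than the requested peptide length")
  }
  n <- config$n_peptides
  n_contam <- round(config$contaminant_fraction * n)
  n_real <- n - n_contam
  alleles <- names(config$allele_motifs)

  with_seed(config$seed + 2L, {
    pep_len <- sample(
      as.integer(names(config$length_weights)), n_real,
      replace = TRUE, prob = config$length_weights
    )
    rows <- purrr::map(seq_len(n_real), function(i) {
      L <- pep_len[i]
      eligible <- which(lens_avail >= L)
      prot <- sample(rep(eligible, 2), 1)
      start <- sample(seq_len(lens_avail[prot] - L + 1), 1)
      seqc <- substr(proteome[[prot]], start, start + L - 1)
      allele <- NA_character_
      anchored <- FALSE
      if (L == 9L) {
        allele <- sample(alleles, 1)
        spec <- config$allele_motifs[[allele]]
        if (runif(1) <= spec$anchor_prob) {
          seqc <- force_anchors(seqc, spec$anchors)
          anchored <- TRUE
        }
      }
      tibble::tibble(
        sequence = seqc, protein_id = names(proteome)[prot],
        allele = allele, anchored = anchored
      )
    })
    real <- dplyr::bind_rows(rows)
    contam <- if (n_contam > 0) {
      clens <- sample(7:25, n_contam, replace = TRUE)
      tibble::tibble(
        sequence = random_aa_sequences(clens, rep(1 / 20, 20)),
        protein_id = NA_character_, allele = NA_character_, anchored = FALSE
      )
    } else {
      real[0, ]
    }
  })

  all_rows <- dplyr::bind_rows(
    dplyr::mutate(real, is_contaminant = FALSE),
    dplyr::mutate(contam, is_contaminant = TRUE)
  )
  all_rows$peptide_id <- sprintf("pep_%05d", seq_len(nrow(all_rows)))
  all_rows <- dplyr::left_join(all_rows, gene_map, by = "protein_id")
  list(
    peptides = tibble::tibble(
      peptide_id = all_rows$peptide_id,
      sequence = all_rows$sequence,
      length = nchar(all_rows$sequence)
    ),
    truth = dplyr::select(
      all_rows, "peptide_id", "allele", "is_contaminant",
      "anchored", "protein_id", "gene_id"
    )
  )
}

#' Generate two differential-expression tables with a planted gene set
#'
#' For both contrasts, planted genes draw `log2fc ~ Normal(mean, sd)` and
#' `padj ~ Uniform(0, planted_padj_max]`; null genes draw
#' `log2fc ~ Normal(0, null_sd)` and `padj ~ Uniform[null_padj_min, 1]`.
#' Adjusted p-values are generated directly: DE testing itself is upstream of
#' this workflow, which consumes DESeq2-style result tables.
#'
#' @param config A [sim_config()].
#' @param gene_map Tibble with a `gene_id` column.
#' @return List with `de1`, `de2` (tibbles `gene_id`, `log2fc`, `padj`) and
#'   `planted` (character vector of planted gene ids).
#' @export
gen_de_tables <- function(config, gene_map) {
  stopifnot(inherits(config, "sim_config"))
  genes <- unique(gene_map$gene_id)
  if (config$planted_overexpressed > length(genes)) {
    abort("planted_overexpressed exceeds number of genes", class = "peptivax_config_error")
  }
  with_seed(config$seed + 3L, {
    planted <- sort(sample(genes, config$planted_overexpressed))
    make_table <- function() {
      is_planted <- genes %in% planted
      tibble::tibble(
        gene_id = genes,
        log2fc = ifelse(
          is_planted,
          rnorm(length(genes), config$planted_log2fc_mean, config$planted_log2fc_sd),
          rnorm(length(genes), 0, config$null_log2fc_sd)
        ),
        padj = ifelse(
          is_planted,
          runif(length(genes), 0, config$planted_padj_max),
          runif(length(genes), config$null_padj_min, 1)
        )
      )
    }
    de1 <- make_table()
    de2 <- make_table()
  })
  list(de1 = de1, de2 = de2, planted = planted)
}

mutate_peptide <- function(sequence, n_mutations) {
  if (n_mutations == 0) {
    return(sequence)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  pos <- sample(seq_along(chars), n_mutations)
  for (p in pos) {
    chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic pathogen-epitope database with planted homologs
#'
#' Random 9-15mer decoy epitopes plus, for a subset of the supplied tumor
#' 9mers, a near-identical homolog copied with `homolog_mutations` random
#' substitutions. Planted pairs are returned as a sidecar tibble.
#'
#' @param config A [sim_config()].
#' @param tumor_peptides Named character vector (names = peptide ids) of
#'   tumor 9mers, or plain character vector.
#' @param n_homologs Number of tumor peptides that receive a planted homolog
#'   (default: min(10, number supplied)).
#' @return List with `db` (named character vector of pathogen records) and
#'   `pairs` (tibble `peptide_id`, `tumor_peptide`, `record_id`,
#'   `homolog_sequence`, `mutations`, `identity`).
#' @export
gen_pathogen_db <- function(config, tumor_peptides,
                            n_homologs = min(10L, length(tumor_peptides))) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(names(tumor_peptides))) {
    names(tumor_peptides) <- sprintf("pep_%05d", seq_along(tumor_peptides))
  }
  if (any(nchar(tumor_peptides) != 9)) abort("tumor peptides must be 9mers")
  with_seed(config$seed + 4L, {
    dlens <- sample(9:15, config$n_pathogen_epitopes, replace = TRUE)
    decoys <- random_aa_sequences(dlens, config$background)
    names(decoys) <- sprintf("path_%04d", seq_along(decoys))
    chosen <- sample(seq_along(tumor_peptides), n_homologs)
    homologs <- vapply(
      tumor_peptides[chosen], mutate_peptide, character(1),
      n_mutations = config$homolog_mutations
    )
  })
  hom_ids <- sprintf("homolog_%03d", seq_along(homologs))
  pairs <- tibble::tibble(
    peptide_id = names(tumor_peptides)[chosen],
    tumor_peptide = unname(tumor_peptides[chosen]),
    record_id = hom_ids,
    homolog_sequence = unname(homologs),
    mutations = config$homolog_mutations,
    identity = (9 - config$homolog_mutations) / 9
  )
  list(db = c(decoys, setNames(unname(homologs), hom_ids)), pairs = pairs)
}

#' Generate a synthetic ELISpot spot-count table
#'
#' Per peptide, `elispot_replicates` replicate counts from a negative
#' binomial with mean `elispot_responder_mean` for planted responders and
#' `elispot_background_mean` otherwise; adjuvant-only and saline control
#' groups draw from the background mean. Variance is
#' `mean + mean^2 / dispersion`.
#'
#' @param config A [sim_config()].
#' @param panel Character vector of peptide group labels.
#' @param responders Subset of `panel` planted as responders.
#' @return Tibble with columns `group`, `replicate`, `spots`.
#' @export
gen_elispot <- function(config, panel, responders = character(0)) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(responders %in% panel)) {
    abort("responders must be a subset of the panel", class = "peptivax_config_error")
  }
  groups <- c(panel, "adjuvant_only", "saline")
  mus <- ifelse(groups %in% responders,
    config$elispot_responder_mean, config$elispot_background_mean
  )
  reps <- config$elispot_replicates
  with_seed(config$seed + 5L, {
    spots <- rnbinom(length(groups) * reps,
      mu = rep(mus, each = reps), size = config$elispot_dispersion
    )
  })
  tibble::tibble(
    group = rep(groups, each = reps),
    replicate = rep(seq_len(reps), length(groups)),
    spots = as.integer(spots)
  )
}

#' Generate a synthetic two-phase SPR sensorgram
#'
#' Exponential rise towards the equilibrium plateau `r_eq` during the
#' association window, then exponential decay towards the dissociation
#' plateau `r_diss`, with Gaussian noise of the configured SD. Window
#' boundaries are attached as attributes `association_end` and
#' `dissociation_end`.
#'
#' @param config A [sim_config()].
#' @param r_eq Equilibrium plateau (degrees).
#' @param r_diss Post-dissociation plateau (degrees); must not exceed `r_eq`.
#' @param association_end,dissociation_end Phase boundaries in seconds.
#' @param tau Exponential time constant (seconds).
#' @param dt Sampling interval (seconds).
#' @return Tibble `time_s`, `response_deg` with phase-boundary attributes.
#' @export
gen_sensorgram <- function(config, r_eq, r_diss,
                           association_end = 300, dissociation_end = 600,
                           tau = 20, dt = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (r_diss > r_eq) abort("r_diss must not exceed r_eq", class = "peptivax_config_error")
  time_s <- seq(0, dissociation_end, by = dt)
  clean <- ifelse(
    time_s <= association_end,
    r_eq * (1 - exp(-time_s / tau)),
    r_diss + (r_eq - r_diss) * exp(-(time_s - association_end) / tau)
  )
  with_seed(config$seed + 6L, {
    noise <- rnorm(length(time_s), 0, config$sensorgram_noise_sd)
  })
  out <- tibble::tibble(time_s = time_s, response_deg = clean + noise)
  attr(out, "association_end") <- association_end
  attr(out, "dissociation_end") <- dissociation_end
  out
}
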