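# End-to-end orchestration over synthetic inputs, plus the bundled printed
# peptide panels used for the in vivo characterization.

#' Theoretical motif model for an allele anchor specification
#'
#' Builds the position frequency matrix implied by an allele spec: anchor
#' columns put `anchor_prob` mass uniformly on the anchor residue set (plus
#' `(1 - anchor_prob)` times the background), all other columns equal the
#' background.
#'
#' @param spec Allele spec: list with `anchors` (named list position ->
#'   residues) and `anchor_prob`.
#' @param background Background residue frequencies.
#' @param length Motif length (default 9).
#' @return A [motif_model()].
#' @export
allele_motif_model <- function(spec, background = rep(1 / 20, 20), length = 9L) {
  freq <- matrix(background, nrow = 20, ncol = length)
  for (pos in names(spec$anchors)) {
    res <- spec$anchors[[pos]]
    col <- (1 - spec$anchor_prob) * background
    col[match(res, AA_ALPHABET)] <- col[match(res, AA_ALPHABET)] +
      spec$anchor_prob / length(res)
    freq[, as.integer(pos)] <- col
  }
  motif_model(freq, background, pseudocount = 0)
}

#' Bundled printed peptide panels
#'
#' Returns (a) the 26-peptide pre-immunization candidate panel and (b) the
#' poly-lysine study list: each entry as printed, with its gene tag, a
#' poly-lysine flag, and the core 9mer. Because the printed poly-lysine
#' tails vary in length (five to seven lysines), the core is parsed as the
#' final nine residues of each entry, which recovers a panel-(a) member for
#' every poly-lysine entry.
#'
#' @return List with tibbles `pre_immunization` (`peptide_id`, `sequence`)
#'   and `polyk` (`sequence`, `gene`, `is_polyk`, `core`).
#' @export
fixture_panel <- function() {
  pre <- c(
    "SYHPALNAI", "SYLTSASSL", "YYVRILSTI", "SYLPPGTSL", "RYLPAPTAL",
    "KYIPAARHL", "AFHSSRTSL", "NYNSVNTRM", "SYSDMKRAL", "FYEKNKTLV",
    "KGPNRGVII", "FYKNGRLAV", "LYKESLSRL", "SYRDVIQEL", "KFYDSKETV",
    "KYLNVREAV", "HYLPDLHHM", "SGPNRFILI", "SYIIGTSSV", "RGPYVYREF",
    "FYATIIHDL", "GYMTPGLTV", "SYLIGRQKI", "AGASRIIGI", "QGPEYIERL",
    "SYIHQRYIL"
  )
  polyk_seq <- c(
    "KKKKKKSYLPPGTSL", "KKKKKKRYLPAPTAL", "KKKKKKYIPAARHL",
    "KKKKKKLYKESLSRL", "KKKKKKYLNVREAV", "KKKKKKKFYATIIHDL",
    "SYLPPGTSL", "RYLPAPTAL", "KYIPAARHL", "LYKESLSRL", "KYLNVREAV",
    "FYATIIHDL"
  )
  polyk_gene <- c(
    "Mavs", "Fanca", "Zw10", "Myh14", "Chac1", "Ndst3",
    "Mavs", "Fanca", "Zw10", "Myh14", "Chac1", "Ndst3"
  )
  list(
    pre_immunization = tibble::tibble(
      peptide_id = sprintf("panel_%02d", seq_along(pre)),
      sequence = pre
    ),
    polyk = tibble::tibble(
      sequence = polyk_seq,
      gene = polyk_gene,
      is_polyk = nchar(polyk_seq) > 9,
      core = substring(polyk_seq, nchar(polyk_seq) - 8)
    )
  )
}

#' Pipeline configuration
#'
#' @param seed Global seed; propagated to the simulation and every
#'   stochastic stage.
#' @param sim A [sim_config()]; its seed is overridden by `seed`.
#' @param min_len,max_len QC length window (default 7-13).
#' @param rank_threshold Binder percent-rank threshold (default 2).
#' @param n_bg Background sample size for rank calibration.
#' @param cluster_k,cluster_sweeps Gibbs clustering parameters for the
#'   motif-deconvolution stage.
#' @param selection A [selection_config()].
#' @param mimicry A [mimicry_config()]; the affinity gate defaults to off
#'   here because the synthetic cohort carries no IC50 measurements.
#' @param n_homologs Planted pathogen homolog pairs.
#' @param responder_fraction Fraction of the candidate union planted as
#'   ELISpot responders.
#' @param spr_r_eq,spr_r_diss,spr_r_virus SPR stage responses in degrees.
#' @param stages Character vector of enabled stages among `qc`, `cluster`,
#'   `select`, `mimicry`, `elispot`, `spr`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = seed),
                            min_len = 7L, max_len = 13L,
                            rank_threshold = 2.0,
                            n_bg = 20000L,
                            cluster_k = 2L, cluster_sweeps = 50L,
                            selection = selection_config(),
                            mimicry = mimicry_config(affinity_mode = "off"),
                            n_homologs = 10L,
                            responder_fraction = 0.5,
                            spr_r_eq = 0.5, spr_r_diss = 0.2,
                            spr_r_virus = 1.4,
                            stages = c("qc", "cluster", "select", "mimicry", "elispot", "spr")) {
  sim$seed <- as.integer(seed)
  structure(
    list(
      seed = as.integer(seed), sim = sim, min_len = min_len, max_len = max_len,
      rank_threshold = rank_threshold, n_bg = as.integer(n_bg),
      cluster_k = as.integer(cluster_k), cluster_sweeps = as.integer(cluster_sweeps),
      selection = selection, mimicry = mimicry, n_homologs = as.integer(n_homologs),
      responder_fraction = responder_fraction,
      spr_r_eq = spr_r_eq, spr_r_diss = spr_r_diss, spr_r_virus = spr_r_virus,
      stages = stages
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `sim`,
#' `selection` and `mimicry` blocks are passed to their constructors.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$sim)) args$sim <- do.call(sim_config, c(y$sim, list(seed = y$seed %||% 1L)))
  if (!is.null(y$selection)) args$selection <- do.call(selection_config, y$selection)
  if (!is.null(y$mimicry)) args$mimicry <- do.call(mimicry_config, y$mimicry)
  do.call(pipeline_config, args)
}

pipeline_log <- function(path, msg) {
  line <- sprintf("%s | %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), msg)
  cat(line, "\n", sep = "", file = path, append = TRUE)
}

run_stage <- function(name, log_path, expr) {
  pipeline_log(log_path, sprintf("stage %s: start", name))
  res <- tryCatch(expr, error = function(e) {
    pipeline_log(log_path, sprintf("stage %s: FAILED (%s)", name, conditionMessage(e)))
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
  pipeline_log(log_path, sprintf("stage %s: done", name))
  res
}

#' Run the synthetic end-to-end candidate-selection pipeline
#'
#' Generates a synthetic cohort (proteome, ligandome with planted motifs and
#' contaminants, two DE contrasts with planted overexpressed genes, pathogen
#' database with planted homologs), then runs the enabled stages: ligandome
#' QC and binder calibration, Gibbs motif deconvolution, the
#' expression-based and mimicry-based selection arms, the ELISpot
#' immunogenicity gate on the union of the two arms, and advisory SPR
#' quantitation of peptides per virion. All intermediate tables and planted
#' truth sidecars are written as TSV under `out_dir`; given one config the
#' report is byte-identical across runs.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the report tibble and every stage result.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  cat("", file = log_path) # truncate
  pipeline_log(log_path, sprintf(
    "run_pipeline seed=%d stages=%s rank_threshold=%g",
    config$seed, paste(config$stages, collapse = ","), config$rank_threshold
  ))
  res <- list(config = config)
  alleles <- names(config$sim$allele_motifs)

  # -- simulate (always: provides the inputs) ------------------------------
  sim <- run_stage("simulate", log_path, {
    prot <- gen_proteome(config$sim)
    lig <- gen_ligandome(config$sim, prot$proteome, prot$gene_map)
    de <- gen_de_tables(config$sim, prot$gene_map)
    write_fasta(prot$proteome, file.path(out_dir, "proteome.fasta"))
    write_peptide_table(lig$peptides, file.path(out_dir, "peptides.tsv"))
    readr::write_tsv(lig$truth, file.path(out_dir, "truth_ligandome.tsv"), progress = FALSE)
    write_de_table(de$de1, file.path(out_dir, "de_contrast1.tsv"))
    write_de_table(de$de2, file.path(out_dir, "de_contrast2.tsv"))
    readr::write_tsv(tibble::tibble(gene_id = de$planted),
      file.path(out_dir, "truth_planted_genes.tsv"),
      progress = FALSE
    )
    list(prot = prot, lig = lig, de = de)
  })
  res$sim <- sim

  # -- qc ------------------------------------------------------------------
  qc <- NULL
  if ("qc" %in% config$stages) {
    qc <- run_stage("qc", log_path, {
      split <- filter_by_length(sim$lig$peptides, config$min_len, config$max_len)
      dist <- length_distribution(split$kept)
      mapped <- map_peptides_to_proteins(split$kept, sim$prot$proteome, sim$prot$gene_map)
      nine <- mapped[mapped$length == 9, ]
      motifs <- lapply(
        config$sim$allele_motifs, allele_motif_model,
        background = config$sim$background
      )
      ranks <- purrr::imap(motifs, function(m, allele) {
        allele_seed <- config$seed + 100L + match(allele, alleles)
        tibble::tibble(
          peptide_id = nine$peptide_id,
          allele = allele,
          rank = calibrate_rank(m, nine$sequence,
            n_bg = config$n_bg, seed = allele_seed
          )
        )
      }) |> dplyr::bind_rows()
      binders <- classify_binders(ranks, threshold = config$rank_threshold)
      rank_wide <- tidyr::pivot_wider(ranks,
        names_from = "allele", values_from = "rank", names_prefix = "rank_"
      )
      nine <- dplyr::left_join(nine, rank_wide, by = "peptide_id") |>
        dplyr::left_join(binders, by = "peptide_id")
      readr::write_tsv(dist, file.path(out_dir, "length_distribution.tsv"), progress = FALSE)
      qc_report <- dplyr::mutate(nine,
        source_proteins = purrr::map_chr(.data$source_proteins, paste, collapse = ";"),
        source_genes = purrr::map_chr(.data$source_genes, paste, collapse = ";")
      )
      readr::write_tsv(qc_report, file.path(out_dir, "qc_report.tsv"), progress = FALSE)
      list(
        split = split, distribution = dist, mapped = mapped, nine = nine,
        ranks = ranks, binders = binders,
        n_source_proteins = attr(mapped, "n_source_proteins")
      )
    })
    res$qc <- qc
  }

  # -- cluster -------------------------------------------------------------
  if ("cluster" %in% config$stages) {
    if (is.null(qc)) abort("stage 'cluster' requires stage 'qc'")
    res$cluster <- run_stage("cluster", log_path, {
      nine <- qc$nine
      sol <- gibbs_cluster(nine$sequence,
        k = config$cluster_k,
        sweeps = config$cluster_sweeps, seed = config$seed + 200L,
        background = config$sim$background
      )
      readr::write_tsv(
        tibble::tibble(peptide_id = nine$peptide_id, cluster = sol$assignment),
        file.path(out_dir, "cluster_assignment.tsv"),
        progress = FALSE
      )
      for (c in seq_len(sol$k)) {
        if (!is.null(sol$cluster_motifs[[c]])) {
          readr::write_tsv(
            motif_frequencies(sol$cluster_motifs[[c]]),
            file.path(out_dir, sprintf("cluster_motif_%d.tsv", c)),
            progress = FALSE
          )
        }
      }
      sol
    })
  }

  # -- selection arms ------------------------------------------------------
  binder_nine <- if (!is.null(qc)) qc$nine[qc$nine$binder, ] else NULL

  if ("select" %in% config$stages) {
    if (is.null(qc)) abort("stage 'select' requires stage 'qc'")
    res$expression <- run_stage("select", log_path, {
      per_gene <- binder_nine |>
        dplyr::select(
          "peptide_id", "sequence", "source_genes",
          dplyr::all_of(paste0("rank_", alleles))
        ) |>
        tidyr::unnest_longer("source_genes", values_to = "gene_id") |>
        dplyr::mutate(gene_id = dplyr::if_else(.data$gene_id == "", NA_character_, .data$gene_id))
      scores <- select_taa_candidates(
        per_gene, sim$de$de1, sim$de$de2,
        config = config$selection, alleles = alleles
      )
      readr::write_tsv(scores, file.path(out_dir, "expression_candidates.tsv"), progress = FALSE)
      scores
    })
  }

  if ("mimicry" %in% config$stages) {
    if (is.null(qc)) abort("stage 'mimicry' requires stage 'qc'")
    res$mimicry <- run_stage("mimicry", log_path, {
      tumor <- setNames(binder_nine$sequence, binder_nine$peptide_id)
      db <- gen_pathogen_db(config$sim, tumor,
        n_homologs = min(config$n_homologs, length(tumor))
      )
      write_fasta(db$db, file.path(out_dir, "pathogen_db.fasta"))
      readr::write_tsv(db$pairs, file.path(out_dir, "truth_homolog_pairs.tsv"), progress = FALSE)
      best <- scan_database(tumor, db$db, config = config$mimicry)
      filtered <- filter_mimics(best, config = config$mimicry)
      readr::write_tsv(filtered, file.path(out_dir, "mimicry_hits.tsv"), progress = FALSE)
      list(db = db, best = best, filtered = filtered)
    })
  }

  # -- union of arms + ELISpot gate ---------------------------------------
  arm_expr <- if (!is.null(res$expression)) {
    unique(res$expression$peptide_id[res$expression$selected])
  } else {
    character(0)
  }
  arm_mim <- if (!is.null(res$mimicry)) {
    unique(res$mimicry$filtered$peptide_id[res$mimicry$filtered$selected])
  } else {
    character(0)
  }
  union_ids <- sort(union(arm_expr, arm_mim))

  if ("elispot" %in% config$stages) {
    res$elispot <- run_stage("elispot", log_path, {
      if (length(union_ids) == 0) {
        pipeline_log(log_path, "elispot: empty candidate union; nothing to gate")
        list(counts = NULL, gate = NULL, responders = character(0))
      } else {
        n_resp <- ceiling(config$responder_fraction * length(union_ids))
        responders <- with_seed(config$seed + 7L, {
          sort(sample(rep(union_ids, 2), n_resp))
        })
        responders <- unique(responders)
        counts <- gen_elispot(config$sim, union_ids, responders)
        readr::write_tsv(counts, file.path(out_dir, "elispot_counts.tsv"), progress = FALSE)
        readr::write_tsv(tibble::tibble(peptide_id = responders),
          file.path(out_dir, "truth_elispot_responders.tsv"),
          progress = FALSE
        )
        gate <- elispot_gate(elispot_summarize(counts))
        readr::write_tsv(gate, file.path(out_dir, "elispot_gate.tsv"), progress = FALSE)
        list(counts = counts, gate = gate, responders = responders)
      }
    })
  }

  # -- advisory SPR quantitation ------------------------------------------
  if ("spr" %in% config$stages) {
    res$spr <- run_stage("spr", log_path, {
      gated <- if (!is.null(res$elispot$gate)) {
        res$elispot$gate$group[res$elispot$gate$selected]
      } else {
        union_ids
      }
      if (length(gated) == 0) {
        NULL
      } else {
        seqs <- setNames(
          sim$lig$peptides$sequence[match(gated, sim$lig$peptides$peptide_id)], gated
        )
        per <- purrr::imap(seqs, function(seqc, id) {
          sg <- gen_sensorgram(config$sim, config$spr_r_eq, config$spr_r_diss)
          ph <- extract_phase_levels(sg)
          out <- peptides_per_virion(ph, config$spr_r_virus, peptide_average_mass(seqc))
          dplyr::mutate(out, peptide_id = id, .before = 1)
        })
        spr_tab <- dplyr::bind_rows(per)
        readr::write_tsv(spr_tab, file.path(out_dir, "spr_quantitation.tsv"), progress = FALSE)
        spr_tab
      }
    })
  }

  # -- report --------------------------------------------------------------
  if (!is.null(qc)) {
    report <- qc$nine |>
      dplyr::select(
        "peptide_id", "sequence",
        dplyr::all_of(paste0("rank_", alleles)), "min_rank", "binder",
        "preferred_allele", "unmapped"
      ) |>
      dplyr::mutate(
        cluster = if (!is.null(res$cluster)) res$cluster$assignment else NA_integer_,
        expression_selected = .data$peptide_id %in% arm_expr,
        mimicry_selected = .data$peptide_id %in% arm_mim,
        arm = dplyr::case_when(
          .data$expression_selected & .data$mimicry_selected ~ "both",
          .data$expression_selected ~ "rnaseq",
          .data$mimicry_selected ~ "mimicry",
          TRUE ~ "none"
        ),
        elispot_selected = if (!is.null(res$elispot$gate)) {
          .data$peptide_id %in% res$elispot$gate$group[res$elispot$gate$selected]
        } else {
          NA
        },
        final_candidate = .data$arm != "none" &
          (is.na(.data$elispot_selected) | .data$elispot_selected)
      )
    report_path <- file.path(out_dir, "report.tsv")
    header <- sprintf(
      "# peptivax report | seed=%d | rank_threshold=%g | fc_min=%g | padj_max=%g | rank_metric_min=%g | fc_quantile=%g | score_min=%g | identity_min=%g",
      config$seed, config$rank_threshold, config$selection$fc_min,
      config$selection$padj_max, config$selection$rank_metric_min,
      config$selection$fc_quantile, config$mimicry$weighted_score_min,
      config$mimicry$identity_min
    )
    writeLines(header, report_path)
    suppressWarnings(readr::write_tsv(report, report_path, append = TRUE, col_names = TRUE, progress = FALSE))
    res$report <- report
  }
  pipeline_log(log_path, "run_pipeline: done")
  invisible(res)
}
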