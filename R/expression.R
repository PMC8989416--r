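#' Selection thresholds for the expression arm
#'
#' @param fc_min Minimum linear fold change in both contrasts (default 1.5).
#' @param padj_max Maximum adjusted p-value in both contrasts (default 0.05).
#' @param rank_metric_min Minimum `-log10(average percent rank)` (default
#'   0.5, i.e. average rank at or below ~0.316%).
#' @param fc_quantile Quantile of average fold change used as the
#'   prioritization gate (default 0.75, the third quartile).
#' @param rank_average Averaging rule for the two allele ranks:
#'   `"arithmetic"` (default) or `"harmonic"`.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(fc_min = 1.5, padj_max = 0.05,
                             rank_metric_min = 0.5, fc_quantile = 0.75,
                             rank_average = c("arithmetic", "harmonic")) {
  rank_average <- match.arg(rank_average)
  if (fc_min <= 0) abort("fc_min must be positive", class = "peptivax_config_error")
  if (padj_max < 0 || padj_max > 1) {
    abort("padj_max must be in [0, 1]", class = "peptivax_config_error")
  }
  if (fc_quantile <= 0 || fc_quantile >= 1) {
    abort("fc_quantile must be in (0, 1)", class = "peptivax_config_error")
  }
  structure(
    list(
      fc_min = fc_min, padj_max = padj_max,
      rank_metric_min = rank_metric_min, fc_quantile = fc_quantile,
      rank_average = rank_average
    ),
    class = "selection_config"
  )
}

#' Genes overexpressed in both differential-expression contrasts
#'
#' A gene is selected iff in *both* tables its `log2fc >= log2(fc_min)` and
#' `padj <= padj_max` (boundaries inclusive). Only upregulation counts: the
#' tumor-associated-antigen definition requires overexpression relative to
#' normal tissue, so downregulated genes never pass. Genes absent from one
#' table are treated as not overexpressed, not as errors (real DE tables are
#' filtered upstream).
#'
#' @param de1,de2 DE tibbles with columns `gene_id`, `log2fc`, `padj`.
#' @param config A [selection_config()].
#' @return Character vector of gene ids overexpressed in both contrasts.
#' @export
intersect_overexpressed <- function(de1, de2, config = selection_config()) {
  pass <- function(de) {
    de$gene_id[de$log2fc >= log2(config$fc_min) & de$padj <= config$padj_max &
      !is.na(de$log2fc) & !is.na(de$padj)]
  }
  sort(intersect(pass(de1), pass(de2)))
}

#' Combined two-allele rank metric
#'
#' Averages the two per-allele percentile ranks (percent units) and returns
#' `-log10(average rank)`: 0 at an average rank of 1%, larger for stronger
#' binders. The arithmetic mean is the default; the harmonic mean is
#' available as an option.
#'
#' @param rank_a,rank_b Percent ranks in (0, 100\].
#' @param average `"arithmetic"` (default) or `"harmonic"`.
#' @return List with numeric vectors `avg_rank` (percent) and `metric`
#'   (`-log10(avg_rank)`).
#' @export
combined_rank_metric <- function(rank_a, rank_b,
                                 average = c("arithmetic", "harmonic")) {
  average <- match.arg(average)
  if (any(rank_a <= 0 | rank_b <= 0, na.rm = TRUE)) {
    abort("ranks must be positive percent values")
  }
  avg <- if (average == "arithmetic") {
    (rank_a + rank_b) / 2
  } else {
    2 / (1 / rank_a + 1 / rank_b)
  }
  list(avg_rank = avg, metric = -log10(avg))
}

#' Quantile gate on average fold changes
#'
#' The threshold is the empirical quantile (linear interpolation between
#' order statistics, R's default type 7) of the supplied values; a value
#' passes iff it is at or above the threshold (inclusive).
#'
#' @param avg_fc Numeric vector of average linear fold changes.
#' @param fc_quantile Quantile in (0, 1), default 0.75.
#' @return List with `threshold` and logical vector `pass`.
#' @export
quartile_gate <- function(avg_fc, fc_quantile = 0.75) {
  if (length(avg_fc) == 0) {
    return(list(threshold = NA_real_, pass = logical(0)))
  }
  threshold <- unname(quantile(avg_fc, probs = fc_quantile, type = 7))
  list(threshold = threshold, pass = avg_fc >= threshold)
}

#' Select tumor-associated-antigen candidates from the expression arm
#'
#' Applies the three gates of the RNA arm to binder peptides: (1) source
#' gene overexpressed in both DE contrasts (fold change and adjusted
#' p-value thresholds), (2) combined allele-rank metric at or above
#' `rank_metric_min`, and (3) average linear fold change at or above the
#' `fc_quantile` quantile computed among DE-passing candidates. A peptide
#' with several source genes contributes one row per gene; peptides lacking
#' a source gene are excluded (reported via the `n_excluded_no_gene`
#' attribute).
#'
#' @param peptides Tibble with columns `peptide_id`, `gene_id`, and two rank
#'   columns named `rank_<allele>`; typically binders only.
#' @param de1,de2 DE tibbles (`gene_id`, `log2fc`, `padj`).
#' @param config A [selection_config()].
#' @param alleles Character vector of the two allele names whose
#'   `rank_<allele>` columns hold the percent ranks.
#' @return Tibble with one row per (peptide, gene): fold changes in both
#'   contrasts, `avg_fc`, `avg_rank`, `rank_metric`, gate flags `pass_de`,
#'   `pass_rank`, `pass_quartile`, and `selected` (conjunction of the
#'   three). The quartile threshold is attached as attribute
#'   `fc_threshold`.
#' @export
select_taa_candidates <- function(peptides, de1, de2,
                                  config = selection_config(),
                                  alleles = c("Kd", "Dd")) {
  rank_cols <- paste0("rank_", alleles)
  missing_cols <- setdiff(c("peptide_id", "gene_id", rank_cols), names(peptides))
  if (length(missing_cols) > 0) {
    abort(sprintf("peptides missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  no_gene <- is.na(peptides$gene_id)
  n_excluded <- sum(no_gene)
  cand <- tibble::as_tibble(peptides[!no_gene, , drop = FALSE])
  if (nrow(cand) == 0) {
    out <- tibble::tibble(
      peptide_id = character(), gene_id = character(),
      log2fc_contrast1 = numeric(), log2fc_contrast2 = numeric(),
      avg_fc = numeric(), avg_rank = numeric(), rank_metric = numeric(),
      pass_de = logical(), pass_rank = logical(), pass_quartile = logical(),
      selected = logical()
    )
    attr(out, "fc_threshold") <- NA_real_
    attr(out, "n_excluded_no_gene") <- n_excluded
    return(out)
  }
  overexpressed <- intersect_overexpressed(de1, de2, config)
  lut1 <- setNames(de1$log2fc, de1$gene_id)
  lut2 <- setNames(de2$log2fc, de2$gene_id)
  rk <- combined_rank_metric(
    cand[[rank_cols[1]]], cand[[rank_cols[2]]],
    average = config$rank_average
  )
  cand <- dplyr::mutate(
    cand,
    log2fc_contrast1 = unname(lut1[.data$gene_id]),
    log2fc_contrast2 = unname(lut2[.data$gene_id]),
    avg_fc = (2^.data$log2fc_contrast1 + 2^.data$log2fc_contrast2) / 2,
    avg_rank = rk$avg_rank,
    rank_metric = rk$metric,
    pass_de = .data$gene_id %in% overexpressed,
    pass_rank = .data$rank_metric >= config$rank_metric_min
  )
  # quantile computed among DE-passing candidates only
  gate <- quartile_gate(cand$avg_fc[cand$pass_de], config$fc_quantile)
  cand$pass_quartile <- if (is.na(gate$threshold)) {
    rep(FALSE, nrow(cand))
  } else {
    !is.na(cand$avg_fc) & cand$avg_fc >= gate$threshold
  }
  cand$selected <- cand$pass_de & cand$pass_rank & cand$pass_quartile
  out <- dplyr::select(
    cand, "peptide_id", "gene_id", dplyr::all_of(rank_cols),
    "log2fc_contrast1", "log2fc_contrast2", "avg_fc", "avg_rank",
    "rank_metric", "pass_de", "pass_rank", "pass_quartile", "selected"
  )
  attr(out, "fc_threshold") <- gate$threshold
  attr(out, "n_excluded_no_gene") <- n_excluded
  out
}
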