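#' Split peptides by length window
#'
#' Partitions the input into peptides whose length lies inside
#' `[min_len, max_len]` (boundaries inclusive) and the rest; input order is
#' preserved and no record is dropped.
#'
#' @param peptides Tibble with a `sequence` column (a `length` column is
#'   recomputed if absent).
#' @param min_len,max_len Inclusive length bounds (defaults 7 and 13, the
#'   conventional MHC-I window).
#' @return List with tibbles `kept` and `removed`.
#' @export
filter_by_length <- function(peptides, min_len = 7L, max_len = 13L) {
  if (min_len > max_len) abort("min_len must not exceed max_len")
  if (!"length" %in% names(peptides)) {
    peptides <- dplyr::mutate(peptides, length = nchar(.data$sequence))
  }
  keep <- peptides$length >= min_len & peptides$length <= max_len
  list(
    kept = tibble::as_tibble(peptides[keep, , drop = FALSE]),
    removed = tibble::as_tibble(peptides[!keep, , drop = FALSE])
  )
}

#' Length distribution of a peptide set
#'
#' @param peptides Tibble with a `sequence` (or `length`) column.
#' @return Tibble with columns `length`, `count`, `percent`; percents sum to
#'   100 over the input.
#' @export
length_distribution <- function(peptides) {
  lens <- if ("length" %in% names(peptides)) peptides$length else nchar(peptides$sequence)
  if (length(lens) == 0) {
    return(tibble::tibble(length = integer(), count = integer(), percent = numeric()))
  }
  tab <- tibble::tibble(length = lens) |>
    dplyr::count(.data$length, name = "count") |>
    dplyr::arrange(.data$length) |>
    dplyr::mutate(percent = 100 * .data$count / sum(.data$count))
  tab
}

#' Map peptides to their source proteins by exact substring search
#'
#' A protein is a source of a peptide iff the peptide occurs as an exact
#' contiguous substring of the protein sequence. Peptides with no source are
#' flagged `unmapped`, never dropped. The number of unique source proteins
#' over the whole set is attached as attribute `n_source_proteins`.
#'
#' @param peptides Tibble with `peptide_id` and `sequence` columns.
#' @param proteome Named character vector of protein sequences.
#' @param gene_map Optional tibble `protein_id`, `gene_id`; when given,
#'   source gene ids are annotated too.
#' @return The input tibble with list-columns `source_proteins` (and
#'   `source_genes` if `gene_map` given), integer `n_sources`, and logical
#'   `unmapped`.
#' @export
map_peptides_to_proteins <- function(peptides, proteome, gene_map = NULL) {
  if (length(proteome) == 0) abort("proteome is empty")
  prot_ids <- names(proteome)
  hits <- purrr::map(peptides$sequence, function(s) {
    prot_ids[stringr::str_detect(proteome, stringr::fixed(s))]
  })
  out <- dplyr::mutate(
    tibble::as_tibble(peptides),
    source_proteins = hits,
    n_sources = lengths(hits),
    unmapped = lengths(hits) == 0
  )
  if (!is.null(gene_map)) {
    lookup <- setNames(gene_map$gene_id, gene_map$protein_id)
    out$source_genes <- purrr::map(hits, function(h) unname(lookup[h]))
  }
  attr(out, "n_source_proteins") <- length(unique(unlist(hits)))
  out
}

#' Percentile-rank calibration of motif scores
#'
#' A peptide's percentile rank is its log-odds score placed within a sample
#' of `n_bg` background peptides drawn i.i.d. from the motif's background
#' frequencies: `rank = 100 * (1 + #[background score >= s]) / (n_bg + 1)`,
#' so rank lies in (0, 100] and small ranks mean strong predicted binding.
#' The 2%-rank convention then separates binders from non-binders.
#'
#' @param motif A [motif_model()].
#' @param peptides Character vector of peptides of motif length.
#' @param n_bg Background sample size (>= 100).
#' @param seed Seed for the background draw.
#' @param bg_scores Optional precomputed background score vector; when given,
#'   `n_bg` and `seed` are ignored (used for toy calibrations and tests).
#' @return Numeric vector of percent ranks, one per peptide.
#' @export
calibrate_rank <- function(motif, peptides, n_bg = 50000L, seed = 1L,
                           bg_scores = NULL) {
  stopifnot(inherits(motif, "motif_model"))
  if (is.null(bg_scores)) {
    if (n_bg < 100) abort("n_bg must be at least 100")
    bg_scores <- with_seed(seed, {
      bg_seqs <- random_aa_sequences(rep(motif$length, n_bg), motif$background)
      score_peptides(motif, bg_seqs)
    })
  }
  n <- length(bg_scores)
  sorted <- sort(bg_scores)
  s <- score_peptides(motif, peptides)
  cnt_lt <- findInterval(s, sorted, left.open = TRUE)
  100 * (1 + (n - cnt_lt)) / (n + 1)
}

#' Classify binders from per-allele percentile ranks
#'
#' A peptide is a binder iff its minimum rank over alleles is at or below the
#' threshold (inclusive, following the 2%-rank convention); the preferred
#' allele of a binder is the argmin rank, ties broken towards the
#' lexicographically first allele and recorded.
#'
#' @param ranks Long tibble with columns `peptide_id`, `allele`, `rank`
#'   (percent in (0, 100\]).
#' @param threshold Rank threshold in percent (default 2).
#' @return Tibble with one row per peptide: `peptide_id`, `min_rank`,
#'   `binder`, `preferred_allele` (NA for non-binders), `rank_tie`.
#' @export
classify_binders <- function(ranks, threshold = 2.0) {
  required <- c("peptide_id", "allele", "rank")
  if (!all(required %in% names(ranks))) {
    abort("ranks must have columns peptide_id, allele, rank")
  }
  if (any(is.na(ranks$rank))) {
    bad <- ranks$peptide_id[is.na(ranks$rank)][1]
    abort(sprintf("missing rank for peptide '%s'", bad))
  }
  n_alleles <- length(unique(ranks$allele))
  counts <- dplyr::count(ranks, .data$peptide_id)
  if (any(counts$n != n_alleles)) {
    bad <- counts$peptide_id[counts$n != n_alleles][1]
    abort(sprintf("peptide '%s' lacks a rank for some allele", bad))
  }
  ranks |>
    dplyr::group_by(.data$peptide_id) |>
    dplyr::arrange(.data$rank, .data$allele, .by_group = TRUE) |>
    dplyr::summarise(
      min_rank = .data$rank[1],
      binder = .data$rank[1] <= threshold,
      preferred_allele = ifelse(.data$rank[1] <= threshold, .data$allele[1], NA_character_),
      rank_tie = sum(.data$rank == .data$rank[1]) > 1,
      .groups = "drop"
    )
}

#' Hypergeometric over-representation test against a gene-set collection
#'
#' For each set, tests whether the selected genes overlap the set more than
#' expected under sampling without replacement from the universe:
#' `p = P[overlap >= observed]` from the hypergeometric distribution. Sets
#' are intersected with the universe before testing; p-values are adjusted
#' across sets with Benjamini-Hochberg.
#'
#' @param selected Character vector of selected gene ids (subset of
#'   `universe`).
#' @param universe Character vector of all tested gene ids.
#' @param gene_sets Named list of character vectors (e.g. from [read_gmt()]).
#' @return Tibble with columns `set`, `set_size`, `overlap`, `expected`,
#'   `p_value`, `p_adjust`, sorted by p-value.
#' @export
overrepresentation_test <- function(selected, universe, gene_sets) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("universe is empty")
  selected <- unique(selected)
  if (!all(selected %in% universe)) {
    abort("selected genes must be a subset of the universe")
  }
  n_univ <- length(universe)
  n_sel <- length(selected)
  rows <- purrr::imap(gene_sets, function(set, nm) {
    set <- intersect(unique(set), universe)
    k <- length(intersect(set, selected))
    m <- length(set)
    p <- if (m == 0) 1 else phyper(k - 1, m, n_univ - m, n_sel, lower.tail = FALSE)
    tibble::tibble(
      set = nm, set_size = m, overlap = k,
      expected = n_sel * m / n_univ, p_value = p
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjust <- p.adjust(out$p_value, method = "BH")
  dplyr::arrange(out, .data$p_value)
}
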