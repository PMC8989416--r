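# Pathogen-mimicry scoring: positionally weighted similarity of tumor 9mers
# to windows of pathogen epitopes, emphasising the central, TCR-facing
# residues of the peptide.

#' Load the packaged BLOSUM62 substitution matrix
#'
#' A standard symmetric log-odds amino-acid substitution matrix shipped as a
#' plain-text data file; any 20 x 20 symmetric matrix with the same
#' row/column order as [aa_alphabet()] can be used in its place.
#'
#' @return Numeric 20 x 20 matrix with residue dimnames.
#' @export
blosum62 <- function() {
  path <- system.file("extdata", "blosum62.tsv", package = "peptivax")
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$residue
  storage.mode(m) <- "numeric"
  m[AA_ALPHABET, AA_ALPHABET]
}

#' Positional weight profiles for mimicry scoring
#'
#' `gaussian` (default): weights `exp(-(i - c)^2 / (2 sigma^2))` centred at
#' `c = (L + 1) / 2`, prioritising similarity at the central, TCR-exposed
#' positions. `flat`: equal weights. `anchor_masked`: flat with P2 and the
#' C-terminal anchor down-weighted, since anchors face the MHC groove rather
#' than the TCR.
#'
#' @param length Peptide length (default 9).
#' @param profile Profile name.
#' @param sigma Gaussian width (default 2).
#' @param anchor_weight Weight given to anchor positions under
#'   `anchor_masked` (default 0.2).
#' @return Numeric vector of nonnegative weights.
#' @export
position_weights <- function(length = 9L,
                             profile = c("gaussian", "flat", "anchor_masked"),
                             sigma = 2, anchor_weight = 0.2) {
  profile <- match.arg(profile)
  center <- (length + 1) / 2
  w <- switch(profile,
    gaussian = exp(-((seq_len(length) - center)^2) / (2 * sigma^2)),
    flat = rep(1, length),
    anchor_masked = {
      w <- rep(1, length)
      w[c(2L, length)] <- anchor_weight
      w
    }
  )
  w
}

#' Mimicry scoring configuration
#'
#' @param matrix 20 x 20 symmetric substitution matrix (default
#'   [blosum62()]).
#' @param weights Positional weight vector, or NULL to build one from
#'   `profile`/`sigma` at scan time.
#' @param profile,sigma Passed to [position_weights()] when `weights` is
#'   NULL.
#' @param weighted_score_min Minimum normalised weighted score (default
#'   0.8).
#' @param identity_min Minimum identity fraction (default 0.8).
#' @param affinity_mode Affinity gate: `"strong_lt50nM"` (IC50 < 50 nM, the
#'   default), `"range_50_500nM"` (50-500 nM inclusive), or `"off"`.
#' @return A list of class `mimicry_config`.
#' @export
mimicry_config <- function(matrix = blosum62(), weights = NULL,
                           profile = "gaussian", sigma = 2,
                           weighted_score_min = 0.8, identity_min = 0.8,
                           affinity_mode = c("strong_lt50nM", "range_50_500nM", "off")) {
  affinity_mode <- match.arg(affinity_mode)
  matrix <- as.matrix(matrix)
  if (!isTRUE(all.equal(matrix, t(matrix)))) {
    warn("substitution matrix is not symmetric; weighted similarity will not be symmetric")
  }
  if (!is.null(weights)) {
    if (any(weights < 0) || all(weights == 0)) {
      abort("weights must be nonnegative and not all zero", class = "peptivax_config_error")
    }
  }
  if (weighted_score_min < 0 || weighted_score_min > 1 ||
    identity_min < 0 || identity_min > 1) {
    abort("thresholds must lie in [0, 1]", class = "peptivax_config_error")
  }
  structure(
    list(
      matrix = matrix, weights = weights, profile = profile, sigma = sigma,
      weighted_score_min = weighted_score_min, identity_min = identity_min,
      affinity_mode = affinity_mode
    ),
    class = "mimicry_config"
  )
}

config_weights <- function(config, length) {
  w <- config$weights %||%
    position_weights(length, profile = config$profile, sigma = config$sigma)
  if (length(w) != length) abort("weight profile length does not match peptide length")
  w
}

#' Positionally weighted similarity between two equal-length peptides
#'
#' `raw = sum_i w_i * s(a_i, b_i)` against the self-score
#' `self = sum_i w_i * s(a_i, a_i)`; the score is `max(0, raw / self)`, so a
#' peptide always scores 1 against itself and mismatches at heavily weighted
#' (central) positions cost more than the same mismatch at the periphery.
#'
#' @param pep_a,pep_b Equal-length amino-acid strings (the self-score is
#'   taken on `pep_a`).
#' @param config A [mimicry_config()].
#' @return Score in \[0, 1\].
#' @export
weighted_similarity <- function(pep_a, pep_b, config = mimicry_config()) {
  if (nchar(pep_a) != nchar(pep_b)) abort("peptides must have equal length")
  check_aa_sequences(c(pep_a, pep_b), "peptide")
  a <- match(strsplit(pep_a, "")[[1]], AA_ALPHABET)
  b <- match(strsplit(pep_b, "")[[1]], AA_ALPHABET)
  w <- config_weights(config, length(a))
  s <- config$matrix
  self <- sum(w * s[cbind(a, a)])
  if (self <= 0) abort("nonpositive self-score; check the substitution matrix")
  raw <- sum(w * s[cbind(a, b)])
  max(0, raw / self)
}

#' Fraction of identical positions between two equal-length peptides
#'
#' @param pep_a,pep_b Equal-length amino-acid strings.
#' @return Matches / length, in \[0, 1\].
#' @export
identity_fraction <- function(pep_a, pep_b) {
  if (nchar(pep_a) != nchar(pep_b)) abort("peptides must have equal length")
  a <- strsplit(pep_a, "")[[1]]
  b <- strsplit(pep_b, "")[[1]]
  mean(a == b)
}

#' Scan a pathogen database for the best mimicry hit per tumor peptide
#'
#' Every ungapped equal-length window of every pathogen record is scored
#' with [weighted_similarity()]; per tumor peptide the window with the
#' maximal weighted score is retained (ties broken towards the lowest record
#' id, then the lowest offset). The scan is exhaustive and deterministic.
#'
#' @param tumor_peptides Named character vector of tumor peptides (names =
#'   peptide ids; generated if absent). All must share one length.
#' @param pathogen_db Named character vector of pathogen records (e.g. from
#'   [read_fasta()]); records shorter than the peptide length are skipped.
#' @param config A [mimicry_config()].
#' @param all_hits If TRUE, also return every window's scores.
#' @return Tibble of best hits: `peptide_id`, `tumor_peptide`, `record_id`,
#'   `offset` (0-based), `pathogen_window`, `weighted_score`,
#'   `identity_fraction`. With `all_hits = TRUE`, a list with `best` and
#'   `hits`.
#' @export
scan_database <- function(tumor_peptides, pathogen_db,
                          config = mimicry_config(), all_hits = FALSE) {
  if (is.null(names(tumor_peptides))) {
    names(tumor_peptides) <- sprintf("pep_%05d", seq_along(tumor_peptides))
  }
  empty <- tibble::tibble(
    peptide_id = character(), tumor_peptide = character(),
    record_id = character(), offset = integer(), pathogen_window = character(),
    weighted_score = numeric(), identity_fraction = numeric()
  )
  if (length(pathogen_db) == 0) {
    warn("empty pathogen database; no hits")
    return(if (all_hits) list(best = empty, hits = empty) else empty)
  }
  check_aa_sequences(tumor_peptides, "tumor peptide")
  check_aa_sequences(pathogen_db, "pathogen record")
  L <- unique(nchar(tumor_peptides))
  if (length(L) != 1) abort("tumor peptides must share one length")
  usable <- pathogen_db[nchar(pathogen_db) >= L]
  if (length(usable) == 0) {
    warn("no pathogen record is at least peptide length; no hits")
    return(if (all_hits) list(best = empty, hits = empty) else empty)
  }
  # enumerate all windows once, in (record id, offset) order
  windows <- purrr::imap(usable, function(seqc, id) {
    offs <- 0:(nchar(seqc) - L)
    tibble::tibble(
      record_id = id, offset = offs,
      pathogen_window = substring(seqc, offs + 1, offs + L)
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$record_id, .data$offset)

  w <- config_weights(config, L)
  s <- config$matrix
  win_idx <- seq_to_index_matrix(windows$pathogen_window)
  n_win <- nrow(win_idx)

  score_one <- function(pep) {
    a <- match(strsplit(pep, "")[[1]], AA_ALPHABET)
    self <- sum(w * s[cbind(a, a)])
    if (self <= 0) abort("nonpositive self-score; check the substitution matrix")
    raw <- numeric(n_win)
    ident <- numeric(n_win)
    for (p in seq_len(L)) {
      raw <- raw + w[p] * s[a[p] + (win_idx[, p] - 1) * 20]
      ident <- ident + (win_idx[, p] == a[p])
    }
    list(score = pmax(0, raw / self), identity = ident / L)
  }

  results <- purrr::imap(tumor_peptides, function(pep, id) {
    sc <- score_one(pep)
    best_i <- which.max(sc$score) # first max = lowest record id, then offset
    best <- tibble::tibble(
      peptide_id = id, tumor_peptide = pep,
      record_id = windows$record_id[best_i],
      offset = windows$offset[best_i],
      pathogen_window = windows$pathogen_window[best_i],
      weighted_score = sc$score[best_i],
      identity_fraction = sc$identity[best_i]
    )
    if (all_hits) {
      hits <- dplyr::mutate(windows,
        peptide_id = id, tumor_peptide = pep,
        weighted_score = sc$score, identity_fraction = sc$identity
      )
      list(best = best, hits = hits)
    } else {
      list(best = best)
    }
  })
  best <- dplyr::bind_rows(purrr::map(results, "best"))
  if (all_hits) {
    list(best = best, hits = dplyr::bind_rows(purrr::map(results, "hits")))
  } else {
    best
  }
}

#' Filter mimicry hits on score, identity and binding affinity
#'
#' A hit is selected iff `weighted_score >= weighted_score_min`,
#' `identity_fraction >= identity_min`, and the affinity gate is satisfied:
#' IC50 < 50 nM under `strong_lt50nM`, 50 <= IC50 <= 500 nM under
#' `range_50_500nM`, ignored under `off`.
#'
#' @param hits Tibble of hits (as from [scan_database()]).
#' @param ic50 Optional named numeric vector of IC50 values in nM keyed by
#'   `peptide_id`; required unless the affinity gate is off.
#' @param config A [mimicry_config()].
#' @return `hits` with added columns `pass_score`, `pass_identity`,
#'   `pass_affinity`, `selected`.
#' @export
filter_mimics <- function(hits, ic50 = NULL, config = mimicry_config()) {
  out <- dplyr::mutate(
    tibble::as_tibble(hits),
    pass_score = .data$weighted_score >= config$weighted_score_min,
    pass_identity = .data$identity_fraction >= config$identity_min
  )
  if (config$affinity_mode == "off") {
    out$pass_affinity <- TRUE
  } else {
    if (is.null(ic50)) abort("ic50 values required when the affinity gate is active")
    vals <- ic50[out$peptide_id]
    if (any(is.na(vals))) {
      abort(sprintf(
        "missing IC50 for peptide '%s'", out$peptide_id[is.na(vals)][1]
      ))
    }
    out$ic50_nM <- unname(vals)
    out$pass_affinity <- switch(config$affinity_mode,
      strong_lt50nM = out$ic50_nM < 50,
      range_50_500nM = out$ic50_nM >= 50 & out$ic50_nM <= 500
    )
  }
  out$selected <- out$pass_score & out$pass_identity & out$pass_affinity
  out
}
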