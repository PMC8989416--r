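#' Construct a position frequency motif model
#'
#' A motif model holds a 20 x L matrix of per-position residue probabilities,
#' a 20-vector of background residue frequencies, and the pseudocount used
#' when the model was estimated. Rows follow [aa_alphabet()] order.
#'
#' @param frequencies Numeric 20 x L matrix; each column must sum to 1
#'   (tolerance 1e-9).
#' @param background Numeric 20-vector of background frequencies summing to 1.
#' @param pseudocount Nonnegative pseudocount scale recorded for provenance.
#' @return An object of class `motif_model`.
#' @export
motif_model <- function(frequencies,
                        background = rep(1 / 20, 20),
                        pseudocount = 0) {
  frequencies <- as.matrix(frequencies)
  background <- as.numeric(background)
  if (nrow(frequencies) != 20) abort("frequency matrix must have 20 rows")
  if (length(background) != 20) abort("background must have 20 entries")
  if (any(frequencies < 0) || any(background < 0)) abort("negative frequency")
  col_sums <- colSums(frequencies)
  if (any(abs(col_sums - 1) > 1e-9)) {
    abort(sprintf(
      "motif column %d sums to %.12f, not 1", which(abs(col_sums - 1) > 1e-9)[1],
      col_sums[which(abs(col_sums - 1) > 1e-9)[1]]
    ))
  }
  if (abs(sum(background) - 1) > 1e-9) abort("background does not sum to 1")
  if (pseudocount < 0) abort("pseudocount must be nonnegative")
  rownames(frequencies) <- AA_ALPHABET
  colnames(frequencies) <- paste0("P", seq_len(ncol(frequencies)))
  names(background) <- AA_ALPHABET
  structure(
    list(
      frequencies = frequencies,
      background = background,
      pseudocount = pseudocount,
      length = ncol(frequencies)
    ),
    class = "motif_model"
  )
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf(
    "<motif_model> length %d, pseudocount %g, KLD %.4f bits\n",
    x$length, x$pseudocount, cluster_kld(x)
  ))
  invisible(x)
}

#' Estimate a motif model from aligned peptides
#'
#' Per-position frequencies are pseudocount-smoothed counts:
#' `f[aa, pos] = (count[aa, pos] + beta * background[aa]) / (n + beta)`.
#'
#' @param peptides Character vector of equal-length amino-acid sequences, or an
#'   integer residue-index matrix (rows = peptides).
#' @param background Background residue frequencies (20-vector, sums to 1).
#' @param pseudocount Smoothing scale `beta` (default 50), distributed over
#'   residues proportionally to the background.
#' @return A [motif_model()].
#' @export
build_motif <- function(peptides,
                        background = rep(1 / 20, 20),
                        pseudocount = 50) {
  idx <- if (is.matrix(peptides)) peptides else {
    check_aa_sequences(peptides, "peptide")
    seq_to_index_matrix(peptides)
  }
  n <- nrow(idx)
  len <- ncol(idx)
  background <- as.numeric(background)
  counts <- matrix(0, nrow = 20, ncol = len)
  for (p in seq_len(len)) {
    counts[, p] <- tabulate(idx[, p], nbins = 20)
  }
  freq <- sweep(counts + pseudocount * background, 2, n + pseudocount, "/")
  motif_model(freq, background, pseudocount)
}

#' Log-odds score of peptides under a motif model (bits)
#'
#' The score of a peptide is the sum over positions of
#' `log2(f[aa, pos] / background[aa])`, i.e. a standard position weight
#' matrix log-odds in bits. Peptide length must equal the motif length.
#'
#' @param motif A [motif_model()].
#' @param peptides Character vector of peptides (all of motif length) or an
#'   integer residue-index matrix.
#' @return Numeric vector of scores in bits.
#' @export
score_peptides <- function(motif, peptides) {
  stopifnot(inherits(motif, "motif_model"))
  idx <- if (is.matrix(peptides)) peptides else {
    check_aa_sequences(peptides, "peptide")
    lens <- nchar(peptides)
    if (any(lens != motif$length)) {
      abort(sprintf(
        "peptide %d has length %d, motif expects %d",
        which(lens != motif$length)[1], lens[lens != motif$length][1], motif$length
      ))
    }
    seq_to_index_matrix(peptides)
  }
  if (ncol(idx) != motif$length) abort("peptide length does not match motif length")
  lod <- log2(motif$frequencies / motif$background) # 20 x L
  pos <- rep(seq_len(ncol(idx)), each = nrow(idx))
  scores <- lod[cbind(as.vector(idx), pos)]
  rowSums(matrix(scores, nrow = nrow(idx)))
}

#' Kullback-Leibler divergence of a motif from its background (bits)
#'
#' `KLD = sum over positions and residues of f * log2(f / background)`,
#' the information content of the motif against the background; zero iff the
#' motif equals the background at every position (Gibbs' inequality).
#'
#' @param motif A [motif_model()].
#' @return Nonnegative scalar in bits.
#' @export
cluster_kld <- function(motif) {
  stopifnot(inherits(motif, "motif_model"))
  f <- motif$frequencies
  bg <- motif$background
  if (any(f > 0 & bg == 0)) {
    abort("nonzero motif frequency over a zero background frequency")
  }
  terms <- ifelse(f > 0, f * log2(f / bg), 0)
  sum(terms)
}

#' Export a motif frequency matrix as a tidy tibble
#'
#' One row per (position, residue) with the smoothed frequency; suitable for
#' writing to TSV for external logo rendering.
#'
#' @param motif A [motif_model()].
#' @return Tibble with columns `position`, `residue`, `frequency`.
#' @export
motif_frequencies <- function(motif) {
  stopifnot(inherits(motif, "motif_model"))
  tibble::tibble(
    position = rep(seq_len(motif$length), each = 20),
    residue = rep(AA_ALPHABET, motif$length),
    frequency = as.vector(motif$frequencies)
  )
}
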