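# Internal helpers shared across modules.

# Validate that sequences use only the 20 standard residues (uppercase).
# Returns invisibly; aborts naming the first offending element.
check_aa_sequences <- function(sequences, what = "sequence") {
  if (any(is.na(sequences) | !nzchar(sequences))) {
    bad <- which(is.na(sequences) | !nzchar(sequences))[1]
    abort(sprintf("%s %d is empty", what, bad), class = "peptivax_format_error")
  }
  ok <- grepl(sprintf("^[%s]+$", paste(AA_ALPHABET, collapse = "")), sequences)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    abort(
      sprintf(
        "%s %d ('%s') contains characters outside the 20-letter amino-acid alphabet",
        what, bad, sequences[bad]
      ),
      class = "peptivax_alphabet_error"
    )
  }
  invisible(sequences)
}

# Map sequences to integer residue indices (1..20); rows = sequences.
# All sequences must share one length.
seq_to_index_matrix <- function(sequences) {
  len <- unique(nchar(sequences))
  if (length(len) != 1) {
    abort("all sequences must have the same length")
  }
  mat <- matrix(
    match(unlist(strsplit(sequences, "", fixed = TRUE)), AA_ALPHABET),
    ncol = len, byrow = TRUE
  )
  if (anyNA(mat)) abort("sequence contains non-standard residue")
  mat
}

# Run code under a local, restored RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Draw n random amino-acid sequences of lengths `lens` from residue
# probabilities `probs` (named or ordered like AA_ALPHABET). Caller seeds.
random_aa_sequences <- function(lens, probs = rep(1 / 20, 20)) {
  probs <- as.numeric(probs)
  stopifnot(length(probs) == 20, all(probs >= 0), sum(probs) > 0)
  total <- sum(lens)
  residues <- sample(AA_ALPHABET, total, replace = TRUE, prob = probs)
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  vapply(
    seq_along(lens),
    function(i) paste(residues[starts[i]:ends[i]], collapse = ""),
    character(1)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
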