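# Shared fixture builders: everything is generated in code at test time.

# n 9mers with forced anchors at P2/P9 over otherwise uniform residues.
make_motif_peptides <- function(n, p2, p9, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    x <- sample(aa_alphabet(), 9, replace = TRUE)
    x[2] <- sample(rep(p2, 2), 1)
    x[9] <- sample(rep(p9, 2), 1)
    paste(x, collapse = "")
  }, character(1))
}

random_peptides <- function(n, len = 9, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(aa_alphabet(), len, replace = TRUE), collapse = "")
  }, character(1))
}

write_tmp_fasta <- function(records, dir = tempdir()) {
  path <- tempfile("fx_", tmpdir = dir, fileext = ".fasta")
  lines <- unlist(purrr::imap(records, function(s, id) c(paste0(">", id), s)))
  writeLines(lines, path)
  path
}

write_tmp_tsv <- function(df, dir = tempdir()) {
  path <- tempfile("fx_", tmpdir = dir, fileext = ".tsv")
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# Independent hypergeometric upper-tail oracle by direct combinatorial
# enumeration over overlap values (no phyper).
hyper_upper_oracle <- function(overlap, set_size, universe_size, n_selected) {
  total <- choose(universe_size, n_selected)
  js <- overlap:min(set_size, n_selected)
  sum(vapply(js, function(j) {
    choose(set_size, j) * choose(universe_size - set_size, n_selected - j)
  }, numeric(1))) / total
}
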