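#' Read a FASTA file into a named character vector
#'
#' Parsing is delegated to [Biostrings::readAAStringSet()]; on top of that the
#' reader enforces the contracts the downstream stages rely on: record ids are
#' the first whitespace-delimited header token and must be unique, sequences
#' are uppercased, and gap characters or residues outside the 20-letter
#' amino-acid alphabet are rejected rather than silently recoded.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector mapping record id to uppercase sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file '%s' does not exist", path))
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      abort(
        sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)),
        class = "peptivax_format_error"
      )
    }
  )
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    abort(
      sprintf("malformed FASTA header (record %d has an empty id)", which(!nzchar(ids))[1]),
      class = "peptivax_format_error"
    )
  }
  if (anyDuplicated(ids)) {
    abort(
      sprintf("duplicate FASTA id '%s' in '%s'", ids[anyDuplicated(ids)], path),
      class = "peptivax_format_error"
    )
  }
  empty <- which(!nzchar(seqs))
  if (length(empty) > 0) {
    # locate the offending header line for the diagnostic
    headers <- grep("^>", readLines(path))
    abort(
      sprintf(
        "empty sequence for record '%s' (header at line %d)",
        ids[empty[1]], headers[empty[1]]
      ),
      class = "peptivax_format_error"
    )
  }
  if (any(grepl("[-.*]", seqs))) {
    abort(
      sprintf("record '%s' contains gap characters", ids[grepl("[-.*]", seqs)][1]),
      class = "peptivax_format_error"
    )
  }
  check_aa_sequences(seqs, what = "FASTA record")
  setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector of amino-acid sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  stopifnot(!is.null(names(sequences)), all(nzchar(names(sequences))))
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a peptide table (TSV)
#'
#' The canonical tabular dialect is tab-separated with a header row. The
#' `sequence` column is required; a missing `peptide_id` column is synthesised
#' as `pep_<row>`. Any column whose name starts with `rank_` is treated as a
#' per-allele percentile rank (percent, in \[0, 100\]). Validation rejects,
#' with a row number, any sequence containing residues outside the standard
#' 20-letter alphabet (including X/B/Z/U).
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `peptide_id`, `sequence`, `length`, plus any
#'   `rank_*` columns.
#' @export
read_peptide_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sequence" %in% names(tab)) {
    abort("peptide table must have a 'sequence' column", class = "peptivax_format_error")
  }
  tab$sequence <- toupper(as.character(tab$sequence))
  ok <- grepl(sprintf("^[%s]+$", paste(AA_ALPHABET, collapse = "")), tab$sequence)
  if (!all(ok)) {
    abort(
      sprintf(
        "row %d: sequence '%s' contains non-amino-acid characters",
        which(!ok)[1], tab$sequence[which(!ok)[1]]
      ),
      class = "peptivax_alphabet_error"
    )
  }
  if (!"peptide_id" %in% names(tab)) {
    tab$peptide_id <- sprintf("pep_%04d", seq_len(nrow(tab)))
  }
  tab$peptide_id <- as.character(tab$peptide_id)
  if (anyDuplicated(tab$peptide_id)) {
    abort(
      sprintf("duplicate peptide_id '%s'", tab$peptide_id[anyDuplicated(tab$peptide_id)]),
      class = "peptivax_format_error"
    )
  }
  rank_cols <- grep("^rank_", names(tab), value = TRUE)
  for (col in rank_cols) {
    v <- tab[[col]]
    if (!is.numeric(v)) abort(sprintf("rank column '%s' is not numeric", col))
    if (any(!is.na(v) & (v < 0 | v > 100))) {
      abort(sprintf("rank column '%s' has values outside [0, 100]", col))
    }
  }
  tab$length <- nchar(tab$sequence)
  dplyr::relocate(tibble::as_tibble(tab), "peptide_id", "sequence", "length")
}

#' Write a peptide table to TSV
#'
#' @param peptides Tibble with at least `peptide_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(peptides, path) {
  readr::write_tsv(peptides, path, progress = FALSE)
  invisible(path)
}

#' Read a differential-expression result table (TSV)
#'
#' Expects columns `gene_id`, `log2fc`, `padj`. Adjusted p-values outside
#' \[0, 1\] and duplicated gene ids are errors: the reader never clips or
#' recodes.
#'
#' @param path Path to a TSV file.
#' @return Tibble with columns `gene_id`, `log2fc`, `padj`.
#' @export
read_de_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("gene_id", "log2fc", "padj")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(
      sprintf("DE table missing column(s): %s", paste(missing, collapse = ", ")),
      class = "peptivax_format_error"
    )
  }
  tab$gene_id <- as.character(tab$gene_id)
  if (!is.numeric(tab$log2fc) || !is.numeric(tab$padj)) {
    abort("log2fc and padj must be numeric", class = "peptivax_format_error")
  }
  if (any(tab$padj < 0 | tab$padj > 1, na.rm = TRUE)) {
    bad <- which(tab$padj < 0 | tab$padj > 1)[1]
    abort(
      sprintf("row %d: padj = %g is outside [0, 1]", bad, tab$padj[bad]),
      class = "peptivax_format_error"
    )
  }
  if (anyDuplicated(tab$gene_id)) {
    abort(
      sprintf("duplicated gene_id '%s'", tab$gene_id[anyDuplicated(tab$gene_id)]),
      class = "peptivax_format_error"
    )
  }
  tibble::as_tibble(tab[, required])
}

#' Write a differential-expression table to TSV
#'
#' @param de Tibble with columns `gene_id`, `log2fc`, `padj`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  readr::write_tsv(de, path, progress = FALSE)
  invisible(path)
}

#' Read an SPR sensorgram (CSV)
#'
#' Expects columns `time_s` (seconds, strictly increasing) and `response_deg`
#' (resonance-angle shift in degrees). At least two points are required.
#'
#' @param path Path to a CSV file.
#' @return Tibble with columns `time_s`, `response_deg`.
#' @export
read_sensorgram <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("time_s", "response_deg")
  if (!all(required %in% names(tab))) {
    abort("sensorgram must have columns time_s and response_deg",
      class = "peptivax_format_error"
    )
  }
  tab <- tibble::as_tibble(tab[, required])
  if (nrow(tab) < 2) {
    abort("sensorgram needs at least 2 points", class = "peptivax_format_error")
  }
  if (any(diff(tab$time_s) <= 0)) {
    abort("sensorgram times must be strictly increasing", class = "peptivax_format_error")
  }
  tab
}

#' Write an SPR sensorgram to CSV
#'
#' @param sensorgram Tibble with columns `time_s`, `response_deg`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensorgram <- function(sensorgram, path) {
  readr::write_csv(sensorgram, path, progress = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then member gene ids.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene ids; names are set names,
#'   descriptions kept as the `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) {
    abort(
      sprintf("GMT line %d has fewer than 3 fields", which(lengths(fields) < 3)[1]),
      class = "peptivax_format_error"
    )
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) {
    abort("duplicate gene-set names in GMT", class = "peptivax_format_error")
  }
  attr(sets, "description") <- setNames(
    vapply(fields, `[[`, character(1), 2), names(sets)
  )
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(!is.null(names(sets)))
  desc <- descriptions %||% attr(sets, "description") %||%
    setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(
    names(sets),
    function(nm) paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"),
    character(1)
  )
  writeLines(lines, path)
  invisible(path)
}
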