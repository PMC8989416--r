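#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Gibbs cluster solution into one row per peptide
#'
#' @param x A `cluster_solution` from [gibbs_cluster()].
#' @param ... Unused.
#' @return Tibble with columns `peptide`, `cluster`.
#' @export
tidy.cluster_solution <- function(x, ...) {
  tibble::tibble(peptide = x$peptides, cluster = x$assignment)
}

#' One-row summary of a Gibbs cluster solution
#'
#' @param x A `cluster_solution`.
#' @param ... Unused.
#' @return Tibble with `k`, `n`, `fitness`, `n_empty_clusters`, `sweeps`,
#'   `seed`.
#' @export
glance.cluster_solution <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n = length(x$peptides),
    fitness = x$fitness,
    n_empty_clusters = sum(x$cluster_sizes == 0),
    sweeps = x$sweeps,
    seed = x$seed
  )
}

#' Tidy extracted SPR phase levels
#'
#' @param x A `phase_levels` from [extract_phase_levels()].
#' @param ... Unused.
#' @return Tibble with one row per phase: `phase`, `response_deg`,
#'   `window_end_s`.
#' @export
tidy.phase_levels <- function(x, ...) {
  tibble::tibble(
    phase = c("equilibrium", "dissociation"),
    response_deg = c(x$r_max, x$r_min),
    window_end_s = c(x$association_end, x$dissociation_end)
  )
}
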