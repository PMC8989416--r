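# ELISpot immunogenicity gate: spot-count summaries per group and the
# absolute/fold inclusion rule.

ELISPOT_CONTROLS <- c("adjuvant_only", "saline")

#' Summarize ELISpot spot counts per group
#'
#' @param counts Tibble with columns `group`, `replicate`, `spots`
#'   (nonnegative counts per 1e6 splenocytes).
#' @return Tibble per group: `group`, `mean`, `sd` (sample SD, 0 when n =
#'   1), `n`, `is_control`.
#' @export
elispot_summarize <- function(counts) {
  required <- c("group", "replicate", "spots")
  if (!all(required %in% names(counts))) {
    abort("counts must have columns group, replicate, spots")
  }
  if (any(counts$spots < 0)) abort("spot counts must be nonnegative")
  counts |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      mean = mean(.data$spots),
      sd = ifelse(dplyr::n() == 1, 0, sd(.data$spots)),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(is_control = .data$group %in% ELISPOT_CONTROLS)
}

#' Immunogenicity gate on ELISpot group means
#'
#' A peptide is selected iff its mean spot count reaches
#' `max(abs_threshold, fold_threshold * control_level)`, where
#' `control_level` is the maximum of the control-group means (conservative
#' aggregation over multiple controls). The comparison is inclusive. Raw
#' means are gated; optional control subtraction is off by default.
#'
#' @param summary Per-group summary from [elispot_summarize()], or a raw
#'   counts tibble (summarised automatically).
#' @param abs_threshold Absolute spot-count threshold (default 100).
#' @param fold_threshold Fold-over-control threshold (default 10).
#' @param subtract_control If TRUE, the control level is subtracted from
#'   peptide means before gating (off by default: the inclusion rule is an
#'   absolute-count rule).
#' @return Tibble per peptide group: `group`, `mean`, `threshold`,
#'   `selected`, and `rationale` stating which bound was binding. The
#'   control level is attached as attribute `control_level`.
#' @export
elispot_gate <- function(summary, abs_threshold = 100, fold_threshold = 10,
                         subtract_control = FALSE) {
  if (!"mean" %in% names(summary)) summary <- elispot_summarize(summary)
  controls <- summary[summary$group %in% ELISPOT_CONTROLS, ]
  if (nrow(controls) == 0) abort("no control group (adjuvant_only/saline) present")
  control_level <- max(controls$mean)
  peptides <- summary[!summary$group %in% ELISPOT_CONTROLS, ]
  threshold <- max(abs_threshold, fold_threshold * control_level)
  binding <- if (abs_threshold >= fold_threshold * control_level) {
    sprintf("absolute threshold %g", abs_threshold)
  } else {
    sprintf("%g-fold over control level %g", fold_threshold, control_level)
  }
  effective_mean <- if (subtract_control) peptides$mean - control_level else peptides$mean
  out <- tibble::tibble(
    group = peptides$group,
    mean = peptides$mean,
    threshold = threshold,
    selected = effective_mean >= threshold,
    rationale = binding
  )
  attr(out, "control_level") <- control_level
  out
}
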