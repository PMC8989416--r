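# SPR-based quantitation of peptides per viral particle: phase-level
# extraction from sensorgrams and the geometric formula chain from sensor
# responses to a peptides-per-virion estimate.

#' SPR detection geometry and conversion constants
#'
#' Defaults are the constants of the measurement: detection spot radius
#' 0.5 mm, virus diameter 100 nm, full-virus-layer response 1.4 degrees,
#' mass conversion 660 ng/cm^2 per degree of response, and the Avogadro
#' constant. Internally all areas are held in cm^2 and masses in g.
#'
#' @param spot_radius_mm Detection spot radius in mm.
#' @param virus_diameter_nm Virus diameter in nm.
#' @param full_layer_response_deg SPR response of a sensor fully covered
#'   with viruses, in degrees.
#' @param mass_conversion_ng_cm2_per_deg Adsorbed mass per area per degree
#'   of response. The source states the 660 ng/cm^2 conversion without an
#'   explicit response unit; the per-degree reading is the only
#'   dimensionally coherent one and is the declared convention here.
#' @param avogadro Avogadro constant, per mol.
#' @return A list of class `spr_geometry` with derived areas
#'   `detection_area_cm2` and `virus_footprint_cm2`.
#' @export
spr_geometry <- function(spot_radius_mm = 0.5,
                         virus_diameter_nm = 100,
                         full_layer_response_deg = 1.4,
                         mass_conversion_ng_cm2_per_deg = 660,
                         avogadro = 6.02214076e23) {
  vals <- c(
    spot_radius_mm, virus_diameter_nm, full_layer_response_deg,
    mass_conversion_ng_cm2_per_deg, avogadro
  )
  if (any(vals <= 0)) abort("all geometry constants must be positive")
  r_cm <- spot_radius_mm / 10
  virus_r_cm <- virus_diameter_nm / 2 * 1e-7
  structure(
    list(
      spot_radius_mm = spot_radius_mm,
      virus_diameter_nm = virus_diameter_nm,
      full_layer_response_deg = full_layer_response_deg,
      mass_conversion_ng_cm2_per_deg = mass_conversion_ng_cm2_per_deg,
      avogadro = avogadro,
      detection_area_cm2 = pi * r_cm^2,
      virus_footprint_cm2 = pi * virus_r_cm^2
    ),
    class = "spr_geometry"
  )
}

#' Extract equilibrium and dissociation plateau levels from a sensorgram
#'
#' The equilibrium level (MAX) is the mean response over the last `window`
#' seconds of the association phase; the dissociation level (MIN) is the
#' mean over the last `window` seconds before `dissociation_end`. Window
#' means rather than single extrema are used for noise robustness; negative
#' means are floored at 0 with a warning.
#'
#' @param sensorgram Tibble with `time_s`, `response_deg` (e.g. from
#'   [read_sensorgram()] or [gen_sensorgram()]).
#' @param association_end,dissociation_end Phase boundaries in seconds;
#'   taken from the sensorgram's attributes when NULL.
#' @param window Averaging window length in seconds (default 10).
#' @return A list of class `phase_levels` with `r_max`, `r_min` (degrees)
#'   and the window metadata.
#' @export
extract_phase_levels <- function(sensorgram, association_end = NULL,
                                 dissociation_end = NULL, window = 10) {
  association_end <- association_end %||% attr(sensorgram, "association_end")
  dissociation_end <- dissociation_end %||% attr(sensorgram, "dissociation_end")
  if (is.null(association_end) || is.null(dissociation_end)) {
    abort("association_end and dissociation_end must be given or attached as attributes")
  }
  t <- sensorgram$time_s
  y <- sensorgram$response_deg
  if (window <= 0) abort("window must be positive")
  if (association_end > max(t) || dissociation_end > max(t) + 1e-9) {
    abort("phase boundaries lie outside the sensorgram time range")
  }
  level <- function(end) {
    in_win <- t >= end - window & t <= end
    if (!any(in_win)) abort("empty averaging window")
    m <- mean(y[in_win])
    if (m < 0) {
      warn(sprintf("negative window mean %.4g floored at 0", m))
      m <- 0
    }
    m
  }
  r_max <- level(association_end)
  r_min <- level(dissociation_end)
  structure(
    list(
      r_max = r_max, r_min = r_min,
      association_end = association_end,
      dissociation_end = dissociation_end,
      window = window
    ),
    class = "phase_levels"
  )
}

#' @export
print.phase_levels <- function(x, ...) {
  cat(sprintf(
    "<phase_levels> MAX (equilibrium) %.4f deg, MIN (dissociation) %.4f deg (window %gs)\n",
    x$r_max, x$r_min, x$window
  ))
  invisible(x)
}

#' Virus coverage and count in the detection area
#'
#' Coverage is the measured virus-phase response over the full-layer
#' response: `C = R_virus / full_layer`. The number of virions is the
#' covered area over one virus footprint:
#' `N_V = (A_S * C) / A_V`. Coverage above 1 is reported with a warning,
#' never clipped.
#'
#' @param r_virus Virus-phase SPR response in degrees (>= 0).
#' @param geometry An [spr_geometry()].
#' @return List with `coverage` (fraction) and `n_virus` (count).
#' @export
virus_surface_count <- function(r_virus, geometry = spr_geometry()) {
  if (any(r_virus < 0)) abort("r_virus must be nonnegative")
  coverage <- r_virus / geometry$full_layer_response_deg
  if (any(coverage > 1)) {
    warn(sprintf("virus coverage %.3g exceeds 100%%; reported unclipped", max(coverage)))
  }
  n_virus <- geometry$detection_area_cm2 * coverage / geometry$virus_footprint_cm2
  list(coverage = coverage, n_virus = n_virus)
}

#' Average (or monoisotopic) mass of a peptide in Da
#'
#' Sum of standard residue masses plus one water (18.0153 Da average,
#' 18.010565 Da monoisotopic).
#'
#' @param sequence Amino-acid string.
#' @param monoisotopic If TRUE use monoisotopic masses (default FALSE:
#'   average masses, matching the bulk mass-per-area context of SPR).
#' @return Mass in Da.
#' @export
peptide_average_mass <- function(sequence, monoisotopic = FALSE) {
  check_aa_sequences(sequence, "peptide")
  chars <- strsplit(sequence, "")[[1]]
  masses <- if (monoisotopic) AA_MASS_MONO else AA_MASS_AVERAGE
  water <- if (monoisotopic) MASS_WATER_MONO else MASS_WATER_AVERAGE
  sum(masses[chars]) + water
}

#' Peptides adsorbed per viral particle from SPR responses
#'
#' The geometric chain: peptide mass per area
#' `m/A = R_peptide * 660 ng/cm^2 per degree`; mass in the detection area
#' `m_P = (m/A) * A_S`; peptide count `N_P = (m_P / M_P) * N_A`; virion
#' count `N_V` from [virus_surface_count()]; result `N_P / N_V`. Computed
#' separately for the equilibrium (MAX) and dissociation (MIN) responses
#' when a [extract_phase_levels()] object is supplied.
#'
#' @param r_peptide Peptide-phase SPR response in degrees, or a
#'   `phase_levels` object (then both phases are evaluated).
#' @param r_virus Virus-phase SPR response in degrees (> 0).
#' @param m_p_da Peptide molecular weight in Da.
#' @param geometry An [spr_geometry()].
#' @return For scalar `r_peptide`: a list with `n_peptides`, `n_virus`,
#'   `coverage`, `peptides_per_virion`. For a `phase_levels` input: a tibble
#'   with one row per phase.
#' @export
peptides_per_virion <- function(r_peptide, r_virus, m_p_da,
                                geometry = spr_geometry()) {
  if (m_p_da <= 0) abort("peptide molecular weight must be positive")
  if (r_virus <= 0) abort("r_virus must be positive: no virions on the sensor")
  if (inherits(r_peptide, "phase_levels")) {
    phases <- tibble::tibble(
      phase = c("equilibrium", "dissociation"),
      r_peptide = c(r_peptide$r_max, r_peptide$r_min)
    )
    res <- purrr::map(
      phases$r_peptide, peptides_per_virion,
      r_virus = r_virus, m_p_da = m_p_da, geometry = geometry
    )
    return(dplyr::mutate(
      phases,
      peptides_per_virion = vapply(res, `[[`, numeric(1), "peptides_per_virion"),
      n_peptides = vapply(res, `[[`, numeric(1), "n_peptides"),
      n_virus = vapply(res, `[[`, numeric(1), "n_virus")
    ))
  }
  if (r_peptide < 0) abort("r_peptide must be nonnegative")
  vir <- virus_surface_count(r_virus, geometry)
  mass_per_area_g_cm2 <- r_peptide * geometry$mass_conversion_ng_cm2_per_deg * 1e-9
  mass_g <- mass_per_area_g_cm2 * geometry$detection_area_cm2
  n_peptides <- mass_g / m_p_da * geometry$avogadro
  list(
    n_peptides = n_peptides,
    n_virus = vir$n_virus,
    coverage = vir$coverage,
    peptides_per_virion = n_peptides / vir$n_virus
  )
}
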