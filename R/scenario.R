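#' DOC end-member mixing scenario
#'
#' Defines the fractional contribution of the three DOC end members
#' (M-DOC, C-DOC, FA) through geologic time as a simplex-valued function
#' of age. Available scenarios:
#'
#' * `"M_only"`, `"C_only"`, `"FA_only"`: a single end member at all ages
#'   (solution-range bracketing).
#' * `"rise_of_algae"`: prokaryote-derived C-DOC before `step_age`
#'   (default 780 Ma), eukaryote-derived M-DOC after, optionally with a
#'   linear ramp of width `ramp_width` centred on the step.
#' * `"proterozoic_active_eukaryotes"`: an even M-DOC/C-DOC mixture
#'   (`proterozoic_m_fraction` of M-DOC, default 0.5) before `step_age`
#'   (default 541 Ma), pure M-DOC after.
#' * `"unconstrained"`: fractions are free and must be found per sample by
#'   [optimize_scenario_free()]; this scenario cannot be evaluated
#'   directly.
#'
#' Fulvic acid (terrestrial humics) defaults to zero in the marine mixing
#' scenarios.
#'
#' @param name Scenario name.
#' @param step_age Transition age (Ma) for the stepped scenarios.
#' @param ramp_width Width (Ma) of an optional linear ramp across the
#'   step; 0 gives a sharp step.
#' @param proterozoic_m_fraction M-DOC fraction before the step in the
#'   Proterozoic-active-eukaryotes scenario.
#' @return An object of class `feoc_scenario`.
#' @export
scenario <- function(name = c("rise_of_algae",
                              "proterozoic_active_eukaryotes",
                              "M_only", "C_only", "FA_only",
                              "unconstrained"),
                     step_age = NULL, ramp_width = 0,
                     proterozoic_m_fraction = 0.5) {
  name <- match.arg(name)
  if (is.null(step_age)) {
    step_age <- switch(name, rise_of_algae = 780,
                       proterozoic_active_eukaryotes = 541, NA_real_)
  }
  .assert(ramp_width >= 0, "ramp_width must be non-negative",
          "feoc_domain_error")
  .assert(proterozoic_m_fraction >= 0 && proterozoic_m_fraction <= 1,
          "proterozoic_m_fraction must lie in [0, 1]", "feoc_domain_error")
  structure(list(name = name, step_age = step_age, ramp_width = ramp_width,
                 proterozoic_m_fraction = proterozoic_m_fraction),
            class = "feoc_scenario")
}

#' End-member fractions at a given age
#'
#' @param scn A [scenario()].
#' @param age Age in Ma, within 0-1650.
#' @return Named numeric vector `(M-DOC, C-DOC, FA)` on the simplex.
#' @export
scenario_fractions <- function(scn, age) {
  .assert(inherits(scn, "feoc_scenario"), "scn must be a scenario()",
          "feoc_domain_error")
  .assert(length(age) == 1 && is.finite(age) && age >= 0 && age <= 1650,
          "age must lie within 0-1650 Ma", "feoc_domain_error")
  unit <- function(i) setNames(as.numeric(seq_len(3) == i), .feoc_endmembers)
  f <- switch(scn$name,
    M_only = unit(1),
    C_only = unit(2),
    FA_only = unit(3),
    rise_of_algae = {
      # fraction of the "old" (C-DOC) state; linear ramp across the step
      old <- if (scn$ramp_width > 0) {
        min(1, max(0, (age - (scn$step_age - scn$ramp_width / 2)) /
                     scn$ramp_width))
      } else as.numeric(age > scn$step_age)
      setNames(c(1 - old, old, 0), .feoc_endmembers)
    },
    proterozoic_active_eukaryotes = {
      if (age > scn$step_age) {
        setNames(c(scn$proterozoic_m_fraction,
                   1 - scn$proterozoic_m_fraction, 0), .feoc_endmembers)
      } else unit(1)
    },
    unconstrained = .assert(FALSE, paste(
      "the unconstrained scenario has no fixed fractions;",
      "use optimize_scenario_free()"), "feoc_domain_error"))
  f
}
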