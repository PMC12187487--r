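#' Convert 24-hour urinary urea to total urinary nitrogen
#'
#' Total nitrogen (g/24 h) is `0.028 g/mmol x urea (mmol/24 h)`: the molar
#' mass of the two nitrogen atoms in one urea molecule.
#'
#' @param urea_mmol Urea excreted, mmol/24 h. Vectorised.
#' @return Nitrogen, g/24 h.
#' @examples
#' urea_to_nitrogen(1000) # 28 g
#' @export
urea_to_nitrogen <- function(urea_mmol) {
  if (any(urea_mmol < 0, na.rm = TRUE)) {
    abort("`urea_mmol` must be non-negative.")
  }
  0.028 * urea_mmol
}

#' Biomarker protein intake from urinary nitrogen
#'
#' Protein intake (g/d) estimated as `6.25 x nitrogen / recovery`, where 6.25
#' is the standard nitrogen-to-protein conversion factor and `recovery` the
#' fraction of ingested nitrogen excreted in a complete 24-h urine
#' (default 0.81).
#'
#' @param nitrogen_g Urinary nitrogen, g/24 h. Vectorised.
#' @param recovery Fraction of ingested N excreted in 24 h, in (0, 1].
#' @return Estimated protein intake, g/d.
#' @examples
#' nitrogen_to_protein(12.96) # 100 g/d
#' @export
nitrogen_to_protein <- function(nitrogen_g, recovery = 0.81) {
  check_recovery(recovery)
  if (any(nitrogen_g < 0, na.rm = TRUE)) {
    abort("`nitrogen_g` must be non-negative.")
  }
  6.25 * nitrogen_g / recovery
}

#' Biomarker potassium intake from 24-hour urinary excretion
#'
#' Potassium intake (mg/d) estimated as `excreted / recovery`, assuming a
#' fraction `recovery` (default 0.80) of ingested potassium is excreted in a
#' complete 24-h urine.
#'
#' @param excreted_mg Potassium excreted, mg/24 h. Vectorised.
#' @param recovery Fraction of ingested K excreted in 24 h, in (0, 1].
#' @return Estimated potassium intake, mg/d.
#' @examples
#' potassium_excretion_to_intake(3413.6) # 4267 mg/d
#' @export
potassium_excretion_to_intake <- function(excreted_mg, recovery = 0.80) {
  check_recovery(recovery)
  if (any(excreted_mg < 0, na.rm = TRUE)) {
    abort("`excreted_mg` must be non-negative.")
  }
  excreted_mg / recovery
}

check_recovery <- function(recovery) {
  if (!is.numeric(recovery) || length(recovery) != 1 ||
      recovery <= 0 || recovery > 1) {
    abort("`recovery` must be a single value in (0, 1].")
  }
  invisible(recovery)
}

#' Convert potassium between mmol and mg
#'
#' Molar mass of potassium: 39.0983 g/mol.
#'
#' @param x Amount to convert. Vectorised.
#' @param from,to Units, `"mmol"` or `"mg"`.
#' @return Converted amount.
#' @examples
#' potassium_convert(100, from = "mmol", to = "mg") # 3909.83
#' @export
potassium_convert <- function(x, from = c("mmol", "mg"), to = c("mg", "mmol")) {
  from <- arg_match(from)
  to <- arg_match(to)
  k_molar <- 39.0983
  if (from == to) return(x)
  if (from == "mmol") x * k_molar else x / k_molar
}

#' Expected 24-hour creatinine excretion
#'
#' Reference daily creatinine excretion used to judge the completeness of a
#' 24-h urine collection: 21 mg/kg body weight for men and 17.5 mg/kg for
#' women (Corder's factors).
#'
#' @param weight_kg Body weight, kg; must be positive. Vectorised.
#' @param sex `"male"` or `"female"` (recycled against `weight_kg`).
#' @return Expected creatinine, mg/24 h.
#' @examples
#' expected_creatinine(70, "male")   # 1470
#' expected_creatinine(60, "female") # 1050
#' @export
expected_creatinine <- function(weight_kg, sex) {
  if (any(weight_kg <= 0, na.rm = TRUE)) {
    abort("`weight_kg` must be positive.")
  }
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("male", "female"))) {
    abort("`sex` must be \"male\" or \"female\".")
  }
  if_else(sex == "male", 21, 17.5) * weight_kg
}

#' Creatinine completeness correction
#'
#' Rescales a 24-h urinary analyte by `expected / observed` creatinine, the
#' standard completeness normalisation: an under-collection (observed below
#' expected) scales the analyte up, an over-collection scales it down. The
#' companion completeness ratio is `observed / expected`.
#'
#' @param value Analyte amount per 24 h. Vectorised.
#' @param observed_creatinine Measured creatinine, mg/24 h; must be positive.
#' @param expected_creatinine Expected creatinine, mg/24 h (see
#'   [expected_creatinine()]).
#' @return A tibble with `corrected` and `completeness_ratio`.
#' @examples
#' creatinine_correct(80, observed_creatinine = 1000,
#'                    expected_creatinine = 1470)
#' @export
creatinine_correct <- function(value, observed_creatinine,
                               expected_creatinine) {
  if (any(observed_creatinine <= 0, na.rm = TRUE)) {
    abort("`observed_creatinine` must be positive (zero indicates an incomplete collection).")
  }
  tibble(
    corrected = value * expected_creatinine / observed_creatinine,
    completeness_ratio = observed_creatinine / expected_creatinine
  )
}

#' Urine volume from collection weight
#'
#' @param weight_g Collection weight, g. Vectorised.
#' @param density Urine density, g/mL (default 1.020).
#' @return Volume, mL.
#' @examples
#' urine_volume_from_weight(1020) # 1000 mL
#' @export
urine_volume_from_weight <- function(weight_g, density = 1.020) {
  if (any(weight_g < 0, na.rm = TRUE)) abort("`weight_g` must be non-negative.")
  if (!is.numeric(density) || length(density) != 1 || density <= 0) {
    abort("`density` must be a single positive value.")
  }
  weight_g / density
}

#' Biomarker intake estimates from a urine table
#'
#' Applies the recovery chain to every collection in a urine table:
#' urea -> nitrogen -> protein, potassium excretion -> intake, both raw and
#' creatinine-corrected, with the completeness ratio alongside. Collections
#' with a duration outside 24 +/- 4 h are flagged (`duration_flagged`), not
#' rescaled.
#'
#' @param urine Tibble with columns `participant_id`, `urea_mmol`,
#'   `potassium_mg`, `creatinine_mg` and optionally `duration_h`.
#' @param participants Tibble with `participant_id`, `sex`, `weight_v1_kg`
#'   (supplies the expected creatinine).
#' @param n_recovery,k_recovery Recovery fractions (defaults 0.81, 0.80).
#' @return A tibble, one row per collection: `nitrogen_g`,
#'   `protein_intake_est`, `potassium_intake_est`, `expected_creatinine_mg`,
#'   `completeness_ratio`, `nitrogen_corrected`, `protein_corrected`,
#'   `potassium_corrected`, `duration_flagged`.
#' @examples
#' study <- simulate_cohort(sim_config(n_participants = 5), seed = 1)
#' biomarker_estimates(study$urine, study$participants)
#' @export
biomarker_estimates <- function(urine, participants,
                                n_recovery = 0.81, k_recovery = 0.80) {
  needed <- c("participant_id", "urea_mmol", "potassium_mg", "creatinine_mg")
  missing_cols <- setdiff(needed, names(urine))
  if (length(missing_cols) > 0) {
    abort(sprintf("`urine` is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  anthro <- participants %>%
    select("participant_id", "sex", "weight_v1_kg")
  out <- urine %>%
    left_join(anthro, by = "participant_id") %>%
    mutate(
      nitrogen_g = urea_to_nitrogen(.data$urea_mmol),
      protein_intake_est = nitrogen_to_protein(.data$nitrogen_g, n_recovery),
      potassium_intake_est =
        potassium_excretion_to_intake(.data$potassium_mg, k_recovery),
      expected_creatinine_mg =
        expected_creatinine(.data$weight_v1_kg, .data$sex)
    )
  corr <- creatinine_correct(out$nitrogen_g, out$creatinine_mg,
                             out$expected_creatinine_mg)
  out$nitrogen_corrected <- corr$corrected
  out$completeness_ratio <- corr$completeness_ratio
  out$protein_corrected <- nitrogen_to_protein(out$nitrogen_corrected,
                                               n_recovery)
  out$potassium_corrected <- potassium_excretion_to_intake(
    creatinine_correct(out$potassium_mg, out$creatinine_mg,
                       out$expected_creatinine_mg)$corrected,
    k_recovery
  )
  dur <- if ("duration_h" %in% names(out)) out$duration_h else 24
  out$duration_flagged <- abs(dur - 24) > 4
  out %>%
    select("participant_id", "nitrogen_g", "protein_intake_est",
           "potassium_intake_est", "expected_creatinine_mg",
           "completeness_ratio", "nitrogen_corrected", "protein_corrected",
           "potassium_corrected", "duration_flagged")
}
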