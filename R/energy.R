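#' Named sets of Weir-equation constants
#'
#' The Weir equation estimates energy expenditure from gas exchange:
#' `EE (kcal/min) = a x VO2 (L/min) + b x VCO2 (L/min)`, with an optional
#' protein correction subtracting `c` kcal per gram of 24-h urinary nitrogen.
#' Two sets ship with the package:
#' \describe{
#'   \item{`weir_classic`}{a = 3.941, b = 1.106, c = 2.17 kcal/g N — the
#'     protein-corrected form (the default).}
#'   \item{`weir_simplified`}{same gas coefficients with no nitrogen term,
#'     for sessions without a urine collection.}
#' }
#' User-defined sets can be registered by passing a list with elements
#' `vo2_kcal_per_l`, `vco2_kcal_per_l`, `protein_kcal_per_g` to [weir_ree()].
#'
#' @param set Name of the constant set.
#' @return A list with elements `name`, `vo2_kcal_per_l`, `vco2_kcal_per_l`,
#'   `protein_kcal_per_g`.
#' @examples
#' weir_constants()
#' weir_constants("weir_simplified")
#' @export
weir_constants <- function(set = c("weir_classic", "weir_simplified")) {
  set <- arg_match(set)
  switch(set,
    weir_classic = list(name = "weir_classic", vo2_kcal_per_l = 3.941,
                        vco2_kcal_per_l = 1.106, protein_kcal_per_g = 2.17),
    weir_simplified = list(name = "weir_simplified", vo2_kcal_per_l = 3.941,
                           vco2_kcal_per_l = 1.106, protein_kcal_per_g = 0)
  )
}

#' Resting energy expenditure by the Weir equation
#'
#' Computes REE (kcal/d) from one or more ventilated-hood measurements: the
#' per-measurement energy expenditure rate `a x VO2 + b x VCO2` (kcal/min) is
#' averaged across measurements with equal weight, scaled to 24 h, and the
#' protein correction `c x urinary nitrogen` (kcal/d) is subtracted.
#'
#' @param vo2_l_min,vco2_l_min Oxygen consumption and carbon dioxide
#'   production, L/min; one value per measurement (equal lengths, at least
#'   one).
#' @param nitrogen_g 24-h urinary nitrogen, g (scalar; 0 drops the protein
#'   correction).
#' @param constants A constant set from [weir_constants()] or a compatible
#'   list.
#' @return REE, kcal/d (scalar).
#' @examples
#' weir_ree(0.25, 0.20, nitrogen_g = 12) # 1711.248
#' @export
weir_ree <- function(vo2_l_min, vco2_l_min, nitrogen_g = 0,
                     constants = weir_constants()) {
  if (length(vo2_l_min) == 0) {
    abort("At least one calorimetry measurement is required.")
  }
  if (length(vo2_l_min) != length(vco2_l_min)) {
    abort("`vo2_l_min` and `vco2_l_min` must have equal lengths.")
  }
  if (any(vo2_l_min < 0 | vco2_l_min < 0, na.rm = TRUE)) {
    abort("Gas exchange rates must be non-negative.")
  }
  rate <- constants$vo2_kcal_per_l * vo2_l_min +
    constants$vco2_kcal_per_l * vco2_l_min
  mean(rate) * 1440 - constants$protein_kcal_per_g * nitrogen_g
}

#' MET values for IPAQ short-form scoring
#'
#' Default metabolic-equivalent values per activity category: vigorous 8.0,
#' moderate 4.0, walking 3.3 (the IPAQ short-form convention), sitting 1.3,
#' and sleep/lying 0.95 for the unaccounted remainder of the day.
#'
#' @param vigorous,moderate,walking,sitting,sleep MET values to override.
#' @return Named numeric vector of MET values.
#' @examples
#' met_table()
#' @export
met_table <- function(vigorous = 8.0, moderate = 4.0, walking = 3.3,
                      sitting = 1.3, sleep = 0.95) {
  c(vigorous = vigorous, moderate = moderate, walking = walking,
    sitting = sitting, sleep = sleep)
}

#' Physical activity level from an IPAQ short-form record
#'
#' Scores the three IPAQ activity categories plus sitting time in MET-hours;
#' hours not covered by any category are assumed spent asleep or lying down
#' and scored at the sleep/lying MET. PAL is total MET-hours divided by 24, so
#' a day spent entirely at rest gives the sleep MET value and PAL is bounded
#' by the smallest and largest MET in the table.
#'
#' @param vigorous_min,moderate_min,walking_min Daily minutes per activity
#'   category. Vectorised.
#' @param sitting_h Daily sitting hours. Vectorised.
#' @param met MET table from [met_table()].
#' @return PAL (dimensionless), same length as the inputs.
#' @examples
#' pal_from_ipaq(0, 60, 30, sitting_h = 8) # 1.243 under default METs
#' @export
pal_from_ipaq <- function(vigorous_min = 0, moderate_min = 0,
                          walking_min = 0, sitting_h = 0,
                          met = met_table()) {
  vig_h <- vigorous_min / 60
  mod_h <- moderate_min / 60
  walk_h <- walking_min / 60
  active_h <- vig_h + mod_h + walk_h + sitting_h
  if (any(c(vig_h, mod_h, walk_h, sitting_h) < 0, na.rm = TRUE)) {
    abort("Activity times must be non-negative.")
  }
  if (any(active_h > 24 + 1e-9, na.rm = TRUE)) {
    abort("Activity categories exceed 24 h/day.")
  }
  sleep_h <- 24 - active_h
  met_hours <- vig_h * met[["vigorous"]] + mod_h * met[["moderate"]] +
    walk_h * met[["walking"]] + sitting_h * met[["sitting"]] +
    sleep_h * met[["sleep"]]
  unname(met_hours / 24)
}

#' Flag implausibly high physical activity levels
#'
#' Records with PAL strictly above `threshold` (default 2.5) are excluded
#' from validity analyses as implausible for a non-athletic cohort.
#'
#' @param pal PAL values.
#' @param threshold Exclusion threshold, strict (default 2.5).
#' @return Logical: `TRUE` where the record should be excluded.
#' @examples
#' flag_pal_exclusion(c(1.4, 2.5, 2.51)) # FALSE FALSE TRUE
#' @export
flag_pal_exclusion <- function(pal, threshold = 2.5) {
  if (any(pal <= 0, na.rm = TRUE)) abort("`pal` must be positive.")
  pal > threshold
}

#' Total energy expenditure from REE and PAL
#'
#' `TEE = REE x PAL`; under the energy-balance assumption of a weight-stable
#' cohort, TEE is the objective reference for reported energy intake.
#'
#' @param ree REE, kcal/d (non-negative).
#' @param pal PAL (positive).
#' @return TEE, kcal/d.
#' @examples
#' tee_from_ree_pal(1500, 1.6) # 2400
#' @export
tee_from_ree_pal <- function(ree, pal) {
  if (any(ree < 0, na.rm = TRUE)) abort("`ree` must be non-negative.")
  if (any(pal <= 0, na.rm = TRUE)) abort("`pal` must be positive.")
  ree * pal
}

#' Goldberg classification of energy-intake reporting plausibility
#'
#' Classifies reporters by the ratio of reported energy intake to basal
#' metabolic rate: under-reporters (UR) below `lower` (strict), over-reporters
#' (OR) above `upper` (strict), acceptable reporters (AR) otherwise — the
#' boundary values themselves are acceptable. Defaults 1.05 and 2.28. Measured
#' resting energy expenditure may be supplied as the BMR argument.
#'
#' @param energy_intake Reported energy intake, kcal/d. Vectorised.
#' @param bmr Basal metabolic rate (or measured REE), kcal/d; positive.
#' @param lower,upper Cut-offs (defaults 1.05, 2.28).
#' @return A tibble with `ratio` and `reporter_class` (factor UR/AR/OR).
#' @examples
#' goldberg_classify(c(1600, 2000, 4000), bmr = 1600)
#' @export
goldberg_classify <- function(energy_intake, bmr, lower = 1.05,
                              upper = 2.28) {
  if (any(bmr <= 0, na.rm = TRUE)) abort("`bmr` must be positive.")
  if (lower >= upper) abort("`lower` must be below `upper`.")
  ratio <- energy_intake / bmr
  cls <- case_when(
    ratio < lower ~ "UR",
    ratio > upper ~ "OR",
    .default = "AR"
  )
  tibble(ratio = ratio,
         reporter_class = factor(cls, levels = c("UR", "AR", "OR")))
}

#' Between-visit weight stability check
#'
#' Percent change is `100 x |w2 - w1| / w1`; a change strictly above
#' `threshold_pct` (default 2.5%) marks the participant as not weight stable,
#' undermining the energy-balance assumption.
#'
#' @param weight_v1,weight_v2 Weights at the two visits, kg. Vectorised.
#' @param threshold_pct Stability threshold in percent (default 2.5).
#' @return A tibble with `percent_change` and `unstable`.
#' @examples
#' weight_stability_check(74.22, 74.20)
#' @export
weight_stability_check <- function(weight_v1, weight_v2,
                                   threshold_pct = 2.5) {
  if (any(weight_v1 <= 0, na.rm = TRUE)) abort("`weight_v1` must be positive.")
  pct <- 100 * abs(weight_v2 - weight_v1) / weight_v1
  tibble(percent_change = pct, unstable = pct > threshold_pct)
}

#' Per-participant energy profiles
#'
#' Chains the energy-metabolism computations over a study: Weir REE from the
#' calorimetry table (using each participant's urinary nitrogen), PAL from the
#' IPAQ table, `TEE = REE x PAL`, the Goldberg EI:BMR ratio against the
#' reported energy intake, and the PAL exclusion flag.
#'
#' @param calorimetry Tibble with `participant_id`, `vo2_l_min`,
#'   `vco2_l_min` (one row per measurement).
#' @param ipaq Tibble with `participant_id`, `vigorous_min_per_day`,
#'   `moderate_min_per_day`, `walking_min_per_day`, `sitting_h_per_day`.
#' @param biomarkers Output of [biomarker_estimates()] (for `nitrogen_g`); may
#'   be `NULL`, in which case the protein correction is dropped.
#' @param energy_intake Tibble with `participant_id` and `energy` — reported
#'   mean daily energy intake, kcal/d — e.g. from [summarize_intake()].
#' @param constants Weir constant set, see [weir_constants()].
#' @param met MET table, see [met_table()].
#' @param goldberg_lower,goldberg_upper,pal_max Cut-offs.
#' @return A tibble, one row per participant: `ree`, `pal`, `tee`,
#'   `ei_bmr_ratio`, `reporter_class`, `pal_excluded`.
#' @examples
#' study <- simulate_cohort(sim_config(n_participants = 8), seed = 2)
#' bm <- biomarker_estimates(study$urine, study$participants)
#' ei <- summarize_intake(study$intake_days, round = 1)
#' energy_profiles(study$calorimetry, study$ipaq, bm, ei)
#' @export
energy_profiles <- function(calorimetry, ipaq, biomarkers, energy_intake,
                            constants = weir_constants(), met = met_table(),
                            goldberg_lower = 1.05, goldberg_upper = 2.28,
                            pal_max = 2.5) {
  nitro <- if (is.null(biomarkers)) {
    tibble(participant_id = unique(calorimetry$participant_id),
           nitrogen_g = 0)
  } else {
    biomarkers %>% select("participant_id", "nitrogen_g")
  }
  ree_tbl <- calorimetry %>%
    left_join(nitro, by = "participant_id") %>%
    group_by(.data$participant_id) %>%
    summarise(
      ree = weir_ree(.data$vo2_l_min, .data$vco2_l_min,
                     nitrogen_g = first(.data$nitrogen_g),
                     constants = constants),
      .groups = "drop"
    )
  pal_tbl <- ipaq %>%
    mutate(pal = pal_from_ipaq(.data$vigorous_min_per_day,
                               .data$moderate_min_per_day,
                               .data$walking_min_per_day,
                               .data$sitting_h_per_day, met = met)) %>%
    select("participant_id", "pal")
  ei_tbl <- energy_intake %>%
    select("participant_id", energy_intake = "energy")
  out <- ree_tbl %>%
    left_join(pal_tbl, by = "participant_id") %>%
    left_join(ei_tbl, by = "participant_id") %>%
    mutate(tee = tee_from_ree_pal(.data$ree, .data$pal))
  gb <- goldberg_classify(out$energy_intake, out$ree,
                          lower = goldberg_lower, upper = goldberg_upper)
  out %>%
    mutate(
      ei_bmr_ratio = gb$ratio,
      reporter_class = gb$reporter_class,
      pal_excluded = flag_pal_exclusion(.data$pal, threshold = pal_max)
    ) %>%
    select("participant_id", "ree", "pal", "tee", "energy_intake",
           "ei_bmr_ratio", "reporter_class", "pal_excluded")
}
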