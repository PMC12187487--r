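#' Configuration for the synthetic weighed-food-record cohort
#'
#' Builds the parameter set that drives [simulate_cohort()]. Defaults describe
#' a healthy middle-aged Northern-European cohort completing two 7-day weighed
#' food records (WFRs) with a 24-hour urine collection on the last day of the
#' first record, fasting serum folate, ventilated-hood indirect calorimetry and
#' an IPAQ short-form activity questionnaire.
#'
#' Intakes are lognormal: each participant has a habitual (long-run average)
#' intake drawn around `true_intake_means` with coefficient of variation
#' `between_person_cv`, and each day's true intake varies around the habitual
#' value with `within_person_cv`. What the participant *reports* is the true
#' daily intake multiplied by a per-participant reporting-bias factor, itself
#' lognormal with mean `reporting_bias_mean` and standard deviation
#' `reporting_bias_sd`; the factor is shared across days and record rounds, so
#' it models the systematic misreporting that Goldberg screening is designed to
#' detect. Recovery biomarkers assume the fractions of ingested nitrogen and
#' potassium excreted in a complete 24-hour urine are `n_recovery_fraction`
#' (default 0.81) and `k_recovery_fraction` (default 0.80).
#'
#' @param n_participants Number of participants (default 71).
#' @param sex_fraction_female Expected fraction of women (default 57/71).
#' @param age_range Inclusive age range in years, default `c(35, 70)`.
#' @param bmi_range Inclusive BMI range in kg/m^2, default `c(22, 32)`.
#' @param true_intake_means Named vector of true habitual intake means, one per
#'   nutrient or food group: energy (kcal/d), protein (g/d), potassium (mg/d),
#'   folate (ug/d), fruit (g/d), vegetables (g/d), fish (g/d), meat (g/d),
#'   fibre (g/d), vitamin_c (mg/d), vitamin_d (ug/d), calcium (mg/d),
#'   sodium (mg/d). Partial named vectors override individual defaults.
#' @param between_person_cv,within_person_cv Coefficients of variation of the
#'   habitual-intake and day-to-day lognormal components. A scalar is recycled
#'   over nutrients; a named vector overrides per nutrient. Zero switches the
#'   component off.
#' @param reporting_bias_mean,reporting_bias_sd Mean and SD of the
#'   per-participant multiplicative reporting-bias factor (1 = unbiased;
#'   defaults 0.92 and 0.15 — mild average under-reporting, calibrated so the
#'   Goldberg screen classifies roughly 13% of a default cohort as
#'   under-reporters).
#' @param n_recovery_fraction,k_recovery_fraction Fractions of ingested
#'   nitrogen / potassium excreted in 24-h urine (defaults 0.81, 0.80).
#' @param assay_cv Named vector of analytical CVs for `folate` (serum, default
#'   0.0605), `urea`, `potassium`, `creatinine` (urine).
#' @param completeness_cv CV of the urine-collection completeness multiplier
#'   (captures over-/under-collection; 0 = every collection complete).
#' @param urine_density Urine density in g/mL used to convert collection weight
#'   to volume (default 1.020).
#' @param supplement_user_fraction Fraction of participants taking supplements.
#' @param supplement_amounts Named daily amounts supplement users add, in the
#'   nutrient's own units (defaults: folate 200 ug, calcium 400 mg,
#'   vitamin_d 10 ug).
#' @param day_dropout_prob Probability that any given WFR day goes unreported
#'   (default 0.023, i.e. about 6.84 of 7 days completed).
#' @param n_days Days per record round (1-7, default 7).
#' @param biomarker_window_days Number of trailing record days whose mean true
#'   intake feeds the 24-h urinary biomarkers (default 3): a 24-h collection
#'   integrates intake over the preceding days through body-pool turnover,
#'   not the final day alone. 1 makes the urine reflect the collection day
#'   only.
#' @param weight_change_sd SD of the relative weight change between visits
#'   (participants are weight stable; default 0.005).
#' @param pal_mean,pal_sd Mean and SD of the true physical activity level.
#' @param energy_balance_cv CV of the deviation of habitual energy intake from
#'   total energy expenditure. The cohort is weight stable, so true energy
#'   intake is generated as `REE x PAL` times this small lognormal deviation;
#'   the `energy` entry of `true_intake_means` documents the schema but is not
#'   a generator input.
#' @param plant_corr Shared-variance fraction of the latent "plant-food
#'   propensity" linking fruit, vegetables, folate, potassium, vitamin C and
#'   fibre across participants (0 = independent nutrients).
#' @param ree_noise_cv CV of calorimetry measurement noise around true REE.
#' @param respiratory_quotient VCO2/VO2 ratio used when synthesising gas
#'   exchange (default 0.85).
#' @param serum_folate_slope Slope of log serum folate on log total folate
#'   intake (the dose-response form is an assumption of the generator).
#' @param serum_folate_ref Named vector `c(intake =, folate =)`: a total folate
#'   intake (ug/d) anchored to a serum concentration (ng/mL); defaults anchor
#'   330 ug/d to 8.75 ng/mL.
#' @param seed Integer seed stored in the config; [simulate_cohort()] uses it
#'   unless overridden.
#' @param zero_noise If `TRUE`, switch off every random component except the
#'   between-person spread (all CVs, bias SD and dropout set to 0, bias mean
#'   set to 1). In this limit biomarker recovery reproduces true intakes
#'   exactly, which is the basis of the round-trip tests.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_participants = 20, seed = 42)
#' cfg$true_intake_means[["protein"]]
#' @export
sim_config <- function(n_participants = 71,
                       sex_fraction_female = 57 / 71,
                       age_range = c(35, 70),
                       bmi_range = c(22, 32),
                       true_intake_means = NULL,
                       between_person_cv = 0.25,
                       within_person_cv = 0.30,
                       reporting_bias_mean = 0.92,
                       reporting_bias_sd = 0.15,
                       n_recovery_fraction = 0.81,
                       k_recovery_fraction = 0.80,
                       assay_cv = NULL,
                       completeness_cv = 0.08,
                       urine_density = 1.020,
                       supplement_user_fraction = 0.7,
                       supplement_amounts = NULL,
                       day_dropout_prob = 0.023,
                       n_days = 7,
                       biomarker_window_days = 3,
                       weight_change_sd = 0.005,
                       pal_mean = 1.55,
                       pal_sd = 0.15,
                       energy_balance_cv = 0.10,
                       plant_corr = 0.5,
                       ree_noise_cv = 0.04,
                       respiratory_quotient = 0.85,
                       serum_folate_slope = 0.8,
                       serum_folate_ref = c(intake = 330, folate = 8.75),
                       seed = 1L,
                       zero_noise = FALSE) {
  default_means <- c(
    energy = 2100, protein = 82, potassium = 4267, folate = 300,
    fruit = 150, vegetables = 241, fish = 30, meat = 82,
    fibre = 19.1, vitamin_c = 107, vitamin_d = 5, calcium = 1000,
    sodium = 2800
  )
  true_intake_means <- .merge_named(default_means, true_intake_means,
                                    "true_intake_means")
  default_assay <- c(folate = 0.0605, urea = 0.03, potassium = 0.012,
                     creatinine = 0.04)
  assay_cv <- .merge_named(default_assay, assay_cv, "assay_cv")
  default_supp <- c(folate = 200, calcium = 400, vitamin_d = 10)
  supplement_amounts <- .merge_named(default_supp, supplement_amounts,
                                     "supplement_amounts")

  between_person_cv <- .per_nutrient(between_person_cv, "between_person_cv")
  within_person_cv <- .per_nutrient(within_person_cv, "within_person_cv")

  if (isTRUE(zero_noise)) {
    within_person_cv[] <- 0
    assay_cv[] <- 0
    completeness_cv <- 0
    reporting_bias_mean <- 1
    reporting_bias_sd <- 0
    day_dropout_prob <- 0
    weight_change_sd <- 0
    ree_noise_cv <- 0
    energy_balance_cv <- 0
  }

  cfg <- structure(list(
    n_participants = n_participants,
    sex_fraction_female = sex_fraction_female,
    age_range = age_range,
    bmi_range = bmi_range,
    true_intake_means = true_intake_means,
    between_person_cv = between_person_cv,
    within_person_cv = within_person_cv,
    reporting_bias_mean = reporting_bias_mean,
    reporting_bias_sd = reporting_bias_sd,
    n_recovery_fraction = n_recovery_fraction,
    k_recovery_fraction = k_recovery_fraction,
    assay_cv = assay_cv,
    completeness_cv = completeness_cv,
    urine_density = urine_density,
    supplement_user_fraction = supplement_user_fraction,
    supplement_amounts = supplement_amounts,
    day_dropout_prob = day_dropout_prob,
    n_days = n_days,
    biomarker_window_days = biomarker_window_days,
    weight_change_sd = weight_change_sd,
    pal_mean = pal_mean,
    pal_sd = pal_sd,
    energy_balance_cv = energy_balance_cv,
    plant_corr = plant_corr,
    ree_noise_cv = ree_noise_cv,
    respiratory_quotient = respiratory_quotient,
    serum_folate_slope = serum_folate_slope,
    serum_folate_ref = serum_folate_ref,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
}

.merge_named <- function(defaults, override, what) {
  if (is.null(override)) return(defaults)
  if (is.null(names(override)) || any(!nzchar(names(override)))) {
    abort(sprintf("`%s` overrides must be a named vector.", what))
  }
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown %s key(s): %s", what,
                  paste(unknown, collapse = ", ")))
  }
  defaults[names(override)] <- override
  defaults
}

.per_nutrient <- function(x, what) {
  if (length(x) == 1 && is.null(names(x))) {
    return(setNames(rep(as.numeric(x), length(.nutrients)), .nutrients))
  }
  .merge_named(setNames(rep(0.25, length(.nutrients)), .nutrients), x, what)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.numeric(cfg$n_participants) || length(cfg$n_participants) != 1 ||
      cfg$n_participants < 0 || cfg$n_participants != round(cfg$n_participants)) {
    abort("`n_participants` must be a single non-negative integer.")
  }
  fr <- c(sex_fraction_female = cfg$sex_fraction_female,
          supplement_user_fraction = cfg$supplement_user_fraction,
          day_dropout_prob = cfg$day_dropout_prob)
  bad <- fr[fr < 0 | fr > 1]
  if (length(bad) > 0) {
    abort(sprintf("Fraction(s) outside [0, 1]: %s",
                  paste(names(bad), collapse = ", ")))
  }
  rec <- c(n_recovery_fraction = cfg$n_recovery_fraction,
           k_recovery_fraction = cfg$k_recovery_fraction)
  if (any(rec <= 0 | rec > 1)) {
    abort("Recovery fractions must lie in (0, 1].")
  }
  cvs <- c(cfg$between_person_cv, cfg$within_person_cv, cfg$assay_cv,
           completeness = cfg$completeness_cv, ree = cfg$ree_noise_cv,
           energy_balance = cfg$energy_balance_cv)
  if (any(cvs < 0 | cvs >= 1)) {
    abort("All CVs must lie in [0, 1).")
  }
  if (cfg$plant_corr < 0 || cfg$plant_corr >= 1) {
    abort("`plant_corr` must lie in [0, 1).")
  }
  if (any(cfg$true_intake_means <= 0)) {
    abort("`true_intake_means` must all be positive.")
  }
  if (cfg$urine_density <= 0) abort("`urine_density` must be positive.")
  if (cfg$n_days < 1 || cfg$n_days > 7) abort("`n_days` must be in 1..7.")
  if (cfg$biomarker_window_days < 1) {
    abort("`biomarker_window_days` must be at least 1.")
  }
  if (cfg$reporting_bias_mean <= 0) {
    abort("`reporting_bias_mean` must be positive.")
  }
  if (diff(cfg$age_range) < 0 || diff(cfg$bmi_range) < 0) {
    abort("`age_range` and `bmi_range` must be increasing.")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  participants: %d (%.0f%% female), age %g-%g y, BMI %g-%g\n",
              x$n_participants, 100 * x$sex_fraction_female,
              x$age_range[1], x$age_range[2], x$bmi_range[1], x$bmi_range[2]))
  cat(sprintf("  records: 2 rounds x %d days; day dropout %.3f\n",
              x$n_days, x$day_dropout_prob))
  cat(sprintf("  reporting bias: mean %.2f, sd %.2f\n",
              x$reporting_bias_mean, x$reporting_bias_sd))
  cat(sprintf("  recovery fractions: N %.2f, K %.2f; seed %d\n",
              x$n_recovery_fraction, x$k_recovery_fraction, x$seed))
  invisible(x)
}

# lognormal draws parameterised by arithmetic mean and CV; cv = 0 degenerates
# to the mean so the zero-noise limit is exact, not approximate
rlnorm_mean_cv <- function(n, mean, cv) {
  if (all(cv == 0)) return(rep_len(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  out <- rlnorm(n, meanlog = meanlog, sdlog = sdlog)
  if (any(cv == 0)) {
    fixed <- rep_len(cv == 0, n)
    out[fixed] <- rep_len(mean, n)[fixed]
  }
  out
}
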