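#' Generate the participant table of a synthetic cohort
#'
#' Draws anthropometrics for a cohort of weight-stable adults: age uniform
#' within `config$age_range`, sex by `config$sex_fraction_female`, height
#' normal around sex-specific means, and weight derived from a BMI drawn
#' uniformly within `config$bmi_range`, so every computed BMI lies inside the
#' configured range by construction. The visit-2 weight differs from visit 1
#' by a small relative change with SD `config$weight_change_sd`, truncated at
#' +/- 2% so the cohort satisfies the 2.5% weight-stability criterion.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per participant: `participant_id`, `sex`
#'   ("male"/"female"), `age`, `height_cm`, `weight_v1_kg`, `weight_v2_kg`,
#'   `bmi`.
#' @examples
#' set.seed(1)
#' generate_cohort(sim_config(n_participants = 5))
#' @export
generate_cohort <- function(config) {
  config <- validate_sim_config(config)
  n <- config$n_participants
  if (n == 0) {
    return(tibble(
      participant_id = integer(), sex = character(), age = numeric(),
      height_cm = numeric(), weight_v1_kg = numeric(),
      weight_v2_kg = numeric(), bmi = numeric()
    ))
  }
  sex <- if_else(runif(n) < config$sex_fraction_female, "female", "male")
  age <- runif(n, config$age_range[1], config$age_range[2])
  height <- rnorm(n, mean = if_else(sex == "female", 166, 179), sd = 6)
  bmi <- runif(n, config$bmi_range[1], config$bmi_range[2])
  weight <- bmi * (height / 100)^2
  delta <- rnorm(n, 0, config$weight_change_sd)
  delta <- pmin(pmax(delta, -0.02), 0.02)
  tibble(
    participant_id = seq_len(n),
    sex = sex,
    age = age,
    height_cm = height,
    weight_v1_kg = weight,
    weight_v2_kg = weight * (1 + delta),
    bmi = bmi
  )
}

#' Generate reported intake days for two weighed-food-record rounds
#'
#' For each participant a habitual intake is drawn per nutrient (lognormal
#' around `config$true_intake_means` with `between_person_cv`); both record
#' rounds share it. Each day's true intake multiplies the habitual value by a
#' lognormal day factor (`within_person_cv`), and the reported diet value is
#' the true daily intake times the participant's reporting-bias factor.
#' Supplement users additionally report fixed daily supplement amounts
#' (`supp_*` columns), which are not subject to reporting bias. Days are
#' dropped independently with `day_dropout_prob`, but at least one day per
#' round is always retained.
#'
#' @param participants Output of [generate_cohort()].
#' @param config A [sim_config()].
#' @return A list of two tibbles: `intake_days` (reported; columns
#'   `participant_id`, `round`, `day`, one column per nutrient, `supp_*`
#'   supplement columns) and `truth` (latent per-participant values:
#'   habitual intakes `true_*`, the reporting bias factor, supplement-user
#'   flag, latent `true_ree` / `true_pal`, the trailing-window biomarker bases
#'   `marker_basis_protein` / `marker_basis_potassium`, and the true intakes
#'   on the urine-collection day, `collection_day_*`). The truth table exists
#'   for testing the
#'   generator and must not be fed to the analysis functions.
#' @export
generate_intake_records <- function(participants, config) {
  config <- validate_sim_config(config)
  if (nrow(participants) == 0) {
    abort("`participants` is empty; generate a cohort first.")
  }
  n <- nrow(participants)
  nut <- .nutrients
  n_days <- config$n_days

  bias <- rlnorm_mean_cv(
    n, config$reporting_bias_mean,
    config$reporting_bias_sd / config$reporting_bias_mean
  )
  supp_user <- runif(n) < config$supplement_user_fraction

  # participant-level energy metabolism: a weight-stable cohort is in energy
  # balance, so true habitual energy intake is TEE = REE x PAL (up to the
  # configured balance noise); true_intake_means[["energy"]] is a schema
  # entry, not a generator input
  ree_true <- mifflin_ree(participants)
  pal_true <- pmin(pmax(rnorm(n, config$pal_mean, config$pal_sd), 1.1), 2.6)
  tee_true <- ree_true * pal_true

  # nutrients rich in plant foods share a latent "plant-food propensity" so
  # fruit/vegetable intake co-varies with folate, potassium, vitamin C and
  # fibre, as the validity comparisons assume
  plant <- c("fruit", "vegetables", "folate", "potassium", "vitamin_c",
             "fibre")
  z_plant <- rnorm(n)
  loading <- sqrt(config$plant_corr)
  habitual <- sapply(nut, function(v) {
    if (v == "energy") {
      return(tee_true * rlnorm_mean_cv(n, 1, config$energy_balance_cv))
    }
    cv <- config$between_person_cv[[v]]
    m <- config$true_intake_means[[v]]
    if (cv == 0) return(rep(m, n))
    sdlog <- sqrt(log1p(cv^2))
    z <- if (v %in% plant) {
      loading * z_plant + sqrt(1 - config$plant_corr) * rnorm(n)
    } else {
      rnorm(n)
    }
    exp(log(m) - sdlog^2 / 2 + sdlog * z)
  })
  habitual <- matrix(habitual, nrow = n,
                     dimnames = list(NULL, nut))

  # full grid of true daily intakes (2 rounds x n_days); reported rows are a
  # subset, but the urine collection day needs the truth even when unreported
  grid <- tidyr::expand_grid(
    participant_id = participants$participant_id,
    round = 1:2,
    day = seq_len(n_days)
  )
  idx <- match(grid$participant_id, participants$participant_id)
  day_true <- sapply(nut, function(v) {
    habitual[idx, v] * rlnorm_mean_cv(nrow(grid), 1, config$within_person_cv[[v]])
  })
  day_true <- matrix(day_true, nrow = nrow(grid), dimnames = list(NULL, nut))

  reported <- day_true * bias[idx]
  intake <- bind_cols_matrix(grid, reported)
  for (v in .supp_nutrients) {
    intake[[paste0("supp_", v)]] <-
      if_else(supp_user[idx], config$supplement_amounts[[v]], 0)
  }

  keep <- runif(nrow(grid)) >= config$day_dropout_prob
  # never drop a whole round: force the last day back in where needed
  kept_per_round <- tapply(keep, list(grid$participant_id, grid$round), sum)
  for (pid in rownames(kept_per_round)) {
    for (r in colnames(kept_per_round)) {
      if (kept_per_round[pid, r] == 0) {
        i <- which(grid$participant_id == as.integer(pid) &
                     grid$round == as.integer(r) & grid$day == n_days)
        keep[i] <- TRUE
      }
    }
  }
  intake_days <- intake[keep, , drop = FALSE]

  truth <- bind_cols_matrix(
    tibble(participant_id = participants$participant_id),
    `colnames<-`(habitual, paste0("true_", nut))
  )
  truth$reporting_bias <- bias
  truth$supplement_user <- supp_user
  truth$true_ree <- ree_true
  truth$true_pal <- pal_true

  # the 24-h urine on the last day of round 1 integrates intake over the
  # preceding days (body-pool turnover), so the biomarker basis is the mean
  # true intake over a short trailing window ending on the collection day
  win <- max(1, n_days - config$biomarker_window_days + 1)
  basis_rows <- grid$round == 1 & grid$day >= win
  coll <- grid$round == 1 & grid$day == n_days
  ord <- match(participants$participant_id, grid$participant_id[coll])
  basis_mean <- function(v) {
    m <- tapply(day_true[basis_rows, v], grid$participant_id[basis_rows],
                mean)[as.character(participants$participant_id)]
    as.vector(m)
  }
  truth$marker_basis_protein <- basis_mean("protein")
  truth$marker_basis_potassium <- basis_mean("potassium")
  truth$collection_day_protein <- day_true[coll, "protein"][ord]
  truth$collection_day_potassium <- day_true[coll, "potassium"][ord]
  truth$collection_day_folate <- day_true[coll, "folate"][ord]

  list(intake_days = as_tibble(intake_days), truth = as_tibble(truth))
}

bind_cols_matrix <- function(df, m) {
  out <- as_tibble(df)
  for (j in colnames(m)) out[[j]] <- m[, j]
  out
}

# Mifflin-St Jeor resting energy expenditure (kcal/d); a generator-side
# convenience to make gas exchange and energy balance realistic — the
# analysis only ever sees measured calorimetry
mifflin_ree <- function(participants) {
  10 * participants$weight_v1_kg + 6.25 * participants$height_cm -
    5 * participants$age + if_else(participants$sex == "male", 5, -161)
}

#' Generate biomarker panels consistent with the latent true intakes
#'
#' Inverts the recovery-biomarker chain so that the analysis can be tested
#' against known truth. On the urine-collection day (last day of round 1):
#' nitrogen excretion is `true protein / 6.25 x n_recovery_fraction`, urea is
#' `nitrogen / 0.028` mmol, potassium excretion is
#' `true potassium x k_recovery_fraction`, and creatinine follows the
#' Corder-style expectation (21 mg/kg men, 17.5 mg/kg women), each multiplied
#' by lognormal assay / collection-completeness noise. Serum folate is
#' log-linear in total (diet + supplement) folate intake. Calorimetry gas
#' exchange is synthesised from a Mifflin-St Jeor-type resting energy
#' expenditure split into VO2/VCO2 at the configured respiratory quotient so
#' that the Weir equation recovers the target REE; IPAQ minutes are solved
#' from the drawn physical activity level so that IPAQ scoring reproduces it.
#'
#' @param participants Output of [generate_cohort()].
#' @param intake Output of [generate_intake_records()] (the full list; the
#'   truth component supplies collection-day intakes so an unreported
#'   collection day is flagged, not dropped).
#' @param config A [sim_config()].
#' @return A list of tibbles `urine`, `serum`, `calorimetry`, `ipaq`, and an
#'   augmented `truth` carrying `true_ree`, `true_pal`, `true_nitrogen`.
#' @export
generate_biomarker_panel <- function(participants, intake, config) {
  config <- validate_sim_config(config)
  truth <- intake$truth
  n <- nrow(participants)
  stopifnot(nrow(truth) == n)

  acv <- config$assay_cv
  nitrogen_true <- truth$marker_basis_protein / 6.25 *
    config$n_recovery_fraction
  urea <- (nitrogen_true / 0.028) * rlnorm_mean_cv(n, 1, acv[["urea"]])
  k_mg <- truth$marker_basis_potassium * config$k_recovery_fraction *
    rlnorm_mean_cv(n, 1, acv[["potassium"]])
  expected_cr <- expected_creatinine(participants$weight_v1_kg,
                                     participants$sex)
  completeness <- rlnorm_mean_cv(n, 1, config$completeness_cv)
  creatinine <- expected_cr * completeness *
    rlnorm_mean_cv(n, 1, acv[["creatinine"]])
  volume <- pmax(rnorm(n, 1600, if (config$completeness_cv > 0) 350 else 0),
                 500)
  reported_day <- intake$intake_days %>%
    filter(.data$round == 1, .data$day == config$n_days)
  urine <- tibble(
    participant_id = participants$participant_id,
    duration_h = 24,
    urine_weight_g = volume * config$urine_density,
    volume_ml = volume,
    urea_mmol = urea,
    potassium_mg = k_mg,
    creatinine_mg = creatinine,
    collection_day_reported =
      participants$participant_id %in% reported_day$participant_id
  )

  supp_folate <- if_else(truth$supplement_user,
                         config$supplement_amounts[["folate"]], 0)
  total_folate <- truth$true_folate + supp_folate
  ref <- config$serum_folate_ref
  folate_mean <- ref[["folate"]] *
    (total_folate / ref[["intake"]])^config$serum_folate_slope
  serum <- tibble(
    participant_id = participants$participant_id,
    folate_ng_ml = folate_mean * rlnorm_mean_cv(n, 1, acv[["folate"]])
  )

  ree_true <- truth$true_ree
  rq <- config$respiratory_quotient
  wc <- weir_constants()
  calorimetry <- purrr::map(1:2, function(m) {
    ree_meas <- ree_true * rlnorm_mean_cv(n, 1, config$ree_noise_cv)
    vo2 <- (ree_meas / 1440 + wc$protein_kcal_per_g * nitrogen_true / 1440) /
      (wc$vo2_kcal_per_l + wc$vco2_kcal_per_l * rq)
    tibble(
      participant_id = participants$participant_id,
      measurement = m,
      vo2_l_min = vo2,
      vco2_l_min = vo2 * rq,
      duration_min = 25
    )
  }) %>%
    list_rbind() %>%
    arrange(.data$participant_id, .data$measurement)

  ipaq <- ipaq_from_pal(participants$participant_id, truth$true_pal)

  truth$true_nitrogen <- nitrogen_true
  list(urine = urine, serum = serum, calorimetry = calorimetry, ipaq = ipaq,
       truth = as_tibble(truth))
}

# invert IPAQ scoring: fix sitting 8 h and moderate 30 min, fill the required
# MET-hours with walking up to 2 h, then vigorous activity
ipaq_from_pal <- function(participant_id, pal, met = met_table()) {
  sit_h <- 8
  mod_h <- 0.5
  need <- 24 * pal - 24 * met[["sleep"]] -
    sit_h * (met[["sitting"]] - met[["sleep"]]) -
    mod_h * (met[["moderate"]] - met[["sleep"]])
  walk_h <- pmin(pmax(need / (met[["walking"]] - met[["sleep"]]), 0), 2)
  vig_h <- pmax(
    (need - walk_h * (met[["walking"]] - met[["sleep"]])) /
      (met[["vigorous"]] - met[["sleep"]]),
    0
  )
  tibble(
    participant_id = participant_id,
    vigorous_min_per_day = vig_h * 60,
    moderate_min_per_day = mod_h * 60,
    walking_min_per_day = walk_h * 60,
    sitting_h_per_day = sit_h
  )
}

#' Simulate a complete synthetic weighed-food-record study
#'
#' Runs the three generator stages ([generate_cohort()],
#' [generate_intake_records()], [generate_biomarker_panel()]) under a single
#' seed and returns the bundled dataset. The same config and seed always give
#' identical tables.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An object of class `study_dataset`: a list of tibbles
#'   `participants`, `intake_days`, `urine`, `serum`, `calorimetry`, `ipaq`,
#'   `truth`, with the config and seed as attributes. The `truth` table is
#'   latent ground truth for testing the pipeline; the analysis functions
#'   never read it.
#' @examples
#' study <- simulate_cohort(sim_config(n_participants = 10), seed = 7)
#' study
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed) {
  config <- validate_sim_config(config)
  seed <- as.integer(seed)
  set.seed(seed)
  participants <- generate_cohort(config)
  if (nrow(participants) == 0) {
    abort("Cannot simulate a study with zero participants.")
  }
  intake <- generate_intake_records(participants, config)
  panel <- generate_biomarker_panel(participants, intake, config)
  structure(
    list(
      participants = participants,
      intake_days = intake$intake_days,
      urine = panel$urine,
      serum = panel$serum,
      calorimetry = panel$calorimetry,
      ipaq = panel$ipaq,
      truth = panel$truth
    ),
    config = config, seed = seed, class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("<study_dataset>\n")
  cat(sprintf("  %d participants, %d intake-day rows (2 rounds)\n",
              nrow(x$participants), nrow(x$intake_days)))
  cat(sprintf("  urine/serum/calorimetry/ipaq rows: %d/%d/%d/%d\n",
              nrow(x$urine), nrow(x$serum), nrow(x$calorimetry),
              nrow(x$ipaq)))
  sd_ <- attr(x, "seed")
  if (!is.null(sd_)) cat(sprintf("  seed: %d\n", sd_))
  invisible(x)
}

#' Write a study dataset to a directory of CSV files
#'
#' One CSV per table: `participants.csv`, `intake_days.csv`, `urine.csv`,
#' `serum.csv`, `calorimetry.csv`, `ipaq.csv`, and — unless
#' `include_truth = FALSE` — `truth.csv`. Keeping the truth table in its own
#' file lets the analysis be run blinded.
#'
#' @param study A `study_dataset` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param include_truth Write the latent truth table too? Default `TRUE`.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, include_truth = TRUE) {
  stopifnot(inherits(study, "study_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("participants", "intake_days", "urine", "serum", "calorimetry",
            "ipaq", if (include_truth) "truth")
  for (tab in tabs) {
    readr::write_csv(study[[tab]], file.path(dir, paste0(tab, ".csv")))
  }
  invisible(dir)
}
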