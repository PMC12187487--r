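test_that("config validation enforces ranges and known keys", {
  expect_error(sim_config(n_participants = -1), "non-negative")
  expect_error(sim_config(true_intake_means = c(gluten = 12)), "Unknown")
  expect_error(sim_config(within_person_cv = c(unknown_nutrient = 0.2)),
               "Unknown")
  expect_error(sim_config(n_recovery_fraction = 0), "Recovery")
  expect_error(sim_config(between_person_cv = 1.2), "CV")
  expect_error(sim_config(urine_density = 0), "positive")
  cfg <- sim_config()
  expect_equal(cfg$n_recovery_fraction, 0.81)
  expect_equal(cfg$k_recovery_fraction, 0.80)
  expect_equal(cfg$assay_cv[["folate"]], 0.0605)
})

test_that("cohort generation respects size, ranges and determinism", {
  cfg <- sim_config(n_participants = 0)
  expect_equal(nrow(generate_cohort(cfg)), 0)

  cfg10 <- sim_config(n_participants = 10)
  set.seed(42); a <- generate_cohort(cfg10)
  set.seed(42); b <- generate_cohort(cfg10)
  expect_identical(a, b)

  cfg1k <- sim_config(n_participants = 1000, bmi_range = c(22, 32))
  set.seed(1)
  coh <- generate_cohort(cfg1k)
  bmi <- coh$weight_v1_kg / (coh$height_cm / 100)^2
  expect_true(all(bmi >= 22 & bmi <= 32))
  expect_true(all(coh$age >= 35 & coh$age <= 70))
  # weight stability by construction
  chg <- weight_stability_check(coh$weight_v1_kg, coh$weight_v2_kg)
  expect_true(all(!chg$unstable))
})

test_that("identical seed and config give bitwise-identical datasets", {
  cfg <- sim_config(n_participants = 25)
  s1 <- simulate_cohort(cfg, seed = 123)
  s2 <- simulate_cohort(cfg, seed = 123)
  for (tab in c("participants", "intake_days", "urine", "serum",
                "calorimetry", "ipaq", "truth")) {
    expect_identical(s1[[tab]], s2[[tab]])
  }
  s3 <- simulate_cohort(cfg, seed = 124)
  expect_false(identical(s1$intake_days, s3$intake_days))
})

test_that("zero within-person noise and unit bias make all days equal", {
  cfg <- sim_config(n_participants = 6, zero_noise = TRUE)
  st <- simulate_cohort(cfg, seed = 2)
  per <- st$intake_days |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(c("protein", "energy")),
                                   ~ max(.x) - min(.x)))
  expect_true(all(abs(per$protein) < 1e-9))
  expect_true(all(abs(per$energy) < 1e-9))
  # reported equals habitual truth
  d1 <- st$intake_days[st$intake_days$round == 1 & st$intake_days$day == 1, ]
  d1 <- d1[order(d1$participant_id), ]
  expect_equal(d1$protein, st$truth$true_protein)
})

test_that("every participant has both rounds with 1-7 days each", {
  cfg <- sim_config(n_participants = 40, day_dropout_prob = 0.3)
  st <- simulate_cohort(cfg, seed = 9)
  counts <- dplyr::count(st$intake_days, participant_id, round)
  expect_equal(nrow(counts), 80) # 40 participants x 2 rounds
  expect_true(all(counts$n >= 1 & counts$n <= 7))
})

test_that("mean reporting bias is recovered by Monte Carlo", {
  cfg <- sim_config(n_participants = 2000, reporting_bias_mean = 0.9,
                    reporting_bias_sd = 0)
  st <- simulate_cohort(cfg, seed = 77)
  weekly <- summarize_intake(st$intake_days, round = 1)
  m <- dplyr::left_join(weekly, st$truth, by = "participant_id")
  ratio <- mean(m$protein / m$true_protein)
  expect_equal(ratio, 0.9, tolerance = 0.01)
})

test_that("round means share the habitual signal across participants", {
  st <- simulate_cohort(sim_config(n_participants = 200), seed = 15)
  r1 <- summarize_intake(st$intake_days, round = 1)
  r2 <- summarize_intake(st$intake_days, round = 2)
  m <- dplyr::inner_join(r1, r2, by = "participant_id",
                         suffix = c("_1", "_2"))
  expect_gt(spearman_banded(m$protein_1, m$protein_2)$rho, 0)
  expect_gt(spearman_banded(m$energy_1, m$energy_2)$rho, 0)
})

test_that("zero-noise biomarkers invert the recovery chain exactly", {
  cfg <- sim_config(n_participants = 10, zero_noise = TRUE)
  st <- simulate_cohort(cfg, seed = 3)
  # urea = (protein / 6.25 x 0.81) / 0.028, potassium at 0.80 recovery
  expect_equal(st$urine$urea_mmol,
               st$truth$marker_basis_protein / 6.25 * 0.81 / 0.028)
  expect_equal(st$urine$potassium_mg,
               st$truth$marker_basis_potassium * 0.80)
  expect_equal(st$urine$creatinine_mg,
               expected_creatinine(st$participants$weight_v1_kg,
                                   st$participants$sex))
  bm <- biomarker_estimates(st$urine, st$participants)
  expect_equal(bm$protein_intake_est, st$truth$true_protein)
  expect_equal(bm$potassium_intake_est, st$truth$true_potassium)
  expect_equal(bm$completeness_ratio, rep(1, 10))
})

test_that("a constant 100 g/d protein intake gives the textbook urea value", {
  cfg <- sim_config(n_participants = 4, zero_noise = TRUE,
                    true_intake_means = c(protein = 100),
                    between_person_cv = 0)
  st <- simulate_cohort(cfg, seed = 1)
  expect_equal(st$urine$urea_mmol, rep((100 / 6.25 * 0.81) / 0.028, 4))
  cfgk <- sim_config(n_participants = 4, zero_noise = TRUE,
                     true_intake_means = c(potassium = 4000),
                     between_person_cv = 0)
  stk <- simulate_cohort(cfgk, seed = 1)
  expect_equal(stk$urine$potassium_mg, rep(3200, 4))
})

test_that("calorimetry and IPAQ invert to the latent REE and PAL", {
  cfg <- sim_config(n_participants = 12, zero_noise = TRUE)
  st <- simulate_cohort(cfg, seed = 21)
  bm <- biomarker_estimates(st$urine, st$participants)
  ep <- energy_profiles(st$calorimetry, st$ipaq, bm,
                        summarize_intake(st$intake_days, round = 1))
  expect_equal(ep$ree, st$truth$true_ree, tolerance = 1e-10)
  expect_equal(ep$pal, st$truth$true_pal, tolerance = 1e-10)
  # energy balance: reported weekly energy equals TEE at zero noise
  expect_equal(ep$energy_intake, ep$tee, tolerance = 1e-10)
})

test_that("supplement users add fixed supplement amounts", {
  cfg <- sim_config(n_participants = 50, supplement_user_fraction = 0.5)
  st <- simulate_cohort(cfg, seed = 33)
  users <- st$truth$participant_id[st$truth$supplement_user]
  sup <- st$intake_days[st$intake_days$participant_id %in% users, ]
  non <- st$intake_days[!st$intake_days$participant_id %in% users, ]
  expect_true(all(sup$supp_folate == 200))
  expect_true(all(non$supp_folate == 0))
  expect_gt(length(users), 0)
  expect_lt(length(users), 50)
})
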