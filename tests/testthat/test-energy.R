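test_that("Weir REE matches hand arithmetic with default constants", {
  # 1440 x (3.941 x 0.25 + 1.106 x 0.20) - 2.17 x 12
  expect_equal(weir_ree(0.25, 0.20, nitrogen_g = 12), 1711.248)
  expect_equal(weir_ree(0, 0, nitrogen_g = 0), 0)
  # averaging two identical measurements changes nothing
  expect_equal(weir_ree(c(0.25, 0.25), c(0.20, 0.20), nitrogen_g = 12),
               weir_ree(0.25, 0.20, nitrogen_g = 12))
  expect_error(weir_ree(numeric(0), numeric(0)), "at least one",
               ignore.case = TRUE)
  expect_error(weir_ree(0.2, c(0.1, 0.2)), "equal lengths")
})

test_that("Weir REE is linear, monotone in gases, decreasing in nitrogen", {
  base <- weir_ree(0.25, 0.20, nitrogen_g = 10)
  expect_gt(weir_ree(0.30, 0.20, nitrogen_g = 10), base)
  expect_gt(weir_ree(0.25, 0.25, nitrogen_g = 10), base)
  expect_lt(weir_ree(0.25, 0.20, nitrogen_g = 14), base)
  # linearity: f(a + b) + f(0) = f(a) + f(b) in each argument
  f <- function(v) weir_ree(v, 0.2, nitrogen_g = 5)
  expect_equal(f(0.1) + f(0.3), f(0.2) + f(0.2))
  simp <- weir_constants("weir_simplified")
  expect_equal(weir_ree(0.25, 0.20, nitrogen_g = 12, constants = simp),
               1440 * (3.941 * 0.25 + 1.106 * 0.20))
})

test_that("IPAQ PAL scoring matches the stated MET table", {
  # all day asleep or lying down
  expect_equal(pal_from_ipaq(0, 0, 0, sitting_h = 0), 0.95)
  # moderate 60 min, walking 30 min, sitting 8 h, remainder asleep
  expect_equal(pal_from_ipaq(0, 60, 30, sitting_h = 8),
               (4.0 + 1.65 + 10.4 + 14.5 * 0.95) / 24)
  # doubling all MET values doubles PAL
  m2 <- met_table(16, 8, 6.6, 2.6, 1.9)
  expect_equal(pal_from_ipaq(30, 60, 30, 8, met = m2),
               2 * pal_from_ipaq(30, 60, 30, 8))
  expect_error(pal_from_ipaq(0, 0, 0, sitting_h = 25), "24 h")
  expect_error(pal_from_ipaq(-10, 0, 0, 0), "non-negative")
})

test_that("PAL stays within the MET table range when categories cover 24 h", {
  set.seed(11)
  met <- met_table()
  for (i in 1:50) {
    h <- diff(c(0, sort(runif(3, 0, 24)), 24)) # 4 positive parts summing 24
    pal <- pal_from_ipaq(h[1] * 60, h[2] * 60, h[3] * 60, sitting_h = h[4])
    expect_gte(pal, min(met))
    expect_lte(pal, max(met))
  }
})

test_that("PAL exclusion threshold is strict at 2.5", {
  expect_equal(flag_pal_exclusion(c(1.4, 2.5, 2.51)), c(FALSE, FALSE, TRUE))
  expect_error(flag_pal_exclusion(0), "positive")
})

test_that("TEE is REE times PAL", {
  expect_equal(tee_from_ree_pal(1500, 1.6), 2400)
  expect_equal(tee_from_ree_pal(0, 1.4), 0)
  expect_equal(tee_from_ree_pal(1730, 1), 1730)
  expect_error(tee_from_ree_pal(-1, 1.2), "non-negative")
  expect_error(tee_from_ree_pal(1500, 0), "positive")
})

test_that("Goldberg boundaries are inclusive to acceptable reporters", {
  g <- goldberg_classify(c(1600, 1.05 * 1600, 2.28 * 1600, 2.30 * 1600),
                         bmr = 1600)
  expect_equal(as.character(g$reporter_class), c("UR", "AR", "AR", "OR"))
  expect_equal(g$ratio[1], 1)
  expect_error(goldberg_classify(2000, bmr = 0), "positive")
})

test_that("Goldberg classifier agrees with the three-branch oracle on a grid", {
  ratios <- c(seq(0.3, 3.2, length.out = 1e5), 1.05, 2.28,
              1.05 - 1e-12, 2.28 + 1e-12)
  got <- goldberg_classify(ratios, bmr = 1)
  expect_equal(as.character(got$reporter_class), oracle_goldberg(ratios))
  # exhaustive, mutually exclusive partition
  expect_false(any(is.na(got$reporter_class)))
})

test_that("weight stability uses a strict 2.5% threshold", {
  v <- weight_stability_check(74.22, 74.20)
  expect_equal(v$percent_change, 100 * 0.02 / 74.22)
  expect_false(v$unstable)
  expect_equal(weight_stability_check(80, 80)$percent_change, 0)
  unst <- weight_stability_check(80, 82.1)
  expect_equal(unst$percent_change, 2.625)
  expect_true(unst$unstable)
  expect_false(weight_stability_check(80, 82)$unstable) # exactly 2.5%
})

test_that("energy_profiles chains REE, PAL, TEE and Goldberg per participant", {
  study <- simulate_cohort(sim_config(n_participants = 15), seed = 8)
  bm <- biomarker_estimates(study$urine, study$participants)
  ei <- summarize_intake(study$intake_days, round = 1)
  ep <- energy_profiles(study$calorimetry, study$ipaq, bm, ei)
  expect_equal(nrow(ep), 15)
  expect_equal(ep$tee, ep$ree * ep$pal)
  expect_equal(ep$ei_bmr_ratio, ep$energy_intake / ep$ree)
  expect_setequal(levels(ep$reporter_class), c("UR", "AR", "OR"))
  expect_equal(ep$pal_excluded, ep$pal > 2.5)
})
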