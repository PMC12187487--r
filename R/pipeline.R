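#' Load a study dataset from a directory of CSV files
#'
#' Reads the table set written by [write_study()] (or assembled to the same
#' schema from a real study export): `participants.csv`, `intake_days.csv`,
#' `urine.csv`, `serum.csv`, `calorimetry.csv`, `ipaq.csv`, and optionally
#' `truth.csv`. Unknown nutrient columns in the intake table are kept but
#' reported with a warning; missing required files or columns are named
#' errors.
#'
#' @param dir Directory containing the CSV files.
#' @return A `study_dataset`.
#' @export
load_study <- function(dir) {
  required <- c("participants", "intake_days", "urine", "serum",
                "calorimetry", "ipaq")
  paths <- file.path(dir, paste0(required, ".csv"))
  absent <- required[!file.exists(paths)]
  if (length(absent) > 0) {
    abort(sprintf("Missing study file(s) in %s: %s", dir,
                  paste0(absent, ".csv", collapse = ", ")))
  }
  tabs <- lapply(paths, readr::read_csv, show_col_types = FALSE)
  names(tabs) <- required

  must_have <- list(
    participants = c("participant_id", "sex", "age", "weight_v1_kg",
                     "weight_v2_kg"),
    intake_days = c("participant_id", "round", "day"),
    urine = c("participant_id", "urea_mmol", "potassium_mg", "creatinine_mg"),
    serum = c("participant_id", "folate_ng_ml"),
    calorimetry = c("participant_id", "vo2_l_min", "vco2_l_min"),
    ipaq = c("participant_id", "vigorous_min_per_day", "moderate_min_per_day",
             "walking_min_per_day", "sitting_h_per_day")
  )
  for (tab in names(must_have)) {
    miss <- setdiff(must_have[[tab]], names(tabs[[tab]]))
    if (length(miss) > 0) {
      abort(sprintf("`%s.csv` is missing column(s): %s", tab,
                    paste(miss, collapse = ", ")))
    }
  }
  if (nrow(tabs$intake_days) == 0) {
    abort("`intake_days.csv` is empty; nothing to analyse.")
  }
  known <- c("participant_id", "round", "day", .nutrients,
             paste0("supp_", .supp_nutrients))
  extra <- setdiff(names(tabs$intake_days), known)
  if (length(extra) > 0) {
    warn(sprintf("Unknown intake column(s) kept but not analysed: %s",
                 paste(extra, collapse = ", ")))
  }
  truth_path <- file.path(dir, "truth.csv")
  tabs$truth <- if (file.exists(truth_path)) {
    readr::read_csv(truth_path, show_col_types = FALSE)
  } else {
    NULL
  }
  structure(tabs, class = "study_dataset")
}

#' Per-participant intake summaries for one record round
#'
#' Summarises the reported intake days of a round either as the mean over all
#' completed days (`weekly_average`, the primary exposure) or as the final
#' registered day (`last_day`, the day of the urine collection in round 1).
#' Total intakes add the supplement contribution to the dietary value
#' (`total_folate`, `total_calcium`, `total_vitamin_d`), and
#' `fruit_veg = fruit + vegetables`.
#'
#' @param intake_days Intake-day tibble (see [simulate_cohort()]).
#' @param round Record round to summarise (1 or 2).
#' @param window `"weekly_average"` (default) or `"last_day"`.
#' @return A tibble, one row per participant with at least one completed day:
#'   `participant_id`, `days_completed`, the nutrient columns, `total_*`
#'   and `fruit_veg`.
#' @examples
#' study <- simulate_cohort(sim_config(n_participants = 6), seed = 3)
#' summarize_intake(study$intake_days, round = 1)
#' @export
summarize_intake <- function(intake_days, round = 1,
                             window = c("weekly_average", "last_day")) {
  window <- arg_match(window)
  nut_cols <- intersect(.nutrients, names(intake_days))
  supp_cols <- intersect(paste0("supp_", .supp_nutrients), names(intake_days))
  d <- intake_days %>% filter(.data$round == .env$round)
  if (nrow(d) == 0) {
    abort(sprintf("No completed days in round %d.", round))
  }
  if (window == "last_day") {
    d <- d %>%
      group_by(.data$participant_id) %>%
      mutate(days_completed = dplyr::n()) %>%
      filter(.data$day == max(.data$day)) %>%
      ungroup()
    out <- d %>% select("participant_id", "days_completed",
                        all_of(c(nut_cols, supp_cols)))
  } else {
    out <- d %>%
      group_by(.data$participant_id) %>%
      summarise(
        days_completed = dplyr::n(),
        across(all_of(c(nut_cols, supp_cols)), mean),
        .groups = "drop"
      )
  }
  for (v in .supp_nutrients) {
    sup <- paste0("supp_", v)
    if (v %in% nut_cols) {
      out[[paste0("total_", v)]] <- out[[v]] +
        if (sup %in% supp_cols) out[[sup]] else 0
    }
  }
  if (all(c("fruit", "vegetables") %in% nut_cols)) {
    out$fruit_veg <- out$fruit + out$vegetables
  }
  out
}

# the variable pairs of the validity analysis; unit_match marks pairs on a
# common scale where Bland-Altman and percent bias are meaningful
.validity_pairs <- function(creatinine_corrected) {
  prot <- if (creatinine_corrected) "protein_corrected" else "protein_intake_est"
  pot <- if (creatinine_corrected) "potassium_corrected" else "potassium_intake_est"
  tibble(
    pair = c("energy_vs_tee", "energy_vs_ree", "protein_vs_urinary_protein",
             "potassium_vs_urinary_potassium", "total_folate_vs_serum_folate",
             "fruit_veg_vs_serum_folate", "fruit_veg_vs_urinary_potassium"),
    intake_var = c("energy", "energy", "protein", "potassium", "total_folate",
                   "fruit_veg", "fruit_veg"),
    biomarker_var = c("tee", "ree", prot, pot, "folate_ng_ml", "folate_ng_ml",
                      "potassium_mg"),
    unit_match = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE)
  )
}

#' Run the validity analysis of a study
#'
#' Compares reported intakes with the corresponding objective measures for
#' every configured variable pair, under the weekly-average and/or last-day
#' exposure windows: banded Spearman correlation, crude and age/sex-adjusted
#' regression R-squared, and — for pairs on a common scale — Bland-Altman
#' agreement and signed percent bias. Participants with PAL above `pal_max`
#' are excluded; reporter classes are counted via the Goldberg cut-offs, and
#' under-reporters are retained unless `keep_underreporters = FALSE`.
#'
#' @param study A `study_dataset`.
#' @param windows Exposure windows to run (default both).
#' @param creatinine_corrected Use creatinine-corrected urinary biomarkers?
#' @param keep_underreporters Keep Goldberg under-reporters? Default `TRUE`.
#' @param pal_max PAL exclusion threshold (default 2.5).
#' @param goldberg_lower,goldberg_upper Goldberg cut-offs.
#' @return An object of class `validity_report`: `$table` (one row per pair
#'   and window), `$bland_altman` (named list of [bland_altman()] objects for
#'   the unit-matched pairs under the weekly window), `$reporters` (Goldberg
#'   class counts), `$exclusions` (accounting), plus [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @examples
#' study <- simulate_cohort(sim_config(n_participants = 30), seed = 4)
#' rep <- run_validity(study, windows = "weekly_average")
#' tidy(rep)
#' @export
run_validity <- function(study,
                         windows = c("weekly_average", "last_day"),
                         creatinine_corrected = FALSE,
                         keep_underreporters = TRUE,
                         pal_max = 2.5,
                         goldberg_lower = 1.05, goldberg_upper = 2.28) {
  stopifnot(inherits(study, "study_dataset"))
  windows <- match.arg(windows, c("weekly_average", "last_day"),
                       several.ok = TRUE)
  bm <- biomarker_estimates(study$urine, study$participants)
  weekly <- summarize_intake(study$intake_days, round = 1,
                             window = "weekly_average")
  ep <- energy_profiles(study$calorimetry, study$ipaq, bm,
                        weekly %>% select("participant_id", "energy"),
                        goldberg_lower = goldberg_lower,
                        goldberg_upper = goldberg_upper, pal_max = pal_max)
  n_input <- nrow(study$participants)
  reporters <- ep %>%
    dplyr::count(.data$reporter_class, .drop = FALSE) %>%
    mutate(proportion = .data$n / sum(.data$n))

  keep_ids <- ep$participant_id[!ep$pal_excluded]
  if (!keep_underreporters) {
    keep_ids <- intersect(keep_ids,
                          ep$participant_id[ep$reporter_class != "UR"])
  }
  n_pal_excluded <- sum(ep$pal_excluded)
  n_ur_excluded <- n_input - n_pal_excluded - length(keep_ids)

  urine_vars <- study$urine %>% select("participant_id", "potassium_mg")
  reference <- ep %>%
    select("participant_id", "ree", "tee") %>%
    left_join(bm, by = "participant_id") %>%
    left_join(study$serum, by = "participant_id") %>%
    left_join(urine_vars, by = "participant_id") %>%
    left_join(study$participants %>%
                select("participant_id", "age", "sex"),
              by = "participant_id") %>%
    filter(.data$participant_id %in% keep_ids)

  pairs <- .validity_pairs(creatinine_corrected)
  ba_list <- list()
  rows <- list()
  for (w in windows) {
    intake <- summarize_intake(study$intake_days, round = 1, window = w)
    merged <- reference %>% left_join(intake, by = "participant_id")
    for (i in seq_len(nrow(pairs))) {
      p <- pairs[i, ]
      x <- merged[[p$intake_var]]
      y <- merged[[p$biomarker_var]]
      ok <- complete.cases(x, y)
      n_ok <- sum(ok)
      row <- tibble(pair = p$pair, window = w, intake_var = p$intake_var,
                    biomarker_var = p$biomarker_var, n = n_ok,
                    estimable = n_ok >= 3)
      if (n_ok >= 3) {
        sp <- spearman_banded(x[ok], y[ok])
        r2c <- regression_r2(merged[ok, ], p$biomarker_var, p$intake_var)
        r2a <- regression_r2(merged[ok, ], p$biomarker_var, p$intake_var,
                             covariates = c("age", "sex"))
        row <- row %>% mutate(
          rho = sp$rho, p_value = sp$p_value, band = as.character(sp$band),
          r2_crude = r2c$r_squared, r2_adjusted = r2a$r_squared
        )
        if (p$unit_match) {
          ba <- bland_altman(x[ok], y[ok])
          row <- row %>% mutate(
            mean_diff = ba$stats$mean_diff, loa_low = ba$stats$loa_low,
            loa_high = ba$stats$loa_high,
            bias_pct = percent_bias(mean(x[ok]), mean(y[ok]))
          )
          if (w == "weekly_average") ba_list[[p$pair]] <- ba
        } else {
          row <- row %>% mutate(mean_diff = NA_real_, loa_low = NA_real_,
                                loa_high = NA_real_, bias_pct = NA_real_)
        }
      } else {
        row <- row %>% mutate(
          rho = NA_real_, p_value = NA_real_, band = NA_character_,
          r2_crude = NA_real_, r2_adjusted = NA_real_, mean_diff = NA_real_,
          loa_low = NA_real_, loa_high = NA_real_, bias_pct = NA_real_
        )
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  exclusions <- tibble(
    n_input = n_input,
    n_pal_excluded = n_pal_excluded,
    n_underreporters_excluded = n_ur_excluded,
    n_analyzed = length(keep_ids)
  )
  structure(
    list(table = list_rbind(rows), bland_altman = ba_list,
         reporters = reporters, exclusions = exclusions,
         settings = list(creatinine_corrected = creatinine_corrected,
                         keep_underreporters = keep_underreporters,
                         pal_max = pal_max,
                         goldberg = c(goldberg_lower, goldberg_upper),
                         windows = windows)),
    class = "validity_report"
  )
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("<validity_report> %d pair-window rows; n analyzed = %d of %d\n",
              nrow(x$table), x$exclusions$n_analyzed, x$exclusions$n_input))
  print(x$table %>% select("pair", "window", "n", "rho", "band",
                           "r2_crude", "bias_pct"), n = Inf)
  invisible(x)
}

#' @export
tidy.validity_report <- function(x, ...) x$table

#' @export
glance.validity_report <- function(x, ...) {
  ar <- x$reporters %>% filter(.data$reporter_class == "AR")
  tibble(
    n_input = x$exclusions$n_input,
    n_analyzed = x$exclusions$n_analyzed,
    n_pal_excluded = x$exclusions$n_pal_excluded,
    acceptable_reporter_pct = 100 * ar$proportion
  )
}

#' Variables available for the reproducibility analysis
#'
#' The default list covers every nutrient and food group in the simulated
#' intake schema.
#'
#' @return Character vector of variable names.
#' @export
reproducibility_vars <- function() {
  c("energy", "protein", "fibre", "calcium", "potassium", "vitamin_c",
    "vitamin_d", "sodium", "folate", "vegetables", "fruit", "fish", "meat")
}

#' Run the reproducibility analysis between the two record rounds
#'
#' For each variable, compares the per-participant weekly averages of round 1
#' and round 2: median and IQR per round, banded Spearman correlation,
#' Wilcoxon signed-rank test, Bland-Altman agreement of the round means,
#' single-measure absolute-agreement ICC, and the Shapiro-Wilk normality
#' route. Participants present in only one round are excluded from the paired
#' statistics and counted.
#'
#' @param study A `study_dataset`.
#' @param vars Variables to analyse (default [reproducibility_vars()]).
#' @return An object of class `reproducibility_report` with `$table`,
#'   `$bland_altman` (per variable), `$exclusions`, and [tidy()] /
#'   [glance()] / [autoplot()] methods.
#' @examples
#' study <- simulate_cohort(sim_config(n_participants = 30), seed = 5)
#' tidy(run_reproducibility(study, vars = c("energy", "protein")))
#' @export
run_reproducibility <- function(study, vars = reproducibility_vars()) {
  stopifnot(inherits(study, "study_dataset"))
  unknown <- setdiff(vars, .nutrients)
  if (length(unknown) > 0) {
    abort(sprintf("Variable(s) not in the intake schema: %s",
                  paste(unknown, collapse = ", ")))
  }
  s1 <- summarize_intake(study$intake_days, round = 1)
  s2 <- summarize_intake(study$intake_days, round = 2)
  paired <- s1 %>%
    select("participant_id", all_of(vars)) %>%
    dplyr::inner_join(s2 %>% select("participant_id", all_of(vars)),
                      by = "participant_id", suffix = c("_r1", "_r2"))
  n_unpaired <- dplyr::n_distinct(c(s1$participant_id, s2$participant_id)) -
    nrow(paired)
  rows <- list()
  ba_list <- list()
  for (v in vars) {
    x1 <- paired[[paste0(v, "_r1")]]
    x2 <- paired[[paste0(v, "_r2")]]
    sp <- spearman_banded(x1, x2)
    wil <- tryCatch(wilcoxon_signed_rank(x1, x2),
                    error = function(e) tibble(statistic = NA_real_,
                                               n_informative = NA_integer_,
                                               p_value = NA_real_,
                                               method = conditionMessage(e)))
    ba <- bland_altman(x1, x2)
    ba_list[[v]] <- ba
    icc <- tryCatch(icc_agreement(x1, x2)$icc,
                    error = function(e) NA_real_)
    gate <- normality_gate(x1)
    rows[[length(rows) + 1]] <- tibble(
      variable = v, n = sp$n,
      median_r1 = median(x1), q1_r1 = unname(quantile(x1, 0.25)),
      q3_r1 = unname(quantile(x1, 0.75)),
      median_r2 = median(x2), q1_r2 = unname(quantile(x2, 0.25)),
      q3_r2 = unname(quantile(x2, 0.75)),
      rho = sp$rho, rho_p = sp$p_value, band = as.character(sp$band),
      wilcoxon_p = wil$p_value,
      mean_diff = ba$stats$mean_diff, loa_low = ba$stats$loa_low,
      loa_high = ba$stats$loa_high,
      icc = icc, normality_route = gate$route, normality_scale = gate$scale
    )
  }
  structure(
    list(table = list_rbind(rows), bland_altman = ba_list,
         exclusions = tibble(n_paired = nrow(paired),
                             n_single_round = n_unpaired)),
    class = "reproducibility_report"
  )
}

#' @export
print.reproducibility_report <- function(x, ...) {
  cat(sprintf("<reproducibility_report> %d variables, n paired = %d\n",
              nrow(x$table), x$exclusions$n_paired))
  print(x$table %>% select("variable", "n", "median_r1", "median_r2", "rho",
                           "band", "wilcoxon_p", "icc"), n = Inf)
  invisible(x)
}

#' @export
tidy.reproducibility_report <- function(x, ...) x$table

#' @export
glance.reproducibility_report <- function(x, ...) {
  tibble(
    n_paired = x$exclusions$n_paired,
    n_variables = nrow(x$table),
    median_rho = median(x$table$rho),
    min_rho = min(x$table$rho),
    max_rho = max(x$table$rho)
  )
}

#' Write analysis reports to CSV files
#'
#' Writes `validity_table.csv`, `reproducibility_table.csv`, `reporters.csv`,
#' one `bland_altman_<name>.csv` of plot coordinates per stored pair, and a
#' `run_log.txt` echoing settings and exclusion accounting.
#'
#' @param validity A `validity_report`, or `NULL`.
#' @param reproducibility A `reproducibility_report`, or `NULL`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(validity = NULL, reproducibility = NULL, out_dir) {
  if (is.null(validity) && is.null(reproducibility)) {
    abort("Nothing to write: both reports are NULL.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  log_lines <- c(sprintf("dietvalidr report written %s",
                         format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path)
    written <<- c(written, path)
  }
  if (!is.null(validity)) {
    stopifnot(inherits(validity, "validity_report"))
    wr(validity$table, "validity_table.csv")
    wr(validity$reporters, "reporters.csv")
    for (nm in names(validity$bland_altman)) {
      wr(tidy(validity$bland_altman[[nm]]),
         sprintf("bland_altman_%s.csv", nm))
    }
    ex <- validity$exclusions
    if (ex$n_input != ex$n_analyzed + ex$n_pal_excluded +
        ex$n_underreporters_excluded) {
      abort("Exclusion accounting does not reconcile with the input count.")
    }
    log_lines <- c(
      log_lines,
      sprintf("validity: creatinine_corrected=%s keep_underreporters=%s pal_max=%g goldberg=[%g,%g]",
              validity$settings$creatinine_corrected,
              validity$settings$keep_underreporters,
              validity$settings$pal_max,
              validity$settings$goldberg[1], validity$settings$goldberg[2]),
      sprintf("validity exclusions: input=%d pal_excluded=%d ur_excluded=%d analyzed=%d",
              ex$n_input, ex$n_pal_excluded, ex$n_underreporters_excluded,
              ex$n_analyzed)
    )
  }
  if (!is.null(reproducibility)) {
    stopifnot(inherits(reproducibility, "reproducibility_report"))
    wr(reproducibility$table, "reproducibility_table.csv")
    log_lines <- c(
      log_lines,
      sprintf("reproducibility: paired=%d single_round=%d",
              reproducibility$exclusions$n_paired,
              reproducibility$exclusions$n_single_round)
    )
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(c(written, file.path(out_dir, "run_log.txt")))
}
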