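#' Interpretation band for a correlation coefficient
#'
#' Bands used for reading validity and reproducibility correlations:
#' below 0.20 poor, 0.20 up to (but excluding) 0.50 acceptable, 0.50 and
#' above strong. Banding is applied to the coefficient as reported (signed);
#' a negative coefficient is therefore "poor".
#'
#' @param rho Correlation coefficient(s) in \[-1, 1\].
#' @return Factor with levels poor/acceptable/strong.
#' @examples
#' rho_band(c(0.19, 0.20, 0.49, 0.50))
#' @export
rho_band <- function(rho) {
  cls <- case_when(
    rho >= 0.50 ~ "strong",
    rho >= 0.20 ~ "acceptable",
    .default = "poor"
  )
  cls[is.na(rho)] <- NA
  factor(cls, levels = c("poor", "acceptable", "strong"))
}

#' Spearman rank correlation with interpretation band
#'
#' Spearman's rho on midranks, with a two-sided p-value (exact for n <= 9
#' without ties, asymptotic t approximation otherwise) and the poor /
#' acceptable / strong band attached. Incomplete pairs are dropped listwise.
#'
#' @param x,y Paired numeric vectors.
#' @return One-row tibble: `rho`, `abs_rho`, `p_value`, `n`, `band`.
#' @examples
#' spearman_banded(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5)) # rho = 0.8
#' @export
spearman_banded <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal lengths.")
  keep <- complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) abort("At least 3 complete pairs are required.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Spearman's rho is undefined for a constant vector.")
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = (n <= 9 && !ties), alternative = "two.sided")
  )
  rho <- unname(ct$estimate)
  tibble(rho = rho, abs_rho = abs(rho), p_value = ct$p.value, n = n,
         band = rho_band(rho))
}

#' Variance explained by ordinary least squares
#'
#' Fits `outcome ~ predictors (+ covariates)` by OLS on a data frame and
#' reports the unadjusted R-squared together with the coefficient table.
#' Covariate adjustment (typically age and sex) appends the covariates as
#' additional model terms.
#'
#' @param data A data frame.
#' @param outcome Name of the outcome column (string).
#' @param predictors Character vector of predictor columns.
#' @param covariates Optional character vector of adjustment columns.
#' @return An object of class `regression_result` with [tidy()] (coefficient
#'   table) and [glance()] (R-squared, n) methods.
#' @examples
#' d <- data.frame(x = 1:6, y = 2 * (1:6))
#' glance(regression_r2(d, "y", "x"))
#' @export
regression_r2 <- function(data, outcome, predictors, covariates = NULL) {
  cols <- c(outcome, predictors, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Column(s) not in `data`: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  d <- data[cols]
  d <- d[complete.cases(d), , drop = FALSE]
  n_terms <- length(predictors) + length(covariates)
  if (nrow(d) <= n_terms + 1) {
    abort("Not enough complete rows for the requested model.")
  }
  rhs <- paste(vapply(c(predictors, covariates),
                      function(v) sprintf("`%s`", v), character(1)),
               collapse = " + ")
  fml <- stats::as.formula(sprintf("`%s` ~ %s", outcome, rhs))
  fit <- lm(fml, data = d)
  if (any(is.na(coef(fit)))) {
    abort("Rank-deficient design: some coefficients are not estimable.")
  }
  # a perfect fit is a legitimate degenerate input (zero-noise data), not a
  # condition the caller needs to hear about
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  coefs <- as.data.frame(sm$coefficients)
  tss <- sum((d[[outcome]] - mean(d[[outcome]]))^2)
  r2 <- if (tss == 0) 0 else 1 - sum(stats::residuals(fit)^2) / tss
  structure(
    list(
      r_squared = r2,
      coefficients = tibble(
        term = rownames(coefs),
        estimate = coefs[["Estimate"]],
        std_error = coefs[["Std. Error"]],
        p_value = coefs[["Pr(>|t|)"]]
      ),
      outcome = outcome,
      predictors = predictors,
      covariates = covariates %||% character(),
      n = nrow(d)
    ),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  adj <- if (length(x$covariates) > 0) {
    sprintf(" (adjusted for %s)", paste(x$covariates, collapse = ", "))
  } else ""
  cat(sprintf("<regression_result> %s ~ %s%s\n", x$outcome,
              paste(x$predictors, collapse = " + "), adj))
  cat(sprintf("  R-squared = %.4f, n = %d\n", x$r_squared, x$n))
  invisible(x)
}

#' @export
tidy.regression_result <- function(x, ...) x$coefficients

#' @export
glance.regression_result <- function(x, ...) {
  tibble(r_squared = x$r_squared, n = x$n,
         adjusted_for = paste(x$covariates, collapse = "+"))
}

#' Bland-Altman agreement analysis
#'
#' Computes the mean of the paired differences `a - b`, their sample standard
#' deviation (denominator n - 1), and the limits of agreement
#' `mean +/- 1.96 x SD`, together with the per-pair (mean, difference)
#' coordinates used for plotting.
#'
#' @param a,b Paired numeric vectors (method A and method B).
#' @return An object of class `bland_altman`; [glance()] returns `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `n`; [tidy()] returns the per-pair
#'   coordinates; [autoplot()] draws the plot.
#' @examples
#' ba <- bland_altman(c(10, 12, 14, 11), c(11, 11, 15, 10))
#' glance(ba)
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal lengths.")
  keep <- complete.cases(a, b)
  a <- a[keep]
  b <- b[keep]
  if (length(a) < 2) abort("At least 2 complete pairs are required.")
  d <- a - b
  m <- (a + b) / 2
  mean_diff <- mean(d)
  sd_diff <- sd(d)
  structure(
    list(
      stats = tibble(
        mean_diff = mean_diff,
        sd_diff = sd_diff,
        loa_low = mean_diff - 1.96 * sd_diff,
        loa_high = mean_diff + 1.96 * sd_diff,
        n = length(d)
      ),
      data = tibble(pair_mean = m, pair_diff = d)
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<bland_altman> n = %d\n", s$n))
  cat(sprintf("  mean difference %.4g, SD %.4g\n", s$mean_diff, s$sd_diff))
  cat(sprintf("  limits of agreement [%.4g, %.4g]\n", s$loa_low, s$loa_high))
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) x$data

#' @export
glance.bland_altman <- function(x, ...) x$stats

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on the paired differences `a - b`. Zero differences are
#' dropped before ranking (the classical Wilcoxon convention; set
#' `zero_method = "pratt"` to rank them first and drop them from the
#' statistic). With at most `exact_max` informative pairs the p-value comes
#' from the exact null distribution of the signed-rank statistic (the
#' tabulated distribution for untied ranks; direct enumeration over sign
#' assignments when absolute differences tie); beyond that a normal
#' approximation with the tie correction is used (no continuity correction).
#'
#' @param a,b Paired numeric vectors.
#' @param zero_method `"drop"` (default) or `"pratt"`.
#' @param exact_max Largest informative n for the exact path (default 12).
#' @return One-row tibble: `statistic` (W+, the sum of ranks of positive
#'   differences), `n_informative`, `p_value`, `method`.
#' @examples
#' wilcoxon_signed_rank(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 5)) # p = 0.0625
#' @export
wilcoxon_signed_rank <- function(a, b, zero_method = c("drop", "pratt"),
                                 exact_max = 12) {
  zero_method <- arg_match(zero_method)
  if (length(a) != length(b)) abort("`a` and `b` must have equal lengths.")
  keep <- complete.cases(a, b)
  d <- (a - b)[keep]
  nonzero <- d != 0
  n_inf <- sum(nonzero)
  if (n_inf == 0) abort("All paired differences are zero; the test is degenerate.")
  if (n_inf < 5) {
    abort("At least 5 informative (nonzero-difference) pairs are required.")
  }
  if (zero_method == "drop") {
    dd <- d[nonzero]
    r <- rank(abs(dd))
    w_plus <- sum(r[dd > 0])
    ties <- table(r)
    has_ties <- any(ties > 1)
    if (n_inf <= exact_max && !has_ties) {
      p <- .signrank_exact_p(w_plus, n_inf)
      method <- "exact"
    } else if (n_inf <= exact_max) {
      p <- .signrank_enum_p(w_plus, r)
      method <- "exact (enumerated, tied ranks)"
    } else {
      mu <- n_inf * (n_inf + 1) / 4
      sigma2 <- n_inf * (n_inf + 1) * (2 * n_inf + 1) / 24 -
        sum(ties^3 - ties) / 48
      p <- 2 * pnorm(-abs(w_plus - mu) / sqrt(sigma2))
      method <- "normal approximation"
    }
  } else {
    # Pratt: rank |d| with zeros included, discard zero ranks from W+
    r <- rank(abs(d))
    w_plus <- sum(r[d > 0])
    n_all <- length(d)
    n0 <- n_all - n_inf
    mu <- (n_all * (n_all + 1) - n0 * (n0 + 1)) / 4
    ties <- table(r[d != 0])
    sigma2 <- (n_all * (n_all + 1) * (2 * n_all + 1) -
                 n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
      sum(ties^3 - ties) / 48
    p <- 2 * pnorm(-abs(w_plus - mu) / sqrt(sigma2))
    method <- "normal approximation (Pratt)"
  }
  tibble(statistic = w_plus, n_informative = n_inf,
         p_value = min(p, 1), method = method)
}

# exact two-sided p with tied midranks: walk the null distribution of W+
# over all sign assignments by convolution
.signrank_enum_p <- function(w, r) {
  # support of W+ on the half-rank grid; convolve one rank at a time
  grid <- seq(0, sum(r), by = 0.5)
  prob <- numeric(length(grid))
  prob[1] <- 1
  for (ri in r) {
    shift <- as.integer(ri / 0.5)
    shifted <- c(numeric(shift), prob[seq_len(length(prob) - shift)])
    prob <- (prob + shifted) / 2
  }
  p_le <- sum(prob[grid <= w + 1e-9])
  p_ge <- sum(prob[grid >= w - 1e-9])
  min(1, 2 * min(p_le, p_ge))
}

# exact two-sided p for the signed-rank statistic, no ties
.signrank_exact_p <- function(w, n) {
  if (w > n * (n + 1) / 4) {
    p <- 2 * (1 - psignrank(w - 1, n))
  } else {
    p <- 2 * psignrank(w, n)
  }
  min(p, 1)
}

#' Paired t-test
#'
#' Classical paired t on the differences `a - b` with `n - 1` degrees of
#' freedom. Identical vectors return `t = 0, p = 1`; a constant nonzero
#' difference (zero variance, nonzero mean) is rejected as degenerate.
#'
#' @param a,b Paired numeric vectors.
#' @return One-row tibble: `t`, `df`, `p_value`, `mean_diff`, `n`.
#' @examples
#' paired_t(c(74.2, 75.1, 73.8), c(74.0, 75.3, 73.5))
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal lengths.")
  keep <- complete.cases(a, b)
  d <- (a - b)[keep]
  n <- length(d)
  if (n < 2) abort("At least 2 complete pairs are required.")
  md <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (md != 0) {
      abort("Differences have zero variance with nonzero mean; t is degenerate.")
    }
    return(tibble(t = 0, df = n - 1, p_value = 1, mean_diff = 0, n = n))
  }
  tstat <- md / (s / sqrt(n))
  tibble(t = tstat, df = n - 1,
         p_value = 2 * pt(-abs(tstat), df = n - 1),
         mean_diff = md, n = n)
}

#' Intraclass correlation between two measurement rounds
#'
#' Single-measure ICC from the two-way ANOVA decomposition of the n x 2
#' subject-by-round matrix. The default, absolute agreement under a two-way
#' mixed-effects model (ICC(A,1)), penalises systematic round differences;
#' `type = "consistency"` (ICC(C,1)) does not.
#'
#' @param round1,round2 Paired numeric vectors.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return One-row tibble: `icc`, `type`, `n`.
#' @examples
#' icc_agreement(c(1, 2, 3, 4), c(1.1, 2.2, 2.9, 4.3))
#' @export
icc_agreement <- function(round1, round2,
                          type = c("agreement", "consistency")) {
  type <- arg_match(type)
  if (length(round1) != length(round2)) {
    abort("`round1` and `round2` must have equal lengths.")
  }
  keep <- complete.cases(round1, round2)
  x <- cbind(round1[keep], round2[keep])
  n <- nrow(x)
  k <- 2
  if (n < 3) abort("At least 3 complete pairs are required.")
  grand <- mean(x)
  if (sum((x - grand)^2) == 0) {
    abort("Zero total variance; the ICC is undefined.")
  }
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((x - grand)^2) - k * sum((row_means - grand)^2) -
    n * sum((col_means - grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- if (type == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  tibble(icc = icc, type = type, n = n)
}

#' Normality gate for choosing parametric vs nonparametric summaries
#'
#' Shapiro-Wilk at `alpha` on the raw values; if normality is rejected and all
#' values are positive, the test is retried on the log scale. The returned
#' route says whether parametric methods are defensible and on which scale;
#' nonparametric variables should be summarised as median and IQR.
#'
#' @param values Numeric vector, 3 <= n <= 5000.
#' @param alpha Significance level (default 0.05).
#' @param log_retry Retry on the log scale after rejection? Default `TRUE`.
#' @return One-row tibble: `route` ("parametric"/"nonparametric"), `scale`
#'   ("raw"/"log"), `shapiro_p_raw`, `shapiro_p_log`, `n`, `note`.
#' @examples
#' set.seed(1)
#' normality_gate(rnorm(100))
#' @export
normality_gate <- function(values, alpha = 0.05, log_retry = TRUE) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000) {
    abort("Shapiro-Wilk requires between 3 and 5000 values.")
  }
  p_raw <- shapiro.test(values)$p.value
  if (p_raw >= alpha) {
    return(tibble(route = "parametric", scale = "raw",
                  shapiro_p_raw = p_raw, shapiro_p_log = NA_real_,
                  n = n, note = ""))
  }
  if (!log_retry) {
    return(tibble(route = "nonparametric", scale = "raw",
                  shapiro_p_raw = p_raw, shapiro_p_log = NA_real_,
                  n = n, note = "log retry disabled"))
  }
  if (any(values <= 0)) {
    return(tibble(route = "nonparametric", scale = "raw",
                  shapiro_p_raw = p_raw, shapiro_p_log = NA_real_, n = n,
                  note = "log retry skipped: non-positive values"))
  }
  p_log <- shapiro.test(log(values))$p.value
  if (p_log >= alpha) {
    tibble(route = "parametric", scale = "log", shapiro_p_raw = p_raw,
           shapiro_p_log = p_log, n = n, note = "normal after log transform")
  } else {
    tibble(route = "nonparametric", scale = "raw", shapiro_p_raw = p_raw,
           shapiro_p_log = p_log, n = n,
           note = "non-normal even after log transform")
  }
}

#' Signed percent bias between a reported and a biomarker-based mean
#'
#' `100 x (reported - biomarker) / denominator`, where the denominator is the
#' biomarker mean by default (bias relative to the objective measure) or the
#' reported mean.
#'
#' @param reported_mean,biomarker_mean Group means on the same scale.
#' @param denominator `"biomarker"` (default) or `"reported"`.
#' @return Signed percent bias (scalar).
#' @examples
#' percent_bias(86, 82)                              # +4.88 %
#' percent_bias(3124, 4267, denominator = "reported") # -36.6 %
#' @export
percent_bias <- function(reported_mean, biomarker_mean,
                         denominator = c("biomarker", "reported")) {
  denominator <- arg_match(denominator)
  den <- if (denominator == "biomarker") biomarker_mean else reported_mean
  if (any(den <= 0, na.rm = TRUE)) {
    abort("The denominator mean must be positive.")
  }
  100 * (reported_mean - biomarker_mean) / den
}
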