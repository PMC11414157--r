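test_that("binarize_cesd applies the >= cutoff and keeps missing scores", {
  expect_equal(binarize_cesd(c(0, 3, 4, 10)), c(0L, 0L, 1L, 1L))
  expect_true(is.na(binarize_cesd(NA)))
  expect_equal(binarize_cesd(3, cutoff = 3), 1L)
  expect_error(binarize_cesd(11), "0..10")
  expect_error(binarize_cesd(2.5), "0..10")
})

test_that("iqr uses linear interpolation between order statistics", {
  expect_equal(iqr(1:9), 4)          # Q1 = 3, Q3 = 7
  expect_equal(iqr(c(1, 2, 3, 4)), 1.5)  # positions 1.75 and 3.25
  expect_equal(iqr(rep(7, 10)), 0)
  expect_equal(iqr(c(NA, 1:9, NA)), 4)
  expect_error(iqr(c(NA, 1)), "at least two")
  # SAS-style alternative changes only the rule, not the ordering
  expect_equal(iqr(c(1, 2, 3, 4), quantile_type = 2L), 2)
})

test_that("design matrices have the documented column structure", {
  df <- make_full_level_cohort()
  spec <- model_spec()
  un <- build_design_matrix(df, spec, adjusted = FALSE)
  expect_equal(ncol(un$X), 2L)  # intercept + exposure
  expect_equal(un$labels, c("(Intercept)", "exposure"))
  ad <- build_design_matrix(df, spec, adjusted = TRUE)
  # 1 intercept + 1 exposure + (4+1+4+1+3+1+1+1+2) indicators + 4 continuous
  expect_equal(ncol(ad$X), 24L)
  expect_true(all(c("age_group60-64", "sexfemale", "income>=5M",
                    "maritalnever", "smokingyes", "hypertension",
                    "mean_temp", "population_density") %in% ad$labels))
  # reference levels are omitted from the columns
  expect_false(any(c("age_group70-74", "sexmale", "income<1M",
                     "education<=high-school", "maritalmarried",
                     "smokingno", "alcoholno", "physical_activityno") %in%
                     ad$labels))
  withdia <- build_design_matrix(df, model_spec(include_diabetes = TRUE))
  expect_equal(ncol(withdia$X), 25L)
  nopa <- build_design_matrix(df, model_spec(include_physical_activity = FALSE))
  expect_equal(ncol(nopa$X), 23L)
  # complete-case exclusions are counted
  df2 <- df
  df2$cesd[1:5] <- NA
  df2$exposure[6] <- NA
  dm2 <- build_design_matrix(df2, spec)
  expect_equal(dm2$n, nrow(df) - 6L)
  expect_equal(dm2$n_missing_outcome, 5L)
  expect_equal(dm2$n_missing_covariates, 1L)
  df3 <- df; df3$cesd <- NA
  expect_error(build_design_matrix(df3, spec), "no analyzable rows")
  df4 <- df; df4$cesd <- 9
  expect_error(build_design_matrix(df4, spec), "constant")
})

test_that("fit_logistic matches closed forms and glm", {
  d <- make_2x2(10, 20, 30, 40)
  f <- fit_logistic(d$y, cbind(`(Intercept)` = 1, exposure = d$x))
  expect_equal(unname(f$beta[2]), log(2 / 3), tolerance = 1e-9)
  expect_equal(unname(f$beta[1]), log(30 / 40), tolerance = 1e-9)
  expect_equal(unname(f$se[2]), sqrt(1 / 10 + 1 / 20 + 1 / 30 + 1 / 40),
               tolerance = 1e-6)
  # intercept-only: logit of prevalence
  f0 <- fit_logistic(rep(c(1, 0), c(25, 75)), matrix(1, 100, 1))
  expect_equal(unname(f0$beta[1]), log(25 / 75), tolerance = 1e-9)
  # random continuous designs: agree with glm to high precision
  set.seed(9)
  for (i in 1:5) {
    n <- 300
    X <- cbind(1, rnorm(n), runif(n))
    y <- rbinom(n, 1, plogis(X %*% c(-0.5, 0.8, -1.2)))
    f <- fit_logistic(y, X)
    g <- glm.fit(X, y, family = binomial(),
                 control = glm.control(epsilon = 1e-12))
    expect_equal(unname(f$beta), unname(coef(g)), tolerance = 1e-8)
    se_glm <- sqrt(diag(chol2inv(qr.R(g$qr))))
    expect_equal(unname(f$se), unname(se_glm), tolerance = 1e-6)
  }
})

test_that("fit_logistic flags degenerate problems", {
  # perfectly separated toy data
  x <- c(-3, -2, -1, 1, 2, 3)
  y <- c(0, 0, 0, 1, 1, 1)
  expect_error(fit_logistic(y, cbind(1, x)), "separat")
  # rank-deficient design
  X <- cbind(1, 1:10, 2 * (1:10))
  expect_error(fit_logistic(rep(c(0, 1), 5), X), "rank deficient")
  expect_error(fit_logistic(rep(1, 10), matrix(1, 10, 1)), "constant")
})

test_that("or_per_iqr scales coefficients with log-symmetric Wald intervals", {
  r <- or_per_iqr(0, 0.1, 2)
  expect_equal(r$or_, 1)
  expect_equal(r$ci_low, exp(-qnorm(0.975) * 0.2), tolerance = 1e-9)
  expect_equal(r$ci_high, exp(qnorm(0.975) * 0.2), tolerance = 1e-9)
  expect_equal(r$p, 1)
  expect_equal(or_per_iqr(log(0.5), 0.2, 1)$or_, 0.5)
  expect_equal(or_per_iqr(-0.2, 0.1, 2)$or_, exp(-0.4))
  # z at alpha = 0.05 is 1.959964
  expect_equal(qnorm(0.975), 1.959964, tolerance = 1e-6)
  r2 <- or_per_iqr(-0.3, 0.15, 1.7)
  expect_equal(log(r2$ci_low) + log(r2$ci_high), 2 * log(r2$or_),
               tolerance = 1e-12)
  expect_error(or_per_iqr(0.5, 0.1, 0), "IQR must be positive")
})

test_that("per-IQR odds ratios are invariant to affine exposure rescaling", {
  set.seed(12)
  df <- make_full_level_cohort(n = 300)
  df$cesd <- ifelse(runif(300) < plogis(-1 + 1.5 * df$exposure), 5L, 1L)
  tab0 <- data.frame(participant_id = df$id, metric = "ndvi", buffer_m = 250,
                     window = "annual", value = df$exposure)
  base <- run_association(df, validate_exposure_table(tab0), model_spec(),
                          "ndvi", 250, "annual", adjusted = FALSE)
  for (fac in c(0.5, 2)) {
    # positive scaling: same per-IQR OR, scaled IQR (values kept in [0, 1])
    tab <- tab0
    tab$value <- tab$value * fac / 2
    scaled <- run_association(df, validate_exposure_table(tab), model_spec(),
                              "ndvi", 250, "annual", adjusted = FALSE)
    expect_equal(scaled$or_, base$or_, tolerance = 1e-6)
    expect_equal(scaled$p, base$p, tolerance = 1e-6)
    expect_equal(scaled$iqr, base$iqr * fac / 2, tolerance = 1e-9)
  }
  # location shift
  tab_s <- tab0
  tab_s$value <- tab_s$value * 0.5 + 0.25
  shifted <- run_association(df, validate_exposure_table(tab_s), model_spec(),
                             "ndvi", 250, "annual", adjusted = FALSE)
  expect_equal(shifted$or_, base$or_, tolerance = 1e-6)
})

test_that("run_association composes exclusions, IQR and the fit", {
  set.seed(13)
  df <- make_full_level_cohort(n = 240)
  df$cesd <- ifelse(runif(240) < plogis(-1.2 + 1.2 * df$exposure), 6L, 2L)
  df$cesd[1:10] <- NA
  tab <- validate_exposure_table(
    data.frame(participant_id = df$id, metric = "ndvi", buffer_m = 250,
               window = "annual", value = df$exposure))
  r <- run_association(df, tab, model_spec(), "ndvi", 250, "annual",
                       adjusted = TRUE)
  expect_s3_class(r, "association_result")
  expect_equal(r$n, 230L)
  expect_equal(r$n_missing_outcome, 10L)
  # IQR is computed on the analysis sample, not all participants
  expect_equal(r$iqr, iqr(df$exposure[-(1:10)]))
  expect_true(r$ci_low <= r$or_ && r$or_ <= r$ci_high)
  expect_equal(r$or_, exp(r$beta * r$iqr), tolerance = 1e-12)
  expect_error(run_association(df, tab, model_spec(), "ndvi", 500, "annual"),
               "no exposure rows")
  # results table serialization
  rt <- results_table(list(r))
  expect_equal(rt$n, 230L)
  expect_equal(rt$or_, r$or_)
})

test_that("income strata form a partition at the 2M KRW line", {
  counts <- c("<1M" = 140, "1-2M" = 160, "2-3M" = 128, "3-5M" = 129,
              ">=5M" = 60)
  df <- data.frame(id = seq_len(617),
                   income = factor(rep(names(counts), counts),
                                   levels = names(counts)))
  s <- stratify_income(df)
  expect_equal(nrow(s$low), 300L)
  expect_equal(nrow(s$high), 317L)
  expect_length(intersect(s$low$id, s$high$id), 0L)
  expect_setequal(c(s$low$id, s$high$id), df$id)
  empty <- stratify_income(df[0, ])
  expect_equal(nrow(empty$low), 0L)
  expect_equal(nrow(empty$high), 0L)
})

test_that("monthly_series returns month-ordered results with per-month IQRs", {
  set.seed(14)
  df <- make_full_level_cohort(n = 200)
  df$cesd <- ifelse(runif(200) < 0.3, 6L, 2L)
  tabs <- lapply(1:12, function(m) {
    data.frame(participant_id = df$id, metric = "ndvi", buffer_m = 250,
               window = sprintf("month-%02d", m), value = df$exposure)
  })
  tab <- validate_exposure_table(do.call(rbind, tabs))
  res <- monthly_series(df, tab, model_spec(), buffer_m = 250)
  expect_length(res, 12L)
  expect_equal(vapply(res, function(r) r$window, character(1)),
               sprintf("month-%02d", 1:12))
  # identical exposure every month -> identical ORs
  ors <- vapply(res, function(r) r$or_, numeric(1))
  expect_equal(max(ors) - min(ors), 0, tolerance = 1e-9)
  # a fully-missing month is skipped with a warning
  tab2 <- tab
  tab2$value[tab2$window == "month-05"] <- NA
  expect_warning(res2 <- monthly_series(df, tab2, model_spec(), 250),
                 "month 05")
  expect_length(res2, 11L)
})

test_that("parameter recovery and CI coverage behave on simulated outcomes", {
  set.seed(15)
  n <- 800
  beta <- -0.9
  cover <- logical(40)
  est <- numeric(40)
  for (i in 1:40) {
    x <- runif(n)
    y <- rbinom(n, 1, plogis(-0.8 + beta * x))
    f <- fit_logistic(y, cbind(1, x))
    est[i] <- f$beta[2]
    ci <- f$beta[2] + c(-1, 1) * qnorm(0.975) * f$se[2]
    cover[i] <- ci[1] <= beta && beta <= ci[2]
  }
  expect_lt(abs(mean(est) - beta), 0.1)
  expect_gte(mean(cover), 0.85)
})

test_that("unadjusted and adjusted ORs agree when covariates are not confounders", {
  set.seed(16)
  df <- make_full_level_cohort(n = 900)
  # outcome depends on exposure only; covariates are pure noise
  df$cesd <- ifelse(runif(900) < plogis(-1.5 - 0.9 * df$exposure), 6L, 2L)
  tab <- validate_exposure_table(
    data.frame(participant_id = df$id, metric = "ndvi", buffer_m = 250,
               window = "annual", value = df$exposure))
  un <- run_association(df, tab, model_spec(), "ndvi", 250, "annual",
                        adjusted = FALSE)
  ad <- run_association(df, tab, model_spec(), "ndvi", 250, "annual",
                        adjusted = TRUE)
  expect_lt(abs(log(ad$or_) - log(un$or_)), 0.2)
})
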