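#' Analysis model specification
#'
#' Captures the outcome definition and adjustment set used by the association
#' stage: the CES-D-10 cutoff defining depressive symptoms (score >= cutoff),
#' whether physical activity and diabetes enter the adjustment set, the
#' significance level, and the quantile rule used for the exposure IQR.
#'
#' Reference levels for the categorical covariates are the modal or first
#' categories: age 70-74, male, income <1M, <=high-school, married, and "no"
#' for smoking/alcohol/physical activity.
#'
#' @param cutoff integer in 1..10; scores at or above it count as depressive
#'   symptoms (default 4).
#' @param include_physical_activity include the physical-activity indicator in
#'   the adjusted model (default TRUE).
#' @param include_diabetes include the diabetes indicator alongside
#'   hypertension and dyslipidemia (default FALSE).
#' @param alpha two-sided significance level for CIs and tests (default 0.05).
#' @param quantile_type quantile algorithm for the IQR: 7 (linear
#'   interpolation at `1 + (n-1)q`, the default) or 2 (SAS-style averaging of
#'   order statistics at discontinuities).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(cutoff = 4L, include_physical_activity = TRUE,
                       include_diabetes = FALSE, alpha = 0.05,
                       quantile_type = 7L) {
  stopifnot(cutoff == round(cutoff), cutoff >= 1, cutoff <= 10,
            alpha > 0, alpha < 1, quantile_type %in% c(2L, 7L))
  structure(list(cutoff = as.integer(cutoff),
                 include_physical_activity = isTRUE(include_physical_activity),
                 include_diabetes = isTRUE(include_diabetes),
                 alpha = alpha, quantile_type = as.integer(quantile_type)),
            class = "model_spec")
}

#' Binarize CES-D-10 scores
#'
#' Scores at or above the cutoff are coded 1 (depressive symptoms), below it
#' 0; missing scores stay `NA` and are excluded downstream with a reported
#' count.
#'
#' @param score integer vector of CES-D-10 totals (0-10) or `NA`.
#' @param cutoff cutoff score, default 4.
#' @return integer vector of 0/1/`NA`.
#' @examples
#' binarize_cesd(c(0, 3, 4, 10, NA))
#' @export
binarize_cesd <- function(score, cutoff = 4L) {
  bad <- which(!is.na(score) & (score != round(score) | score < 0 | score > 10))
  if (length(bad)) {
    stop(sprintf("CES-D scores must be integers in 0..10 (offending value %s)",
                 score[bad[1L]]), call. = FALSE)
  }
  as.integer(ifelse(is.na(score), NA, score >= cutoff))
}

#' Interquartile range of an exposure
#'
#' Q3 - Q1 with quartiles by linear interpolation between order statistics at
#' position `1 + (n-1)q` (quantile type 7); `quantile_type = 2` gives the
#' SAS-style empirical-distribution rule. The IQR choice affects per-IQR odds
#' ratios only through the scaling constant.
#'
#' @param values numeric vector; `NA` dropped; needs >= 2 non-missing values.
#' @param quantile_type 7 (default) or 2.
#' @return the IQR (>= 0; 0 for constant input).
#' @examples
#' iqr(1:9)        # 4
#' iqr(c(1, 2, 3, 4))  # 1.5
#' @export
iqr <- function(values, quantile_type = 7L) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) stop("need at least two non-missing values for an IQR",
                           call. = FALSE)
  q <- stats::quantile(v, probs = c(0.25, 0.75), type = quantile_type,
                       names = FALSE)
  q[2L] - q[1L]
}

# covariates entering the adjusted model, in design order
adjustment_covariates <- function(spec) {
  covs <- c("age_group", "sex", "income", "education", "marital",
            "smoking", "alcohol")
  if (spec$include_physical_activity) covs <- c(covs, "physical_activity")
  covs <- c(covs, "hypertension", "dyslipidemia")
  if (spec$include_diabetes) covs <- c(covs, "diabetes")
  c(covs, "mean_temp", "crime_rate", "population_density", "park_area_pc")
}

reference_levels <- c(age_group = "70-74", sex = "male", income = "<1M",
                      education = "<=high-school", marital = "married",
                      smoking = "no", alcohol = "no", physical_activity = "no")

#' Build the outcome vector and predictor matrix for a logistic model
#'
#' Drops rows with a missing outcome or any missing modeled field
#' (complete-case analysis) and reports the counts. The exposure enters as a
#' continuous column named `exposure` (unscaled; per-IQR scaling is applied to
#' the fitted coefficient). Categorical covariates enter as treatment
#' contrasts against fixed reference levels; levels absent from the analysis
#' sample are dropped so the matrix stays full rank.
#'
#' @param participants participant data.frame including an exposure column.
#' @param spec a [model_spec].
#' @param exposure_column name of the exposure column (default `"exposure"`).
#' @param adjusted if `FALSE`, the model is intercept + exposure only.
#' @return list with elements `y` (0/1 vector), `X` (model matrix), `labels`
#'   (column names), `n`, `n_cases`, `n_missing_outcome`,
#'   `n_missing_covariates`, and `rows` (row indices kept).
#' @export
build_design_matrix <- function(participants, spec = model_spec(),
                                exposure_column = "exposure", adjusted = TRUE) {
  df <- as.data.frame(participants)
  stopifnot(exposure_column %in% names(df))
  y_all <- binarize_cesd(df$cesd, spec$cutoff)
  covs <- if (adjusted) adjustment_covariates(spec) else character(0)
  model_cols <- c(exposure_column, covs)
  outcome_ok <- !is.na(y_all)
  n_missing_outcome <- sum(!outcome_ok)
  cov_ok <- rowSums(is.na(df[, model_cols, drop = FALSE])) == 0
  keep <- which(outcome_ok & cov_ok)
  n_missing_covariates <- sum(outcome_ok & !cov_ok)
  if (length(keep) == 0L) {
    stop("no analyzable rows remain after complete-case exclusions", call. = FALSE)
  }
  y <- y_all[keep]
  if (length(unique(y)) < 2L) {
    stop("outcome is constant in the analysis sample; model cannot be fit",
         call. = FALSE)
  }
  sub <- df[keep, , drop = FALSE]
  for (nm in intersect(covs, names(reference_levels))) {
    f <- droplevels(as.factor(sub[[nm]]))
    if (!(reference_levels[[nm]] %in% levels(f))) {
      sub[[nm]] <- f  # reference absent from sample: first remaining level
    } else {
      sub[[nm]] <- stats::relevel(f, ref = reference_levels[[nm]])
    }
  }
  for (nm in intersect(covs, c("hypertension", "dyslipidemia", "diabetes"))) {
    sub[[nm]] <- as.numeric(sub[[nm]])
  }
  sub$.exposure <- as.numeric(sub[[exposure_column]])
  rhs <- paste(c(".exposure", covs), collapse = " + ")
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = sub)
  colnames(X)[colnames(X) == ".exposure"] <- "exposure"
  list(y = y, X = X, labels = colnames(X),
       n = length(y), n_cases = sum(y),
       n_missing_outcome = n_missing_outcome,
       n_missing_covariates = n_missing_covariates,
       rows = keep)
}

#' Maximum-likelihood logistic regression by Newton/IRLS
#'
#' Maximizes the Bernoulli log-likelihood from a zero start by Newton's
#' method (iteratively reweighted least squares). Convergence is declared when
#' the largest absolute score falls below `tol_score`, the largest
#' coefficient update falls below `tol_beta`, or the log-likelihood has
#' plateaued (relative change below `tol_loglik`, the criterion that resolves
#' quasi-separated fits whose aliased coefficients drift toward infinity
#' while the likelihood no longer moves), within `max_iter` iterations.
#' The covariance is the inverse observed information at the optimum. Complete
#' separation (every observation fitted to its outcome, so the MLE is not
#' finite) and non-convergence raise errors; a quasi-separation diagnostic
#' (`n_pinned`: observations with fitted probability within 1e-8 of 0/1) is
#' returned for fits with isolated perfectly-predicted cells.
#'
#' @param y 0/1 outcome vector.
#' @param X numeric model matrix, full column rank, including the intercept.
#' @param max_iter,tol_score,tol_beta,tol_loglik convergence controls.
#' @return list with `beta` (named), `vcov`, `se`, `converged`, `iterations`,
#'   `n_pinned`, `loglik`.
#' @export
fit_logistic <- function(y, X, max_iter = 100L, tol_score = 1e-8,
                         tol_beta = 1e-10, tol_loglik = 1e-11) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) stop("outcome vector is constant", call. = FALSE)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop(sprintf("model matrix is rank deficient (aliased: %s)",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  p <- ncol(X)
  beta <- rep(0, p)
  converged <- FALSE
  it <- 0L
  # Newton steps are solved on a column-rescaled design (unit column norms)
  # so the information matrix stays well conditioned when covariates live on
  # very different scales (e.g. population density vs. exposure in [0, 1])
  cn <- sqrt(colSums(X^2))
  cn[cn == 0] <- 1
  Xs <- X / rep(cn, each = nrow(X))
  singular_stop <- function(e) {
    stop("information matrix is singular; data may be (quasi-)separated",
         call. = FALSE)
  }
  ll_old <- -Inf
  repeat {
    it <- it + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(X, y - mu))
    ll <- sum(ifelse(y == 1, stats::plogis(eta, log.p = TRUE),
                     stats::plogis(-eta, log.p = TRUE)))
    w <- pmax(mu * (1 - mu), 1e-12)
    A <- Xs * sqrt(w)
    ch <- tryCatch(chol(crossprod(A)), error = singular_stop)
    delta <- backsolve(ch, forwardsolve(t(ch), drop(crossprod(Xs, y - mu)))) / cn
    beta <- beta + delta
    if (max(abs(score)) < tol_score || max(abs(delta)) < tol_beta ||
        abs(ll - ll_old) < tol_loglik * (abs(ll) + 0.1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    if (it >= max_iter) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  pinned <- mu < 1e-8 | mu > 1 - 1e-8
  if (all(abs(y - mu) < 1e-6)) {
    stop(paste("logistic fit did not reach a finite maximum:",
               "data are completely separated",
               "(every observation is perfectly predicted)"), call. = FALSE)
  }
  if (!converged) {
    hint <- if (any(pinned)) {
      sprintf(" (%d fitted probabilities pinned at 0/1: possible quasi-separation)",
              sum(pinned))
    } else ""
    stop(sprintf("logistic fit did not converge in %d iterations%s",
                 max_iter, hint), call. = FALSE)
  }
  sw <- sqrt(pmax(mu * (1 - mu), 1e-12))
  ch <- tryCatch(chol(crossprod(Xs * sw)), error = singular_stop)
  vcov <- chol2inv(ch) / outer(cn, cn)
  se <- sqrt(diag(vcov))
  names(beta) <- colnames(X)
  names(se) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  ll <- sum(ifelse(y == 1, stats::plogis(eta, log.p = TRUE),
                   stats::plogis(-eta, log.p = TRUE)))
  list(beta = beta, vcov = vcov, se = se, converged = converged,
       iterations = it, n_pinned = sum(pinned), loglik = ll)
}

#' Odds ratio per IQR increment with Wald CI and p-value
#'
#' Scales a fitted log-odds coefficient to an interquartile-range increment:
#' `OR = exp(beta * IQR)`, CI `exp((beta +/- z * se) * IQR)` with
#' `z = qnorm(1 - alpha/2)` (1.959964 at alpha = 0.05), and a two-sided Wald
#' test of `beta = 0` (invariant to the IQR scaling).
#'
#' @param beta_exposure fitted exposure coefficient (log-odds per exposure unit).
#' @param se_exposure its standard error (>= 0).
#' @param iqr_value IQR of the exposure in the analysis sample (> 0).
#' @param alpha two-sided level, default 0.05.
#' @return list with `or_`, `ci_low`, `ci_high`, `p`.
#' @examples
#' or_per_iqr(log(0.5), 0.2, 1)
#' @export
or_per_iqr <- function(beta_exposure, se_exposure, iqr_value, alpha = 0.05) {
  stopifnot(se_exposure >= 0)
  if (!is.finite(iqr_value) || iqr_value <= 0) {
    stop("IQR must be positive: the exposure is degenerate in this sample",
         call. = FALSE)
  }
  z <- stats::qnorm(1 - alpha / 2)
  or_ <- exp(beta_exposure * iqr_value)
  half <- z * se_exposure * iqr_value
  p <- if (se_exposure == 0) {
    if (beta_exposure == 0) 1 else 0
  } else {
    2 * stats::pnorm(-abs(beta_exposure / se_exposure))
  }
  list(or_ = or_, ci_low = exp(beta_exposure * iqr_value - half),
       ci_high = exp(beta_exposure * iqr_value + half), p = p)
}

#' Fit one exposure-depression contrast
#'
#' Joins one exposure (metric x buffer x window) to the participants, applies
#' the outcome cutoff and complete-case exclusions, computes the IQR on the
#' analysis sample (so stratum- and month-specific models use their own IQR),
#' fits the logistic model, and reports the odds ratio per IQR increment.
#'
#' @param participants participant data.frame.
#' @param exposures an `exposure_table`.
#' @param spec a [model_spec].
#' @param metric `"ndvi"` or `"bluegreen"`.
#' @param buffer_m buffer radius in meters.
#' @param window `"annual"`, `"static"`, or `"month-XX"`.
#' @param adjusted fit the covariate-adjusted model (default TRUE).
#' @param stratum label recorded in the result (`"all"`, `"low_income"`,
#'   `"high_income"`).
#' @return an `association_result` (list) with the fitted contrast and its
#'   metadata.
#' @export
run_association <- function(participants, exposures, spec = model_spec(),
                            metric, buffer_m, window, adjusted = TRUE,
                            stratum = "all") {
  sel <- exposures$metric == metric & exposures$buffer_m == buffer_m &
    exposures$window == window
  if (!any(sel)) {
    stop(sprintf("no exposure rows for metric=%s buffer=%g window=%s",
                 metric, buffer_m, window), call. = FALSE)
  }
  exp_sub <- exposures[sel, c("participant_id", "value")]
  df <- as.data.frame(participants)
  df$exposure <- exp_sub$value[match(as.character(df$id),
                                     exp_sub$participant_id)]
  dm <- build_design_matrix(df, spec, exposure_column = "exposure",
                            adjusted = adjusted)
  iqr_value <- iqr(df$exposure[dm$rows], quantile_type = spec$quantile_type)
  if (dm$n_cases < 10L) {
    warning(sprintf("only %d cases in the %s analysis sample; estimates unstable",
                    dm$n_cases, stratum), call. = FALSE)
  }
  fit <- fit_logistic(dm$y, dm$X)
  scaled <- or_per_iqr(fit$beta[["exposure"]], fit$se[["exposure"]], iqr_value,
                       alpha = spec$alpha)
  structure(list(
    metric = metric, buffer_m = buffer_m, window = window, stratum = stratum,
    adjusted = isTRUE(adjusted), n = dm$n, n_cases = dm$n_cases,
    iqr = iqr_value, beta = unname(fit$beta[["exposure"]]),
    se = unname(fit$se[["exposure"]]),
    or_ = scaled$or_, ci_low = scaled$ci_low, ci_high = scaled$ci_high,
    p = scaled$p,
    n_missing_outcome = dm$n_missing_outcome,
    n_missing_covariates = dm$n_missing_covariates,
    reference_levels = reference_levels[intersect(names(reference_levels),
                                                  adjustment_covariates(spec))],
    converged = fit$converged, n_pinned = fit$n_pinned
  ), class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s %gm [%s, %s, %s]: OR/IQR %.3f (%.3f-%.3f), p=%.4g, n=%d (%d cases)\n",
              x$metric, x$buffer_m, x$window, x$stratum,
              if (x$adjusted) "adjusted" else "unadjusted",
              x$or_, x$ci_low, x$ci_high, x$p, x$n, x$n_cases))
  invisible(x)
}

#' Collect association results into the standard results table
#'
#' @param results a list of `association_result` objects (a single result is
#'   wrapped automatically).
#' @return data.frame with columns `metric`, `buffer_m`, `window`, `stratum`,
#'   `adjusted`, `n`, `n_cases`, `iqr`, `beta`, `se`, `or_`, `ci_low`,
#'   `ci_high`, `p`.
#' @export
results_table <- function(results) {
  if (inherits(results, "association_result")) results <- list(results)
  if (length(results) == 0L) return(empty_results_df())
  rows <- lapply(results, function(r) {
    data.frame(metric = r$metric, buffer_m = r$buffer_m, window = r$window,
               stratum = r$stratum, adjusted = r$adjusted,
               n = as.integer(r$n), n_cases = as.integer(r$n_cases),
               iqr = r$iqr, beta = r$beta, se = r$se, or_ = r$or_,
               ci_low = r$ci_low, ci_high = r$ci_high, p = r$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Split participants into low- and high-income strata
#'
#' Low income: monthly household income below 2 million KRW (levels `<1M`,
#' `1-2M`); high income: 2 million KRW or more (levels `2-3M`, `3-5M`,
#' `>=5M`). The two strata partition the input.
#'
#' @param participants participant data.frame with an `income` column.
#' @return list with data.frames `low` and `high`.
#' @export
stratify_income <- function(participants) {
  income <- as.character(participants$income)
  low_levels <- c("<1M", "1-2M")
  high_levels <- c("2-3M", "3-5M", ">=5M")
  bad <- setdiff(stats::na.omit(unique(income)), c(low_levels, high_levels))
  if (length(bad)) {
    stop(sprintf("unknown income level(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  list(low = participants[income %in% low_levels, , drop = FALSE],
       high = participants[income %in% high_levels, , drop = FALSE])
}

#' Monthly association series
#'
#' Fits one adjusted model per calendar month at a given radius, each using
#' that month's own exposure IQR. Months whose exposure is missing for every
#' participant are skipped with a warning; results are returned in month
#' order.
#'
#' @param participants participant data.frame.
#' @param exposures an `exposure_table` containing `month-XX` NDVI windows.
#' @param spec a [model_spec].
#' @param buffer_m buffer radius in meters.
#' @param adjusted fit adjusted models (default TRUE).
#' @return list of `association_result`, one per available month, in month
#'   order.
#' @export
monthly_series <- function(participants, exposures, spec = model_spec(),
                           buffer_m = 250, adjusted = TRUE) {
  out <- list()
  for (m in 1:12) {
    w <- sprintf("month-%02d", m)
    sel <- exposures$metric == "ndvi" & exposures$buffer_m == buffer_m &
      exposures$window == w
    if (!any(sel) || all(is.na(exposures$value[sel]))) {
      warning(sprintf("month %02d has no exposure values at %g m; skipped",
                      m, buffer_m), call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- run_association(
      participants, exposures, spec, metric = "ndvi", buffer_m = buffer_m,
      window = w, adjusted = adjusted)
  }
  out
}
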