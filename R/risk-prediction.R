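# Risk predictors, case-control designs and accuracy metrics.
#
# Predictors: noise-calibrated scores with a specified liability-scale R2
# (simulation stand-ins for PRS of known strength), LASSO estimated disease
# liability from quantitative traits, and the rank-normalized quantitative
# risk score (QRS) built from it. Case-control designs: interval-censored
# incident case prediction and prevalent case association, both
# down-sampled to a 1:1 ratio. Accuracy: observed-scale R2 on residualized
# outcomes, AUC, logistic/linear/Cox effect sizes, and the
# ascertainment-corrected conversion of observed-scale R2 to the liability
# scale (Lee et al. 2012, eq. 14).

#' Calibrate a noisy predictor against a liability
#'
#' Adds Gaussian noise of variance var(L) * (1 - t) / t to the liability
#' and standardizes, so the squared correlation between score and
#' liability is approximately the target t (exactly t in expectation).
#'
#' @param liability numeric liability vector.
#' @param target_r2_liab target squared correlation in (0, 1].
#' @param seed integer seed.
#' @return standardized numeric score with attributes `target_r2_liab` and
#'   `kind`.
#' @export
calibrate_predictor <- function(liability, target_r2_liab, seed = NULL) {
  check_number(target_r2_liab, "target_r2_liab", lower = 1e-12, upper = 1)
  vl <- stats::var(liability)
  if (!is.finite(vl) || vl == 0) stop_param("liability must be non-constant")
  with_seed(seed, {
    noise_var <- vl * (1 - target_r2_liab) / target_r2_liab
    score <- liability + stats::rnorm(length(liability), 0, sqrt(noise_var))
    score <- standardize(score)
    attr(score, "target_r2_liab") <- target_r2_liab
    attr(score, "kind") <- "calibrated"
    score
  })
}

#' Rank-based inverse normal transformation
#'
#' Maps values to Phi^-1((rank - c) / (n - 2c + 1)) with Blom offset
#' c = 3/8 by default; ties receive the average rank, so the map is
#' order-preserving.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @param offset rank offset c.
#' @return transformed vector.
#' @export
rank_normal <- function(values, offset = 3 / 8) {
  if (length(unique(values)) < 2L) {
    stop_param("rank-normal transform undefined for constant input")
  }
  n <- length(values)
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - offset) / (n - 2 * offset + 1))
}

#' LASSO estimated disease liability
#'
#' Fits an L1-regularized *linear* model of case-control status on the
#' quantitative traits (linear rather than logistic, consistent with a
#' liability-threshold view of the binary outcome), with k-fold
#' cross-validation and no age covariate. The penalty is chosen by the
#' standard 1se rule or a stricter 2se analogue (largest penalty whose CV
#' error is within two CV standard errors of the minimum). Out-of-fold
#' predictions are returned as the estimated liability, so the score for
#' each individual never uses their own outcome.
#'
#' @param quant_traits numeric matrix (individuals x traits).
#' @param disease_status 0/1 vector (cases = union of prevalent and
#'   incident cases).
#' @param n_folds CV folds (default 10).
#' @param rule `"2se"` (default) or `"1se"`.
#' @param seed integer seed for fold assignment.
#' @return list with `score` (out-of-fold predictions), `coefficients`
#'   (named vector incl. intercept), `lambda`, `rule`, `fit` (the
#'   cv.glmnet object).
#' @export
fit_estimated_liability <- function(quant_traits, disease_status,
                                    n_folds = 10L, rule = c("2se", "1se"),
                                    seed = NULL) {
  rule <- match.arg(rule)
  x <- as.matrix(quant_traits)
  y <- as.numeric(disease_status)
  if (sum(y == 1) < n_folds) {
    stop_param("fewer cases than cross-validation folds")
  }
  with_seed(seed, {
    foldid <- sample(rep_len(seq_len(n_folds), nrow(x)))
    fit <- glmnet::cv.glmnet(x, y, family = "gaussian", foldid = foldid,
                             keep = TRUE)
    lambda <- if (rule == "1se") {
      fit$lambda.1se
    } else {
      imin <- which.min(fit$cvm)
      max(fit$lambda[fit$cvm <= fit$cvm[imin] + 2 * fit$cvsd[imin]])
    }
    i <- which.min(abs(fit$lambda - lambda))
    score <- fit$fit.preval[, i]
    cf <- stats::coef(fit, s = lambda)
    list(score = as.numeric(score),
         coefficients = stats::setNames(as.numeric(cf), rownames(cf)),
         lambda = lambda, rule = rule, fit = fit)
  })
}

# ---- case-control designs on a cohort table --------------------------------

disease_dx <- function(cohort, disease) {
  dx <- cohort$diagnoses
  if (is.null(dx) || !disease %in% dx$disease) {
    stop_param("no diagnoses recorded for disease: ", disease)
  }
  dx <- dx[dx$disease == disease, ]
  # earliest record per individual
  dx <- dx[order(dx$id, dx$age_at_diagnosis), ]
  dx[!duplicated(dx$id), ]
}

#' Incident case-control sets by age-at-diagnosis quintile
#'
#' Cases are split into `n_bins` quantile intervals of first-diagnosis
#' age. Within interval \[lo, hi\]: cases are individuals first diagnosed
#' inside it; controls are individuals not diagnosed by the interval end
#' who were either followed to the end of the interval or (by default,
#' matching an interval-censoring convention) lost to follow-up within
#' it. Individuals diagnosed before the interval are excluded entirely.
#' Controls are down-sampled uniformly to a 1:1 ratio.
#'
#' @param cohort a `cohort_table` with diagnoses and censor ages.
#' @param disease disease name.
#' @param n_bins number of age intervals (default 5).
#' @param seed integer seed for control down-sampling.
#' @param include_ltfu include individuals lost to follow-up within the
#'   interval as controls (default TRUE); set FALSE to require follow-up
#'   to the interval end.
#' @return list of `case_control_set` objects (ids are subject ids), each
#'   with `interval` (lo, hi) and `median_case_age`.
#' @export
incident_case_sets <- function(cohort, disease, n_bins = 5L, seed = NULL,
                               include_ltfu = TRUE) {
  stopifnot(inherits(cohort, "cohort_table"))
  dx <- disease_dx(cohort, disease)
  sub <- cohort$subjects
  dx_age <- dx$age_at_diagnosis[match(sub$id, dx$id)] # NA = never diagnosed
  qs <- stats::quantile(dx$age_at_diagnosis,
                        probs = seq(0, 1, length.out = n_bins + 1))
  case_bin <- as.integer(cut(dx_age, qs, include.lowest = TRUE))
  with_seed(seed, {
    lapply(seq_len(n_bins), function(k) {
      lo <- qs[k]
      hi <- qs[k + 1L]
      cases <- which(!is.na(case_bin) & case_bin == k)
      healthy_by_end <- is.na(dx_age) | dx_age > hi
      followed <- sub$censor_age >= hi
      ltfu <- sub$censor_age >= lo & sub$censor_age < hi
      eligible <- healthy_by_end &
        (followed | (include_ltfu & ltfu))
      controls <- which(eligible)
      if (!length(cases)) stop_param("no cases in interval ", k)
      if (!length(controls)) {
        stop_param("no eligible controls in interval ", k)
      }
      if (length(controls) > length(cases)) {
        controls <- sort(sample(controls, length(cases)))
      }
      structure(list(cases = sub$id[cases], controls = sub$id[controls],
                     bin = k, design = "incident",
                     interval = c(lo = unname(lo), hi = unname(hi)),
                     median_case_age = stats::median(dx_age[cases])),
                class = "case_control_set")
    })
  })
}

#' Prevalent case-control sets at fixed baseline age points
#'
#' At each age point (conventionally the five median case ages of the
#' incident intervals): eligible individuals are those followed past the
#' age point; cases are those with at least one diagnosis before it;
#' controls are eligible individuals without a diagnosis by the age
#' point, sampled to a 1:1 ratio.
#'
#' @param cohort a `cohort_table`.
#' @param disease disease name.
#' @param baseline_ages numeric vector of age points.
#' @param seed integer seed for control sampling.
#' @return list of `case_control_set` objects.
#' @export
prevalent_case_sets <- function(cohort, disease, baseline_ages,
                                seed = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  dx <- disease_dx(cohort, disease)
  sub <- cohort$subjects
  dx_age <- dx$age_at_diagnosis[match(sub$id, dx$id)]
  with_seed(seed, {
    lapply(seq_along(baseline_ages), function(k) {
      a <- baseline_ages[k]
      eligible <- sub$censor_age >= a
      cases <- which(eligible & !is.na(dx_age) & dx_age < a)
      controls <- which(eligible & (is.na(dx_age) | dx_age >= a))
      if (!length(cases)) stop_param("no prevalent cases at age ", a)
      if (!length(controls)) stop_param("no controls at age ", a)
      if (length(controls) > length(cases)) {
        controls <- sort(sample(controls, length(cases)))
      }
      structure(list(cases = sub$id[cases], controls = sub$id[controls],
                     bin = k, design = "prevalent",
                     baseline_age = a,
                     median_case_age = stats::median(dx_age[cases])),
                class = "case_control_set")
    })
  })
}

# ---- accuracy metrics ------------------------------------------------------

#' Observed-scale R2 of a score against a binary outcome
#'
#' The outcome is residualized on the covariates (with intercept) and the
#' value is the squared Pearson correlation between residual and score.
#'
#' @param score numeric score vector.
#' @param outcome 0/1 outcome of matching length.
#' @param covariates optional covariate matrix; NULL for mean-centering.
#' @return an `accuracy_estimate` list: metric = "r2_obs", `value`, `se`
#'   (delta-method), `n`, `P` (case proportion).
#' @export
observed_r2 <- function(score, outcome, covariates = NULL) {
  if (stats::sd(score) == 0) stop_param("score is constant")
  if (length(score) != length(outcome)) stop_param("length mismatch")
  resid <- residualize(as.numeric(outcome), covariates)
  r <- stats::cor(resid, score)
  n <- length(score)
  se_r <- (1 - r^2) / sqrt(max(n - 3, 1))
  structure(list(metric = "r2_obs", value = r^2, se = 2 * abs(r) * se_r,
                 n = n, P = mean(outcome)),
            class = "accuracy_estimate")
}

#' @export
print.accuracy_estimate <- function(x, ...) {
  cat(sprintf("<accuracy_estimate> %s = %.4f (se %.4f), n = %d\n",
              x$metric, x$value, if (is.na(x$se)) NA else x$se, x$n))
  invisible(x)
}

#' Association metrics for a score on a case-control sample
#'
#' Computes one of: `auc` (Mann-Whitney concordance probability, no
#' covariate adjustment), `log_or` (logistic coefficient of the
#' standardized score, covariate-adjusted), `linear_effect` (linear-model
#' coefficient), or `log_hr` (Cox proportional-hazards coefficient,
#' requiring follow-up times).
#'
#' @param score numeric score vector.
#' @param outcome 0/1 outcome.
#' @param covariates optional covariate matrix for the regression metrics.
#' @param metric one of "auc", "log_or", "linear_effect", "log_hr".
#' @param time follow-up times (for `log_hr`), event = outcome.
#' @return an `accuracy_estimate` with `value`, `se`, `converged`.
#' @export
association_metrics <- function(score, outcome,
                                covariates = NULL,
                                metric = c("auc", "log_or", "linear_effect",
                                           "log_hr"),
                                time = NULL) {
  metric <- match.arg(metric)
  outcome <- as.numeric(outcome)
  n <- length(score)
  if (metric == "auc") {
    r <- rank(score)
    n1 <- sum(outcome == 1)
    n0 <- n - n1
    if (n1 == 0 || n0 == 0) stop_param("need both cases and controls")
    auc <- (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    # Hanley-McNeil standard error
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                  (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
    return(structure(list(metric = "auc", value = auc, se = se, n = n,
                          converged = TRUE),
                     class = "accuracy_estimate"))
  }
  s <- standardize(score)
  df <- data.frame(outcome = outcome, score = s)
  if (!is.null(covariates)) {
    df <- cbind(df, as.data.frame(covariates))
  }
  rhs <- paste(setdiff(names(df), c("outcome")), collapse = " + ")
  if (metric == "log_or") {
    fit <- suppressWarnings(
      stats::glm(stats::as.formula(paste("outcome ~", rhs)),
                 family = stats::binomial(), data = df)
    )
    co <- summary(fit)$coefficients["score", ]
    conv <- fit$converged && abs(co[1]) < 15
    return(structure(list(metric = "log_or", value = unname(co[1]),
                          se = unname(co[2]), n = n, converged = conv),
                     class = "accuracy_estimate"))
  }
  if (metric == "linear_effect") {
    fit <- stats::lm(stats::as.formula(paste("outcome ~", rhs)), data = df)
    co <- summary(fit)$coefficients["score", ]
    return(structure(list(metric = "linear_effect", value = unname(co[1]),
                          se = unname(co[2]), n = n, converged = TRUE),
                     class = "accuracy_estimate"))
  }
  if (is.null(time)) stop_param("`time` is required for log_hr")
  df$time <- time
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(time, outcome) ~", rhs)),
    data = df
  )
  co <- summary(fit)$coefficients["score", , drop = TRUE]
  structure(list(metric = "log_hr", value = unname(co["coef"]),
                 se = unname(co["se(coef)"]), n = n, converged = TRUE),
            class = "accuracy_estimate")
}

#' Observed-scale to liability-scale R2 (ascertainment corrected)
#'
#' Implements the case-control transformation of Lee et al. (2012,
#' Genet. Epidemiol., eq. 14): with threshold t = Phi^-1(1 - K), height
#' z = phi(t), mean case liability m = z / K and
#' C = K(1-K)/z^2 * K(1-K)/(P(1-P)),
#' theta = m (P-K)/(1-K) * (m (P-K)/(1-K) - t),
#' the liability-scale R2 is R2_obs * C / (1 + R2_obs * theta * C).
#'
#' @param r2_obs observed-scale R2 (>= 0).
#' @param K population prevalence in (0, 1).
#' @param P case proportion in the analysed sample in (0, 1).
#' @return liability-scale R2.
#' @export
liability_r2_transform <- function(r2_obs, K, P) {
  check_number(K, "K", 1e-12, 1 - 1e-12)
  check_number(P, "P", 1e-12, 1 - 1e-12)
  if (!is.numeric(r2_obs) || any(r2_obs < 0)) {
    stop_param("`r2_obs` must be non-negative")
  }
  t <- stats::qnorm(1 - K)
  z <- stats::dnorm(t)
  m <- z / K
  C <- K * (1 - K) / z^2 * K * (1 - K) / (P * (1 - P))
  theta <- m * (P - K) / (1 - K) * (m * (P - K) / (1 - K) - t)
  r2_obs * C / (1 + r2_obs * theta * C)
}

# Inverse of liability_r2_transform for the same (K, P).
observed_r2_from_liability <- function(r2_liab, K, P) {
  t <- stats::qnorm(1 - K)
  z <- stats::dnorm(t)
  m <- z / K
  C <- K * (1 - K) / z^2 * K * (1 - K) / (P * (1 - P))
  theta <- m * (P - K) / (1 - K) * (m * (P - K) / (1 - K) - t)
  r2_liab / (C * (1 - r2_liab * theta))
}

#' Liability-scale correlation between a quantitative trait and a disease
#'
#' Maps the point-biserial (observed) correlation to the liability scale
#' through the same ascertainment-corrected framework as
#' [liability_r2_transform()], preserving sign.
#'
#' @param quant numeric trait vector.
#' @param binary 0/1 disease vector.
#' @param K population prevalence; defaults to the sample case
#'   proportion (no ascertainment).
#' @return liability-scale correlation.
#' @export
liability_scale_correlation <- function(quant, binary, K = mean(binary)) {
  if (stats::sd(quant) == 0) stop_param("quantitative trait is constant")
  if (length(unique(binary)) < 2L) stop_param("binary trait is constant")
  r <- stats::cor(quant, as.numeric(binary))
  sign(r) * sqrt(liability_r2_transform(r^2, K = K, P = mean(binary)))
}

# ---- QRS pipeline ----------------------------------------------------------

#' QRS-based estimate of expected age-dependent PRS accuracy
#'
#' Runs the six-step quantitative-risk-score procedure: (1) rank-normalize
#' the estimated liability into a QRS; (2) residualize the QRS on age and
#' sex and the standardized PRS on sex (plus principal components when
#' supplied); (3) compute whole-population liability-scale R2 of both
#' against case status (cases = union of prevalent and incident);
#' (4) add Gaussian noise to the QRS so its liability-scale R2 matches
#' the PRS's; (5) compute per-age-bin incident observed-scale R2 for the
#' noise-matched QRS and for the PRS on the same case-control sets;
#' (6) repeat the noise draw and control down-sampling `n_mc` times and
#' report the mean and standard deviation per bin.
#'
#' @param estimated_liability numeric vector (e.g. from
#'   [fit_estimated_liability()]), one value per cohort individual.
#' @param prs numeric PRS vector, same individuals.
#' @param cohort a `cohort_table`.
#' @param disease disease name in the diagnoses table.
#' @param pcs optional matrix of principal-component covariates for the
#'   PRS adjustment.
#' @param n_bins number of incident age bins.
#' @param n_mc Monte-Carlo replicates (default 50).
#' @param seed integer seed.
#' @param include_ltfu passed to [incident_case_sets()].
#' @return list with `per_bin` (data.frame: bin, median_case_age,
#'   qrs_r2_mean, qrs_r2_sd, prs_r2_mean, prs_r2_sd), `r2_liab_qrs`,
#'   `r2_liab_prs` (whole-population, pre-matching QRS and PRS),
#'   `noise_var`, `n_mc`.
#' @export
qrs_pipeline <- function(estimated_liability, prs, cohort, disease,
                         pcs = NULL, n_bins = 5L, n_mc = 50L, seed = NULL,
                         include_ltfu = TRUE) {
  stopifnot(inherits(cohort, "cohort_table"))
  sub <- cohort$subjects
  n <- nrow(sub)
  stopifnot(length(estimated_liability) == n, length(prs) == n)
  dx <- disease_dx(cohort, disease)
  status <- as.integer(sub$id %in% dx$id)
  K <- mean(status)

  # (1) rank-normal QRS; (2) covariate adjustment
  qrs <- rank_normal(estimated_liability)
  qrs_cov <- cbind(age = sub$baseline_age, sex = sub$sex)
  prs_cov <- if (is.null(pcs)) {
    cbind(sex = sub$sex)
  } else {
    cbind(sex = sub$sex, as.matrix(pcs))
  }
  qrs_adj <- residualize(qrs, qrs_cov)
  prs_adj <- residualize(standardize(prs), prs_cov)

  # (3) whole-population liability-scale R2 (P = K: unascertained sample)
  r2o_qrs <- observed_r2(qrs_adj, status, qrs_cov)$value
  r2o_prs <- observed_r2(prs_adj, status, prs_cov)$value
  r2l_qrs <- liability_r2_transform(r2o_qrs, K = K, P = K)
  r2l_prs <- liability_r2_transform(r2o_prs, K = K, P = K)

  # (4) noise variance matching QRS liability-scale R2 to the PRS's
  if (r2l_qrs <= r2l_prs) {
    warning("QRS liability-scale R2 already at or below the PRS's; ",
            "no noise added")
    noise_var <- 0
  } else {
    r2o_target <- observed_r2_from_liability(r2l_prs, K = K, P = K)
    noise_var <- stats::var(qrs_adj) * (r2o_qrs / r2o_target - 1)
  }

  sets <- incident_case_sets(cohort, disease, n_bins = n_bins,
                             seed = if (is.null(seed)) NULL
                             else derive_seed(seed, "bins"),
                             include_ltfu = include_ltfu)
  per_bin_r2 <- function(score, covnames_qrs = TRUE, ccsets) {
    vapply(ccsets, function(cc) {
      ids <- c(cc$cases, cc$controls)
      idx <- match(ids, sub$id)
      out <- as.integer(ids %in% cc$cases)
      cov <- if (covnames_qrs) qrs_cov[idx, , drop = FALSE]
        else prs_cov[idx, , drop = FALSE]
      observed_r2(score[idx], out, cov)$value
    }, numeric(1))
  }

  with_seed(seed, {
    qrs_mat <- matrix(NA_real_, n_mc, n_bins)
    prs_mat <- matrix(NA_real_, n_mc, n_bins)
    for (r in seq_len(n_mc)) {
      qrs_r <- qrs_adj + stats::rnorm(n, 0, sqrt(noise_var))
      sets_r <- incident_case_sets(cohort, disease, n_bins = n_bins,
                                   seed = sample.int(2^30, 1L),
                                   include_ltfu = include_ltfu)
      qrs_mat[r, ] <- per_bin_r2(qrs_r, TRUE, sets_r)
      prs_mat[r, ] <- per_bin_r2(prs_adj, FALSE, sets_r)
    }
    per_bin <- data.frame(
      bin = seq_len(n_bins),
      median_case_age = vapply(sets, `[[`, numeric(1), "median_case_age"),
      qrs_r2_mean = colMeans(qrs_mat),
      qrs_r2_sd = apply(qrs_mat, 2L, stats::sd),
      prs_r2_mean = colMeans(prs_mat),
      prs_r2_sd = apply(prs_mat, 2L, stats::sd)
    )
    list(per_bin = per_bin, r2_liab_qrs = r2l_qrs, r2_liab_prs = r2l_prs,
         noise_var = noise_var, n_mc = n_mc, K = K)
  })
}
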