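# Scaling, meta-analysis and denoising of between-age correlations.
#
# Correlations between age bins are compared on a common 10-year gap under
# the working model that liability autocorrelation decays exponentially,
# rho(delta) = exp(-beta * delta); the 10-year scaling
# exp(10 * log(rho) / delta) is exact under that model. The denoised
# longitudinal estimator uses the ratio corr(v1, v3) / corr(v1, v2), in
# which the multiplicative measurement-error attenuation of visit 1
# cancels (and, under constant liability variance, the attenuation of
# visits 2 and 3 cancels as well), leaving the liability correlation over
# the visit-2-to-visit-3 gap.

#' Scale a correlation to a 10-year age gap
#'
#' Returns exp(10 * log(rho) / age_gap), the correlation implied at a
#' 10-year gap under exponential decay. rho = 1 maps to 1 for any gap.
#'
#' @param rho positive correlation.
#' @param age_gap age gap in years (> 0).
#' @return scaled correlation.
#' @export
scale_to_10yr <- function(rho, age_gap) {
  check_number(age_gap, "age_gap", lower = 1e-12)
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho <= 0) {
    stop_param("`rho` must be positive: 10-year scaling is undefined for ",
               "non-positive correlations (estimate excluded)")
  }
  exp(10 * log(rho) / age_gap)
}

#' Inverse-variance weighted meta-analysis
#'
#' Pools estimates with weights 1/se^2; the pooled standard error is
#' 1/sqrt(sum of weights). The intended default input is the four
#' neighboring age-bin-pair estimates (bins 1-2, 2-3, 3-4, 4-5) after
#' 10-year scaling.
#'
#' @param values numeric vector of estimates.
#' @param ses matching positive standard errors.
#' @return list with `value` and `se`.
#' @export
meta_analyse_scaled <- function(values, ses) {
  if (!length(values)) stop_param("no estimates to meta-analyse")
  if (length(values) != length(ses) || any(!is.finite(ses)) || any(ses <= 0)) {
    stop_param("`ses` must be positive and match `values` in length")
  }
  w <- 1 / ses^2
  list(value = sum(w * values) / sum(w), se = 1 / sqrt(sum(w)))
}

#' One-sided test of a correlation being less than 1
#'
#' z = (1 - value) / se; the one-sided p-value is the upper normal tail,
#' so value = 1 gives p = 0.5 and values above 1 give p > 0.5 (no
#' evidence for a deficit). The two-sided p is reported alongside.
#'
#' @param value pooled correlation estimate.
#' @param se its standard error (> 0).
#' @return list with `z`, `p_one_sided`, `p_two_sided`.
#' @export
test_corr_lt_1 <- function(value, se) {
  check_number(se, "se", lower = 1e-300)
  z <- (1 - value) / se
  list(z = z,
       p_one_sided = stats::pnorm(z, lower.tail = FALSE),
       p_two_sided = 2 * stats::pnorm(-abs(z)))
}

#' Denoised longitudinal phenotypic correlation
#'
#' For individuals with exactly three measurements, computes the ratio
#' corr(v1, v3) / corr(v1, v2) across individuals, which cancels
#' measurement-error attenuation; the per-year log decay is
#' log(ratio) / mean(t3 - t2), reported on the 10-year scale via
#' [scale_to_10yr()]. The standard error is a bootstrap over individuals.
#'
#' @param visits data.frame with columns id, visit (1/2/3), age, value.
#'   Individuals lacking all three visits are dropped.
#' @param n_bootstrap bootstrap replicates (default 200).
#' @param seed integer seed.
#' @param min_abs_corr |corr(v1, v2)| below this triggers an
#'   unstable-ratio error.
#' @return a `correlation_estimate`: list with `rho_raw` (the ratio),
#'   `age_gap` (mean t3 - t2), `rho_10yr`, `se` (bootstrap se of
#'   rho_10yr), `ci` (percentile 95% CI), `beta` (implied per-year decay),
#'   `n`, `kind = "denoised"`.
#' @export
denoised_phenotypic_correlation <- function(visits, n_bootstrap = 200L,
                                            seed = NULL, min_abs_corr = 0.05) {
  need <- c("id", "visit", "age", "value")
  if (!all(need %in% names(visits))) {
    stop_param("`visits` must have columns: ", paste(need, collapse = ", "))
  }
  wide <- stats::reshape(visits[need], direction = "wide", idvar = "id",
                         timevar = "visit")
  v <- paste0("value.", 1:3)
  a <- paste0("age.", 1:3)
  if (!all(c(v, a) %in% names(wide))) {
    stop_param("denoising requires three visits per individual")
  }
  wide <- wide[stats::complete.cases(wide[, c(v, a)]), ]
  n <- nrow(wide)
  if (n < 10L) stop_param("too few individuals with three complete visits")
  gap <- mean(wide[[a[3L]]] - wide[[a[2L]]])

  ratio_of <- function(d) {
    r12 <- stats::cor(d[[v[1L]]], d[[v[2L]]])
    r13 <- stats::cor(d[[v[1L]]], d[[v[3L]]])
    c(r12 = r12, ratio = r13 / r12)
  }
  pt <- ratio_of(wide)
  if (abs(pt["r12"]) < min_abs_corr) {
    stop_param(sprintf(
      "unstable ratio: |corr(v1, v2)| = %.3f below tolerance %.3f",
      abs(pt["r12"]), min_abs_corr))
  }
  if (pt["ratio"] <= 0) {
    stop_param("non-positive correlation ratio: 10-year scaling undefined")
  }
  rho10 <- scale_to_10yr(unname(pt["ratio"]), gap)
  boot <- with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      d <- wide[sample.int(n, n, replace = TRUE), ]
      r <- ratio_of(d)
      if (abs(r["r12"]) < 1e-8 || r["ratio"] <= 0) return(NA_real_)
      exp(10 * log(r["ratio"]) / gap)
    }, numeric(1))
  })
  boot <- boot[is.finite(boot)]
  structure(
    list(rho_raw = unname(pt["ratio"]), age_gap = gap, rho_10yr = rho10,
         se = stats::sd(boot),
         ci = unname(stats::quantile(boot, c(0.025, 0.975))),
         beta = -log(rho10) / 10, n = n, n_bootstrap = length(boot),
         kind = "denoised"),
    class = "correlation_estimate"
  )
}

#' @export
print.correlation_estimate <- function(x, ...) {
  cat(sprintf(
    "<correlation_estimate> kind=%s: rho_10yr = %.4f (se %.4f), n = %d\n",
    x$kind, x$rho_10yr, x$se, x$n))
  invisible(x)
}
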