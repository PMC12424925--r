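# Linear age trends in per-bin metric series, variance decomposition and
# the attribution statistics (tau, combined expected change).
#
# A metric series holds one estimate with standard error per age bin
# (heritability, observed-scale R2, logHR, ...). Trends are fitted by
# maximum likelihood treating each bin value as Normal(a * age + b, se),
# i.e. weighted least squares with known noise; the null a = 0 is tested
# by a likelihood ratio against chi-square(1). This relies on the per-bin
# estimates coming from non-overlapping samples. Slope uncertainty is
# Monte-Carlo: each bin value is redrawn from Normal(point, se), the model
# refitted, and the standard deviation of slopes reported (reading the
# Gaussian's spread parameter as the standard error, the conventional
# meaning).

#' Construct a metric series
#'
#' @param value per-bin estimates.
#' @param se per-bin standard errors (> 0).
#' @param median_age per-bin median ages (distinct).
#' @param metric metric label (e.g. "h2", "r2_obs", "log_hr").
#' @param n optional per-bin sample sizes.
#' @param bin bin indices; defaults to 1..k.
#' @return a `metric_series` data.frame.
#' @export
metric_series <- function(value, se, median_age, metric = "metric",
                          n = NA_integer_, bin = seq_along(value)) {
  k <- length(value)
  if (length(se) != k || length(median_age) != k) {
    stop_param("`value`, `se`, `median_age` must have equal length")
  }
  if (any(!is.finite(se)) || any(se <= 0)) stop_param("`se` must be positive")
  structure(
    data.frame(bin = bin, median_age = median_age, value = value, se = se,
               n = n, metric = metric),
    class = c("metric_series", "data.frame")
  )
}

#' Fit a linear age trend to a metric series
#'
#' ML fit of value_k ~ Normal(a * age_k + b, se_k) (weighted least squares
#' with known per-bin noise), likelihood-ratio test of a = 0 against
#' chi-square(1), and a Monte-Carlo slope standard error from resampling
#' each bin value from Normal(point, se).
#'
#' @param series a [metric_series()] (>= 3 bins, distinct median ages).
#' @param n_mc Monte-Carlo replicates (default 1000).
#' @param seed integer seed.
#' @return a `trend_estimate`: list with `a` (slope per year), `b`
#'   (intercept), `a_se` (Monte-Carlo), `lrt_stat`, `lrt_p`, `mc_slopes`,
#'   `series`.
#' @export
fit_metric_trend <- function(series, n_mc = 1000L, seed = NULL) {
  stopifnot(inherits(series, "metric_series") || is.data.frame(series))
  if (nrow(series) < 3L) stop_param("need at least 3 bins to fit a trend")
  if (anyDuplicated(series$median_age)) {
    stop_param("median ages must be distinct")
  }
  age <- series$median_age
  v <- series$value
  w <- 1 / series$se^2

  wls <- function(vals) {
    sw <- sum(w)
    mx <- sum(w * age) / sw
    my <- sum(w * vals) / sw
    a <- sum(w * (age - mx) * (vals - my)) / sum(w * (age - mx)^2)
    b <- my - a * mx
    c(a = a, b = b)
  }
  fit1 <- wls(v)
  chisq1 <- sum(w * (v - fit1["a"] * age - fit1["b"])^2)
  b0 <- sum(w * v) / sum(w)
  chisq0 <- sum(w * (v - b0)^2)
  lrt <- max(chisq0 - chisq1, 0)
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)

  mc_slopes <- with_seed(seed, {
    vapply(seq_len(n_mc), function(i) {
      wls(stats::rnorm(length(v), v, series$se))[["a"]]
    }, numeric(1))
  })
  structure(
    list(a = unname(fit1["a"]), b = unname(fit1["b"]),
         a_se = stats::sd(mc_slopes), lrt_stat = lrt, lrt_p = p,
         mc_slopes = mc_slopes, series = series),
    class = "trend_estimate"
  )
}

#' @export
print.trend_estimate <- function(x, ...) {
  cat(sprintf(
    "<trend_estimate> slope = %.5f/yr (MC se %.5f), LRT p = %.3g\n",
    x$a, x$a_se, x$lrt_p))
  invisible(x)
}

#' Relative 10-year change of a metric
#'
#' 10 * slope / whole-population estimate, with the standard error
#' propagated through the Monte-Carlo slope draws.
#'
#' @param trend a `trend_estimate` from [fit_metric_trend()].
#' @param population_estimate the metric's whole-population value
#'   (non-zero denominator).
#' @return list with `rel_change_10yr` and `se`.
#' @export
relative_10yr_change <- function(trend, population_estimate) {
  stopifnot(inherits(trend, "trend_estimate"))
  if (!is.numeric(population_estimate) || population_estimate == 0) {
    stop_param("`population_estimate` must be non-zero")
  }
  draws <- 10 * trend$mc_slopes / population_estimate
  list(rel_change_10yr = 10 * trend$a / population_estimate,
       se = stats::sd(draws))
}

#' Decompose per-bin phenotypic variance into genetic and environmental
#' parts
#'
#' Per bin: var(G) = h2 * var(P) and var(E) = (1 - h2) * var(P), so
#' var(G) + var(E) = var(P) by construction. Ten-year changes of each
#' component come from [fit_metric_trend()] on the derived series, with
#' component standard errors combining the h2 and var(P) uncertainties
#' (independent-delta approximation).
#'
#' @param h2_series [metric_series()] of per-bin heritability.
#' @param phen_var per-bin phenotypic variances (matching bins).
#' @param phen_var_se their standard errors; defaults to
#'   var * sqrt(2/(n-1)) using the series' n.
#' @param n_mc,seed passed to [fit_metric_trend()].
#' @return list with `per_bin` (data.frame bin, median_age, var_g, var_e,
#'   var_p and ses), `trend_g`, `trend_e` (trend estimates), and
#'   `delta_10yr` (data.frame of 10-year changes with MC se).
#' @export
variance_decomposition <- function(h2_series, phen_var, phen_var_se = NULL,
                                   n_mc = 1000L, seed = NULL) {
  k <- nrow(h2_series)
  if (length(phen_var) != k) stop_param("bins of the two series must match")
  if (is.null(phen_var_se)) {
    if (all(is.na(h2_series$n))) {
      stop_param("supply `phen_var_se` or per-bin n in the series")
    }
    phen_var_se <- phen_var * sqrt(2 / (h2_series$n - 1))
  }
  h2 <- h2_series$value
  var_g <- h2 * phen_var
  var_e <- (1 - h2) * phen_var
  # independent delta-method ses
  se_g <- sqrt(phen_var^2 * h2_series$se^2 + h2^2 * phen_var_se^2)
  se_e <- sqrt(phen_var^2 * h2_series$se^2 + (1 - h2)^2 * phen_var_se^2)
  mk <- function(vals, ses, lab) {
    metric_series(vals, ses, h2_series$median_age, metric = lab,
                  n = h2_series$n, bin = h2_series$bin)
  }
  trend_g <- fit_metric_trend(mk(var_g, se_g, "var_g"), n_mc = n_mc,
                              seed = if (is.null(seed)) NULL
                              else derive_seed(seed, "var_g"))
  trend_e <- fit_metric_trend(mk(var_e, se_e, "var_e"), n_mc = n_mc,
                              seed = if (is.null(seed)) NULL
                              else derive_seed(seed, "var_e"))
  list(
    per_bin = data.frame(bin = h2_series$bin,
                         median_age = h2_series$median_age,
                         var_g = var_g, var_g_se = se_g,
                         var_e = var_e, var_e_se = se_e,
                         var_p = phen_var, var_p_se = phen_var_se),
    trend_g = trend_g, trend_e = trend_e,
    delta_10yr = data.frame(
      component = c("var_g", "var_e"),
      delta = c(10 * trend_g$a, 10 * trend_e$a),
      se = c(10 * trend_g$a_se, 10 * trend_e$a_se)
    )
  )
}

#' Proportion of PRS accuracy decline explained (tau)
#'
#' tau = sum over diseases of max(dQRS_d, dPRS_d) divided by the sum of
#' dPRS_d, where the inputs are signed relative 10-year changes
#' (negative = decline). The elementwise max caps each disease's explained
#' decline at 100%: a QRS declining faster than the PRS contributes the
#' PRS value to both numerator and denominator, so tau <= 1 whenever all
#' PRS changes are declines.
#'
#' @param delta_qrs per-disease relative 10-year changes of the model
#'   prediction (e.g. QRS R2).
#' @param delta_prs per-disease relative 10-year changes of PRS R2.
#' @return tau (proportion).
#' @export
tau_explained <- function(delta_qrs, delta_prs) {
  if (length(delta_qrs) != length(delta_prs)) {
    stop_param("inputs must have equal length")
  }
  denom <- sum(delta_prs)
  if (denom == 0) stop_param("tau undefined: PRS changes sum to zero")
  sum(pmax(delta_qrs, delta_prs)) / denom
}

#' Expected combined change under the EA + liability-threshold model
#'
#' Returns 1 - (1 + dR2_QRS) * (1 + dh2), the model-implied relative
#' 10-year decline when the liability-threshold contribution (captured by
#' the QRS change) and the exposure-accumulation contribution (captured
#' by the heritability change of estimated liability) act together; the
#' returned number is positive for a decline. The standard error treats
#' the two inputs as independent Monte-Carlo draws.
#'
#' @param delta_qrs signed relative 10-year change of QRS R2.
#' @param delta_h2 signed relative 10-year change of estimated-liability
#'   heritability.
#' @param se_qrs,se_h2 optional standard errors for the Monte-Carlo se.
#' @param n_mc Monte-Carlo replicates.
#' @param seed integer seed.
#' @return list with `expected_change` and `se` (NA when no ses given).
#' @export
combined_expected_change <- function(delta_qrs, delta_h2, se_qrs = NULL,
                                     se_h2 = NULL, n_mc = 1000L,
                                     seed = NULL) {
  value <- 1 - (1 + delta_qrs) * (1 + delta_h2)
  se <- NA_real_
  if (!is.null(se_qrs) && !is.null(se_h2)) {
    draws <- with_seed(seed, {
      q <- stats::rnorm(n_mc, delta_qrs, se_qrs)
      h <- stats::rnorm(n_mc, delta_h2, se_h2)
      1 - (1 + q) * (1 + h)
    })
    se <- stats::sd(draws)
  }
  list(expected_change = value, se = se)
}

#' Two-sample z-test for a difference in slopes (or any two independent
#' estimates)
#'
#' z = (x - y) / sqrt(se_x^2 + se_y^2), with a two-sided normal p-value.
#'
#' @param x,y estimates (or `trend_estimate` objects, whose slopes are
#'   compared).
#' @param se_x,se_y standard errors (taken from the trend objects when
#'   omitted).
#' @return list with `z` and `p`.
#' @export
slope_difference_test <- function(x, y, se_x = NULL, se_y = NULL) {
  if (inherits(x, "trend_estimate")) {
    se_x <- x$a_se
    x <- x$a
  }
  if (inherits(y, "trend_estimate")) {
    se_y <- y$a_se
    y <- y$a
  }
  if (is.null(se_x) || is.null(se_y)) stop_param("standard errors required")
  z <- (x - y) / sqrt(se_x^2 + se_y^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
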