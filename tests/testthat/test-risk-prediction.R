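test_that("calibrated predictors realize their target liability-scale R2", {
  set.seed(201)
  L <- rnorm(100000)
  # t = 1: zero noise, score is the standardized liability
  s1 <- calibrate_predictor(L, 1, seed = 202)
  expect_equal(as.numeric(s1), (L - mean(L)) / sd(L), tolerance = 1e-12)
  # t = 0.5: realized squared correlation within 0.01
  s5 <- calibrate_predictor(L, 0.5, seed = 203)
  expect_lt(abs(cor(s5, L)^2 - 0.5), 0.01)
  # weakest tier: noise variance is 19 x var(L), r2 ~ 0.05
  s05 <- calibrate_predictor(L, 0.05, seed = 204)
  expect_lt(abs(cor(s05, L)^2 - 0.05), 0.005)
  expect_error(calibrate_predictor(L, 0), "target_r2_liab")
  expect_error(calibrate_predictor(rep(1, 10), 0.5), "non-constant")
})

test_that("rank-normal transform is order-preserving with Blom quantiles", {
  set.seed(205)
  x <- rexp(500)
  z <- rank_normal(x)
  expect_equal(cor(x, z, method = "spearman"), 1)
  expect_lt(abs(mean(z)), 0.01)
  expect_lt(abs(sd(z) - 1), 0.05)
  # n = 3 plug-in oracle: Phi^-1((r - 3/8) / (n + 1/4))
  z3 <- rank_normal(c(10, 30, 20))
  expect_equal(z3, qnorm((c(1, 3, 2) - 3 / 8) / 3.25), tolerance = 1e-12)
  expect_equal(z3[2], -z3[1], tolerance = 1e-12)
  # ties share the average rank
  zt <- rank_normal(c(1, 1, 2))
  expect_equal(zt[1], zt[2])
  expect_error(rank_normal(rep(2, 5)), "constant")
})

test_that("LASSO estimated liability selects informative traits", {
  set.seed(206)
  n <- 600
  X <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, paste0("t", 1:12)))
  liab <- X[, 1] + rnorm(n, 0, 0.5)
  status <- as.integer(liab > quantile(liab, 0.7))
  fit <- fit_estimated_liability(X, status, seed = 207)
  cf <- fit$coefficients[paste0("t", 1:12)]
  expect_gt(abs(cf["t1"]), 0)
  expect_gte(sum(cf[-1] == 0), 8)  # most noise traits dropped
  expect_gt(cor(fit$score, liab), 0.3)
  # 2se penalty is at least as strong as 1se
  fit1 <- fit_estimated_liability(X, status, rule = "1se", seed = 207)
  expect_gte(fit$lambda, fit1$lambda)
  expect_error(fit_estimated_liability(X, rep(0, n)), "fewer cases")
})

test_that("incident case sets follow the interval-censoring rules on a toy table", {
  co <- make_toy_cohort()
  sets <- incident_case_sets(co, "d1", n_bins = 5, seed = 208)
  # 10 diagnoses at distinct ages -> 2 cases per quintile
  expect_length(sets, 5)
  for (cc in sets) {
    expect_length(cc$cases, 2)
    expect_length(cc$controls, 2)
    expect_length(intersect(cc$cases, cc$controls), 0)
  }
  # brute-force check of bin 3 (dx ages 47..56 quintiles): cases are the
  # 5th and 6th earliest diagnoses; anyone diagnosed earlier is excluded
  dx_ages <- c(41, 44, 47, 50, 53, 56, 59, 62, 65, 68)
  qs <- quantile(dx_ages, probs = seq(0, 1, 0.2))
  expected_cases <- sprintf("s%02d", which(dx_ages > qs[3] &
                                             dx_ages <= qs[4]))
  expect_setequal(sets[[3]]$cases, expected_cases)
  # controls never include anyone diagnosed by the interval end
  for (cc in sets) {
    dxc <- dx_ages[match(cc$controls, sprintf("s%02d", 1:10))]
    expect_true(all(is.na(dxc) | dxc > cc$interval["hi"]))
  }
})

test_that("loss to follow-up within the interval is a control only when enabled", {
  co <- make_toy_cohort()
  # individual s11 (never diagnosed) censored inside bin 5's interval
  co$subjects$censor_age[co$subjects$id == "s11"] <- 66.5
  s_with <- incident_case_sets(co, "d1", seed = 1, include_ltfu = TRUE)
  s_without <- incident_case_sets(co, "d1", seed = 1, include_ltfu = FALSE)
  last <- length(s_with)
  # eligible pools before down-sampling differ exactly by s11; with only
  # 2 never-diagnosed subjects the pools are small enough to be exhaustive
  expect_true("s11" %in% s_with[[last]]$controls)
  expect_false("s11" %in% s_without[[last]]$controls)
})

test_that("prevalent case sets accumulate cases across age points", {
  co <- make_toy_cohort()
  inc <- incident_case_sets(co, "d1", seed = 209)
  ages <- vapply(inc, `[[`, numeric(1), "median_case_age")
  prev <- prevalent_case_sets(co, "d1", baseline_ages = ages, seed = 210)
  dx_ages <- c(41, 44, 47, 50, 53, 56, 59, 62, 65, 68)
  for (k in seq_along(prev)) {
    expected_cases <- sum(dx_ages < ages[k])
    # control pool: the 2 never-diagnosed plus anyone diagnosed later,
    # capped at the case count by 1:1 down-sampling
    pool <- sum(dx_ages >= ages[k]) + 2
    expect_length(prev[[k]]$cases, expected_cases)
    expect_length(prev[[k]]$controls, min(expected_cases, pool))
  }
  # counts grow with the age point
  ns <- vapply(prev, function(x) length(x$cases), integer(1))
  expect_true(all(diff(ns) > 0))
  expect_error(prevalent_case_sets(co, "d1", baseline_ages = 30),
               "no prevalent cases")
})

test_that("observed R2 matches the direct correlation formula", {
  y <- c(1, 1, 1, 0, 0, 0)
  s <- c(2, 1, 0, 1, 0, -1)
  # hand formula: r = cov(y, s) / (sd(y) sd(s))
  r_hand <- sum((y - mean(y)) * (s - mean(s))) /
    sqrt(sum((y - mean(y))^2) * sum((s - mean(s))^2))
  est <- observed_r2(s, y)
  expect_equal(est$value, r_hand^2, tolerance = 1e-12)
  # score equal to the residualized outcome gives R2 = 1
  set.seed(211)
  yy <- rbinom(50, 1, 0.5)
  covs <- cbind(rnorm(50))
  res <- yy - fitted(lm(yy ~ covs))
  expect_equal(observed_r2(res, yy, covs)$value, 1, tolerance = 1e-8)
  # orthogonal score
  expect_lt(observed_r2(rnorm(5000), rbinom(5000, 1, 0.5))$value, 0.002)
  expect_error(observed_r2(rep(1, 10), rbinom(10, 1, 0.5)), "constant")
})

test_that("association metrics behave at the boundaries and under a survival oracle", {
  # perfectly separating score
  out <- c(rep(0, 20), rep(1, 20))
  sc <- c(rnorm(20, -3), rnorm(20, 3))
  expect_equal(association_metrics(sc, out, metric = "auc")$value, 1)
  # independent score
  set.seed(212)
  o2 <- rbinom(4000, 1, 0.5)
  s2 <- rnorm(4000)
  a <- association_metrics(s2, o2, metric = "auc")
  expect_lt(abs(a$value - 0.5), 3 * a$se)
  lo <- association_metrics(s2, o2, metric = "log_or")
  expect_lt(abs(lo$value), 3 * lo$se)
  le <- association_metrics(s2, o2, metric = "linear_effect")
  expect_lt(abs(le$value), 3 * le$se)
  # exponential survival with hazard ratio e per unit score -> log HR ~ 1
  set.seed(213)
  n <- 4000
  s3 <- rnorm(n)
  time <- rexp(n, rate = exp(s3))
  hr <- association_metrics(s3, rep(1, n), metric = "log_hr", time = time)
  expect_lt(abs(hr$value - 1), 3 * hr$se)
  expect_error(association_metrics(s3, rep(1, n), metric = "log_hr"),
               "time")
})

test_that("liability-scale transformation is exact at 0, monotone, and invertible", {
  expect_equal(liability_r2_transform(0, 0.1, 0.5), 0)
  grid <- seq(0.01, 0.2, by = 0.01)
  vals <- liability_r2_transform(grid, 0.1, 0.5)
  expect_true(all(diff(vals) > 0))
  # algebraic inverse round-trips
  back <- agearch:::observed_r2_from_liability(vals, 0.1, 0.5)
  expect_equal(back, grid, tolerance = 1e-10)
  # unascertained sample (P = K) reduces to the classic K(1-K)/z^2 factor
  K <- 0.2
  z <- dnorm(qnorm(1 - K))
  expect_equal(liability_r2_transform(0.01, K, K),
               0.01 * K * (1 - K) / z^2, tolerance = 1e-3)
  expect_error(liability_r2_transform(-0.1, 0.1, 0.5), "non-negative")
})

test_that("liability-scale correlation recovers a known latent correlation", {
  set.seed(214)
  n <- 200000
  l <- rnorm(n)
  quant <- 0.6 * l + sqrt(1 - 0.36) * rnorm(n)
  K <- 0.2
  binary <- as.integer(l > qnorm(1 - K))
  r <- liability_scale_correlation(quant, binary)
  expect_lt(abs(r - 0.6), 0.02)
  expect_equal(liability_scale_correlation(-quant, binary), -r,
               tolerance = 1e-12)
  # independent trait
  expect_lt(abs(liability_scale_correlation(rnorm(n), binary)), 0.01)
  expect_error(liability_scale_correlation(rep(1, 10), rep(0:1, 5)),
               "constant")
})

test_that("QRS pipeline matches liability-scale R2 and reports Monte-Carlo spread", {
  g <- simulate_genotypes(4000, 300, seed = 215)
  cfg <- cohort_config(
    traits = list(trait_spec("t1", h2 = 0.5),
                  trait_spec("t2", h2 = 0.3)),
    diseases = disease_spec("d", h2 = 0.5, prevalence = 0.25,
                            link_trait = "t1", link_rho = 0.8),
    n_visits = 1, followup_years = 30
  )
  out <- simulate_cohort(g, cfg, seed = 216)
  co <- out$cohort
  dsim <- out$liability$diseases$d
  prs <- calibrate_predictor(dsim$liability$G, 0.3, seed = 217)
  v1 <- co$visits[co$visits$visit == 1, ]
  X <- cbind(t1 = v1$value[v1$trait == "t1"][match(co$subjects$id,
                                                   v1$id[v1$trait == "t1"])],
             t2 = v1$value[v1$trait == "t2"][match(co$subjects$id,
                                                   v1$id[v1$trait == "t2"])])
  status <- as.integer(co$subjects$id %in%
                         co$diagnoses$id[co$diagnoses$disease == "d"])
  el <- fit_estimated_liability(X, status, seed = 218)
  qp <- qrs_pipeline(el$score, prs, co, "d", n_mc = 12, seed = 219)

  expect_equal(nrow(qp$per_bin), 5)
  expect_true(all(qp$per_bin$qrs_r2_sd > 0))
  expect_gte(qp$noise_var, 0)
  # noise matching: reconstruct matched QRS draws and verify their average
  # liability-scale R2 hits the PRS target (tolerance reflects this n)
  qrs_adj <- agearch:::residualize(rank_normal(el$score),
                                   cbind(co$subjects$baseline_age,
                                         co$subjects$sex))
  set.seed(220)
  r2l_draws <- replicate(20, {
    matched <- qrs_adj + rnorm(length(qrs_adj), 0, sqrt(qp$noise_var))
    r2o <- observed_r2(matched, status,
                       cbind(co$subjects$baseline_age,
                             co$subjects$sex))$value
    liability_r2_transform(r2o, qp$K, qp$K)
  })
  expect_lt(abs(mean(r2l_draws) - qp$r2_liab_prs), 0.01)
  # a PRS already stronger than the QRS triggers the zero-noise path
  dsim <- out$liability$diseases$d
  prs_strong <- calibrate_predictor(dsim$liability$G + dsim$liability$E0,
                                    0.99, seed = 221)
  expect_warning(
    qp0 <- qrs_pipeline(el$score, prs_strong, co, "d", n_mc = 2,
                        seed = 222),
    "no noise added")
  expect_equal(qp0$noise_var, 0)
})
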