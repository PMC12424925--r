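test_that("GRM has unit diagonal mean, near-zero off-diagonals, and flags duplicates", {
  g <- simulate_genotypes(80, 500, seed = 61)
  A <- compute_grm(g)
  expect_equal(mean(diag(A)), 1, tolerance = 0.05)
  off <- A[upper.tri(A)]
  expect_lt(abs(mean(off)), 0.02)
  # duplicating an individual gives a cross-entry matching the diagonal
  dup <- genotype_matrix(rbind(g$dosages, g$dosages[1, ]))
  A2 <- compute_grm(dup)
  expect_equal(A2[1, 81], A2[1, 1], tolerance = 1e-12)
  # brute-force oracle for one entry: mean of standardized cross-products
  Z <- standardize_genotypes(g)$Z
  expect_equal(A[2, 3], mean(Z[2, ] * Z[3, ]), tolerance = 1e-12)
})

test_that("monomorphic SNPs are excluded with a warning", {
  g <- simulate_genotypes(30, 10, seed = 62)
  d <- g$dosages
  d[, 4] <- 1L
  g2 <- genotype_matrix(d)
  expect_warning(std <- standardize_genotypes(g2), "monomorphic")
  expect_identical(std$kept, setdiff(1:10, 4))
})

test_that("HE slope equals the brute-force pairwise regression", {
  set.seed(63)
  n <- 40
  g <- simulate_genotypes(n, 60, seed = 63)
  A <- compute_grm(g)
  y <- make_heritable_phenotype(g, 0.4, 64)
  ys <- (y - mean(y)) / sd(y)
  pairs <- t(utils::combn(n, 2))
  x <- A[pairs]
  p <- ys[pairs[, 1]] * ys[pairs[, 2]]
  oracle <- unname(coef(lm(p ~ x))[2])
  est <- he_heritability(y, NULL, A, n_jackknife_blocks = 8)
  expect_equal(est$h2, oracle, tolerance = 1e-10)
  # leave-block-out algebra agrees with direct recomputation
  drop_idx <- 1:5
  keep <- setdiff(1:n, drop_idx)
  kp <- t(utils::combn(keep, 2))
  oracle_loo <- unname(coef(lm(ys[kp[, 1]] * ys[kp[, 2]] ~ A[kp]))[2])
  pre <- agearch:::he_precompute(A, ys)
  loo <- agearch:::he_slope_from_sums(
    agearch:::he_pair_sums(pre, drop_idx = drop_idx))
  expect_equal(loo, oracle_loo, tolerance = 1e-10)
})

test_that("HE heritability is calibrated: null, recovery, and degenerate input", {
  g <- simulate_genotypes(1500, 600, seed = 65)
  A <- compute_grm(g)
  set.seed(66)
  noise <- rnorm(1500)
  est0 <- he_heritability(noise, NULL, A)
  expect_lt(abs(est0$h2), 3 * est0$se)
  y <- make_heritable_phenotype(g, 0.5, 67)
  est <- he_heritability(y, NULL, A)
  expect_lt(abs(est$h2 - 0.5), 3 * est$se)
  expect_error(he_heritability(rep(1, 1500), NULL, A), "constant")
  # phenotype equal to a covariate leaves a constant residual
  x <- rnorm(1500)
  expect_error(he_heritability(x, cbind(x), A), "constant")
})

test_that("HE estimator is unbiased and its jackknife se tracks the empirical sd", {
  reps <- 50
  h2hat <- numeric(reps)
  sehat <- numeric(reps)
  for (i in seq_len(reps)) {
    g <- simulate_genotypes(500, 300, seed = 700 + i)
    A <- compute_grm(g)
    y <- make_heritable_phenotype(g, 0.3, 800 + i)
    e <- he_heritability(y, NULL, A, n_jackknife_blocks = 25)
    h2hat[i] <- e$h2
    sehat[i] <- e$se
  }
  mc_se <- sd(h2hat) / sqrt(reps)
  expect_lt(abs(mean(h2hat) - 0.3), 3 * mc_se)
  # never truncated: sampling spread at this size must produce estimates
  # outside [0, 1] occasionally, or at least a continuum of values
  expect_gt(sd(h2hat), 0.01)
  ratio <- mean(sehat) / sd(h2hat)
  expect_gt(ratio, 1 / 1.5)
  expect_lt(ratio, 1.5)
})

test_that("cross-sample HE genetic correlation recovers shared, null, and mixed G", {
  # same G, fresh environmental noise -> rg ~ 1
  d <- make_two_bin_phenotypes(1000, 500, h2 = 0.5, rg = 1, seed = 91)
  K <- compute_cross_grm(d$ga, d$gb)
  e1 <- he_genetic_correlation(d$ya, d$yb, K, grm_a = compute_grm(d$ga),
                               grm_b = compute_grm(d$gb),
                               n_jackknife_blocks = 25)
  expect_lt(abs(e1$rg - 1), 3 * e1$se)
  # independent genetic effects -> rg ~ 0
  d0 <- make_two_bin_phenotypes(1000, 500, h2 = 0.5, rg = 0, seed = 92)
  K0 <- compute_cross_grm(d0$ga, d0$gb)
  e0 <- he_genetic_correlation(d0$ya, d0$yb, K0, grm_a = compute_grm(d0$ga),
                               grm_b = compute_grm(d0$gb),
                               n_jackknife_blocks = 25)
  expect_lt(abs(e0$rg), 3 * e0$se)
  # rg = 0.5 mixture recovered within 3 se
  d5 <- make_two_bin_phenotypes(1500, 700, h2 = 0.5, rg = 0.5, seed = 93)
  K5 <- compute_cross_grm(d5$ga, d5$gb)
  e5 <- he_genetic_correlation(d5$ya, d5$yb, K5, grm_a = compute_grm(d5$ga),
                               grm_b = compute_grm(d5$gb),
                               n_jackknife_blocks = 25)
  expect_lt(abs(e5$rg - 0.5), 3 * e5$se)
})

test_that("genetic correlation errors on non-positive heritability", {
  d <- make_two_bin_phenotypes(300, 200, h2 = 0.5, rg = 1, seed = 94)
  K <- compute_cross_grm(d$ga, d$gb)
  set.seed(95)
  expect_error(
    he_genetic_correlation(rnorm(300), d$yb, K, h2_a = -0.1, h2_b = 0.5),
    "non-positive heritability")
  expect_error(
    he_genetic_correlation(d$ya, d$yb, K),
    "supply either")
})

test_that("per-bin estimates form quintiles and track EA-driven heritability decline", {
  g <- simulate_genotypes(5000, 800, seed = 96)
  cfg <- cohort_config(
    traits = list(trait_spec("flat", h2 = 0.5),
                  trait_spec("ea", h2 = 0.5, ea_var = 0.4)),
    n_visits = 1
  )
  out <- simulate_cohort(g, cfg, seed = 97)
  grm <- compute_grm(g)
  tab_flat <- per_bin_estimates(out$cohort, "flat", grm,
                                n_jackknife_blocks = 25)
  tab_ea <- per_bin_estimates(out$cohort, "ea", grm,
                              n_jackknife_blocks = 25)
  # quintile boundaries: each bin n within 1 of n/5
  expect_true(all(abs(tab_flat$n - 1000) <= 1))
  expect_true(all(diff(tab_flat$median_age) > 0))
  # flat trait: per-bin estimates consistent with a common value
  pooled <- sum(tab_flat$estimate / tab_flat$se^2) / sum(1 / tab_flat$se^2)
  expect_true(all(abs(tab_flat$estimate - pooled) <= 3.5 * tab_flat$se))
  # EA trait: generator arithmetic h2_k = h2 / (1 + k * ea_var)
  expected <- 0.5 / (1 + (1:5) * 0.4)
  expect_true(all(abs(tab_ea$estimate - expected) <= 3.5 * tab_ea$se))
  # declining point estimates overall: bin 5 clearly below bin 1
  expect_lt(tab_ea$estimate[5], tab_ea$estimate[1])
  # phenotypic variance grows for the EA trait, flat otherwise
  expect_gt(tab_ea$phen_var[5], tab_ea$phen_var[1])
  expect_true(all(c("phen_var_male", "phen_var_female") %in%
                    names(tab_ea)))
})

test_that("undersized bins are skipped with a warning", {
  g <- simulate_genotypes(120, 100, seed = 98)
  cfg <- cohort_config(traits = trait_spec("t", h2 = 0.3), n_visits = 1)
  out <- simulate_cohort(g, cfg, seed = 99)
  grm <- compute_grm(g)
  ws <- capture_warnings(
    tab <- per_bin_estimates(out$cohort, "t", grm, min_bin_n = 500))
  expect_true(length(ws) == 5 && all(grepl("skipped", ws)))
  expect_null(tab)
})
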