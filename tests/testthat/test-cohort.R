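test_that("cohort traits carry the configured genetic architecture", {
  g <- simulate_genotypes(4000, 800, seed = 21)
  cfg <- cohort_config(
    traits = list(trait_spec("null_trait", h2 = 0),
                  trait_spec("herit_trait", h2 = 0.5)),
    n_visits = 1
  )
  out <- simulate_cohort(g, cfg, seed = 22)
  # liability decomposes additively
  ht <- out$liability$traits$herit_trait
  expect_equal(ht$liability, ht$G + ht$E + ht$ea_sum, tolerance = 1e-12)
  expect_lt(abs(var(ht$G) - 0.5), 0.06)
  # HE regression recovers the generating h2 within 3 jackknife se
  grm <- compute_grm(g)
  v <- out$cohort$visits
  y <- v$value[v$trait == "herit_trait"][match(out$cohort$subjects$id,
                                               v$id[v$trait == "herit_trait"])]
  est <- he_heritability(y, cbind(out$cohort$subjects$sex), grm)
  expect_lt(abs(est$h2 - 0.5), 3 * est$se)
  # h2 = 0: HE estimate consistent with zero genetics
  yn <- v$value[v$trait == "null_trait"][match(out$cohort$subjects$id,
                                               v$id[v$trait == "null_trait"])]
  est0 <- he_heritability(yn, NULL, grm)
  expect_lt(abs(est0$h2), 3 * est0$se)
})

test_that("visits without measurement error repeat the liability exactly", {
  g <- simulate_genotypes(500, 100, seed = 23)
  cfg <- cohort_config(traits = trait_spec("t", h2 = 0.4,
                                           measurement_error_var = 0),
                       n_visits = 2)
  out <- simulate_cohort(g, cfg, seed = 24)
  v <- out$cohort$visits
  v1 <- v$value[v$visit == 1][order(v$id[v$visit == 1])]
  v2 <- v$value[v$visit == 2][order(v$id[v$visit == 2])]
  expect_equal(cor(v1, v2), 1)
})

test_that("EA traits show growing variance across baseline-age bins", {
  g <- simulate_genotypes(6000, 400, seed = 25)
  cfg <- cohort_config(traits = trait_spec("ea_t", h2 = 0.3, ea_var = 0.3),
                       n_visits = 1)
  out <- simulate_cohort(g, cfg, seed = 26)
  sub <- out$cohort$subjects
  lt <- out$liability$traits$ea_t
  v_by_bin <- tapply(lt$liability, sub$age_bin, var)
  # generator arithmetic: var in bin k is 1 + k * ea_var
  expect_lt(max(abs(v_by_bin - (1 + (1:5) * 0.3))), 0.25)
  expect_true(all(diff(v_by_bin) > 0))
  # var(G) constant across bins
  g_by_bin <- tapply(lt$G, sub$age_bin, var)
  expect_lt(max(g_by_bin) - min(g_by_bin), 0.12)
})

test_that("disease onset, diagnosis ages and censoring are coherent", {
  g <- simulate_genotypes(3000, 200, seed = 27)
  cfg <- cohort_config(
    traits = trait_spec("t", h2 = 0.4),
    diseases = disease_spec("d1", h2 = 0.5, prevalence = 0.3,
                            medication_flag = "d1_med"),
    n_visits = 1
  )
  out <- simulate_cohort(g, cfg, seed = 28)
  dx <- out$cohort$diagnoses
  sub <- out$cohort$subjects
  expect_true(all(dx$age_at_diagnosis <=
                    sub$censor_age[match(dx$id, sub$id)]))
  expect_true("d1_med" %in% names(sub))
  # medicated mostly among the diagnosed
  med_dx <- mean(sub$d1_med[sub$id %in% dx$id])
  med_no <- mean(sub$d1_med[!sub$id %in% dx$id])
  expect_gt(med_dx, med_no)
  # onset machinery matches the configured prevalence scale
  onset <- out$liability$diseases$d1$liability$onset_bin
  expect_equal(sum(!is.na(onset)), 5 * floor(0.3 / 5 * 3000))
})

test_that("stationary-decay longitudinal liability has the closed-form correlation", {
  v <- simulate_longitudinal_liability(30000, "stationary_decay", beta = 0.02,
                                       visit_ages = c(50, 60),
                                       measurement_error_var = 0, seed = 31)
  w <- reshape(v[c("id", "visit", "value")], direction = "wide",
               idvar = "id", timevar = "visit")
  expect_lt(abs(cor(w$value.1, w$value.2) - exp(-0.2)), 0.01)
  # beta = 0: liability identical across visits
  v0 <- simulate_longitudinal_liability(100, "stationary_decay", beta = 0,
                                        visit_ages = c(50, 55, 60),
                                        measurement_error_var = 0.5,
                                        seed = 32)
  w0 <- reshape(v0[c("id", "visit", "liability")], direction = "wide",
                idvar = "id", timevar = "visit")
  expect_equal(w0$liability.1, w0$liability.3)
})

test_that("wiener-mode variance grows linearly; stationary mode is product-multiplicative", {
  v <- simulate_longitudinal_liability(40000, "wiener", beta = 0.05,
                                       visit_ages = c(50, 60, 70),
                                       measurement_error_var = 0, seed = 33)
  by_visit <- as.numeric(tapply(v$liability, v$visit, var))
  expect_equal(by_visit, c(1, 1.5, 2), tolerance = 0.05)
  # stationary: corr(t1,t3) = corr(t1,t2) * corr(t2,t3) exactly in the model
  vs <- simulate_longitudinal_liability(40000, "stationary_decay",
                                        beta = 0.03,
                                        visit_ages = c(50, 55, 65),
                                        measurement_error_var = 0, seed = 34)
  w <- reshape(vs[c("id", "visit", "value")], direction = "wide",
               idvar = "id", timevar = "visit")
  r12 <- cor(w$value.1, w$value.2)
  r23 <- cor(w$value.2, w$value.3)
  r13 <- cor(w$value.1, w$value.3)
  expect_lt(abs(r13 - r12 * r23), 0.02)
})

test_that("medication corrections shift flagged values and keep originals", {
  co <- make_visit_cohort(n = 100, seed = 41)
  rules <- list(
    medication_rule("sbp", "med_flag", 15, unit_mode = "absolute")
  )
  co2 <- apply_medication_correction(co, rules)
  v <- co2$visits
  raw <- v[v$trait == "sbp" & v$visit == 1, ]
  corr <- v[v$trait == "sbp_corrected" & v$visit == 1, ]
  corr <- corr[match(raw$id, corr$id), ]
  flagged <- co$subjects$med_flag[match(raw$id, co$subjects$id)] == 1
  expect_equal(corr$value[flagged], raw$value[flagged] + 15)
  expect_equal(corr$value[!flagged], raw$value[!flagged])
  # sd-mode uses the whole-population standard deviation
  co3 <- apply_medication_correction(
    co, medication_rule("sbp", "med_flag", 0.5, unit_mode = "sd"))
  sd_pop <- sd(co$visits$value[co$visits$trait == "sbp"])
  v3 <- co3$visits
  raw3 <- v3[v3$trait == "sbp" & v3$visit == 2, ]
  corr3 <- v3[v3$trait == "sbp_corrected" & v3$visit == 2, ]
  corr3 <- corr3[match(raw3$id, corr3$id), ]
  fl <- co$subjects$med_flag[match(raw3$id, co$subjects$id)] == 1
  expect_equal(corr3$value[fl], raw3$value[fl] + 0.5 * sd_pop)
  expect_error(
    apply_medication_correction(co, medication_rule("sbp", "nope", 1)),
    "unknown medication flag")
  expect_error(
    apply_medication_correction(co, medication_rule("nope", "med_flag", 1)),
    "unknown trait")
})

test_that("stacked rules on one trait compose additively", {
  co <- make_visit_cohort(n = 50, seed = 43)
  co2 <- apply_medication_correction(co, list(
    medication_rule("sbp", "med_flag", 10),
    medication_rule("sbp", "med_flag", 5)
  ))
  v <- co2$visits
  raw <- v[v$trait == "sbp" & v$visit == 1, ]
  corr <- v[v$trait == "sbp_corrected" & v$visit == 1, ]
  corr <- corr[match(raw$id, corr$id), ]
  fl <- co$subjects$med_flag[match(raw$id, co$subjects$id)] == 1
  expect_equal(corr$value[fl], raw$value[fl] + 15)
})

test_that("age-matched resampling equalizes group age distributions", {
  set.seed(51)
  n <- 6000
  subjects <- data.frame(
    id = as.character(seq_len(n)), sex = 0L,
    baseline_age = c(rnorm(n / 2, 50, 6), rnorm(n / 2, 60, 6)),
    censor_age = 90
  )
  co <- cohort_table(subjects)
  grp <- rep(c(0, 1), each = n / 2)
  res <- age_matched_resample(co, grp, n_per_group = 1000, seed = 52)
  m1 <- mean(subjects$baseline_age[res$group1])
  m2 <- mean(subjects$baseline_age[res$group2])
  expect_lt(abs(m1 - m2), 1)
  # raw difference was ~10 years
  expect_gt(abs(mean(subjects$baseline_age[grp == 1]) -
                  mean(subjects$baseline_age[grp == 0])), 8)
  # reproducible
  res2 <- age_matched_resample(co, grp, n_per_group = 1000, seed = 52)
  expect_identical(res, res2)
  expect_error(age_matched_resample(co, grp, n_per_group = n), "exceeds")
  # disjoint supports are infeasible
  subjects$baseline_age <- c(rep(45, n / 2), rep(75, n / 2))
  co2 <- cohort_table(subjects)
  expect_error(age_matched_resample(co2, grp, 10), "overlap")
})

test_that("identically distributed groups get near-uniform weights", {
  set.seed(53)
  n <- 4000
  subjects <- data.frame(id = as.character(seq_len(n)), sex = 0L,
                         baseline_age = runif(n, 40, 79), censor_age = 90)
  co <- cohort_table(subjects)
  grp <- rep(c(0, 1), n / 2)
  res <- age_matched_resample(co, grp, n_per_group = 800, seed = 54)
  m1 <- mean(subjects$baseline_age[res$group1])
  m2 <- mean(subjects$baseline_age[res$group2])
  expect_lt(abs(m1 - m2), 1)
})

test_that("cohort table enforces its invariants", {
  s <- data.frame(id = "a", sex = 0L, baseline_age = 50, censor_age = 60)
  expect_error(
    cohort_table(s, diagnoses = data.frame(id = "a", disease = "d",
                                           age_at_diagnosis = 70)),
    "censoring age")
  bad_visits <- data.frame(id = "a", trait = "t", visit = 1:2,
                           age = c(55, 55), value = 0)
  expect_error(cohort_table(s, visits = bad_visits), "strictly increasing")
  expect_error(cohort_table(data.frame(id = "a")), "must contain")
})
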