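# Shared fixture builders; all fixtures are generated in code.

# Genotype panel split into two disjoint samples sharing SNP frequencies,
# with phenotypes of given heritability and genetic correlation.
make_two_bin_phenotypes <- function(n_per_bin, m, h2, rg, seed) {
  set.seed(seed)
  g <- simulate_genotypes(2 * n_per_bin, m, seed = seed + 1)
  ia <- seq_len(n_per_bin)
  ib <- n_per_bin + ia
  ga <- genotype_matrix(g$dosages[ia, ])
  gb <- genotype_matrix(g$dosages[ib, ])
  Za <- standardize_genotypes(ga)$Z
  Zb <- standardize_genotypes(gb)$Z
  u <- rnorm(m)
  ba <- sqrt(h2 / m) * (sqrt(rg) * u + sqrt(1 - rg) * rnorm(m))
  bb <- sqrt(h2 / m) * (sqrt(rg) * u + sqrt(1 - rg) * rnorm(m))
  list(
    ga = ga, gb = gb,
    ya = as.numeric(Za %*% ba + rnorm(n_per_bin, 0, sqrt(1 - h2))),
    yb = as.numeric(Zb %*% bb + rnorm(n_per_bin, 0, sqrt(1 - h2)))
  )
}

# Phenotype with known h2 on top of a genotype panel.
make_heritable_phenotype <- function(genotypes, h2, seed) {
  set.seed(seed)
  Z <- standardize_genotypes(genotypes)$Z
  m <- ncol(Z)
  b <- rnorm(m, 0, sqrt(h2 / m))
  as.numeric(Z %*% b + rnorm(nrow(Z), 0, sqrt(1 - h2)))
}

# Tiny hand-checkable cohort: 12 individuals, one disease with known
# diagnosis ages, wide follow-up so everyone is observed.
make_toy_cohort <- function() {
  subjects <- data.frame(
    id = sprintf("s%02d", 1:12),
    sex = rep(c(0L, 1L), 6),
    baseline_age = c(45, 50, 55, 60, 65, 70, 48, 53, 58, 63, 68, 73),
    censor_age = rep(85, 12)
  )
  # 10 diagnosed at distinct ages, 2 never diagnosed
  diagnoses <- data.frame(
    id = sprintf("s%02d", 1:10),
    disease = "d1",
    age_at_diagnosis = c(41, 44, 47, 50, 53, 56, 59, 62, 65, 68)
  )
  cohort_table(subjects, visits = NULL, diagnoses = diagnoses)
}

# Cohort with one trait measured at three visits, for medication and
# correlation tests.
make_visit_cohort <- function(n = 200, seed = 42, noise = 0) {
  set.seed(seed)
  subjects <- data.frame(
    id = sprintf("v%04d", seq_len(n)),
    sex = rbinom(n, 1, 0.5),
    baseline_age = runif(n, 40, 79),
    censor_age = 90,
    med_flag = rbinom(n, 1, 0.3)
  )
  liab <- rnorm(n, 130, 15)
  visits <- do.call(rbind, lapply(1:3, function(v) {
    data.frame(id = subjects$id, trait = "sbp", visit = v,
               age = subjects$baseline_age + (v - 1) * 4,
               value = liab + rnorm(n, 0, noise))
  }))
  cohort_table(subjects, visits = visits, diagnoses = NULL)
}
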