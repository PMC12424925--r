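# Synthetic cohort generation.
#
# Emulates the inputs the downstream analysis assumes: a middle-aged cohort
# (baseline ages 40-79), sex, unlinked genotypes, quantitative traits with a
# specified heritability and optional exposure-accumulation structure across
# baseline-age bins, up to three longitudinal visits with measurement error,
# liability-threshold disease onset ages, censoring, and medication flags.

#' Specify a quantitative trait for cohort simulation
#'
#' @param name trait name.
#' @param h2 heritability of the trait liability in \[0, 1\].
#' @param ea_var per-age-bin exposure-accumulation variance (>= 0). An
#'   individual whose baseline age falls in bin k receives k independent
#'   Normal(0, ea_var) increments, so trait variance grows and heritability
#'   falls as h2 / (1 + k * ea_var) across baseline-age bins.
#' @param measurement_error_var variance of the iid per-visit measurement
#'   noise.
#' @param age_slope linear fixed effect of baseline age bin on the trait.
#' @param sex_var_ratio ratio of male to female environmental variance
#'   (1 = none).
#' @return a `trait_spec` list.
#' @export
trait_spec <- function(name, h2, ea_var = 0, measurement_error_var = 0,
                       age_slope = 0, sex_var_ratio = 1) {
  check_number(h2, "h2", 0, 1)
  check_number(ea_var, "ea_var", lower = 0)
  check_number(measurement_error_var, "measurement_error_var", lower = 0)
  check_number(sex_var_ratio, "sex_var_ratio", lower = 0)
  structure(list(name = name, h2 = h2, ea_var = ea_var,
                 measurement_error_var = measurement_error_var,
                 age_slope = age_slope, sex_var_ratio = sex_var_ratio),
            class = "trait_spec")
}

#' Specify a disease for cohort simulation
#'
#' Onset is generated by the liability-threshold simulators: total
#' prevalence is split evenly over `n_bins` onset bins and each bin's cases
#' are the top slice of (current) disease liability.
#'
#' @param name disease name.
#' @param h2 liability-scale heritability.
#' @param prevalence lifetime prevalence in (0, 1).
#' @param ea_var per-bin liability increment variance (0 = linear model).
#' @param medication_flag optional name of a medication flag; diagnosed
#'   individuals carry the flag with probability `p_medicated`.
#' @param p_medicated probability a diagnosed individual is medicated.
#' @param p_background background medication rate among the undiagnosed.
#' @param link_trait optional trait name whose genetic and environmental
#'   components are mixed into the disease liability, making the trait an
#'   informative predictor of the disease (as quantitative risk factors
#'   are for real diseases).
#' @param link_rho mixing weight in \[0, 1\] for the linked trait; the
#'   liability correlation between disease and trait is at most this.
#' @return a `disease_spec` list.
#' @export
disease_spec <- function(name, h2, prevalence, ea_var = 0,
                         medication_flag = NULL, p_medicated = 0.8,
                         p_background = 0.02, link_trait = NULL,
                         link_rho = 0.6) {
  check_number(h2, "h2", 0, 1)
  check_number(prevalence, "prevalence", 1e-6, 1 - 1e-6)
  check_number(ea_var, "ea_var", lower = 0)
  check_number(link_rho, "link_rho", 0, 1)
  structure(list(name = name, h2 = h2, prevalence = prevalence,
                 ea_var = ea_var, medication_flag = medication_flag,
                 p_medicated = p_medicated, p_background = p_background,
                 link_trait = link_trait, link_rho = link_rho),
            class = "disease_spec")
}

#' Configuration for [simulate_cohort()]
#'
#' @param traits list of [trait_spec()] objects.
#' @param diseases list of [disease_spec()] objects.
#' @param n_visits number of longitudinal visits (1-3).
#' @param visit_spacing years between consecutive visits.
#' @param age_range baseline-age range in years (uniformly sampled).
#' @param n_bins number of baseline-age bins (quintiles by default).
#' @param followup_years follow-up after baseline for censoring.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(traits, diseases = list(), n_visits = 3L,
                          visit_spacing = 4, age_range = c(40, 79),
                          n_bins = 5L, followup_years = 15) {
  n_visits <- check_count(n_visits, "n_visits")
  if (n_visits > 3L) stop_param("`n_visits` must be between 1 and 3")
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  if (inherits(diseases, "disease_spec")) diseases <- list(diseases)
  stopifnot(all(vapply(traits, inherits, logical(1), "trait_spec")),
            all(vapply(diseases, inherits, logical(1), "disease_spec")))
  structure(list(traits = traits, diseases = diseases, n_visits = n_visits,
                 visit_spacing = visit_spacing, age_range = age_range,
                 n_bins = as.integer(n_bins),
                 followup_years = followup_years),
            class = "cohort_config")
}

#' Simulate a cohort on top of a genotype matrix
#'
#' For each trait, per-SNP effects are drawn Normal(0, h2/m) on standardized
#' genotypes so that the genetic component G has variance h2 in expectation;
#' E is independent Normal(0, 1 - h2) (sex-scaled when requested); traits
#' with `ea_var > 0` additionally accumulate k independent Normal(0, ea_var)
#' increments for individuals in baseline-age bin k, giving the
#' exposure-accumulation signature (var(G) constant, var(E) growing).
#' Observed visit values add iid measurement noise to the trait liability.
#' Disease onset comes from the liability-threshold simulators applied to a
#' disease liability built the same way; onset bins are mapped to
#' age-at-first-diagnosis in years, and diagnoses after the censoring age
#' are unobserved.
#'
#' @param genotypes a `genotype_matrix`.
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return list with `cohort` (a `cohort_table`) and `liability` (per-trait
#'   and per-disease latent components: G, E, EA sums and the disease
#'   `simulated_disease` objects).
#' @export
simulate_cohort <- function(genotypes, config, seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "cohort_config"))
  n <- nrow(genotypes$dosages)
  Z <- standardize_genotypes(genotypes)$Z
  m <- ncol(Z)
  with_seed(seed, {
    subjects <- data.frame(
      id = genotypes$individual_ids,
      sex = stats::rbinom(n, 1L, 0.5),
      baseline_age = stats::runif(n, config$age_range[1L],
                                  config$age_range[2L])
    )
    subjects$censor_age <- pmin(subjects$baseline_age + config$followup_years,
                                85)
    breaks <- stats::quantile(subjects$baseline_age,
                              probs = seq(0, 1, length.out = config$n_bins + 1))
    subjects$age_bin <- as.integer(cut(subjects$baseline_age, breaks,
                                       include.lowest = TRUE))
    visit_ages <- outer(subjects$baseline_age,
                        (seq_len(config$n_visits) - 1L) * config$visit_spacing,
                        `+`)

    liability <- list(traits = list(), diseases = list())
    visits <- list()
    for (sp in config$traits) {
      b <- stats::rnorm(m, 0, sqrt(sp$h2 / m))
      G <- as.numeric(Z %*% b)
      e_sd <- sqrt(1 - sp$h2) *
        ifelse(subjects$sex == 1L, sqrt(sp$sex_var_ratio), 1)
      E <- stats::rnorm(n, 0, e_sd)
      ea_sum <- if (sp$ea_var > 0) {
        vapply(seq_len(n), function(i) {
          sum(stats::rnorm(subjects$age_bin[i], 0, sqrt(sp$ea_var)))
        }, numeric(1))
      } else {
        numeric(n)
      }
      liab <- G + E + ea_sum + sp$age_slope * subjects$age_bin
      liability$traits[[sp$name]] <- data.frame(id = subjects$id, G = G,
                                                E = E, ea_sum = ea_sum,
                                                liability = liab)
      for (v in seq_len(config$n_visits)) {
        noise <- stats::rnorm(n, 0, sqrt(sp$measurement_error_var))
        visits[[length(visits) + 1L]] <- data.frame(
          id = subjects$id, trait = sp$name, visit = v,
          age = visit_ages[, v], value = liab + noise
        )
      }
    }

    diagnoses <- list()
    onset_breaks <- seq(config$age_range[1L], config$age_range[2L] + 1,
                        length.out = config$n_bins + 1L)
    for (dsp in config$diseases) {
      b <- stats::rnorm(m, 0, sqrt(1 / m))
      g_own <- as.numeric(Z %*% b)
      e_own <- stats::rnorm(n)
      if (!is.null(dsp$link_trait)) {
        if (is.null(liability$traits[[dsp$link_trait]])) {
          stop_param("disease '", dsp$name, "' links to unknown trait: ",
                     dsp$link_trait)
        }
        lt <- liability$traits[[dsp$link_trait]]
        rho <- dsp$link_rho
        g1 <- if (stats::sd(lt$G) > 0) lt$G / stats::sd(lt$G) else lt$G
        e1 <- lt$E / stats::sd(lt$E)
        Gd <- sqrt(dsp$h2) * (rho * g1 + sqrt(1 - rho^2) *
                                g_own / stats::sd(g_own))
        Ed <- sqrt(1 - dsp$h2) * (rho * e1 + sqrt(1 - rho^2) * e_own)
      } else {
        Gd <- sqrt(dsp$h2) * g_own / stats::sd(g_own)
        Ed <- sqrt(1 - dsp$h2) * e_own
      }
      sim <- disease_from_components(Gd, Ed, n_bins = config$n_bins,
                                     bin_fraction = dsp$prevalence /
                                       config$n_bins,
                                     increment_var = dsp$ea_var)
      liability$diseases[[dsp$name]] <- sim
      onset <- sim$liability$onset_bin
      dx_age <- rep(NA_real_, n)
      has_onset <- which(!is.na(onset))
      dx_age[has_onset] <- stats::runif(length(has_onset),
                                        onset_breaks[onset[has_onset]],
                                        onset_breaks[onset[has_onset] + 1L])
      observed <- !is.na(dx_age) & dx_age <= subjects$censor_age
      if (any(observed)) {
        diagnoses[[length(diagnoses) + 1L]] <- data.frame(
          id = subjects$id[observed], disease = dsp$name,
          age_at_diagnosis = dx_age[observed]
        )
      }
      if (!is.null(dsp$medication_flag)) {
        p <- ifelse(observed, dsp$p_medicated, dsp$p_background)
        subjects[[dsp$medication_flag]] <- stats::rbinom(n, 1L, p)
      }
    }

    cohort <- cohort_table(
      subjects = subjects,
      visits = if (length(visits)) do.call(rbind, visits) else NULL,
      diagnoses = if (length(diagnoses)) do.call(rbind, diagnoses) else NULL
    )
    list(cohort = cohort, liability = liability)
  })
}

# Run the (EA) liability-threshold onset machinery on externally supplied
# G and E components, consuming the current RNG stream.
disease_from_components <- function(G, E0, n_bins, bin_fraction,
                                    increment_var = 0) {
  n <- length(G)
  tie_perm <- sample.int(n)
  n_cases_bin <- floor(bin_fraction * n)
  L <- G + E0
  onset <- rep(NA_integer_, n)
  liab_cols <- matrix(NA_real_, nrow = n, ncol = n_bins,
                      dimnames = list(NULL, paste0("L_bin", seq_len(n_bins))))
  incr <- matrix(0, nrow = n, ncol = max(n_bins - 1L, 0L))
  for (k in seq_len(n_bins)) {
    if (k > 1L && increment_var > 0) {
      incr[, k - 1L] <- stats::rnorm(n, 0, sqrt(increment_var))
      L <- L + incr[, k - 1L]
    }
    liab_cols[, k] <- L
    healthy <- which(is.na(onset))
    ord <- healthy[order(-L[healthy], tie_perm[healthy])]
    if (n_cases_bin > 0L) {
      onset[ord[seq_len(min(n_cases_bin, length(ord)))]] <- k
    }
  }
  new_simulated_disease(G, E0, liab_cols, onset, incr, n_bins, bin_fraction,
                        h2 = stats::var(G) / stats::var(G + E0),
                        model = if (increment_var > 0) "ea" else "linear",
                        increment_var = increment_var)
}

#' Construct a cohort table
#'
#' @param subjects data.frame with at least id, sex, baseline_age,
#'   censor_age; medication flags as extra 0/1 columns.
#' @param visits long data.frame (id, trait, visit, age, value) or NULL.
#' @param diagnoses data.frame (id, disease, age_at_diagnosis) or NULL.
#' @return a `cohort_table` object.
#' @export
cohort_table <- function(subjects, visits = NULL, diagnoses = NULL) {
  req <- c("id", "sex", "baseline_age", "censor_age")
  if (!all(req %in% names(subjects))) {
    stop_param("`subjects` must contain columns: ", paste(req, collapse = ", "))
  }
  if (!is.null(visits)) {
    ok <- tapply(visits$age, visits[c("id", "trait")], function(a) {
      all(diff(sort(a)) > 0) || length(a) == 1L
    })
    if (any(!ok, na.rm = TRUE)) {
      stop_param("visit ages must be strictly increasing per individual")
    }
  }
  if (!is.null(diagnoses)) {
    cens <- subjects$censor_age[match(diagnoses$id, subjects$id)]
    if (any(diagnoses$age_at_diagnosis > cens)) {
      stop_param("age_at_diagnosis must not exceed the censoring age")
    }
  }
  structure(list(subjects = subjects, visits = visits, diagnoses = diagnoses),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d individuals", nrow(x$subjects)))
  if (!is.null(x$visits)) {
    cat(sprintf(", %d traits x %d visits",
                length(unique(x$visits$trait)),
                length(unique(x$visits$visit))))
  }
  if (!is.null(x$diagnoses)) {
    cat(sprintf(", %d diagnoses (%d diseases)", nrow(x$diagnoses),
                length(unique(x$diagnoses$disease))))
  }
  cat("\n")
  invisible(x)
}

#' Simulate longitudinal liability with measurement error
#'
#' Two latent processes are offered. `stationary_decay`: liability has
#' constant unit variance and corr(l_t, l_(t+delta)) = exp(-beta * delta)
#' (a stationary Ornstein-Uhlenbeck-type autocorrelation); this is the
#' process under which the ratio-of-correlations denoising recovers the
#' decay exactly. `wiener`: independent increments of variance beta per
#' year on top of a unit-variance start, so liability variance grows
#' linearly with time. Observed values add iid Normal(0,
#' measurement_error_var) noise at every visit.
#'
#' @param n number of individuals.
#' @param process `"stationary_decay"` or `"wiener"`.
#' @param beta decay rate (per year) for stationary_decay, or increment
#'   variance per year for wiener; >= 0.
#' @param visit_ages numeric vector of at least 2 strictly increasing ages.
#' @param measurement_error_var per-visit noise variance.
#' @param seed integer seed.
#' @return data.frame (id, visit, age, liability, value).
#' @export
simulate_longitudinal_liability <- function(n, process = c("stationary_decay",
                                                           "wiener"),
                                            beta, visit_ages,
                                            measurement_error_var = 0,
                                            seed = NULL) {
  n <- check_count(n, "n", lower = 2L)
  process <- match.arg(process)
  check_number(beta, "beta", lower = 0)
  if (length(visit_ages) < 2L || any(diff(visit_ages) <= 0)) {
    stop_param("`visit_ages` must be >= 2 strictly increasing ages")
  }
  check_number(measurement_error_var, "measurement_error_var", lower = 0)
  k <- length(visit_ages)
  with_seed(seed, {
    liab <- matrix(NA_real_, n, k)
    liab[, 1L] <- stats::rnorm(n)
    for (v in seq_len(k - 1L)) {
      delta <- visit_ages[v + 1L] - visit_ages[v]
      if (process == "stationary_decay") {
        rho <- exp(-beta * delta)
        liab[, v + 1L] <- rho * liab[, v] +
          stats::rnorm(n, 0, sqrt(1 - rho^2))
      } else {
        liab[, v + 1L] <- liab[, v] + stats::rnorm(n, 0, sqrt(beta * delta))
      }
    }
    obs <- liab + stats::rnorm(n * k, 0, sqrt(measurement_error_var))
    data.frame(
      id = rep(seq_len(n), times = k),
      visit = rep(seq_len(k), each = n),
      age = rep(visit_ages, each = n),
      liability = as.vector(liab),
      value = as.vector(obs)
    )
  })
}

#' Define a medication-correction rule
#'
#' @param trait trait (visit-table) name the correction applies to.
#' @param flag name of the 0/1 medication column in the subjects table.
#' @param correction additive correction for flagged individuals, in trait
#'   units (`unit_mode = "absolute"`) or in whole-population standard
#'   deviations (`unit_mode = "sd"`).
#' @param unit_mode `"absolute"` or `"sd"`.
#' @return a `medication_rule` list.
#' @export
medication_rule <- function(trait, flag, correction,
                            unit_mode = c("absolute", "sd")) {
  unit_mode <- match.arg(unit_mode)
  check_number(correction, "correction")
  structure(list(trait = trait, flag = flag, correction = correction,
                 unit_mode = unit_mode),
            class = "medication_rule")
}

#' Apply medication corrections to trait measurements
#'
#' For each rule, flagged individuals' values of the target trait are
#' shifted additively; `sd`-mode corrections are multiples of the standard
#' deviation of the uncorrected trait computed in the entire population.
#' Both corrected and uncorrected values are retained: corrected
#' measurements appear as a new trait named `<trait>_corrected` in the
#' visits table. Multiple rules targeting the same trait compose on the
#' corrected values.
#'
#' @param cohort a `cohort_table`.
#' @param rules a list of [medication_rule()] objects (or a single rule).
#' @return the `cohort_table` with corrected trait columns added.
#' @export
apply_medication_correction <- function(cohort, rules) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (inherits(rules, "medication_rule")) rules <- list(rules)
  stopifnot(all(vapply(rules, inherits, logical(1), "medication_rule")))
  visits <- cohort$visits
  if (is.null(visits)) stop_param("cohort has no visit table")
  corrected <- list()
  for (rule in rules) {
    if (!rule$flag %in% names(cohort$subjects)) {
      stop_param("unknown medication flag: ", rule$flag)
    }
    if (!rule$trait %in% visits$trait) {
      stop_param("unknown trait: ", rule$trait)
    }
    key <- paste0(rule$trait, "_corrected")
    if (is.null(corrected[[key]])) {
      corrected[[key]] <- visits[visits$trait == rule$trait, ]
      corrected[[key]]$trait <- key
    }
    amount <- rule$correction
    if (rule$unit_mode == "sd") {
      amount <- amount * stats::sd(visits$value[visits$trait == rule$trait])
    }
    flagged <- cohort$subjects$id[cohort$subjects[[rule$flag]] == 1L]
    sel <- corrected[[key]]$id %in% flagged
    corrected[[key]]$value[sel] <- corrected[[key]]$value[sel] + amount
  }
  cohort$visits <- rbind(visits, do.call(rbind, unname(corrected)))
  rownames(cohort$visits) <- NULL
  cohort
}

#' Draw two age-matched samples by inverse-density weighting
#'
#' Sampling weights within each group are proportional to the inverse of
#' that group's age density (histogram-estimated on the shared support),
#' scaled by a common target density — the bin-wise minimum of the two
#' groups' densities, the largest target for which 1:1 matching is
#' feasible — so the two drawn samples have matched age distributions.
#'
#' @param table a `cohort_table` (baseline_age is the matching variable).
#' @param group_label logical/0-1 vector, one per individual, defining the
#'   two groups.
#' @param n_per_group number of individuals to draw from each group.
#' @param seed integer seed.
#' @param bin_width histogram bin width (years) for the density estimate.
#' @return list with integer index vectors `group1` and `group2` (rows of
#'   the subjects table).
#' @export
age_matched_resample <- function(table, group_label, n_per_group, seed = NULL,
                                 bin_width = 2) {
  stopifnot(inherits(table, "cohort_table"))
  age <- table$subjects$baseline_age
  g <- as.logical(group_label)
  if (length(g) != length(age)) {
    stop_param("`group_label` must have one entry per individual")
  }
  idx1 <- which(!g)
  idx2 <- which(g)
  if (!length(idx1) || !length(idx2)) stop_param("both groups must be non-empty")
  n_per_group <- check_count(n_per_group, "n_per_group")
  if (n_per_group > min(length(idx1), length(idx2))) {
    stop_param("`n_per_group` exceeds the smaller group size")
  }
  lo <- max(min(age[idx1]), min(age[idx2]))
  hi <- min(max(age[idx1]), max(age[idx2]))
  if (lo >= hi) stop_param("age supports of the two groups do not overlap")
  breaks <- seq(lo, hi + bin_width, by = bin_width)
  bin_of <- function(idx) {
    b <- rep(NA_integer_, length(idx))
    inside <- age[idx] >= lo & age[idx] <= hi
    b[inside] <- findInterval(age[idx][inside], breaks,
                              rightmost.closed = TRUE)
    b
  }
  b1 <- bin_of(idx1)
  b2 <- bin_of(idx2)
  nb <- length(breaks)
  c1 <- tabulate(b1[!is.na(b1)], nbins = nb)
  c2 <- tabulate(b2[!is.na(b2)], nbins = nb)
  target <- pmin(c1, c2)
  if (n_per_group > sum(target)) {
    stop_param("age matching infeasible: shared age support holds only ",
               sum(target), " matchable individuals per group")
  }
  # per-bin quotas proportional to the target density, capped at capacity;
  # identical quotas in both groups make the drawn age distributions match
  quota <- floor(n_per_group * target / sum(target))
  quota <- pmin(quota, target)
  short <- n_per_group - sum(quota)
  while (short > 0) {
    room <- which(quota < target)
    take <- room[order(-(target[room] - quota[room]))][seq_len(min(short,
                                                                   length(room)))]
    quota[take] <- quota[take] + 1L
    short <- n_per_group - sum(quota)
  }
  with_seed(seed, {
    draw <- function(idx, b) {
      picked <- unlist(lapply(which(quota > 0), function(bb) {
        pool <- idx[!is.na(b) & b == bb]
        pool[sample.int(length(pool), quota[bb])]
      }))
      sort(picked)
    }
    list(group1 = draw(idx1, b1), group2 = draw(idx2, b2))
  })
}
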