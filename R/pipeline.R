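# End-to-end pipeline: simulate -> estimate -> correlate -> predict ->
# trends -> attribute, driven by a single configuration with derived,
# logged seeds per stage, writing every interchange table to disk.

.schemas <- list(
  subjects    = c("id", "sex", "baseline_age", "censor_age"),
  visits      = c("id", "visit", "age", "value"),
  diagnoses   = c("id", "disease", "age_at_diagnosis"),
  estimates   = c("trait", "bin", "median_age", "n", "estimate", "se",
                  "metric"),
  scores      = c("id", "score_name", "value"),
  case_control = c("disease", "bin", "id", "role"),
  correlations = c("trait", "kind", "rho_10yr", "se", "z", "p"),
  trends      = c("name", "metric", "slope", "slope_se", "rel_change_10yr",
                  "rel_se", "lrt_p"),
  attribution = c("disease", "delta_qrs", "delta_prs", "delta_h2",
                  "expected_combined", "z", "p", "tau")
)

#' Registered pipeline table schemas
#'
#' @return named list of required column sets for each interchange table.
#' @export
pipeline_schemas <- function() .schemas

check_schema <- function(df, schema) {
  if (!schema %in% names(.schemas)) {
    stop_param("unknown schema: ", schema, "; registered: ",
               paste(names(.schemas), collapse = ", "))
  }
  required <- .schemas[[schema]]
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_param(sprintf("table does not match schema '%s': missing column(s) %s",
                       schema, paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning(sprintf("schema '%s': extra column(s) preserved: %s",
                    schema, paste(extra, collapse = ", ")))
  }
  invisible(df)
}

#' Write an interchange table (tab-separated, header-checked)
#'
#' @param df data.frame conforming to the schema (extra columns are
#'   preserved with a warning).
#' @param path output path.
#' @param schema schema name; see [pipeline_schemas()].
#' @return invisibly, the path.
#' @export
write_pipeline_table <- function(df, path, schema) {
  check_schema(df, schema)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an interchange table
#'
#' @param path tab-separated file with a header.
#' @param schema schema name; see [pipeline_schemas()].
#' @return data.frame.
#' @export
read_pipeline_table <- function(path, schema) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  check_schema(df, schema)
  df
}

#' Default pipeline configuration
#'
#' A demo-scale configuration: 5,000 individuals, 2,000 SNPs, two
#' quantitative traits (one with exposure accumulation), one
#' liability-threshold disease, three visits.
#'
#' @param n_individuals,n_snps cohort dimensions.
#' @param seed master seed; every stage derives its own logged seed.
#' @return a `run_config` list.
#' @export
default_run_config <- function(n_individuals = 5000L, n_snps = 2000L,
                               seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    cohort = list(
      n_individuals = as.integer(n_individuals),
      n_snps = as.integer(n_snps),
      maf_range = c(0.05, 0.5),
      n_visits = 3L,
      visit_spacing = 4,
      age_range = c(40, 79),
      followup_years = 15,
      traits = list(
        list(name = "trait_ea", h2 = 0.5, ea_var = 0.1,
             measurement_error_var = 0.3),
        list(name = "trait_flat", h2 = 0.5, ea_var = 0,
             measurement_error_var = 0.3)
      ),
      diseases = list(
        list(name = "disease1", h2 = 0.5, prevalence = 0.2, ea_var = 0,
             link_trait = "trait_flat", link_rho = 0.7)
      )
    ),
    estimators = list(
      n_bins = 5L,
      n_jackknife_blocks = 50L,
      min_bin_n = 50L,
      genetic_correlation = FALSE
    ),
    prediction = list(
      prs_r2_liab = 0.3,
      n_mc = 20L,
      n_folds = 10L,
      lasso_rule = "2se"
    ),
    trends = list(n_mc = 1000L)
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with blocks seed, cohort, estimators, prediction,
#'   trends.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(structure(cfg, class = "run_config"))
}

#' Write a pipeline configuration to YAML
#'
#' @param config a `run_config`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' @param config a `run_config` list.
#' @return the config, invisibly errors naming any missing block.
#' @export
validate_run_config <- function(config) {
  required <- c("seed", "cohort", "estimators", "prediction", "trends")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop_param("configuration is missing required block(s): ",
               paste(missing, collapse = ", "))
  }
  for (blk in c("n_individuals", "n_snps", "traits")) {
    if (is.null(config$cohort[[blk]])) {
      stop_param("configuration block 'cohort' is missing field: ", blk)
    }
  }
  invisible(config)
}

cohort_config_from_run <- function(config) {
  cc <- config$cohort
  traits <- lapply(cc$traits, function(t) {
    do.call(trait_spec, t)
  })
  diseases <- lapply(cc$diseases, function(d) do.call(disease_spec, d))
  cohort_config(traits = traits, diseases = diseases,
                n_visits = cc$n_visits %||% 3L,
                visit_spacing = cc$visit_spacing %||% 4,
                age_range = cc$age_range %||% c(40, 79),
                n_bins = config$estimators$n_bins %||% 5L,
                followup_years = cc$followup_years %||% 15)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes simulate -> estimate -> correlate -> predict -> trends ->
#' attribute on a single configuration, writing all interchange tables
#' and a summary report to `output_dir`. Deterministic given
#' `config$seed`: each stage uses a seed derived from it.
#'
#' @param config a `run_config` (see [default_run_config()],
#'   [read_run_config()]).
#' @param output_dir directory for output tables (created if needed).
#' @param verbose log stage progress via `message()`.
#' @return (invisibly) a report list with the cohort, estimates tables,
#'   correlation estimates, per-disease prediction results, trends and
#'   attribution table.
#' @export
run_pipeline <- function(config, output_dir = tempfile("agearch_run_"),
                         verbose = TRUE) {
  config <- validate_run_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  seed <- config$seed
  stage_fail <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  # --- simulate -------------------------------------------------------------
  sim <- tryCatch({
    say("simulate", "n = %d, m = %d SNPs, seed = %d",
        config$cohort$n_individuals, config$cohort$n_snps, seed)
    geno <- simulate_genotypes(config$cohort$n_individuals,
                               config$cohort$n_snps,
                               maf_range = config$cohort$maf_range %||%
                                 c(0.05, 0.5),
                               seed = derive_seed(seed, "genotypes"))
    cc <- cohort_config_from_run(config)
    out <- simulate_cohort(geno, cc, seed = derive_seed(seed, "cohort"))
    write_plink(geno, file.path(output_dir, "genotypes"))
    # cohort tables intentionally carry columns beyond the required schema
    # (age bins, trait labels, medication flags)
    suppressWarnings({
      write_pipeline_table(out$cohort$subjects,
                           file.path(output_dir, "subjects.tsv"), "subjects")
      if (!is.null(out$cohort$visits)) {
        write_pipeline_table(out$cohort$visits,
                             file.path(output_dir, "visits.tsv"), "visits")
      }
      if (!is.null(out$cohort$diagnoses)) {
        write_pipeline_table(out$cohort$diagnoses,
                             file.path(output_dir, "diagnoses.tsv"),
                             "diagnoses")
      }
    })
    c(out, list(genotypes = geno))
  }, error = function(e) stage_fail("simulate", e))

  cohort <- sim$cohort
  est_cfg <- config$estimators

  # --- estimate -------------------------------------------------------------
  estimates <- tryCatch({
    say("estimate", "GRM and per-bin heritability (%d bins)",
        est_cfg$n_bins %||% 5L)
    grm <- compute_grm(sim$genotypes)
    tabs <- lapply(config$cohort$traits, function(t) {
      per_bin_estimates(cohort, t$name, grm,
                        n_bins = est_cfg$n_bins %||% 5L,
                        min_bin_n = est_cfg$min_bin_n %||% 50L,
                        n_jackknife_blocks =
                          est_cfg$n_jackknife_blocks %||% 100L)
    })
    tab <- do.call(rbind, tabs)
    suppressWarnings(
      write_pipeline_table(tab, file.path(output_dir, "estimates.tsv"),
                           "estimates"))
    list(table = tab, grm = grm)
  }, error = function(e) stage_fail("estimate", e))

  # --- correlate ------------------------------------------------------------
  correlations <- tryCatch({
    rows <- list()
    if ((config$cohort$n_visits %||% 3L) >= 3L) {
      for (t in config$cohort$traits) {
        say("correlate", "denoised phenotypic correlation: %s", t$name)
        vis <- cohort$visits[cohort$visits$trait == t$name, ]
        ce <- denoised_phenotypic_correlation(
          vis, n_bootstrap = 200L,
          seed = derive_seed(seed, paste0("denoise_", t$name)))
        tst <- test_corr_lt_1(ce$rho_10yr, ce$se)
        rows[[t$name]] <- data.frame(trait = t$name, kind = "denoised",
                                     rho_10yr = ce$rho_10yr, se = ce$se,
                                     z = tst$z, p = tst$p_one_sided)
      }
    }
    tab <- if (length(rows)) do.call(rbind, rows) else NULL
    if (!is.null(tab)) {
      rownames(tab) <- NULL
      write_pipeline_table(tab, file.path(output_dir, "correlations.tsv"),
                           "correlations")
    }
    tab
  }, error = function(e) stage_fail("correlate", e))

  # --- predict --------------------------------------------------------------
  pred_cfg <- config$prediction
  trait_names <- vapply(config$cohort$traits, `[[`, character(1), "name")
  prediction <- tryCatch({
    lapply(config$cohort$diseases, function(d) {
      say("predict", "disease %s: PRS + QRS per-bin incident R2", d$name)
      dsim <- sim$liability$diseases[[d$name]]
      prs <- calibrate_predictor(dsim$liability$G,
                                 pred_cfg$prs_r2_liab %||% 0.3,
                                 seed = derive_seed(seed,
                                                    paste0("prs_", d$name)))
      # baseline (visit 1) trait matrix
      v1 <- cohort$visits[cohort$visits$visit == 1L &
                            cohort$visits$trait %in% trait_names, ]
      X <- do.call(cbind, lapply(trait_names, function(tn) {
        v <- v1[v1$trait == tn, ]
        v$value[match(cohort$subjects$id, v$id)]
      }))
      colnames(X) <- trait_names
      dx <- disease_dx(cohort, d$name)
      status <- as.integer(cohort$subjects$id %in% dx$id)
      el <- fit_estimated_liability(X, status,
                                    n_folds = pred_cfg$n_folds %||% 10L,
                                    rule = pred_cfg$lasso_rule %||% "2se",
                                    seed = derive_seed(seed,
                                                       paste0("lasso_",
                                                              d$name)))
      qp <- qrs_pipeline(el$score, prs, cohort, d$name,
                         n_bins = est_cfg$n_bins %||% 5L,
                         n_mc = pred_cfg$n_mc %||% 50L,
                         seed = derive_seed(seed, paste0("qrs_", d$name)))
      # whole-population denominators for relative changes
      prs_adj <- residualize(standardize(prs),
                             cbind(sex = cohort$subjects$sex))
      r2_pop_prs <- observed_r2(prs_adj, status,
                                cbind(sex = cohort$subjects$sex))$value
      list(disease = d$name, qrs = qp, r2_pop_prs = r2_pop_prs,
           estimated_liability = el$score, prs = prs, status = status)
    })
  }, error = function(e) stage_fail("predict", e))

  # --- trends + attribute ---------------------------------------------------
  trends_cfg <- config$trends
  result <- tryCatch({
    say("trends", "fitting linear age trends")
    trend_rows <- list()
    h2_trends <- list()
    for (tn in trait_names) {
      s <- estimates$table[estimates$table$trait == tn, ]
      ms <- metric_series(s$estimate, s$se, s$median_age, metric = "h2",
                          n = s$n, bin = s$bin)
      tr <- fit_metric_trend(ms, n_mc = trends_cfg$n_mc %||% 1000L,
                             seed = derive_seed(seed, paste0("trend_", tn)))
      pop_h2 <- sum(s$estimate / s$se^2) / sum(1 / s$se^2)
      rel <- relative_10yr_change(tr, pop_h2)
      h2_trends[[tn]] <- tr
      trend_rows[[paste0(tn, "_h2")]] <- data.frame(
        name = tn, metric = "h2", slope = tr$a, slope_se = tr$a_se,
        rel_change_10yr = rel$rel_change_10yr, rel_se = rel$se,
        lrt_p = tr$lrt_p)
    }
    say("attribute", "per-disease attribution")
    grm <- estimates$grm
    attr_rows <- list()
    deltas_qrs <- c()
    deltas_prs <- c()
    for (pr in prediction) {
      pb <- pr$qrs$per_bin
      qrs_ms <- metric_series(pb$qrs_r2_mean, pmax(pb$qrs_r2_sd, 1e-8),
                              pb$median_case_age, metric = "r2_obs_qrs")
      prs_ms <- metric_series(pb$prs_r2_mean, pmax(pb$prs_r2_sd, 1e-8),
                              pb$median_case_age, metric = "r2_obs_prs")
      tq <- fit_metric_trend(qrs_ms, n_mc = trends_cfg$n_mc %||% 1000L,
                             seed = derive_seed(seed,
                                                paste0("tq_", pr$disease)))
      tp <- fit_metric_trend(prs_ms, n_mc = trends_cfg$n_mc %||% 1000L,
                             seed = derive_seed(seed,
                                                paste0("tp_", pr$disease)))
      # after noise matching the QRS shares the PRS's whole-population R2,
      # so both relative changes use the same denominator
      rel_q <- relative_10yr_change(tq, max(pr$r2_pop_prs, 1e-8))
      rel_p <- relative_10yr_change(tp, max(pr$r2_pop_prs, 1e-8))
      # estimated-liability per-bin h2 for the EA contribution
      co2 <- cohort
      el_rows <- data.frame(id = cohort$subjects$id, trait = "est_liab",
                            visit = 1L, age = cohort$subjects$baseline_age,
                            value = pr$estimated_liability)
      co2$visits <- rbind(cohort$visits, el_rows)
      eh <- per_bin_estimates(co2, "est_liab", grm,
                              n_bins = est_cfg$n_bins %||% 5L,
                              min_bin_n = est_cfg$min_bin_n %||% 50L,
                              n_jackknife_blocks =
                                est_cfg$n_jackknife_blocks %||% 100L)
      eh_ms <- metric_series(eh$estimate, eh$se, eh$median_age,
                             metric = "h2", n = eh$n, bin = eh$bin)
      th <- fit_metric_trend(eh_ms, n_mc = trends_cfg$n_mc %||% 1000L,
                             seed = derive_seed(seed,
                                                paste0("th_", pr$disease)))
      pop_h2 <- sum(eh$estimate / eh$se^2) / sum(1 / eh$se^2)
      rel_h <- relative_10yr_change(th, pop_h2)
      comb <- combined_expected_change(rel_q$rel_change_10yr,
                                       rel_h$rel_change_10yr,
                                       se_qrs = rel_q$se, se_h2 = rel_h$se,
                                       seed = derive_seed(seed,
                                                          paste0("cb_",
                                                                 pr$disease)))
      zt <- slope_difference_test(rel_q$rel_change_10yr,
                                  rel_p$rel_change_10yr,
                                  se_x = rel_q$se, se_y = rel_p$se)
      deltas_qrs <- c(deltas_qrs, rel_q$rel_change_10yr)
      deltas_prs <- c(deltas_prs, rel_p$rel_change_10yr)
      attr_rows[[pr$disease]] <- data.frame(
        disease = pr$disease,
        delta_qrs = rel_q$rel_change_10yr, delta_prs = rel_p$rel_change_10yr,
        delta_h2 = rel_h$rel_change_10yr,
        expected_combined = comb$expected_change,
        z = zt$z, p = zt$p)
      trend_rows[[paste0(pr$disease, "_qrs")]] <- data.frame(
        name = pr$disease, metric = "r2_obs_qrs", slope = tq$a,
        slope_se = tq$a_se, rel_change_10yr = rel_q$rel_change_10yr,
        rel_se = rel_q$se, lrt_p = tq$lrt_p)
      trend_rows[[paste0(pr$disease, "_prs")]] <- data.frame(
        name = pr$disease, metric = "r2_obs_prs", slope = tp$a,
        slope_se = tp$a_se, rel_change_10yr = rel_p$rel_change_10yr,
        rel_se = rel_p$se, lrt_p = tp$lrt_p)
    }
    trends_tab <- do.call(rbind, trend_rows)
    rownames(trends_tab) <- NULL
    write_pipeline_table(trends_tab, file.path(output_dir, "trends.tsv"),
                         "trends")
    attribution <- NULL
    if (length(attr_rows)) {
      attribution <- do.call(rbind, attr_rows)
      rownames(attribution) <- NULL
      tau <- tryCatch(tau_explained(attribution$delta_qrs,
                                    attribution$delta_prs),
                      error = function(e) NA_real_)
      attribution$tau <- tau
      write_pipeline_table(attribution,
                           file.path(output_dir, "attribution.tsv"),
                           "attribution")
    }
    list(trends = trends_tab, attribution = attribution)
  }, error = function(e) stage_fail("trends", e))

  report <- list(config = config, output_dir = output_dir,
                 cohort = cohort, estimates = estimates$table,
                 correlations = correlations, prediction = prediction,
                 trends = result$trends, attribution = result$attribution)
  writeLines(c(
    sprintf("agearch pipeline run (seed %d)", seed),
    sprintf("output: %s", output_dir),
    "",
    "trends:",
    utils::capture.output(print(result$trends)),
    "",
    "attribution:",
    utils::capture.output(print(result$attribution))
  ), file.path(output_dir, "summary.txt"))
  say("done", "tables written to %s", output_dir)
  invisible(report)
}
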