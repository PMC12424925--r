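# Liability-threshold disease simulators.
#
# Disease onset is modelled on a latent liability scale. The linear model
# keeps each individual's liability fixed while the population threshold
# effectively falls with age: at each of `n_bins` age bins the top
# `bin_fraction` of not-yet-diseased individuals (ranked by current
# liability) become cases. The exposure-accumulation (EA) variant adds an
# independent Normal(0, increment_var) environmental increment to every
# individual's liability when moving to each older bin, so environmental
# variance accumulates with age while genetic variance stays constant.
# Ranking by percentile makes both simulators invariant to proportional
# amplification of the liability scale.

#' Simulate the linear liability-threshold disease model
#'
#' Liability L = G + E with G ~ Normal(0, h2) and E ~ Normal(0, 1 - h2) is
#' fixed over age. Onset bin k contains the individuals ranked in the
#' ((k-1)f, kf] top fraction of L, so each bin holds exactly
#' `floor(bin_fraction * n)` cases and bin 1 is the youngest onset group.
#'
#' @param n number of individuals.
#' @param h2 liability-scale heritability in \[0, 1\].
#' @param n_bins number of age bins (default 5).
#' @param bin_fraction fraction of the population becoming cases per bin
#'   (default 0.02).
#' @param seed integer seed.
#' @return a `simulated_disease` object: list with `liability` (data.frame
#'   id, G, E0, onset_bin and per-bin liability columns), `ea_increments`
#'   (NULL here), `n_bins`, `bin_fraction`, `h2`, `thresholds` (implied
#'   liability cut at each bin).
#' @export
simulate_linear_threshold <- function(n, h2, n_bins = 5L,
                                      bin_fraction = 0.02, seed = NULL) {
  n <- check_count(n, "n", lower = 10L)
  check_number(h2, "h2", 0, 1)
  n_bins <- check_count(n_bins, "n_bins")
  if (!is.numeric(bin_fraction) || bin_fraction <= 0) {
    stop_param("`bin_fraction` must be positive")
  }
  if (n_bins * bin_fraction >= 1) {
    stop_param("`n_bins * bin_fraction` must be < 1")
  }
  with_seed(seed, {
    G <- stats::rnorm(n, 0, sqrt(h2))
    E0 <- stats::rnorm(n, 0, sqrt(1 - h2))
    L <- G + E0
    onset <- onset_from_ranks(L, n_bins, bin_fraction,
                              tie_perm = sample.int(n))
    liab_cols <- matrix(L, nrow = n, ncol = n_bins,
                        dimnames = list(NULL, paste0("L_bin", seq_len(n_bins))))
    new_simulated_disease(G, E0, liab_cols, onset, NULL, n_bins, bin_fraction,
                          h2, model = "linear")
  })
}

#' Simulate the exposure-accumulation liability-threshold disease model
#'
#' Initial liability is drawn as in [simulate_linear_threshold()]. When the
#' population moves to each older age bin, every individual receives an
#' independent Normal(0, increment_var) environmental increment added
#' cumulatively to their liability; that bin's cases are then the top
#' `bin_fraction` of current liability among the not-yet-diseased. Case
#' counts per bin equal the linear simulator's. At the default
#' increment_var = 0.05 over five bins, the cumulative increments present
#' in bin 5 carry about 20% of the initial liability variance.
#'
#' @inheritParams simulate_linear_threshold
#' @param increment_var variance of the per-bin environmental increment
#'   (>= 0); 0 reduces to the linear model.
#' @return a `simulated_disease` object; `ea_increments` holds the n x
#'   (n_bins - 1) matrix of increments applied on entering bins 2..n_bins.
#' @export
simulate_ea_threshold <- function(n, h2, n_bins = 5L, bin_fraction = 0.02,
                                  increment_var = 0.05, seed = NULL) {
  n <- check_count(n, "n", lower = 10L)
  check_number(h2, "h2", 0, 1)
  n_bins <- check_count(n_bins, "n_bins")
  check_number(increment_var, "increment_var", lower = 0)
  if (!is.numeric(bin_fraction) || bin_fraction <= 0) {
    stop_param("`bin_fraction` must be positive")
  }
  if (n_bins * bin_fraction >= 1) {
    stop_param("`n_bins * bin_fraction` must be < 1")
  }
  n_cases_bin <- floor(bin_fraction * n)
  with_seed(seed, {
    G <- stats::rnorm(n, 0, sqrt(h2))
    E0 <- stats::rnorm(n, 0, sqrt(1 - h2))
    tie_perm <- sample.int(n)
    L <- G + E0
    onset <- rep(NA_integer_, n)
    liab_cols <- matrix(NA_real_, nrow = n, ncol = n_bins,
                        dimnames = list(NULL, paste0("L_bin", seq_len(n_bins))))
    incr <- matrix(0, nrow = n, ncol = max(n_bins - 1L, 0L))
    for (k in seq_len(n_bins)) {
      if (k > 1L) {
        incr[, k - 1L] <- stats::rnorm(n, 0, sqrt(increment_var))
        L <- L + incr[, k - 1L]
      }
      liab_cols[, k] <- L
      healthy <- which(is.na(onset))
      ord <- healthy[order(-L[healthy], tie_perm[healthy])]
      onset[ord[seq_len(min(n_cases_bin, length(ord)))]] <- k
    }
    new_simulated_disease(G, E0, liab_cols, onset, incr, n_bins, bin_fraction,
                          h2, model = "ea", increment_var = increment_var)
  })
}

# Rank-based onset assignment for the linear model: bin k = individuals in
# the ((k-1)f, kf] top fraction of liability; ties broken by a seeded
# permutation.
onset_from_ranks <- function(L, n_bins, bin_fraction, tie_perm) {
  n <- length(L)
  per_bin <- floor(bin_fraction * n)
  ord <- order(-L, tie_perm)
  onset <- rep(NA_integer_, n)
  for (k in seq_len(n_bins)) {
    idx <- ord[((k - 1L) * per_bin + 1L):(k * per_bin)]
    onset[idx] <- k
  }
  onset
}

new_simulated_disease <- function(G, E0, liab_cols, onset, incr, n_bins,
                                  bin_fraction, h2, model,
                                  increment_var = NULL) {
  n <- length(G)
  thresholds <- vapply(seq_len(n_bins), function(k) {
    cases_k <- which(onset == k)
    if (!length(cases_k)) return(NA_real_)
    min(liab_cols[cases_k, k])
  }, numeric(1))
  structure(
    list(
      liability = data.frame(id = seq_len(n), G = G, E0 = E0, liab_cols,
                             onset_bin = onset),
      ea_increments = incr,
      n_bins = n_bins,
      bin_fraction = bin_fraction,
      h2 = h2,
      model = model,
      increment_var = increment_var,
      thresholds = thresholds
    ),
    class = "simulated_disease"
  )
}

#' @export
print.simulated_disease <- function(x, ...) {
  n <- nrow(x$liability)
  cat(sprintf("<simulated_disease> model=%s, n=%d, h2=%.2f, %d bins x %.1f%%\n",
              x$model, n, x$h2, x$n_bins, 100 * x$bin_fraction))
  cat("  cases per bin:",
      paste(tabulate(x$liability$onset_bin, x$n_bins), collapse = ", "), "\n")
  invisible(x)
}

#' Build a case-control set from a simulated disease
#'
#' Prevalent design at bin k: cases are individuals with onset at or before
#' bin k; controls are individuals not yet diseased at bin k. Incident
#' design at bin k: cases have onset exactly at bin k; controls are
#' individuals below that bin's liability threshold, i.e. never diseased by
#' the end of bin k (incident cases themselves are excluded). Controls are
#' down-sampled uniformly at random to a 1:1 ratio with cases.
#'
#' @param sim a `simulated_disease`.
#' @param design `"prevalent"` or `"incident"`.
#' @param bin age-bin index.
#' @param seed integer seed for control down-sampling.
#' @return a `case_control_set`: list with integer vectors `cases`,
#'   `controls`, plus `bin` and `design`.
#' @export
sim_case_control_sets <- function(sim, design = c("prevalent", "incident"),
                                  bin, seed = NULL) {
  stopifnot(inherits(sim, "simulated_disease"))
  design <- match.arg(design)
  bin <- check_count(bin, "bin")
  if (bin > sim$n_bins) stop_param("`bin` exceeds the number of bins")
  onset <- sim$liability$onset_bin
  if (design == "prevalent") {
    cases <- which(!is.na(onset) & onset <= bin)
    controls <- which(is.na(onset) | onset > bin)
  } else {
    cases <- which(!is.na(onset) & onset == bin)
    controls <- which(is.na(onset) | onset > bin)
  }
  if (!length(cases)) stop_param("no cases in bin ", bin)
  with_seed(seed, {
    if (length(controls) > length(cases)) {
      controls <- sort(sample(controls, length(cases)))
    }
    structure(list(cases = cases, controls = controls, bin = bin,
                   design = design),
              class = "case_control_set")
  })
}

#' @export
print.case_control_set <- function(x, ...) {
  cat(sprintf("<case_control_set> %s, bin %d: %d cases, %d controls\n",
              x$design, x$bin, length(x$cases), length(x$controls)))
  invisible(x)
}

#' Write a simulated disease as a per-individual table
#'
#' Columns: id, G, E0, per-bin liability, onset_bin (NA for disease-free).
#'
#' @param sim a `simulated_disease`.
#' @param path output path (tab-separated).
#' @return invisibly, the path.
#' @export
write_simulated_disease <- function(sim, path) {
  stopifnot(inherits(sim, "simulated_disease"))
  utils::write.table(sim$liability, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
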