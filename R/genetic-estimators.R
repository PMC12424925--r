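# Haseman-Elston variance-component estimation.
#
# Moment-based substitutes for REML heritability and summary-statistic
# genetic correlation, applied per age bin. Within a sample, the HE
# regression fits E[y_i y_j] = c + h2 * A_ij over unordered pairs i < j of
# a standardized phenotype against the GRM; across two disjoint samples
# (two age bins, so no sample overlap) the cross-product regression slope
# estimates the genetic covariance, which is normalized by the per-sample
# heritabilities to give a genetic correlation. Standard errors come from a
# delete-one-block jackknife over individuals. Estimates are deliberately
# never truncated to [0, 1] (or [-1, 1]): truncation would bias
# downstream trend fits.

#' Standardize genotype dosages per SNP
#'
#' Centers and scales each SNP by its empirical mean and standard
#' deviation. Monomorphic SNPs (zero variance) are dropped with a warning.
#'
#' @param genotypes a `genotype_matrix`.
#' @return list with `Z` (n x m' standardized matrix) and `kept` (indices
#'   of retained SNPs).
#' @export
standardize_genotypes <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  X <- genotypes$dosages
  mu <- colMeans(X)
  s <- apply(X, 2L, stats::sd)
  keep <- which(s > 0)
  if (length(keep) < ncol(X)) {
    warning(sprintf("excluded %d monomorphic SNP(s) from standardization",
                    ncol(X) - length(keep)))
  }
  if (!length(keep)) stop_param("all SNPs are monomorphic")
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2L, mu[keep]), 2L, s[keep], `/`)
  list(Z = Z, kept = keep)
}

#' Compute a genetic relationship matrix
#'
#' GRM entry (i, k) is the average over SNPs of z_ij * z_kj with z the
#' per-SNP standardized dosages; the diagonal averages to about 1.
#'
#' @param genotypes a `genotype_matrix`.
#' @return an n x n symmetric matrix of class `grm` with attribute
#'   `n_snps`.
#' @export
compute_grm <- function(genotypes) {
  if (nrow(genotypes$dosages) < 2L) stop_param("need at least 2 individuals")
  std <- standardize_genotypes(genotypes)
  A <- tcrossprod(std$Z) / length(std$kept)
  attr(A, "n_snps") <- length(std$kept)
  class(A) <- c("grm", class(A))
  A
}

#' Cross-sample genetic relatedness block
#'
#' Relatedness between every individual of sample A and every individual
#' of sample B, standardizing each SNP on the pooled sample so the two
#' blocks share a scale.
#'
#' @param genotypes_a,genotypes_b `genotype_matrix` objects over the same
#'   SNP set (disjoint individuals).
#' @return an n_a x n_b matrix with attribute `n_snps`.
#' @export
compute_cross_grm <- function(genotypes_a, genotypes_b) {
  stopifnot(inherits(genotypes_a, "genotype_matrix"),
            inherits(genotypes_b, "genotype_matrix"),
            ncol(genotypes_a$dosages) == ncol(genotypes_b$dosages))
  X <- rbind(genotypes_a$dosages, genotypes_b$dosages)
  pooled <- genotype_matrix(X)
  std <- standardize_genotypes(pooled)
  na <- nrow(genotypes_a$dosages)
  K <- tcrossprod(std$Z[seq_len(na), , drop = FALSE],
                  std$Z[-seq_len(na), , drop = FALSE]) / length(std$kept)
  attr(K, "n_snps") <- length(std$kept)
  K
}

# Pair-sum statistics for the within-sample HE regression over unordered
# pairs i < j. Totals and row aggregates are precomputed once so that
# leave-block-out sums need only O(n + |block|^2) work per block.
he_precompute <- function(A, y) {
  d <- diag(A)
  list(
    A = A, y = y, d = d, n = length(y),
    T1 = sum(A), Td = sum(d),
    T2 = sum(A * A), T2d = sum(d^2),
    r1 = rowSums(A), r2 = rowSums(A * A),
    u = as.numeric(A %*% y), q = drop(crossprod(y, A %*% y)),
    sy = sum(y), sy2 = sum(y^2)
  )
}

# Pair sums with an optional deleted block of individuals.
he_pair_sums <- function(pre, drop_idx = NULL) {
  if (is.null(drop_idx) || !length(drop_idx)) {
    nk <- pre$n
    sumA <- pre$T1
    sumA2 <- pre$T2
    sumd <- pre$Td
    sumd2 <- pre$T2d
    sy <- pre$sy
    sy2 <- pre$sy2
    quad <- pre$q
    dyy <- sum(pre$d * pre$y^2)
  } else {
    D <- drop_idx
    AD <- pre$A[D, D, drop = FALSE]
    yD <- pre$y[D]
    nk <- pre$n - length(D)
    sumA <- pre$T1 - 2 * sum(pre$r1[D]) + sum(AD)
    sumA2 <- pre$T2 - 2 * sum(pre$r2[D]) + sum(AD^2)
    sumd <- pre$Td - sum(pre$d[D])
    sumd2 <- pre$T2d - sum(pre$d[D]^2)
    sy <- pre$sy - sum(yD)
    sy2 <- pre$sy2 - sum(yD^2)
    quad <- pre$q - 2 * sum(yD * pre$u[D]) + drop(crossprod(yD, AD %*% yD))
    dyy <- sum(pre$d * pre$y^2) - sum(pre$d[D] * yD^2)
  }
  list(
    np  = nk * (nk - 1) / 2,
    Sx  = (sumA - sumd) / 2,
    Sxx = (sumA2 - sumd2) / 2,
    Sy  = (sy^2 - sy2) / 2,
    Sxy = (quad - dyy) / 2
  )
}

he_slope_from_sums <- function(s) {
  denom <- s$Sxx - s$Sx^2 / s$np
  if (denom <= 0) stop_param("degenerate GRM: no variance in off-diagonals")
  (s$Sxy - s$Sx * s$Sy / s$np) / denom
}

#' Haseman-Elston heritability with block-jackknife standard error
#'
#' The phenotype is residualized on the covariates, standardized, and the
#' products y_i * y_j over pairs i < j are regressed (with intercept) on
#' the off-diagonal GRM entries; the slope estimates h2. The standard
#' error is a delete-one-block jackknife over contiguous blocks of
#' individuals. Estimates are not truncated to [0, 1].
#'
#' @param phenotype numeric vector.
#' @param covariates optional matrix/data.frame of covariates (an
#'   intercept is added); NULL for mean-centering only.
#' @param grm GRM from [compute_grm()] with matching dimension.
#' @param n_jackknife_blocks number of jackknife blocks (default 100).
#' @return a `heritability_estimate`: list with `h2`, `se`, `n`,
#'   `n_blocks`.
#' @export
he_heritability <- function(phenotype, covariates = NULL, grm,
                            n_jackknife_blocks = 100L) {
  n <- length(phenotype)
  if (nrow(grm) != n) stop_param("phenotype length must match GRM dimension")
  if (stats::sd(phenotype) == 0) stop_param("phenotype is constant")
  y <- residualize(phenotype, covariates)
  if (stats::sd(y) < 1e-10 * max(stats::sd(phenotype), 1)) {
    stop_param("phenotype residual is constant after covariate adjustment")
  }
  y <- standardize(y)
  pre <- he_precompute(grm, y)
  h2 <- he_slope_from_sums(he_pair_sums(pre))
  blocks <- index_blocks(n, n_jackknife_blocks)
  B <- length(blocks)
  jack <- vapply(blocks, function(b) {
    he_slope_from_sums(he_pair_sums(pre, drop_idx = b))
  }, numeric(1))
  se <- sqrt((B - 1) / B * sum((jack - mean(jack))^2))
  structure(list(h2 = h2, se = se, n = n, n_blocks = B),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("<heritability_estimate> h2 = %.4f (se %.4f), n = %d\n",
              x$h2, x$se, x$n))
  invisible(x)
}

# Cross-sample pair sums over all (i in A, j in B) cells, with O(n) removal
# of a block of A rows and B columns.
he_cross_precompute <- function(K, ya, yb) {
  list(
    K = K, ya = ya, yb = yb,
    T1 = sum(K), T2 = sum(K * K),
    row1 = rowSums(K), row2 = rowSums(K * K),
    col1 = colSums(K), col2 = colSums(K * K),
    ua = as.numeric(K %*% yb),          # per-A-row weighted sums
    ub = as.numeric(crossprod(K, ya)),  # per-B-col weighted sums
    q = drop(crossprod(ya, K %*% yb)),
    sa = sum(ya), sb = sum(yb)
  )
}

he_cross_sums <- function(pre, drop_a = NULL, drop_b = NULL) {
  na <- length(pre$ya)
  nb <- length(pre$yb)
  if (is.null(drop_a)) drop_a <- integer(0)
  if (is.null(drop_b)) drop_b <- integer(0)
  KD <- pre$K[drop_a, drop_b, drop = FALSE]
  yaD <- pre$ya[drop_a]
  ybD <- pre$yb[drop_b]
  list(
    np  = (na - length(drop_a)) * (nb - length(drop_b)),
    Sx  = pre$T1 - sum(pre$row1[drop_a]) - sum(pre$col1[drop_b]) + sum(KD),
    Sxx = pre$T2 - sum(pre$row2[drop_a]) - sum(pre$col2[drop_b]) + sum(KD^2),
    Sy  = (pre$sa - sum(yaD)) * (pre$sb - sum(ybD)),
    Sxy = pre$q - sum(yaD * pre$ua[drop_a]) - sum(ybD * pre$ub[drop_b]) +
      drop(crossprod(yaD, KD %*% ybD))
  )
}

#' Cross-sample Haseman-Elston genetic correlation
#'
#' For two phenotypes measured on disjoint samples (e.g. two age bins, so
#' there is no sample overlap), regresses the cross products
#' y_a,i * y_b,j on the cross-sample relatedness entries to estimate the
#' genetic covariance, then divides by sqrt(h2_a * h2_b). Heritabilities
#' are estimated from `grm_a`/`grm_b` when supplied, or taken from
#' `h2_a`/`h2_b`. Standard error by joint delete-one-block jackknife over
#' both samples; estimates are not clamped to [-1, 1].
#'
#' @param pheno_a,pheno_b phenotype vectors on samples A and B.
#' @param grm_cross A x B relatedness block from [compute_cross_grm()].
#' @param grm_a,grm_b within-sample GRMs (optional if h2 values given).
#' @param h2_a,h2_b known heritabilities (used, and held fixed in the
#'   jackknife, when the GRMs are not supplied).
#' @param covariates_a,covariates_b optional covariate matrices.
#' @param n_jackknife_blocks number of jackknife blocks.
#' @return a `genetic_correlation_estimate`: list with `rg`, `se`,
#'   `gcov`, `h2_a`, `h2_b`.
#' @export
he_genetic_correlation <- function(pheno_a, pheno_b, grm_cross,
                                   grm_a = NULL, grm_b = NULL,
                                   h2_a = NULL, h2_b = NULL,
                                   covariates_a = NULL, covariates_b = NULL,
                                   n_jackknife_blocks = 100L) {
  na <- length(pheno_a)
  nb <- length(pheno_b)
  stopifnot(nrow(grm_cross) == na, ncol(grm_cross) == nb)
  ya <- standardize(residualize(pheno_a, covariates_a))
  yb <- standardize(residualize(pheno_b, covariates_b))

  pre_a <- if (!is.null(grm_a)) he_precompute(grm_a, ya) else NULL
  pre_b <- if (!is.null(grm_b)) he_precompute(grm_b, yb) else NULL
  point_h2a <- if (!is.null(pre_a)) {
    he_slope_from_sums(he_pair_sums(pre_a))
  } else {
    h2_a
  }
  point_h2b <- if (!is.null(pre_b)) {
    he_slope_from_sums(he_pair_sums(pre_b))
  } else {
    h2_b
  }
  if (is.null(point_h2a) || is.null(point_h2b)) {
    stop_param("supply either within-sample GRMs or h2 values")
  }
  if (point_h2a <= 0 || point_h2b <= 0) {
    stop_param(sprintf(paste0("genetic correlation undefined: non-positive ",
                              "heritability (h2_a = %.3f, h2_b = %.3f)"),
                       point_h2a, point_h2b))
  }
  pre_x <- he_cross_precompute(grm_cross, ya, yb)
  rg_from <- function(drop_a = NULL, drop_b = NULL) {
    s <- he_cross_sums(pre_x, drop_a, drop_b)
    gcov <- (s$Sxy - s$Sx * s$Sy / s$np) / (s$Sxx - s$Sx^2 / s$np)
    h2a <- if (!is.null(pre_a)) {
      he_slope_from_sums(he_pair_sums(pre_a, drop_a))
    } else {
      point_h2a
    }
    h2b <- if (!is.null(pre_b)) {
      he_slope_from_sums(he_pair_sums(pre_b, drop_b))
    } else {
      point_h2b
    }
    if (h2a <= 0 || h2b <= 0) return(NA_real_)
    gcov / sqrt(h2a * h2b)
  }
  rg <- rg_from()
  blocks_a <- index_blocks(na, n_jackknife_blocks)
  blocks_b <- index_blocks(nb, n_jackknife_blocks)
  B <- min(length(blocks_a), length(blocks_b))
  jack <- vapply(seq_len(B), function(i) {
    rg_from(blocks_a[[i]], blocks_b[[i]])
  }, numeric(1))
  jack <- jack[is.finite(jack)]
  Bj <- length(jack)
  se <- sqrt((Bj - 1) / Bj * sum((jack - mean(jack))^2))
  s <- he_cross_sums(pre_x)
  gcov <- (s$Sxy - s$Sx * s$Sy / s$np) / (s$Sxx - s$Sx^2 / s$np)
  structure(list(rg = rg, se = se, gcov = gcov,
                 h2_a = point_h2a, h2_b = point_h2b, n_a = na, n_b = nb),
            class = "genetic_correlation_estimate")
}

#' @export
print.genetic_correlation_estimate <- function(x, ...) {
  cat(sprintf("<genetic_correlation_estimate> rg = %.4f (se %.4f)\n",
              x$rg, x$se))
  invisible(x)
}

#' Per-age-bin heritability estimates for a trait
#'
#' Splits the cohort into baseline-age quantile bins, and within each bin
#' runs [he_heritability()] on the trait's first-visit measurement with sex
#' and within-bin baseline age as covariates. Also returns per-bin
#' phenotypic variance (overall and by sex, for variance decomposition)
#' and bin median ages, in the estimates-table interchange format.
#'
#' @param cohort a `cohort_table`.
#' @param trait trait name present in the visits table.
#' @param grm full-cohort GRM (subset per bin internally).
#' @param n_bins number of age bins (default 5).
#' @param visit which visit's measurement to analyse (default 1).
#' @param min_bin_n bins smaller than this are skipped with a warning.
#' @param n_jackknife_blocks jackknife blocks per bin.
#' @return data.frame with one row per bin: trait, bin, median_age, n,
#'   estimate, se, metric ("h2"), phen_var, phen_var_se, phen_var_male,
#'   phen_var_female.
#' @export
per_bin_estimates <- function(cohort, trait, grm, n_bins = 5L, visit = 1L,
                              min_bin_n = 50L, n_jackknife_blocks = 100L) {
  stopifnot(inherits(cohort, "cohort_table"))
  sub <- cohort$subjects
  vis <- cohort$visits[cohort$visits$trait == trait &
                         cohort$visits$visit == visit, ]
  if (!nrow(vis)) stop_param("trait not found in visit table: ", trait)
  y <- vis$value[match(sub$id, vis$id)]
  breaks <- stats::quantile(sub$baseline_age,
                            probs = seq(0, 1, length.out = n_bins + 1))
  bin <- as.integer(cut(sub$baseline_age, breaks, include.lowest = TRUE))
  rows <- lapply(seq_len(n_bins), function(k) {
    idx <- which(bin == k & !is.na(y))
    if (length(idx) < min_bin_n) {
      warning(sprintf("bin %d skipped: n = %d < %d", k, length(idx),
                      min_bin_n))
      return(NULL)
    }
    est <- he_heritability(
      y[idx],
      covariates = cbind(sex = sub$sex[idx], age = sub$baseline_age[idx]),
      grm = grm[idx, idx, drop = FALSE],
      n_jackknife_blocks = n_jackknife_blocks
    )
    pv <- stats::var(y[idx])
    males <- idx[sub$sex[idx] == 1L]
    females <- idx[sub$sex[idx] == 0L]
    data.frame(
      trait = trait, bin = k,
      median_age = stats::median(sub$baseline_age[idx]),
      n = length(idx), estimate = est$h2, se = est$se, metric = "h2",
      phen_var = pv, phen_var_se = pv * sqrt(2 / (length(idx) - 1)),
      phen_var_male = if (length(males) > 1) stats::var(y[males]) else NA,
      phen_var_female = if (length(females) > 1) stats::var(y[females]) else NA
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
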