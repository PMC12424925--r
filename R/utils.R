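# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so package functions are
#' reproducible given `seed` without clobbering the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Derive a child seed from a master seed and a stage label, stably across
# platforms. Kept below 2^31 - 1.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483587) + 1L
}

stop_param <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop_param(sprintf("`%s` must be a single number in [%s, %s]",
                       name, format(lower), format(upper)))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower ||
      x != floor(x)) {
    stop_param(sprintf("`%s` must be an integer >= %d", name, lower))
  }
  invisible(as.integer(x))
}

# Standardize a vector to mean 0, sd 1 (denominator n - 1).
standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop_param("cannot standardize a constant vector")
  }
  (x - mean(x)) / s
}

# Residualize y on a covariate matrix (adds an intercept if absent).
residualize <- function(y, covariates = NULL) {
  if (is.null(covariates)) {
    return(y - mean(y))
  }
  x <- as.matrix(covariates)
  if (!any(apply(x, 2L, function(col) all(col == col[1L])))) {
    x <- cbind(1, x)
  }
  stats::lm.fit(x, y)$residuals
}

# Contiguous index blocks for jackknife / cross-validation.
index_blocks <- function(n, n_blocks) {
  n_blocks <- min(n_blocks, n)
  split(seq_len(n), cut(seq_len(n), breaks = n_blocks, labels = FALSE))
}
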