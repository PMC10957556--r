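# AUC-over-threshold summarization, Benjamini-Hochberg FDR control, and the
# PCA explained-inertia null-reference procedure.

#' Area under a metric-vs-density curve
#'
#' Trapezoidal integral of a global metric across the density sweep; the
#' threshold-free per-subject summary used for group comparisons. The axis is
#' the raw density fraction (e.g. 0.06..0.32).
#'
#' @param values metric values, one per grid point.
#' @param grid strictly increasing densities, same length as `values`.
#' @return the trapezoid integral.
#' @export
metric_auc <- function(values, grid) {
  if (length(values) != length(grid)) {
    stop("values and grid must have the same length", call. = FALSE)
  }
  if (length(grid) < 2) stop("need at least 2 grid points", call. = FALSE)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing",
                                 call. = FALSE)
  pracma::trapz(grid, values)
}

#' Benjamini-Hochberg rejection mask
#'
#' Standard step-up FDR procedure at level `q` (wraps `p.adjust`). The mask
#' is monotone in p: every rejected p-value is smaller than every accepted
#' one.
#'
#' @param pvalues vector of p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return logical rejection mask.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH") <= q
}

#' Percent variance explained by each principal dimension
#'
#' Correlation-matrix PCA: variables are standardized internally, so the
#' eigenvalue fractions are scale-free. Suitable for mixed-unit tables.
#'
#' @param data numeric matrix or data.frame, observations x variables, with
#'   n_obs > n_vars >= 2.
#' @return vector of nonnegative fractions (descending, summing to 1).
#' @export
pca_explained <- function(data) {
  x <- as.matrix(data)
  if (ncol(x) < 2) stop("need at least 2 variables", call. = FALSE)
  if (nrow(x) <= ncol(x)) {
    stop("need more observations than variables", call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(which(sds == 0), collapse = ", "), call. = FALSE)
  }
  ev <- eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  sort(ev / sum(ev), decreasing = TRUE)
}

#' Null reference for PCA explained inertia
#'
#' Simulates `n_sim` tables of i.i.d. standard-normal entries with the shape
#' of the observed table, records the percent of total inertia captured by
#' the first `n_dims` principal dimensions of each, and returns the 95th
#' percentile of that distribution. An observed inertia above this reference
#' indicates more shared structure among the variables than expected from
#' unstructured noise.
#'
#' @param n_obs observations per simulated table.
#' @param n_vars variables per table.
#' @param n_dims leading dimensions summed (default 2).
#' @param n_sim number of simulated tables (>= 500; default 2000).
#' @param seed integer seed.
#' @param probs quantile of the null distribution (default 0.95).
#' @return the reference percent (0-100).
#' @export
inertia_null_reference <- function(n_obs, n_vars, n_dims = 2, n_sim = 2000,
                                   seed = 1, probs = 0.95) {
  if (n_dims > n_vars) stop("n_dims must not exceed n_vars", call. = FALSE)
  if (n_sim < 500) stop("n_sim must be at least 500", call. = FALSE)
  set.seed(seed)
  pct <- vapply(seq_len(n_sim), function(i) {
    x <- matrix(stats::rnorm(n_obs * n_vars), n_obs, n_vars)
    fr <- pca_explained(x)
    100 * sum(fr[seq_len(n_dims)])
  }, numeric(1))
  unname(stats::quantile(pct, probs))
}

#' Observed PCA inertia vs. the simulated null reference
#'
#' Runs correlation-matrix PCA on the observed table, computes the percent
#' inertia of the first `n_dims` dimensions, and compares it against the
#' 95th-percentile reference from [inertia_null_reference()] for tables of
#' the same shape.
#'
#' @param data observations x variables table.
#' @param n_dims leading dimensions summed (default 2).
#' @param n_sim simulated tables for the reference.
#' @param seed integer seed.
#' @return list with `observed_pct`, `reference_pct_95`, `significant`,
#'   `n_obs`, `n_vars`, `n_sim`, `seed`.
#' @export
pca_inertia_test <- function(data, n_dims = 2, n_sim = 2000, seed = 1) {
  x <- as.matrix(data)
  fr <- pca_explained(x)
  obs <- 100 * sum(fr[seq_len(n_dims)])
  ref <- inertia_null_reference(nrow(x), ncol(x), n_dims = n_dims,
                                n_sim = n_sim, seed = seed)
  list(observed_pct = obs, reference_pct_95 = ref,
       significant = obs > ref,
       n_obs = nrow(x), n_vars = ncol(x), n_sim = n_sim, seed = seed)
}
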