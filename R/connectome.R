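# From ROI timeseries to Fisher-z connectivity matrices and
# density-thresholded weighted graphs.

#' Construct a subject timeseries object
#'
#' @param data numeric matrix, nodes x timepoints.
#' @param subject_id subject identifier.
#' @param node_ids optional node labels; defaults to `node_01`, ...
#' @return an object of class `subject_timeseries`.
#' @export
subject_timeseries <- function(data, subject_id = "subject",
                               node_ids = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 2) stop("need at least 2 nodes", call. = FALSE)
  if (ncol(data) < 4) {
    stop("need at least 4 timepoints (Fisher-z variance requires T - 3 > 0)",
         call. = FALSE)
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("timeseries contains missing or non-finite values", call. = FALSE)
  }
  if (is.null(node_ids)) {
    node_ids <- sprintf("node_%02d", seq_len(nrow(data)))
  }
  stopifnot(length(node_ids) == nrow(data))
  structure(
    list(subject_id = subject_id, node_ids = as.character(node_ids),
         data = unname(data)),
    class = "subject_timeseries"
  )
}

#' Fisher-z connectivity matrix from ROI timeseries
#'
#' Computes all pairwise Pearson correlations between node timeseries and
#' applies the Fisher variance-stabilizing transform z = atanh(r). To keep z
#' finite, r is clipped at |r| = 1 - 1e-7 before the transform. The diagonal
#' (self-correlation) is set to exactly 0.
#'
#' @param ts a `subject_timeseries` object.
#' @return an object of class `connectivity_matrix` with fields `subject_id`,
#'   `z` (N x N symmetric, zero diagonal) and `node_ids`.
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "subject_timeseries"))
  v <- apply(ts$data, 1, stats::var)
  if (any(v == 0)) {
    bad <- ts$node_ids[which(v == 0)]
    stop("zero-variance timeseries for node(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(t(ts$data))
  clip <- 1 - 1e-7
  r <- pmin(pmax(r, -clip), clip)
  z <- atanh(r)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  structure(
    list(subject_id = ts$subject_id, z = unname(z), node_ids = ts$node_ids),
    class = "connectivity_matrix"
  )
}

#' Wrap an existing Fisher-z matrix as a connectivity_matrix
#'
#' @param z symmetric numeric matrix with zero diagonal.
#' @param subject_id subject identifier.
#' @param node_ids optional node labels.
#' @return a `connectivity_matrix`.
#' @export
as_connectivity_matrix <- function(z, subject_id = "subject",
                                   node_ids = NULL) {
  z <- as.matrix(z)
  stop_if_not_square_symmetric(z, "connectivity matrix")
  if (any(diag(z) != 0)) stop("diagonal must be zero", call. = FALSE)
  if (any(!is.finite(z))) stop("entries must be finite", call. = FALSE)
  if (is.null(node_ids)) node_ids <- sprintf("node_%02d", seq_len(nrow(z)))
  structure(
    list(subject_id = subject_id, z = unname(z),
         node_ids = as.character(node_ids)),
    class = "connectivity_matrix"
  )
}

# Deterministic descending ranking of the upper-triangle edges of a symmetric
# matrix: by signed weight, ties broken by lexicographic (i, j).
ranked_edges <- function(z) {
  n <- nrow(z)
  pairs <- upper_pairs(n)
  w <- z[pairs]
  ord <- order(-w, pairs[, 1], pairs[, 2])
  list(pairs = pairs[ord, , drop = FALSE], w = w[ord])
}

#' Proportional (density) thresholding of a connectivity matrix
#'
#' Retains the strongest fraction `density` of the N(N-1)/2 possible
#' undirected edges, ranked by signed Fisher-z weight (strongest positive
#' first); edge-count ties at the cutoff are broken by lexicographic node
#' index so the result is deterministic. Retained edges keep their weights;
#' all other entries are zero. The retained count is
#' round(density * N(N-1)/2), rounding half away from zero.
#'
#' @param C a `connectivity_matrix`.
#' @param density edge density in (0, 1].
#' @return an object of class `thresholded_network` with fields `density`,
#'   `weights` and `node_ids`.
#' @export
proportional_threshold <- function(C, density) {
  stopifnot(inherits(C, "connectivity_matrix"))
  if (!is.numeric(density) || length(density) != 1 ||
      density <= 0 || density > 1) {
    stop("density must be a single value in (0, 1]", call. = FALSE)
  }
  n <- nrow(C$z)
  n_possible <- n * (n - 1) / 2
  n_keep <- as.integer(round_half_up(density * n_possible))
  re <- ranked_edges(C$z)
  keep <- seq_len(n_keep)
  w <- matrix(0, n, n)
  ij <- re$pairs[keep, , drop = FALSE]
  w[ij] <- re$w[keep]
  w[ij[, c(2, 1), drop = FALSE]] <- re$w[keep]
  if (n_keep > 0 && any(re$w[keep] < 0)) {
    warning("retained edges include negative weights; ",
            "weighted graph metrics assume nonnegative connectivity",
            call. = FALSE)
  }
  structure(
    list(density = density, weights = w, node_ids = C$node_ids),
    class = "thresholded_network"
  )
}

#' Build a thresholded_network directly from a weight matrix
#'
#' Convenience constructor for toy graphs and null-model outputs.
#'
#' @param weights symmetric numeric matrix, zero diagonal.
#' @param density nominal density; computed from the nonzero entries if NULL.
#' @param node_ids optional labels.
#' @return a `thresholded_network`.
#' @export
as_thresholded_network <- function(weights, density = NULL, node_ids = NULL) {
  weights <- as.matrix(weights)
  stop_if_not_square_symmetric(weights, "weight matrix")
  diag(weights) <- 0
  n <- nrow(weights)
  if (is.null(density)) {
    density <- sum(weights[upper.tri(weights)] != 0) / (n * (n - 1) / 2)
  }
  if (is.null(node_ids)) node_ids <- sprintf("node_%02d", seq_len(n))
  structure(
    list(density = density, weights = unname(weights),
         node_ids = as.character(node_ids)),
    class = "thresholded_network"
  )
}

#' Density sweep over a grid of thresholds
#'
#' Applies [proportional_threshold()] at each grid value. Because the edge
#' ranking is fixed, the edge sets are nested: every edge present at a lower
#' density is present at every higher one.
#'
#' @param C a `connectivity_matrix`.
#' @param grid strictly increasing densities, each in (0, 1]. Default is the
#'   14-level 6--32% grid in steps of 2%.
#' @return a named list of `thresholded_network`s (names are the densities).
#' @export
density_sweep <- function(C, grid = density_grid()) {
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing",
                                 call. = FALSE)
  nets <- lapply(grid, function(d) proportional_threshold(C, d))
  names(nets) <- formatC(grid, format = "g")
  nets
}

#' Default density grid: 6% to 32% in 2% steps
#'
#' @return numeric vector of 14 densities.
#' @export
density_grid <- function() seq(0.06, 0.32, by = 0.02)

#' Bootstrap edge-significance threshold across a cohort
#'
#' For every edge, forms a percentile bootstrap confidence interval (level
#' `alpha`, i.e. the alpha/2 and 1 - alpha/2 quantiles) of the cohort mean
#' Fisher z by resampling subjects with replacement. An edge is significant
#' when its CI excludes 0. Returns the smallest significant |r| and the
#' fraction of edges deemed significant (the density a significance-based
#' threshold would imply).
#'
#' @param cohort list of `connectivity_matrix` objects (same N).
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param alpha CI level (two-sided), default 0.05.
#' @param seed integer seed.
#' @return list with `r_crit`, `implied_density`, `significant` (logical
#'   matrix over edges) and `mean_z`.
#' @export
bootstrap_edge_threshold <- function(cohort, n_boot = 1000, alpha = 0.05,
                                     seed = 1) {
  stopifnot(length(cohort) >= 3, n_boot >= 100)
  zs <- vapply(cohort, function(C) C$z, cohort[[1]]$z)
  n <- dim(zs)[1]
  ns <- dim(zs)[3]
  pairs <- upper_pairs(n)
  edge_mat <- apply(zs, 3, function(m) m[pairs]) # edges x subjects
  if (all(apply(edge_mat, 1, stats::var) == 0)) {
    stop("degenerate cohort: no between-subject variability", call. = FALSE)
  }
  set.seed(seed)
  boot_means <- matrix(0, nrow(edge_mat), n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(ns, ns, replace = TRUE)
    boot_means[, b] <- rowMeans(edge_mat[, idx, drop = FALSE])
  }
  lo <- apply(boot_means, 1, stats::quantile, probs = alpha / 2)
  hi <- apply(boot_means, 1, stats::quantile, probs = 1 - alpha / 2)
  sig <- (lo > 0) | (hi < 0)
  mean_z <- rowMeans(edge_mat)
  r_crit <- if (any(sig)) min(abs(tanh(mean_z[sig]))) else NA_real_
  sig_mat <- matrix(FALSE, n, n)
  sig_mat[pairs] <- sig
  sig_mat <- sig_mat | t(sig_mat)
  list(r_crit = r_crit,
       implied_density = mean(sig),
       significant = sig_mat,
       mean_z = mean_z)
}

#' Read a subject timeseries from a TSV file
#'
#' Expects nodes x timepoints, tab-separated, no header.
#'
#' @param path file path.
#' @param subject_id subject identifier; defaults to the file stem.
#' @return a `subject_timeseries`.
#' @export
read_timeseries_tsv <- function(path, subject_id = NULL) {
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  subject_timeseries(m, subject_id = subject_id)
}

#' Write a connectivity matrix as TSV
#'
#' Writes the Fisher-z matrix with a header row of node ids.
#'
#' @param C a `connectivity_matrix`.
#' @param path output file path.
#' @export
write_connectivity_tsv <- function(C, path) {
  m <- C$z
  colnames(m) <- C$node_ids
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}
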