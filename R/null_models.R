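# Strength- and degree-preserving randomization of signed connectivity
# matrices, null ensembles, and lattice reference networks.

# Signed binary swap phase: exchanges the weights in the 2 x 2 submatrix
# {a,c} x {b,d} (w_ab <-> w_ad and w_cb <-> w_cd) only when sign(w_ab) ==
# sign(w_cd), sign(w_ad) == sign(w_cb) and the two signs differ (zero counts
# as its own sign). Every accepted swap relocates edges while preserving
# each node's positive-edge count, negative-edge count and the weight
# multiset exactly; on a sparse positive matrix it reduces to the classic
# degree-preserving double-edge swap.
signed_swap <- function(w, n_attempts) {
  n <- nrow(w)
  for (it in seq_len(n_attempts)) {
    v <- sample.int(n, 4)
    a <- v[1]; b <- v[2]; c_ <- v[3]; d <- v[4]
    s_ab <- sign(w[a, b]); s_cd <- sign(w[c_, d])
    s_ad <- sign(w[a, d]); s_cb <- sign(w[c_, b])
    if (s_ab != s_cd || s_ad != s_cb || s_ab == s_ad) next
    tmp <- w[a, b]; w[a, b] <- w[b, a] <- w[a, d]; w[a, d] <- w[d, a] <- tmp
    tmp <- w[c_, d]; w[c_, d] <- w[d, c_] <- w[c_, b]; w[c_, b] <- w[b, c_] <- tmp
  }
  w
}

# Greedy strength re-sort for one sign: given the randomized topology's
# edge list and the original node strengths, assigns the sorted weight
# multiset largest-first to the edge whose endpoints have the largest
# residual strength capacity, decrementing residuals after each assignment.
# Deterministic; approximates the original strength sequence closely.
resort_weights <- function(w_abs_orig, adj_new) {
  n <- nrow(adj_new)
  pairs <- which(upper.tri(adj_new) & adj_new, arr.ind = TRUE)
  n_edges <- nrow(pairs)
  out <- matrix(0, n, n)
  if (n_edges == 0) return(out)
  wts <- sort(w_abs_orig[upper.tri(w_abs_orig)][
    w_abs_orig[upper.tri(w_abs_orig)] > 0], decreasing = TRUE)
  resid <- rowSums(w_abs_orig)
  unassigned <- rep(TRUE, n_edges)
  i_idx <- pairs[, 1]; j_idx <- pairs[, 2]
  for (m in seq_len(n_edges)) {
    score <- resid[i_idx] + resid[j_idx]
    score[!unassigned] <- -Inf
    e <- which.max(score)
    wv <- wts[m]
    out[i_idx[e], j_idx[e]] <- out[j_idx[e], i_idx[e]] <- wv
    resid[i_idx[e]] <- resid[i_idx[e]] - wv
    resid[j_idx[e]] <- resid[j_idx[e]] - wv
    unassigned[e] <- FALSE
  }
  out
}

#' Signed strength/degree-preserving randomization
#'
#' Randomizes a signed Fisher-z connectivity matrix while preserving, per
#' sign, the binary degree sequence and the weight multiset exactly and the
#' node strength sequence approximately. The binary swap phase performs
#' `n_swap_iters` passes of sign-constrained weight swaps over the edge list
#' (positive and negative edges are relocated without ever changing a node's
#' count of positive or negative edges); the per-sign weight multisets are
#' then re-sorted onto the new topology by a residual-strength greedy so
#' that node strengths track the originals (correlations typically
#' >= 0.99 for positive and >= 0.98 for negative sequences).
#'
#' @param C a `connectivity_matrix` (or symmetric signed matrix).
#' @param n_swap_iters swap passes over the edge list (default 5).
#' @param seed integer seed.
#' @return randomized symmetric signed matrix, zero diagonal.
#' @export
randomize_signed <- function(C, n_swap_iters = 5, seed = 1) {
  z <- if (inherits(C, "connectivity_matrix")) C$z else as.matrix(C)
  stop_if_not_square_symmetric(z, "connectivity matrix")
  n_edges <- sum(z[upper.tri(z)] != 0)
  if (n_edges < 2) {
    warning("too few edges to swap; returning a copy", call. = FALSE)
    return(z)
  }
  set.seed(seed)
  w <- signed_swap(z, n_swap_iters * n_edges)
  pos <- resort_weights(pmax(z, 0), w > 0)
  neg <- resort_weights(pmax(-z, 0), w < 0)
  out <- pos - neg
  diag(out) <- 0
  out
}

#' Ensemble of signed randomizations
#'
#' `m` independent randomized matrices with per-replicate seeds derived from
#' the master seed.
#'
#' @param C a `connectivity_matrix` or symmetric matrix.
#' @param m ensemble size (default 100).
#' @param n_swap_iters swap passes per randomization.
#' @param seed master seed.
#' @return object of class `null_ensemble`: list with `matrices`, `seeds`,
#'   `n_swap_iters`.
#' @export
null_ensemble <- function(C, m = 100, n_swap_iters = 5, seed = 1) {
  stopifnot(m >= 1)
  seeds <- vapply(seq_len(m), function(i) derive_seed(seed, i), integer(1))
  mats <- lapply(seeds, function(s) randomize_signed(C, n_swap_iters, s))
  structure(list(matrices = mats, seeds = seeds,
                 n_swap_iters = n_swap_iters),
            class = "null_ensemble")
}

#' Positive-part null ensemble for a thresholded network
#'
#' Randomizes a (nonnegative) thresholded network's topology and weights; a
#' convenience for small-world and rich-club normalization where the inputs
#' are already positive.
#'
#' @param net a `thresholded_network`.
#' @param m ensemble size.
#' @param n_swap_iters swap passes.
#' @param seed master seed.
#' @return list of `thresholded_network`s.
#' @export
null_ensemble_net <- function(net, m = 20, n_swap_iters = 5, seed = 1) {
  ens <- null_ensemble(net$weights, m = m, n_swap_iters = n_swap_iters,
                       seed = seed)
  lapply(ens$matrices, function(w)
    as_thresholded_network(w, density = net$density, node_ids = net$node_ids))
}

#' Degree-preserving lattice reference network
#'
#' Latticization by conditional double-edge swaps: candidate swaps are
#' accepted only when they reduce the total node-index distance
#' sum |i - j| over edges, i.e. move edge mass toward the diagonal band
#' (nodes ordered by index). Afterwards the weight multiset is re-sorted so
#' the largest weights sit on the most band-central edges. Degree sequence
#' and weight multiset are preserved exactly.
#'
#' @param net a `thresholded_network`.
#' @param seed integer seed.
#' @param n_swap_iters swap-attempt passes over the edge list (default 10).
#' @return a latticized `thresholded_network`.
#' @export
lattice_reference <- function(net, seed = 1, n_swap_iters = 10) {
  w <- net_weights(net)
  n <- nrow(w)
  pairs <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  n_edges <- nrow(pairs)
  if (n_edges < 2) return(net)
  set.seed(seed)
  adj <- w != 0
  edges <- pairs # i < j throughout
  cost <- function(i, j) abs(i - j)
  for (it in seq_len(n_swap_iters * n_edges)) {
    e <- sample.int(n_edges, 2)
    a <- edges[e[1], 1]; b <- edges[e[1], 2]
    c_ <- edges[e[2], 1]; d <- edges[e[2], 2]
    if (length(unique(c(a, b, c_, d))) < 4) next
    # candidate rewiring (a,d) & (c,b), chosen over (a,c) & (b,d) at random
    if (stats::runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
    p1 <- sort(c(a, d)); p2 <- sort(c(c_, b))
    if (adj[p1[1], p1[2]] || adj[p2[1], p2[2]]) next
    old_cost <- cost(a, b) + cost(c_, d)
    new_cost <- cost(p1[1], p1[2]) + cost(p2[1], p2[2])
    if (new_cost >= old_cost) next
    adj[a, b] <- adj[b, a] <- FALSE
    adj[c_, d] <- adj[d, c_] <- FALSE
    adj[p1[1], p1[2]] <- adj[p1[2], p1[1]] <- TRUE
    adj[p2[1], p2[2]] <- adj[p2[2], p2[1]] <- TRUE
    edges[e[1], ] <- p1
    edges[e[2], ] <- p2
  }
  # re-sort weights: largest weights on the most band-central edges
  weights_sorted <- sort(w[upper.tri(w)][w[upper.tri(w)] != 0],
                         decreasing = TRUE)
  band <- abs(edges[, 1] - edges[, 2])
  ord <- order(band, edges[, 1], edges[, 2])
  out <- matrix(0, n, n)
  ij <- edges[ord, , drop = FALSE]
  out[ij] <- weights_sorted
  out[ij[, c(2, 1), drop = FALSE]] <- weights_sorted
  as_thresholded_network(out, density = net$density, node_ids = net$node_ids)
}
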