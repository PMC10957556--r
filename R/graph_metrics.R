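# Weighted node-level and global graph measures, small-world indices,
# participation coefficient and rich-club curves. All operate on a
# `thresholded_network` with nonnegative weights; path lengths use the
# standard connectivity convention length = 1/weight.

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

net_weights <- function(net) {
  if (inherits(net, "thresholded_network")) net$weights else as.matrix(net)
}

#' Node degree and strength
#'
#' Degree is the count of nonzero incident edges; strength the sum of
#' incident edge weights.
#'
#' @param net a `thresholded_network`.
#' @return data.frame with node_id, degree, strength.
#' @export
degree_strength <- function(net) {
  w <- net_weights(net)
  data.frame(node_id = net$node_ids,
             degree = as.integer(rowSums(w != 0)),
             strength = rowSums(w))
}

# elementwise cube root of the max-normalized weight matrix
cube_root_norm <- function(w) {
  mx <- max(w)
  if (mx == 0) return(w)
  (w / mx)^(1 / 3)
}

#' Weighted clustering coefficient and transitivity
#'
#' Node clustering uses the geometric-mean (Onnela) formulation on weights
#' normalized by the network maximum:
#' CC_i = (1 / (k_i (k_i - 1))) * sum_{j,h} (w~_ij w~_ih w~_jh)^(1/3).
#' Transitivity is the network-level analogue, total geometric-mean triangle
#' intensity normalized by the total number of connected triples. Nodes with
#' degree < 2 get CC = 0.
#'
#' @param net a `thresholded_network` with nonnegative weights.
#' @return list with `cc` (per-node vector) and `transitivity`.
#' @export
clustering_transitivity <- function(net) {
  w <- net_weights(net)
  if (any(w < 0)) stop("clustering requires nonnegative weights",
                       call. = FALSE)
  k <- rowSums(w != 0)
  w3 <- cube_root_norm(w)
  tri <- diag(w3 %*% w3 %*% w3) # 2 x triangle intensity per node
  denom <- k * (k - 1)
  cc <- ifelse(denom > 0, tri / denom, 0)
  transitivity <- if (sum(denom) > 0) sum(tri) / sum(denom) else 0
  list(cc = cc, transitivity = transitivity)
}

#' Characteristic path length and global efficiency
#'
#' Edge lengths are 1/weight; shortest paths by Dijkstra. CPL is the mean of
#' finite pairwise distances; pairs in different components are excluded from
#' CPL and contribute efficiency 0. Global efficiency is the mean of
#' 1/distance over all node pairs.
#'
#' @param net a `thresholded_network`.
#' @return list with `cpl` (NA, flagged, if no pair is connected),
#'   `global_efficiency`, and `n_disconnected_pairs`.
#' @export
path_metrics <- function(net) {
  g <- as_igraph(net)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                         algorithm = "dijkstra")
  du <- d[upper.tri(d)]
  finite <- is.finite(du)
  cpl <- if (any(finite)) mean(du[finite]) else NA_real_
  eff <- mean(ifelse(finite, 1 / du, 0))
  list(cpl = cpl, global_efficiency = eff,
       n_disconnected_pairs = sum(!finite))
}

#' Weighted local efficiency
#'
#' For each node, the global efficiency of the subgraph induced by its
#' neighbors, computed on weights normalized by the network maximum (so the
#' result lies in [0, 1]). Nodes with degree < 2 get 0.
#'
#' @param net a `thresholded_network` with nonnegative weights.
#' @return numeric vector, one value per node.
#' @export
local_efficiency <- function(net) {
  w <- net_weights(net)
  if (any(w < 0)) stop("local efficiency requires nonnegative weights",
                       call. = FALSE)
  mx <- max(w)
  wn <- if (mx > 0) w / mx else w
  n <- nrow(wn)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(wn[i, ] > 0)
    if (length(nb) < 2) next
    sub <- wn[nb, nb, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    ew <- igraph::E(g)$weight
    d <- igraph::distances(g, weights = if (length(ew)) 1 / ew else NULL)
    du <- d[upper.tri(d)]
    out[i] <- mean(ifelse(is.finite(du), 1 / du, 0))
  }
  out
}

#' Assortativity by degree or strength
#'
#' Pearson correlation of endpoint degree (or strength) over the symmetrized
#' edge list: each undirected edge contributes both (x_i, x_j) and
#' (x_j, x_i). Returns NA with a warning when the endpoint values have zero
#' variance (e.g. a regular graph), which is distinct from an assortativity
#' of 0.
#'
#' @param net a `thresholded_network`.
#' @param mode `"degree"` or `"strength"`.
#' @return correlation in [-1, 1], or NA if undefined.
#' @export
assortativity_index <- function(net, mode = c("strength", "degree")) {
  mode <- match.arg(mode)
  w <- net_weights(net)
  ds <- degree_strength(net)
  v <- if (mode == "degree") ds$degree else ds$strength
  pairs <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  if (nrow(pairs) < 2) stop("need at least 2 edges", call. = FALSE)
  x <- c(v[pairs[, 1]], v[pairs[, 2]])
  y <- c(v[pairs[, 2]], v[pairs[, 1]])
  if (stats::var(x) == 0) {
    warning("assortativity undefined: zero variance of endpoint ", mode,
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Participation coefficient
#'
#' P_i = 1 - sum_m (d_im / d_i)^2, where d_im is node i's degree restricted
#' to module m and d_i its total degree. Nodes with d_i = 0 get P = 0. A
#' strength-weighted variant (using edge weights in place of edge counts) is
#' available via `weighted = TRUE`.
#'
#' @param net a `thresholded_network`.
#' @param partition integer module affiliation covering every node.
#' @param weighted use strength instead of degree.
#' @return numeric vector of participation coefficients in [0, 1).
#' @export
participation_coefficient <- function(net, partition, weighted = FALSE) {
  w <- net_weights(net)
  n <- nrow(w)
  if (length(partition) != n) {
    stop("partition length must equal number of nodes", call. = FALSE)
  }
  a <- if (weighted) w else (w != 0) + 0
  d <- rowSums(a)
  mods <- sort(unique(partition))
  frac2 <- matrix(0, n, length(mods))
  for (mi in seq_along(mods)) {
    cols <- partition == mods[mi]
    frac2[, mi] <- rowSums(a[, cols, drop = FALSE])
  }
  p <- 1 - rowSums((frac2 / ifelse(d > 0, d, 1))^2)
  ifelse(d > 0, p, 0)
}

#' Small-world coefficient and lattice-referenced small-world measure
#'
#' gamma = transitivity(net) / mean transitivity of the random ensemble;
#' lambda = CPL(net) / mean CPL of the ensemble; SWC = gamma / lambda.
#' SWM is the omega-style lattice-referenced measure
#' CPL_rand / CPL - CC / CC_lattice, using the same transitivity statistic
#' for CC and a degree-preserving latticized reference.
#'
#' @param net a `thresholded_network`.
#' @param null_ensemble list of null networks (or weight matrices) matched to
#'   `net`, e.g. from [null_ensemble()].
#' @param lattice_ref latticized reference network, e.g. from
#'   [lattice_reference()]; required for SWM (NULL gives SWM = NA).
#' @return list with gamma, lambda, swc, swm.
#' @export
small_world <- function(net, null_ensemble, lattice_ref = NULL) {
  stopifnot(length(null_ensemble) >= 1)
  t_net <- clustering_transitivity(net)$transitivity
  p_net <- path_metrics(net)$cpl
  ens <- lapply(null_ensemble, function(m) {
    nm <- if (inherits(m, "thresholded_network")) m else
      as_thresholded_network(m)
    c(t = clustering_transitivity(nm)$transitivity, l = path_metrics(nm)$cpl)
  })
  t_rand <- mean(vapply(ens, `[[`, 0, "t"))
  l_rand <- mean(vapply(ens, `[[`, 0, "l"))
  if (t_rand == 0 || l_rand == 0 || is.na(p_net)) {
    stop("small-world indices undefined: degenerate null ensemble or ",
         "disconnected network", call. = FALSE)
  }
  gamma <- t_net / t_rand
  lambda <- p_net / l_rand
  swm <- NA_real_
  if (!is.null(lattice_ref)) {
    t_latt <- clustering_transitivity(lattice_ref)$transitivity
    if (t_latt > 0) swm <- l_rand / p_net - t_net / t_latt
  }
  list(gamma = gamma, lambda = lambda, swc = gamma / lambda, swm = swm)
}

# phi_w(k) for one weight matrix: subgraph of nodes with degree > k; ratio of
# its summed weights to the sum of the same number of globally largest
# weights. NA where fewer than 2 nodes remain or the subgraph has no edges.
rich_club_phi <- function(w, k_grid) {
  k <- rowSums(w != 0)
  wt_sorted <- sort(w[upper.tri(w)][w[upper.tri(w)] > 0], decreasing = TRUE)
  vapply(k_grid, function(kk) {
    keep <- which(k > kk)
    if (length(keep) < 2) return(NA_real_)
    sub <- w[keep, keep, drop = FALSE]
    e_gt <- sum(sub[upper.tri(sub)] != 0)
    if (e_gt == 0) return(NA_real_)
    sum(sub[upper.tri(sub)]) / sum(wt_sorted[seq_len(e_gt)])
  }, numeric(1))
}

#' Weighted rich-club curve with null normalization
#'
#' For each degree level k, Phi_w(k) is the ratio of the summed edge weights
#' among nodes of degree > k to the sum of the equally many largest weights
#' anywhere in the network. Phi_norm(k) = Phi_w(k) / mean Phi of the null
#' ensemble at k. Levels where the club has fewer than 2 nodes or no edges,
#' or where the null mean is 0/undefined, are NA.
#'
#' @param net a `thresholded_network` with nonnegative weights.
#' @param null_ensemble list of matched null networks or weight matrices.
#' @return data.frame with k, phi, phi_rand_mean, phi_norm.
#' @export
rich_club <- function(net, null_ensemble) {
  w <- net_weights(net)
  if (any(w < 0)) stop("rich club requires nonnegative weights",
                       call. = FALSE)
  kmax <- max(rowSums(w != 0))
  if (kmax < 2) {
    return(data.frame(k = integer(0), phi = numeric(0),
                      phi_rand_mean = numeric(0), phi_norm = numeric(0)))
  }
  k_grid <- seq_len(kmax - 1)
  phi <- rich_club_phi(w, k_grid)
  phi_rand <- vapply(null_ensemble, function(m) {
    wm <- if (inherits(m, "thresholded_network")) m$weights else as.matrix(m)
    rich_club_phi(wm, k_grid)
  }, numeric(length(k_grid)))
  if (is.null(dim(phi_rand))) phi_rand <- matrix(phi_rand, nrow = length(k_grid))
  phi_rand_mean <- rowMeans(phi_rand, na.rm = TRUE)
  phi_rand_mean[!is.finite(phi_rand_mean)] <- NA_real_
  phi_norm <- ifelse(!is.na(phi) & !is.na(phi_rand_mean) & phi_rand_mean > 0,
                     phi / phi_rand_mean, NA_real_)
  data.frame(k = k_grid, phi = phi, phi_rand_mean = phi_rand_mean,
             phi_norm = phi_norm)
}

#' All global metrics for one network
#'
#' Convenience wrapper returning transitivity, CPL, global efficiency and
#' strength assortativity in one row.
#'
#' @param net a `thresholded_network`.
#' @return one-row data.frame.
#' @export
global_metrics <- function(net) {
  ct <- clustering_transitivity(net)
  pm <- path_metrics(net)
  r <- tryCatch(suppressWarnings(assortativity_index(net, "strength")),
                error = function(e) NA_real_)
  data.frame(transitivity = ct$transitivity, cpl = pm$cpl,
             global_efficiency = pm$global_efficiency, assortativity = r)
}

#' All nodal metrics for one network
#'
#' Degree, strength, clustering, local efficiency and (given a partition)
#' participation coefficient at a single density.
#'
#' @param net a `thresholded_network`.
#' @param partition optional module affiliation for the participation
#'   coefficient.
#' @return data.frame with one row per node.
#' @export
node_metrics <- function(net, partition = NULL) {
  out <- degree_strength(net)
  out$clustering <- clustering_transitivity(net)$cc
  out$local_efficiency <- local_efficiency(net)
  if (!is.null(partition)) {
    out$participation <- participation_coefficient(net, partition)
  }
  out
}
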