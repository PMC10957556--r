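# Shared toy graphs and brute-force oracles used across the suite.

# weight matrix from an edge list: rows (i, j, w)
wmat <- function(n, edges) {
  w <- matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    w[i, j] <- w[j, i] <- edges[r, 3]
  }
  w
}

tnet <- function(w) as_thresholded_network(w)

unit_triangle <- function() tnet(wmat(3, cbind(c(1, 1, 2), c(2, 3, 3), 1)))

star_graph <- function(n_leaves = 5) {
  tnet(wmat(n_leaves + 1, cbind(1, 1 + seq_len(n_leaves), 1)))
}

path_abc <- function() tnet(wmat(3, cbind(c(1, 2), c(2, 3), 1)))

# two unit-weight 4-cliques joined by a single bridge edge (8 nodes)
two_clique_bridge <- function() {
  edges <- rbind(
    t(combn(1:4, 2)),
    t(combn(5:8, 2)),
    c(4, 5)
  )
  tnet(wmat(8, cbind(edges, 1)))
}

er_net <- function(n = 60, m = 283, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnm(n, m)
  tnet(igraph::as_adjacency_matrix(g, sparse = FALSE) * 1)
}

# weighted ER: unit topology with Uniform(0.5, 1.5) weights
er_weighted <- function(n = 60, m = 283, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnm(n, m)
  w <- igraph::as_adjacency_matrix(g, sparse = FALSE) * 1
  u <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  vals <- stats::runif(nrow(u), 0.5, 1.5)
  w[u] <- vals
  w[u[, c(2, 1)]] <- vals
  tnet(w)
}

# all set partitions of 1..n as label vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, next_label) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible(NULL))
    }
    for (lab in seq_len(next_label)) {
      rec(c(labels, lab), max(next_label, lab + 1))
    }
  }
  rec(integer(0), 1)
  out
}

# brute-force maximum modularity over all partitions (feasible for n <= 8)
brute_force_max_q <- function(net) {
  parts <- all_partitions(nrow(net$weights))
  qs <- vapply(parts, function(p) modularity_value(net, p), numeric(1))
  list(q = max(qs), partition = parts[[which.max(qs)]], n_partitions = length(parts))
}

# brute-force weighted global efficiency via exhaustive simple-path search
brute_force_efficiency <- function(w) {
  n <- nrow(w)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  # enumerate all simple paths between every pair
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      stack <- list(list(v = s, seen = s, d = 0))
      while (length(stack)) {
        st <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        if (st$v == t) {
          best[s, t] <- min(best[s, t], st$d)
          next
        }
        for (nb in which(w[st$v, ] > 0)) {
          if (nb %in% st$seen) next
          stack[[length(stack) + 1]] <-
            list(v = nb, seen = c(st$seen, nb), d = st$d + 1 / w[st$v, nb])
        }
      }
      best[t, s] <- best[s, t]
    }
  }
  du <- best[upper.tri(best)]
  list(distances = best,
       cpl = mean(du[is.finite(du)]),
       efficiency = mean(ifelse(is.finite(du), 1 / du, 0)))
}
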