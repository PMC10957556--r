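# Modularity maximization (Louvain) with co-assignment consensus over
# repeated runs.

#' Newman-Girvan weighted modularity
#'
#' Q = (1/2m) * sum_ij (w_ij - s_i s_j / 2m) delta(c_i, c_j), with m the
#' total edge weight. Deterministic; operates on the (nonnegative) weights
#' of the thresholded network.
#'
#' @param net a `thresholded_network`.
#' @param affiliation integer module labels covering every node.
#' @param gamma_res resolution parameter (default 1).
#' @return modularity Q.
#' @export
modularity_value <- function(net, affiliation, gamma_res = 1) {
  w <- net_weights(net)
  n <- nrow(w)
  if (length(affiliation) != n) {
    stop("affiliation must cover all nodes", call. = FALSE)
  }
  two_m <- sum(w)
  if (two_m == 0) stop("empty graph", call. = FALSE)
  s <- rowSums(w)
  same <- outer(affiliation, affiliation, "==")
  sum((w - gamma_res * outer(s, s) / two_m) * same) / two_m
}

# relabel so module ids are contiguous from 1, ordered by descending size
# (ties by first appearance)
canonicalize_labels <- function(affiliation) {
  tab <- table(affiliation)
  first <- tapply(seq_along(affiliation), affiliation, min)
  ord <- names(tab)[order(-tab, first)]
  match(as.character(affiliation), ord)
}

#' One Louvain modularity-maximization run
#'
#' Runs the Louvain algorithm (igraph implementation) from a seeded random
#' state on the positive thresholded weights. Q is recomputed with
#' [modularity_value()].
#'
#' @param net a `thresholded_network`.
#' @param seed integer seed (Louvain's node ordering is stochastic).
#' @param gamma_res resolution parameter.
#' @return object of class `fc_partition`: list with `affiliation`
#'   (canonical labels, contiguous from 1), `Q`, `gamma_res`, `seed`.
#' @export
louvain_once <- function(net, seed = 1, gamma_res = 1) {
  g <- as_igraph(net)
  if (any(igraph::E(g)$weight < 0)) {
    stop("Louvain operates on nonnegative weights", call. = FALSE)
  }
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                                resolution = gamma_res)
  aff <- canonicalize_labels(igraph::membership(cl))
  structure(
    list(affiliation = aff,
         Q = modularity_value(net, aff, gamma_res),
         gamma_res = gamma_res, seed = seed),
    class = "fc_partition"
  )
}

#' Consensus community structure over repeated Louvain runs
#'
#' Runs Louvain `n_iter` times with derived seeds, builds the node-pair
#' co-assignment matrix (fraction of runs placing each pair in the same
#' module), thresholds it at `tau` and re-clusters the thresholded
#' co-assignment graph, iterating until all runs agree (standard consensus
#' clustering). A "median" community structure of many stochastic restarts
#' is ill-defined on raw label vectors, so the stable affiliation is obtained
#' by consensus while the run-to-run Q distribution is summarized by its
#' median.
#'
#' @param net a `thresholded_network`.
#' @param n_iter number of Louvain restarts (default 100).
#' @param seed master seed.
#' @param tau co-assignment threshold (default 0.5).
#' @param gamma_res resolution parameter.
#' @param max_rounds consensus iteration cap.
#' @return object of class `consensus_result`: `final_partition`
#'   (`fc_partition` with Q evaluated on `net`), `n_modules`,
#'   `module_sizes`, `Q_runs` (length `n_iter`), `Q_summary` (median).
#' @export
consensus_partition <- function(net, n_iter = 100, seed = 1, tau = 0.5,
                                gamma_res = 1, max_rounds = 20) {
  stopifnot(n_iter >= 1)
  n <- nrow(net$weights)
  runs <- lapply(seq_len(n_iter), function(i)
    louvain_once(net, seed = derive_seed(seed, i), gamma_res = gamma_res))
  q_runs <- vapply(runs, `[[`, 0, "Q")
  memb <- do.call(rbind, lapply(runs, `[[`, "affiliation"))

  round <- 0L
  repeat {
    round <- round + 1L
    if (all_rows_identical(memb) || round > max_rounds) break
    co <- co_assignment(memb)
    co[co < tau] <- 0
    diag(co) <- 0
    if (sum(co) == 0) {
      # threshold wiped out all agreement; fall back to the best single run
      memb <- memb[rep(which.max(q_runs), nrow(memb)), , drop = FALSE]
      break
    }
    co_net <- as_thresholded_network(co)
    memb <- do.call(rbind, lapply(seq_len(nrow(memb)), function(i)
      louvain_once(co_net,
                   seed = derive_seed(seed, 1000L * round + i),
                   gamma_res = gamma_res)$affiliation))
  }

  aff <- canonicalize_labels(memb[1, ])
  final <- structure(
    list(affiliation = aff, Q = modularity_value(net, aff, gamma_res),
         gamma_res = gamma_res, seed = seed),
    class = "fc_partition"
  )
  sizes <- as.integer(table(aff))
  structure(
    list(final_partition = final,
         n_modules = length(sizes),
         module_sizes = sizes,
         Q_runs = q_runs,
         Q_summary = stats::median(q_runs)),
    class = "consensus_result"
  )
}

all_rows_identical <- function(m) {
  if (nrow(m) == 1) return(TRUE)
  all(apply(m, 1, function(r) identical(r, m[1, ])))
}

# fraction of runs assigning each node pair to the same module
co_assignment <- function(memb) {
  n <- ncol(memb)
  co <- matrix(0, n, n)
  for (i in seq_len(nrow(memb))) {
    co <- co + outer(memb[i, ], memb[i, ], "==")
  }
  co / nrow(memb)
}

#' Module census across subjects
#'
#' Tabulates module count and sizes per subject, with per-group medians and
#' IQRs when a group label is supplied.
#'
#' @param results list of `consensus_result` objects.
#' @param subject_ids optional subject identifiers.
#' @param groups optional group label per subject.
#' @return list with `subjects` (one row each: n_modules, module sizes) and
#'   `group_summary` (median and IQR of n_modules per group; NULL if no
#'   groups given).
#' @export
module_census <- function(results, subject_ids = NULL, groups = NULL) {
  stopifnot(length(results) >= 1)
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("subject_%02d", seq_along(results))
  }
  subjects <- data.frame(
    subject_id = subject_ids,
    n_modules = vapply(results, `[[`, 0L, "n_modules"),
    module_sizes = vapply(results, function(r)
      paste(r$module_sizes, collapse = ","), ""),
    Q = vapply(results, function(r) r$final_partition$Q, 0),
    Q_median_runs = vapply(results, `[[`, 0, "Q_summary")
  )
  group_summary <- NULL
  if (!is.null(groups)) {
    subjects$group <- groups
    agg <- split(subjects$n_modules, groups)
    group_summary <- data.frame(
      group = names(agg),
      median_n_modules = vapply(agg, stats::median, 0),
      iqr_n_modules = vapply(agg, stats::IQR, 0)
    )
    rownames(group_summary) <- NULL
  }
  list(subjects = subjects, group_summary = group_summary)
}
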