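# End-to-end pipeline: (optional) simulation -> connectivity -> density
# sweep -> graph metrics -> null models -> consensus communities -> AUC
# summaries, with a reproducibility manifest.

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. Either `input_dir` (a
#' directory of per-subject TSV timeseries plus `metadata.csv`) or `cohort`
#' (a [cohort_spec()] to simulate) must be given.
#'
#' @param out_dir output directory.
#' @param input_dir directory with per-subject `<id>.tsv` timeseries and a
#'   `metadata.csv` (subject_id, group, sex); NULL to simulate instead.
#' @param cohort a `cohort_spec` used when `input_dir` is NULL.
#' @param grid density sweep grid (default 6-32% in 2% steps).
#' @param nodal_density single density for node-level metrics (default 0.16).
#' @param consensus_iters Louvain restarts per consensus (default 100).
#' @param null_m null-ensemble size (default 20).
#' @param n_swap_iters swap passes for randomization (default 5).
#' @param seed master seed; all pipeline randomness derives from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, input_dir = NULL, cohort = NULL,
                            grid = density_grid(), nodal_density = 0.16,
                            consensus_iters = 100, null_m = 20,
                            n_swap_iters = 5, seed = 1) {
  if (is.null(input_dir) && is.null(cohort)) {
    stop("provide input_dir or a cohort_spec", call. = FALSE)
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input directory does not exist: ", input_dir, call. = FALSE)
  }
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing",
                                 call. = FALSE)
  structure(
    list(out_dir = out_dir, input_dir = input_dir, cohort = cohort,
         grid = grid, nodal_density = nodal_density,
         consensus_iters = as.integer(consensus_iters),
         null_m = as.integer(null_m),
         n_swap_iters = as.integer(n_swap_iters), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Global metric profile of one subject across the density sweep
#'
#' Thresholds the connectivity matrix at each grid density and records
#' transitivity, CPL, global efficiency, strength assortativity, and the
#' modularity Q summarized as the median over `n_louvain` seeded restarts.
#'
#' @param C a `connectivity_matrix`.
#' @param grid density grid.
#' @param n_louvain Louvain restarts per density for the Q median.
#' @param seed integer seed.
#' @return data.frame with one row per density.
#' @export
subject_global_profile <- function(C, grid = density_grid(), n_louvain = 100,
                                   seed = 1) {
  nets <- density_sweep(C, grid)
  rows <- lapply(seq_along(grid), function(i) {
    net <- nets[[i]]
    gm <- global_metrics(net)
    qs <- vapply(seq_len(n_louvain), function(j)
      louvain_once(net, seed = derive_seed(seed, i * 1000L + j))$Q,
      numeric(1))
    gm$modularity_q <- stats::median(qs)
    gm$density <- grid[i]
    gm
  })
  out <- do.call(rbind, rows)
  out[, c("density", "transitivity", "cpl", "global_efficiency",
          "assortativity", "modularity_q")]
}

load_cohort_dir <- function(input_dir) {
  meta_path <- file.path(input_dir, "metadata.csv")
  if (!file.exists(meta_path)) {
    stop("metadata.csv not found in ", input_dir, call. = FALSE)
  }
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    f <- file.path(input_dir, paste0(meta$subject_id[i], ".tsv"))
    if (!file.exists(f)) stop("timeseries file missing: ", f, call. = FALSE)
    ts <- as.matrix(utils::read.table(f, sep = "\t", header = FALSE))
    list(subject_id = meta$subject_id[i], group = meta$group[i],
         sex = meta$sex[i], timeseries = ts, planted_partition = NULL)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> connectivity -> density sweep -> global
#' metrics -> AUC -> nodal metrics + consensus communities at the nodal
#' density, writes tidy CSV outputs and a JSON manifest (seeds, parameters,
#' file checksums) to `config$out_dir`, and returns the manifest invisibly.
#' Reruns with an identical config reproduce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  note <- function(...) {
    warnings_log <<- c(warnings_log, paste0(...))
  }

  cohort <- if (!is.null(config$input_dir)) {
    load_cohort_dir(config$input_dir)
  } else {
    make_cohort(config$cohort)
  }

  conn_dir <- file.path(config$out_dir, "connectivity")
  dir.create(conn_dir, showWarnings = FALSE)
  global_rows <- list()
  auc_rows <- list()
  node_rows <- list()
  comm_rows <- list()
  census <- list()

  for (si in seq_along(cohort)) {
    s <- cohort[[si]]
    stage <- "connectivity"
    res <- tryCatch({
      ts <- subject_timeseries(s$timeseries, subject_id = s$subject_id)
      C <- correlation_matrix(ts)
      write_connectivity_tsv(C, file.path(conn_dir,
                                          paste0(s$subject_id, ".tsv")))

      stage <- "global metrics"
      prof <- subject_global_profile(C, grid = config$grid,
                                     n_louvain = config$consensus_iters,
                                     seed = derive_seed(config$seed, si))
      long <- stats::reshape(
        prof, direction = "long",
        varying = setdiff(names(prof), "density"),
        v.names = "value", timevar = "metric",
        times = setdiff(names(prof), "density")
      )
      long <- data.frame(subject_id = s$subject_id, group = s$group,
                         metric = long$metric, density = long$density,
                         value = long$value)

      stage <- "AUC"
      aucs <- do.call(rbind, lapply(split(long, long$metric), function(d) {
        d <- d[order(d$density), ]
        ok <- !is.na(d$value)
        data.frame(subject_id = s$subject_id, group = s$group,
                   metric = d$metric[1],
                   auc = if (sum(ok) >= 2)
                     metric_auc(d$value[ok], d$density[ok]) else NA_real_)
      }))

      stage <- "nodal metrics and communities"
      net <- proportional_threshold(C, config$nodal_density)
      cons <- consensus_partition(net, n_iter = config$consensus_iters,
                                  seed = derive_seed(config$seed,
                                                     10000L + si))
      nm <- node_metrics(net, partition = cons$final_partition$affiliation)
      nm <- data.frame(subject_id = s$subject_id, group = s$group,
                       density = config$nodal_density, nm)
      cm <- data.frame(subject_id = s$subject_id, node_id = net$node_ids,
                       module = cons$final_partition$affiliation)
      list(global = long, auc = aucs, node = nm, comm = cm, cons = cons)
    }, error = function(e) {
      stop("pipeline failed at stage '", stage, "' for subject ",
           s$subject_id, ": ", conditionMessage(e), call. = FALSE)
    })
    global_rows[[si]] <- res$global
    auc_rows[[si]] <- res$auc
    node_rows[[si]] <- res$node
    comm_rows[[si]] <- res$comm
    census[[si]] <- res$cons
  }

  paths <- c(
    global_metrics = file.path(config$out_dir, "global_metrics.csv"),
    auc = file.path(config$out_dir, "auc.csv"),
    node_metrics = file.path(config$out_dir, "node_metrics.csv"),
    communities = file.path(config$out_dir, "communities.csv"),
    module_census = file.path(config$out_dir, "module_census.csv")
  )
  write_tidy <- function(rows, path) {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  write_tidy(global_rows, paths["global_metrics"])
  write_tidy(auc_rows, paths["auc"])
  write_tidy(node_rows, paths["node_metrics"])
  write_tidy(comm_rows, paths["communities"])
  cen <- module_census(census,
                       subject_ids = vapply(cohort, `[[`, "", "subject_id"),
                       groups = vapply(cohort, `[[`, "", "group"))
  utils::write.csv(cen$subjects, paths["module_census"], row.names = FALSE,
                   quote = FALSE)

  out_files <- c(paths, list.files(conn_dir, full.names = TRUE))
  manifest <- list(
    package_version = as.character(utils::packageVersion("fcgraph")),
    seed = config$seed,
    parameters = list(grid = config$grid,
                      nodal_density = config$nodal_density,
                      consensus_iters = config$consensus_iters,
                      null_m = config$null_m,
                      n_swap_iters = config$n_swap_iters),
    n_subjects = length(cohort),
    outputs = as.list(stats::setNames(unname(tools::md5sum(out_files)),
                                      basename(out_files))),
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
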