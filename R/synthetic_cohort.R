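# Synthetic cohort generator: ROI timeseries with planted modular covariance
# (group-varying between-module coupling) and toy behavior tables. Emulates a
# three-age-group resting-state design (3 groups x n = 10, 60 nodes, 600
# timepoints) so the whole downstream pipeline is testable without scan data.

#' Specify a synthetic cohort
#'
#' Defines the study design the generator emulates: group labels, subjects
#' per group, node/timepoint counts, the planted module layout, and the
#' within- and between-module correlations per group. Lower `rho_between`
#' means a more modular functional network; the default group gradient
#' (0.05, 0.10, 0.15 for the youngest to oldest group) encodes declining
#' modular segregation with age.
#'
#' @param groups character vector of group labels.
#' @param n_per_group subjects per group.
#' @param n_nodes number of ROIs (default 60).
#' @param n_timepoints timeseries length (default 600).
#' @param module_sizes sizes of the planted modules; must sum to `n_nodes`.
#' @param rho_within within-module correlation, one value per group
#'   (recycled if scalar), each in (0, 1).
#' @param rho_between between-module correlation per group, each in
#'   `[0, rho_within)`.
#' @param noise_sd sd of additive i.i.d. Gaussian measurement noise on top of
#'   the multivariate-normal signal (default 0.5).
#' @param seed master seed; per-subject streams are derived from it.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = c("10wo", "30wo", "60wo"),
                        n_per_group = 10,
                        n_nodes = 60,
                        n_timepoints = 600,
                        module_sizes = c(15, 15, 15, 15),
                        rho_within = 0.5,
                        rho_between = c(0.05, 0.10, 0.15),
                        noise_sd = 0.5,
                        seed = 1) {
  groups <- as.character(groups)
  ng <- length(groups)
  rho_within <- rep_len(rho_within, ng)
  rho_between <- rep_len(rho_between, ng)
  if (sum(module_sizes) != n_nodes) {
    stop("module_sizes must sum to n_nodes", call. = FALSE)
  }
  if (any(module_sizes <= 0)) stop("module sizes must be positive",
                                   call. = FALSE)
  if (any(rho_within <= 0 | rho_within >= 1)) {
    stop("rho_within must lie in (0, 1)", call. = FALSE)
  }
  if (any(rho_between < 0 | rho_between >= rho_within)) {
    stop("rho_between must lie in [0, rho_within)", call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  names(rho_within) <- names(rho_between) <- groups
  spec <- structure(
    list(groups = groups, n_per_group = as.integer(n_per_group),
         n_nodes = as.integer(n_nodes),
         n_timepoints = as.integer(n_timepoints),
         module_sizes = as.integer(module_sizes),
         rho_within = rho_within, rho_between = rho_between,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "cohort_spec"
  )
  # every group's implied block covariance must be PSD
  for (g in groups) block_covariance(spec, g)
  spec
}

#' Planted block covariance for one group
#'
#' Symmetric matrix with unit diagonal, `rho_within` for node pairs in the
#' same module and `rho_between` otherwise. Rejects parameter combinations
#' whose covariance is not positive semi-definite.
#'
#' @param spec a `cohort_spec`.
#' @param group one of `spec$groups`.
#' @return `n_nodes` x `n_nodes` covariance matrix.
#' @export
block_covariance <- function(spec, group) {
  stopifnot(inherits(spec, "cohort_spec"), group %in% spec$groups)
  part <- planted_partition(spec)
  same <- outer(part, part, "==")
  sigma <- ifelse(same, spec$rho_within[group], spec$rho_between[group])
  diag(sigma) <- 1
  ev_min <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-10) {
    stop("block covariance for group ", group,
         " is not positive semi-definite (smallest eigenvalue ",
         format(ev_min), "); reduce rho_within or rho_between",
         call. = FALSE)
  }
  sigma
}

#' Planted module affiliation implied by a cohort spec
#'
#' @param spec a `cohort_spec`.
#' @return integer affiliation vector of length `n_nodes`.
#' @export
planted_partition <- function(spec) {
  rep(seq_along(spec$module_sizes), spec$module_sizes)
}

#' Generate a synthetic cohort of ROI timeseries
#'
#' Each subject's node x timepoint matrix is drawn as timepoints of a
#' zero-mean multivariate normal with the group's block covariance, plus
#' independent Gaussian noise of sd `noise_sd`; each node series is then
#' L2-normalized (which leaves all pairwise correlations unchanged).
#' Per-subject RNG streams are derived from the master seed, so cohorts are
#' reproducible subject by subject.
#'
#' @param spec a `cohort_spec`.
#' @return list of subjects; each has `subject_id`, `group`, `sex`,
#'   `timeseries` (matrix, nodes x timepoints) and `planted_partition`.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  part <- planted_partition(spec)
  subjects <- vector("list", length(spec$groups) * spec$n_per_group)
  k <- 0L
  for (gi in seq_along(spec$groups)) {
    g <- spec$groups[gi]
    sigma <- block_covariance(spec, g)
    for (si in seq_len(spec$n_per_group)) {
      k <- k + 1L
      set.seed(derive_seed(spec$seed, k))
      x <- MASS::mvrnorm(spec$n_timepoints, mu = rep(0, spec$n_nodes),
                         Sigma = sigma)
      ts <- t(x) + matrix(stats::rnorm(spec$n_nodes * spec$n_timepoints,
                                       sd = spec$noise_sd),
                          spec$n_nodes, spec$n_timepoints)
      ts <- ts / sqrt(rowSums(ts^2))
      dimnames(ts) <- NULL
      subjects[[k]] <- list(
        subject_id = sprintf("%s_%02d", g, si),
        group = g,
        sex = if (si %% 2 == 1) "F" else "M",
        timeseries = ts,
        planted_partition = part
      )
    }
  }
  subjects
}

#' Default per-group behavioral effect parameters
#'
#' Means and sds, per group, for the toy behavior tables: open-field margin
#' distance (cm), freezing counts on days 1-3, and 24 h sucrose and water
#' volumes (mL). The defaults plant a young group with higher margin-distance
#' activity and stronger fear recall, and no group difference in sucrose
#' preference.
#'
#' @param groups group labels the parameters are indexed by.
#' @return nested list: one element per measure, each with `mean` and `sd`
#'   vectors named by group.
#' @export
default_effect_params <- function(groups = c("10wo", "30wo", "60wo")) {
  per_group <- function(m, s) list(mean = stats::setNames(rep_len(m, length(groups)), groups),
                                   sd = stats::setNames(rep_len(s, length(groups)), groups))
  list(
    margin_distance = per_group(c(2600, 2100, 2000), 300),
    freezing_d1 = per_group(c(20, 25, 25), 8),
    freezing_d2 = per_group(c(55, 40, 42), 10),
    freezing_d3 = per_group(c(45, 32, 35), 10),
    sucrose_volume = per_group(6, 1.2),
    water_volume = per_group(2, 0.8)
  )
}

#' Toy behavior tables for a synthetic cohort
#'
#' Draws one record per subject from per-group normal distributions and
#' truncates counts and volumes at zero (physical nonnegativity).
#' Deterministic given the spec's seed.
#'
#' @param spec a `cohort_spec`.
#' @param effect_params per-group means/sds as produced by
#'   [default_effect_params()].
#' @return data.frame with one row per subject: subject_id, group, sex,
#'   margin_distance, freezing_d1..d3, sucrose_volume, water_volume.
#' @export
behavior_tables <- function(spec, effect_params = default_effect_params(spec$groups)) {
  stopifnot(inherits(spec, "cohort_spec"))
  for (nm in names(effect_params)) {
    p <- effect_params[[nm]]
    if (any(p$sd < 0)) stop("negative sd for ", nm, call. = FALSE)
    if (!all(spec$groups %in% names(p$mean)) ||
        !all(spec$groups %in% names(p$sd))) {
      stop("effect_params for ", nm, " must name every group", call. = FALSE)
    }
  }
  measures <- names(effect_params)
  n_total <- length(spec$groups) * spec$n_per_group
  rows <- vector("list", n_total)
  k <- 0L
  for (g in spec$groups) {
    for (si in seq_len(spec$n_per_group)) {
      k <- k + 1L
      set.seed(derive_seed(spec$seed, 100000L + k))
      vals <- vapply(measures, function(nm) {
        p <- effect_params[[nm]]
        max(0, stats::rnorm(1, p$mean[[g]], p$sd[[g]]))
      }, numeric(1))
      rows[[k]] <- data.frame(
        subject_id = sprintf("%s_%02d", g, si), group = g,
        sex = if (si %% 2 == 1) "F" else "M",
        as.list(vals), check.names = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a cohort to disk
#'
#' Per-subject timeseries as TSV (nodes x timepoints, no header), a metadata
#' CSV (subject_id, group, sex), and a JSON sidecar with the cohort spec and
#' seed.
#'
#' @param cohort output of [make_cohort()].
#' @param spec the `cohort_spec` used.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (s in cohort) {
    f <- file.path(dir, paste0(s$subject_id, ".tsv"))
    utils::write.table(s$timeseries, f, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  meta <- data.frame(
    subject_id = vapply(cohort, `[[`, "", "subject_id"),
    group = vapply(cohort, `[[`, "", "group"),
    sex = vapply(cohort, `[[`, "", "sex")
  )
  mf <- file.path(dir, "metadata.csv")
  utils::write.csv(meta, mf, row.names = FALSE, quote = FALSE)
  sf <- file.path(dir, "cohort_spec.json")
  jsonlite::write_json(unclass(spec), sf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, mf, sf))
}
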