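test_that("Fisher-z matrix handles perfect and anti-correlation by clipping", {
  set.seed(1)
  base <- rnorm(50)
  ts <- subject_timeseries(rbind(base, base, -base) + 0,
                           node_ids = c("a", "b", "c"))
  C <- correlation_matrix(ts)
  zmax <- atanh(1 - 1e-7)
  expect_equal(C$z[1, 2], zmax)
  expect_equal(C$z[1, 3], -zmax)
  expect_equal(C$z, t(C$z))
  expect_equal(diag(C$z), rep(0, 3))
})

test_that("zero-variance nodes are rejected by name", {
  m <- rbind(rnorm(20), rep(1, 20))
  ts <- subject_timeseries(m, node_ids = c("ok", "flat"))
  expect_error(correlation_matrix(ts), "flat")
})

test_that("white-noise z spread matches Fisher sampling theory", {
  set.seed(42)
  ts <- subject_timeseries(matrix(rnorm(60 * 600), 60, 600))
  C <- correlation_matrix(ts)
  sd_obs <- sd(C$z[upper.tri(C$z)])
  sd_theory <- 1 / sqrt(600 - 3) # 0.0409
  expect_lt(abs(sd_obs - sd_theory) / sd_theory, 0.10)
})

test_that("correlation matrix is invariant to per-node affine rescaling", {
  set.seed(3)
  m <- matrix(rnorm(8 * 100), 8, 100)
  m2 <- m * runif(8, 0.5, 3) + rnorm(8)
  expect_equal(correlation_matrix(subject_timeseries(m))$z,
               correlation_matrix(subject_timeseries(m2))$z,
               tolerance = 1e-10)
})

test_that("proportional threshold retains exactly round(d * N(N-1)/2) edges", {
  set.seed(4)
  ts <- subject_timeseries(matrix(rnorm(60 * 100), 60, 100))
  C <- correlation_matrix(ts)
  n_edges <- function(net) sum(net$weights[upper.tri(net$weights)] != 0)
  expect_equal(n_edges(proportional_threshold(C, 0.16)), 283) # round(283.2)
  expect_equal(n_edges(suppressWarnings(proportional_threshold(C, 1))),
               1770)
  # white noise has negative z among the top 32%; the warning is expected
  for (d in density_grid()) {
    expect_equal(n_edges(suppressWarnings(proportional_threshold(C, d))),
                 round(d * 1770))
  }
  expect_error(proportional_threshold(C, 0), "density")
  expect_error(proportional_threshold(C, 1.2), "density")
})

test_that("thresholding keeps retained weights and breaks ties determinately", {
  # equal weights at the cutoff: lexicographically smallest (i, j) retained
  z <- matrix(0, 4, 4)
  z[1, 2] <- z[2, 1] <- 0.9
  z[1, 3] <- z[3, 1] <- 0.5
  z[2, 4] <- z[4, 2] <- 0.5
  z[3, 4] <- z[4, 3] <- 0.2
  C <- as_connectivity_matrix(z)
  net <- proportional_threshold(C, 2 / 6)
  expect_equal(net$weights[1, 2], 0.9)
  expect_equal(net$weights[1, 3], 0.5) # (1,3) beats (2,4) on tie
  expect_equal(net$weights[2, 4], 0)
  expect_identical(net, proportional_threshold(C, 2 / 6))
})

test_that("density sweep is nested and consistent with single thresholds", {
  set.seed(5)
  ts <- subject_timeseries(matrix(rnorm(20 * 80), 20, 80))
  C <- correlation_matrix(ts)
  nets <- suppressWarnings(density_sweep(C, seq(0.1, 0.5, by = 0.1)))
  for (i in seq_len(length(nets) - 1)) {
    lo <- nets[[i]]$weights != 0
    hi <- nets[[i + 1]]$weights != 0
    expect_true(all(hi[lo])) # edge sets nested
  }
  single <- proportional_threshold(C, 0.16)
  expect_equal(density_sweep(C, 0.16)[[1]], single)
  expect_error(density_sweep(C, c(0.2, 0.1)), "increasing")
  # retained weights unchanged by thresholding
  w <- nets[[2]]$weights
  expect_equal(w[w != 0], C$z[w != 0])
})

test_that("bootstrap edge threshold calibrates to the nominal level on null data", {
  set.seed(6)
  n_sub <- 12
  cohort <- lapply(seq_len(n_sub), function(i) {
    z <- matrix(0, 30, 30)
    noise <- matrix(rnorm(30 * 30, sd = 0.05), 30, 30)
    z <- noise + t(noise)
    diag(z) <- 0
    as_connectivity_matrix(z, subject_id = paste0("s", i))
  })
  res <- bootstrap_edge_threshold(cohort, n_boot = 500, alpha = 0.05,
                                  seed = 9)
  expect_gt(res$implied_density, 0.01)
  expect_lt(res$implied_density, 0.15)
})

test_that("a common strong edge is always significant and runs reproduce", {
  set.seed(7)
  cohort <- lapply(1:6, function(i) {
    z <- matrix(rnorm(100, sd = 0.01), 10, 10)
    z <- (z + t(z)) / 2
    z[1, 2] <- z[2, 1] <- 1
    diag(z) <- 0
    as_connectivity_matrix(z)
  })
  r1 <- bootstrap_edge_threshold(cohort, n_boot = 200, alpha = 0.01, seed = 3)
  expect_true(r1$significant[1, 2])
  r2 <- bootstrap_edge_threshold(cohort, n_boot = 200, alpha = 0.01, seed = 3)
  expect_identical(r1, r2)
  # degenerate all-identical cohort rejected
  same <- replicate(4, as_connectivity_matrix(matrix(0, 5, 5)),
                    simplify = FALSE)
  expect_error(bootstrap_edge_threshold(same, n_boot = 100), "degenerate")
})

test_that("timeseries and connectivity matrices round-trip through TSV", {
  set.seed(8)
  ts <- subject_timeseries(matrix(rnorm(5 * 30), 5, 30), subject_id = "s1")
  dir <- withr::local_tempdir()
  f <- file.path(dir, "s1.tsv")
  write.table(ts$data, f, sep = "\t", row.names = FALSE, col.names = FALSE)
  ts2 <- read_timeseries_tsv(f)
  expect_equal(ts2$data, ts$data, tolerance = 1e-12)
  expect_equal(ts2$subject_id, "s1")
  C <- correlation_matrix(ts)
  fz <- file.path(dir, "s1_z.tsv")
  write_connectivity_tsv(C, fz)
  z2 <- as.matrix(read.table(fz, sep = "\t", header = TRUE))
  expect_equal(unname(z2), C$z, tolerance = 1e-12)
})
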