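# Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' Deterministically maps (master seed, stream index) to a new 32-bit seed so
#' that every subject, null replicate or bootstrap stream gets an independent,
#' reproducible RNG stream. Uses a Lehmer-style multiplicative step modulo the
#' Mersenne prime 2^31 - 1.
#'
#' @param master integer master seed.
#' @param index nonnegative integer stream index.
#' @return a positive integer seed below 2^31.
#' @keywords internal
derive_seed <- function(master, index) {
  m <- 2147483647 # 2^31 - 1
  x <- (abs(as.double(master)) %% m)
  # two multiplicative steps keep adjacent indices well separated
  x <- (x * 48271 + as.double(index) * 16807 + 1) %% m
  x <- (x * 69621 + 1) %% m
  as.integer(x %% (m - 1L)) + 1L
}

# round-half-away-from-zero (base round() is banker's rounding)
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

stop_if_not_square_symmetric <- function(m, what = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(what, " must be a square matrix", call. = FALSE)
  }
  if (max(abs(m - t(m))) > tol) {
    stop(what, " must be symmetric", call. = FALSE)
  }
  invisible(m)
}

# upper-triangle index pairs (i < j) in column-major order
upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}
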