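#' Matrix generators for the classical bipartite topologies
#'
#' These functions build the binary incidence matrices whose normalized mutual
#' information S has a closed-form counterpart (see the `s_*` family of
#' functions): regular ("uniform") and random fills, perfectly nested
#' matrices, modular (block-diagonal) matrices with isometric, rectangular or
#' increasing modules, and compound matrices whose modules are internally
#' nested.
#'
#' Modular generators attach the planted module membership of each row and
#' column as attributes `row_modules` and `col_modules`, which
#' [swap_experiment()] and [bipartite_modularity()] use as the reference
#' partition.
#'
#' @name generators
NULL

with_seed_ <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Uniform (regular) random matrix
#'
#' A square binary matrix in which every row and every column has exactly
#' `k = rho * n` interactions: the marginal distributions are flat on both
#' sides. The matrix is built from `k` cyclically shifted diagonals and then
#' shuffled by seeded degree-preserving checkerboard swaps; the arrangement
#' does not affect any entropy quantity (for a binary matrix H(X,Y) = log NM),
#' so the shuffle only varies the visual pattern.
#'
#' @param n Matrix side (number of species on each side).
#' @param rho Occupancy; `rho * n` must be a whole number in `1..n`.
#' @param seed Optional integer seed for the cosmetic shuffle.
#' @return An [interaction_matrix()] with all margins equal to `rho * n`.
#' @examples
#' margins(matrix_uniform_regular(10, 0.5))$kx
#' @export
matrix_uniform_regular <- function(n, rho, seed = NULL) {
  k <- rho * n
  if (abs(k - round(k)) > 1e-9) {
    stop(sprintf(
      "rho * n must be a whole number: feasible rho at n = %d are k/%d for k in 1..%d",
      n, n, n), call. = FALSE)
  }
  k <- as.integer(round(k))
  if (k < 1 || k > n) stop("rho * n must lie in 1..n", call. = FALSE)
  mat <- matrix(0L, n, n)
  for (s in seq_len(k) - 1L) {
    idx <- cbind(seq_len(n), ((seq_len(n) - 1L + s) %% n) + 1L)
    mat[idx] <- 1L
  }
  mat <- interaction_matrix(mat)
  if (!is.null(seed) && k < n) {
    mat <- with_seed_(seed, shuffle_swaps(mat, 2L * n * k))
  }
  mat
}

# apply up to n_attempts random checkerboard swaps (attempts, not successes)
shuffle_swaps <- function(mat, n_attempts) {
  for (i in seq_len(n_attempts)) {
    sw <- sample_checkerboard(mat, exhaustive_fallback = FALSE)
    if (!is.null(sw)) mat <- apply_swap(mat, sw)
  }
  mat
}

#' Random fill matrix
#'
#' Binary matrix with `round(rho * nx * ny)` ones placed uniformly at random
#' without replacement; only total occupancy is fixed, the marginal totals
#' vary freely. This is the Monte Carlo relaxation of
#' [matrix_uniform_regular()].
#'
#' @param nx,ny Matrix dimensions.
#' @param rho Target occupancy in `(0, 1]`.
#' @param seed Optional integer seed; the same seed reproduces the matrix.
#' @return An [interaction_matrix()].
#' @export
matrix_random_fill <- function(nx, ny, rho, seed = NULL) {
  if (rho <= 0 || rho > 1) stop("rho must lie in (0, 1]", call. = FALSE)
  n1 <- round_half_up(rho * nx * ny)
  if (n1 < 1) stop("rho too small: no cell would be occupied", call. = FALSE)
  cells <- with_seed_(seed, sample.int(nx * ny, n1))
  mat <- matrix(0L, nx, ny)
  mat[cells] <- 1L
  interaction_matrix(mat)
}

round_half_up <- function(x) floor(x + 0.5)

#' Fully packed nested matrix
#'
#' The square matrix occupied above the antidiagonal: row `i` (rows ordered by
#' decreasing degree) carries `n - i + 1` ones, left-packed, so the degree
#' sequence on each side is `n, n-1, ..., 1` and the total number of
#' interactions is `n(n+1)/2`. This is the maximally nested half-filled
#' matrix: every species' partner set is contained in that of every more
#' generalist species.
#'
#' @param n Matrix side, at least 2.
#' @return An [interaction_matrix()].
#' @examples
#' matrix_nested_packed(4)
#' @export
matrix_nested_packed <- function(n) {
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  mat <- matrix(0L, n, n)
  for (i in seq_len(n)) mat[i, seq_len(n - i + 1L)] <- 1L
  interaction_matrix(mat)
}

#' Perfectly nested matrix of arbitrary size and occupancy
#'
#' Builds a binary matrix whose rows, ordered by decreasing degree, are
#' left-packed with non-increasing lengths, so each row's partner set is a
#' subset of every larger row's set (perfect nestedness), with no empty rows
#' or columns. Row lengths follow the power-curve boundary
#' `len(i) = ceiling(ny * (1 - ((i-1)/nx)^gamma))` with `gamma` tuned by
#' bisection to reach the target occupancy; single-cell adjustments (applied
#' to seeded random rows, preserving the nested ordering) make the achieved
#' count exact.
#'
#' @param nx,ny Matrix dimensions.
#' @param rho Target occupancy. Feasible range runs from
#'   `(nx + ny - 1)/(nx * ny)` (one full row, all other rows singletons) to 1.
#' @param seed Optional integer seed for the boundary adjustment.
#' @return An [interaction_matrix()] whose occupied cell count equals
#'   `round(rho * nx * ny)`.
#' @export
matrix_nested_general <- function(nx, ny, rho, seed = NULL) {
  target <- round_half_up(rho * nx * ny)
  lo <- nx + ny - 1L
  if (target < lo || target > nx * ny) {
    stop(sprintf(
      "infeasible rho: a perfectly nested %d x %d matrix needs occupancy in [%.4g, 1]",
      nx, ny, lo / (nx * ny)), call. = FALSE)
  }
  profile_for <- function(gamma) {
    len <- ceiling(ny * (1 - ((seq_len(nx) - 1) / nx)^gamma))
    pmin(ny, pmax(1L, as.integer(len)))
  }
  g_lo <- 1e-6; g_hi <- 1e6
  for (iter in 1:200) {
    g <- sqrt(g_lo * g_hi)
    tot <- sum(profile_for(g))
    if (tot < target) g_lo <- g else g_hi <- g
    if (tot == target) break
  }
  len <- profile_for(sqrt(g_lo * g_hi))
  len <- with_seed_(seed, adjust_profile(len, ny, target))
  mat <- matrix(0L, nx, ny)
  for (i in seq_len(nx)) mat[i, seq_len(len[i])] <- 1L
  interaction_matrix(mat)
}

# add/remove single cells to hit the target total while keeping the profile
# non-increasing, within 1..ny, and the first row full (no empty columns)
adjust_profile <- function(len, ny, target) {
  len[1L] <- ny
  repeat {
    diff <- target - sum(len)
    if (diff == 0) break
    if (diff > 0) {
      ok <- which(len < c(ny, len[-length(len)]))
    } else {
      ok <- which(len > c(len[-1L], 1L) & seq_along(len) > 1L)
      if (length(ok) == 0) ok <- which(len > 1L & seq_along(len) > 1L)
    }
    i <- if (length(ok) == 1L) ok else sample(ok, 1L)
    len[i] <- len[i] + sign(diff)
  }
  stopifnot(all(diff(len) <= 0), all(len >= 1), len[1L] == ny)
  len
}

#' Modular (block-diagonal) matrices
#'
#' `matrix_modular_isometric(m, t)` builds the square block-diagonal matrix of
#' `m` fully occupied `t x t` modules (side `N = m t`, occupancy `1/m`);
#' `matrix_modular_rect(m, t, z)` generalizes to `t x z` modules
#' (`NX = m t`, `NY = m z`); `matrix_modular_increasing(m)` uses square
#' modules of increasing side `1, 2, ..., m` (side `N = m(m+1)/2`).
#'
#' @param m Number of modules.
#' @param t Module rows (side, for square modules).
#' @param z Module columns.
#' @return An [interaction_matrix()] with planted partition attributes
#'   `row_modules` and `col_modules`.
#' @examples
#' matrix_modular_isometric(3, 2)
#' @export
matrix_modular_isometric <- function(m, t) {
  matrix_modular_rect(m, t, t)
}

#' @rdname matrix_modular_isometric
#' @export
matrix_modular_rect <- function(m, t, z) {
  if (m < 1 || t < 1 || z < 1) stop("m, t, z must be >= 1", call. = FALSE)
  block_diagonal(rep(list(matrix(1L, t, z)), m))
}

#' @rdname matrix_modular_isometric
#' @export
matrix_modular_increasing <- function(m) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  block_diagonal(lapply(seq_len(m), function(t) matrix(1L, t, t)))
}

#' Compound matrix: nested modules on a modular skeleton
#'
#' Block-diagonal matrix of `m` modules, each the `t x t` fully packed nested
#' pattern of [matrix_nested_packed()]. Combines the two classical topologies:
#' modular at large scale, nested within modules.
#'
#' @param m Number of modules.
#' @param t Module side, at least 2.
#' @return An [interaction_matrix()] with planted partition attributes.
#' @export
matrix_compound_nested <- function(m, t) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (t < 2) stop("t must be >= 2", call. = FALSE)
  block <- unclass(matrix_nested_packed(t))
  block_diagonal(rep(list(block), m))
}

block_diagonal <- function(blocks) {
  nr <- vapply(blocks, nrow, integer(1))
  nc <- vapply(blocks, ncol, integer(1))
  mat <- matrix(0L, sum(nr), sum(nc))
  r0 <- cumsum(c(0L, nr))
  c0 <- cumsum(c(0L, nc))
  for (b in seq_along(blocks)) {
    mat[r0[b] + seq_len(nr[b]), c0[b] + seq_len(nc[b])] <- blocks[[b]]
  }
  mat <- interaction_matrix(mat)
  attr(mat, "row_modules") <- rep(seq_along(blocks), nr)
  attr(mat, "col_modules") <- rep(seq_along(blocks), nc)
  mat
}
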