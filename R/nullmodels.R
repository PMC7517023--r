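#' Degree-preserving checkerboard swap
#'
#' A checkerboard is a 2 x 2 submatrix of the form `[[1,0],[0,1]]` or
#' `[[0,1],[1,0]]` on some pair of rows and columns; swapping it for its
#' mirror changes exactly four cells while preserving every row and column
#' sum. Repeated swaps are the standard degree-preserving null model for
#' binary interaction matrices.
#'
#' Candidates are drawn by rejection: a pair of rows and a pair of columns is
#' sampled uniformly and retried if it is not a checkerboard, with a cap of
#' `10 * nrow * ncol` attempts before falling back to exhaustive enumeration
#' (so rejection sampling is not exactly uniform over checkerboards; the
#' fallback draw is).
#'
#' @param mat A binary [interaction_matrix()].
#' @param seed Optional integer seed.
#' @return A new matrix differing from `mat` in exactly 4 cells, with
#'   identical margins. Errors if the matrix contains no checkerboard
#'   (swap-rigid).
#' @examples
#' checkerboard_swap(diag(2), seed = 1)
#' @export
checkerboard_swap <- function(mat, seed = NULL) {
  mat <- as_interaction_matrix(mat)
  if (!is_binary(mat)) {
    stop("checkerboard swaps are defined for binary matrices", call. = FALSE)
  }
  with_seed_(seed, {
    sw <- sample_checkerboard(mat)
    apply_swap(mat, sw)
  })
}

# sample rows (i1,i2) and cols (j1,j2) forming a checkerboard; NULL if the
# rejection cap is hit and exhaustive_fallback is FALSE
sample_checkerboard <- function(mat, exhaustive_fallback = TRUE) {
  nr <- nrow(mat); nc <- ncol(mat)
  if (nr >= 2 && nc >= 2) {
    for (a in seq_len(10L * nr * nc)) {
      i <- sample.int(nr, 2L)
      j <- sample.int(nc, 2L)
      sub <- mat[i, j]
      if (is_checkerboard(sub)) return(list(i = i, j = j))
    }
  }
  if (!exhaustive_fallback) return(NULL)
  cand <- enumerate_checkerboards(mat)
  if (length(cand) == 0) {
    stop("matrix is swap-rigid: it contains no 2 x 2 checkerboard",
         call. = FALSE)
  }
  cand[[sample.int(length(cand), 1L)]]
}

is_checkerboard <- function(sub) {
  (sub[1, 1] == 1 && sub[2, 2] == 1 && sub[1, 2] == 0 && sub[2, 1] == 0) ||
    (sub[1, 1] == 0 && sub[2, 2] == 0 && sub[1, 2] == 1 && sub[2, 1] == 1)
}

enumerate_checkerboards <- function(mat) {
  out <- list()
  nr <- nrow(mat); nc <- ncol(mat)
  for (i1 in seq_len(nr - 1L)) for (i2 in (i1 + 1L):nr) {
    for (j1 in seq_len(nc - 1L)) for (j2 in (j1 + 1L):nc) {
      if (is_checkerboard(mat[c(i1, i2), c(j1, j2)])) {
        out[[length(out) + 1L]] <- list(i = c(i1, i2), j = c(j1, j2))
      }
    }
  }
  out
}

apply_swap <- function(mat, sw) {
  mat[sw$i, sw$j] <- 1L - mat[sw$i, sw$j]
  mat
}

#' Nestedness by overlap and decreasing fill (NODF)
#'
#' For every pair of rows and every pair of columns: if the two marginal
#' totals are equal (or the smaller is zero) the pair contributes 0; otherwise
#' it contributes `100 * (shared interactions) / (smaller marginal total)`.
#' NODF is the mean contribution over all row pairs and column pairs, a value
#' in `[0, 100]`; a fully packed nested matrix with all-distinct margins
#' scores 100, a diagonal matrix (all margins equal) scores 0. This pairwise
#' form does not depend on row or column order.
#'
#' @param mat A binary [interaction_matrix()] with at least 2 rows and 2
#'   columns.
#' @return NODF, in `[0, 100]`.
#' @examples
#' nodf(matrix_nested_packed(5)) # 100
#' @export
nodf <- function(mat) {
  mat <- as_interaction_matrix(mat)
  if (!is_binary(mat)) stop("NODF is defined for binary matrices", call. = FALSE)
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    stop("NODF needs at least 2 rows and 2 columns", call. = FALSE)
  }
  m <- unclass(mat)
  (nodf_axis_sum(m) + nodf_axis_sum(t(m))) /
    (choose(nrow(m), 2) + choose(ncol(m), 2))
}

# sum of pairwise contributions over rows of m
nodf_axis_sum <- function(m) {
  deg <- rowSums(m)
  overlap <- m %*% t(m)
  tot <- 0
  n <- nrow(m)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    lo <- min(deg[i], deg[j])
    if (deg[i] != deg[j] && lo > 0) {
      tot <- tot + 100 * overlap[i, j] / lo
    }
  }
  tot
}

#' Bipartite (Barber-style) modularity for a known partition
#'
#' For a partition assigning every row and every column to a module,
#' \deqn{Q = \sum_k (e_{kk} - a_k b_k)} where \eqn{e_{kk}} is the fraction of
#' all interactions that fall inside module `k`, and \eqn{a_k}, \eqn{b_k} are
#' the fractions of interactions involving, respectively, the rows and the
#' columns of module `k`. A block-diagonal matrix of `m` equal full modules
#' scores `1 - 1/m` with its planted partition; a matrix whose cells are
#' proportional to the products of the margins scores 0.
#'
#' @param mat An [interaction_matrix()].
#' @param row_modules,col_modules Module labels for each row / column.
#'   Default: the planted partition attributes set by the modular generators.
#' @return Modularity Q, in `[-1, 1]`.
#' @examples
#' bipartite_modularity(matrix_modular_isometric(3, 4)) # 2/3
#' @export
bipartite_modularity <- function(mat, row_modules = NULL, col_modules = NULL) {
  mat <- as_interaction_matrix(mat)
  if (is.null(row_modules)) row_modules <- attr(mat, "row_modules")
  if (is.null(col_modules)) col_modules <- attr(mat, "col_modules")
  if (is.null(row_modules) || is.null(col_modules)) {
    stop("no partition: supply row_modules and col_modules (or use a modular generator)",
         call. = FALSE)
  }
  if (length(row_modules) != nrow(mat) || length(col_modules) != ncol(mat) ||
      anyNA(row_modules) || anyNA(col_modules)) {
    stop("partition must assign a module to every row and every column",
         call. = FALSE)
  }
  nm <- sum(mat)
  mods <- union(unique(row_modules), unique(col_modules))
  q <- 0
  for (k in mods) {
    rk <- row_modules == k
    ck <- col_modules == k
    ekk <- sum(mat[rk, ck, drop = FALSE]) / nm
    ak <- sum(mat[rk, , drop = FALSE]) / nm
    bk <- sum(mat[, ck, drop = FALSE]) / nm
    q <- q + ekk - ak * bk
  }
  q
}

#' Heuristic module search by bipartite label propagation
#'
#' A simple seeded label-propagation heuristic for matrices without a known
#' partition: labels start distinct and each row (then column) repeatedly
#' adopts the label carrying most of its interactions, until no label changes.
#' This is a quick heuristic, not an optimizer: use the planted partition when
#' one exists.
#'
#' @param mat A binary [interaction_matrix()].
#' @param seed Optional integer seed (update order is shuffled).
#' @param max_iter Maximum sweeps.
#' @return A list with `row_modules`, `col_modules` (integer labels) and the
#'   achieved `modularity`.
#' @export
detect_modules <- function(mat, seed = NULL, max_iter = 100L) {
  mat <- as_interaction_matrix(mat)
  with_seed_(seed, {
    rl <- seq_len(nrow(mat))
    cl <- nrow(mat) + seq_len(ncol(mat))
    for (it in seq_len(max_iter)) {
      changed <- FALSE
      for (i in sample(seq_len(nrow(mat)))) {
        w <- tapply(mat[i, ], cl, sum)
        best <- as.integer(names(w)[which.max(w)])
        if (max(w) > 0 && best != rl[i]) { rl[i] <- best; changed <- TRUE }
      }
      for (j in sample(seq_len(ncol(mat)))) {
        w <- tapply(mat[, j], rl, sum)
        best <- as.integer(names(w)[which.max(w)])
        if (max(w) > 0 && best != cl[j]) { cl[j] <- best; changed <- TRUE }
      }
      if (!changed) break
    }
    labs <- match(c(rl, cl), unique(c(rl, cl)))
    rl <- labs[seq_len(nrow(mat))]
    cl <- labs[nrow(mat) + seq_len(ncol(mat))]
    list(row_modules = rl, col_modules = cl,
         modularity = bipartite_modularity(mat, rl, cl))
  })
}

#' Sequential swap experiment: is S sensitive to topology?
#'
#' Applies `n_swaps` sequential checkerboard swaps to a matrix and records,
#' at step 0 and every `record_every` accepted swaps (plus the final step),
#' the normalized mutual information S, NODF nestedness, and the modularity of
#' the initial (planted) partition. Swaps preserve all margins, so S is
#' mathematically constant along the trajectory while the topological metrics
#' decay — the demonstration that mutual information measures specialization,
#' not topology.
#'
#' @param mat A binary [interaction_matrix()], e.g.
#'   `matrix_compound_nested(3, 5)`.
#' @param n_swaps Number of accepted swaps.
#' @param record_every Record interval in accepted swaps.
#' @param seed Optional integer seed; the trajectory is reproducible.
#' @param row_modules,col_modules Partition used for the modularity track;
#'   defaults to the matrix's planted partition. If none is available,
#'   modularity is reported as `NA`.
#' @return A tibble of class `swap_trajectory` with columns `step`, `s`,
#'   `nodf`, `modularity`.
#' @examples
#' swap_experiment(matrix_compound_nested(3, 5), n_swaps = 20, seed = 1)
#' @export
swap_experiment <- function(mat, n_swaps, record_every = 1L, seed = NULL,
                            row_modules = NULL, col_modules = NULL) {
  mat <- as_interaction_matrix(mat)
  if (is.null(row_modules)) row_modules <- attr(mat, "row_modules")
  if (is.null(col_modules)) col_modules <- attr(mat, "col_modules")
  measure <- function(m, step) {
    tibble::tibble(
      step = step,
      s = entropy_decomposition(m)$s,
      nodf = nodf(m),
      modularity = if (is.null(row_modules)) NA_real_ else
        bipartite_modularity(m, row_modules, col_modules)
    )
  }
  rows <- list(measure(mat, 0L))
  if (n_swaps > 0) {
    rows <- c(rows, with_seed_(seed, {
      acc <- list()
      for (step in seq_len(n_swaps)) {
        mat <- apply_swap(mat, sample_checkerboard(mat))
        if (step %% record_every == 0L || step == n_swaps) {
          acc[[length(acc) + 1L]] <- measure(mat, step)
        }
      }
      acc
    }))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("swap_trajectory", class(out))
  out
}

#' Plot a swap trajectory
#'
#' Shows S, NODF (rescaled to `[0, 1]`) and modularity against the number of
#' accepted swaps: the topology metrics decay while S stays flat.
#'
#' @param object A `swap_trajectory` from [swap_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot swap_trajectory
#' @export
autoplot.swap_trajectory <- function(object, ...) {
  df <- tibble::tibble(
    step = rep(object$step, 3),
    metric = rep(c("S", "NODF / 100", "modularity Q"), each = nrow(object)),
    value = c(object$s, object$nodf / 100, object$modularity)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "accepted swaps", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
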