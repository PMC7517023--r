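#' Shannon entropy of a probability vector
#'
#' \eqn{H = -\sum_i p_i \log p_i}, with the convention \eqn{0 \log 0 = 0}.
#' The probabilities must be non-negative and sum to one (relative tolerance
#' 1e-9).
#'
#' @param p Numeric vector of probabilities.
#' @param base Logarithm base; `exp(1)` (nats, default), `2` (bits) or `10`.
#' @return The entropy, a value in `[0, log(length(p))]`.
#' @examples
#' shannon_entropy(rep(1 / 4, 4)) # log(4)
#' shannon_entropy(c(0.5, 0.25, 0.25), base = 2) # 1.5 bits
#' @export
shannon_entropy <- function(p, base = exp(1)) {
  if (any(p < 0)) stop("probabilities must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9 * max(1, sum(p))) {
    stop(sprintf("probabilities must sum to 1 (got %.12g)", sum(p)),
         call. = FALSE)
  }
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

# entropy of an unnormalized non-negative weight vector
entropy_of_counts <- function(k, base = exp(1)) {
  k <- k[k > 0]
  p <- k / sum(k)
  -sum(p * log(p, base = base))
}

#' Entropy decomposition and normalized mutual information of a web
#'
#' Computes the full Shannon decomposition of a bipartite interaction matrix:
#' the marginal entropies H(X) and H(Y) of the two species sets, the joint
#' entropy H(X,Y) of the interaction distribution, the mutual information
#' I(X;Y) = H(X) + H(Y) - H(X,Y), its normalization S = I(X;Y) / H(X,Y), and
#' the specialization index H2' (see [h2prime()]).
#'
#' Probabilities are cell values divided by the interaction total NM, so
#' weighted matrices are handled by the same formulas. For a binary matrix
#' every occupied cell has probability 1/NM and H(X,Y) = log(NM) exactly.
#' S and H2' do not depend on the logarithm base; the raw entropies are
#' reported in the base requested.
#'
#' S ranges from 0 (no reciprocal specialization: generalists only, or a fully
#' occupied matrix) to 1 (perfect one-to-one matching, the diagonal matrix).
#'
#' @param mat An [interaction_matrix()] or coercible matrix.
#' @param base Logarithm base for the reported entropies; default natural log
#'   (nats).
#' @return An object of class `entropy_decomposition`: a list with elements
#'   `hx`, `hy`, `hxy`, `mi`, `s`, `h2prime`, `nm`, `rho`, `base`.
#' @examples
#' entropy_decomposition(matrix_modular_isometric(3, 40))$s # about 0.1296
#' @export
entropy_decomposition <- function(mat, base = exp(1)) {
  mat <- as_interaction_matrix(mat)
  mar <- margins(mat)
  hxy <- entropy_of_counts(as.vector(mat), base = base)
  if (hxy == 0) {
    stop("S is undefined: a single occupied cell gives H(X,Y) = 0",
         call. = FALSE)
  }
  hx <- entropy_of_counts(mar$kx, base = base)
  hy <- entropy_of_counts(mar$ky, base = base)
  mi <- hx + hy - hxy
  structure(
    list(hx = hx, hy = hy, hxy = hxy, mi = mi, s = mi / hxy,
         h2prime = h2prime(mat), nm = mar$nm, rho = mar$rho, base = base),
    class = "entropy_decomposition"
  )
}

#' @export
print.entropy_decomposition <- function(x, digits = 6, ...) {
  unit <- if (isTRUE(all.equal(x$base, 2))) "bits" else
    if (isTRUE(all.equal(x$base, exp(1)))) "nats" else
      sprintf("log base %g", x$base)
  cat(sprintf("<entropy_decomposition (%s)>\n", unit))
  print(glance.entropy_decomposition(x), digits = digits)
  invisible(x)
}

#' Tidy an entropy decomposition
#'
#' @param x An `entropy_decomposition` object.
#' @param ... Unused.
#' @return `tidy()` returns a two-column tibble of metric names and values;
#'   `glance()` a one-row tibble with columns `hx`, `hy`, `hxy`, `mi`, `s`,
#'   `h2prime`, `nm`, `rho`.
#' @method tidy entropy_decomposition
#' @export
tidy.entropy_decomposition <- function(x, ...) {
  tibble::tibble(
    metric = c("H(X)", "H(Y)", "H(X,Y)", "I(X;Y)", "S", "H2'", "NM", "rho"),
    value = c(x$hx, x$hy, x$hxy, x$mi, x$s, x$h2prime, x$nm, x$rho)
  )
}

#' @rdname tidy.entropy_decomposition
#' @method glance entropy_decomposition
#' @export
glance.entropy_decomposition <- function(x, ...) {
  tibble::tibble(hx = x$hx, hy = x$hy, hxy = x$hxy, mi = x$mi, s = x$s,
                 h2prime = x$h2prime, nm = x$nm, rho = x$rho)
}

#' Specialization index H2'
#'
#' H2' rescales the mutual information of a web by its attainable range given
#' the observed marginal totals:
#' \deqn{H2' = \frac{H(X,Y)_{max} - H(X,Y)}{H(X,Y)_{max} - H(X,Y)_{min}}}
#' with \eqn{H(X,Y)_{max} = H(X) + H(Y)} (independent sets: each cell
#' proportional to the product of its marginals). \eqn{H(X,Y)_{min}} is the
#' smallest joint entropy over tables with the observed margins; no closed
#' form exists, so it is approximated by a greedy packing heuristic that
#' repeatedly places the largest feasible count in the cell whose row and
#' column have the largest remaining totals. The heuristic gives an upper
#' bound on the maximal mutual information, hence `h2prime` is a lower bound
#' estimate, exact in the common cases (see the package vignette); the result
#' is clamped to `[0, 1]`.
#'
#' @inheritParams entropy_decomposition
#' @return A value in `[0, 1]`: 0 for perfectly proportional (unspecialized)
#'   interaction, 1 for maximal reciprocal specialization.
#' @examples
#' h2prime(matrix(c(2, 0, 0, 2), 2)) # 1: perfect reciprocal specialization
#' h2prime(matrix(1, 3, 3)) # 0: independence
#' @export
h2prime <- function(mat) {
  mat <- as_interaction_matrix(mat)
  if (nrow(mat) == 1 && ncol(mat) == 1) {
    stop("H2' is undefined for a 1 x 1 matrix: the margins admit one table",
         call. = FALSE)
  }
  mar <- margins(mat)
  hx <- entropy_of_counts(mar$kx)
  hy <- entropy_of_counts(mar$ky)
  hxy <- entropy_of_counts(as.vector(mat))
  hxy_max <- hx + hy
  hxy_min <- entropy_of_counts(min_entropy_table(mar$kx, mar$ky))
  if (hxy_max - hxy_min < .Machine$double.eps^0.5) {
    # margins force (near) independence; no specialization is expressible
    return(0)
  }
  min(1, max(0, (hxy_max - hxy) / (hxy_max - hxy_min)))
}

# Greedy low-entropy table with given margins: repeatedly fill the cell at the
# (largest remaining row total, largest remaining column total) pair with the
# maximum allowed count. Ties broken by first index. Returns cell counts.
min_entropy_table <- function(kx, ky) {
  kx <- as.numeric(kx)
  ky <- as.numeric(ky)
  out <- numeric(0)
  while (sum(kx) > 0) {
    i <- which.max(kx)
    j <- which.max(ky)
    a <- min(kx[i], ky[j])
    out <- c(out, a)
    kx[i] <- kx[i] - a
    ky[j] <- ky[j] - a
  }
  out
}
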