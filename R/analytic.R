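#' Log hyperfactorial functions
#'
#' `log_hyperfactorial(n)` is \eqn{\log Hyp(n) = \sum_{i=1}^{n} i \log i}, the
#' logarithm of the hyperfactorial \eqn{1^1 2^2 \cdots n^n};
#' `log_hyperfactorial_sq(n)` is the squared-index analogue
#' \eqn{\sum_{i=1}^{n} i^2 \log i}. Both are computed directly in log space —
#' the hyperfactorial itself overflows long before the sizes of interest.
#' They are the combinatorial kernels of the closed forms for nested and
#' increasing-module matrices.
#'
#' @param n Integer, at least 1.
#' @return The log-space sum, in nats.
#' @examples
#' log_hyperfactorial(3) # log(108)
#' @export
log_hyperfactorial <- function(n) {
  n <- check_count(n, 1, "n")
  i <- seq_len(n)
  sum(i * log(i))
}

#' @rdname log_hyperfactorial
#' @export
log_hyperfactorial_sq <- function(n) {
  n <- check_count(n, 1, "n")
  i <- seq_len(n)
  sum(i^2 * log(i))
}

check_count <- function(x, min, name) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("%s must be a whole number >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

analytic_result <- function(family, s, rho, nm = NA_real_, hx = NA_real_,
                            hxy = NA_real_) {
  tibble::tibble(family = family, s = s, rho = rho, nm = nm, hx = hx,
                 hxy = hxy)
}

#' Closed-form S for uniform (flat-margin) matrices
#'
#' For a binary matrix with flat marginal distributions on both sides and
#' occupancy `rho`, \deqn{S = \frac{\log(1/\rho)}{\log(\rho N_X N_Y)}.} Only
#' the product `nx * ny` matters: an 80 x 20 matrix has the same S as a
#' 40 x 40 matrix at equal occupancy. Vectorized over `rho`.
#'
#' @param nx,ny Matrix dimensions.
#' @param rho Occupancy in `(0, 1]`, with `rho * nx * ny > 1`.
#' @return A tibble with columns `family`, `s`, `rho`, `nm`, `hx`, `hxy`
#'   (one row per value of `rho`).
#' @examples
#' s_uniform(10, 10, 0.5)$s # log(2) / log(50)
#' @export
s_uniform <- function(nx, ny, rho) {
  if (any(rho <= 0 | rho > 1)) stop("rho must lie in (0, 1]", call. = FALSE)
  nm <- rho * nx * ny
  if (any(nm <= 1)) {
    stop("rho * nx * ny must exceed 1 (S is undefined at a single interaction)",
         call. = FALSE)
  }
  analytic_result("uniform", log(1 / rho) / log(nm), rho, nm = nm,
                  hxy = log(nm))
}

#' Closed-form S for the fully packed nested matrix
#'
#' For the half-occupied maximally nested square matrix of side `n` (degrees
#' `1..n` on each side, `NM = n(n+1)/2`):
#' \deqn{S = \frac{2\left(\log NM - \log Hyp(n)/NM\right) - \log NM}{\log NM}.}
#'
#' @param n Matrix side, at least 2.
#' @inherit s_uniform return
#' @examples
#' s_nested_packed(20)$s # about 0.0567
#' @export
s_nested_packed <- function(n) {
  n <- check_count(n, 2, "n")
  nm <- n * (n + 1) / 2
  hx <- log(nm) - log_hyperfactorial(n) / nm
  analytic_result("nested_packed", (2 * hx - log(nm)) / log(nm),
                  rho = nm / n^2, nm = nm, hx = hx, hxy = log(nm))
}

#' Closed-form S for isometric modular matrices
#'
#' For a square matrix of side `n` made of `m = n / t` fully occupied `t x t`
#' modules, \deqn{S = \frac{\log n - \log t}{\log n + \log t},} and the
#' occupancy is `1/m` (see [occupancy_modular()]). The single-module limit
#' `t = n` is the full matrix (S = 0); `t = 1` is the diagonal matrix (S = 1).
#'
#' @param n Matrix side.
#' @param t Module side; must divide `n`.
#' @inherit s_uniform return
#' @examples
#' s_modular_isometric(120, 40)$s # log(3) / log(4800), about 0.1296
#' @export
s_modular_isometric <- function(n, t) {
  n <- check_count(n, 1, "n")
  t <- check_count(t, 1, "t")
  if (n %% t != 0) stop("t must divide n", call. = FALSE)
  if (n == 1) {
    stop("S is undefined for the 1 x 1 matrix (a single interaction)",
         call. = FALSE)
  }
  m <- n / t
  analytic_result("modular_isometric",
                  (log(n) - log(t)) / (log(n) + log(t)),
                  rho = 1 / m, nm = n * t, hx = log(n), hxy = log(n * t))
}

#' @rdname s_modular_isometric
#' @param m Number of modules.
#' @export
occupancy_modular <- function(m) {
  1 / check_count(m, 1, "m")
}

#' Do two isometric modular matrices share the same S?
#'
#' Matrices of sides `n1`, `n2` with module sides `t1`, `t2` have identical
#' normalized mutual information exactly when `log(n1)/log(t1) =
#' log(n2)/log(t2)`, i.e. when module side and matrix side stand in the same
#' power relationship (`log_t n` equal). Diagonal matrices (`t = 1`, S = 1)
#' form their own equivalence class.
#'
#' @param n1,t1,n2,t2 Sides of the two matrices and their modules (`t` must
#'   divide `n`).
#' @param tol Relative tolerance on the log ratio.
#' @return `TRUE` or `FALSE`.
#' @examples
#' equal_s_condition(9, 3, 64, 8) # TRUE: log_3 9 == log_8 64 == 2
#' @export
equal_s_condition <- function(n1, t1, n2, t2, tol = 1e-9) {
  for (p in list(c(n1, t1), c(n2, t2))) {
    if (p[1] %% p[2] != 0) stop("t must divide n", call. = FALSE)
  }
  if (t1 == 1 || t2 == 1) return(t1 == 1 && t2 == 1)
  r1 <- log(n1) / log(t1)
  r2 <- log(n2) / log(t2)
  abs(r1 - r2) <= tol * max(abs(r1), abs(r2))
}

#' Closed-form S for rectangular modular matrices
#'
#' For `m` fully occupied `t x z` modules on the diagonal of an
#' `(m t) x (m z)` matrix, \deqn{S = \frac{\log m}{\log(m t z)}.} Reduces to
#' the isometric form when `t = z`.
#'
#' @param m Number of modules.
#' @param t,z Module rows and columns.
#' @inherit s_uniform return
#' @examples
#' s_modular_rect(4, 2, 3)$s # log(4) / log(24)
#' @export
s_modular_rect <- function(m, t, z) {
  m <- check_count(m, 1, "m")
  t <- check_count(t, 1, "t")
  z <- check_count(z, 1, "z")
  if (m * t * z <= 1) {
    stop("m * t * z must exceed 1 (S is undefined at a single interaction)",
         call. = FALSE)
  }
  analytic_result("modular_rect", log(m) / log(m * t * z), rho = 1 / m,
                  nm = m * t * z, hxy = log(m * t * z))
}

#' Closed-form S for modules of increasing size
#'
#' For square modules of sides `1, 2, ..., m` on the diagonal: side
#' `N = m(m+1)/2`, interactions `NM = m(m+1)(2m+1)/6`, occupancy
#' `rho = 2(2m+1) / (3m(m+1))`, marginal entropy
#' `H(X) = log NM - log Hyp2(m) / NM` (with `Hyp2` the squared-index
#' hyperfactorial), and \deqn{S = \frac{2 H(X) - \log NM}{\log NM}.}
#'
#' @param m Number of modules, at least 2.
#' @inherit s_uniform return
#' @examples
#' s_increasing(3)$s # about 0.3147
#' @export
s_increasing <- function(m) {
  m <- check_count(m, 2, "m")
  nm <- m * (m + 1) * (2 * m + 1) / 6
  n <- m * (m + 1) / 2
  hx <- log(nm) - log_hyperfactorial_sq(m) / nm
  analytic_result("modular_increasing", (2 * hx - log(nm)) / log(nm),
                  rho = nm / n^2, nm = nm, hx = hx, hxy = log(nm))
}

#' Closed-form S for compound (nested-modular) matrices
#'
#' For `m` internally nested `t x t` modules, each carrying
#' `Km = t(t+1)/2` interactions (`NM = m Km`):
#' \deqn{H(X) = \log NM - \frac{m}{NM} \log Hyp(t), \quad
#'       S = \frac{2 H(X) - \log NM}{\log NM}.}
#' With `m = 1` this is the packed nested matrix.
#'
#' @param m Number of modules.
#' @param t Module side, at least 2.
#' @inherit s_uniform return
#' @examples
#' s_compound(4, 5)$s # about 0.405
#' @export
s_compound <- function(m, t) {
  m <- check_count(m, 1, "m")
  t <- check_count(t, 2, "t")
  km <- t * (t + 1) / 2
  nm <- m * km
  hx <- log(nm) - (m / nm) * log_hyperfactorial(t)
  analytic_result("compound_nested", (2 * hx - log(nm)) / log(nm),
                  rho = nm / (m * t)^2, nm = nm, hx = hx, hxy = log(nm))
}
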