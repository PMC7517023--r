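# Independent oracles used across the test files. These recompute quantities
# from first principles (explicit loops, exhaustive enumeration) and must stay
# independent of the package internals they check.

# entropy decomposition by direct summation over cells and margins
brute_decompose <- function(mat, base = exp(1)) {
  mat <- unclass(mat)
  nm <- sum(mat)
  h <- function(w) {
    tot <- 0
    for (v in w) if (v > 0) tot <- tot - (v / nm) * log(v / nm, base = base)
    tot
  }
  hx <- h(rowSums(mat))
  hy <- h(colSums(mat))
  hxy <- h(as.vector(mat))
  list(hx = hx, hy = hy, hxy = hxy, mi = hx + hy - hxy,
       s = (hx + hy - hxy) / hxy)
}

# all non-negative integer tables with the given margins (tiny cases only)
enumerate_tables <- function(kx, ky) {
  out <- list()
  fill <- function(tab, row, kx_left, ky_left) {
    if (row > length(kx)) {
      if (all(ky_left == 0)) out[[length(out) + 1L]] <<- tab
      return(invisible())
    }
    cells <- expand_row(kx_left[row], ky_left)
    for (r in cells) {
      tab2 <- tab
      tab2[row, ] <- r
      fill(tab2, row + 1L, kx_left, ky_left - r)
    }
  }
  expand_row <- function(total, caps) {
    if (length(caps) == 1) {
      if (total <= caps) return(list(total)) else return(list())
    }
    res <- list()
    for (a in 0:min(total, caps[1])) {
      for (rest in expand_row(total - a, caps[-1])) {
        res[[length(res) + 1L]] <- c(a, rest)
      }
    }
    res
  }
  fill(matrix(0L, length(kx), length(ky)), 1L, kx, ky)
  out
}

# exact H2' by exhaustive search over all margin-preserving tables
brute_h2prime <- function(mat) {
  mat <- unclass(mat)
  nm <- sum(mat)
  ent <- function(v) { p <- v[v > 0] / nm; -sum(p * log(p)) }
  hx <- ent(rowSums(mat)); hy <- ent(colSums(mat))
  hxy_min <- min(vapply(enumerate_tables(rowSums(mat), colSums(mat)),
                        function(tb) ent(as.vector(tb)), numeric(1)))
  if (hx + hy - hxy_min < 1e-12) return(0)
  (hx + hy - ent(as.vector(mat))) / (hx + hy - hxy_min)
}

# random non-negative integer matrix guaranteed non-degenerate
random_count_matrix <- function(nx, ny, weighted = FALSE) {
  repeat {
    vals <- if (weighted) rpois(nx * ny, 0.8) else rbinom(nx * ny, 1, 0.4)
    if (sum(vals > 0) >= 2) break
  }
  matrix(vals, nx, ny)
}
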