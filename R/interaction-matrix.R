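#' Construct an interaction (incidence) matrix
#'
#' An interaction matrix records interactions between two sets of species in a
#' bipartite network: rows are the species of one set (X, e.g. plants), columns
#' the species of the other set (Y, e.g. pollinators). Entries are non-negative
#' integers (or weights): `a[i, j] > 0` means species `i` of X interacts with
#' species `j` of Y.
#'
#' @param x A numeric matrix (or object coercible to one) with non-negative
#'   entries and at least one positive entry.
#' @param row_labels,col_labels Optional character vectors of species labels.
#'   Defaults to existing dimnames, or `X1..`, `Y1..` when absent.
#'
#' @return A numeric matrix of class `interaction_matrix` with unique row and
#'   column labels.
#' @examples
#' interaction_matrix(diag(2))
#' @export
interaction_matrix <- function(x, row_labels = NULL, col_labels = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) {
    stop("interaction matrix entries must be numeric", call. = FALSE)
  }
  if (anyNA(x)) {
    stop("interaction matrix contains missing values", call. = FALSE)
  }
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative entry at row %d, column %d", bad[1L], bad[2L]),
         call. = FALSE)
  }
  if (all(x == 0)) {
    stop("degenerate input: all entries are zero", call. = FALSE)
  }
  if (is.null(row_labels)) row_labels <- rownames(x)
  if (is.null(col_labels)) col_labels <- colnames(x)
  if (is.null(row_labels)) row_labels <- paste0("X", seq_len(nrow(x)))
  if (is.null(col_labels)) col_labels <- paste0("Y", seq_len(ncol(x)))
  if (anyDuplicated(row_labels) || anyDuplicated(col_labels)) {
    stop("row and column labels must be unique within each axis",
         call. = FALSE)
  }
  dimnames(x) <- list(row_labels, col_labels)
  class(x) <- c("interaction_matrix", class(unclass(x)))
  x
}

#' @rdname interaction_matrix
#' @export
as_interaction_matrix <- function(x) {
  if (inherits(x, "interaction_matrix")) x else interaction_matrix(x)
}

is_binary <- function(x) all(x == 0 | x == 1)

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("<interaction_matrix: %d x %d, %s, %d interactions>\n",
              nrow(x), ncol(x),
              if (is_binary(x)) "binary" else "weighted",
              sum(x > 0)))
  print(unclass(x), ...)
  invisible(x)
}

#' Marginal totals and occupancy of an interaction matrix
#'
#' Species degrees are the marginal totals of the matrix: `kx[i]` is the row
#' sum (number of interactions of species `i` in set X) and `ky[j]` the column
#' sum. `nm` is the grand total of interactions and `rho` the occupancy
#' (connectance): the fraction of cells that are occupied. For weighted
#' matrices `nm` is the weighted total while `rho` still counts nonzero cells.
#'
#' @param mat An [interaction_matrix()] or coercible matrix.
#' @return A list of class `margin_summary` with elements `kx`, `ky`, `nm`,
#'   `rho`.
#' @examples
#' margins(matrix_nested_packed(4))
#' @export
margins <- function(mat) {
  mat <- as_interaction_matrix(mat)
  kx <- rowSums(mat)
  ky <- colSums(mat)
  structure(
    list(kx = kx, ky = ky, nm = sum(mat),
         rho = sum(mat > 0) / length(mat)),
    class = "margin_summary"
  )
}

#' @export
print.margin_summary <- function(x, ...) {
  cat(sprintf("<margin_summary: NM = %g, rho = %.4g>\n", x$nm, x$rho))
  cat("kx:", x$kx, "\n")
  cat("ky:", x$ky, "\n")
  invisible(x)
}

#' @method tidy margin_summary
#' @export
tidy.margin_summary <- function(x, ...) {
  tibble::tibble(
    set = rep(c("X", "Y"), c(length(x$kx), length(x$ky))),
    species = c(names(x$kx), names(x$ky)),
    degree = unname(c(x$kx, x$ky))
  )
}

#' @method glance margin_summary
#' @export
glance.margin_summary <- function(x, ...) {
  tibble::tibble(nx = length(x$kx), ny = length(x$ky),
                 nm = x$nm, rho = x$rho)
}

#' Incidence plot of an interaction matrix
#'
#' Draws the matrix as a tile grid, rows on the vertical axis with the first
#' row on top, matching the conventional printed orientation of interaction
#' webs.
#'
#' @param object An [interaction_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot interaction_matrix
#' @export
autoplot.interaction_matrix <- function(object, ...) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(object)), times = ncol(object)),
    col = rep(seq_len(ncol(object)), each = nrow(object)),
    value = as.vector(unclass(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile(colour = "grey80", linewidth = 0.2) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "grey10") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "species of Y", y = "species of X", fill = "a_ij") +
    ggplot2::theme_minimal()
}
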