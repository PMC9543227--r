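#' Connectivity matrices and edge vector bookkeeping
#'
#' Connectivity matrices are plain numeric `n x n` matrices constrained to
#' be symmetric with zero diagonal and entries in `[0, 1]` (PLV-like
#' weights). For edgewise statistics the upper triangle is flattened into a
#' canonical edge vector; `all_edges()` fixes the edge order used
#' everywhere (column-major upper triangle, 0-based endpoints `i < j`).
#'
#' @name connectivity_matrix
NULL

#' Validate a connectivity matrix
#'
#' @param m numeric matrix.
#' @param tol symmetry tolerance.
#' @param what label used in error messages (e.g. a file name).
#' @return `m`, invisibly, if valid; otherwise an error naming the first
#'   offending entry.
#' @export
validate_connectivity <- function(m, tol = 1e-8, what = "connectivity matrix") {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m)) {
    stop_input("%s: must be a square numeric matrix", what)
  }
  if (any(!is.finite(m))) stop_input("%s: non-finite entries", what)
  asym <- abs(m - t(m))
  if (any(asym > tol)) {
    k <- sort(which(asym == max(asym), arr.ind = TRUE)[1, ])
    stop_input("%s: asymmetric at (%d,%d): %g vs %g (0-based indices)",
               what, k[1] - 1L, k[2] - 1L, m[k[1], k[2]], m[k[2], k[1]])
  }
  if (any(abs(diag(m)) > tol)) {
    stop_input("%s: nonzero diagonal at region %d", what,
               which(abs(diag(m)) > tol)[1] - 1L)
  }
  if (any(m < -tol) || any(m > 1 + tol)) {
    k <- which(m < -tol | m > 1 + tol, arr.ind = TRUE)[1, ]
    stop_input("%s: entry %g at (%d,%d) outside [0,1]",
               what, m[k[1], k[2]], k[1] - 1L, k[2] - 1L)
  }
  invisible(m)
}

#' All undirected edges of an n-region network in canonical order
#'
#' @param n number of regions.
#' @return data.frame with 0-based columns `i`, `j` (`i < j`), one row per
#'   unordered pair, in the column-major upper-triangle order used by
#'   [mat_to_edgevec()].
#' @export
all_edges <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L)
}

#' Flatten the upper triangle of a symmetric matrix into the canonical
#' edge vector
#' @param m symmetric matrix.
#' @return numeric vector of length `n(n-1)/2` in [all_edges()] order.
#' @export
mat_to_edgevec <- function(m) m[upper.tri(m)]

#' Rebuild a symmetric zero-diagonal matrix from a canonical edge vector
#' @param v edge vector in [all_edges()] order.
#' @param n number of regions.
#' @export
edgevec_to_mat <- function(v, n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m + t(m)
}

# Row positions of a specific edge set within the canonical edge vector.
edge_positions <- function(edges, n) {
  i <- pmin(edges$i, edges$j)
  j <- pmax(edges$i, edges$j)
  if (any(i == j)) stop_input("self-loop edge (%d,%d)", i[which(i == j)[1]],
                              j[which(i == j)[1]])
  if (any(j >= n | i < 0)) stop_input("edge endpoint outside 0..%d", n - 1)
  # column-major upper triangle: position of (i,j), 0-based, is
  # j(j-1)/2 + i + 1 in 1-based vector coordinates
  as.integer(j * (j - 1) / 2 + i + 1)
}

#' Read / write a connectivity matrix as delimited text
#'
#' Plain whitespace-delimited square numeric matrices; read matrices are
#' validated (symmetry, zero diagonal, `[0,1]` range) with the file named
#' in any error.
#'
#' @param path file path.
#' @rdname matrix_io
#' @export
read_matrix_txt <- function(path) {
  if (!file.exists(path)) stop_input("matrix file not found: %s", path)
  m <- as.matrix(read.table(path, header = FALSE))
  dimnames(m) <- NULL
  validate_connectivity(m, what = path)
  m
}

#' @param m matrix to write.
#' @rdname matrix_io
#' @export
write_matrix_txt <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_len(nrow(m))) {
    cat(fmt_num(m[r, ]), sep = " ", file = con)
    cat("\n", file = con)
  }
  invisible(path)
}
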