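## The XP descriptor pipeline: spatial distance matrix -> extension matrix S
## (distances weighted by equilibrium electronegativity and branching degree)
## -> correction matrix Q = S %*% t(S) -> eigenvalue spectrum -> indices
## XP1 = |smallest eigenvalue|, XP2 = |largest eigenvalue|.

#' Spatial topological distance matrix of a molecule
#'
#' In `"bond-path"` mode (default) the entry (i, j) is the shortest-path
#' distance through the bond network with each bond weighted by its Euclidean
#' length -- the spatial analogue of the classical graph distance matrix.  In
#' `"euclidean"` mode it is the direct through-space distance.
#'
#' @param graph A [molecular_graph()] with coordinates.
#' @param mode `"bond-path"` or `"euclidean"`.
#' @return An n x n matrix of distances in Angstrom with attribute `mode`;
#'   rows/columns named by atom labels.
#' @export
spatial_distance_matrix <- function(graph, mode = c("bond-path", "euclidean")) {
  mode <- match.arg(mode)
  atoms <- graph$atoms
  if (!all(c("x", "y", "z") %in% names(atoms)))
    stop("graph has no coordinates")
  miss <- which(is.na(atoms$x) | is.na(atoms$y) | is.na(atoms$z))
  if (length(miss))
    stop("missing coordinates for atom(s): ",
         paste(atoms$label[miss], collapse = ", "))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (mode == "euclidean") {
    d <- as.matrix(stats::dist(xyz))
  } else {
    if (n > 1 && nrow(graph$bonds) == 0) stop("graph is disconnected")
    lens <- sqrt(rowSums((xyz[graph$bonds$i, , drop = FALSE] -
                          xyz[graph$bonds$j, , drop = FALSE])^2))
    ig <- igraph::graph_from_edgelist(as.matrix(graph$bonds[, c("i", "j")]),
                                      directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0, n - igraph::vcount(ig)))
    d <- igraph::distances(ig, weights = lens)
    if (any(!is.finite(d))) stop("graph is disconnected")
  }
  dimnames(d) <- list(atoms$label, atoms$label)
  attr(d, "mode") <- mode
  d
}

#' Extension matrix S from distances, electronegativities and branching
#'
#' Combines the spatial distance matrix with the equilibrium
#' electronegativity vector `e` and the branching-degree vector `v`.  Under
#' the default `"diagonal"` strategy the two atomic vectors act as column
#' scalings, `S[i, j] = d3[i, j] * e[j] * v[j]`.  The `"literal"` strategy is
#' the matrix product read literally, `S = (d3 %*% e) %*% t(v)`, an outer
#' product of rank at most 1 (kept selectable for comparison; it cannot carry
#' two informative indices).
#'
#' @param d3 n x n distance matrix.
#' @param e Numeric electronegativity vector, length n.
#' @param v Numeric branching-degree vector, length n.
#' @param strategy `"diagonal"` (default) or `"literal"`.
#' @return n x n extension matrix.
#' @export
extension_matrix <- function(d3, e, v, strategy = c("diagonal", "literal")) {
  strategy <- match.arg(strategy)
  d3 <- as.matrix(d3)
  n <- nrow(d3)
  if (ncol(d3) != n) stop("d3 must be square")
  if (length(e) != n || length(v) != n)
    stop("e and v must have length ", n)
  s <- if (strategy == "diagonal") {
    sweep(d3, 2, as.numeric(e) * as.numeric(v), `*`)
  } else {
    (d3 %*% as.numeric(e)) %*% t(as.numeric(v))
  }
  attr(s, "strategy") <- strategy
  s
}

#' Correction matrix Q = S %*% t(S)
#'
#' The Gram matrix of the extension matrix's rows; always symmetric positive
#' semidefinite.
#'
#' @param s Square extension matrix.
#' @return n x n correction matrix.
#' @export
correction_matrix <- function(s) {
  s <- as.matrix(s)
  if (nrow(s) != ncol(s)) stop("extension matrix must be square")
  tcrossprod(s)
}

#' Eigenvalue spectrum of a correction matrix
#'
#' Uses the symmetric eigensolver when the input is symmetric to within
#' `tol * max|Q|`; otherwise a general eigensolver whose imaginary parts are
#' discarded if negligible (at most `tol` times the spectral radius) and an
#' error is raised otherwise.  Eigenvalues are returned sorted ascending.
#'
#' @param q Square matrix.
#' @param tol Relative tolerance (default 1e-8).
#' @return Object of class `xp_spectrum` with fields `eigenvalues` (ascending),
#'   `max_imag_discarded` and `symmetric_input`.
#' @export
q_spectrum <- function(q, tol = 1e-8) {
  q <- as.matrix(q)
  if (nrow(q) != ncol(q)) stop("q must be square")
  scale <- max(abs(q), 1e-300)
  sym <- isSymmetric(unname(q), tol = tol * scale)
  if (sym) {
    lam <- eigen(q, symmetric = TRUE, only.values = TRUE)$values
    max_im <- 0
  } else {
    lam <- eigen(q, only.values = TRUE)$values
    max_im <- max(abs(Im(lam)))
    rad <- max(abs(lam), 1e-300)
    if (max_im > tol * rad)
      stop(sprintf("non-negligible imaginary eigenvalue parts (max |Im| = %g)",
                   max_im))
    lam <- Re(lam)
  }
  structure(list(eigenvalues = sort(lam),
                 max_imag_discarded = max_im,
                 symmetric_input = sym),
            class = "xp_spectrum")
}

#' @export
print.xp_spectrum <- function(x, ...) {
  cat(sprintf("<xp_spectrum> n = %d, range [%g, %g], symmetric input: %s\n",
              length(x$eigenvalues), min(x$eigenvalues), max(x$eigenvalues),
              x$symmetric_input))
  invisible(x)
}

#' XP1 and XP2 indices from an eigenvalue spectrum
#'
#' `XP1 = |smallest eigenvalue|`, `XP2 = |largest eigenvalue|` of the
#' correction matrix, with eigenvalues sorted ascending.
#'
#' @param spectrum An `xp_spectrum` or a numeric eigenvalue vector.
#' @return Named numeric vector `c(xp1 = , xp2 = )`.
#' @export
#' @examples
#' xp_indices(c(-9.3541, 5.1485, 58.2157))  # xp1 9.3541, xp2 58.2157
xp_indices <- function(spectrum) {
  lam <- if (inherits(spectrum, "xp_spectrum")) spectrum$eigenvalues
         else as.numeric(spectrum)
  if (!length(lam)) stop("empty spectrum")
  lam <- sort(lam)
  c(xp1 = abs(lam[1]), xp2 = abs(lam[length(lam)]))
}

#' All descriptor matrices for one molecule
#'
#' Computes the spatial distance matrix, equilibrium-electronegativity
#' vector, branching-degree vector, extension matrix and correction matrix.
#'
#' @param graph A [molecular_graph()] with coordinates.
#' @param strategy Extension-matrix strategy, see [extension_matrix()].
#' @param mode Distance mode, see [spatial_distance_matrix()].
#' @param depth_limit Group-tree depth for [en_vector()].
#' @param en_table Optional electronegativity overrides.
#' @return List with elements `d3`, `e`, `v`, `s`, `q`, `strategy`, `mode`.
#' @export
descriptor_matrices <- function(graph, strategy = c("diagonal", "literal"),
                                mode = c("bond-path", "euclidean"),
                                depth_limit = 3, en_table = NULL) {
  strategy <- match.arg(strategy)
  mode <- match.arg(mode)
  d3 <- spatial_distance_matrix(graph, mode)
  e <- en_vector(graph, depth_limit, en_table)
  v <- branching_vector(graph)
  s <- extension_matrix(d3, e, v, strategy)
  list(d3 = d3, e = e, v = v, s = s, q = correction_matrix(s),
       strategy = strategy, mode = mode)
}

#' Compute the XP indices of a molecule
#'
#' End-to-end pipeline: equilibrium electronegativities, branching degrees
#' and bond-length-weighted distances are combined into the extension matrix
#' S, the correction matrix Q = S St is diagonalized, and XP1/XP2 are the
#' absolute values of the extreme eigenvalues.
#'
#' @inheritParams descriptor_matrices
#' @param tol Relative tolerance for the eigensolver, see [q_spectrum()].
#' @return Object of class `xp_index_result` with fields `name`, `xp1`,
#'   `xp2`, `spectrum`, `strategy`, `mode`, `depth_limit`, `n_atoms`.
#' @export
#' @examples
#' res <- compute_indices(idealized_geometry("2,8"))
#' c(res$xp1, res$xp2)
compute_indices <- function(graph, strategy = c("diagonal", "literal"),
                            mode = c("bond-path", "euclidean"),
                            depth_limit = 3, tol = 1e-8, en_table = NULL) {
  strategy <- match.arg(strategy)
  mode <- match.arg(mode)
  mats <- descriptor_matrices(graph, strategy, mode, depth_limit, en_table)
  spec <- q_spectrum(mats$q, tol)
  xp <- xp_indices(spec)
  structure(list(name = graph$name,
                 xp1 = unname(xp["xp1"]), xp2 = unname(xp["xp2"]),
                 spectrum = spec, strategy = strategy, mode = mode,
                 depth_limit = depth_limit, n_atoms = n_atoms(graph)),
            class = "xp_index_result")
}

#' @export
print.xp_index_result <- function(x, ...) {
  cat(sprintf("<xp_index_result> %s: XP1 = %.4f, XP2 = %.4f (%s, %s, depth %d, %d atoms)\n",
              x$name, x$xp1, x$xp2, x$strategy, x$mode, x$depth_limit, x$n_atoms))
  invisible(x)
}

#' Serialize an index result to JSON
#'
#' @param result An `xp_index_result`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
index_result_json <- function(result, path = NULL) {
  payload <- list(name = result$name, xp1 = result$xp1, xp2 = result$xp2,
                  eigenvalues = result$spectrum$eigenvalues,
                  strategy = result$strategy, mode = result$mode,
                  depth_limit = result$depth_limit, n_atoms = result$n_atoms,
                  package_version = as.character(utils::packageVersion("xpqspr")))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
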