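## Hydrogen-suppressed molecular graphs for the xanthone scaffold and its
## brominated congeners.  Atoms are stored in a fixed, documented order so all
## downstream matrices are deterministic: skeleton atoms C1..C8, the four
## ring-fusion carbons (C4a, C9a, C8a, C10a), the ether oxygen O10, the
## carbonyl carbon C9 and carbonyl oxygen O9, then bromines ascending by
## substitution position.

#' Construct a hydrogen-suppressed molecular graph
#'
#' @param name Molecule identifier.
#' @param atoms Data frame with columns `label`, `element`, `h_count` and
#'   optionally `x`, `y`, `z` (coordinates in Angstrom).
#' @param bonds Data frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (bond order; kept for file fidelity, unused by the descriptor
#'   math).
#' @return An object of class `molecular_graph`.
#' @export
molecular_graph <- function(name, atoms, bonds) {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  if (!all(c("label", "element", "h_count") %in% names(atoms)))
    stop("atoms needs columns label, element, h_count")
  if (nrow(bonds) && !all(c("i", "j") %in% names(bonds)))
    stop("bonds needs columns i, j")
  if (!"order" %in% names(bonds)) bonds$order <- rep(1L, nrow(bonds))
  n <- nrow(atoms)
  if (any(atoms$element == "H"))
    stop("explicit hydrogens are not allowed; use h_count")
  if (any(atoms$h_count < 0)) stop("negative h_count")
  if (nrow(bonds)) {
    if (any(bonds$i == bonds$j)) stop("self-bond")
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))
      stop("bond endpoint out of range")
  }
  g <- structure(list(name = name, atoms = atoms, bonds = bonds),
                 class = "molecular_graph")
  if (n > 1 && !is_connected_graph(g)) stop("graph is not connected")
  g
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %s: %d heavy atoms, %d bonds, formula-H %d\n",
              x$name, nrow(x$atoms), nrow(x$bonds), sum(x$atoms$h_count)))
  invisible(x)
}

n_atoms <- function(graph) nrow(graph$atoms)

has_coordinates <- function(graph) {
  all(c("x", "y", "z") %in% names(graph$atoms)) &&
    !anyNA(graph$atoms[, c("x", "y", "z")])
}

## adjacency list (1-based), used by BFS / group-tree growth
adjacency_list <- function(graph) {
  n <- n_atoms(graph)
  adj <- vector("list", n)
  for (k in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds$i[k]; j <- graph$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, sort)
}

is_connected_graph <- function(graph) {
  n <- n_atoms(graph)
  if (n <= 1) return(TRUE)
  adj <- adjacency_list(graph)
  seen <- logical(n)
  queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    new <- adj[[v]][!seen[adj[[v]]]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

## Idealized planar coordinates for the xanthone skeleton.  The central
## pyranone ring is built mirror-symmetrically about the y axis from exact
## bond lengths (C-O 1.36, C-C 1.39, C=O 1.22 A); the benzo rings are regular
## hexagons (side 1.39 A) fused on the C4a-C9a / C8a-C10a edges.  All bonded
## distances therefore equal the idealized table values exactly.
xanthone_coordinates <- function() {
  cc <- 1.39; co <- 1.36; cdo <- 1.22
  s60 <- sqrt(3) / 2
  o10  <- c(0, 0)
  c4a  <- c(-co * s60, co / 2)
  c9a  <- c4a + c(0, cc)
  c9   <- c(0, c9a[2] + sqrt(cc^2 - c4a[1]^2))
  o9   <- c9 + c(0, cdo)
  ctrA <- c(c4a[1] - cc * s60, (c4a[2] + c9a[2]) / 2)
  hexv <- function(theta) ctrA + cc * c(cos(theta), sin(theta))
  c1 <- hexv(pi / 2); c2 <- hexv(5 * pi / 6)
  c3 <- hexv(7 * pi / 6); c4 <- hexv(3 * pi / 2)
  mirror <- function(p) c(-p[1], p[2])
  xy <- rbind(c1, c2, c3, c4,                       # C1..C4
              mirror(c4), mirror(c3), mirror(c2), mirror(c1),  # C5..C8
              c4a, c9a, mirror(c9a), mirror(c4a),   # C4a C9a C8a C10a
              o10, c9, o9)
  data.frame(x = xy[, 1], y = xy[, 2], z = 0)
}

#' Build the xanthone skeleton graph
#'
#' Returns the 15-heavy-atom tricyclic graph of xanthone
#' (dibenzo-gamma-pyrone, C13H8O2) with idealized planar coordinates:
#' aromatic C-C 1.39 A, aromatic C-O 1.36 A, C=O 1.22 A.  Substitutable
#' positions 1-8 carry one implicit hydrogen each.
#'
#' @return A [molecular_graph()] named `"XTH"` with coordinates.
#' @export
#' @examples
#' xth <- build_xanthone()
#' nrow(xth$atoms)           # 15 heavy atoms
#' sum(xth$atoms$h_count)    # 8 hydrogens (C13H8O2)
build_xanthone <- function() {
  labels <- c(paste0("C", 1:8), "C4a", "C9a", "C8a", "C10a", "O10", "C9", "O9")
  atoms <- data.frame(
    label = labels,
    element = c(rep("C", 12), "O", "C", "O"),
    h_count = c(rep(1L, 8), rep(0L, 7)),
    stringsAsFactors = FALSE
  )
  atoms <- cbind(atoms, xanthone_coordinates())
  bonds <- data.frame(
    ## benzo ring A,   central pyranone ring,   benzo ring C,   C9=O9
    i = c(1, 2, 3, 4, 9, 10,   9, 13, 12, 11, 14,   12, 5, 6, 7, 8,  14),
    j = c(2, 3, 4, 9, 10, 1,  13, 12, 11, 14, 10,    5, 6, 7, 8, 11, 15),
    order = c(rep(1L, 16), 2L)
  )
  molecular_graph("XTH", atoms, bonds)
}

#' Parse a substitution-pattern string
#'
#' Comma-separated ring positions, e.g. `"1,2,8"`.  `""`, `"0"` and `"XTH"`
#' denote the unsubstituted parent.
#'
#' @param pattern Pattern string or integer vector.
#' @return Sorted integer vector of positions (possibly empty).
#' @export
parse_pattern <- function(pattern) {
  if (is.numeric(pattern)) pos <- as.integer(pattern)
  else {
    pattern <- trimws(pattern)
    if (pattern %in% c("", "0", "XTH")) return(integer(0))
    pos <- suppressWarnings(as.integer(strsplit(pattern, ",")[[1]]))
  }
  if (anyNA(pos) || any(pos < 1 | pos > 8))
    stop("invalid substitution pattern: positions must be in 1..8")
  if (anyDuplicated(pos)) stop("duplicated position in pattern")
  sort(pos)
}

#' Mirror image of a substitution pattern
#'
#' Applies the C2v mirror map of the xanthone scaffold
#' (1<->8, 2<->7, 3<->6, 4<->5).
#'
#' @param positions Integer vector of positions.
#' @return Sorted mirrored positions.
#' @export
mirror_pattern <- function(positions) sort(9L - as.integer(positions))

#' Canonical representative of a pattern under the mirror symmetry
#'
#' Of a pattern and its mirror image, returns whichever sorted position
#' vector is lexicographically smaller.
#'
#' @param positions Integer vector of positions (or pattern string).
#' @return Sorted integer vector, the canonical representative.
#' @export
#' @examples
#' canonicalize_pattern(c(7, 8))  # 1,2
canonicalize_pattern <- function(positions) {
  if (is.character(positions)) positions <- parse_pattern(positions)
  p <- sort(as.integer(positions))
  q <- mirror_pattern(p)
  for (k in seq_along(p)) {
    if (p[k] < q[k]) return(p)
    if (p[k] > q[k]) return(q)
  }
  p
}

pattern_string <- function(positions) {
  if (!length(positions)) "XTH" else paste(positions, collapse = ",")
}

#' Systematic congener name for a substitution pattern
#'
#' @param positions Integer vector of positions.
#' @return e.g. `"2,8-DBXTH"`; `"XTH"` for the empty pattern.
#' @export
congener_name <- function(positions) {
  k <- length(positions)
  if (k == 0) return("XTH")
  pre <- c("MB", "DB", "TriB", "TeB", "PeB", "HxB", "HpB", "OB")[k]
  paste0(paste(positions, collapse = ","), "-", pre, "XTH")
}

#' Enumerate all symmetry-distinct bromination patterns
#'
#' All non-empty subsets of positions 1..8, reduced to canonical
#' representatives under the scaffold's mirror symmetry and sorted by
#' (substituent count, lexicographic order).  There are exactly 135.
#'
#' @return List of sorted integer vectors.
#' @export
#' @examples
#' length(enumerate_patterns())                 # 135
#' table(lengths(enumerate_patterns()))         # 4 16 28 38 28 16 4 1
enumerate_patterns <- function() {
  out <- list()
  for (k in 1:8) {
    subs <- utils::combn(8, k, simplify = FALSE)
    canon <- unique(lapply(subs, canonicalize_pattern))
    key <- vapply(canon, function(p) paste(sprintf("%02d", p), collapse = ""), "")
    out <- c(out, canon[order(key)])
  }
  out
}

#' Attach bromine substituents to the xanthone skeleton
#'
#' Appends one Br atom per requested position, bonded to that ring carbon,
#' decrementing its implicit-hydrogen count.  When the skeleton carries
#' coordinates, each bromine is placed in-plane along the exocyclic bisector
#' at 1.89 A.  Bromines are appended in ascending position order so atom
#' ordering stays deterministic.
#'
#' @param graph The xanthone skeleton from [build_xanthone()].
#' @param pattern Substitution pattern (string or integer vector).
#' @return A new [molecular_graph()]; its name follows [congener_name()].
#' @export
#' @examples
#' g <- brominate(build_xanthone(), "2,8")
#' g$name            # "2,8-DBXTH"
#' nrow(g$atoms)     # 17
brominate <- function(graph, pattern) {
  pos <- if (is.character(pattern)) parse_pattern(pattern) else sort(as.integer(pattern))
  if (!length(pos)) return(graph)
  if (any(pos < 1 | pos > 8)) stop("substitution positions must be in 1..8")
  if (anyDuplicated(pos)) stop("duplicated substitution position")
  atoms <- graph$atoms
  bonds <- graph$bonds
  if (any(atoms$h_count[pos] < 1))
    stop("position(s) already substituted: ",
         paste(pos[atoms$h_count[pos] < 1], collapse = ","))
  coords <- has_coordinates(graph)
  adj <- adjacency_list(graph)
  for (p in pos) {
    atoms$h_count[p] <- atoms$h_count[p] - 1L
    br <- data.frame(label = paste0("Br", p), element = "Br", h_count = 0L,
                     stringsAsFactors = FALSE)
    if (coords) {
      at <- as.numeric(atoms[p, c("x", "y", "z")])
      nb <- adj[[p]]
      u <- at - colMeans(atoms[nb, c("x", "y", "z")])
      u <- u / sqrt(sum(u^2))
      brxyz <- at + 1.89 * u
      br$x <- brxyz[1]; br$y <- brxyz[2]; br$z <- brxyz[3]
    } else if (all(c("x", "y", "z") %in% names(atoms))) {
      br$x <- NA_real_; br$y <- NA_real_; br$z <- NA_real_
    }
    atoms <- rbind(atoms, br)
    bonds <- rbind(bonds, data.frame(i = p, j = nrow(atoms), order = 1L))
  }
  molecular_graph(congener_name(pos), atoms, bonds)
}

#' Idealized planar geometry for a congener
#'
#' Convenience wrapper producing the idealized-geometry congener graph for a
#' substitution pattern: the planar xanthone skeleton (aromatic C-C 1.39 A,
#' C-O 1.36 A, C=O 1.22 A) with bromines at 1.89 A.  This geometry generator
#' exists so the descriptor pipeline can run end to end without any external
#' quantum-chemical optimization; its indices are not expected to match the
#' bundled reference table.
#'
#' @param pattern Substitution pattern (string or integer vector).
#' @return A [molecular_graph()] with coordinates.
#' @export
idealized_geometry <- function(pattern) brominate(build_xanthone(), pattern)

#' Branching degree of an atom
#'
#' `v = z - h + 1` where `z` is the valence-electron count and `h` the
#' implicit-hydrogen count.  Aromatic CH carbons give 4, substituted /
#' fusion / carbonyl carbons 5, oxygen 7 and bromine 8.
#'
#' @param element Element symbol (vectorized).
#' @param h_count Implicit-hydrogen count (vectorized).
#' @return Integer vector of branching degrees.
#' @export
branching_degree <- function(element, h_count) {
  valence_electrons(element) - as.integer(h_count) + 1L
}

#' Branching-degree vector of a graph
#'
#' @param graph A [molecular_graph()].
#' @return Integer vector, one entry per heavy atom in graph order.
#' @export
branching_vector <- function(graph) {
  branching_degree(graph$atoms$element, graph$atoms$h_count)
}
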