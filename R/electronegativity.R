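## Group electronegativity by stepwise equal-weight averaging, and the
## per-atom equilibrium electronegativity built from it.  A group is a tree:
## an anchor atom plus substituent subtrees; its electronegativity is the
## equal-weight mean of the anchor's Pauling value with the (recursively
## averaged) values of the attached groups.  Every result is therefore a
## convex combination of Pauling values of the atoms in the tree.

#' Construct a group structure tree
#'
#' `element` is the anchor atom's symbol; `...` are the attached groups,
#' each either an element symbol (single-atom group, e.g. an H) or another
#' `group_tree`.
#'
#' @param element Anchor element symbol.
#' @param ... Children: symbols or `group_tree` objects.
#' @return An object of class `group_tree`.
#' @export
#' @examples
#' group_tree("C", "H", "H")                         # =CH2
#' group_tree("C", "H", "H", group_tree("C", "N"))   # -CH2CN
group_tree <- function(element, ...) {
  children <- lapply(list(...), function(ch) {
    if (inherits(ch, "group_tree")) ch
    else if (is.character(ch) && length(ch) == 1) group_tree(ch)
    else stop("children must be element symbols or group_tree objects")
  })
  structure(list(element = element, children = children), class = "group_tree")
}

#' Group electronegativity of a structure tree
#'
#' A single atom's group electronegativity is its Pauling value.  For a
#' larger group, every substituent group attached to the anchor atom is first
#' averaged within itself, then the anchor value and the group values are
#' averaged with equal weights:
#' `chi_G = (chi_anchor + sum(chi_group)) / (1 + n_groups)`.
#'
#' @param tree A [group_tree()].
#' @param en_table Optional electronegativity overrides (see [pauling_en()]).
#' @return Group electronegativity (dimensionless).
#' @export
#' @examples
#' group_en(group_tree("C", "H", "H"))                    # 2.3167 (=CH2)
#' group_en(group_tree("C", "H", "I", "I"))               # 2.5175 (-CHI2)
#' group_en(group_tree("C", "H", "H", group_tree("C", "N")))  # 2.4363
group_en <- function(tree, en_table = NULL) {
  if (!inherits(tree, "group_tree")) stop("tree must be a group_tree")
  chi0 <- pauling_en(tree$element, en_table)
  if (!length(tree$children)) return(chi0)
  kids <- vapply(tree$children, group_en, 0, en_table = en_table)
  (chi0 + sum(kids)) / (1 + length(kids))
}

## Grow the group tree rooted at heavy atom `root`, leading away from the
## atom whose equilibrium electronegativity is being computed.  `path` holds
## atom indices already on the root-to-leaf path (cycles terminate there);
## `depth` counts remaining levels below the current node.  Implicit
## hydrogens become single-atom leaf children.
grow_group_tree <- function(graph, adj, root, path, depth) {
  node <- list(element = graph$atoms$element[root], children = list())
  class(node) <- "group_tree"
  if (depth > 0) {
    h <- graph$atoms$h_count[root]
    if (h > 0) node$children <- rep(list(group_tree("H")), h)
    for (nb in adj[[root]]) {
      if (nb %in% path) next
      node$children <- c(node$children,
                         list(grow_group_tree(graph, adj, nb, c(path, root), depth - 1)))
    }
  }
  node
}

#' Equilibrium electronegativity of one atom
#'
#' `chi_i = (chi_iA + sum(chi_G)) / (1 + l)` where `chi_iA` is the atom's
#' Pauling value, one group is rooted at each heavy neighbour (grown away
#' from atom `i`, truncated at `depth_limit` levels, never revisiting an atom
#' already on the current path), each implicit hydrogen contributes a
#' single-atom group, and `l` is the number of directly attached groups.
#'
#' @param graph A [molecular_graph()].
#' @param atom_index 1-based atom index.
#' @param depth_limit Levels grown below each neighbour root (default 3).
#' @param en_table Optional electronegativity overrides.
#' @return Equilibrium electronegativity of the atom.
#' @export
equilibrium_en <- function(graph, atom_index, depth_limit = 3, en_table = NULL) {
  n <- n_atoms(graph)
  if (atom_index < 1 || atom_index > n) stop("atom_index out of range")
  if (depth_limit < 1) stop("depth_limit must be >= 1")
  adj <- adjacency_list(graph)
  equilibrium_en_impl(graph, adj, atom_index, depth_limit, en_table)
}

equilibrium_en_impl <- function(graph, adj, atom_index, depth_limit, en_table) {
  chi_a <- pauling_en(graph$atoms$element[atom_index], en_table)
  h <- graph$atoms$h_count[atom_index]
  nbs <- adj[[atom_index]]
  l <- length(nbs) + h
  if (l == 0) return(chi_a)
  chi_h <- if (h > 0) h * pauling_en("H", en_table) else 0
  chi_g <- vapply(nbs, function(nb) {
    group_en(grow_group_tree(graph, adj, nb, atom_index, depth_limit - 1),
             en_table = en_table)
  }, 0)
  (chi_a + chi_h + sum(chi_g)) / (1 + l)
}

#' Equilibrium-electronegativity vector of a molecule
#'
#' Applies [equilibrium_en()] to every heavy atom, in graph atom order.
#'
#' @inheritParams equilibrium_en
#' @return Numeric vector of length `n_atoms`.
#' @export
#' @examples
#' e <- en_vector(build_xanthone())
#' range(e)   # within the Pauling range of H, C, O
en_vector <- function(graph, depth_limit = 3, en_table = NULL) {
  adj <- adjacency_list(graph)
  vapply(seq_len(n_atoms(graph)), function(i) {
    equilibrium_en_impl(graph, adj, i, depth_limit, en_table)
  }, 0)
}
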