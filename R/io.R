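## Readers and writers: XYZ and MOL/SDF V2000 structure files (explicit
## hydrogens are collapsed onto their heavy atom on input, since the
## descriptor machinery works on hydrogen-suppressed graphs), delimited
## distance matrices and property tables.

covalent_radius <- function(symbol) {
  r <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, Br = 1.20, I = 1.39)[symbol]
  if (anyNA(r)) stop("no covalent radius for: ",
                     paste(unique(symbol[is.na(r)]), collapse = ", "))
  unname(r)
}

## distance-based bond perception used for XYZ input (factor 1.25 on the sum
## of covalent radii separates bonded pairs from ortho contacts cleanly in
## rigid aromatic systems)
perceive_bonds <- function(element, xyz, factor = 1.25) {
  n <- length(element)
  if (n < 2) return(data.frame(i = integer(0), j = integer(0), order = integer(0)))
  d <- as.matrix(stats::dist(xyz))
  r <- covalent_radius(element)
  cut <- factor * outer(r, r, `+`)
  hit <- which(d <= cut & upper.tri(d), arr.ind = TRUE)
  data.frame(i = hit[, 1], j = hit[, 2], order = 1L)
}

## collapse explicit H atoms onto their bonded (or nearest) heavy atom
suppress_hydrogens <- function(name, element, xyz, bonds, labels = NULL) {
  heavy <- which(element != "H")
  hyd <- which(element == "H")
  idx_map <- match(seq_along(element), heavy)
  h_count <- integer(length(heavy))
  for (h in hyd) {
    partners <- c(bonds$j[bonds$i == h], bonds$i[bonds$j == h])
    partners <- partners[element[partners] != "H"]
    if (!length(partners)) {
      dd <- sqrt(colSums((t(xyz[heavy, , drop = FALSE]) - xyz[h, ])^2))
      partners <- heavy[which.min(dd)]
    }
    k <- idx_map[partners[1]]
    h_count[k] <- h_count[k] + 1L
  }
  bonds <- bonds[element[bonds$i] != "H" & element[bonds$j] != "H", , drop = FALSE]
  atoms <- data.frame(
    label = if (is.null(labels)) paste0(element[heavy], seq_along(heavy))
            else labels[heavy],
    element = element[heavy],
    h_count = h_count,
    x = xyz[heavy, 1], y = xyz[heavy, 2], z = xyz[heavy, 3],
    stringsAsFactors = FALSE
  )
  molecular_graph(name, atoms,
                  data.frame(i = idx_map[bonds$i], j = idx_map[bonds$j],
                             order = bonds$order))
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ layout: atom count, comment line, then `element x y z` rows
#' (Angstrom).  Bonds are perceived from covalent radii; explicit hydrogens
#' are collapsed into per-atom `h_count`s.  If the comment line contains a
#' token `h_counts=1,0,...` (as written by [write_xyz()] for
#' hydrogen-suppressed output) those counts are used instead.
#'
#' @param path File path.
#' @return A [molecular_graph()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("malformed XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1 || length(lines) < n + 2)
    stop("malformed XYZ file: ", path)
  comment <- lines[2]
  rows <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  if (any(lengths(rows) < 4)) stop("malformed XYZ atom line in: ", path)
  element <- vapply(rows, `[`, "", 1)
  xyz <- t(vapply(rows, function(r) suppressWarnings(as.numeric(r[2:4])), numeric(3)))
  if (anyNA(xyz)) stop("non-numeric coordinate in: ", path)
  name <- trimws(sub("h_counts=\\S*", "", comment))
  if (!nzchar(name)) name <- basename(path)
  bonds <- perceive_bonds(element, xyz)
  g <- suppress_hydrogens(name, element, xyz, bonds)
  hm <- regmatches(comment, regexpr("h_counts=\\S+", comment))
  if (length(hm)) {
    hc <- as.integer(strsplit(sub("h_counts=", "", hm), ",")[[1]])
    if (length(hc) != n_atoms(g))
      stop("h_counts annotation length mismatch in: ", path)
    g$atoms$h_count <- hc
  }
  g
}

#' Write a molecule to an XYZ file
#'
#' Heavy atoms only; the implicit-hydrogen counts are recorded on the
#' comment line as `h_counts=...` so [read_xyz()] can restore them.
#'
#' @param graph A [molecular_graph()] with coordinates.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(graph, path) {
  if (!has_coordinates(graph)) stop("graph has no coordinates")
  at <- graph$atoms
  lines <- c(
    as.character(nrow(at)),
    sprintf("%s h_counts=%s", graph$name, paste(at$h_count, collapse = ",")),
    sprintf("%-2s %14.8f %14.8f %14.8f", at$element, at$x, at$y, at$z)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a molecule from a MOL/SDF V2000 file
#'
#' Parses the first structure of a V2000 connection table (counts line, atom
#' block, bond block).  Explicit hydrogens are collapsed into `h_count`s.
#'
#' @param path File path.
#' @return A [molecular_graph()].
#' @export
read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4) stop("malformed MOL/SDF file: ", path)
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || length(lines) < 4 + na + nb)
    stop("malformed V2000 counts line in: ", path)
  atom_lines <- lines[5:(4 + na)]
  element <- trimws(substr(atom_lines, 32, 34))
  xyz <- cbind(as.numeric(substr(atom_lines, 1, 10)),
               as.numeric(substr(atom_lines, 11, 20)),
               as.numeric(substr(atom_lines, 21, 30)))
  if (anyNA(xyz)) stop("non-numeric coordinate in: ", path)
  if (nb > 0) {
    bond_lines <- lines[(5 + na):(4 + na + nb)]
    bonds <- data.frame(
      i = as.integer(substr(bond_lines, 1, 3)),
      j = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9))
    )
  } else bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  name <- trimws(lines[1])
  if (!nzchar(name)) name <- basename(path)
  suppress_hydrogens(name, element, xyz, bonds)
}

#' Read a structure file by extension
#'
#' Dispatches on the file extension: `.xyz` to [read_xyz()], `.sdf`/`.mol`
#' to [read_sdf()].
#'
#' @param path File path.
#' @return A [molecular_graph()].
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         xyz = read_xyz(path),
         sdf = ,
         mol = read_sdf(path),
         stop("unsupported structure format: .", ext))
}

#' Write a distance matrix as delimited text
#'
#' Square tab-separated matrix with a header row of atom labels.
#'
#' @param d Square numeric matrix (row/col names used as labels).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  d <- as.matrix(d)
  if (is.null(colnames(d))) colnames(d) <- paste0("a", seq_len(ncol(d)))
  utils::write.table(format(d, digits = 12, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a distance matrix from delimited text
#'
#' @param path Path to a square delimited matrix with a header row.
#' @return Numeric matrix with dimnames from the header.
#' @export
read_distance_matrix <- function(path) {
  d <- as.matrix(utils::read.delim(path, header = TRUE, check.names = FALSE))
  storage.mode(d) <- "double"
  if (nrow(d) != ncol(d)) stop("distance matrix is not square: ", path)
  rownames(d) <- colnames(d)
  d
}

#' Read / write a property table
#'
#' Tab-separated table with a header; `"-"` and empty cells become `NA`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_property_table <- function(path) {
  utils::read.delim(path, header = TRUE, na.strings = c("-", "NA", ""),
                    comment.char = "#")
}

#' @rdname read_property_table
#' @param table Data frame to write.
#' @export
write_property_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "-")
  invisible(path)
}
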