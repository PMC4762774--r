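#' Element table used by the descriptor machinery
#'
#' Valence-electron counts and Pauling electronegativities for the elements
#' supported by the toolkit.  `z` counts main-group valence electrons; `chi`
#' is on the Pauling scale (dimensionless).  Values for H, C, N and I are the
#' ones used in the worked group-electronegativity examples; O and Br are the
#' standard Pauling values.
#'
#' @return A data frame with columns `symbol`, `z`, `chi`.
#' @export
#' @examples
#' element_table()
element_table <- function() {
  data.frame(
    symbol = c("H", "C", "N", "O", "Br", "I"),
    z      = c(1L,  4L,  5L,  6L,  7L,   7L),
    chi    = c(2.20, 2.55, 3.04, 3.44, 2.96, 2.66),
    stringsAsFactors = FALSE
  )
}

#' Pauling electronegativity of an element
#'
#' @param symbol Character vector of element symbols.
#' @param en_table Optional named numeric vector overriding individual
#'   electronegativities, e.g. `c(O = 3.50)`.  Unnamed elements fall back to
#'   [element_table()].
#' @return Numeric vector of electronegativities.
#' @export
pauling_en <- function(symbol, en_table = NULL) {
  tab <- element_table()
  chi <- tab$chi[match(symbol, tab$symbol)]
  if (!is.null(en_table)) {
    if (is.null(names(en_table)) || any(names(en_table) == ""))
      stop("en_table must be a fully named numeric vector")
    hit <- match(symbol, names(en_table))
    chi[!is.na(hit)] <- en_table[hit[!is.na(hit)]]
  }
  if (anyNA(chi))
    stop("unsupported element(s): ",
         paste(unique(symbol[is.na(chi)]), collapse = ", "))
  unname(chi)
}

#' Valence-electron count of an element
#'
#' @param symbol Character vector of element symbols.
#' @return Integer vector of valence-electron counts.
#' @export
valence_electrons <- function(symbol) {
  tab <- element_table()
  z <- tab$z[match(symbol, tab$symbol)]
  if (anyNA(z))
    stop("unsupported element(s): ",
         paste(unique(symbol[is.na(z)]), collapse = ", "))
  unname(z)
}

#' Read electronegativity overrides from a key-value config file
#'
#' Each non-comment line has the form `symbol = value` (e.g. `O = 3.50`).
#' Lines starting with `#` and blank lines are ignored.
#'
#' @param path Path to the config file.
#' @return Named numeric vector suitable for the `en_table` argument of the
#'   electronegativity functions.
#' @export
read_en_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(stats::setNames(numeric(0), character(0)))
  parts <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  vals <- vapply(parts, function(p) suppressWarnings(as.numeric(trimws(p[2]))), 0)
  if (anyNA(vals))
    stop("non-numeric electronegativity value in config")
  stats::setNames(vals, vapply(parts, function(p) trimws(p[1]), ""))
}
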