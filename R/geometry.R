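#' Molecular geometry
#'
#' An ordered set of mass points: element symbols, isotopic masses (amu) and
#' Cartesian coordinates (Angstrom). Atom ordering is significant and is
#' preserved by every transformation in the package. Masses default to the
#' principal isotopes via [atomic_mass()]; per-atom overrides may be given
#' explicitly.
#'
#' @param species_id identifier, e.g. `"KA"`.
#' @param elements character vector of element symbols (or `"X"` for
#'   abstract mass points, in which case `masses` is required).
#' @param coords numeric N x 3 matrix of Cartesian coordinates in Angstrom.
#' @param masses optional numeric vector of masses in amu.
#' @return Object of class `"geometry"`.
#' @examples
#' hf <- geometry("HF", c("H", "F"), rbind(c(0, 0, 0), c(0, 0, 0.92)),
#'                masses = c(1.0078250319, 18.99840316))
#' @export
geometry <- function(species_id, elements, coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be an N x 3 matrix")
  n <- nrow(coords)
  if (n < 2) stop("a geometry needs at least 2 atoms")
  if (length(elements) != n) stop("elements and coords disagree in length")
  if (is.null(masses)) {
    masses <- vapply(elements, atomic_mass, numeric(1))
  }
  if (length(masses) != n) stop("masses and coords disagree in length")
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    stop("all masses must be positive and finite")
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(species_id = species_id,
                 elements = as.character(elements),
                 masses = as.numeric(masses),
                 coords = coords),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat("<geometry '", x$species_id, "': ", length(x$elements), " atoms>\n",
      sep = "")
  df <- data.frame(element = x$elements, mass = x$masses, x$coords)
  print(df, digits = 8)
  invisible(x)
}

n_atoms <- function(g) length(g$elements)

#' Read a geometry from an XYZ file
#'
#' Standard XYZ: first line atom count, second line comment, then one
#' `element x y z` record per atom (Angstrom). Extra whitespace is
#' tolerated; a count line that disagrees with the body is an error naming
#' the offending line.
#'
#' @param path file path.
#' @param species_id identifier for the resulting geometry; defaults to the
#'   comment line (or the file name if the comment is blank).
#' @param masses optional mass overrides, as for [geometry()].
#' @return A [geometry()].
#' @export
read_xyz <- function(path, species_id = NULL, masses = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("malformed XYZ '", path, "': fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stop("malformed XYZ '", path, "': line 1 is not an atom count")
  if (length(lines) < 2 + n) {
    stop("malformed XYZ '", path, "': count line says ", n, " atoms but body ends at line ",
         length(lines))
  }
  comment <- trimws(lines[2])
  body <- lines[3:(2 + n)]
  el <- character(n); xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(tok) < 4) stop("malformed XYZ '", path, "': line ", i + 2, " has fewer than 4 fields")
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(v))) stop("malformed XYZ '", path, "': non-numeric coordinate at line ", i + 2)
    el[i] <- tok[1]; xyz[i, ] <- v
  }
  if (is.null(species_id)) {
    species_id <- if (nzchar(comment)) comment else basename(path)
  }
  geometry(species_id, el, xyz, masses = masses)
}

#' Write a geometry to an XYZ file
#'
#' @param g a [geometry()].
#' @param path file path.
#' @param digits coordinate precision (decimal places).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(g, path, digits = 10) {
  fmt <- paste0("%-3s %", digits + 6, ".", digits, "f %", digits + 6, ".",
                digits, "f %", digits + 6, ".", digits, "f")
  lines <- c(as.character(n_atoms(g)), g$species_id,
             sprintf(fmt, g$elements, g$coords[, 1], g$coords[, 2], g$coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}
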