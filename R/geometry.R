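#' Molecular geometry specification
#'
#' Constructs a validated molecule specification for a closed-shell
#' calculation. Coordinates are Cartesian, in angstrom.
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`.
#' @param charge Integer total charge.
#' @param spin_multiplicity Integer spin multiplicity; must be 1, since all
#'   correlated machinery in this package assumes a closed-shell restricted
#'   reference with spatial orbitals.
#' @param basis_name,aux_basis_name Orbital and auxiliary (density-fitting)
#'   basis-set labels, passed through to the SCF backend.
#' @param comment Free-text comment (second line of an XYZ file).
#' @return An object of class `molecule_spec`.
#' @export
molecule_spec <- function(atoms, charge = 0L, spin_multiplicity = 1L,
                          basis_name = "cc-pVDZ", aux_basis_name = "cc-pVDZ-RI",
                          comment = "") {
  stopifnot(is.data.frame(atoms))
  if (nrow(atoms) < 1L)
    stop("molecule must contain at least one atom", call. = FALSE)
  if (!all(c("element", "x", "y", "z") %in% names(atoms)))
    stop("atoms must have columns element, x, y, z", call. = FALSE)
  atomic_number(atoms$element)  # errors on unknown symbols
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z))
    stop("coordinate parse failure: NA coordinate", call. = FALSE)
  if (spin_multiplicity != 1L)
    stop("closed-shell reference required: spin_multiplicity must be 1",
         call. = FALSE)
  structure(
    list(atoms = atoms, charge = as.integer(charge),
         spin_multiplicity = as.integer(spin_multiplicity),
         basis_name = basis_name, aux_basis_name = aux_basis_name,
         comment = comment),
    class = "molecule_spec")
}

#' Read a molecular geometry from an XYZ file
#'
#' Standard XYZ layout: first line is the atom count, second line a free
#' comment, then one `El x y z` record per atom (angstrom).
#'
#' @param path Path to the XYZ file.
#' @param charge,spin_multiplicity,basis_name,aux_basis_name Passed to
#'   [molecule_spec()].
#' @return A `molecule_spec`.
#' @export
load_geometry <- function(path, charge = 0L, spin_multiplicity = 1L,
                          basis_name = "cc-pVDZ",
                          aux_basis_name = "cc-pVDZ-RI") {
  if (!file.exists(path)) stop("geometry file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(length(lines))]
  if (length(lines) < 1L) stop("empty XYZ file", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[[1L]])))
  if (is.na(n) || n < 1L)
    stop("malformed atom count line: ", sQuote(lines[[1L]]), call. = FALSE)
  comment <- if (length(lines) >= 2L) lines[[2L]] else ""
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n)
    stop("atom count mismatch: header declares ", n, " atoms, found ",
         length(body), call. = FALSE)
  fields <- strsplit(trimws(body), "\\s+")
  if (any(vapply(fields, length, 1L) < 4L))
    stop("coordinate parse failure: expected 'El x y z' records",
         call. = FALSE)
  el <- vapply(fields, `[[`, "", 1L)
  coord <- vapply(fields, function(f) {
    v <- suppressWarnings(as.numeric(f[2:4]))
    if (anyNA(v)) stop("coordinate parse failure in record: ",
                       paste(f, collapse = " "), call. = FALSE)
    v
  }, numeric(3))
  atoms <- data.frame(element = el, x = coord[1, ], y = coord[2, ],
                      z = coord[3, ], stringsAsFactors = FALSE)
  molecule_spec(atoms, charge = charge, spin_multiplicity = spin_multiplicity,
                basis_name = basis_name, aux_basis_name = aux_basis_name,
                comment = comment)
}

#' @export
print.molecule_spec <- function(x, ...) {
  cat("Molecule:", nrow(x$atoms), "atoms, charge", x$charge,
      ", multiplicity", x$spin_multiplicity, "\n")
  cat("Basis:", x$basis_name, "/ aux:", x$aux_basis_name, "\n")
  invisible(x)
}

#' Number of frozen-core orbitals for a molecule
#'
#' Decides how many of the lowest (core) occupied spatial orbitals are
#' excluded from the correlated space. The `auto` policy freezes the standard
#' chemical core per element (none for H/He, the 1s shell for first-row
#' atoms, and in general the orbitals of the preceding noble gas); `none`
#' correlates all electrons.
#'
#' @param mol A `molecule_spec`.
#' @param policy `"auto"`, `"none"`, or a non-negative integer count.
#' @param n_occupied Total number of occupied spatial orbitals, used to
#'   validate an explicit count (optional for `auto`/`none`).
#' @return Integer number of frozen spatial orbitals.
#' @export
select_frozen_core <- function(mol, policy = "auto", n_occupied = NULL) {
  if (is.numeric(policy)) {
    n <- as.integer(policy)
    if (n < 0L) stop("explicit frozen-core count must be >= 0", call. = FALSE)
    if (!is.null(n_occupied) && n > n_occupied)
      stop("explicit frozen-core count ", n, " exceeds the ", n_occupied,
           " occupied orbitals", call. = FALSE)
    return(n)
  }
  policy <- match.arg(policy, c("auto", "none"))
  if (policy == "none") return(0L)
  z <- atomic_number(mol$atoms$element)
  sum(.core_orbitals_for_z(z))
}
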