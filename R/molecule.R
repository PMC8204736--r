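#' Construct a molecule
#'
#' A molecule is an ordered list of atoms with explicit connectivity and an
#' integer net charge. Coordinates live in [conformer()] objects so that one
#' molecule can carry several geometries for a simultaneous multi-conformer
#' charge fit.
#'
#' @param elements character vector of element symbols (one per atom).
#' @param bonds two- or three-column matrix (or data.frame) of 1-based atom
#'   index pairs, optionally with an integer bond order in the third column
#'   (defaults to 1).
#' @param net_charge integer net molecular charge in elementary charges.
#' @param name optional molecule name.
#' @return an object of class `"molecule"` with components `name`,
#'   `elements`, `atomic_numbers`, `bonds` (matrix with columns i, j, order)
#'   and `net_charge`.
#' @examples
#' water <- molecule(c("O", "H", "H"), rbind(c(1, 2), c(1, 3)))
#' water
#' @export
molecule <- function(elements, bonds, net_charge = 0L, name = "molecule") {
  elements <- as.character(elements)
  n <- length(elements)
  if (n < 1L) stop("a molecule needs at least one atom")
  unknown <- setdiff(unique(elements), names(ATOMIC_NUMBERS))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(bonds) || length(bonds) == 0L) {
    bonds <- matrix(integer(0), ncol = 3L)
  } else {
    bonds <- as.matrix(bonds)
    if (ncol(bonds) == 2L) bonds <- cbind(bonds, 1L)
    if (ncol(bonds) != 3L) stop("bonds must have 2 or 3 columns")
    storage.mode(bonds) <- "integer"
  }
  colnames(bonds) <- c("i", "j", "order")
  if (nrow(bonds) > 0L) {
    if (any(bonds[, 1:2] < 1L) || any(bonds[, 1:2] > n)) {
      stop("bond atom index out of range")
    }
    if (any(bonds[, "i"] == bonds[, "j"])) stop("bond joins an atom to itself")
    key <- paste(pmin(bonds[, "i"], bonds[, "j"]),
                 pmax(bonds[, "i"], bonds[, "j"]))
    if (anyDuplicated(key)) stop("duplicate bond")
  }
  if (net_charge != round(net_charge)) stop("net_charge must be an integer")
  structure(
    list(name = name,
         elements = elements,
         atomic_numbers = unname(ATOMIC_NUMBERS[elements]),
         bonds = bonds,
         net_charge = as.integer(round(net_charge))),
    class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("Molecule '%s': %d atoms (%s), %d bonds, net charge %+d e\n",
              x$name, length(x$elements),
              paste(names(sort(table(x$elements), decreasing = TRUE)),
                    sort(table(x$elements), decreasing = TRUE),
                    sep = "", collapse = " "),
              nrow(x$bonds), x$net_charge))
  invisible(x)
}

n_atoms <- function(molecule) length(molecule$elements)

#' Construct a conformer
#'
#' A conformer binds one 3D geometry (Angstrom) to a molecule.
#'
#' @param molecule a [molecule()].
#' @param coordinates numeric matrix, one row per atom, columns x, y, z in
#'   Angstrom.
#' @return an object of class `"conformer"`.
#' @export
conformer <- function(molecule, coordinates) {
  stopifnot(inherits(molecule, "molecule"))
  coordinates <- as.matrix(coordinates)
  if (!is.numeric(coordinates) || ncol(coordinates) != 3L) {
    stop("coordinates must be an n x 3 numeric matrix")
  }
  if (nrow(coordinates) != n_atoms(molecule)) {
    stop("coordinate count (", nrow(coordinates),
         ") does not match atom count (", n_atoms(molecule), ")")
  }
  if (!all(is.finite(coordinates))) stop("coordinates must be finite")
  if (nrow(coordinates) > 1L) {
    d <- as.matrix(stats::dist(coordinates))
    diag(d) <- Inf
    if (min(d) < 0.5) {
      stop(sprintf("atoms closer than 0.5 Angstrom (min distance %.3f)",
                   min(d)))
    }
  }
  dimnames(coordinates) <- list(NULL, c("x", "y", "z"))
  structure(list(molecule = molecule, coordinates = coordinates),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("Conformer of '%s' (%d atoms)\n",
              x$molecule$name, nrow(x$coordinates)))
  invisible(x)
}

# adjacency list from the bond table
adjacency_list <- function(molecule) {
  n <- n_atoms(molecule)
  adj <- vector("list", n)
  for (k in seq_len(nrow(molecule$bonds))) {
    i <- molecule$bonds[k, "i"]; j <- molecule$bonds[k, "j"]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

#' Heuristic bond perception from distances
#'
#' Builds a bond list by connecting atom pairs closer than 1.2 times the sum
#' of their single-bond covalent radii. This is a convenience fallback for
#' XYZ input without a bond list; supplied connectivity is always preferred.
#'
#' @param elements character vector of element symbols.
#' @param coordinates n x 3 matrix, Angstrom.
#' @return integer matrix with columns i, j, order (all orders 1).
#' @export
perceive_bonds <- function(elements, coordinates) {
  coordinates <- as.matrix(coordinates)
  n <- length(elements)
  missing <- setdiff(unique(elements), names(COVALENT_RADII))
  if (length(missing) > 0L) {
    stop("no covalent radius for element(s): ", paste(missing, collapse = ", "))
  }
  rc <- COVALENT_RADII[elements]
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (sqrt(sum((coordinates[i, ] - coordinates[j, ])^2)) <=
          1.2 * (rc[i] + rc[j])) {
        out[[length(out) + 1L]] <- c(i, j, 1L)
      }
    }
  }
  if (length(out) == 0L) return(matrix(integer(0), ncol = 3L,
                                       dimnames = list(NULL, c("i", "j", "order"))))
  m <- do.call(rbind, out)
  colnames(m) <- c("i", "j", "order")
  m
}
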