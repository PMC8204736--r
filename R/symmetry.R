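#' Topological symmetry classes by iterative color refinement
#'
#' Partitions atoms into chemical-equivalence classes: two atoms receive the
#' same class label iff they are indistinguishable under iterative
#' neighborhood color refinement seeded by (element, degree). Each round
#' replaces an atom's color with the rank of the pair (own color, sorted
#' multiset of neighbor colors); refinement runs to a fixed point. The
#' result is deterministic and invariant under permutation of the atom
#' input order. It is never finer than the graph-automorphism orbits; for
#' molecular graphs of the size handled here it coincides with them in
#' practice, although highly regular graphs can in principle merge
#' inequivalent atoms.
#'
#' @param molecule a [molecule()].
#' @return integer vector of class labels, contiguous from 0, one per atom.
#' @examples
#' eth <- mock_fixture("ethane")
#' assign_symmetry_classes(eth$molecule)  # carbons one class, hydrogens one
#' @export
assign_symmetry_classes <- function(molecule) {
  stopifnot(inherits(molecule, "molecule"))
  n <- n_atoms(molecule)
  adj <- adjacency_list(molecule)
  degree <- vapply(adj, length, integer(1))
  if (n > 1L && !is_connected(adj, n)) {
    warning("molecule is disconnected; symmetry classes computed per component")
  }
  sig <- paste(molecule$elements, degree)
  colors <- as.integer(factor(sig, levels = sort(unique(sig)))) - 1L
  repeat {
    sig <- vapply(seq_len(n), function(i) {
      nb <- sort(colors[adj[[i]]])
      paste(colors[i], paste(nb, collapse = ","), sep = "|")
    }, character(1))
    new_colors <- as.integer(factor(sig, levels = sort(unique(sig)))) - 1L
    if (length(unique(new_colors)) == length(unique(colors))) break
    colors <- new_colors
  }
  # relabel contiguously in order of first appearance-independent sort key
  as.integer(factor(colors, levels = sort(unique(colors)))) - 1L
}

is_connected <- function(adj, n) {
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in adj[[v]]) {
      if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
    }
  }
  all(seen)
}

#' Polar hydrogens
#'
#' Returns the indices of hydrogens bonded to nitrogen or oxygen — the
#' SMARTS pattern `[#1:1]-[#7,#8]` expressed on the explicit bond graph.
#'
#' @param molecule a [molecule()].
#' @return integer vector of atom indices (possibly empty).
#' @export
classify_polar_hydrogens <- function(molecule) {
  stopifnot(inherits(molecule, "molecule"))
  adj <- adjacency_list(molecule)
  h <- which(molecule$elements == "H")
  unbonded <- h[vapply(adj[h], length, integer(1)) == 0L]
  if (length(unbonded) > 0L) {
    stop("hydrogen atom(s) without any bond (malformed input): ",
         paste(unbonded, collapse = ", "))
  }
  h[vapply(adj[h], function(nb) {
    any(molecule$elements[nb] %in% c("N", "O"))
  }, logical(1))]
}

#' Assign the five Lennard-Jones types
#'
#' Maps every atom to one of the five LJ types C, N, O, H_polar and
#' H_nonpolar; hydrogens are split by [classify_polar_hydrogens()]. Only
#' H, C, N and O are supported by the five-type scheme.
#'
#' @param molecule a [molecule()].
#' @return character vector of per-atom type labels.
#' @examples
#' assign_lj_types(mock_fixture("methanol")$molecule)
#' @export
assign_lj_types <- function(molecule) {
  stopifnot(inherits(molecule, "molecule"))
  bad <- which(!molecule$elements %in% c("H", "C", "N", "O"))
  if (length(bad) > 0L) {
    stop(sprintf("unsupported element for five-type LJ scheme: %s (atom %d)",
                 molecule$elements[bad[1]], bad[1]))
  }
  types <- molecule$elements
  polar <- classify_polar_hydrogens(molecule)
  types[types == "H"] <- "H_nonpolar"
  types[polar] <- "H_polar"
  types
}

#' LJ type names used throughout the package
#' @return character vector of the five type labels.
#' @export
lj_type_names <- function() c("C", "N", "O", "H_polar", "H_nonpolar")
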