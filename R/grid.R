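#' Merz-Singh-Kollman grid settings
#'
#' The shells span 1.6 to 2.0 times the Bondi radius with 0.2 R spacing,
#' i.e. scale factors 1.6, 1.8, 2.0, each layer populated at an areal
#' density of 2.4 points per square Angstrom.
#'
#' @param scale_factors strictly increasing sphere scalings, all > 1.
#' @param density points per square Angstrom per layer.
#' @return an object of class `"grid_settings"`.
#' @export
grid_settings <- function(scale_factors = c(1.6, 1.8, 2.0), density = 2.4) {
  scale_factors <- as.numeric(scale_factors)
  if (length(scale_factors) < 1L || any(scale_factors <= 1) ||
      any(diff(scale_factors) <= 0)) {
    stop("scale_factors must be strictly increasing and all > 1")
  }
  if (!is.numeric(density) || density <= 0) stop("density must be > 0")
  structure(list(scale_factors = scale_factors, density = density),
            class = "grid_settings")
}

#' ESP grid container
#'
#' Holds surface points (Bohr) and, optionally, electrostatic-potential
#' values (Hartree/e) at those points, plus a phase tag and free-text
#' provenance.
#'
#' @param points n x 3 numeric matrix of coordinates in Bohr.
#' @param values optional numeric vector of potentials (Hartree/e), same
#'   length as `nrow(points)`.
#' @param phase `"gas"`, `"aqueous"`, or `NA` if not yet set.
#' @param provenance character vector of free-text provenance notes.
#' @return an object of class `"esp_grid"`.
#' @export
esp_grid <- function(points, values = NULL, phase = NA_character_,
                     provenance = character(0)) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  if (!all(is.finite(points))) stop("grid points must be finite")
  if (!is.null(values)) {
    values <- as.numeric(values)
    if (length(values) != nrow(points)) {
      stop("values length (", length(values),
           ") does not match point count (", nrow(points), ")")
    }
    if (!all(is.finite(values))) stop("ESP values must be finite")
  }
  if (!is.na(phase) && !phase %in% c("gas", "aqueous")) {
    stop("phase must be 'gas' or 'aqueous'")
  }
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(list(points = points, values = values, phase = phase,
                 provenance = provenance),
            class = "esp_grid")
}

#' @export
print.esp_grid <- function(x, ...) {
  cat(sprintf("ESP grid: %d points (Bohr), %s, phase %s\n",
              nrow(x$points),
              if (is.null(x$values)) "no values" else "with values (Hartree/e)",
              if (is.na(x$phase)) "<unset>" else x$phase))
  invisible(x)
}

#' Attach potential values to a grid
#'
#' @param grid an [esp_grid()].
#' @param values numeric vector of potentials (Hartree/e), one per point.
#' @param note provenance note appended to the grid.
#' @return the grid with values attached (existing values are overwritten,
#'   recorded in provenance).
#' @export
attach_values <- function(grid, values, note = "values attached") {
  stopifnot(inherits(grid, "esp_grid"))
  if (!is.null(grid$values)) note <- paste(note, "(overwrote existing values)")
  esp_grid(grid$points, values, grid$phase, c(grid$provenance, note))
}

# Deterministic golden-angle spiral of n unit vectors.
sphere_spiral <- function(n) {
  if (n < 1L) return(matrix(numeric(0), ncol = 3L))
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  theta <- pi * (3 - sqrt(5)) * k
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(theta), rho * sin(theta), z)
}

# Molecule-fixed orthonormal frame from the first three non-collinear
# atoms, so the emitted grid co-rotates with the conformer. Falls back to
# lab axes for single atoms and collinear geometries.
molecular_frame <- function(coords) {
  n <- nrow(coords)
  if (n >= 2L) {
    for (j in 2:n) {
      v1 <- coords[j, ] - coords[1, ]
      if (sqrt(sum(v1^2)) > 1e-8) {
        e1 <- v1 / sqrt(sum(v1^2))
        if (n >= 3L) {
          for (k in 2:n) {
            v2 <- coords[k, ] - coords[1, ]
            v2 <- v2 - sum(v2 * e1) * e1
            if (sqrt(sum(v2^2)) > 1e-8) {
              e2 <- v2 / sqrt(sum(v2^2))
              e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
                      e1[3] * e2[1] - e1[1] * e2[3],
                      e1[1] * e2[2] - e1[2] * e2[1])
              return(cbind(e1, e2, e3))
            }
          }
        }
        # collinear: complete e1 with a deterministic perpendicular
        ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        e2 <- ref - sum(ref * e1) * e1
        e2 <- e2 / sqrt(sum(e2^2))
        e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
                e1[3] * e2[1] - e1[1] * e2[3],
                e1[1] * e2[2] - e1[2] * e2[1])
        return(cbind(e1, e2, e3))
      }
    }
  }
  diag(3)
}

#' Build a Merz-Singh-Kollman shell grid
#'
#' For each scale factor s and atom i, n = round(density * 4 pi (s R_i)^2)
#' candidate points are placed on the sphere of radius s R_i around atom i
#' by a deterministic golden-angle spiral; a candidate is retained iff its
#' distance to every other atom j is at least s R_j (per-layer exclusion at
#' that layer's own scale). Points are emitted in atom-index, then scale,
#' then spiral order, converted to Bohr. Spiral directions are expressed in
#' a molecule-fixed frame so that rigid motions of the conformer transform
#' the grid identically.
#'
#' @param conf a [conformer()].
#' @param settings a [grid_settings()].
#' @param radii named radii vector (Angstrom); defaults to Bondi radii of
#'   the conformer's elements.
#' @return an [esp_grid()] with points only (Bohr).
#' @examples
#' g <- build_msk_grid(mock_fixture("water")$conformers[[1]])
#' nrow(g$points)
#' @export
build_msk_grid <- function(conf, settings = grid_settings(),
                           radii = NULL) {
  stopifnot(inherits(conf, "conformer"), inherits(settings, "grid_settings"))
  elements <- conf$molecule$elements
  if (is.null(radii)) radii <- bondi_radii(elements)
  missing <- setdiff(unique(elements), names(radii))
  if (length(missing) > 0L) {
    stop("no radius provided for element(s): ", paste(missing, collapse = ", "))
  }
  if (any(radii <= 0)) stop("radii must be strictly positive")
  r_atom <- unname(radii[elements])
  coords <- conf$coordinates
  n <- nrow(coords)
  frame <- molecular_frame(coords)
  layers <- list()
  for (i in seq_len(n)) {
    for (s in settings$scale_factors) {
      r <- s * r_atom[i]
      npts <- round(settings$density * 4 * pi * r^2)
      if (npts < 1L) next
      pts <- sphere_spiral(npts) %*% t(frame) * r
      pts <- sweep(pts, 2L, coords[i, ], "+")
      keep <- rep(TRUE, npts)
      for (j in seq_len(n)) {
        if (j == i) next
        dj <- sqrt(rowSums(sweep(pts, 2L, coords[j, ], "-")^2))
        keep <- keep & (dj >= s * r_atom[j] - 1e-10)
      }
      if (any(keep)) layers[[length(layers) + 1L]] <- pts[keep, , drop = FALSE]
    }
  }
  if (length(layers) == 0L) {
    stop("MSK grid is empty after exclusion (fully buried atom set)")
  }
  pts <- do.call(rbind, layers) * BOHR_PER_ANGSTROM
  esp_grid(pts, provenance = sprintf(
    "MSK grid: scales [%s], density %g pts/A^2",
    paste(settings$scale_factors, collapse = ", "), settings$density))
}
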