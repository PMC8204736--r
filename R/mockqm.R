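#' Reference charge model for the synthetic-ESP engine
#'
#' The mock QM engine replaces the quantum-chemistry step with a Coulomb
#' superposition over hidden reference point charges. The aqueous phase is
#' emulated by scaling the charges away from their mean by the polarization
#' factor lambda, which preserves the net charge exactly and, for neutral
#' molecules, scales the dipole by exactly lambda. Gaussian noise of width
#' `noise_sigma` (Hartree/e) can be added to the grid values to emulate
#' numerical scatter.
#'
#' @param charges per-atom reference charges (e).
#' @param aqueous_polarization lambda >= 1 (dimensionless).
#' @param noise_sigma Gaussian noise width (Hartree/e), >= 0.
#' @param seed integer RNG seed recorded in grid provenance.
#' @return an object of class `"reference_charge_model"`.
#' @export
reference_charge_model <- function(charges, aqueous_polarization = 1.2,
                                   noise_sigma = 0, seed = 1L) {
  charges <- as.numeric(charges)
  if (!all(is.finite(charges))) stop("charges must be finite")
  if (aqueous_polarization < 1) stop("aqueous_polarization must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(charges = charges,
                 aqueous_polarization = aqueous_polarization,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "reference_charge_model")
}

#' Electrostatic potential of point charges
#'
#' Coulomb superposition in atomic units: V(p) = sum_i q_i / |p - r_i|,
#' with atom positions converted from Angstrom to Bohr.
#'
#' @param conf a [conformer()] (coordinates in Angstrom).
#' @param charges per-atom charges (e).
#' @param points n x 3 matrix of evaluation points in Bohr.
#' @return numeric vector of potentials (Hartree/e).
#' @export
point_charge_esp <- function(conf, charges, points) {
  stopifnot(inherits(conf, "conformer"))
  charges <- as.numeric(charges)
  if (length(charges) != nrow(conf$coordinates)) {
    stop("one charge per atom required")
  }
  points <- as.matrix(points)
  r <- conf$coordinates * BOHR_PER_ANGSTROM
  v <- numeric(nrow(points))
  for (i in seq_along(charges)) {
    d <- sqrt(rowSums(sweep(points, 2L, r[i, ], "-")^2))
    if (any(d < 0.1)) {
      stop(sprintf("grid point within 0.1 Bohr of nucleus %d (singular)", i))
    }
    v <- v + charges[i] / d
  }
  v
}

#' Phase-specific charges from a reference model
#'
#' Gas phase returns the reference charges unchanged. The aqueous phase
#' applies q' = lambda q + (1 - lambda) Q / N, where Q is the net charge
#' and N the atom count; the sum is preserved exactly for any lambda.
#'
#' @param model a [reference_charge_model()].
#' @param molecule the [molecule()] the charges belong to.
#' @param phase `"gas"` or `"aqueous"`.
#' @return numeric per-atom charges (e).
#' @export
make_phase_charges <- function(model, molecule, phase = c("gas", "aqueous")) {
  stopifnot(inherits(model, "reference_charge_model"),
            inherits(molecule, "molecule"))
  phase <- match.arg(phase)
  q <- model$charges
  if (length(q) != n_atoms(molecule)) stop("charge/atom count mismatch")
  if (abs(sum(q) - molecule$net_charge) > 1e-12) {
    stop(sprintf("reference charges sum to %.15g, not the net charge %d",
                 sum(q), molecule$net_charge))
  }
  if (phase == "gas") return(q)
  lambda <- model$aqueous_polarization
  lambda * q + (1 - lambda) * molecule$net_charge / length(q)
}

#' Synthesize an ESP grid from hidden reference charges
#'
#' Builds the MSK grid for the conformer, evaluates the Coulomb ESP of the
#' phase-appropriate reference charges at its points and adds seeded
#' Gaussian noise of width `noise_sigma`. With zero noise the values equal
#' the point-charge ESP exactly, which makes the generating charges the
#' exact global minimizer of an unrestrained fit.
#'
#' @inheritParams build_msk_grid
#' @param model a [reference_charge_model()].
#' @param phase `"gas"` or `"aqueous"`.
#' @return an [esp_grid()] with values and phase tag set.
#' @export
synthesize_esp <- function(conf, model, settings = grid_settings(),
                           phase = c("gas", "aqueous"), radii = NULL) {
  phase <- match.arg(phase)
  grid <- build_msk_grid(conf, settings, radii)
  q <- make_phase_charges(model, conf$molecule, phase)
  v <- point_charge_esp(conf, q, grid$points)
  seed_used <- model$seed + (phase == "aqueous")
  if (model$noise_sigma > 0) {
    v <- v + with_preserved_rng(seed_used,
                                stats::rnorm(length(v), 0, model$noise_sigma))
  }
  esp_grid(grid$points, v, phase,
           c(grid$provenance,
             sprintf("mock QM ESP: phase %s, lambda %g, noise_sigma %g, seed %d",
                     phase, model$aqueous_polarization, model$noise_sigma,
                     seed_used)))
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# --- idealized geometry helpers -------------------------------------------

# three unit vectors at tetrahedral angle (109.47 deg) from +z, pointing
# downward, at the given azimuths (degrees)
tetra_cap <- function(azimuth_deg, sign_z = -1) {
  az <- azimuth_deg * pi / 180
  t(vapply(az, function(a) {
    c(sqrt(8) / 3 * cos(a), sqrt(8) / 3 * sin(a), sign_z / 3)
  }, numeric(3)))
}

#' Built-in molecule fixtures
#'
#' Idealized small-molecule geometries (standard bond lengths and angles)
#' with plausible reference charges, spanning the chemistry the method
#' targets: water, an alcohol (methanol, two O-H rotamers), alkanes
#' (methane, ethane), an amine (ammonia), a nitrile (acetonitrile) and a
#' cation (methylammonium). Each fixture returns the molecule, its
#' conformers and a [reference_charge_model()] whose charges sum exactly to
#' the net charge.
#'
#' @param name fixture name; see [mock_fixture_names()].
#' @param ... passed to [reference_charge_model()] (e.g. `noise_sigma`,
#'   `seed`, `aqueous_polarization`).
#' @return list with components `molecule`, `conformers`, `model`.
#' @examples
#' fx <- mock_fixture("methanol")
#' length(fx$conformers)
#' @export
mock_fixture <- function(name, ...) {
  builders <- list(
    water = fixture_water, methanol = fixture_methanol,
    methane = fixture_methane, ethane = fixture_ethane,
    ammonia = fixture_ammonia, acetonitrile = fixture_acetonitrile,
    methylammonium = fixture_methylammonium)
  if (!name %in% names(builders)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(builders), collapse = ", "))
  }
  builders[[name]](...)
}

#' @rdname mock_fixture
#' @export
mock_fixture_names <- function() {
  c("water", "methanol", "methane", "ethane", "ammonia",
    "acetonitrile", "methylammonium")
}

fixture_water <- function(...) {
  mol <- molecule(c("O", "H", "H"), rbind(c(1, 2), c(1, 3)), 0L, "water")
  half <- 104.52 / 2 * pi / 180
  xyz <- rbind(c(0, 0, 0),
               0.9572 * c(cos(half), sin(half), 0),
               0.9572 * c(cos(half), -sin(half), 0))
  list(molecule = mol, conformers = list(conformer(mol, xyz)),
       model = reference_charge_model(c(-0.8, 0.4, 0.4), ...))
}

fixture_methanol <- function(...) {
  mol <- molecule(c("C", "O", "H", "H", "H", "H"),
                  rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(2, 6)),
                  0L, "methanol")
  geom <- function(oh_azimuth_deg) {
    c_pos <- c(0, 0, 0); o_pos <- c(0, 0, 1.43)
    hc <- sweep(1.09 * tetra_cap(c(0, 120, 240)), 2L, c_pos, "+")
    a <- 108.5 * pi / 180; phi <- oh_azimuth_deg * pi / 180
    ho <- o_pos + 0.96 * c(sin(a) * cos(phi), sin(a) * sin(phi), -cos(a))
    rbind(c_pos, o_pos, hc, ho)
  }
  # staggered (O-H between two methyl hydrogens) and eclipsed rotamers
  list(molecule = mol,
       conformers = list(conformer(mol, geom(60)), conformer(mol, geom(0))),
       model = reference_charge_model(
         c(0.12, -0.60, 0.04, 0.04, 0.04, 0.36), ...))
}

fixture_methane <- function(...) {
  mol <- molecule(c("C", "H", "H", "H", "H"),
                  cbind(1L, 2:5), 0L, "methane")
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  xyz <- rbind(c(0, 0, 0), 1.09 * dirs)
  list(molecule = mol, conformers = list(conformer(mol, xyz)),
       model = reference_charge_model(c(-0.4, 0.1, 0.1, 0.1, 0.1), ...))
}

fixture_ethane <- function(...) {
  mol <- molecule(c("C", "C", "H", "H", "H", "H", "H", "H"),
                  rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5),
                        c(2, 6), c(2, 7), c(2, 8)),
                  0L, "ethane")
  c1 <- c(0, 0, 0); c2 <- c(0, 0, 1.54)
  h1 <- sweep(1.09 * tetra_cap(c(0, 120, 240), -1), 2L, c1, "+")
  h2 <- sweep(1.09 * tetra_cap(c(60, 180, 300), 1), 2L, c2, "+")
  xyz <- rbind(c1, c2, h1, h2)
  list(molecule = mol, conformers = list(conformer(mol, xyz)),
       model = reference_charge_model(c(-0.06, -0.06, rep(0.02, 6)), ...))
}

fixture_ammonia <- function(...) {
  mol <- molecule(c("N", "H", "H", "H"), cbind(1L, 2:4), 0L, "ammonia")
  alpha <- acos(sqrt(0.1417))  # H-N-H angle ~106.7 deg
  az <- c(0, 120, 240) * pi / 180
  h <- t(vapply(az, function(a) {
    1.01 * c(sin(alpha) * cos(a), sin(alpha) * sin(a), cos(alpha))
  }, numeric(3)))
  xyz <- rbind(c(0, 0, 0), h)
  list(molecule = mol, conformers = list(conformer(mol, xyz)),
       model = reference_charge_model(c(-0.9, 0.3, 0.3, 0.3), ...))
}

fixture_acetonitrile <- function(...) {
  mol <- molecule(c("C", "C", "N", "H", "H", "H"),
                  rbind(c(1, 2, 1), c(2, 3, 3),
                        c(1, 4, 1), c(1, 5, 1), c(1, 6, 1)),
                  0L, "acetonitrile")
  c1 <- c(0, 0, 0); c2 <- c(0, 0, 1.46); n <- c(0, 0, 2.62)
  h <- sweep(1.09 * tetra_cap(c(0, 120, 240), -1), 2L, c1, "+")
  xyz <- rbind(c1, c2, n, h)
  list(molecule = mol, conformers = list(conformer(mol, xyz)),
       model = reference_charge_model(
         c(-0.10, 0.40, -0.48, 0.06, 0.06, 0.06), ...))
}

fixture_methylammonium <- function(...) {
  mol <- molecule(c("C", "N", "H", "H", "H", "H", "H", "H"),
                  rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5),
                        c(2, 6), c(2, 7), c(2, 8)),
                  1L, "methylammonium")
  c1 <- c(0, 0, 0); n <- c(0, 0, 1.50)
  hc <- sweep(1.09 * tetra_cap(c(0, 120, 240), -1), 2L, c1, "+")
  hn <- sweep(1.01 * tetra_cap(c(60, 180, 300), 1), 2L, n, "+")
  xyz <- rbind(c1, n, hc, hn)
  list(molecule = mol, conformers = list(conformer(mol, xyz)),
       model = reference_charge_model(
         c(0.10, -0.30, 0.12, 0.12, 0.12, 0.28, 0.28, 0.28), ...))
}
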