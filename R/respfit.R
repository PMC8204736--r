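#' Fit settings for restrained ESP charge fitting
#'
#' The two-stage protocol uses a weak hyperbolic restraint of 0.005 e/a0^2
#' in stage 1 (all charges free) and a stronger 0.01 e/a0^2 in stage 2
#' (symmetry enforced, apolar refit only), both centered at zero. The
#' hyperbola tightness b = 0.1 e is the classic RESP value; hydrogens are
#' excluded from the restraint by default, following the original RESP
#' convention.
#'
#' @param stage1_restraint restraint strength a1 (e/a0^2).
#' @param stage2_restraint restraint strength a2 (e/a0^2).
#' @param hyperbola_b hyperbola tightness b (e).
#' @param restrain_hydrogens if TRUE hydrogens are restrained too.
#' @param convergence_tol convergence threshold on the max charge update (e).
#' @param max_iterations cap on restraint-reweighting iterations.
#' @return an object of class `"fit_settings"`.
#' @export
fit_settings <- function(stage1_restraint = 0.005, stage2_restraint = 0.01,
                         hyperbola_b = 0.1, restrain_hydrogens = FALSE,
                         convergence_tol = 1e-10, max_iterations = 500L) {
  if (stage1_restraint < 0 || stage2_restraint < 0 || hyperbola_b < 0) {
    stop("restraint strengths and hyperbola_b must be >= 0")
  }
  if (convergence_tol <= 0) stop("convergence_tol must be > 0")
  structure(list(stage1_restraint = stage1_restraint,
                 stage2_restraint = stage2_restraint,
                 hyperbola_b = hyperbola_b,
                 restrain_hydrogens = isTRUE(restrain_hydrogens),
                 convergence_tol = convergence_tol,
                 max_iterations = as.integer(max_iterations)),
            class = "fit_settings")
}

#' Equality constraints for a charge fit
#'
#' @param total_charge target total charge (e).
#' @param equivalence_groups list of integer vectors of atom indices forced
#'   to carry equal charges; groups must be disjoint.
#' @param frozen named numeric vector of fixed charges, names = atom
#'   indices; frozen atoms may not appear in equivalence groups.
#' @param n_atoms number of atoms of the molecule being fitted.
#' @return an object of class `"constraint_set"`.
#' @export
constraint_set <- function(total_charge, equivalence_groups = list(),
                           frozen = numeric(0), n_atoms) {
  frozen_idx <- as.integer(names(frozen))
  if (length(frozen) > 0L && (anyNA(frozen_idx) ||
                              any(frozen_idx < 1L | frozen_idx > n_atoms))) {
    stop("frozen must be a named vector with atom-index names in range")
  }
  if (anyDuplicated(frozen_idx)) stop("duplicate frozen atom")
  grp_atoms <- unlist(equivalence_groups)
  if (length(grp_atoms) > 0L) {
    if (any(grp_atoms < 1L | grp_atoms > n_atoms)) {
      stop("equivalence-group atom index out of range")
    }
    if (anyDuplicated(grp_atoms)) stop("equivalence groups must be disjoint")
    if (length(intersect(grp_atoms, frozen_idx)) > 0L) {
      stop("frozen atoms may not appear in equivalence groups")
    }
  }
  free <- setdiff(seq_len(n_atoms), frozen_idx)
  if (length(free) == 0L &&
      abs(sum(frozen) - total_charge) > 1e-9) {
    stop("infeasible constraints: all atoms frozen but frozen charges sum to ",
         sum(frozen), ", not ", total_charge)
  }
  structure(list(total_charge = total_charge,
                 equivalence_groups = lapply(equivalence_groups, as.integer),
                 frozen = frozen,
                 free = free,
                 n_atoms = as.integer(n_atoms)),
            class = "constraint_set")
}

#' Charge set container
#'
#' @param charges per-atom charges (e).
#' @param phase `"gas"`, `"aqueous"` or `"mixed"`.
#' @param molecule the [molecule()] the charges belong to.
#' @param delta mixing parameter in `[0, 1]`; required iff phase is mixed.
#' @param metadata list of fit metadata (restraints, iterations, residual).
#' @return an object of class `"charge_set"`.
#' @export
charge_set <- function(charges, phase, molecule, delta = NULL,
                       metadata = list()) {
  stopifnot(inherits(molecule, "molecule"))
  charges <- as.numeric(charges)
  if (length(charges) != n_atoms(molecule)) stop("one charge per atom required")
  if (!phase %in% c("gas", "aqueous", "mixed")) {
    stop("phase must be gas, aqueous or mixed")
  }
  if (phase == "mixed") {
    if (is.null(delta)) stop("delta required for mixed charge sets")
    if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]")
  } else if (!is.null(delta)) {
    stop("delta only allowed for mixed charge sets")
  }
  if (abs(sum(charges) - molecule$net_charge) > 1e-10) {
    stop(sprintf("charges sum to %.12g, not the net charge %d",
                 sum(charges), molecule$net_charge))
  }
  structure(list(charges = charges, phase = phase, delta = delta,
                 molecule_name = molecule$name,
                 net_charge = molecule$net_charge,
                 elements = molecule$elements,
                 metadata = metadata),
            class = "charge_set")
}

#' @export
print.charge_set <- function(x, digits = 4, ...) {
  tag <- if (x$phase == "mixed") sprintf("mixed (delta = %g)", x$delta) else x$phase
  cat(sprintf("Charge set for '%s' [%s], sum %+.*f e\n",
              x$molecule_name, tag, digits, sum(x$charges)))
  print(data.frame(atom = seq_along(x$charges), element = x$elements,
                   charge = round(x$charges, digits)), row.names = FALSE)
  invisible(x)
}

# design matrix rows for one grid: A[p, i] = 1 / |p - r_i| (Bohr)
esp_design_matrix <- function(conf, points) {
  r <- conf$coordinates * BOHR_PER_ANGSTROM
  n <- nrow(r)
  a <- matrix(0, nrow(points), n)
  for (i in seq_len(n)) {
    a[, i] <- 1 / sqrt(rowSums(sweep(points, 2L, r[i, ], "-")^2))
  }
  a
}

# reduction matrix T (n_atoms x n_params): equivalence groups collapse to a
# single column, frozen atoms map to no column
reduction_matrix <- function(constraints) {
  n <- constraints$n_atoms
  in_group <- rep(0L, n)
  for (g in seq_along(constraints$equivalence_groups)) {
    in_group[constraints$equivalence_groups[[g]]] <- g
  }
  frozen_idx <- as.integer(names(constraints$frozen))
  cols <- list()
  param_of_atom <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (i %in% frozen_idx) next
    if (in_group[i] > 0L) {
      key <- paste0("g", in_group[i])
    } else {
      key <- paste0("a", i)
    }
    if (is.null(cols[[key]])) cols[[key]] <- integer(0)
    cols[[key]] <- c(cols[[key]], i)
    param_of_atom[i] <- match(key, names(cols))
  }
  m <- length(cols)
  tmat <- matrix(0, n, m)
  for (j in seq_len(m)) tmat[cols[[j]], j] <- 1
  list(t = tmat, param_of_atom = param_of_atom)
}

#' Multi-conformer restrained ESP charge fit
#'
#' Minimizes the summed squared ESP misfit over all conformer grids plus a
#' hyperbolic restraint a * (sqrt(q^2 + b^2) - b) on each restrained atom,
#' subject to the total-charge constraint, equivalence equalities and
#' frozen charges. Conformers enter with equal weight: every grid point
#' contributes one least-squares row. The hyperbolic restraint is handled
#' by the classic RESP fixed point: the restraint contributes a diagonal
#' a / sqrt(q_prev^2 + b^2) refreshed from the previous iterate, starting
#' from the unrestrained constrained solution, until the largest charge
#' update falls below `convergence_tol`. Equality constraints are applied
#' exactly by column-collapsing the design matrix; the total-charge
#' constraint enters as a Lagrange row.
#'
#' @param grids list of [esp_grid()]s with values, one per conformer, all of
#'   one phase.
#' @param conformers list of [conformer()]s aligned 1:1 with `grids`.
#' @param constraints a [constraint_set()].
#' @param restraint restraint strength a (e/a0^2).
#' @param settings a [fit_settings()] (supplies b, tolerance, iteration cap,
#'   hydrogen-restraint flag).
#' @return a [charge_set()] with fit metadata.
#' @export
solve_restrained_fit <- function(grids, conformers, constraints, restraint,
                                 settings = fit_settings()) {
  if (length(grids) != length(conformers) || length(grids) == 0L) {
    stop("grids and conformers must align 1:1 and be non-empty")
  }
  molecule <- conformers[[1L]]$molecule
  n <- n_atoms(molecule)
  phases <- vapply(grids, function(g) g$phase, character(1))
  if (anyNA(phases)) stop("every grid needs its phase tag set before fitting")
  if (length(unique(phases)) != 1L) stop("grids mix phases")
  for (g in grids) {
    if (is.null(g$values)) stop("grid without ESP values")
  }
  red <- reduction_matrix(constraints)
  tmat <- red$t
  m <- ncol(tmat)
  frozen_idx <- as.integer(names(constraints$frozen))
  f <- numeric(n)
  f[frozen_idx] <- constraints$frozen
  if (m == 0L) {
    return(charge_set(f, phases[1L], molecule,
                      metadata = list(restraint = restraint, iterations = 0L,
                                      rms_residual = NA_real_)))
  }
  for (g in grids) {
    if (nrow(g$points) < m) {
      stop("a grid has fewer points than free parameters")
    }
  }
  ata <- matrix(0, m, m)
  atb <- numeric(m)
  n_points <- 0L
  ss_v <- 0
  design <- vector("list", length(grids))
  for (k in seq_along(grids)) {
    a_full <- esp_design_matrix(conformers[[k]], grids[[k]]$points)
    design[[k]] <- a_full
    at <- a_full %*% tmat
    b <- grids[[k]]$values - a_full %*% f
    ata <- ata + crossprod(at)
    atb <- atb + drop(crossprod(at, b))
    n_points <- n_points + nrow(a_full)
    ss_v <- ss_v + sum(b^2)
  }
  # restrained atoms: free heavy atoms (plus hydrogens if requested)
  restrained <- constraints$free
  if (!settings$restrain_hydrogens) {
    restrained <- restrained[molecule$elements[restrained] != "H"]
  }
  csum <- colSums(tmat)                 # atoms per reduced parameter
  q_target <- constraints$total_charge - sum(constraints$frozen)
  b_hyp <- settings$hyperbola_b
  solve_kkt <- function(diag_w) {
    bmat <- ata
    diag(bmat) <- diag(bmat) + diag_w
    kkt <- rbind(cbind(bmat, csum), c(csum, 0))
    qr_k <- qr(kkt)
    if (qr_k$rank < ncol(kkt)) {
      stop("rank-deficient design after constraint reduction")
    }
    sol <- qr.coef(qr_k, c(atb, q_target))
    sol[seq_len(m)]
  }
  u <- solve_kkt(numeric(m))
  q <- drop(tmat %*% u) + f
  iterations <- 0L
  if (restraint > 0 && length(restrained) > 0L) {
    repeat {
      iterations <- iterations + 1L
      w_atom <- numeric(n)
      w_atom[restrained] <- restraint / sqrt(q[restrained]^2 + b_hyp^2)
      diag_w <- colSums(tmat * w_atom)  # per-parameter restraint weight
      u_new <- solve_kkt(diag_w)
      q_new <- drop(tmat %*% u_new) + f
      delta_max <- max(abs(q_new - q))
      q <- q_new
      if (delta_max <= settings$convergence_tol) break
      if (iterations >= settings$max_iterations) {
        stop(sprintf(
          "restraint iteration did not converge in %d iterations (last max update %.3g e)",
          settings$max_iterations, delta_max))
      }
    }
  }
  rss <- 0
  for (k in seq_along(grids)) {
    rss <- rss + sum((grids[[k]]$values - design[[k]] %*% q)^2)
  }
  charge_set(q, phases[1L], molecule,
             metadata = list(restraint = restraint,
                             restrained_atoms = restrained,
                             iterations = iterations,
                             n_points = n_points,
                             rms_residual = sqrt(rss / n_points)))
}

#' Mix gas- and aqueous-phase charge sets
#'
#' Per-atom linear combination q = (1 - delta) q_gas + delta q_aqueous.
#' delta = 0 reproduces the gas set, delta = 1 the aqueous set, and
#' delta = 0.5 the per-atom mean; the total charge is independent of delta.
#'
#' @param q_gas gas-phase [charge_set()].
#' @param q_aqueous aqueous-phase [charge_set()].
#' @param delta mixing parameter in `[0, 1]`.
#' @return a mixed [charge_set()].
#' @export
mix_charges <- function(q_gas, q_aqueous, delta) {
  stopifnot(inherits(q_gas, "charge_set"), inherits(q_aqueous, "charge_set"))
  if (q_gas$phase != "gas" || q_aqueous$phase != "aqueous") {
    stop("arguments must be a gas-phase and an aqueous-phase charge set")
  }
  if (q_gas$molecule_name != q_aqueous$molecule_name ||
      length(q_gas$charges) != length(q_aqueous$charges) ||
      q_gas$net_charge != q_aqueous$net_charge) {
    stop("charge sets belong to different molecules")
  }
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0 || delta > 1) {
    stop("delta must be a single value in [0, 1]")
  }
  q <- (1 - delta) * q_gas$charges + delta * q_aqueous$charges
  mol <- structure(list(name = q_gas$molecule_name,
                        elements = q_gas$elements,
                        bonds = matrix(integer(0), ncol = 3L),
                        net_charge = q_gas$net_charge),
                   class = "molecule")
  charge_set(q, "mixed", mol, delta = delta,
             metadata = list(gas = q_gas$metadata, aqueous = q_aqueous$metadata))
}

#' Dipole moment from point charges
#'
#' mu = sum_i q_i r_i in e*Angstrom; the magnitude is also reported in
#' Debye (4.80321 D per e*Angstrom). For neutral molecules the dipole is
#' origin-independent; for ions it is computed about the center of nuclear
#' charge, with a warning.
#'
#' @param conf a [conformer()].
#' @param charges a [charge_set()] or numeric per-atom charges (e).
#' @return list with `vector` (e*Angstrom) and `magnitude_debye`.
#' @export
dipole_from_charges <- function(conf, charges) {
  stopifnot(inherits(conf, "conformer"))
  q <- if (inherits(charges, "charge_set")) charges$charges else as.numeric(charges)
  if (length(q) != nrow(conf$coordinates)) stop("one charge per atom required")
  r <- conf$coordinates
  if (abs(sum(q)) > 1e-9) {
    z <- conf$molecule$atomic_numbers
    origin <- colSums(z * r) / sum(z)
    warning("net charge is nonzero; dipole computed about the center of nuclear charge")
    r <- sweep(r, 2L, origin, "-")
  }
  mu <- colSums(q * r)
  list(vector = mu, magnitude_debye = sqrt(sum(mu^2)) * DEBYE_PER_E_ANGSTROM)
}
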