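#' Lennard-Jones parameter set over the five atom types
#'
#' @param epsilon named vector of well depths (kJ/mol), one per type in
#'   [lj_type_names()].
#' @param rmin_half named vector of r_min-half values (Angstrom).
#' @return an object of class `"lj_parameter_set"`; `as.numeric()` yields
#'   the flat length-10 physical vector (epsilon then rmin_half per type).
#' @export
lj_parameter_set <- function(epsilon, rmin_half) {
  types <- lj_type_names()
  epsilon <- epsilon[types]; rmin_half <- rmin_half[types]
  if (anyNA(epsilon) || anyNA(rmin_half)) {
    stop("epsilon and rmin_half must be named with all five LJ types")
  }
  if (any(epsilon < 0)) stop("epsilon must be >= 0")
  if (any(rmin_half <= 0)) stop("rmin_half must be > 0")
  structure(list(epsilon = epsilon, rmin_half = rmin_half),
            class = "lj_parameter_set")
}

#' @export
as.double.lj_parameter_set <- function(x, ...) {
  types <- lj_type_names()
  stats::setNames(c(rbind(x$epsilon, x$rmin_half)),
                  c(rbind(paste0(types, ".epsilon"),
                          paste0(types, ".rmin_half"))))
}

#' @export
print.lj_parameter_set <- function(x, ...) {
  print(data.frame(type = lj_type_names(),
                   epsilon_kJ_mol = unname(x$epsilon),
                   rmin_half_A = unname(x$rmin_half)), row.names = FALSE)
  invisible(x)
}

#' Physical-to-mathematical parameter mapping
#'
#' Physical parameters K are shifted by their initial values K0 and scaled
#' by prior widths t: k_i = (K_i - K0_i) / t_i. Default prior widths are
#' 0.4184 kJ/mol for every epsilon and 1.0 Angstrom for every r_min-half.
#'
#' @param k0 initial physical parameter vector (named, length 10 for the
#'   five-type LJ scheme, but any labelled vector is accepted).
#' @param priors per-parameter prior widths t (same length as `k0`); if
#'   NULL, derived from names ending in `.epsilon` / `.rmin_half`.
#' @return an object of class `"parameter_mapping"`.
#' @export
parameter_mapping <- function(k0, priors = NULL) {
  if (inherits(k0, "lj_parameter_set")) k0 <- as.numeric(k0)
  k0 <- unlist(k0)
  if (is.null(priors)) {
    if (is.null(names(k0))) stop("priors required when k0 is unnamed")
    priors <- ifelse(grepl("\\.epsilon$", names(k0)), 0.4184,
                     ifelse(grepl("\\.rmin_half$", names(k0)), 1.0, NA_real_))
    if (anyNA(priors)) stop("cannot infer priors from parameter names")
    priors <- stats::setNames(priors, names(k0))
  }
  priors <- unlist(priors)
  if (length(priors) != length(k0)) stop("priors and k0 lengths differ")
  if (any(priors <= 0)) stop("prior widths must be > 0")
  structure(list(k0 = k0, priors = priors), class = "parameter_mapping")
}

#' Map physical parameters to mathematical parameters and back
#'
#' @param physical physical parameter vector K.
#' @param mapping a [parameter_mapping()].
#' @return `map_parameters()`: mathematical vector k = (K - K0)/t;
#'   `unmap_parameters()`: physical vector K = K0 + t*k.
#' @export
map_parameters <- function(physical, mapping) {
  stopifnot(inherits(mapping, "parameter_mapping"))
  if (inherits(physical, "lj_parameter_set")) physical <- as.numeric(physical)
  if (length(physical) != length(mapping$k0)) stop("length mismatch")
  (physical - mapping$k0) / mapping$priors
}

#' @rdname map_parameters
#' @param mathematical mathematical parameter vector k.
#' @export
unmap_parameters <- function(mathematical, mapping) {
  stopifnot(inherits(mapping, "parameter_mapping"))
  if (length(mathematical) != length(mapping$k0)) stop("length mismatch")
  mapping$k0 + mapping$priors * mathematical
}

# default unit-removal scales d_p; dielectric and HFE have no published
# scale and must be user-supplied
default_property_scale <- function(kind) {
  switch(kind, HOV = 0.3, density = 30, NA_real_)
}

#' Single-property objective contribution
#'
#' L = (y - y_ref)^2 / d^2: the squared deviation, made dimensionless by
#' the property scale d (0.3 kJ/mol for heats of vaporization, 30 kg/m^3
#' for densities).
#'
#' @param y predicted property value.
#' @param y_ref reference (experimental) value, same units.
#' @param d_p property scale, same units.
#' @return dimensionless non-negative contribution.
#' @export
property_residual <- function(y, y_ref, d_p) {
  if (!is.finite(d_p) || d_p <= 0) stop("property scale d_p must be > 0")
  (y - y_ref)^2 / d_p^2
}

#' Property dataset entry
#'
#' @param molecule molecule identifier.
#' @param kind one of `"density"`, `"HOV"`, `"dielectric"`, `"HFE"`.
#' @param y_ref reference value (kg/m^3, kJ/mol, dimensionless, kJ/mol).
#' @param d_p property scale; defaults to 0.3 kJ/mol for HOV and
#'   30 kg/m^3 for density, and must be supplied for dielectric and HFE.
#' @return one-row data.frame; rows can be `rbind`-ed into a dataset.
#' @export
property_datum <- function(molecule, kind, y_ref, d_p = NULL) {
  kind <- match.arg(kind, c("density", "HOV", "dielectric", "HFE"))
  if (is.null(d_p)) d_p <- default_property_scale(kind)
  if (!is.finite(d_p) || d_p <= 0) {
    stop("property scale d_p must be supplied (> 0) for kind '", kind, "'")
  }
  data.frame(molecule = molecule, kind = kind, y_ref = y_ref, d_p = d_p,
             stringsAsFactors = FALSE)
}

#' Regularized property objective
#'
#' @param mapping a [parameter_mapping()].
#' @param dataset data.frame of [property_datum()] rows (may be empty).
#' @param provider function(K_physical, molecule, kind) -> predicted value.
#' @param w_reg Tikhonov regularization weight (default 10).
#' @return an object of class `"objective_spec"`.
#' @export
objective_spec <- function(mapping, dataset = NULL, provider = NULL,
                           w_reg = 10) {
  stopifnot(inherits(mapping, "parameter_mapping"))
  if (is.null(dataset)) {
    dataset <- data.frame(molecule = character(0), kind = character(0),
                          y_ref = numeric(0), d_p = numeric(0))
  }
  if (nrow(dataset) > 0L && !is.function(provider)) {
    stop("a provider function is required for a non-empty dataset")
  }
  if (w_reg < 0) stop("w_reg must be >= 0")
  structure(list(mapping = mapping, dataset = dataset, provider = provider,
                 w_reg = w_reg),
            class = "objective_spec")
}

#' Evaluate the regularized objective
#'
#' L(k) = sum over molecules m and properties p of
#' (y_p^m(k) - y_ref)^2 / d_p^2, plus w_reg |k|^2. The per-datum
#' breakdown sums to L exactly.
#'
#' @param k mathematical parameter vector.
#' @param spec an [objective_spec()].
#' @return list with `value`, `regularization`, and `breakdown` (the
#'   dataset with predicted values and contributions).
#' @export
objective <- function(k, spec) {
  stopifnot(inherits(spec, "objective_spec"))
  physical <- unmap_parameters(k, spec$mapping)
  ds <- spec$dataset
  contrib <- numeric(nrow(ds))
  pred <- numeric(nrow(ds))
  for (r in seq_len(nrow(ds))) {
    y <- tryCatch(spec$provider(physical, ds$molecule[r], ds$kind[r]),
                  error = function(e) {
                    stop(sprintf("provider failed for %s/%s: %s",
                                 ds$molecule[r], ds$kind[r], conditionMessage(e)))
                  })
    if (!is.finite(y)) {
      stop(sprintf("provider returned non-finite value for %s/%s",
                   ds$molecule[r], ds$kind[r]))
    }
    pred[r] <- y
    contrib[r] <- property_residual(y, ds$y_ref[r], ds$d_p[r])
  }
  reg <- spec$w_reg * sum(k^2)
  breakdown <- ds
  breakdown$predicted <- pred
  breakdown$contribution <- contrib
  list(value = sum(contrib) + reg, regularization = reg,
       breakdown = breakdown)
}

#' Trajectory summary for liquid-property estimation
#'
#' Per-frame post-processing data from a finished simulation: potential
#' energies (kJ/mol), box volumes (nm^3) and box dipole vectors (e*nm).
#'
#' @param energies per-frame potential energies (kJ/mol).
#' @param volumes per-frame box volumes (nm^3), liquid phase only.
#' @param dipoles per-frame box dipole vectors, n x 3 matrix (e*nm).
#' @param n_molecules molecules in the box.
#' @param temperature K.
#' @param pressure atm.
#' @param molar_mass g/mol.
#' @return an object of class `"trajectory_summary"`.
#' @export
trajectory_summary <- function(energies, volumes = NULL, dipoles = NULL,
                               n_molecules = 1L, temperature = 298,
                               pressure = 1, molar_mass = NA_real_) {
  energies <- as.numeric(energies)
  if (length(energies) < 1L) stop("at least one frame required")
  if (!is.null(volumes)) {
    volumes <- as.numeric(volumes)
    if (length(volumes) != length(energies)) stop("frame count mismatch (volumes)")
  }
  if (!is.null(dipoles)) {
    dipoles <- as.matrix(dipoles)
    if (ncol(dipoles) != 3L || nrow(dipoles) != length(energies)) {
      stop("dipoles must be an n_frames x 3 matrix")
    }
  }
  if (n_molecules < 1L) stop("n_molecules must be >= 1")
  if (temperature <= 0) stop("temperature must be > 0")
  structure(list(energies = energies, volumes = volumes, dipoles = dipoles,
                 n_molecules = as.integer(n_molecules),
                 temperature = temperature, pressure = pressure,
                 molar_mass = molar_mass),
            class = "trajectory_summary")
}

#' Heat of vaporization from gas- and liquid-phase summaries
#'
#' HOV = <U_gas> - <U_liquid>/n_molecules + R T, with
#' R = 0.0083145 kJ/(mol K).
#'
#' @param gas,liquid [trajectory_summary()] objects at the same temperature.
#' @return heat of vaporization (kJ/mol).
#' @export
hov_from_summaries <- function(gas, liquid) {
  stopifnot(inherits(gas, "trajectory_summary"),
            inherits(liquid, "trajectory_summary"))
  if (abs(gas$temperature - liquid$temperature) > 1e-9) {
    stop("gas and liquid summaries are at different temperatures")
  }
  mean(gas$energies) / gas$n_molecules -
    mean(liquid$energies) / liquid$n_molecules +
    GAS_CONSTANT_KJ * gas$temperature
}

#' Liquid density from the mean box volume
#'
#' rho = n M / (N_A <V>) in kg/m^3.
#'
#' @param liquid a [trajectory_summary()] with volumes and molar mass.
#' @return density (kg/m^3).
#' @export
density_from_summaries <- function(liquid) {
  stopifnot(inherits(liquid, "trajectory_summary"))
  if (is.null(liquid$volumes)) stop("liquid summary has no volumes")
  if (any(liquid$volumes <= 0)) stop("volumes must be positive")
  if (!is.finite(liquid$molar_mass)) stop("molar mass not set")
  mean_v_m3 <- mean(liquid$volumes) * 1e-27
  liquid$n_molecules * liquid$molar_mass * 1e-3 / (AVOGADRO * mean_v_m3)
}

#' Static dielectric constant from box-dipole fluctuations
#'
#' eps = 1 + (<M.M> - <M>.<M>) / (3 eps0 <V> kB T), with the box dipole M
#' converted from e*nm to C*m and the volume to m^3.
#'
#' @param liquid a [trajectory_summary()] with dipoles and volumes.
#' @return dielectric constant (>= 1).
#' @export
dielectric_from_summaries <- function(liquid) {
  stopifnot(inherits(liquid, "trajectory_summary"))
  if (is.null(liquid$dipoles)) stop("liquid summary has no box dipoles")
  if (nrow(liquid$dipoles) < 2L) stop("at least two frames required")
  if (is.null(liquid$volumes)) stop("liquid summary has no volumes")
  m <- liquid$dipoles * ELEMENTARY_CHARGE_C * 1e-9   # C*m
  msq <- mean(rowSums(m^2))
  mbar <- colMeans(m)
  fluct <- msq - sum(mbar^2)
  mean_v <- mean(liquid$volumes) * 1e-27             # m^3
  1 + fluct / (3 * VACUUM_PERMITTIVITY * mean_v *
                 BOLTZMANN_J * liquid$temperature)
}

#' Mean unsigned error
#'
#' @param values_model,values_expt equal-length numeric vectors.
#' @return mean absolute deviation.
#' @export
mue <- function(values_model, values_expt) {
  if (length(values_model) != length(values_expt)) stop("length mismatch")
  if (length(values_model) < 1L) stop("at least one value pair required")
  mean(abs(values_model - values_expt))
}

#' Mean relative error against a baseline model
#'
#' E = (1/N_P) sum_j (E_j^model - E_j^baseline) / E_j^baseline over the
#' per-property mean unsigned errors.
#'
#' @param e_model,e_baseline per-property MUE vectors (same length); all
#'   baseline entries must be > 0.
#' @return mean relative error (dimensionless; negative means better than
#'   baseline).
#' @export
relative_error_profile <- function(e_model, e_baseline) {
  if (length(e_model) != length(e_baseline)) stop("length mismatch")
  if (length(e_model) < 1L) stop("at least one property required")
  if (any(e_baseline <= 0)) stop("baseline MUEs must be > 0")
  mean((e_model - e_baseline) / e_baseline)
}

#' Derivative-free objective minimization with step/objective stopping
#'
#' Compass (coordinate-poll) search in mathematical-parameter space:
#' at each iteration the objective is polled at +/- step along every
#' coordinate; the best improving poll is accepted (so accepted-step
#' objective values never increase), otherwise the step is halved.
#' Terminates when the accepted step size ||dk|| falls below `step_tol`
#' (default 0.01), when the objective change of an accepted step falls
#' below `obj_tol` (default 1.0), or at `max_iter` evaluated iterations.
#'
#' @param spec an [objective_spec()].
#' @param k_start starting mathematical parameter vector.
#' @param step0 initial poll step size.
#' @param step_tol stopping threshold on the accepted step norm.
#' @param obj_tol stopping threshold on the objective decrease.
#' @param max_iter iteration cap.
#' @return list with `k` (final parameters), `physical` (unmapped), `value`
#'   (final objective), `trace` (data.frame of accepted (iteration, L,
#'   step) with the k vectors in `trace_k`), and `converged`
#'   (the stopping rule that fired).
#' @export
optimize_objective <- function(spec, k_start, step0 = 0.5,
                               step_tol = 0.01, obj_tol = 1.0,
                               max_iter = 10000L) {
  stopifnot(inherits(spec, "objective_spec"))
  k <- as.numeric(k_start)
  l <- objective(k, spec)$value
  step <- step0
  trace_k <- list(k)
  trace <- data.frame(iteration = 0L, L = l, step = NA_real_)
  converged <- "max_iter"
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    best_l <- l
    best_k <- NULL
    for (j in seq_along(k)) {
      for (s in c(-1, 1)) {
        kc <- k
        kc[j] <- kc[j] + s * step
        lc <- objective(kc, spec)$value
        if (lc < best_l) { best_l <- lc; best_k <- kc }
      }
    }
    if (is.null(best_k)) {
      step <- step / 2
      if (step < step_tol) { converged <- "step_size"; break }
      next
    }
    dl <- l - best_l
    k <- best_k
    l <- best_l
    trace_k[[length(trace_k) + 1L]] <- k
    trace <- rbind(trace, data.frame(iteration = iter, L = l, step = step))
    if (step < step_tol) { converged <- "step_size"; break }
    if (dl < obj_tol) { converged <- "objective_change"; break }
  }
  list(k = k, physical = unmap_parameters(k, spec$mapping), value = l,
       trace = trace, trace_k = trace_k, converged = converged)
}
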