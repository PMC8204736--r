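#' Two-stage restrained ESP fit for one phase
#'
#' Stage 1 fits all charges independently under the weak restraint
#' (default 0.005 e/a0^2). Stage 2 enforces chemical symmetry and refits
#' only the apolar parts — carbons bearing at least one nonpolar hydrogen
#' together with those hydrogens — under the stronger restraint (default
#' 0.01 e/a0^2), with every other atom frozen at its stage-1 value and
#' equivalence groups taken from the topological symmetry classes
#' restricted to the refit set. If the refit set is empty (no apolar C-H
#' group) the stage-1 result is returned unchanged.
#'
#' @param molecule a [molecule()].
#' @param conformers list of [conformer()]s of that molecule.
#' @param grids list of [esp_grid()]s with values, one per conformer, all
#'   tagged with the same phase.
#' @param settings a [fit_settings()].
#' @return an object of class `"resp_fit"`: components `charges` (final
#'   [charge_set()]), `stage1` (stage-1 charge set), `refit_set`,
#'   `molecule`, `conformers`, `grids`, `settings`.
#' @examples
#' fx <- mock_fixture("methanol")
#' grids <- lapply(fx$conformers, synthesize_esp, model = fx$model,
#'                 phase = "gas")
#' fit <- two_stage_fit(fx$molecule, fx$conformers, grids)
#' coef(fit)
#' @export
two_stage_fit <- function(molecule, conformers, grids,
                          settings = fit_settings()) {
  stopifnot(inherits(molecule, "molecule"))
  n <- n_atoms(molecule)
  stage1 <- solve_restrained_fit(
    grids, conformers,
    constraint_set(molecule$net_charge, n_atoms = n),
    restraint = settings$stage1_restraint, settings = settings)

  polar_h <- classify_polar_hydrogens(molecule)
  hydrogens <- which(molecule$elements == "H")
  nonpolar_h <- setdiff(hydrogens, polar_h)
  adj <- adjacency_list(molecule)
  refit_c <- which(vapply(seq_len(n), function(i) {
    molecule$elements[i] == "C" && any(adj[[i]] %in% nonpolar_h)
  }, logical(1)))
  refit_h <- intersect(unlist(adj[refit_c]), nonpolar_h)
  refit <- sort(c(refit_c, refit_h))

  if (length(refit) == 0L) {
    final <- stage1
    final$metadata <- c(final$metadata, list(stage2 = "skipped (no apolar C-H group)"))
  } else {
    classes <- assign_symmetry_classes(molecule)
    groups <- split(refit, classes[refit])
    groups <- unname(groups[vapply(groups, length, integer(1)) >= 2L])
    frozen_idx <- setdiff(seq_len(n), refit)
    frozen <- stats::setNames(stage1$charges[frozen_idx], frozen_idx)
    final <- solve_restrained_fit(
      grids, conformers,
      constraint_set(molecule$net_charge, equivalence_groups = groups,
                     frozen = frozen, n_atoms = n),
      restraint = settings$stage2_restraint, settings = settings)
    final$metadata <- list(stage1 = stage1$metadata, stage2 = final$metadata)
  }
  structure(list(charges = final, stage1 = stage1, refit_set = refit,
                 molecule = molecule, conformers = conformers, grids = grids,
                 settings = settings),
            class = "resp_fit")
}

#' @export
coef.resp_fit <- function(object, ...) {
  stats::setNames(object$charges$charges,
                  paste0(object$molecule$elements,
                         seq_along(object$charges$charges)))
}

#' @export
print.resp_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-stage restrained ESP fit: '%s', phase %s, %d conformer(s)\n",
              x$molecule$name, x$charges$phase, length(x$conformers)))
  print(round(coef(x), digits))
  invisible(x)
}

#' @export
fitted.resp_fit <- function(object, ...) {
  lapply(seq_along(object$grids), function(k) {
    point_charge_esp(object$conformers[[k]], object$charges$charges,
                     object$grids[[k]]$points)
  })
}

#' @export
residuals.resp_fit <- function(object, ...) {
  fit <- fitted(object)
  lapply(seq_along(fit), function(k) object$grids[[k]]$values - fit[[k]])
}

#' Predict the ESP of a fitted charge set at arbitrary points
#'
#' @param object a `"resp_fit"`.
#' @param points n x 3 matrix of points (Bohr).
#' @param conformer_index which conformer geometry to use.
#' @param ... unused.
#' @return numeric potentials (Hartree/e).
#' @export
predict.resp_fit <- function(object, points, conformer_index = 1L, ...) {
  point_charge_esp(object$conformers[[conformer_index]],
                   object$charges$charges, as.matrix(points))
}

#' @export
summary.resp_fit <- function(object, ...) {
  res <- residuals(object)
  out <- list(molecule = object$molecule$name,
              phase = object$charges$phase,
              n_conformers = length(object$conformers),
              n_points = sum(vapply(object$grids,
                                    function(g) nrow(g$points), numeric(1))),
              refit_set = object$refit_set,
              charges = coef(object),
              rms_residual = sqrt(mean(unlist(res)^2)))
  class(out) <- "summary.resp_fit"
  out
}

#' @export
print.summary.resp_fit <- function(x, ...) {
  cat(sprintf("Two-stage fit of '%s' [%s]: %d conformer(s), %d ESP points\n",
              x$molecule, x$phase, x$n_conformers, x$n_points))
  cat(sprintf("Stage-2 refit atoms: %s\n",
              if (length(x$refit_set)) paste(x$refit_set, collapse = ", ")
              else "none"))
  print(round(x$charges, 4))
  cat(sprintf("RMS ESP residual: %.3e Hartree/e\n", x$rms_residual))
  invisible(x)
}

#' Derive delta-mixed charges from gas- and aqueous-phase ESP grids
#'
#' The full pipeline: a two-stage restrained fit against the gas-phase
#' grids of all conformers, a second independent fit against the
#' aqueous-phase grids, and a per-atom linear combination
#' q = (1 - delta) q_gas + delta q_aqueous. delta tunes the polarity of
#' the final charges between the gas-phase (delta = 0) and aqueous-phase
#' (delta = 1) limits; 0.6 is the recommended default.
#'
#' @param molecule a [molecule()].
#' @param conformers list of [conformer()]s.
#' @param gas_grids,aqueous_grids lists of [esp_grid()]s with values, one
#'   per conformer, tagged gas / aqueous.
#' @param delta mixing parameter in `[0, 1]`.
#' @param settings a [fit_settings()].
#' @return an object of class `"resp2"`: components `gas` and `aqueous`
#'   (two [two_stage_fit()] objects), `charges` (mixed [charge_set()]),
#'   `delta`, `molecule`, `conformers`.
#' @examples
#' fx <- mock_fixture("water")
#' gas <- lapply(fx$conformers, synthesize_esp, model = fx$model, phase = "gas")
#' aq <- lapply(fx$conformers, synthesize_esp, model = fx$model, phase = "aqueous")
#' model <- resp2(fx$molecule, fx$conformers, gas, aq, delta = 0.6)
#' coef(model)
#' @export
resp2 <- function(molecule, conformers, gas_grids, aqueous_grids,
                  delta = 0.6, settings = fit_settings()) {
  gas <- two_stage_fit(molecule, conformers, gas_grids, settings)
  aqueous <- two_stage_fit(molecule, conformers, aqueous_grids, settings)
  mixed <- mix_charges(gas$charges, aqueous$charges, delta)
  structure(list(gas = gas, aqueous = aqueous, charges = mixed,
                 delta = delta, molecule = molecule, conformers = conformers,
                 settings = settings),
            class = "resp2")
}

#' Extract charges from a delta-mixed fit
#'
#' @param object a `"resp2"` model.
#' @param delta optionally re-mix at a different delta without refitting.
#' @param ... unused.
#' @return named per-atom charges (e).
#' @export
coef.resp2 <- function(object, delta = NULL, ...) {
  q <- if (is.null(delta)) object$charges
       else mix_charges(object$gas$charges, object$aqueous$charges, delta)
  stats::setNames(q$charges,
                  paste0(object$molecule$elements, seq_along(q$charges)))
}

#' @export
print.resp2 <- function(x, digits = 4, ...) {
  cat(sprintf("RESP2 charges for '%s' (delta = %g, %d conformer(s))\n",
              x$molecule$name, x$delta, length(x$conformers)))
  print(round(coef(x), digits))
  invisible(x)
}

#' @export
summary.resp2 <- function(object, ...) {
  tab <- data.frame(
    atom = seq_len(n_atoms(object$molecule)),
    element = object$molecule$elements,
    class = assign_symmetry_classes(object$molecule),
    lj_type = tryCatch(assign_lj_types(object$molecule),
                       error = function(e) NA_character_),
    q_gas = object$gas$charges$charges,
    q_aqueous = object$aqueous$charges$charges,
    q_mixed = object$charges$charges)
  dip <- if (object$molecule$net_charge == 0L) {
    c(gas = dipole_from_charges(object$conformers[[1L]],
                                object$gas$charges)$magnitude_debye,
      aqueous = dipole_from_charges(object$conformers[[1L]],
                                    object$aqueous$charges)$magnitude_debye,
      mixed = dipole_from_charges(object$conformers[[1L]],
                                  object$charges)$magnitude_debye)
  } else NULL
  out <- list(molecule = object$molecule$name, delta = object$delta,
              table = tab, dipoles_debye = dip)
  class(out) <- "summary.resp2"
  out
}

#' @export
print.summary.resp2 <- function(x, digits = 4, ...) {
  cat(sprintf("RESP2 fit of '%s', delta = %g\n", x$molecule, x$delta))
  tab <- x$table
  tab[c("q_gas", "q_aqueous", "q_mixed")] <-
    round(tab[c("q_gas", "q_aqueous", "q_mixed")], digits)
  print(tab, row.names = FALSE)
  if (!is.null(x$dipoles_debye)) {
    cat(sprintf("Dipole (conformer 1): gas %.3f D, aqueous %.3f D, mixed %.3f D\n",
                x$dipoles_debye["gas"], x$dipoles_debye["aqueous"],
                x$dipoles_debye["mixed"]))
  }
  invisible(x)
}

#' @export
predict.resp2 <- function(object, points, conformer_index = 1L,
                          phase = c("mixed", "gas", "aqueous"), ...) {
  phase <- match.arg(phase)
  q <- switch(phase, mixed = object$charges$charges,
              gas = object$gas$charges$charges,
              aqueous = object$aqueous$charges$charges)
  point_charge_esp(object$conformers[[conformer_index]], q, as.matrix(points))
}

#' @export
residuals.resp2 <- function(object, ...) {
  list(gas = residuals(object$gas), aqueous = residuals(object$aqueous))
}

#' Charge profile across the mixing parameter
#'
#' @param x a `"resp2"` model.
#' @param deltas values of the mixing parameter to display.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the matrix of charges (atoms x deltas).
#' @export
plot.resp2 <- function(x, deltas = seq(0, 1, by = 0.05), ...) {
  qm <- vapply(deltas, function(d) unname(coef(x, delta = d)),
               numeric(n_atoms(x$molecule)))
  graphics::matplot(deltas, t(qm), type = "l", lty = 1,
                    xlab = expression(delta), ylab = "charge (e)",
                    main = sprintf("'%s': charges vs mixing parameter",
                                   x$molecule$name), ...)
  invisible(qm)
}
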