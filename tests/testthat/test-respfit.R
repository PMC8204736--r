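unrestrained <- fit_settings(stage1_restraint = 0, stage2_restraint = 0)

test_that("zero-restraint fits recover the generating charges exactly", {
  for (nm in c("water", "methanol", "methylammonium")) {
    fx <- mock_fixture(nm)
    grids <- fixture_gas_grids(fx)
    cs <- solve_restrained_fit(
      grids, fx$conformers,
      constraint_set(fx$molecule$net_charge,
                     n_atoms = length(fx$molecule$elements)),
      restraint = 0)
    expect_lt(max(abs(cs$charges - fx$model$charges)), 1e-6)
    expect_lt(abs(sum(cs$charges) - fx$molecule$net_charge), 1e-10)
  }
})

test_that("the zero-restraint solver agrees with a direct constrained LS oracle", {
  fx <- mock_fixture("water", noise_sigma = 5e-4, seed = 21L)
  grid <- synthesize_esp(fx$conformers[[1]], fx$model, phase = "gas")
  cs <- solve_restrained_fit(
    list(grid), fx$conformers,
    constraint_set(0, n_atoms = 3), restraint = 0)
  a <- vapply(1:3, function(i) {
    r <- fx$conformers[[1]]$coordinates[i, ] / 0.52917721067
    1 / sqrt(rowSums(sweep(grid$points, 2L, r, "-")^2))
  }, numeric(nrow(grid$points)))
  oracle <- constrained_ls_oracle(a, grid$values, 0)
  expect_lt(max(abs(cs$charges - oracle)), 1e-8)
})

test_that("a dominating restraint drives all restrained charges to zero", {
  fx <- mock_fixture("water")
  grids <- fixture_gas_grids(fx)
  cs <- solve_restrained_fit(
    grids, fx$conformers, constraint_set(0, n_atoms = 3),
    restraint = 1e6,
    settings = fit_settings(restrain_hydrogens = TRUE,
                            convergence_tol = 1e-12))
  expect_lt(max(abs(cs$charges)), 1e-4)
  expect_lt(abs(sum(cs$charges)), 1e-10)
})

test_that("the fitted charges vary continuously with the restraint strength", {
  fx <- mock_fixture("methanol")
  grids <- fixture_gas_grids(fx)
  con <- constraint_set(0, n_atoms = 6)
  q1 <- solve_restrained_fit(grids, fx$conformers, con, 0.005)$charges
  q2 <- solve_restrained_fit(grids, fx$conformers, con, 0.005 + 1e-6)$charges
  expect_lt(max(abs(q1 - q2)), 1e-3)
})

test_that("conformer order is irrelevant and duplicating a grid doubles its weight", {
  fx <- mock_fixture("methanol", noise_sigma = 1e-3, seed = 5L)
  g1 <- synthesize_esp(fx$conformers[[1]], fx$model, phase = "gas")
  fx2 <- mock_fixture("methanol", noise_sigma = 1e-3, seed = 6L)
  g2 <- synthesize_esp(fx2$conformers[[2]], fx2$model, phase = "gas")
  con <- constraint_set(0, n_atoms = 6)
  q_12 <- solve_restrained_fit(list(g1, g2),
                               fx$conformers, con, 0.005)$charges
  q_21 <- solve_restrained_fit(list(g2, g1),
                               list(fx$conformers[[2]], fx$conformers[[1]]),
                               con, 0.005)$charges
  expect_equal(q_12, q_21, tolerance = 1e-10)

  # duplicated grid = doubled weight: compare against row-duplicated LS
  q_dup <- solve_restrained_fit(
    list(g1, g1, g2),
    list(fx$conformers[[1]], fx$conformers[[1]], fx$conformers[[2]]),
    con, 0)$charges
  gd <- esp_grid(rbind(g1$points, g1$points), c(g1$values, g1$values), "gas")
  q_stack <- solve_restrained_fit(
    list(gd, g2), fx$conformers, con, 0)$charges
  expect_equal(q_dup, q_stack, tolerance = 1e-9)
})

test_that("equality constraints and frozen charges are honored exactly", {
  fx <- mock_fixture("methanol", noise_sigma = 1e-3, seed = 8L)
  grids <- fixture_gas_grids(fx)
  con <- constraint_set(0, equivalence_groups = list(c(3L, 4L, 5L)),
                        frozen = c("2" = -0.61), n_atoms = 6)
  cs <- solve_restrained_fit(grids, fx$conformers, con, 0.005)
  q <- cs$charges
  expect_identical(q[3], q[4])
  expect_identical(q[4], q[5])
  expect_identical(q[2], -0.61)
  expect_lt(abs(sum(q)), 1e-10)
})

test_that("constraint sets reject inconsistent specifications", {
  expect_error(constraint_set(0, list(c(1L, 2L), c(2L, 3L)), n_atoms = 4),
               "disjoint")
  expect_error(constraint_set(0, list(c(1L, 2L)), frozen = c("1" = 0.1),
                              n_atoms = 4), "frozen atoms may not")
  expect_error(constraint_set(0, frozen = c("1" = 0.3, "2" = 0.3),
                              n_atoms = 2), "infeasible")
  expect_error(constraint_set(0, list(c(1L, 9L)), n_atoms = 4),
               "out of range")
})

test_that("the solver reports non-convergence with the iteration cap", {
  fx <- mock_fixture("water")
  grids <- fixture_gas_grids(fx)
  expect_error(
    solve_restrained_fit(grids, fx$conformers, constraint_set(0, n_atoms = 3),
                         restraint = 0.01,
                         settings = fit_settings(max_iterations = 1L,
                                                 convergence_tol = 1e-14)),
    "did not converge")
})

test_that("grids must carry values and matching phases", {
  fx <- mock_fixture("water")
  g <- build_msk_grid(fx$conformers[[1]])
  expect_error(
    solve_restrained_fit(list(g), fx$conformers,
                         constraint_set(0, n_atoms = 3), 0),
    "phase")
  gas <- synthesize_esp(fx$conformers[[1]], fx$model, phase = "gas")
  aq <- synthesize_esp(fx$conformers[[1]], fx$model, phase = "aqueous")
  expect_error(
    solve_restrained_fit(list(gas, aq),
                         list(fx$conformers[[1]], fx$conformers[[1]]),
                         constraint_set(0, n_atoms = 3), 0),
    "mix phases")
})

test_that("stage 2 symmetrizes the apolar refit set and freezes everything else", {
  fx <- mock_fixture("methanol", noise_sigma = 1e-3, seed = 13L)
  grids <- fixture_gas_grids(fx)
  fit <- two_stage_fit(fx$molecule, fx$conformers, grids)
  q <- fit$charges$charges
  expect_identical(q[3], q[4])
  expect_identical(q[4], q[5])                 # methyl H equalized
  expect_identical(q[2], fit$stage1$charges[2]) # O frozen
  expect_identical(q[6], fit$stage1$charges[6]) # hydroxyl H frozen
  expect_setequal(fit$refit_set, c(1L, 3L, 4L, 5L))
  expect_lt(abs(sum(q)), 1e-10)
})

test_that("two-stage fitting with symmetric truth and no restraint recovers the truth", {
  for (nm in c("methanol", "ethane", "acetonitrile")) {
    fx <- mock_fixture(nm)
    grids <- fixture_gas_grids(fx)
    fit <- two_stage_fit(fx$molecule, fx$conformers, grids, unrestrained)
    expect_lt(max(abs(fit$charges$charges - fx$model$charges)), 1e-4)
  }
})

test_that("molecules with no apolar C-H group skip stage 2", {
  fx <- mock_fixture("water")
  fit <- two_stage_fit(fx$molecule, fx$conformers, fixture_gas_grids(fx))
  expect_length(fit$refit_set, 0L)
  expect_identical(fit$charges$charges, fit$stage1$charges)
})

test_that("charge mixing is affine with the documented endpoints", {
  fx <- mock_fixture("methanol")
  gas <- fixture_gas_grids(fx)
  aq <- lapply(fx$conformers, synthesize_esp, model = fx$model,
               phase = "aqueous")
  fit_g <- two_stage_fit(fx$molecule, fx$conformers, gas)$charges
  fit_a <- two_stage_fit(fx$molecule, fx$conformers, aq)$charges
  expect_identical(mix_charges(fit_g, fit_a, 0)$charges, fit_g$charges)
  expect_identical(mix_charges(fit_g, fit_a, 1)$charges, fit_a$charges)
  expect_equal(mix_charges(fit_g, fit_a, 0.5)$charges,
               (fit_g$charges + fit_a$charges) / 2)
  for (d in seq(0, 1, by = 0.25)) {
    m <- mix_charges(fit_g, fit_a, d)
    expect_equal(m$charges, fit_g$charges + d * (fit_a$charges - fit_g$charges))
    expect_lt(abs(sum(m$charges) - 0), 1e-10)
    expect_identical(m$delta, d)
    expect_identical(m$phase, "mixed")
  }
  expect_error(mix_charges(fit_g, fit_a, 1.2), "\\[0, 1\\]")
  expect_error(mix_charges(fit_a, fit_g, 0.5), "gas-phase")
  other <- two_stage_fit(mock_fixture("water")$molecule,
                         mock_fixture("water")$conformers,
                         lapply(mock_fixture("water")$conformers,
                                synthesize_esp,
                                model = mock_fixture("water")$model,
                                phase = "aqueous"))$charges
  expect_error(mix_charges(fit_g, other, 0.5), "different molecules")
})

test_that("hand-computed per-atom mixing value is reproduced", {
  mol <- molecule(c("O", "H"), rbind(c(1, 2)), -1L, "toy")
  qg <- charge_set(c(-0.5, -0.5), "gas", mol)
  qa <- charge_set(c(-0.7, -0.3), "aqueous", mol)
  expect_equal(mix_charges(qg, qa, 0.6)$charges[1], -0.62)
})

test_that("dipoles match the definition and conversion constant", {
  mol <- molecule(c("H", "H"), rbind(c(1, 2)))
  conf <- conformer(mol, rbind(c(0, 0, 0), c(1, 0, 0)))
  d <- dipole_from_charges(conf, c(0.5, -0.5))
  expect_equal(d$vector, c(x = -0.5, y = 0, z = 0))
  expect_equal(d$magnitude_debye, 0.5 * 4.80321)
  expect_equal(dipole_from_charges(conf, c(0, 0))$magnitude_debye, 0)
  fx <- mock_fixture("water")
  q <- fx$model$charges
  r <- fx$conformers[[1]]$coordinates
  brute <- colSums(q * r)
  expect_equal(dipole_from_charges(fx$conformers[[1]], q)$vector, brute,
               ignore_attr = TRUE)
  ion <- mock_fixture("methylammonium")
  expect_warning(dipole_from_charges(ion$conformers[[1]], ion$model$charges),
                 "center of nuclear charge")
})

test_that("the resp2 model object exposes the standard methods coherently", {
  fx <- mock_fixture("methanol")
  gas <- fixture_gas_grids(fx)
  aq <- lapply(fx$conformers, synthesize_esp, model = fx$model,
               phase = "aqueous")
  m <- resp2(fx$molecule, fx$conformers, gas, aq, delta = 0.6,
             settings = unrestrained)
  expect_s3_class(m, "resp2")
  q <- coef(m)
  expect_length(q, 6L)
  # unrestrained noiseless: mixed charges = (1-d+d*lambda) * truth
  expect_equal(unname(q), (0.4 + 0.6 * 1.2) * fx$model$charges,
               tolerance = 1e-6)
  expect_equal(unname(coef(m, delta = 0)), fx$model$charges,
               tolerance = 1e-6)
  res <- residuals(m)
  expect_lt(max(abs(unlist(res$gas))), 1e-8)
  pred <- predict(m, matrix(c(10, 0, 0), 1), phase = "gas")
  expect_equal(pred,
               point_charge_esp(fx$conformers[[1]], fx$model$charges,
                                matrix(c(10, 0, 0), 1)),
               tolerance = 1e-6)
  s <- summary(m)
  expect_s3_class(s, "summary.resp2")
  expect_equal(nrow(s$table), 6L)
  expect_output(print(m), "delta = 0.6")
  expect_output(print(summary(m$gas)), "RMS ESP residual")
})

test_that("mixed-fit dipoles grow monotonically with delta for polarized fixtures", {
  fx <- mock_fixture("acetonitrile")
  gas <- fixture_gas_grids(fx)
  aq <- lapply(fx$conformers, synthesize_esp, model = fx$model,
               phase = "aqueous")
  m <- resp2(fx$molecule, fx$conformers, gas, aq)
  mags <- vapply(seq(0, 1, by = 0.05), function(d) {
    dipole_from_charges(fx$conformers[[1]],
                        unname(coef(m, delta = d)))$magnitude_debye
  }, numeric(1))
  expect_true(all(diff(mags) >= -1e-12))
})
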