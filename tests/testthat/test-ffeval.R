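smirnoffish_lj <- function() {
  lj_parameter_set(
    epsilon = c(C = 0.4577, N = 0.7113, O = 0.8803,
                H_polar = 0.0657, H_nonpolar = 0.0657),
    rmin_half = c(C = 1.9080, N = 1.8240, O = 1.6612,
                  H_polar = 0.6000, H_nonpolar = 1.4870))
}

test_that("parameter mapping shifts and scales by the prior widths", {
  k0 <- smirnoffish_lj()
  mapping <- parameter_mapping(k0)
  expect_equal(unname(map_parameters(as.numeric(k0), mapping)), rep(0, 10))
  shifted <- as.numeric(k0)
  shifted["C.epsilon"] <- shifted["C.epsilon"] + 0.4184
  expect_equal(unname(map_parameters(shifted, mapping)["C.epsilon"]), 1)
  shifted["O.rmin_half"] <- shifted["O.rmin_half"] + 0.25
  expect_equal(unname(map_parameters(shifted, mapping)["O.rmin_half"]), 0.25)
  set.seed(1)
  for (i in 1:5) {
    k <- stats::rnorm(10)
    expect_equal(unname(map_parameters(unmap_parameters(k, mapping), mapping)),
                 k, tolerance = 1e-14)
  }
})

test_that("property residuals are unit-free squared deviations", {
  expect_equal(property_residual(40.3, 40.0, 0.3), 1.0)
  expect_equal(property_residual(1004, 974, 30), 1.0)
  expect_equal(property_residual(5, 5, 0.3), 0)
  expect_error(property_residual(1, 1, 0), "d_p")
  expect_equal(property_datum("x", "HOV", 40)$d_p, 0.3)
  expect_equal(property_datum("x", "density", 990)$d_p, 30)
  expect_error(property_datum("x", "dielectric", 24), "must be supplied")
})

test_that("the regularized objective decomposes exactly", {
  mapping <- parameter_mapping(smirnoffish_lj())
  # empty dataset: pure Tikhonov term with w_reg = 10
  spec0 <- objective_spec(mapping)
  k_unit <- c(1, rep(0, 9))
  expect_equal(objective(k_unit, spec0)$value, 10)
  expect_equal(objective(rep(0, 10), spec0)$value, 0)

  # perfect provider at k = 0
  ds <- rbind(property_datum("methanol", "HOV", 37.5),
              property_datum("methanol", "density", 792),
              property_datum("ethane", "HOV", 14.7))
  perfect <- function(K, molecule, kind) {
    ds$y_ref[ds$molecule == molecule & ds$kind == kind]
  }
  spec <- objective_spec(mapping, ds, perfect)
  expect_equal(objective(rep(0, 10), spec)$value, 0)

  # hand-set deviations sum as expected
  off <- function(K, molecule, kind) {
    perfect(K, molecule, kind) + if (kind == "HOV") 0.6 else 15
  }
  spec2 <- objective_spec(mapping, ds, off)
  res <- objective(k_unit, spec2)
  hand <- (0.6 / 0.3)^2 + (15 / 30)^2 + (0.6 / 0.3)^2 + 10 * 1
  expect_equal(res$value, hand)
  expect_equal(sum(res$breakdown$contribution) + res$regularization,
               res$value, tolerance = 1e-10)

  broken <- function(K, molecule, kind) stop("boom")
  spec3 <- objective_spec(mapping, ds, broken)
  expect_error(objective(k_unit, spec3), "methanol/HOV")
})

test_that("heat of vaporization follows the mean-energy difference plus RT", {
  gas <- trajectory_summary(rep(0, 100), temperature = 298)
  liq <- trajectory_summary(rep(-40 * 700, 100), n_molecules = 700,
                            temperature = 298)
  expect_equal(hov_from_summaries(gas, liq), 42.477721, tolerance = 1e-6)
  # equal per-molecule energies: HOV reduces to RT
  liq0 <- trajectory_summary(rep(0, 10), n_molecules = 700, temperature = 298)
  expect_equal(hov_from_summaries(gas, liq0), 0.0083145 * 298)
  # averaging oracle on random frames; order irrelevant
  set.seed(2)
  ug <- stats::rnorm(50, -2, 1); ul <- stats::rnorm(50, -30 * 700, 500)
  g2 <- trajectory_summary(ug); l2 <- trajectory_summary(ul, n_molecules = 700)
  expect_equal(hov_from_summaries(g2, l2),
               mean(ug) - mean(ul) / 700 + 0.0083145 * 298)
  l2r <- trajectory_summary(rev(ul), n_molecules = 700)
  expect_equal(hov_from_summaries(g2, l2), hov_from_summaries(g2, l2r))
  g_hot <- trajectory_summary(ug, temperature = 300)
  expect_error(hov_from_summaries(g_hot, l2), "different temperatures")
})

test_that("density comes from the mean volume in SI units", {
  liq <- trajectory_summary(rep(0, 10), volumes = rep(21.5, 10),
                            n_molecules = 700, molar_mass = 18.015)
  expect_equal(density_from_summaries(liq), 974.0, tolerance = 0.1)
  liq2 <- trajectory_summary(rep(0, 10), volumes = rep(43.0, 10),
                             n_molecules = 700, molar_mass = 18.015)
  expect_equal(density_from_summaries(liq2),
               density_from_summaries(liq) / 2)
  set.seed(3)
  v <- stats::runif(200, 20, 23)
  liq3 <- trajectory_summary(numeric(200), volumes = v, n_molecules = 700,
                             molar_mass = 18.015)
  expect_equal(density_from_summaries(liq3),
               700 * 18.015e-3 / (6.02214076e23 * mean(v) * 1e-27))
  expect_error(density_from_summaries(
    trajectory_summary(0, volumes = -1, molar_mass = 18)), "positive")
})

test_that("dielectric constant reflects box-dipole fluctuations", {
  eps0 <- 8.8541878128e-12; kb <- 1.380649e-23; e <- 1.602176634e-19
  v_nm3 <- 21.5; t <- 298
  # constant dipole: no fluctuation, eps = 1
  const <- trajectory_summary(numeric(10), volumes = rep(v_nm3, 10),
                              dipoles = matrix(rep(c(3, -1, 2), each = 10), 10),
                              temperature = t)
  expect_equal(dielectric_from_summaries(const), 1)
  # rotating constant-magnitude dipole with zero mean: analytic second moment
  m0 <- 2.5
  dip <- m0 * rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  rot <- trajectory_summary(numeric(4), volumes = rep(v_nm3, 4),
                            dipoles = dip, temperature = t)
  analytic <- 1 + (m0 * e * 1e-9)^2 /
    (3 * eps0 * v_nm3 * 1e-27 * kb * t)
  expect_equal(dielectric_from_summaries(rot), analytic, tolerance = 1e-12)
  # frame reordering is irrelevant
  rot2 <- trajectory_summary(numeric(4), volumes = rep(v_nm3, 4),
                             dipoles = dip[c(3, 1, 4, 2), ], temperature = t)
  expect_equal(dielectric_from_summaries(rot2),
               dielectric_from_summaries(rot))
  expect_error(dielectric_from_summaries(
    trajectory_summary(numeric(3), volumes = rep(1, 3))), "dipole")
})

test_that("Gaussian dipole fluctuations reproduce the closed form at large n", {
  set.seed(17)
  n <- 1e5; sigma <- 0.8; v_nm3 <- 21.5; t <- 298
  dip <- matrix(stats::rnorm(3 * n, 0, sigma), n, 3)
  liq <- trajectory_summary(numeric(n), volumes = rep(v_nm3, n),
                            dipoles = dip, temperature = t)
  eps0 <- 8.8541878128e-12; kb <- 1.380649e-23; e <- 1.602176634e-19
  analytic <- 1 + 3 * (sigma * e * 1e-9)^2 /
    (3 * eps0 * v_nm3 * 1e-27 * kb * t)
  measured <- dielectric_from_summaries(liq)
  expect_lt(abs(measured - analytic) / (analytic - 1), 0.05)
  expect_gte(measured, 1)
})

test_that("MUE and the relative-error profile match brute-force loops", {
  expect_equal(mue(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mue(c(1, 3), c(2, 2)), 1.0)
  expect_equal(relative_error_profile(c(2, 2), c(2, 2)), 0)
  expect_equal(relative_error_profile(c(1, 2, 3, 4), c(2, 4, 6, 8)), -0.5)
  set.seed(23)
  for (rep in 1:100) {
    n <- sample(2:20, 1)
    xm <- stats::rnorm(n); xe <- stats::rnorm(n)
    acc <- 0
    for (i in seq_len(n)) acc <- acc + abs(xm[i] - xe[i])
    expect_equal(mue(xm, xe), acc / n, tolerance = 1e-12)
    np <- sample(2:6, 1)
    em <- stats::runif(np, 0.1, 5); eb <- stats::runif(np, 0.1, 5)
    acc2 <- 0
    for (j in seq_len(np)) acc2 <- acc2 + (em[j] - eb[j]) / eb[j]
    expect_equal(relative_error_profile(em, eb), acc2 / np,
                 tolerance = 1e-12)
  }
  expect_error(mue(numeric(0), numeric(0)), "at least one")
  expect_error(relative_error_profile(1, 0), "> 0")
})

test_that("the optimizer finds a quadratic minimum and stops under the rules", {
  mapping <- parameter_mapping(stats::setNames(rep(1, 2), c("a", "b")),
                               stats::setNames(rep(1, 2), c("a", "b")))
  k_star <- c(0.8, -0.6)
  provider <- function(K, molecule, kind) {
    k <- K - 1   # priors 1, k0 1
    sqrt(500 * sum((k - k_star)^2))
  }
  ds <- property_datum("surrogate", "HOV", y_ref = 0, d_p = 1)
  spec <- objective_spec(mapping, ds, provider, w_reg = 0)
  res <- optimize_objective(spec, k_start = c(0, 0))
  expect_lt(sqrt(sum((res$k - k_star)^2)), 0.05)
  expect_true(res$converged %in% c("step_size", "objective_change"))
  expect_true(all(diff(res$trace$L) <= 0))

  # starting at the minimum accepts no step
  res0 <- optimize_objective(spec, k_start = k_star)
  expect_equal(res0$k, k_star)
  expect_equal(nrow(res0$trace), 1L)
})

test_that("a dataset-free objective is pulled to k = 0 by the regularizer", {
  mapping <- parameter_mapping(stats::setNames(rep(0, 3), c("a", "b", "c")),
                               stats::setNames(rep(1, 3), c("a", "b", "c")))
  spec <- objective_spec(mapping, w_reg = 10)
  res <- optimize_objective(spec, k_start = c(1.7, -2.3, 0.9),
                            obj_tol = 1e-3, step_tol = 0.01)
  expect_lt(sqrt(sum(res$k^2)), 0.05)
})

test_that("LJ parameter sets validate and flatten consistently", {
  k0 <- smirnoffish_lj()
  v <- as.numeric(k0)
  expect_length(v, 10L)
  expect_equal(unname(v["N.rmin_half"]), 1.8240)
  expect_error(lj_parameter_set(c(C = -1), c(C = 1)), "named with all five")
})
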