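# Free energy, chemical potentials and the traction potential.
# Frozen reference values were computed independently with a symbolic
# oracle (exact rationals, 12 significant digits).

test_that("free energy matches symbolic oracle values", {
  expect_equal(free_energy(0.5, gel_params()), -0.350039326183, tolerance = 1e-10)
  expect_equal(free_energy(0.45, gel_params(chi = 0.75)), -0.146778635049,
               tolerance = 1e-10)
  # all terms vanish in the dilute limit when mu_s0 = 0
  expect_equal(free_energy(1e-12, gel_params(chi = 2)), 0, tolerance = 1e-10)
  # domain guard
  expect_error(free_energy(0, gel_params()), "inside")
  expect_error(free_energy(1.2, gel_params()), "inside")
})

test_that("analytic derivatives agree with finite differences and closed forms", {
  p <- gel_params(chi = 0.6)
  expect_equal(free_energy_derivatives(0.3, p)$fprime, -0.405364784105,
               tolerance = 1e-10)
  expect_equal(free_energy_derivatives(0.5, gel_params(chi = 0.75))$fpp, 0.52,
               tolerance = 1e-12)

  h <- 1e-6
  h2 <- 1e-4 # larger step for the second difference (cancellation noise)
  for (th in c(0.05, 0.3, 0.5, 0.77, 0.95)) {
    fd1 <- (free_energy(th + h, p) - free_energy(th - h, p)) / (2 * h)
    fd2 <- (free_energy(th + h2, p) - 2 * free_energy(th, p) +
              free_energy(th - h2, p)) / h2^2
    d <- free_energy_derivatives(th, p)
    expect_equal(d$fprime, fd1, tolerance = 1e-7)
    expect_equal(d$fpp, fd2, tolerance = 1e-5)
  }

  # a large mixing parameter opens a spinodal window where f'' < 0
  fpp_grid <- free_energy_derivatives(seq(0.05, 0.95, by = 0.01),
                                      gel_params(chi = 3))$fpp
  expect_true(any(fpp_grid < 0))
})

test_that("chemical potential identities hold across random states", {
  set.seed(42)
  for (k in 1:200) {
    p <- gel_params(N = runif(1, 2, 500), chi = runif(1, -2, 3),
                    mu_p0 = runif(1, -1, 1), mu_s0 = runif(1, -1, 1))
    th <- runif(1, 1e-4, 1 - 1e-4)
    mu <- chemical_potentials(th, p)
    f <- free_energy(th, p)
    fp <- free_energy_derivatives(th, p)$fprime
    # theta_p mu_p + theta_s mu_s = f ; mu_p - mu_s = f'
    expect_equal(th * mu$mu_p + (1 - th) * mu$mu_s, f, tolerance = 1e-12)
    expect_equal(mu$mu_p - mu$mu_s, fp, tolerance = 1e-12)
  }
  # the cell-free swelling equilibrium: mu_s crosses mu_s^e near theta = 0.45
  expect_lt(abs(chemical_potentials(0.45, gel_params(chi = 0.75))$mu_s), 1e-3)
})

test_that("external solvent potential is the standard free energy of pure solvent", {
  expect_identical(external_solvent_potential(gel_params()), 0)
  expect_identical(external_solvent_potential(gel_params(mu_s0 = 0.3)), 0.3)
  # continuous with the dilute limit of mu_s
  p <- gel_params(chi = 1.2, mu_s0 = 0.3)
  expect_equal(chemical_potentials(1e-10, p)$mu_s,
               external_solvent_potential(p), tolerance = 1e-8)
})

test_that("traction potential is monotone, saturating, and zero without cells", {
  p <- gel_params(tau0 = 1, lambda = 1)
  expect_equal(cell_potential(0, p)$G, 0)
  expect_equal(cell_potential(1, p)$G, 0.5)
  n <- seq(0, 50, by = 0.05)
  cp <- cell_potential(n, p)
  expect_true(all(cp$dG >= 0))
  expect_true(all(diff(cp$G) >= 0))
  expect_true(all(cp$G <= p$tau0 / p$lambda))
  expect_equal(cell_potential(1e6, p)$G, p$tau0 / p$lambda, tolerance = 1e-10)
  expect_error(cell_potential(-0.1, p), ">= 0")
})

test_that("standard free energies cancel from every dynamical quantity", {
  base <- gel_params(chi = 0.8, tau0 = 0.5)
  shifted <- gel_params(chi = 0.8, tau0 = 0.5, mu_p0 = 2.3, mu_s0 = -1.7)
  th <- seq(0.05, 0.95, by = 0.05)
  # mu_s - mu_s^e, f'' and theta_p G are what the model actually uses;
  # the cancellation is exact in exact arithmetic (round-off tolerance here)
  expect_equal(
    chemical_potentials(th, base)$mu_s - external_solvent_potential(base),
    chemical_potentials(th, shifted)$mu_s - external_solvent_potential(shifted),
    tolerance = 1e-13)
  expect_identical(free_energy_derivatives(th, base)$fpp,
                   free_energy_derivatives(th, shifted)$fpp)
  expect_identical(cell_potential(th, base)$G, cell_potential(th, shifted)$G)
})
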