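# Uniform steady states, stability classification, bifurcation relations.

test_that("equilibrium residual reproduces reported equilibria and dissolution", {
  # cell-free swelling case: root at theta* ~ 0.45
  p <- gel_params(chi = 0.75)
  expect_lt(abs(equilibrium_residual(0.45, 0.6, 0, p)), 1e-3)
  # strong traction case: theta* = 0.86 printed to 2 d.p.
  pc <- gel_params(chi = 0.75, tau0 = 1)
  expect_lt(abs(equilibrium_residual(0.86, 0.6, 1, pc)), 0.02)
  # chi = 0 cell-free: mu_s < mu_s^e everywhere, no root, gel dissolves
  p0 <- gel_params(chi = 0)
  grid <- seq(1e-4, 1 - 1e-4, length.out = 10000)
  expect_true(all(equilibrium_residual(grid, 0.6, 0, p0) < 0))
})

test_that("steady-state solver finds exactly the brute-force sign-scan roots", {
  set.seed(7)
  for (k in 1:25) {
    p <- gel_params(chi = runif(1, -0.5, 2), tau0 = runif(1, 0, 1),
                    lambda = runif(1, 0.5, 2))
    theta_i <- runif(1, 0.15, 0.7)
    n_bar <- sample(c(0, 1), 1)
    eq <- solve_uniform_steady_states(theta_i, n_bar, p)
    grid <- seq(1e-6, 1 - 1e-6, length.out = 10000)
    res <- equilibrium_residual(grid, theta_i, n_bar, p)
    brute <- which(res[-1] * res[-length(res)] < 0)
    expect_equal(nrow(eq), length(brute))
    if (nrow(eq) > 0) {
      # every refined root lies in a brute-force bracket and satisfies the
      # residual and mass-conservation identities
      expect_true(all(abs(eq$residual) < 1e-10))
      expect_equal(eq$L_star * eq$theta_star, rep(theta_i, nrow(eq)))
      expect_equal(eq$L_star * eq$n_star, rep(n_bar, nrow(eq)))
      for (r in eq$theta_star)
        expect_true(any(grid[brute] <= r & r <= grid[brute + 1]))
    }
  }
})

test_that("reference equilibria match reported values to 2 d.p.", {
  p <- gel_params(chi = 0.75)
  eq <- solve_uniform_steady_states(0.6, 0, p)
  st <- eq[eq$stable == "stable", ]
  expect_2dp(st$theta_star, 0.45)
  expect_2dp(st$L_star, 1.34)

  pc <- gel_params(chi = 0.75, tau0 = 1)
  eq2 <- solve_uniform_steady_states(0.2, 1, pc)
  st2 <- eq2[eq2$stable == "stable", ]
  expect_2dp(st2$theta_star, 0.91)
  expect_2dp(st2$n_star, 4.54)
  expect_2dp(st2$L_star, 0.22)

  # below the cell-free existence threshold no equilibria remain
  expect_identical(nrow(solve_uniform_steady_states(0.6, 0, gel_params(chi = 0.5))), 0L)
})

test_that("stability classification follows the growth factor", {
  # cell-free: sign of f''(theta*)
  p <- gel_params(chi = 0.75)
  eq <- solve_uniform_steady_states(0.6, 0, p)
  fpp <- free_energy_derivatives(eq$theta_star, p)$fpp
  expect_identical(eq$stable, ifelse(fpp > 0, "stable", "unstable"))
  expect_identical(sort(unique(eq$stable)), c("stable", "unstable"))
  # the low-theta branch is the unstable one
  expect_identical(eq$stable[which.min(eq$theta_star)], "unstable")

  # traction always reduces z (affine with negative slope in tau0)
  z_at_tau <- vapply(c(0, 0.25, 0.5, 1), function(t0)
    growth_factor(0.5, 1, gel_params(chi = 0.6, tau0 = t0))$z, numeric(1))
  expect_true(all(diff(z_at_tau) < 0))

  # z is affine in N01 with slope -theta* 2 tau0/(1+lambda)^2
  pz <- gel_params(chi = 0.6, tau0 = 0.8)
  zs <- vapply(0:3, function(N01) growth_factor(0.5, N01, pz)$z, numeric(1))
  expect_equal(diff(zs), rep(-0.5 * 2 * 0.8 / 4, 3), tolerance = 1e-12)
})

test_that("bifurcation inversions are consistent and anchor values hold", {
  # explicit chi inversion recovers the cell-free swelling equilibrium
  expect_equal(chi_for_theta(0.45, tau0 = 0), 0.75, tolerance = 5e-3)
  # round trip chi <-> tau0
  for (th in c(0.2, 0.45, 0.7)) {
    tau <- 0.6
    chi <- chi_for_theta(th, tau0 = tau)
    expect_equal(tau0_for_theta(th, chi = chi), tau, tolerance = 1e-10)
  }
  # tau0 is affine in chi with slope -(1+lambda) * theta
  taus <- tau0_for_theta(0.5, chi = c(0, 0.5, 1.0))
  expect_equal(diff(taus), rep(-2 * 0.5 * 0.5, 2), tolerance = 1e-12)

  # chi = 0 anchors of the cell branches
  f9 <- stats::uniroot(function(th) chi_for_theta(th, tau0 = 0.25),
                       c(0.1, 0.4), tol = 1e-12)$root
  f10 <- stats::uniroot(function(th) chi_for_theta(th, tau0 = 1),
                        c(0.4, 0.7), tol = 1e-12)$root
  expect_2dp(f9, 0.2)
  expect_2dp(f10, 0.58)
})

test_that("cell-free existence threshold is the fold of the bifurcation curve", {
  thr <- cell_free_existence_threshold(100)
  expect_2dp(thr$chi_min, 0.62)
  # tangency: dchi/dtheta = 0 at the minimiser
  h <- 1e-5
  dchi <- (chi_for_theta(thr$theta + h) - chi_for_theta(thr$theta - h)) / (2 * h)
  expect_lt(abs(dchi), 1e-4)
  # stable and unstable branches meet at the fold
  curve <- bifurcation_curve(seq(0.02, 0.6, by = 0.001))
  flip <- which(diff(curve$stable == "stable") != 0)
  expect_lt(abs(curve$theta_star[flip] - thr$theta), 2e-3)
  # the mixing entropy of the network vanishes with chain length: threshold falls
  thrs <- vapply(c(50, 100, 1000, 1e4), function(N)
    cell_free_existence_threshold(N)$chi_min, numeric(1))
  expect_true(all(diff(thrs) < 0))
})

test_that("marginal quadratic agrees with direct root finding of G - theta f''", {
  set.seed(11)
  for (k in 1:30) {
    p <- gel_params(chi = runif(1, -1.5, 3), N = sample(c(10, 100, 1000), 1))
    if (p$chi == 0) next
    G <- runif(1, 0, 0.8)
    roots <- marginal_roots(G, p)
    grid <- seq(1e-5, 1 - 1e-5, length.out = 10000)
    fn <- G - grid * free_energy_derivatives(grid, p)$fpp
    brute <- which(fn[-1] * fn[-length(fn)] < 0)
    expect_equal(length(roots), length(brute))
    if (length(roots))
      expect_true(all(abs(G - roots * free_energy_derivatives(roots, p)$fpp) < 1e-8))
  }
  # chi < 0: f'' > 0 everywhere, no marginal fractions at G = 0
  expect_identical(marginal_roots(0, gel_params(chi = -0.5)), numeric(0))
})
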