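# Moving-boundary PDE solver: velocity BVP, one-step oracle agreement,
# conservation, fixed points, regime classification plumbing.

test_that("velocity BVP reproduces the analytic early-time field", {
  p <- params_swelling()
  X <- gel_grid(0.002)
  st <- short_time_uniform(0.6, 0, p, T_hat = 0, X = X)
  v <- solve_velocity(rep(0.6, length(X)), rep(0, length(X)), 1, p, dX = 0.002)
  # uniform coefficients: exact solution A0 sinh(alpha X)
  expect_lt(max(abs(v$v_p - st$A0 * sinh(st$alpha * X))), 1e-6)
  expect_equal(v$v_p[1], 0)
  # volume-averaged flux vanishes identically
  expect_equal(0.6 * v$v_p + 0.4 * v$v_s, rep(0, length(X)), tolerance = 1e-15)

  # no drag: uniform strain, velocity linear in X
  p0 <- gel_params(chi = 0.75, eta_s = 0.25, xi = 0, R = 0.5)
  v0 <- solve_velocity(rep(0.6, length(X)), rep(0, length(X)), 1, p0, dX = 0.002)
  expect_lt(max(abs(diff(diff(v0$v_p)))), 1e-12)

  # at an equilibrium the net force, and hence the velocity, vanishes
  eq <- solve_uniform_steady_states(0.6, 0, p)
  th_star <- eq$theta_star[eq$stable == "stable"]
  veq <- solve_velocity(rep(th_star, length(X)), rep(0, length(X)),
                        0.6 / th_star, p, dX = 0.002)
  expect_lt(max(abs(veq$v_p)), 1e-10)
})

test_that("a uniform equilibrium is a fixed point of the dynamics", {
  p <- params_traction()
  eq <- solve_uniform_steady_states(0.6, 1, p)
  st <- eq[eq$stable == "stable", ]
  M <- 101
  s <- coarse_settings(t_end = 1)
  one <- gel_step(rep(st$theta_star, M), rep(st$n_star, M), st$L_star, p, s)
  expect_lt(max(abs(one$theta_p - st$theta_star)), 1e-10)
  expect_lt(max(abs(one$n - st$n_star)), 1e-10)
  expect_lt(abs(one$L - st$L_star), 1e-10)

  # the equilibrium condition involves only (theta, n): starting the clock
  # at L(0) = 1 the state stays put and the boundary never moves
  traj <- simulate_gel(st$theta_star, st$n_star, p,
                       coarse_settings(t_end = 1, steady_tol = 1e-30))
  S <- length(traj$T)
  expect_lt(max(abs(traj$theta_p[, S] - st$theta_star)), 1e-6)
  expect_lt(abs(traj$L[S] - 1), 1e-6)
})

test_that("solver matches the short-time expansion to O(T^2) from uniform ICs", {
  p <- params_traction()
  s <- gel_settings(dX = 0.002, dT = 5e-4, t_end = 50 * 5e-4,
                    snapshot_times = c(25, 50) * 5e-4, steady_tol = 1e-30)
  traj <- simulate_gel(0.6, 1, p, s)
  X <- traj$X
  err <- vapply(2:3, function(j) {
    st <- short_time_uniform(0.6, 1, p, T_hat = traj$T[j], X = X)
    max(abs(traj$theta_p[, j] - st$theta_p[, 1]))
  }, numeric(1))
  errL <- vapply(2:3, function(j) {
    st <- short_time_uniform(0.6, 1, p, T_hat = traj$T[j], X = X)
    abs(traj$L[j] - st$L)
  }, numeric(1))
  # truncation of the expansion: doubling T quadruples the error
  expect_lt(err[2] / err[1], 4 * 1.3)
  expect_gt(err[2] / err[1], 4 / 1.3)
  expect_lt(errL[2] / errL[1], 4 * 1.3)
  expect_gt(errL[2] / errL[1], 4 / 1.3)
  expect_lt(err[1], 1e-5)
})

test_that("mass is conserved and symmetric ICs are enforced", {
  p <- params_traction()
  traj <- simulate_gel(function(X) 0.5 + 0.05 * cos(pi * X),
                       function(X) 1 + 0.025 * cos(pi * X), p,
                       coarse_settings(t_end = 2))
  drift <- mass_audit(traj)
  expect_lt(drift["polymer"], 5e-3)
  expect_lt(drift["cells"], 5e-3)
  # per-step conservation of the spatial operator: one step moves total mass
  # by far less than the transported amount
  m <- traj$masses
  expect_lt(max(abs(diff(m$polymer))), 1e-6)

  expect_error(simulate_gel(function(X) 0.5 + 0.05 * X, 1, p,
                            coarse_settings(t_end = 1)),
               "dX = 0 at X = 0")
  expect_error(simulate_gel(1.2, 1, p, coarse_settings(t_end = 1)), "inside")
})

test_that("steady states converge to the equilibrium prediction under refinement", {
  p <- gel_params(chi = 1.5, eta_s = 0.25, xi = 0.5, R = 0.5)
  eq <- solve_uniform_steady_states(0.6, 0, p)
  th_star <- eq$theta_star[eq$stable == "stable"]
  errs <- vapply(c(0.02, 0.01), function(dx) {
    traj <- simulate_gel(0.6, 0, p, gel_settings(dX = dx, t_end = 40))
    abs(steady_state(traj)$theta_star - th_star)
  }, numeric(1))
  expect_lt(errs[2], errs[1] + 1e-12)
  expect_lt(errs[2], 5e-4)
})

test_that("regime detection distinguishes swelling, contraction and steady", {
  p_swell <- params_swelling()
  tr_sw <- simulate_gel(0.6, 0, p_swell, coarse_settings(t_end = 3))
  expect_identical(detect_regime(tr_sw), "swelling")

  p_con <- gel_params(chi = 1.5, eta_s = 0.25, xi = 0.5, R = 0.5)
  tr_co <- simulate_gel(0.6, 0, p_con, coarse_settings(t_end = 3))
  expect_identical(detect_regime(tr_co), "contraction")

  eq <- solve_uniform_steady_states(0.6, 0, p_swell)
  st <- eq[eq$stable == "stable", ]
  tr_eq <- simulate_gel(st$theta_star, 0, p_swell, coarse_settings(t_end = 0.5))
  expect_identical(detect_regime(tr_eq), "steady")
})

test_that("dissolution is detected when the network fraction collapses", {
  # strongly mixing-favourable gel has no steady state: it swells unboundedly
  p <- gel_params(chi = -1, eta_s = 0.25, xi = 0.5, R = 0.5)
  traj <- simulate_gel(0.1, 0, p,
                       gel_settings(dX = 0.01, t_end = 200,
                                    dissolution_theta = 0.04))
  expect_identical(traj$termination, "dissolved")
  expect_identical(detect_regime(traj), "dissolving")
  expect_true(all(diff(traj$series$L) > -1e-9))
})
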