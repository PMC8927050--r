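#' Solver settings for the moving-boundary simulation
#'
#' @param dX Spatial step on the mapped domain (default 0.002, i.e. 501
#'   nodes).
#' @param dT Time step (default 0.0005).
#' @param t_end Simulation horizon in dimensionless time.
#' @param snapshot_times Times at which full spatial fields are stored;
#'   `NULL` means 200 evenly spaced times plus first and last.
#' @param steady_tol Steady-state threshold on `max |v_p|` (default 1e-8).
#' @param steady_consec Consecutive sub-threshold steps required (default
#'   10).
#' @param clamp_eps Floor applied to `theta_p` and `theta_s` (default
#'   1e-10); activations are counted and reported.
#' @param dissolution_theta Dissolution is declared when `max theta_p` falls
#'   below this level (default 1e-3).
#' @param series_every Coarse time-series cadence in steps (default 100).
#' @return An object of class `gel_settings`.
#' @export
gel_settings <- function(dX = 0.002, dT = 5e-4, t_end = 100,
                         snapshot_times = NULL, steady_tol = 1e-8,
                         steady_consec = 10, clamp_eps = 1e-10,
                         dissolution_theta = 1e-3, series_every = 100) {
  stopifnot(dX > 0, dT > 0, t_end > 0, steady_tol > 0, steady_consec >= 1,
            clamp_eps > 0, dissolution_theta > 0, series_every >= 1)
  M <- round(1 / dX) + 1
  if (abs((M - 1) * dX - 1) > 1e-12)
    stop("dX must divide the unit interval evenly", call. = FALSE)
  structure(list(dX = dX, dT = dT, t_end = t_end,
                 snapshot_times = snapshot_times, steady_tol = steady_tol,
                 steady_consec = steady_consec, clamp_eps = clamp_eps,
                 dissolution_theta = dissolution_theta,
                 series_every = series_every),
            class = "gel_settings")
}

#' Uniform grid on the mapped domain
#'
#' @param dX Node spacing; must divide 1 exactly.
#' @return Numeric vector of node coordinates from 0 to 1.
#' @export
gel_grid <- function(dX = 0.002) {
  M <- round(1 / dX) + 1
  seq(0, 1, length.out = M)
}

resolve_ic <- function(ic, X, what) {
  v <- if (is.function(ic)) ic(X) else if (length(ic) == 1L) rep(ic, length(X)) else ic
  if (length(v) != length(X))
    stop(what, ": initial condition has wrong length", call. = FALSE)
  as.numeric(v)
}

#' Quasi-static polymer velocity field
#'
#' Solves the two-point boundary-value problem for the polymer velocity
#' `v_p(X)` given the current fields: viscous network/solvent stresses
#' balanced against interphase drag, the osmotic force
#' `-theta_p theta_s f'' dtheta_p/dX / L` and the traction force
#' `theta_s d(theta_p G)/dX / L`, with `v_p(0) = 0` and the interface
#' stress/resistance condition at `X = 1`. The solvent velocity follows
#' from zero volume-averaged flux as `v_s = -theta_p v_p / theta_s`.
#'
#' @param theta_p Polymer fraction per node, strictly inside (0, 1).
#' @param n Cell density per node (>= 0).
#' @param L Current gel length (> 0).
#' @param params A [gel_params()] object.
#' @param dX Node spacing.
#' @return List with `v_p` and the derived `v_s`.
#' @export
solve_velocity <- function(theta_p, n, L, params, dX = 0.002) {
  stopifnot(length(n) == length(theta_p), L > 0)
  vp <- .gel_velocity_cpp(as.numeric(theta_p), as.numeric(n), L, dX,
                          unclass(params))
  list(v_p = vp, v_s = -theta_p * vp / (1 - theta_p))
}

#' Advance the gel state by one time step
#'
#' One operator-split semi-implicit step: the velocity is solved
#' quasi-statically from the current state, the boundary speed is
#' `Ldot = v_p(1)`, the polymer fraction and cell density are advanced by
#' Crank-Nicolson transport (conservative fluxes, central advection,
#' no-flux diffusion for the cells) with `v_p`, `L`, `Ldot` frozen, and `L`
#' is advanced by forward Euler.
#'
#' @inheritParams solve_velocity
#' @param settings A [gel_settings()] object (supplies `dX`, `dT`,
#'   `clamp_eps`).
#' @return List with updated `theta_p`, `n`, `L`, plus the `v_p` used,
#'   `Ldot`, and the number of clamped nodes.
#' @export
gel_step <- function(theta_p, n, L, params, settings = gel_settings()) {
  .gel_step_cpp(as.numeric(theta_p), as.numeric(n), L, settings$dX,
                settings$dT, unclass(params), settings$clamp_eps)
}

#' Simulate the moving-boundary gel model
#'
#' Integrates the mapped-domain model from initial fields until a steady
#' state (`max |v_p|` below `steady_tol` for `steady_consec` consecutive
#' steps), dissolution (`max theta_p` below `dissolution_theta`), or
#' `t_end`. Initial conditions may be numeric vectors on the grid, single
#' values, or functions of `X`; the polymer initial condition must have
#' zero slope at `X = 0` (symmetry about the gel centre).
#'
#' @param theta_i Initial polymer fraction: scalar, vector or function of
#'   X, values in (0, 1).
#' @param n_i Initial cell density: scalar, vector or function of X,
#'   values >= 0.
#' @param params A [gel_params()] object.
#' @param settings A [gel_settings()] object.
#' @return An object of class `gel_trajectory`: snapshot times `T`, lengths
#'   `L`, field matrices `theta_p`, `n`, `v_p` (nodes x snapshots), the grid
#'   `X`, a coarse time `series` data frame, per-snapshot polymer and cell
#'   masses, the termination reason, and the inputs.
#' @examples
#' \donttest{
#' p <- gel_params(chi = 0.75, eta_s = 0.25, xi = 0.5, R = 0.5)
#' traj <- simulate_gel(0.6, 0, p, gel_settings(t_end = 2, dX = 0.01))
#' traj
#' }
#' @export
simulate_gel <- function(theta_i, n_i, params, settings = gel_settings()) {
  X <- gel_grid(settings$dX)
  th0 <- resolve_ic(theta_i, X, "theta_i")
  n0 <- resolve_ic(n_i, X, "n_i")
  if (any(th0 <= 0 | th0 >= 1))
    stop("theta_i must lie strictly inside (0,1)", call. = FALSE)
  if (any(n0 < 0)) stop("n_i must be >= 0", call. = FALSE)
  # symmetry about the origin: second-order one-sided slope estimate at X=0
  slope0 <- (-3 * th0[1] + 4 * th0[2] - th0[3]) / (2 * settings$dX)
  if (abs(slope0) > max(1e-8, 10 * settings$dX^2))
    stop("theta_i must satisfy d(theta_i)/dX = 0 at X = 0", call. = FALSE)

  snap <- settings$snapshot_times
  if (is.null(snap))
    snap <- seq(0, settings$t_end, length.out = 201)
  snap <- sort(unique(snap))

  raw <- .gel_simulate_cpp(th0, n0, settings$dX, settings$dT,
                           settings$t_end, unclass(params), snap,
                           settings$steady_tol, settings$steady_consec,
                           settings$clamp_eps, settings$dissolution_theta,
                           settings$series_every)

  masses <- data.frame(
    T = raw$T,
    polymer = raw$L * apply(raw$theta_p, 2, trapz_unit, dX = settings$dX),
    cells = raw$L * apply(raw$n, 2, trapz_unit, dX = settings$dX))

  structure(list(T = raw$T, L = raw$L, theta_p = raw$theta_p, n = raw$n,
                 v_p = raw$v_p, X = X,
                 series = as.data.frame(raw$series), masses = masses,
                 termination = raw$termination, clamped = raw$clamped,
                 steps = raw$steps, params = params, settings = settings),
            class = "gel_trajectory")
}

# trapezoidal quadrature on the unit mapped domain
trapz_unit <- function(y, dX) {
  dX * (sum(y) - 0.5 * (y[1] + y[length(y)]))
}

#' @export
print.gel_trajectory <- function(x, ...) {
  S <- length(x$T)
  cat("<gel_trajectory>\n")
  cat(sprintf("  %d snapshots over T = [0, %.4g]; %d nodes; termination: %s\n",
              S, max(x$T), nrow(x$theta_p), x$termination))
  cat(sprintf("  L: %.4f -> %.4f;  mean theta_p: %.4f -> %.4f\n",
              x$L[1], x$L[S], mean(x$theta_p[, 1]), mean(x$theta_p[, S])))
  drift <- mass_audit(x)
  cat(sprintf("  mass drift: polymer %.2e%%, cells %.2e%%\n",
              drift["polymer"], drift["cells"]))
  if (x$clamped > 0)
    cat(sprintf("  note: theta_p clamp activated %d times\n", x$clamped))
  invisible(x)
}

#' Mass audit of a trajectory
#'
#' Percentage change between the first and last snapshots of the total
#' polymer mass `L * integral(theta_p dX)` and cell mass
#' `L * integral(n dX)` (trapezoidal quadrature). The scheme's conservative
#' flux form keeps both drifts at the round-off/time-coupling level.
#'
#' @param trajectory A [simulate_gel()] result.
#' @return Named numeric vector `c(polymer = , cells = )`, in percent.
#' @export
mass_audit <- function(trajectory) {
  m <- trajectory$masses
  if (nrow(m) < 2) stop("mass_audit needs at least 2 snapshots", call. = FALSE)
  drift <- function(col) {
    m0 <- m[[col]][1]
    if (m0 == 0) return(0)
    100 * abs(m[[col]][nrow(m)] - m0) / m0
  }
  c(polymer = drift("polymer"), cells = drift("cells"))
}

#' Classify the qualitative regime of a trajectory
#'
#' Heuristic classification from the coarse time series: monotone length
#' increase is "swelling", monotone decrease "contraction"; repeated sign
#' changes in the time derivative of `theta_p` at the gel centre while the
#' length changes monotonically mark the "oscillating" regime; trajectories
#' that hit the dissolution threshold (or are headed there monotonically
#' with no steady state) are "dissolving"; a trajectory that never leaves
#' its initial state is "steady".
#'
#' @param trajectory A [simulate_gel()] result with at least 3 snapshots.
#' @param min_cycles Minimum number of swell/contract switches at the gel
#'   centre to call the regime oscillating (default 2).
#' @return One of "swelling", "contraction", "oscillating", "dissolving",
#'   "steady".
#' @export
detect_regime <- function(trajectory, min_cycles = 2) {
  s <- trajectory$series
  if (nrow(s) < 3) stop("detect_regime needs at least 3 series points", call. = FALSE)
  dL <- diff(s$L)
  L_span <- max(abs(s$L - 1))
  tol_L <- 1e-9
  mono_up <- all(dL >= -tol_L)
  mono_down <- all(dL <= tol_L)

  # sign switches of d(theta_p)/dT at X = 0, ignoring round-off wiggles
  d0 <- diff(s$theta_p0)
  thr <- max(1e-9, 1e-4 * max(abs(d0)))
  sgn <- sign(d0[abs(d0) > thr])
  switches <- if (length(sgn) > 1) sum(diff(sgn) != 0) else 0

  if (switches >= min_cycles && (mono_up || mono_down))
    return("oscillating")
  if (trajectory$termination == "dissolved")
    return("dissolving")
  if (L_span < 1e-8) return("steady")
  if (mono_up) return("swelling")
  if (mono_down) return("contraction")
  # non-monotone but not oscillating at the centre: label by net change
  if (s$L[nrow(s)] > 1) "swelling" else "contraction"
}

#' Steady-state summary of a trajectory
#'
#' Mean final polymer fraction and cell density, final length, and the mass
#' conservation checks `L* mean(theta*) = mean(theta_i)`,
#' `L* mean(n*) = mean(n_i)`.
#'
#' @param trajectory A [simulate_gel()] result.
#' @return Named list with `theta_star`, `n_star`, `L_star`, `termination`.
#' @export
steady_state <- function(trajectory) {
  S <- length(trajectory$T)
  dX <- trajectory$settings$dX
  list(theta_star = trapz_unit(trajectory$theta_p[, S], dX),
       n_star = trapz_unit(trajectory$n[, S], dX),
       L_star = trajectory$L[S],
       termination = trajectory$termination)
}
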