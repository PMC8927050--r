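#' Residual of the spatially uniform equilibrium condition
#'
#' A uniform state is an equilibrium when the cell traction and osmotic
#' forces balance at the gel boundary:
#' \deqn{\theta_p G(n) + \mu_s(\theta_p) - \mu_s^e = 0.}
#' Mass conservation ties the candidate polymer fraction to the cell
#' density: a gel started uniform at `(theta_i, n_bar_i)` that equilibrates
#' uniformly at `theta` has length `L = theta_i / theta` and hence cell
#' density `n = n_bar_i * theta / theta_i`.
#'
#' @param theta Candidate equilibrium polymer fraction(s) in (0, 1).
#' @param theta_i Initial uniform polymer fraction in (0, 1).
#' @param n_bar_i Initial mean cell density (>= 0).
#' @param params A [gel_params()] object.
#' @return The residual, vectorised over `theta`. A root is an equilibrium;
#'   no sign change anywhere on (0, 1) means the gel has no uniform steady
#'   state (it dissolves).
#' @export
equilibrium_residual <- function(theta, theta_i, n_bar_i, params) {
  check_theta(theta)
  if (theta_i <= 0 || theta_i >= 1) stop("theta_i must be in (0,1)", call. = FALSE)
  if (n_bar_i < 0) stop("n_bar_i must be >= 0", call. = FALSE)
  n <- n_bar_i * theta / theta_i
  G <- cell_potential(n, params)$G
  theta * G + mu_s_closed(theta, params) - external_solvent_potential(params)
}

#' Solve for all spatially uniform steady states
#'
#' Scans a uniform grid on (eps, 1 - eps) for sign changes of
#' [equilibrium_residual()] and refines each bracket with [stats::uniroot()].
#' Scanning (rather than a single Newton start) guarantees that none of the
#' possible 0, 1 or 2 roots are missed. Each root is completed to a full
#' equilibrium point by mass conservation and labelled by the short-time
#' growth factor (see [classify_stability()]).
#'
#' @inheritParams equilibrium_residual
#' @param n_grid Number of scan points (default 2001).
#' @param eps Exclusion zone at the endpoints (default 1e-6).
#' @param tol Root refinement tolerance on theta (default 1e-12).
#' @param N01 Cell/polymer perturbation amplitude ratio used for the
#'   stability label (default 1).
#' @return A data frame with one row per equilibrium and columns
#'   `theta_star`, `n_star`, `L_star`, `stable` ("stable", "unstable" or
#'   "marginal") and `residual`. Zero rows means no uniform equilibrium
#'   exists (dissolution predicted).
#' @examples
#' solve_uniform_steady_states(0.6, 0, gel_params(chi = 0.75))
#' @export
solve_uniform_steady_states <- function(theta_i, n_bar_i, params,
                                        n_grid = 2001, eps = 1e-6,
                                        tol = 1e-12, N01 = 1) {
  grid <- seq(eps, 1 - eps, length.out = n_grid)
  res <- equilibrium_residual(grid, theta_i, n_bar_i, params)
  sgn <- sign(res)
  flips <- which(sgn[-1] * sgn[-n_grid] < 0)
  roots <- numeric(0)
  for (i in flips) {
    r <- stats::uniroot(function(th) equilibrium_residual(th, theta_i, n_bar_i, params),
                        lower = grid[i], upper = grid[i + 1], tol = tol)
    roots <- c(roots, r$root)
  }
  # exact zeros that land on grid points
  roots <- sort(unique(c(roots, grid[res == 0])))
  out <- data.frame(theta_star = numeric(0), n_star = numeric(0),
                    L_star = numeric(0), stable = character(0),
                    residual = numeric(0), stringsAsFactors = FALSE)
  for (th in roots) {
    L <- theta_i / th
    n <- n_bar_i * th / theta_i
    lab <- classify_stability(th, n, params, N01 = N01)
    out <- rbind(out, data.frame(
      theta_star = th, n_star = n, L_star = L, stable = lab,
      residual = equilibrium_residual(th, theta_i, n_bar_i, params),
      stringsAsFactors = FALSE))
  }
  out
}

#' Short-time growth factor of a uniform equilibrium
#'
#' The linear-stability coefficient of a cosine perturbation about a uniform
#' equilibrium (with cell density scaled so that `n* = 1`):
#' \deqn{z = \theta^* f''(\theta^*) - \frac{\tau_0}{1+\lambda}
#'   - \theta^*\frac{2\tau_0 N_{01}}{(1+\lambda)^2}.}
#' Perturbation amplitudes of both the polymer fraction and the cell
#' density decay when `z > 0` and grow when `z < 0`. Cell traction only ever
#' lowers `z`: adding cells pushes an equilibrium towards instability.
#'
#' @param theta_star Equilibrium polymer fraction in (0, 1).
#' @param N01 Ratio of cell to polymer perturbation amplitudes.
#' @param params A [gel_params()] object whose `tau0`, `lambda` refer to the
#'   `n* = 1` scaling.
#' @return List with `z` and `verdict` ("stable", "unstable" or "marginal",
#'   the last when `|z| < 1e-10`).
#' @export
growth_factor <- function(theta_star, N01, params) {
  check_theta(theta_star)
  fpp <- free_energy_derivatives(theta_star, params)$fpp
  opl <- 1 + params$lambda
  z <- theta_star * fpp - params$tau0 / opl -
    theta_star * 2 * params$tau0 * N01 / opl^2
  verdict <- if (abs(z) < 1e-10) "marginal" else if (z > 0) "stable" else "unstable"
  list(z = z, verdict = verdict)
}

#' Stability label for an arbitrary uniform equilibrium
#'
#' Rescales the cell density so the equilibrium sits at `n* = 1` (which maps
#' `tau0 -> tau0 n*^2`, `lambda -> lambda n*^2` and leaves the traction
#' potential unchanged) and applies the growth-factor criterion. For a
#' cell-free equilibrium this reduces to the sign of `f''(theta*)`. The
#' criterion is derived for the zero-drag limit; it is applied as a label to
#' all equilibria, which numerical simulations support.
#'
#' @param theta_star,n_star Equilibrium polymer fraction and cell density.
#' @param params A [gel_params()] object.
#' @param N01 Perturbation amplitude ratio (default 1).
#' @return "stable", "unstable" or "marginal".
#' @export
classify_stability <- function(theta_star, n_star, params, N01 = 1) {
  p <- params
  p$tau0 <- params$tau0 * n_star^2
  p$lambda <- params$lambda * n_star^2
  growth_factor(theta_star, N01, p)$verdict
}

#' Mixing parameter that balances a given equilibrium polymer fraction
#'
#' Explicit inversion of the uniform equilibrium condition (with `n* = 1`
#' scaling) for the Flory parameter:
#' \deqn{\chi = -\frac{\theta\tau_0/(1+\lambda) + \log(1-\theta)
#'   + \theta(1 - 1/N)}{\theta^2}.}
#' Tracing `theta` over (0, 1) draws the equilibrium branches of the
#' bifurcation diagram in the `(chi, theta*)` plane.
#'
#' @param theta Equilibrium polymer fraction(s) in (0, 1).
#' @param tau0,lambda,N Model parameters (`tau0 = 0` for the cell-free
#'   curve).
#' @return `chi`, vectorised over `theta`.
#' @export
chi_for_theta <- function(theta, tau0 = 0, lambda = 1, N = 100) {
  check_theta(theta)
  -(theta * tau0 / (1 + lambda) + log(1 - theta) + theta * (1 - 1 / N)) / theta^2
}

#' Traction strength that balances a given equilibrium polymer fraction
#'
#' The companion inversion of [chi_for_theta()]: at fixed `theta*`, the
#' traction strength is affine in `chi` with slope `-(1 + lambda) * theta`,
#' the linear trade-off between mixing energy and cell force that maintains
#' the same equilibrium.
#'
#' @param theta Equilibrium polymer fraction(s) in (0, 1).
#' @param chi,lambda,N Model parameters.
#' @return `tau0`, vectorised over `theta`.
#' @export
tau0_for_theta <- function(theta, chi = 0, lambda = 1, N = 100) {
  check_theta(theta)
  -(1 + lambda) * (log(1 - theta) + chi * theta^2 + theta * (1 - 1 / N)) / theta
}

#' Existence threshold for cell-free equilibria
#'
#' The saddle-node value of the mixing parameter below which a cell-free gel
#' has no uniform steady state for any initial polymer fraction (the gel
#' dissolves): the minimum over `theta` of [chi_for_theta()] at `tau0 = 0`.
#'
#' @param N Polymer chain length.
#' @return List with `chi_min` and the minimising `theta`.
#' @examples
#' cell_free_existence_threshold(100)$chi_min # ~0.62
#' @export
cell_free_existence_threshold <- function(N = 100) {
  opt <- stats::optimize(function(th) chi_for_theta(th, tau0 = 0, N = N),
                         interval = c(1e-6, 1 - 1e-6), tol = 1e-12)
  list(chi_min = opt$objective, theta = opt$minimum)
}

#' Marginal polymer fractions where traction balances the osmotic stiffness
#'
#' Roots in (0, 1) of \eqn{G - \theta_p f''(\theta_p) = 0}, computed from
#' the equivalent quadratic
#' \deqn{\theta_p^2 + \left\{\frac{1}{2\chi}\left(1 + G - \frac{1}{N}\right)
#'   - 1\right\}\theta_p - \frac{1}{2\chi}\left(G - \frac{1}{N}\right) = 0.}
#' At most two such fractions exist, which is why a continuous equilibrium
#' profile must in fact be spatially uniform.
#'
#' @param G_value Value of the traction potential `G` (>= 0).
#' @param params A [gel_params()] object with `chi != 0`.
#' @return Numeric vector (possibly empty) of roots in (0, 1).
#' @export
marginal_roots <- function(G_value, params) {
  chi <- params$chi
  if (chi == 0) stop("marginal_roots: requires chi != 0", call. = FALSE)
  b <- (1 + G_value - 1 / params$N) / (2 * chi) - 1
  cc <- -(G_value - 1 / params$N) / (2 * chi)
  disc <- b^2 - 4 * cc
  if (disc < 0) return(numeric(0))
  r <- (-b + c(-1, 1) * sqrt(disc)) / 2
  sort(r[r > 0 & r < 1])
}

#' Trace an equilibrium branch of the bifurcation diagram
#'
#' Sweeps the equilibrium polymer fraction over a grid and reports, for each
#' value, the mixing parameter that balances it (via [chi_for_theta()])
#' together with the growth factor and stability label.
#'
#' @param theta Grid of equilibrium polymer fractions in (0, 1).
#' @param tau0,lambda,N Model parameters (`tau0 = 0` gives the cell-free
#'   fold).
#' @param N01 Perturbation amplitude ratio for the stability label.
#' @return Data frame with columns `theta_star`, `chi`, `z`, `stable`.
#' @export
bifurcation_curve <- function(theta = seq(0.01, 0.99, by = 0.005),
                              tau0 = 0, lambda = 1, N = 100, N01 = 1) {
  chi <- chi_for_theta(theta, tau0 = tau0, lambda = lambda, N = N)
  z <- vapply(seq_along(theta), function(i) {
    p <- gel_params(N = N, chi = chi[i], tau0 = tau0, lambda = lambda)
    growth_factor(theta[i], N01, p)$z
  }, numeric(1))
  data.frame(theta_star = theta, chi = chi, z = z,
             stable = ifelse(abs(z) < 1e-10, "marginal",
                             ifelse(z > 0, "stable", "unstable")),
             stringsAsFactors = FALSE)
}
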