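#' @useDynLib gelmech, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Shared domain guard: the logarithmic mixing terms diverge at the endpoints,
# and the model never evaluates there. Callers inside the PDE solver clamp to
# [1e-10, 1 - 1e-10] before calling.
check_theta <- function(theta_p) {
  if (!is.numeric(theta_p) || any(!is.finite(theta_p)))
    stop("theta_p must be finite numeric", call. = FALSE)
  if (any(theta_p <= 0 | theta_p >= 1))
    stop("theta_p must lie strictly inside (0, 1)", call. = FALSE)
  invisible(theta_p)
}

#' Flory-Huggins free energy density
#'
#' Dimensionless free energy per unit volume of the polymer-solvent mixture,
#' \deqn{f(\theta_p) = \frac{\theta_p}{N}\log\theta_p + \theta_s\log\theta_s
#'   + \chi\,\theta_p\theta_s + \mu_p^0\theta_p + \mu_s^0\theta_s,}
#' with \eqn{\theta_s = 1 - \theta_p}. The log terms are the entropy of
#' mixing (always favouring swelling); the \eqn{\chi} term is the energy of
#' mixing and can favour either swelling or phase separation.
#'
#' @param theta_p Polymer volume fraction(s), strictly inside (0, 1).
#' @param params A [gel_params()] object.
#' @return Free energy density, vectorised over `theta_p`.
#' @examples
#' free_energy(0.5, gel_params())
#' @export
free_energy <- function(theta_p, params) {
  check_theta(theta_p)
  ts <- 1 - theta_p
  theta_p / params$N * log(theta_p) + ts * log(ts) +
    params$chi * theta_p * ts + params$mu_p0 * theta_p + params$mu_s0 * ts
}

#' First and second derivatives of the free energy
#'
#' `fprime` is the analytic derivative of [free_energy()] with respect to
#' `theta_p`; `fpp` is the second derivative
#' \deqn{f'' = \frac{1}{N\theta_p} + \frac{1}{1-\theta_p} - 2\chi,}
#' whose sign governs the spinodal and (in the cell-free model) the
#' stability of uniform equilibria.
#'
#' @inheritParams free_energy
#' @return List with components `fprime` and `fpp`, vectorised.
#' @export
free_energy_derivatives <- function(theta_p, params) {
  check_theta(theta_p)
  ts <- 1 - theta_p
  fprime <- (log(theta_p) + 1) / params$N - log(ts) - 1 +
    params$chi * (1 - 2 * theta_p) + params$mu_p0 - params$mu_s0
  fpp <- 1 / (params$N * theta_p) + 1 / ts - 2 * params$chi
  list(fprime = fprime, fpp = fpp)
}

#' Chemical potentials of polymer and solvent
#'
#' \deqn{\mu_p = f + \theta_s f', \qquad \mu_s = f - \theta_p f'.}
#' These satisfy the identities
#' \eqn{\theta_p\mu_p + \theta_s\mu_s = f} and \eqn{\mu_p - \mu_s = f'}.
#' The solvent potential reduces to the closed form
#' \eqn{\mu_s = \log(1-\theta_p) + \theta_p(1 - 1/N) + \chi\theta_p^2 + \mu_s^0},
#' the osmotic driver of the model: solvent flows into the gel where
#' \eqn{\mu_s < \mu_s^e} and out where \eqn{\mu_s > \mu_s^e}.
#'
#' @inheritParams free_energy
#' @return List with components `mu_p` and `mu_s`, vectorised.
#' @export
chemical_potentials <- function(theta_p, params) {
  check_theta(theta_p)
  f <- free_energy(theta_p, params)
  fp <- free_energy_derivatives(theta_p, params)$fprime
  list(mu_p = f + (1 - theta_p) * fp, mu_s = f - theta_p * fp)
}

# Closed form of mu_s (same value as chemical_potentials()$mu_s); used by the
# solver's hot paths.
mu_s_closed <- function(theta_p, params) {
  log(1 - theta_p) + theta_p * (1 - 1 / params$N) +
    params$chi * theta_p^2 + params$mu_s0
}

#' Chemical potential of the external solvent bath
#'
#' In the pure-solvent region outside the gel, `theta_p = 0` and the solvent
#' potential is the constant \eqn{\mu_s^e = f(0) = \mu_s^0}. Only the
#' difference `mu_s - mu_s_e` enters the model, which is why the standard
#' free energies never appear in the dynamics.
#'
#' @param params A [gel_params()] object.
#' @return The scalar `mu_s0`.
#' @export
external_solvent_potential <- function(params) {
  params$mu_s0
}

#' Hill-form cell traction potential
#'
#' \deqn{G(n) = \frac{\tau_0 n^2}{1 + \lambda n^2},}
#' a monotone saturating potential: the traction force a cell population
#' exerts on the network is the gradient of \eqn{\theta_p G}, always directed
#' up cell-density gradients (\eqn{G' > 0} for all \eqn{n > 0}), and
#' saturating at \eqn{\tau_0/\lambda} by contact inhibition.
#'
#' @param n Cell density (>= 0), vectorised.
#' @param params A [gel_params()] object.
#' @return List with components `G` and `dG` (derivative with respect to `n`).
#' @export
cell_potential <- function(n, params) {
  if (any(!is.finite(n)) || any(n < 0))
    stop("cell density n must be finite and >= 0", call. = FALSE)
  denom <- 1 + params$lambda * n^2
  list(G = params$tau0 * n^2 / denom,
       dG = 2 * params$tau0 * n / denom^2)
}
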