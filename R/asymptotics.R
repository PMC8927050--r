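# Closed-form short-time solutions. These double as the independent oracle
# for the PDE solver: both expansions are exact to O(T^2) in time, so the
# solver must agree with them to that order from matching initial data.

# cosh(alpha * X) / cosh(alpha), computed via scaled exponentials so large
# alpha cannot overflow.
cosh_ratio <- function(alpha, X) {
  exp(alpha * (X - 1)) * (1 + exp(-2 * alpha * X)) / (1 + exp(-2 * alpha))
}
tanh_stable <- function(alpha) tanh(alpha)

#' Short-time decay wavenumber
#'
#' \deqn{\alpha = +\sqrt{\frac{\theta\xi}{(2+\kappa_p)\theta(1-\theta)
#'   + (2\eta_s+\kappa_s)\theta^2}},}
#' the spatial decay rate of the early-time velocity field
#' `v_p ~ sinh(alpha X)`; reduces to
#' `sqrt(theta xi / (2 theta (1-theta) + 2 eta_s theta^2))` at zero bulk
#' viscosities, and to 0 in the no-drag limit (spatially uniform early-time
#' response).
#'
#' @param theta Uniform polymer fraction in (0, 1).
#' @param params A [gel_params()] object.
#' @return Non-negative scalar `alpha`.
#' @export
short_time_alpha <- function(theta, params) {
  check_theta(theta)
  C1 <- 2 + params$kappa_p
  C2 <- 2 * params$eta_s + params$kappa_s
  sqrt(theta * params$xi / (C1 * theta * (1 - theta) + C2 * theta^2))
}

#' Short-time solution from uniform initial conditions
#'
#' Leading-order solution for a gel started uniform at `(theta_i, n_i)`:
#' \deqn{L = 1 + T A_0\sinh\alpha, \quad
#'   \theta_p = \theta_i(1 - T\,\alpha A_0\cosh(\alpha X)), \quad
#'   n = n_i(1 - T\,\alpha A_0\cosh(\alpha X)),}
#' where the boundary-velocity coefficient
#' \deqn{A_0 = -\frac{\theta_i G(n_i) + \mu_s(\theta_i) - \mu_s^e}
#'   {\alpha\cosh\alpha\,[(2+\kappa_p)\theta_i
#'   + (2\eta_s+\kappa_s)\theta_i^2/(1-\theta_i)] + \mathcal{R}\sinh\alpha}}
#' vanishes exactly when the initial state is an equilibrium. Its sign
#' decides the early fate of the gel: positive means swelling (solvent
#' influx), negative contraction. In the no-drag limit the fields stay
#' spatially uniform. The bookkeeping small parameters of the expansion
#' only ever appear as the products passed here (time `T_hat` directly).
#'
#' @param theta_i Uniform initial polymer fraction in (0, 1).
#' @param n_i Uniform initial cell density (1 under the standard scaling;
#'   0 for a cell-free gel).
#' @param params A [gel_params()] object.
#' @param T_hat Time(s) at which to evaluate.
#' @param X Node coordinates in `[0, 1]`.
#' @return List with `alpha`, `A0`, and evaluators' output: `L` (per time),
#'   `theta_p` and `n` (matrices, nodes x times).
#' @export
short_time_uniform <- function(theta_i, n_i = 1, params,
                               T_hat = 0, X = gel_grid()) {
  check_theta(theta_i)
  C1 <- 2 + params$kappa_p
  C2 <- 2 * params$eta_s + params$kappa_s
  alpha <- short_time_alpha(theta_i, params)
  K <- C1 * theta_i + C2 * theta_i^2 / (1 - theta_i)
  force0 <- theta_i * cell_potential(n_i, params)$G +
    mu_s_closed(theta_i, params) - external_solvent_potential(params)

  if (params$xi > 0) {
    # scaled by cosh(alpha): A0 sinh(a) = -F tanh(a) / (a K + R tanh(a))
    denom <- alpha * K + params$R * tanh_stable(alpha)
    A0 <- -force0 / (alpha * cosh(alpha) * K + params$R * sinh(alpha))
    L_rate <- -force0 * tanh_stable(alpha) / denom
    c0 <- -force0 * alpha * cosh_ratio(alpha, X) / denom
  } else {
    A0 <- NA_real_ # sinh/cosh limits are taken jointly below
    L_rate <- -force0 / (K + params$R)
    c0 <- rep(-force0 / (K + params$R), length(X))
  }
  L <- 1 + T_hat * L_rate
  theta_p <- theta_i * (1 - outer(c0, T_hat))
  n <- n_i * (1 - outer(c0, T_hat))
  list(alpha = alpha, A0 = A0, L_rate = L_rate, L = L,
       theta_p = theta_p, n = n)
}

#' Short-time solution for a perturbed equilibrium
#'
#' Leading-order evolution of a cosine perturbation of amplitude `eps`
#' (polymer) and `eps * N01` (cells), wavenumber `gamma = Z * pi`, about a
#' uniform equilibrium `theta_star` with the cell density scaled so
#' `n* = 1`. With drag the response mixes a boundary mode
#' `cosh(alpha X)` (gel length changes at rate `A01 sinh(alpha)`) with the
#' decaying/growing cosine mode governed by the growth factor `z`; without
#' drag the length is constant at this order and only the cosine
#' amplitudes evolve. The integer constraint on `gamma` keeps the
#' perturbations mass-free over the domain.
#'
#' With drag present the cell field of this expansion violates the no-flux
#' boundary condition at `X = 1` in a boundary layer (a singular
#' perturbation effect); the result carries a `boundary_layer_warning`
#' flag instead of a correction.
#'
#' @param theta_star Equilibrium polymer fraction in (0, 1).
#' @param N01 Cell/polymer perturbation amplitude ratio.
#' @param Z Positive integer mode number; `gamma = Z * pi`.
#' @param params A [gel_params()] object (`tau0`, `lambda` in the `n* = 1`
#'   scaling).
#' @param T_hat Time(s) at which to evaluate.
#' @param X Node coordinates in `[0, 1]`.
#' @param eps Perturbation amplitude (the expansion is linear in it).
#' @return List with `z`, `H`, `A01`, `alpha`, `gamma`, the fields `L`,
#'   `theta_p`, `n` (matrices, nodes x times), and
#'   `boundary_layer_warning`.
#' @export
short_time_perturbed <- function(theta_star, N01 = 1, Z = 1, params,
                                 T_hat = 0, X = gel_grid(), eps = 0.01) {
  check_theta(theta_star)
  if (length(Z) != 1 || Z != round(Z) || Z < 1)
    stop("Z must be a positive integer (gamma = Z*pi)", call. = FALSE)
  gamma <- Z * pi
  z <- growth_factor(theta_star, N01, params)$z
  C1 <- 2 + params$kappa_p
  C2 <- 2 * params$eta_s + params$kappa_s
  H <- C1 * theta_star * (1 - theta_star) + C2 * theta_star^2
  alpha <- short_time_alpha(theta_star, params)
  cosgX <- cos(gamma * X)

  if (params$xi > 0) {
    # A01 sinh/cosh terms evaluated in cosh-scaled form
    denom <- H / (1 - theta_star) * alpha * cosh(alpha) +
      params$R * sinh(alpha)
    A01 <- alpha^2 * z * cos(gamma) / (alpha^2 + gamma^2) / denom
    denom_scaled <- H / (1 - theta_star) * alpha + params$R * tanh_stable(alpha)
    A01_sinh <- alpha^2 * z * cos(gamma) / (alpha^2 + gamma^2) *
      tanh_stable(alpha) / denom_scaled
    aA01_cosh <- alpha^3 * z * cos(gamma) / (alpha^2 + gamma^2) *
      cosh_ratio(alpha, X) / denom_scaled
    mode <- (1 - theta_star) * gamma^2 / (H * (alpha^2 + gamma^2)) * z * cosgX
    theta_p <- theta_star + eps * outer(cosgX, rep(1, length(T_hat))) -
      eps * theta_star * outer(aA01_cosh + mode, T_hat)
    n <- 1 + eps * N01 * outer(cosgX, rep(1, length(T_hat))) -
      eps * outer(aA01_cosh + mode + params$D * gamma^2 * N01 * cosgX, T_hat)
    L <- 1 + eps * A01_sinh * T_hat
    warn <- TRUE
  } else {
    A01 <- 0
    decay <- (1 - theta_star) / H * z
    theta_p <- theta_star + eps * outer(cosgX, rep(1, length(T_hat))) -
      eps * theta_star * decay * outer(cosgX, T_hat)
    n <- 1 + eps * N01 * outer(cosgX, rep(1, length(T_hat))) -
      eps * outer((decay + params$D * gamma^2 * N01) * cosgX, T_hat)
    L <- rep(1, length(T_hat))
    warn <- FALSE
  }
  list(z = z, H = H, A01 = A01, alpha = alpha, gamma = gamma,
       L = L, theta_p = theta_p, n = n, boundary_layer_warning = warn)
}
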