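#' Dimensionless model parameters
#'
#' Bundles every dimensionless constant of the gel model, grouped by role:
#' free-energy (mixing) parameters, cell-traction parameters, and mechanical
#' ratios. All quantities are dimensionless; lengths are scaled on the initial
#' gel length, time on the ratio of polymer viscosity to the free-energy
#' density scale, and cell density on its initial mean (so an initially
#' uniform seeded gel has `n = 1`).
#'
#' @param N Polymer chain length (> 0). Entropy of mixing of the network
#'   scales as `1/N`, so large `N` means the network contributes little
#'   mixing entropy.
#' @param chi Flory interaction parameter. `chi > 0` favours phase
#'   separation (contraction/syneresis), `chi < 0` favours mixing (swelling).
#' @param mu_p0,mu_s0 Standard free energies of pure polymer and pure
#'   solvent. They cancel from every quantity the dynamics uses (only
#'   `mu_s - mu_s_e` and derivatives of `f` enter the model) but are kept for
#'   generality.
#' @param tau0 Cell traction strength (>= 0). `tau0 = 0` turns cells into
#'   passive tracers.
#' @param lambda Contact inhibition parameter (> 0); the traction potential
#'   saturates at `tau0 / lambda` as the cell density grows.
#' @param eta_s Solvent/polymer dynamic viscosity ratio (>= 0).
#' @param kappa_p,kappa_s Bulk/polymer viscosity ratios (>= 0). Both default
#'   to zero: they only ever appear in the combinations `2 + kappa_p` and
#'   `2 eta_s + kappa_s`.
#' @param xi Interphase drag coefficient (>= 0), friction proportional to
#'   `theta_p * theta_s * (v_p - v_s)`.
#' @param R Interface resistance (>= 0): permeability-type coefficient
#'   opposing solvent flux across the gel boundary.
#' @param D Cell random-motility (diffusion) coefficient (>= 0).
#'
#' @return An object of class `gel_params`: a validated named list.
#' @examples
#' p <- gel_params(chi = 0.75, eta_s = 0.25, xi = 0.5, R = 0.5)
#' p
#' @export
gel_params <- function(N = 100, chi = 0, mu_p0 = 0, mu_s0 = 0,
                       tau0 = 0, lambda = 1,
                       eta_s = 1, kappa_p = 0, kappa_s = 0,
                       xi = 0, R = 0, D = 0) {
  p <- list(N = N, chi = chi, mu_p0 = mu_p0, mu_s0 = mu_s0,
            tau0 = tau0, lambda = lambda,
            eta_s = eta_s, kappa_p = kappa_p, kappa_s = kappa_s,
            xi = xi, R = R, D = D)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("gel_params: '", nm, "' must be a single finite number", call. = FALSE)
  }
  if (p$N <= 0) stop("gel_params: N must be > 0", call. = FALSE)
  if (p$lambda <= 0) stop("gel_params: lambda must be > 0", call. = FALSE)
  for (nm in c("tau0", "eta_s", "kappa_p", "kappa_s", "xi", "R", "D"))
    if (p[[nm]] < 0) stop("gel_params: ", nm, " must be >= 0", call. = FALSE)
  structure(p, class = "gel_params")
}

#' @export
print.gel_params <- function(x, ...) {
  cat("<gel_params> (dimensionless)\n")
  cat(sprintf("  energy:    N = %g, chi = %g, mu_p0 = %g, mu_s0 = %g\n",
              x$N, x$chi, x$mu_p0, x$mu_s0))
  cat(sprintf("  cells:     tau0 = %g, lambda = %g, D = %g\n",
              x$tau0, x$lambda, x$D))
  cat(sprintf("  mechanics: eta_s = %g, kappa_p = %g, kappa_s = %g, xi = %g, R = %g\n",
              x$eta_s, x$kappa_p, x$kappa_s, x$xi, x$R))
  invisible(x)
}

#' Convert physical constants to the dimensionless parameter set
#'
#' Documentation helper for relating laboratory quantities to the
#' dimensionless groups used throughout the package. The scales are: length
#' on the initial gel size `L0`, time on `eta_p * nu_m / (kB * Temp)`, cell
#' density on the characteristic (mean initial) density `n0`. Not used
#' internally - the model is solved entirely in dimensionless form.
#'
#' @param kB Boltzmann constant (J/K).
#' @param Temp Absolute temperature (K).
#' @param nu_m Monomer characteristic volume (m^3).
#' @param eta_p Polymer dynamic viscosity (Pa s).
#' @param L0 Initial gel length (m).
#' @param n0 Characteristic cell density (cells/m^3).
#' @param eta_s,kappa_p,kappa_s Phase viscosities (Pa s).
#' @param xi Dimensional drag (Pa s/m^2).
#' @param R Dimensional interface resistance (Pa s/m).
#' @param D Dimensional cell diffusivity (m^2/s).
#' @param tau0 Dimensional traction strength (J m^3, per squared density).
#' @param lambda Dimensional contact inhibition (m^6).
#'
#' @return Named list of the dimensionless ratios.
#' @export
nondimensionalise <- function(kB = 1.380649e-23, Temp = 310, nu_m, eta_p, L0, n0,
                              eta_s = 0, kappa_p = 0, kappa_s = 0,
                              xi = 0, R = 0, D = 0, tau0 = 0, lambda = 0) {
  list(
    eta_s = eta_s / eta_p,
    kappa_p = kappa_p / eta_p,
    kappa_s = kappa_s / eta_p,
    xi = L0^2 * xi / eta_p,
    R = L0 * R / eta_p,
    tau0 = tau0 * n0^2 * nu_m / (kB * Temp),
    lambda = n0^2 * lambda,
    D = eta_p * nu_m * D / (kB * Temp * L0^2),
    time_scale = eta_p * nu_m / (kB * Temp)
  )
}
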