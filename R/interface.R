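#' Scenario configuration
#'
#' Bundles everything one simulation needs: parameters, initial-condition
#' specification and solver settings. The initial condition is either
#' `"uniform"` or `"cosine"`; a cosine specification perturbs one field by
#' `amplitude * cos(Z * pi * X)` about its mean, keeping the perturbation
#' mass-free and symmetric about the gel centre.
#'
#' @param name Scenario name.
#' @param params A [gel_params()] object.
#' @param theta_i Mean initial polymer fraction in (0, 1).
#' @param n_i Mean initial cell density (>= 0; 0 for a cell-free gel).
#' @param ic_kind "uniform" or "cosine".
#' @param perturb Which field carries the cosine: "theta" or "n".
#' @param amplitude Cosine amplitude.
#' @param Z Positive integer mode number.
#' @param settings A [gel_settings()] object.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(name, params, theta_i, n_i,
                            ic_kind = c("uniform", "cosine"),
                            perturb = c("theta", "n"), amplitude = 0, Z = 1,
                            settings = gel_settings()) {
  ic_kind <- match.arg(ic_kind)
  perturb <- match.arg(perturb)
  stopifnot(theta_i > 0, theta_i < 1, n_i >= 0)
  if (ic_kind == "cosine") stopifnot(Z == round(Z), Z >= 1)
  structure(list(name = name, params = params, theta_i = theta_i, n_i = n_i,
                 ic_kind = ic_kind, perturb = perturb,
                 amplitude = amplitude, Z = Z, settings = settings),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s\n", x$name))
  cat(sprintf("  IC: %s (theta_i = %g, n_i = %g", x$ic_kind, x$theta_i, x$n_i))
  if (x$ic_kind == "cosine")
    cat(sprintf(", %s + %g cos(%d pi X)", x$perturb, x$amplitude, x$Z))
  cat(")\n")
  print(x$params)
  invisible(x)
}

ic_functions <- function(config) {
  th_fun <- function(X) rep(config$theta_i, length(X))
  n_fun <- function(X) rep(config$n_i, length(X))
  if (config$ic_kind == "cosine") {
    a <- config$amplitude
    Z <- config$Z
    if (config$perturb == "theta")
      th_fun <- function(X) config$theta_i + a * cos(Z * pi * X)
    else
      n_fun <- function(X) config$n_i + a * cos(Z * pi * X)
  }
  list(theta_i = th_fun, n_i = n_fun)
}

#' Run a scenario
#'
#' @param config A [scenario_config()] (or registry name).
#' @param settings Optional [gel_settings()] overriding the config's.
#' @return A `gel_trajectory` (see [simulate_gel()]).
#' @export
run_scenario <- function(config, settings = NULL) {
  if (is.character(config)) config <- scenario_registry(config)
  ic <- ic_functions(config)
  simulate_gel(ic$theta_i, ic$n_i, config$params,
               if (is.null(settings)) config$settings else settings)
}

# horizons chosen from the reported equilibration times, with headroom
registry_table <- function() {
  base_mech <- list(eta_s = 0.25, xi = 0.5, R = 0.5)
  small_mech <- list(eta_s = 0.1, xi = 0.1, R = 0.1)
  list(
    fig3a = list(theta_i = 0.6, n_i = 0, chi = 0.75, mech = base_mech,
                 tau0 = 0, D = 0, t_end = 250),
    fig3b = list(theta_i = 0.6, n_i = 0, chi = 1.5, mech = base_mech,
                 tau0 = 0, D = 0, t_end = 60),
    fig3c = list(theta_i = 0.25, n_i = 0, chi = 0.75, mech = base_mech,
                 tau0 = 0, D = 0, t_end = 300),
    fig4a = list(theta_i = 0.6, n_i = 1, chi = 0.75, mech = base_mech,
                 tau0 = 0.1, D = 0.01, t_end = 250),
    fig4b = list(theta_i = 0.6, n_i = 1, chi = 0.75, mech = base_mech,
                 tau0 = 1, D = 0.01, t_end = 100),
    fig5_base = list(theta_i = 0.6, n_i = 1, chi = 0.75, mech = small_mech,
                     tau0 = 1, D = 0, t_end = 30),
    fig5_drag = list(theta_i = 0.6, n_i = 1, chi = 0.75,
                     mech = list(eta_s = 0.1, xi = 5, R = 0.1),
                     tau0 = 1, D = 0, t_end = 60),
    fig5_resistance = list(theta_i = 0.6, n_i = 1, chi = 0.75,
                           mech = list(eta_s = 0.1, xi = 0.1, R = 5),
                           tau0 = 1, D = 0, t_end = 60),
    fig5_viscosity = list(theta_i = 0.6, n_i = 1, chi = 0.75,
                          mech = list(eta_s = 5, xi = 0.1, R = 0.1),
                          tau0 = 1, D = 0, t_end = 160),
    fig7a = list(theta_i = 0.6, n_i = 1, chi = 0.75,
                 mech = list(eta_s = 0.1, xi = 5, R = 0.1),
                 tau0 = 1, D = 0.005, t_end = 80),
    fig7c = list(theta_i = 0.6, n_i = 1, chi = 0.75,
                 mech = list(eta_s = 0.1, xi = 5, R = 0.1),
                 tau0 = 1, D = 1, t_end = 40),
    fig8a = list(theta_i = 0.2, n_i = 1, chi = 0.75, mech = base_mech,
                 tau0 = 1, D = 0.01, t_end = 40),
    fig8c = list(theta_i = 0.2, n_i = 0, chi = 1.5, mech = base_mech,
                 tau0 = 0, D = 0, t_end = 60),
    fig9 = list(theta_i = 0.6, n_i = 0, chi = 0.75, mech = base_mech,
                tau0 = 0, D = 0, t_end = 250,
                cosine = list(perturb = "theta", amplitude = 0.025, Z = 1)),
    fig10 = list(theta_i = 0.6, n_i = 1, chi = 0.75, mech = base_mech,
                 tau0 = 1, D = 0, t_end = 60,
                 cosine = list(perturb = "theta", amplitude = 0.025, Z = 1)),
    # caption amplitude 0.025 (the running text mentions 0.05 once)
    fig11 = list(theta_i = 0.6, n_i = 1, chi = 0.75, mech = base_mech,
                 tau0 = 1, D = 0, t_end = 60,
                 cosine = list(perturb = "n", amplitude = 0.025, Z = 1)),
    fig12 = list(theta_i = 0.5, n_i = 1, chi = -0.1,
                 mech = list(eta_s = 0.1, xi = 1.5, R = 1.5),
                 tau0 = 0.8, D = 0, t_end = 4000),
    fig12c = list(theta_i = 0.5, n_i = 1, chi = -0.1,
                  mech = list(eta_s = 0.1, xi = 1.5, R = 0.5),
                  tau0 = 0.8, D = 0, t_end = 4000),
    fig12d = list(theta_i = 0.5, n_i = 1, chi = -0.1,
                  mech = list(eta_s = 0.1, xi = 0.5, R = 1.5),
                  tau0 = 0.8, D = 0, t_end = 4000),
    fig12e = list(theta_i = 0.5, n_i = 1, chi = -0.1,
                  mech = list(eta_s = 0.1, xi = 0.5, R = 0.5),
                  tau0 = 0.8, D = 0, t_end = 4000))
}

#' Reference scenario registry
#'
#' Returns the exact parameter set of one of the package's reference
#' scenarios: cell-free swelling/contraction (`fig3a`-`fig3c`), cell-seeded
#' swelling/contraction (`fig4a`, `fig4b`), mechanical-parameter sweeps
#' (`fig5_*`), cell diffusion (`fig7a`, `fig7c`), reduced initial polymer
#' (`fig8a`, `fig8c`), non-uniform initial conditions (`fig9`-`fig11`) and
#' the oscillating swelling regime and its suppressed variants
#' (`fig12`-`fig12e`).
#'
#' @param name Scenario name; call with no arguments to list valid names.
#' @return A [scenario_config()].
#' @examples
#' scenario_registry("fig3a")
#' @export
scenario_registry <- function(name) {
  tab <- registry_table()
  if (missing(name)) return(names(tab))
  if (!name %in% names(tab))
    stop("unknown scenario '", name, "'; valid names: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  e <- tab[[name]]
  params <- gel_params(chi = e$chi, tau0 = e$tau0, D = e$D,
                       eta_s = e$mech$eta_s, xi = e$mech$xi, R = e$mech$R)
  if (is.null(e$cosine))
    scenario_config(name, params, e$theta_i, e$n_i,
                    settings = gel_settings(t_end = e$t_end))
  else
    scenario_config(name, params, e$theta_i, e$n_i, ic_kind = "cosine",
                    perturb = e$cosine$perturb, amplitude = e$cosine$amplitude,
                    Z = e$cosine$Z,
                    settings = gel_settings(t_end = e$t_end))
}

# documented Table-2 style ranges; values outside produce a warning only
param_ranges <- list(theta_i = c(0.2, 0.7), n_i = c(0, 1), tau0 = c(0, 1),
                     D = c(0, 1), chi = c(-0.1, 1.5), R = c(0, 5),
                     xi = c(0, 5), eta_s = c(0, 5))

#' Load a scenario configuration from a YAML file
#'
#' The file holds sections `energy`, `cells`, `mechanics`, `ic` and
#' `solver`; omitted keys take the model defaults (`N = 100`,
#' `lambda = 1`, `mu_p0 = mu_s0 = 0`, `kappa_p = kappa_s = 0`). Values
#' outside the documented study ranges produce a warning, unknown keys an
#' error.
#'
#' @param path Path to a YAML file.
#' @return A [scenario_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  # keep single-letter keys like "N" verbatim (YAML 1.1 would read them as
  # booleans); no config field is a logical, so this is lossless
  y <- yaml::read_yaml(path, handlers = list("bool#yes" = function(x) x,
                                             "bool#no" = function(x) x))
  known <- c("name", "energy", "cells", "mechanics", "ic", "solver")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "), call. = FALSE)

  pick <- function(block, key, default) {
    v <- y[[block]][[key]]
    if (is.null(v)) default else v
  }
  allowed <- list(energy = c("N", "chi", "mu_p0", "mu_s0"),
                  cells = c("tau0", "lambda", "D", "n_i"),
                  mechanics = c("eta_s", "kappa_p", "kappa_s", "xi", "R"),
                  ic = c("kind", "theta_i", "n_i", "perturb", "amplitude", "Z"),
                  solver = c("dX", "dT", "t_end", "steady_tol",
                             "dissolution_theta"))
  for (blk in names(allowed)) {
    bad <- setdiff(names(y[[blk]]), allowed[[blk]])
    if (length(bad))
      stop("unknown key(s) in [", blk, "]: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }

  params <- gel_params(
    N = pick("energy", "N", 100), chi = pick("energy", "chi", 0),
    mu_p0 = pick("energy", "mu_p0", 0), mu_s0 = pick("energy", "mu_s0", 0),
    tau0 = pick("cells", "tau0", 0), lambda = pick("cells", "lambda", 1),
    D = pick("cells", "D", 0),
    eta_s = pick("mechanics", "eta_s", 1),
    kappa_p = pick("mechanics", "kappa_p", 0),
    kappa_s = pick("mechanics", "kappa_s", 0),
    xi = pick("mechanics", "xi", 0), R = pick("mechanics", "R", 0))

  theta_i <- pick("ic", "theta_i", 0.5)
  n_i <- pick("ic", "n_i", pick("cells", "n_i", 0))
  for (nm in names(param_ranges)) {
    v <- switch(nm, theta_i = theta_i, n_i = n_i, params[[nm]])
    rng <- param_ranges[[nm]]
    if (!is.null(v) && (v < rng[1] || v > rng[2]))
      warning(sprintf("config value %s = %g outside documented range [%g, %g]",
                      nm, v, rng[1], rng[2]), call. = FALSE)
  }

  settings <- gel_settings(
    dX = pick("solver", "dX", 0.002), dT = pick("solver", "dT", 5e-4),
    t_end = pick("solver", "t_end", 100),
    steady_tol = pick("solver", "steady_tol", 1e-8),
    dissolution_theta = pick("solver", "dissolution_theta", 1e-3))

  scenario_config(y$name %||% "unnamed",
                  params, theta_i, n_i,
                  ic_kind = pick("ic", "kind", "uniform"),
                  perturb = pick("ic", "perturb", "theta"),
                  amplitude = pick("ic", "amplitude", 0),
                  Z = pick("ic", "Z", 1), settings = settings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scenario configuration to a YAML file
#'
#' Inverse of [load_config()]: the written file reads back to an identical
#' configuration.
#'
#' @param config A [scenario_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  p <- config$params
  s <- config$settings
  y <- list(
    name = config$name,
    energy = list(N = p$N, chi = p$chi, mu_p0 = p$mu_p0, mu_s0 = p$mu_s0),
    cells = list(tau0 = p$tau0, lambda = p$lambda, D = p$D),
    mechanics = list(eta_s = p$eta_s, kappa_p = p$kappa_p,
                     kappa_s = p$kappa_s, xi = p$xi, R = p$R),
    ic = list(kind = config$ic_kind, theta_i = config$theta_i,
              n_i = config$n_i, perturb = config$perturb,
              amplitude = config$amplitude, Z = config$Z),
    solver = list(dX = s$dX, dT = s$dT, t_end = s$t_end,
                  steady_tol = s$steady_tol,
                  dissolution_theta = s$dissolution_theta))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Summarise a finished run
#'
#' @param trajectory A [simulate_gel()] result.
#' @return A list (class `run_summary`) with the termination reason, steady
#'   values (present only when the run terminated steady), 2-d.p. rounded
#'   copies for direct comparison against reported values, the mass drift
#'   and the regime label.
#' @export
run_summary <- function(trajectory) {
  ss <- steady_state(trajectory)
  drift <- mass_audit(trajectory)
  out <- list(termination = trajectory$termination,
              regime = detect_regime(trajectory),
              mass_drift_pct = as.list(drift),
              clamped = trajectory$clamped)
  if (trajectory$termination == "steady") {
    out$steady <- list(theta_star = ss$theta_star, n_star = ss$n_star,
                       L_star = ss$L_star)
    out$steady_2dp <- lapply(out$steady, round, digits = 2)
  }
  structure(out, class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("<run_summary>", x$termination, "/", x$regime, "\n")
  if (!is.null(x$steady))
    cat(sprintf("  steady: theta* = %.4f, n* = %.4f, L* = %.4f\n",
                x$steady$theta_star, x$steady$n_star, x$steady$L_star))
  cat(sprintf("  mass drift: polymer %.2e%%, cells %.2e%%\n",
              x$mass_drift_pct$polymer, x$mass_drift_pct$cells))
  invisible(x)
}

#' Write trajectory outputs to disk
#'
#' Writes three deterministic, byte-stable files: a time-series CSV
#' (columns `T`, `L`, `theta_p` and `n` at `X = 0` and `X = 1`, `max_vp`),
#' a spatial-snapshot CSV in long format (`T`, `X`, `theta_p`, `n`, `v_p`),
#' and a JSON run summary.
#'
#' @param trajectory A [simulate_gel()] result.
#' @param dir Output directory (created if needed).
#' @param stem Filename stem (default "run").
#' @return Named character vector of the files written, invisibly.
#' @export
write_outputs <- function(trajectory, dir, stem = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  series_path <- file.path(dir, paste0(stem, "_series.csv"))
  snap_path <- file.path(dir, paste0(stem, "_snapshots.csv"))
  summary_path <- file.path(dir, paste0(stem, "_summary.json"))

  ser <- trajectory$series
  names(ser) <- c("T", "L", "theta_p_X0", "theta_p_X1", "n_X0", "n_X1",
                  "max_vp")
  utils::write.csv(ser, series_path, row.names = FALSE)

  S <- length(trajectory$T)
  M <- length(trajectory$X)
  long <- data.frame(
    T = rep(trajectory$T, each = M), X = rep(trajectory$X, S),
    theta_p = as.vector(trajectory$theta_p), n = as.vector(trajectory$n),
    v_p = as.vector(trajectory$v_p))
  utils::write.csv(long, snap_path, row.names = FALSE)

  jsonlite::write_json(unclass(run_summary(trajectory)), summary_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(series = series_path, snapshots = snap_path,
              summary = summary_path))
}
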