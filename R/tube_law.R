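# Tube law and timestep operations exposed at the R level.  The compiled core
# uses the same closed forms (single source in src/core.cpp).

#' Viscoelastic tube-law pressure
#'
#' P = external_pressure + elastic(A) + viscous(dA/dt) with the elastic part
#' beta/A0 (sqrt(A) - sqrt(A0)) (zero at A = A0) and the Kelvin-Voigt viscous
#' part gamma dA/dt (zero in steady state).
#'
#' @param A cross-sectional area (cm^2), vectorized.
#' @param dA_dt area rate of change (cm^2/s).
#' @param A0 unstressed area (cm^2).
#' @param beta elastic tube-law coefficient (mmHg cm).
#' @param gamma wall viscosity coefficient (mmHg s/cm^2).
#' @param external_pressure tissue pressure (mmHg).
#' @return pressure (mmHg).
#' @export
tube_law_pressure <- function(A, dA_dt = 0, A0, beta, gamma = 0,
                              external_pressure = 0) {
  if (any(A <= 0))
    stop("collapse error: non-positive area passed to the tube law")
  n <- max(length(A), length(A0), length(beta))
  cpp_tube_law(rep_len(A, n), rep_len(dA_dt, n), rep_len(A0, n),
               rep_len(beta, n), rep_len(gamma, n), external_pressure)
}

#' Local wave speed of the elastic tube law
#'
#' c = sqrt(k A dP/dA / rho) with k the mmHg-to-CGS conversion; for this law
#' c = sqrt(k beta sqrt(A) / (2 rho A0)).
#'
#' @inheritParams tube_law_pressure
#' @param rho blood density (g/cm^3).
#' @return wave speed (cm/s).
#' @export
wave_speed <- function(A, A0, beta, rho = 1.06) {
  n <- max(length(A), length(A0), length(beta))
  cpp_wave_speed(rep_len(A, n), rep_len(A0, n), rep_len(beta, n), rho)
}

# beta profile of a segment at its cell grid, plus the initialized state
discretize_segment <- function(seg, numerics, init_pressure = NULL) {
  g <- segment_grid(seg, numerics$dx_max)
  rho <- numerics$rho
  betac <- beta_from_c0(g$A0c, g$c0c, rho)
  betaf <- beta_from_c0(g$A0f, g$c0f, rho)
  P0 <- init_pressure %||% numerics$init_pressure
  A <- area_at_pressure(g$A0c, betac, P0, seg$external_pressure)
  kf <- 2 * pi * (seg$friction_zeta + 2) * numerics$mu / rho
  list(n = g$n, dx = g$dx, kf = kf, gamma = seg$wall_viscosity,
       pext = seg$external_pressure, rho = rho,
       A = A, Q = rep(0, g$n),
       A0c = g$A0c, betac = betac, A0f = g$A0f, betaf = betaf)
}

#' Stable time step for the explicit 1D scheme
#'
#' dt = cfl * min over all grid cells of dx / (|u| + c), evaluated at the
#' network's current (initialization) state.
#'
#' @param net a `cv_network` with at least one segment, or a single
#'   discretized segment as produced internally.
#' @param cfl Courant number in (0, 1].
#' @return time step (s).
#' @export
stable_timestep <- function(net, cfl = 0.9) {
  stopifnot(cfl > 0, cfl <= 1)
  segs <- if (inherits(net, "cv_network"))
    lapply(net$segments, discretize_segment, numerics = net$numerics)
  else list(net)
  dts <- vapply(segs, function(s) {
    c <- wave_speed(s$A, s$A0c, s$betac, s$rho)
    u <- abs(s$Q / s$A)
    s$dx / max(u + c)
  }, 0)
  cfl * min(dts)
}
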