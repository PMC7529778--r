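# Segment- and junction-level solver operations.  These drive the compiled
# kernels directly and exist so the numerical building blocks can be exercised
# (and verified against analytic oracles) outside a whole-network run.

BC_CODES <- c(closed = 0L, flow = 1L, nonreflecting = 2L, impedance = 3L,
              pressure = 4L)

#' Advance a single 1D segment
#'
#' Integrates one arterial segment for `n_steps` of size `dt` with the
#' two-step Lax-Wendroff finite-volume scheme (Poiseuille friction,
#' viscoelastic wall correction by operator splitting).
#'
#' @param seg an [artery_segment()] or a discretized segment state as
#'   returned by a previous call.
#' @param dt time step (s); must satisfy the CFL condition (checked).
#' @param n_steps number of steps.
#' @param bc_in,bc_out boundary conditions: one of `"closed"`,
#'   `"flow"` (prescribed flow, see `value_in`/`value_out`),
#'   `"nonreflecting"`, `"impedance"` (outlet only; see `Z_out`, `P_out`),
#'   `"pressure"` (prescribed pressure).
#' @param value_in,value_out prescribed boundary values; scalar, or a vector
#'   sampled per step (recycled).
#' @param Z_out,P_out terminal impedance (mmHg s/ml) and distal pressure
#'   (mmHg) for `bc_out = "impedance"`.
#' @param numerics numeric parameters when `seg` is an [artery_segment()].
#' @param init_pressure initial uniform pressure (mmHg).
#' @param sample_cell cell index (1-based) at which time series are sampled.
#' @param sample_stride sample every this many steps.
#' @return list with final state (`A`, `Q`, discretization fields) and
#'   sampled series `t`, `A_s`, `Q_s`, `P_s`, `volume`, plus the per-step
#'   boundary fluxes `q_in`, `q_out`.
#' @export
advance_segment <- function(seg, dt, n_steps = 1L,
                            bc_in = "closed", value_in = 0,
                            bc_out = "closed", value_out = 0,
                            Z_out = 1, P_out = 0,
                            numerics = list(rho = 1.06, mu = 0.04,
                                            dx_max = 0.25, init_pressure = 80),
                            init_pressure = NULL,
                            sample_cell = NULL, sample_stride = 1L) {
  st <- if (inherits(seg, "cv_segment"))
    discretize_segment(seg, numerics, init_pressure) else seg
  if (is.null(sample_cell)) sample_cell <- ceiling(st$n / 2)
  res <- cpp_advance_segment(st, as.integer(n_steps), dt,
                             BC_CODES[[bc_in]], as.numeric(value_in),
                             BC_CODES[[bc_out]], as.numeric(value_out),
                             Z_out, P_out,
                             as.integer(sample_cell) - 1L,
                             as.integer(sample_stride))
  out <- st
  out$A <- res$A
  out$Q <- res$Q
  out$series <- data.frame(t = res$t, A = res$A_s, Q = res$Q_s, P = res$P_s,
                           volume = res$volume)
  out$q_in <- res$q_in
  out$q_out <- res$q_out
  out$volume <- res$final_volume
  out
}

#' Solve a bifurcation (junction) coupling
#'
#' Given the outgoing Riemann invariant of the parent outlet and of each
#' daughter inlet, finds the interface states enforcing exact mass
#' conservation and continuity of total pressure (Newton iteration on the
#' interface areas).
#'
#' @param parent list with `W1` (outgoing invariant u + 4c of the parent,
#'   cm/s), `A0`, `beta`, optionally `pext` and an initial guess `A`.
#' @param daughters list of lists with `W2` (invariant u - 4c), `A0`, `beta`,
#'   optionally `pext`, `A`.
#' @param rho blood density (g/cm^3).
#' @return list with interface areas, velocities and flows on each side and
#'   the converged residuals (`residual_mass` ml/s, `residual_ptot` mmHg).
#' @export
solve_junction <- function(parent, daughters, rho = 1.06) {
  stopifnot(length(daughters) >= 1)
  g <- function(el, f, d = NA_real_) if (is.null(el[[f]])) d else el[[f]]
  cpp_solve_junction(
    parent$W1, parent$A0, parent$beta, g(parent, "pext", 0),
    vapply(daughters, `[[`, 0, "W2"),
    vapply(daughters, `[[`, 0, "A0"),
    vapply(daughters, `[[`, 0, "beta"),
    vapply(daughters, function(d) g(d, "pext", 0), 0),
    rho,
    g(parent, "A", -1), vapply(daughters, function(d) g(d, "A", -1), 0))
}
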