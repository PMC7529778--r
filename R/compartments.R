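# Lumped-compartment stepping and the two 1D<->0D interfaces.
#
# advance_compartments() integrates a lumped-only network (0 segments are
# legal) through the same compiled engine as full runs, so the 0D machinery
# can be tested in isolation against closed-form solutions.

#' Advance the lumped compartments of a network
#'
#' Integrates a (typically lumped-only) network for `n_steps` explicit steps
#' of size `dt` using the same staggered update as full closed-loop runs.
#' Volume bookkeeping is exact: the change of each compartment volume equals
#' the net inter-compartment flux times dt.
#'
#' @param net a `cv_network` (0 segments allowed).
#' @param dt time step (s).
#' @param n_steps number of steps.
#' @param record sites to record, as for [run_simulation()]; default records
#'   P and V of every compartment.
#' @param hr heart-rate override (bpm); irrelevant for networks without
#'   chambers but sets the internal beat bookkeeping.
#' @return a `cv_run` store (see [run_simulation()]).
#' @export
advance_compartments <- function(net, dt, n_steps, record = NULL, hr = 60) {
  duration <- dt * n_steps
  run_simulation(net, n_beats = 1L, record_sites = record, dt = dt,
                 hr = 60 / duration, sample_stride = 1L,
                 check_convergence = FALSE)
}

#' Couple a terminal 1D artery to its arteriole (interface step)
#'
#' Solves the boundary state of a terminal artery against the series
#' characteristic impedance and the current arteriole pressure: the outgoing
#' 1D characteristic is honored and the boundary satisfies
#' Q = (P_boundary - P_arteriole) / Z.
#'
#' @param terminal list describing the terminal face: `A` (current boundary
#'   area guess, cm^2), `u` (velocity, cm/s), `A0`, `beta`, optionally `pext`;
#'   alternatively give `W1` directly.
#' @param interface list with `impedance` (Z_c) and optionally
#'   `access_resistance` (lumped in series).
#' @param arteriole_pressure current arteriole pressure (mmHg).
#' @param rho blood density (g/cm^3).
#' @return list with the coupled boundary values `A`, `u`, `Q`, `P`.
#' @export
arteriolar_interface_step <- function(terminal, interface, arteriole_pressure,
                                      rho = 1.06) {
  W1 <- terminal$W1
  if (is.null(W1)) {
    cc <- wave_speed(terminal$A, terminal$A0, terminal$beta, rho)
    W1 <- terminal$u + 4 * cc
  }
  Z <- interface$impedance + (interface$access_resistance %||% 0)
  stopifnot(Z > 0)
  pext <- terminal$pext %||% 0
  cpp_solve_terminal(W1, terminal$A0, terminal$beta, pext, Z,
                     arteriole_pressure, rho,
                     terminal$A %||% terminal$A0)
}

#' Aortic root interface (0D -> 1D)
#'
#' Computes the ascending-aorta inlet boundary data from the left-ventricular
#' pressure and the aortic valve state.  The inlet flow equals the valve flow
#' (opening^2 dP / R_open); a closed valve gives zero inlet flow and pure
#' reflection of the incoming characteristic.
#'
#' @param lv_pressure left ventricular pressure (mmHg).
#' @param valve an aortic `cv_valve` (fields `opening`, `R_open`).
#' @param inlet list describing the inlet face: `A` (area guess), `W2`
#'   (incoming invariant u - 4c extrapolated from the interior), `A0`,
#'   `beta`, optionally `pext`, and `P` (current root pressure used for the
#'   valve pressure difference).
#' @param rho blood density (g/cm^3).
#' @return list with `Q` (inlet flow, ml/s), `A`, `u`, `P` at the inlet face.
#' @export
aortic_root_interface <- function(lv_pressure, valve, inlet, rho = 1.06) {
  root_P <- inlet$P %||% tube_law_pressure(inlet$A, 0, inlet$A0, inlet$beta,
                                           external_pressure = inlet$pext %||% 0)
  q <- valve$opening^2 * (lv_pressure - root_P) / valve$R_open
  pext <- inlet$pext %||% 0
  if (valve$opening == 0 || q == 0) {
    # closed valve: u = 0, 4c = -W2
    co <- -inlet$W2 / 4
    k <- .MMHG * inlet$beta / (2 * rho * inlet$A0)
    A <- (co^2 / k)^2
    return(list(Q = 0, A = A, u = 0,
                P = tube_law_pressure(A, 0, inlet$A0, inlet$beta,
                                      external_pressure = pext)))
  }
  res <- cpp_solve_inflow(inlet$W2, q, inlet$A0, inlet$beta, pext, rho,
                          inlet$A %||% inlet$A0)
  list(Q = q, A = res$A, u = res$u, P = res$P)
}
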