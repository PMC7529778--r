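# Time-varying elastance chambers and dynamic valves.

#' Chamber elastance at a given time
#'
#' E(t) = E_min + E_amp e(phi) with phi = (t mod RR)/RR and e the normalized
#' activation (periodic, continuous, attaining 0 and 1 within each beat).
#'
#' @param chamber a [heart_chamber()].
#' @param t time (s), vectorized.
#' @param RR beat period (s).
#' @return elastance (mmHg/ml).
#' @export
elastance <- function(chamber, t, RR) {
  stopifnot(all(t >= 0), RR > 0)
  a <- chamber$activation
  phi <- (t %% RR) / RR
  chamber$E_min + chamber$E_amp * cpp_activation(phi, a$onset, a$duration, a$peak)
}

#' Chamber pressure from the elastance law
#'
#' P = E(t) (V - V0): linear in volume at fixed time, increasing in both V
#' and E; P = 0 (the law's reference offset) at V = V0.
#'
#' @param chamber a [heart_chamber()].
#' @param V chamber volume (ml).
#' @param t time (s).
#' @param RR beat period (s).
#' @return pressure (mmHg).
#' @export
chamber_pressure <- function(chamber, V, t, RR) {
  stopifnot(all(V >= 0))
  elastance(chamber, t, RR) * (V - chamber$V0)
}

#' Update a valve state
#'
#' Advances the opening dynamics one step.  Four effects act on the opening
#' rate: the transvalvular pressure difference and the dynamic blood-motion
#' term (both scaled by a lever arm that vanishes when fully open), tissue
#' friction damping, and a vortex term promoting closure under reverse flow.
#' The opening is clamped to [0, 1]; flow is opening^2 dP / R_open, exactly 0
#' when closed.
#'
#' @param valve a [valve_state()].
#' @param dP pressure difference across the valve (mmHg).
#' @param local_flow current flow through the valve (ml/s).
#' @param dt time step (s).
#' @return the updated `cv_valve`, with `flow` set to the new flow.
#' @export
valve_update <- function(valve, dP, local_flow = 0, dt) {
  res <- cpp_valve_step(valve$opening, valve$omega, dP, local_flow, dt,
                        valve$coeff_pressure, valve$coeff_friction,
                        valve$coeff_blood_motion, valve$coeff_vortex,
                        valve$R_open)
  valve$opening <- res$opening
  valve$omega <- res$omega
  valve$flow <- res$flow
  valve
}
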