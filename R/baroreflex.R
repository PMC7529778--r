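# Short-term baroregulation: afferent sensing and efferent effectors.

#' Afferent baroreceptor pressure
#'
#' Combines the aortic-root and carotid-sinus pressures (weighted average)
#' and advances the first-order low-pass filter one step.  A constant input
#' converges monotonically to that constant.
#'
#' @param aortic_P aortic root pressure (mmHg).
#' @param carotid_P carotid sinus pressure (mmHg).
#' @param filter_state current filtered value (mmHg).
#' @param dt time step (s).
#' @param block a [baroreflex_block()] providing `w_aortic` and
#'   `tau_afferent`.
#' @return list with `instantaneous` (weighted input) and `filtered` (new
#'   filter state), both mmHg.
#' @export
afferent_pressure <- function(aortic_P, carotid_P, filter_state, dt, block) {
  p <- block$w_aortic * aortic_P + (1 - block$w_aortic) * carotid_P
  f <- filter_state + dt * (p - filter_state) / block$tau_afferent
  list(instantaneous = p, filtered = f)
}

# static sigmoid shared by all effectors; z > 0 when pressure is below setpoint
brx_static <- function(block, filtered) {
  tanh((block$setpoint - filtered) / block$slope)
}

#' Baroreflex effector multipliers
#'
#' Advances the five effector multipliers (heart rate, ventricular elastance
#' amplitude, peripheral arterial resistance, venous unstressed volume,
#' venous compliance) one step of their first-order lag towards the
#' sigmoidal static curves.  All multipliers equal 1 at the setpoint
#' equilibrium; sensed pressure below the setpoint raises HR, elastance and
#' resistance multipliers and lowers the venous V0 and C multipliers
#' (negative feedback).
#'
#' @param afferent filtered afferent pressure (mmHg).
#' @param block a [baroreflex_block()].
#' @param state named numeric vector of current multipliers
#'   (`hr`, `e_amp`, `resistance`, `v0_venous`, `c_venous`); defaults to all 1.
#' @param dt time step (s).
#' @return named numeric vector of updated multipliers.
#' @export
baroreflex_effectors <- function(afferent, block,
                                 state = c(hr = 1, e_amp = 1, resistance = 1,
                                           v0_venous = 1, c_venous = 1),
                                 dt) {
  z <- brx_static(block, afferent)
  g <- block$gains; tau <- block$taus
  target <- c(hr = 1 + g$hr * z,
              e_amp = 1 + g$e_amp * z,
              resistance = 1 + g$resistance * z,
              v0_venous = 1 - g$v0_venous * z,
              c_venous = 1 - g$c_venous * z)
  tv <- c(hr = tau$hr, e_amp = tau$e_amp, resistance = tau$resistance,
          v0_venous = tau$v0_venous, c_venous = tau$c_venous)
  state + dt * (target - state[names(target)]) / tv
}

#' Re-baseline the baroreflex for the weightlessness configuration
#'
#' Long-term adaptation alters only the baselines: the baseline heart rate is
#' increased by 13% and the average aortic-carotid sinus pressure setpoint is
#' decreased by 10%.  Gains and time constants are unchanged.  The block is
#' tagged; applying the change twice is an error.
#'
#' @param block a [baroreflex_block()].
#' @return the re-baselined block, tagged `gravity = "0g"`.
#' @export
set_0g_baselines <- function(block) {
  if (identical(attr(block, "gravity"), "0g"))
    stop("idempotency error: baroreflex block already configured for 0g")
  block$hr_baseline <- block$hr_baseline * 1.13
  block$setpoint <- block$setpoint * 0.90
  attr(block, "gravity") <- "0g"
  block
}
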