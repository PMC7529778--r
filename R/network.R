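# Data model for the closed-loop circulation.
#
# A cv_network holds 1D arterial segments, lumped (0D) compartments, four
# heart chambers, four valves, the junction tree, the two 1D<->0D interfaces,
# and the baroreflex block.  Units are fixed: mmHg, ml, s, cm.

REGIONS <- c("head-arms", "cardiac-thoracic", "upper-abdomen",
             "lower-abdomen", "legs")
VIP_SIDES <- c(upper = "upper", lower = "lower")
COMPARTMENT_CLASSES <- c("arteriole", "capillary", "venule", "vein",
                         "vena-cava", "pulmonary-artery", "pulmonary-vein",
                         "reservoir")

#' 1D arterial segment
#'
#' Describes one tapered viscoelastic vessel of the 1D tree.  The unstressed
#' lumen follows a linear radius taper from `r_prox` to `r_dist`; the elastic
#' tube-law coefficient is parameterized by the unstressed wave speeds
#' `c0_prox`/`c0_dist` (cm/s), from which beta(x) = 2 rho sqrt(A0) c0^2 / k
#' with k the mmHg-to-CGS conversion.
#'
#' @param id token used to reference the segment.
#' @param name anatomical label.
#' @param length vessel length (cm).
#' @param r_prox,r_dist unstressed radii at the proximal/distal end (cm).
#' @param c0_prox,c0_dist unstressed pulse wave speeds at the ends (cm/s).
#' @param wall_viscosity Kelvin-Voigt wall viscosity coefficient
#'   (mmHg s/cm^2); 0 gives the purely elastic tube law.
#' @param friction_zeta velocity-profile coefficient of the Poiseuille-type
#'   dissipation term (9 approximates a blunted arterial profile).
#' @param external_pressure external (tissue) pressure (mmHg).
#' @param region one of `REGIONS`.
#' @param vip_side `"upper"` or `"lower"` relative to the volume indifference
#'   point.
#' @return an object of class `cv_segment`.
#' @export
artery_segment <- function(id, name = id, length, r_prox, r_dist = r_prox,
                           c0_prox, c0_dist = c0_prox,
                           wall_viscosity = 0, friction_zeta = 9,
                           external_pressure = 0,
                           region = "cardiac-thoracic", vip_side = "upper") {
  structure(list(
    id = id, name = name, length = length,
    r_prox = r_prox, r_dist = r_dist,
    c0_prox = c0_prox, c0_dist = c0_dist,
    wall_viscosity = wall_viscosity, friction_zeta = friction_zeta,
    external_pressure = external_pressure,
    region = region, vip_side = vip_side
  ), class = "cv_segment")
}

#' Lumped RLC compartment
#'
#' A 0D element obeying V = V0 + C P, discharging through its outlet
#' resistance `R` (and inertance `L` if positive) into `downstream`.
#'
#' @param id,name identifier and site label.
#' @param R outlet resistance (mmHg s/ml).
#' @param L outlet inertance (mmHg s^2/ml).
#' @param C compliance (ml/mmHg).
#' @param V0 unstressed volume (ml).
#' @param P initial pressure (mmHg); the initial volume is V0 + C P.
#' @param downstream id of the element receiving the outflow (compartment or
#'   chamber id); `NA` only for fixture reservoirs.
#' @param class compartment class tag (see `COMPARTMENT_CLASSES`).
#' @param region,vip_side regional tags used by the gravity configurator.
#' @param peripheral logical: outlet resistance under baroreflex control.
#' @param venous logical: V0 and C under baroreflex control.
#' @param rectifier logical: outlet flow is one-way (venous valving).
#' @param territory optional arterial territory tag used by the gravity
#'   configurator (e.g. "carotid", "vertebral").
#' @param P_fix for `class = "reservoir"` only: fixed pressure (mmHg).
#' @return an object of class `cv_compartment`.
#' @export
compartment_0d <- function(id, name = id, R, L = 0, C, V0, P = 0,
                           downstream = NA_character_,
                           class = "vein", region = "cardiac-thoracic",
                           vip_side = "upper", peripheral = FALSE,
                           venous = FALSE, rectifier = FALSE,
                           territory = NA_character_, P_fix = NA_real_) {
  structure(list(
    id = id, name = name, R = R, L = L, C = C, V0 = V0,
    V = V0 + C * P, P_init = P, downstream = downstream, class = class,
    region = region, vip_side = vip_side, peripheral = peripheral,
    venous = venous, rectifier = rectifier, territory = territory,
    P_fix = P_fix
  ), class = "cv_compartment")
}

#' Heart chamber with time-varying elastance
#'
#' Chamber pressure is P = E(t) (V - V0) with
#' E(t) = E_min + E_amp e(t/RR); the normalized activation e rises from 0 to 1
#' and back within each beat (raised-cosine ramp up to `peak`, ramp down to
#' `duration`, both fractions of RR, starting at phase `onset`).  Atria use a
#' late-diastolic onset, producing the atrial kick.
#'
#' @param id one of "LV", "LA", "RV", "RA".
#' @param E_min,E_amp minimum elastance and activation amplitude (mmHg/ml).
#' @param V0 unstressed volume (ml).
#' @param V initial volume (ml).
#' @param onset,duration,peak activation timing as fractions of RR.
#' @param R_source internal (source) resistance of the chamber
#'   (mmHg s/ml): flow-dependent pressure loss during ejection, in series
#'   with the outflow valve.
#' @return an object of class `cv_chamber`.
#' @export
heart_chamber <- function(id, E_min, E_amp, V0, V,
                          onset = 0, duration = 0.4, peak = 0.5,
                          R_source = if (id %in% c("LV", "RV")) 0.06 else 0) {
  structure(list(
    id = id, E_min = E_min, E_amp = E_amp, V0 = V0, V = V,
    activation = list(onset = onset, duration = duration, peak = peak),
    ventricle = id %in% c("LV", "RV"), R_source = R_source
  ), class = "cv_chamber")
}

#' Heart valve with dynamic opening
#'
#' The opening fraction obeys a second-order dynamics driven by four effects:
#' the transvalvular pressure difference (`coeff_pressure`), friction from
#' the neighboring tissue (`coeff_friction`), the dynamic motion of the blood
#' on the leaflet (`coeff_blood_motion`), and the downstream vortex promoting
#' closure on reverse flow (`coeff_vortex`).  Flow is
#' Q = opening^2 dP / R_open, hence exactly 0 when closed.
#'
#' @param id one of "MV", "AV", "TV", "PV".
#' @param from chamber upstream of the valve.
#' @param to element downstream ("1d_root" for the aortic valve feeding the
#'   ascending aorta inlet).
#' @param coeff_pressure,coeff_friction,coeff_blood_motion,coeff_vortex
#'   coefficients of the four opening/closing terms.
#' @param R_open resistance of the fully open valve (mmHg s/ml).
#' @param L_blood blood inertance of the valve orifice (mmHg s^2/ml); limits
#'   the flow acceleration through the open valve.
#' @param opening initial opening in [0, 1].
#' @return an object of class `cv_valve`.
#' @export
valve_state <- function(id, from, to, coeff_pressure = 3000,
                        coeff_friction = 60, coeff_blood_motion = 2,
                        coeff_vortex = 10, R_open = 0.006,
                        L_blood = 5e-4, opening = 0) {
  structure(list(
    id = id, from = from, to = to,
    coeff_pressure = coeff_pressure, coeff_friction = coeff_friction,
    coeff_blood_motion = coeff_blood_motion, coeff_vortex = coeff_vortex,
    R_open = R_open, L_blood = L_blood, opening = opening, omega = 0
  ), class = "cv_valve")
}

#' Short-term baroreflex block
#'
#' Afferent pressure is a weighted average of the aortic root and carotid
#' sinus pressures, low-pass filtered with time constant `tau_afferent`.
#' Each effector multiplier relaxes (first-order lag) towards a sigmoidal
#' static curve 1 +/- G tanh((setpoint - p)/slope); all multipliers equal 1
#' at the setpoint.  Signs implement negative feedback: pressure below the
#' setpoint raises heart rate, ventricular elastance amplitude and peripheral
#' resistance, and lowers venous unstressed volume and compliance.
#'
#' @param setpoint baseline average aortic-carotid sinus pressure (mmHg).
#' @param hr_baseline baseline heart rate (bpm).
#' @param gains named list: hr, e_amp, resistance, v0_venous, c_venous
#'   (dimensionless, all >= 0).
#' @param taus named list of effector time constants (s): hr, e_amp,
#'   resistance, v0_venous, c_venous.
#' @param tau_afferent afferent filter time constant (s).
#' @param slope width of the sigmoid (mmHg).
#' @param w_aortic afferent weight of the aortic site (carotid gets 1 - w).
#' @param carotid_site segment id providing the carotid sinus pressure.
#' @param enabled logical.
#' @return an object of class `cv_baroreflex`.
#' @export
baroreflex_block <- function(setpoint, hr_baseline,
                             gains = list(hr = 0.25, e_amp = 0.25,
                                          resistance = 0.2, v0_venous = 0.25,
                                          c_venous = 0.08),
                             taus = list(hr = 3, e_amp = 8, resistance = 6,
                                         v0_venous = 10, c_venous = 20),
                             tau_afferent = 2, slope = 12, w_aortic = 0.5,
                             carotid_site = NULL, enabled = TRUE) {
  structure(list(
    setpoint = setpoint, hr_baseline = hr_baseline, gains = gains,
    taus = taus, tau_afferent = tau_afferent, slope = slope,
    w_aortic = w_aortic, carotid_site = carotid_site, enabled = enabled
  ), class = "cv_baroreflex")
}

#' Assemble a cardiovascular network
#'
#' @param segments list of [artery_segment()] objects (may be empty for
#'   lumped-only networks).
#' @param compartments list of [compartment_0d()] objects.
#' @param chambers list of [heart_chamber()] objects (all four, or empty for
#'   heartless fixtures).
#' @param valves list of [valve_state()] objects.
#' @param junctions list of `list(parent =, daughters =)` segment adjacencies.
#' @param interfaces list of `list(segment =, arteriole =, impedance =,
#'   access_resistance =)` terminal 1D -> 0D couplings; `impedance` is the
#'   characteristic impedance Z_c (mmHg s/ml) and `access_resistance` the
#'   additional arteriolar access resistance lumped in series with it.
#' @param root list describing the ascending-aorta inlet: `segment`, `mode`
#'   ("valve", "inflow", "closed" or "none"), optional `qin` (inflow samples
#'   over one beat for mode "inflow").
#' @param baroreflex a [baroreflex_block()].
#' @param numerics list: `rho` (g/cm^3), `mu` (poise), `dx_max` (cm),
#'   `init_pressure` (mmHg, arterial initialization).
#' @param meta list: `name`, `gravity` ("1g"/"0g"), free-form notes.
#' @return object of class `cv_network`.
#' @export
cardiovascular_network <- function(segments = list(), compartments = list(),
                                   chambers = list(), valves = list(),
                                   junctions = list(), interfaces = list(),
                                   root = list(segment = NULL, mode = "none"),
                                   baroreflex = baroreflex_block(93, 75, enabled = FALSE),
                                   numerics = list(rho = 1.06, mu = 0.04,
                                                   dx_max = 0.25,
                                                   init_pressure = 80),
                                   meta = list(name = "network", gravity = "1g")) {
  names(segments) <- vapply(segments, `[[`, "", "id")
  names(compartments) <- vapply(compartments, `[[`, "", "id")
  names(chambers) <- vapply(chambers, `[[`, "", "id")
  names(valves) <- vapply(valves, `[[`, "", "id")
  structure(list(
    segments = segments, compartments = compartments, chambers = chambers,
    valves = valves, junctions = junctions, interfaces = interfaces,
    root = root, baroreflex = baroreflex, numerics = numerics, meta = meta
  ), class = "cv_network")
}

#' @export
print.cv_network <- function(x, ...) {
  cat("<cv_network> ", x$meta$name, " [", x$meta$gravity, "]\n", sep = "")
  cat("  1D segments:    ", length(x$segments), "\n")
  cat("  0D compartments:", length(x$compartments), "\n")
  cat("  heart chambers: ", length(x$chambers),
      " valves: ", length(x$valves), "\n")
  cat("  junctions:      ", length(x$junctions),
      " terminal interfaces: ", length(x$interfaces), "\n")
  cat("  total blood volume: ",
      tryCatch(sprintf("%.0f ml", total_blood_volume(x)), error = function(e) "n/a"),
      "\n", sep = "")
  invisible(x)
}

# unstressed area profile and derived quantities at the cell/face grids
segment_grid <- function(seg, dx_max) {
  n <- max(3L, as.integer(ceiling(seg$length / dx_max)))
  dx <- seg$length / n
  xc <- (seq_len(n) - 0.5) * dx
  xf <- (0:n) * dx
  lin <- function(a, b, x) a + (b - a) * x / seg$length
  r_c <- lin(seg$r_prox, seg$r_dist, xc)
  r_f <- lin(seg$r_prox, seg$r_dist, xf)
  c0_c <- lin(seg$c0_prox, seg$c0_dist, xc)
  c0_f <- lin(seg$c0_prox, seg$c0_dist, xf)
  list(n = n, dx = dx, xc = xc, xf = xf,
       A0c = pi * r_c^2, A0f = pi * r_f^2, c0c = c0_c, c0f = c0_f)
}

beta_from_c0 <- function(A0, c0, rho) 2 * rho * sqrt(A0) * c0^2 / .MMHG

# area at a given pressure from the inverted elastic tube law
area_at_pressure <- function(A0, beta, P, pext = 0) {
  (sqrt(A0) + (P - pext) * A0 / beta)^2
}

# segment blood volume at the network's initialization pressure
segment_volume <- function(seg, numerics) {
  g <- segment_grid(seg, numerics$dx_max)
  beta <- beta_from_c0(g$A0c, g$c0c, numerics$rho)
  A <- area_at_pressure(g$A0c, beta, numerics$init_pressure,
                        seg$external_pressure)
  sum(A) * g$dx
}

#' Total blood volume of a network
#'
#' Sum of all compartment volumes (V = V0 + C P), chamber volumes, and 1D
#' segment volumes (area profile integrated at the network's arterial
#' initialization pressure).
#'
#' @param net a `cv_network`.
#' @return total volume (ml).
#' @export
total_blood_volume <- function(net) {
  vc <- sum(vapply(net$compartments, function(co) {
    if (co$class == "reservoir") return(0)
    stopifnot(abs(co$V - (co$V0 + co$C * co$P_init)) < 1e-6 * max(1, co$V))
    co$V
  }, 0))
  vh <- sum(vapply(net$chambers, `[[`, 0, "V"))
  vs <- sum(vapply(net$segments, segment_volume, 0, numerics = net$numerics))
  v <- vc + vh + vs
  stopifnot(v > 0)
  v
}

# regional volume decomposition used by the gravity configurator
regional_volumes <- function(net) {
  out <- setNames(numeric(length(REGIONS)), REGIONS)
  for (co in net$compartments) {
    if (co$class == "reservoir") next
    out[co$region] <- out[co$region] + co$V
  }
  for (ch in net$chambers) out["cardiac-thoracic"] <- out["cardiac-thoracic"] + ch$V
  for (sg in net$segments)
    out[sg$region] <- out[sg$region] + segment_volume(sg, net$numerics)
  out
}

# VIP partition volumes (upper/lower body)
vip_volumes <- function(net) {
  out <- c(upper = 0, lower = 0)
  for (co in net$compartments) {
    if (co$class == "reservoir") next
    out[co$vip_side] <- out[co$vip_side] + co$V
  }
  for (ch in net$chambers) out["upper"] <- out["upper"] + ch$V
  for (sg in net$segments)
    out[sg$vip_side] <- out[sg$vip_side] + segment_volume(sg, net$numerics)
  out
}

#' Validate a cardiovascular network
#'
#' Checks every structural invariant of the data model and returns a
#' diagnostics report: a character vector with one entry per violated
#' invariant, empty for a valid network.
#'
#' @param net a `cv_network`.
#' @return character vector of problems (zero length if valid).
#' @export
validate_network <- function(net) {
  p <- character()
  say <- function(...) p[[length(p) + 1L]] <<- sprintf(...)

  seg_ids <- names(net$segments)
  comp_ids <- names(net$compartments)
  ch_ids <- names(net$chambers)

  for (sg in net$segments) {
    if (!is.finite(sg$length) || sg$length <= 0)
      say("segment '%s': length must be > 0 (got %g)", sg$id, sg$length)
    if (sg$r_prox <= 0 || sg$r_dist <= 0)
      say("segment '%s': radii must be > 0", sg$id)
    if (sg$r_dist > sg$r_prox + 1e-12)
      say("segment '%s': A0 must be non-increasing along the taper", sg$id)
    if (sg$c0_prox <= 0 || sg$c0_dist <= 0)
      say("segment '%s': wall stiffness (c0) must be > 0", sg$id)
    if (sg$wall_viscosity < 0)
      say("segment '%s': wall viscosity must be >= 0", sg$id)
    if (!sg$region %in% REGIONS)
      say("segment '%s': unknown region '%s'", sg$id, sg$region)
    if (!sg$vip_side %in% VIP_SIDES)
      say("segment '%s': vip_side must be upper/lower", sg$id)
  }

  for (co in net$compartments) {
    if (co$class == "reservoir") {
      if (!is.finite(co$P_fix)) say("reservoir '%s': P_fix missing", co$id)
      next
    }
    if (co$R < 0) say("compartment '%s': R must be >= 0", co$id)
    if (co$L < 0) say("compartment '%s': L must be >= 0", co$id)
    if (!is.finite(co$C) || co$C <= 0) say("compartment '%s': C must be > 0", co$id)
    if (co$V0 < 0) say("compartment '%s': V0 must be >= 0", co$id)
    if (abs(co$V - (co$V0 + co$C * co$P_init)) > 1e-9 * max(1, abs(co$V)))
      say("compartment '%s': V = V0 + C P violated", co$id)
    if (!co$class %in% COMPARTMENT_CLASSES)
      say("compartment '%s': unknown class '%s'", co$id, co$class)
    if (!co$region %in% REGIONS)
      say("compartment '%s': unknown region '%s'", co$id, co$region)
    if (!is.na(co$downstream) &&
        !co$downstream %in% c(comp_ids, ch_ids))
      say("compartment '%s': dangling downstream '%s'", co$id, co$downstream)
    if (is.na(co$downstream))
      say("compartment '%s': open loop (no downstream connection)", co$id)
  }

  if (length(net$chambers) > 0) {
    need <- c("LA", "LV", "RA", "RV")
    if (!setequal(ch_ids, need))
      say("chambers must be exactly {LA, LV, RA, RV} (got %s)",
          paste(ch_ids, collapse = ","))
    for (ch in net$chambers) {
      if (!is.finite(ch$E_min) || ch$E_min <= 0)
        say("chamber '%s': E_min must be > 0", ch$id)
      if (ch$E_amp < 0) say("chamber '%s': E_amp must be >= 0", ch$id)
      a <- ch$activation
      if (a$duration <= 0 || a$duration >= 1 || a$peak <= 0 || a$peak >= 1)
        say("chamber '%s': activation timing fractions out of range", ch$id)
    }
    # atrial kick precedes ventricular activation
    if (all(c("LA", "LV") %in% ch_ids)) {
      la <- net$chambers$LA$activation; lv <- net$chambers$LV$activation
      la_peak <- (la$onset + la$duration * la$peak) %% 1
      if (!(la_peak > lv$onset + lv$duration || la_peak < lv$onset))
        say("atrial activation must precede ventricular activation")
    }
  }

  for (v in net$valves) {
    if (v$opening < 0 || v$opening > 1)
      say("valve '%s': opening must lie in [0,1] (got %g)", v$id, v$opening)
    if (!v$from %in% ch_ids)
      say("valve '%s': upstream chamber '%s' missing", v$id, v$from)
    if (!identical(v$to, "1d_root") && !v$to %in% c(comp_ids, ch_ids))
      say("valve '%s': downstream element '%s' missing", v$id, v$to)
    if (v$R_open <= 0) say("valve '%s': R_open must be > 0", v$id)
  }

  # 1D topology: rooted tree
  if (length(net$segments) > 0) {
    if (is.null(net$root$segment) || !net$root$segment %in% seg_ids) {
      say("root segment missing or unknown")
    } else {
      daughters <- unlist(lapply(net$junctions, `[[`, "daughters"))
      parents <- vapply(net$junctions, `[[`, "", "parent")
      if (anyDuplicated(daughters))
        say("segment(s) %s appear as daughter more than once (not a tree)",
            paste(unique(daughters[duplicated(daughters)]), collapse = ","))
      if (net$root$segment %in% daughters)
        say("root segment '%s' cannot be a junction daughter", net$root$segment)
      orphans <- setdiff(seg_ids, c(net$root$segment, daughters))
      if (length(orphans) > 0)
        say("segment(s) %s unreachable from the root",
            paste(orphans, collapse = ","))
      bad <- setdiff(c(parents, daughters), seg_ids)
      if (length(bad) > 0)
        say("junction references unknown segment(s) %s",
            paste(bad, collapse = ","))
      term <- setdiff(seg_ids, parents)
      iface_seg <- vapply(net$interfaces, `[[`, "", "segment")
      for (tid in term)
        if (sum(iface_seg == tid) != 1L)
          say("terminal segment '%s' must have exactly one arteriolar interface", tid)
      for (i in net$interfaces) {
        if (!i$segment %in% seg_ids)
          say("interface references unknown segment '%s'", i$segment)
        if (!i$arteriole %in% comp_ids)
          say("interface of '%s': dangling arteriole '%s'", i$segment, i$arteriole)
        if (!is.finite(i$impedance) || i$impedance <= 0)
          say("interface of '%s': characteristic impedance must be > 0", i$segment)
      }
    }
  }
  p
}
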