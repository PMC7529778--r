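# Transform the supine 1g baseline into the long-term weightlessness (0g)
# adaptation point.  The change set is applied in a fixed order:
# blood shift -> total volume reduction -> cardiac changes -> vascular
# changes -> baroreflex re-baselining.  Shift and reduction act on "zones"
# (every volume-holding element: compartments, chambers, 1D segments) and
# preserve each zone's V0/V ratio exactly.

#' Weightlessness configuration change set
#'
#' Constructs the change set describing the long-term 0g adaptation point:
#' regional blood shifts (ml, summing to zero), the total blood volume
#' reduction fraction, the cardiac factors (ventricular elastance amplitude
#' and minimum, pulmonary compliances, chamber unstressed volume), the
#' vascular factors (leg venous compliance, carotid/vertebral and lower-body
#' resistances) and the baroreflex baseline factors (heart rate and
#' setpoint).
#'
#' @param blood_shift named numeric vector of regional volume shifts (ml).
#' @param volume_reduction_fraction total blood volume reduction fraction.
#' @param ventricular_E_amp_factor,ventricular_E_min_factor ventricular
#'   elastance amplitude/minimum factors.
#' @param pulmonary_artery_C_factor,pulmonary_vein_C_factor pulmonary
#'   compliance factors.
#' @param chamber_V0_factor unstressed-volume factor for all four chambers.
#' @param legs_venous_C_factor leg venous compliance factor.
#' @param carotid_vertebral_R_factor,lower_body_R_factor arterial resistance
#'   factors.
#' @param hr_baseline_factor,setpoint_factor baroreflex baseline factors.
#' @return object of class `gravity_delta`.
#' @export
gravity_delta <- function(blood_shift = c("legs" = -235,
                                          "lower-abdomen" = -234,
                                          "head-arms" = 133,
                                          "cardiac-thoracic" = 202,
                                          "upper-abdomen" = 134),
                          volume_reduction_fraction = 0.115,
                          ventricular_E_amp_factor = 0.73,
                          ventricular_E_min_factor = 1.03,
                          pulmonary_artery_C_factor = 1.04,
                          pulmonary_vein_C_factor = 1.05,
                          chamber_V0_factor = 0.10,
                          legs_venous_C_factor = 1.27,
                          carotid_vertebral_R_factor = 1.10,
                          lower_body_R_factor = 0.90,
                          hr_baseline_factor = 1.13,
                          setpoint_factor = 0.90) {
  d <- structure(list(
    blood_shift = blood_shift,
    volume_reduction_fraction = volume_reduction_fraction,
    ventricular_E_amp_factor = ventricular_E_amp_factor,
    ventricular_E_min_factor = ventricular_E_min_factor,
    pulmonary_artery_C_factor = pulmonary_artery_C_factor,
    pulmonary_vein_C_factor = pulmonary_vein_C_factor,
    chamber_V0_factor = chamber_V0_factor,
    legs_venous_C_factor = legs_venous_C_factor,
    carotid_vertebral_R_factor = carotid_vertebral_R_factor,
    lower_body_R_factor = lower_body_R_factor,
    hr_baseline_factor = hr_baseline_factor,
    setpoint_factor = setpoint_factor
  ), class = "gravity_delta")
  if (abs(sum(d$blood_shift)) > 1e-9)
    stop("gravity delta: regional blood shifts must sum to 0 ml (got ",
         sum(d$blood_shift), ")")
  if (!setequal(names(d$blood_shift), REGIONS))
    stop("gravity delta: blood shift must name every region")
  if (d$volume_reduction_fraction <= 0 || d$volume_reduction_fraction >= 1)
    stop("gravity delta: reduction fraction must lie in (0,1)")
  facs <- unlist(d[grepl("_factor$", names(d))])
  if (any(facs <= 0)) stop("gravity delta: all factors must be > 0")
  d
}

# scale one zone's volume by f, preserving V0/V exactly
scale_zone <- function(net, id, kind, f) {
  if (kind == "compartment") {
    co <- net$compartments[[id]]
    co$V <- co$V * f
    co$V0 <- co$V0 * f
    co$P_init <- (co$V - co$V0) / co$C
    net$compartments[[id]] <- co
  } else if (kind == "chamber") {
    ch <- net$chambers[[id]]
    ch$V <- ch$V * f
    ch$V0 <- ch$V0 * f
    net$chambers[[id]] <- ch
  } else {  # 1D segment: radii scale with sqrt(f) so A0 (and the volume at
    # any fixed pressure) scales by exactly f; wall stiffness expressed as c0
    # is preserved
    sg <- net$segments[[id]]
    sg$r_prox <- sg$r_prox * sqrt(f)
    sg$r_dist <- sg$r_dist * sqrt(f)
    net$segments[[id]] <- sg
  }
  net
}

region_zones <- function(net) {
  z <- list()
  for (co in net$compartments)
    if (co$class != "reservoir")
      z[[length(z) + 1]] <- list(id = co$id, kind = "compartment",
                                 region = co$region, V = co$V)
  for (ch in net$chambers)
    z[[length(z) + 1]] <- list(id = ch$id, kind = "chamber",
                               region = "cardiac-thoracic", V = ch$V)
  for (sg in net$segments)
    z[[length(z) + 1]] <- list(id = sg$id, kind = "segment", region = sg$region,
                               V = segment_volume(sg, net$numerics))
  z
}

record_change <- function(log, family, element, before, after) {
  rbind(log, data.frame(family = family, element = element,
                        before = before, after = after))
}

#' Apply the microgravity blood shift
#'
#' Moves the stated volumes between regions: within each region every zone's
#' volume is scaled proportionally to its share of the region's 1g-supine
#' volume, and each zone's unstressed volume is rescaled so V0/V is
#' unchanged.  The shifts sum to zero, so total blood volume is invariant.
#'
#' @param net a 1g-tagged `cv_network`.
#' @param delta a [gravity_delta()].
#' @param allocation within-region allocation rule; only `"proportional"`
#'   (volumes proportional to the 1g condition) is implemented.
#' @return the shifted network (tagged so the ordering of the 0g pipeline can
#'   be enforced), with a `changes` attribute.
#' @export
apply_blood_shift <- function(net, delta = gravity_delta(),
                              allocation = "proportional") {
  allocation <- match.arg(allocation)
  if (!identical(net$meta$gravity, "1g"))
    stop("blood shift must start from a 1g-tagged network")
  if (isTRUE(net$meta$shift_applied))
    stop("ordering error: blood shift already applied")
  rv <- regional_volumes(net)
  log <- data.frame()
  for (r in names(delta$blood_shift)) {
    dv <- delta$blood_shift[[r]]
    if (dv == 0) next
    if (rv[[r]] + dv <= 0)
      stop(sprintf("configuration error: shift of %+g ml exceeds region '%s' volume (%g ml)",
                   dv, r, rv[[r]]))
    f <- 1 + dv / rv[[r]]
    for (z in region_zones(net))
      if (z$region == r) net <- scale_zone(net, z$id, z$kind, f)
    log <- record_change(log, "blood_shift", r, rv[[r]], rv[[r]] + dv)
  }
  net$meta$shift_applied <- TRUE
  attr(net, "changes") <- log
  net
}

#' Apply the total blood volume reduction
#'
#' Scales every zone's volume by (1 - fraction) relative to the
#' configuration after blood shift, rescaling unstressed volumes to preserve
#' V0/V.  Must be called after [apply_blood_shift()] (ordering enforced).
#'
#' @param net a network with the blood shift applied.
#' @param fraction reduction fraction (default 0.115).
#' @return the reduced network.
#' @export
apply_volume_reduction <- function(net, fraction = 0.115) {
  if (!isTRUE(net$meta$shift_applied))
    stop("ordering error: apply_blood_shift must precede the volume reduction")
  if (isTRUE(net$meta$reduction_applied))
    stop("ordering error: volume reduction already applied")
  stopifnot(fraction >= 0, fraction < 1)
  before <- total_blood_volume(net)
  f <- 1 - fraction
  if (fraction > 0)
    for (z in region_zones(net)) net <- scale_zone(net, z$id, z$kind, f)
  net$meta$reduction_applied <- TRUE
  attr(net, "changes") <- record_change(data.frame(), "volume_reduction",
                                        "total", before, before * f)
  net
}

#' Apply the cardiac function changes
#'
#' Ventricular elastance amplitudes x0.73 and minima x1.03; pulmonary artery
#' compliance x1.04 and pulmonary vein compliance x1.05; unstressed volumes
#' of all four cardiac chambers x0.10 (the stated implementation of the 10%
#' cardiac volume reduction).
#'
#' @param net a `cv_network`.
#' @param delta a [gravity_delta()].
#' @return the modified network.
#' @export
apply_cardiac_changes <- function(net, delta = gravity_delta()) {
  log <- data.frame()
  for (id in names(net$chambers)) {
    ch <- net$chambers[[id]]
    if (ch$ventricle) {
      log <- record_change(log, "ventricular_E_amp", id, ch$E_amp,
                           ch$E_amp * delta$ventricular_E_amp_factor)
      log <- record_change(log, "ventricular_E_min", id, ch$E_min,
                           ch$E_min * delta$ventricular_E_min_factor)
      ch$E_amp <- ch$E_amp * delta$ventricular_E_amp_factor
      ch$E_min <- ch$E_min * delta$ventricular_E_min_factor
    }
    log <- record_change(log, "chamber_V0", id, ch$V0,
                         ch$V0 * delta$chamber_V0_factor)
    ch$V0 <- ch$V0 * delta$chamber_V0_factor
    net$chambers[[id]] <- ch
  }
  for (id in names(net$compartments)) {
    co <- net$compartments[[id]]
    fac <- switch(co$class,
                  "pulmonary-artery" = delta$pulmonary_artery_C_factor,
                  "pulmonary-vein" = delta$pulmonary_vein_C_factor,
                  NULL)
    if (is.null(fac)) next
    fam <- if (co$class == "pulmonary-artery") "pulmonary_artery_C"
           else "pulmonary_vein_C"
    log <- record_change(log, fam, id, co$C, co$C * fac)
    co$C <- co$C * fac
    co$P_init <- (co$V - co$V0) / co$C
    net$compartments[[id]] <- co
  }
  attr(net, "changes") <- log
  net
}

#' Apply the vascular changes
#'
#' Leg venous compliance x1.27; arteriolar resistances (access resistance of
#' the terminal interface plus the arteriole outlet resistance) x1.10 for
#' carotid and vertebral territories, x0.90 for every lower-body territory.
#' Characteristic impedances (vessel wave properties) are untouched.
#'
#' @param net a `cv_network`.
#' @param delta a [gravity_delta()].
#' @return the modified network.
#' @export
apply_vascular_changes <- function(net, delta = gravity_delta()) {
  log <- data.frame()
  for (id in names(net$compartments)) {
    co <- net$compartments[[id]]
    if (co$class == "vein" && co$region == "legs") {
      log <- record_change(log, "legs_venous_C", id, co$C,
                           co$C * delta$legs_venous_C_factor)
      co$C <- co$C * delta$legs_venous_C_factor
      co$P_init <- (co$V - co$V0) / co$C
      net$compartments[[id]] <- co
      next
    }
    if (co$class == "arteriole") {
      if (is.na(co$vip_side) || is.na(co$region))
        stop("configuration error: arteriole '", id, "' lacks region tags")
      is_cv <- !is.na(co$territory) && co$territory %in% c("carotid", "vertebral")
      fac <- if (is_cv) delta$carotid_vertebral_R_factor
             else if (co$vip_side == "lower") delta$lower_body_R_factor
             else NA_real_
      if (is.na(fac)) next
      fam <- if (is_cv) "carotid_vertebral_R" else "lower_body_R"
      log <- record_change(log, fam, id, co$R, co$R * fac)
      co$R <- co$R * fac
      net$compartments[[id]] <- co
      # matching access resistance on the terminal interface
      for (k in seq_along(net$interfaces)) {
        i <- net$interfaces[[k]]
        if (identical(i$arteriole, id) && (i$access_resistance %||% 0) > 0) {
          net$interfaces[[k]]$access_resistance <- i$access_resistance * fac
          log <- record_change(log, fam, paste0(i$segment, ":access"),
                               i$access_resistance, i$access_resistance * fac)
        }
      }
    }
  }
  attr(net, "changes") <- log
  net
}

#' Configure a network for long-term weightlessness
#'
#' Applies, in order: blood shift, total volume reduction, cardiac changes,
#' vascular changes and baroreflex re-baselining.  The output is tagged "0g"
#' (re-running on it is an error) and carries a complete change report.
#'
#' @param net a validated 1g-tagged `cv_network`.
#' @param delta a [gravity_delta()].
#' @return the 0g network; `attr(net, "changes")` is a data.frame listing
#'   every changed parameter with before/after values.
#' @export
configure_0g <- function(net, delta = gravity_delta()) {
  if (identical(net$meta$gravity, "0g"))
    stop("idempotency error: network already configured for 0g")
  if (!identical(net$meta$gravity, "1g"))
    stop("configure_0g requires a 1g-tagged network")
  log <- data.frame()
  net <- apply_blood_shift(net, delta)
  log <- rbind(log, attr(net, "changes"))
  net <- apply_volume_reduction(net, delta$volume_reduction_fraction)
  log <- rbind(log, attr(net, "changes"))
  net <- apply_cardiac_changes(net, delta)
  log <- rbind(log, attr(net, "changes"))
  net <- apply_vascular_changes(net, delta)
  log <- rbind(log, attr(net, "changes"))
  b <- net$baroreflex
  net$baroreflex <- set_0g_baselines(b)
  log <- record_change(log, "hr_baseline", "baroreflex", b$hr_baseline,
                       net$baroreflex$hr_baseline)
  log <- record_change(log, "setpoint", "baroreflex", b$setpoint,
                       net$baroreflex$setpoint)
  net$meta$gravity <- "0g"
  net$meta$name <- paste0(net$meta$name, "-0g")
  attr(net, "changes") <- log
  net
}
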