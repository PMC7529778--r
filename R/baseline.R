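# The supine 1g baseline network.
#
# The arterial tree is a reduced 28-segment version of the adult systemic
# tree covering every reporting site of the analysis layer; distal beds,
# venous return and the pulmonary circulation are lumped.  Resistances are
# derived in closed form from a target mean operating point (flows and
# pressures of the normal supine adult at HR 75, CO ~5.3 l/min,
# MAP ~93 mmHg); compliances and unstressed volumes set the volume
# distribution (total blood volume ~5.3 l, predominantly venous).
#
# The packaged YAML document (inst/extdata/baseline_1g_supine.yaml) is
# written by write_network() from this builder and can be edited without
# code changes.

# segments: id, length, radii, unstressed wave speeds, region, vip side
BASELINE_SEGMENTS <- read.csv(text = "
id,length,r_prox,r_dist,c0_prox,c0_dist,region,vip_side
ascending_aorta,4,1.45,1.42,560,560,cardiac-thoracic,upper
aortic_arch,5,1.40,1.30,570,575,cardiac-thoracic,upper
arch_b,4,1.30,1.24,575,585,cardiac-thoracic,upper
thoracic_aorta,16,1.20,0.95,560,590,cardiac-thoracic,upper
abdominal_aorta_A,8,0.90,0.82,570,590,upper-abdomen,upper
abdominal_mid,6,0.80,0.72,590,610,upper-abdomen,upper
abdominal_aorta_E,10,0.68,0.58,610,640,lower-abdomen,lower
head_arms_trunk,8,0.62,0.58,550,560,head-arms,upper
l_common_carotid,17,0.37,0.35,600,620,head-arms,upper
l_internal_carotid,12,0.24,0.22,700,710,head-arms,upper
l_external_carotid,12,0.22,0.20,700,710,head-arms,upper
l_subclavian,7,0.42,0.40,600,610,head-arms,upper
l_vertebral,15,0.19,0.18,750,760,head-arms,upper
l_brachial,24,0.32,0.28,700,720,head-arms,upper
intercostals,8,0.40,0.38,600,610,cardiac-thoracic,upper
thoracic_other,8,0.40,0.38,600,610,cardiac-thoracic,upper
celiac_A,3,0.45,0.43,550,555,upper-abdomen,upper
gastric,7,0.26,0.24,600,620,upper-abdomen,upper
hepatosplenic,7,0.33,0.31,600,620,upper-abdomen,upper
l_renal,6,0.28,0.26,600,620,upper-abdomen,upper
mesenteric,6,0.35,0.33,600,620,lower-abdomen,lower
inner_iliac,8,0.28,0.26,640,650,lower-abdomen,lower
r_leg_trunk,12,0.40,0.35,600,620,legs,lower
external_iliac,14,0.32,0.30,620,640,legs,lower
deep_femoral,12,0.255,0.24,650,670,legs,lower
femoral,25,0.27,0.24,640,670,legs,lower
anterior_tibial,30,0.13,0.125,700,720,legs,lower
posterior_tibial,31,0.18,0.17,700,720,legs,lower
", strip.white = TRUE)

BASELINE_JUNCTIONS <- list(
  list(parent = "ascending_aorta", daughters = c("head_arms_trunk", "aortic_arch")),
  list(parent = "aortic_arch", daughters = c("l_common_carotid", "arch_b")),
  list(parent = "arch_b", daughters = c("l_subclavian", "thoracic_aorta")),
  list(parent = "l_common_carotid",
       daughters = c("l_internal_carotid", "l_external_carotid")),
  list(parent = "l_subclavian", daughters = c("l_vertebral", "l_brachial")),
  list(parent = "thoracic_aorta",
       daughters = c("intercostals", "thoracic_other", "abdominal_aorta_A")),
  list(parent = "abdominal_aorta_A", daughters = c("celiac_A", "abdominal_mid")),
  list(parent = "celiac_A", daughters = c("gastric", "hepatosplenic")),
  list(parent = "abdominal_mid",
       daughters = c("l_renal", "mesenteric", "abdominal_aorta_E")),
  list(parent = "abdominal_aorta_E",
       daughters = c("inner_iliac", "r_leg_trunk", "external_iliac")),
  list(parent = "external_iliac", daughters = c("deep_femoral", "femoral")),
  list(parent = "femoral", daughters = c("anterior_tibial", "posterior_tibial"))
)

# terminal beds: target mean flow (ml/s), artery mean pressure, arteriole
# node mean pressure, downstream venous node, arteriole compliance, territory
BASELINE_TERMINALS <- read.csv(text = "
segment,q,p_artery,p_arteriole,venous_node,C_a,territory
head_arms_trunk,10.40,92.5,75.0,ha_veins,0.050,NA
l_internal_carotid,2.16,92.3,80.4,ha_veins,0.015,carotid
l_external_carotid,2.34,92.3,80.4,ha_veins,0.015,carotid
l_vertebral,1.60,92.5,70.6,ha_veins,0.012,vertebral
l_brachial,4.29,92.3,75.0,ha_veins,0.020,NA
intercostals,9.93,92.6,85.4,thoracic_veins,0.040,NA
thoracic_other,10.19,92.6,85.0,thoracic_veins,0.040,NA
gastric,4.92,89.4,48.9,u_abd_venules,0.020,NA
hepatosplenic,5.25,89.9,55.0,u_abd_venules,0.025,NA
l_renal,8.50,90.4,66.2,u_abd_venules,0.030,NA
mesenteric,11.27,90.5,60.0,l_abd_venules,0.050,NA
inner_iliac,2.20,90.5,78.7,l_abd_venules,0.030,NA
r_leg_trunk,8.50,89.5,62.0,legs_capillaries,0.060,NA
deep_femoral,3.07,89.4,68.1,legs_capillaries,0.030,NA
anterior_tibial,2.01,84.4,38.2,legs_capillaries,0.035,NA
posterior_tibial,1.22,84.9,64.4,legs_capillaries,0.035,NA
", strip.white = TRUE, na.strings = "NA")

# venous chain: node, mean pressure, downstream, C, V0, class, region, vip
BASELINE_VENOUS <- read.csv(text = "
id,p,downstream,C,V0,class,region,vip_side,venous
ha_veins,6.40,svc,5.3,430,vein,head-arms,upper,TRUE
thoracic_veins,6.70,ivc,2,140,vein,cardiac-thoracic,upper,TRUE
u_abd_venules,12.00,u_abd_veins,1.5,160,venule,upper-abdomen,upper,TRUE
u_abd_veins,8.30,ivc,19,700,vein,upper-abdomen,upper,TRUE
l_abd_venules,12.10,l_abd_veins,1.5,150,venule,lower-abdomen,lower,TRUE
l_abd_veins,8.50,ivc,19,600,vein,lower-abdomen,lower,TRUE
legs_capillaries,25.50,legs_veins,0.35,70,capillary,legs,lower,FALSE
legs_veins,7.10,ivc,16,480,vein,legs,lower,TRUE
svc,6.00,RA,2.0,110,vena-cava,cardiac-thoracic,upper,TRUE
ivc,6.00,RA,3.0,160,vena-cava,lower-abdomen,lower,TRUE
pulmonary_arteries,15.00,pulmonary_veins,1.5,118,pulmonary-artery,cardiac-thoracic,upper,FALSE
pulmonary_veins,8.00,LA,5.5,420,pulmonary-vein,cardiac-thoracic,upper,FALSE
", strip.white = TRUE)

# venous outlet resistances (mmHg s/ml) and inertances
BASELINE_VENOUS_R <- c(
  ha_veins = 0.0221, thoracic_veins = 0.0348, u_abd_venules = 0.211,
  u_abd_veins = 0.134, l_abd_venules = 0.281, l_abd_veins = 0.200,
  legs_capillaries = 1.314, legs_veins = 0.0797,
  svc = 0.030, ivc = 0.025,
  pulmonary_arteries = 0.080, pulmonary_veins = 0.008)
BASELINE_VENOUS_L <- c(svc = 0.0008, ivc = 0.0008, pulmonary_arteries = 0.0002)

#' Build the supine 1g baseline network
#'
#' Constructs the packaged supine baseline: 28 arterial segments, 16 terminal
#' beds, lumped venous return and pulmonary circulation, four elastance
#' chambers with atrial kick, four dynamic valves, and the baroreflex block.
#' Terminal access resistances and arteriole outlet resistances are derived
#' from the target mean operating point so the steady state reproduces normal
#' supine hemodynamics.
#'
#' @param hr baseline heart rate (bpm).
#' @param wall_viscosity_large,wall_viscosity_small Kelvin-Voigt wall
#'   viscosity for vessels above/below 0.5 cm radius (mmHg s/cm^2).
#' @param venous_rectifiers logical: represent venous valving in the leg
#'   veins by a flow-rectifying outlet resistance (off in the packaged
#'   baseline).
#' @return a validated `cv_network` tagged `1g`.
#' @export
baseline_network_1g <- function(hr = 75, wall_viscosity_large = 0.03,
                                wall_viscosity_small = 0.5,
                                venous_rectifiers = FALSE) {
  rho <- 1.06
  segs <- lapply(seq_len(nrow(BASELINE_SEGMENTS)), function(i) {
    s <- BASELINE_SEGMENTS[i, ]
    gamma_w <- if (s$r_prox >= 0.5) wall_viscosity_large
               else if (s$r_prox >= 0.25) wall_viscosity_small
               else 6 * wall_viscosity_small
    artery_segment(s$id, length = s$length, r_prox = s$r_prox,
                   r_dist = s$r_dist, c0_prox = s$c0_prox, c0_dist = s$c0_dist,
                   wall_viscosity = gamma_w,
                   region = s$region, vip_side = s$vip_side)
  })
  names(segs) <- BASELINE_SEGMENTS$id

  comps <- list()
  ifaces <- list()
  for (i in seq_len(nrow(BASELINE_TERMINALS))) {
    tr <- BASELINE_TERMINALS[i, ]
    seg <- segs[[tr$segment]]
    A0_d <- pi * seg$r_dist^2
    Zc <- rho * seg$c0_dist / (A0_d * .MMHG)
    R_total <- (tr$p_artery - tr$p_arteriole) / tr$q
    R_access <- max(0, R_total - Zc)
    vn <- BASELINE_VENOUS[BASELINE_VENOUS$id == tr$venous_node, ]
    R_out <- 1.07 * (tr$p_arteriole - vn$p) / tr$q
    aid <- paste0(tr$segment, "_arterioles")
    comps[[aid]] <- compartment_0d(
      aid, R = R_out, C = tr$C_a, V0 = 8, P = tr$p_arteriole,
      downstream = tr$venous_node, class = "arteriole",
      region = seg$region, vip_side = seg$vip_side, peripheral = TRUE,
      territory = if (is.na(tr$territory)) NA_character_ else tr$territory)
    ifaces[[length(ifaces) + 1]] <- list(
      segment = tr$segment, arteriole = aid, impedance = Zc,
      access_resistance = R_access)
  }
  for (i in seq_len(nrow(BASELINE_VENOUS))) {
    v <- BASELINE_VENOUS[i, ]
    comps[[v$id]] <- compartment_0d(
      v$id, R = BASELINE_VENOUS_R[[v$id]],
      L = if (v$id %in% names(BASELINE_VENOUS_L)) BASELINE_VENOUS_L[[v$id]] else 0,
      C = v$C, V0 = v$V0, P = v$p, downstream = v$downstream,
      class = v$class, region = v$region, vip_side = v$vip_side,
      venous = v$venous,
      rectifier = venous_rectifiers && v$id == "legs_veins")
  }

  chambers <- list(
    heart_chamber("LA", E_min = 0.16, E_amp = 0.13, V0 = 5, V = 60,
                  onset = 0.85, duration = 0.15, peak = 0.55),
    heart_chamber("LV", E_min = 0.068, E_amp = 2.15, V0 = 7.3, V = 125,
                  onset = 0, duration = 0.40, peak = 0.55),
    heart_chamber("RA", E_min = 0.09, E_amp = 0.07, V0 = 5, V = 60,
                  onset = 0.85, duration = 0.15, peak = 0.55),
    heart_chamber("RV", E_min = 0.047, E_amp = 0.52, V0 = 7, V = 125,
                  onset = 0, duration = 0.40, peak = 0.55))

  valves <- list(
    valve_state("MV", from = "LA", to = "LV", coeff_pressure = 8000,
                coeff_friction = 100, coeff_blood_motion = 2,
                coeff_vortex = 150, R_open = 0.004, L_blood = 4e-4),
    valve_state("AV", from = "LV", to = "1d_root", coeff_pressure = 8000,
                coeff_friction = 100, coeff_blood_motion = 2,
                coeff_vortex = 150, R_open = 0.006, L_blood = 6e-4),
    valve_state("TV", from = "RA", to = "RV", coeff_pressure = 8000,
                coeff_friction = 100, coeff_blood_motion = 2,
                coeff_vortex = 150, R_open = 0.003, L_blood = 4e-4),
    valve_state("PV", from = "RV", to = "pulmonary_arteries",
                coeff_pressure = 8000, coeff_friction = 100,
                coeff_blood_motion = 2, coeff_vortex = 150, R_open = 0.0045, L_blood = 5e-4))

  brx <- baroreflex_block(setpoint = 92.3, hr_baseline = hr,
                          gains = list(hr = 0.08, e_amp = 0.6,
                                       resistance = 0.4, v0_venous = 0.3,
                                       c_venous = 0.25),
                          taus = list(hr = 6, e_amp = 25, resistance = 25,
                                      v0_venous = 25, c_venous = 25),
                          tau_afferent = 8,
                          carotid_site = "l_common_carotid", enabled = TRUE)

  cardiovascular_network(
    segments = segs, compartments = comps, chambers = chambers,
    valves = valves, junctions = BASELINE_JUNCTIONS, interfaces = ifaces,
    root = list(segment = "ascending_aorta", mode = "valve"),
    baroreflex = brx,
    numerics = list(rho = rho, mu = 0.04, dx_max = 0.25, init_pressure = 80),
    meta = list(name = "supine-baseline", gravity = "1g"))
}

#' Path of the packaged supine baseline document
#' @return file path of the YAML parameter document shipped with the package.
#' @export
baseline_document_path <- function() {
  system.file("extdata", "baseline_1g_supine.yaml", package = "cardiodecon",
              mustWork = TRUE)
}

# default record set: every site of the comparison tables plus the signals
# required by the cardiac indexes
#' @export
default_record_sites <- function(net = baseline_network_1g()) {
  c(names(net$segments),
    names(Filter(function(co) co$class != "reservoir", net$compartments)),
    names(net$chambers), names(net$valves), "aortic_root")
}
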