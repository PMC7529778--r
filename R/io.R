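# Network parameter documents: versioned YAML, one document per configuration.
# Doubles are written with 17 significant digits so load(serialize(net))
# reproduces every parameter bit-exactly.

DOC_SCHEMA_VERSION <- 1L

strip_class <- function(x) {
  x <- unclass(x)
  lapply(x, function(el) if (is.list(el)) strip_class(el) else el)
}

#' Serialize a network to a parameter document
#'
#' @param net a `cv_network`.
#' @param path file to write; if `NULL`, the YAML text is returned.
#' @return `path` invisibly, or the YAML string when `path` is `NULL`.
#' @seealso [load_network()]
#' @export
write_network <- function(net, path = NULL) {
  doc <- list(
    schema = "cv-network",
    schema_version = DOC_SCHEMA_VERSION,
    units = list(pressure = "mmHg", volume = "ml", time = "s", length = "cm"),
    meta = net$meta,
    numerics = net$numerics,
    segments = lapply(unname(net$segments), strip_class),
    compartments = lapply(unname(net$compartments), strip_class),
    chambers = lapply(unname(net$chambers), strip_class),
    valves = lapply(unname(net$valves), strip_class),
    junctions = net$junctions,
    interfaces = net$interfaces,
    root = net$root,
    baroreflex = strip_class(net$baroreflex)
  )
  txt <- yaml::as.yaml(doc, precision = 17L)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

load_error <- function(...) stop("network document error: ", sprintf(...), call. = FALSE)

#' Load and validate a network from a parameter document
#'
#' Reads a YAML configuration document (or an already-parsed list), rebuilds
#' the typed network object and validates every invariant.  Any violation
#' aborts with a message naming the offending element.
#'
#' @param x path to a YAML document, a YAML string, or a parsed list.
#' @return a validated `cv_network`.
#' @export
load_network <- function(x) {
  doc <- if (is.list(x)) x
         else if (is.character(x) && length(x) == 1 && file.exists(x))
           yaml::read_yaml(x)
         else yaml::yaml.load(paste(x, collapse = "\n"))
  if (!identical(doc$schema, "cv-network"))
    load_error("not a cv-network document (schema field missing or wrong)")
  if (is.null(doc$units) ||
      !identical(doc$units[c("pressure", "volume", "time", "length")],
                 list(pressure = "mmHg", volume = "ml", time = "s", length = "cm")))
    load_error("units must be declared as mmHg/ml/s/cm")

  num <- function(el, f, what, default = NULL) {
    v <- el[[f]]
    if (is.null(v)) {
      if (!is.null(default)) return(default)
      load_error("%s: missing field '%s'", what, f)
    }
    as.numeric(v)
  }

  segs <- lapply(doc$segments, function(s) {
    artery_segment(
      id = s$id, name = s$name %||% s$id,
      length = num(s, "length", s$id),
      r_prox = num(s, "r_prox", s$id), r_dist = num(s, "r_dist", s$id),
      c0_prox = num(s, "c0_prox", s$id), c0_dist = num(s, "c0_dist", s$id),
      wall_viscosity = num(s, "wall_viscosity", s$id, 0),
      friction_zeta = num(s, "friction_zeta", s$id, 9),
      external_pressure = num(s, "external_pressure", s$id, 0),
      region = s$region %||% "cardiac-thoracic",
      vip_side = s$vip_side %||% "upper")
  })
  comps <- lapply(doc$compartments, function(s) {
    co <- compartment_0d(
      id = s$id, name = s$name %||% s$id,
      R = num(s, "R", s$id), L = num(s, "L", s$id, 0),
      C = num(s, "C", s$id), V0 = num(s, "V0", s$id),
      P = num(s, "P_init", s$id, 0),
      downstream = if (is.null(s$downstream) || is.na(s$downstream))
        NA_character_ else s$downstream,
      class = s$class %||% "vein", region = s$region %||% "cardiac-thoracic",
      vip_side = s$vip_side %||% "upper",
      peripheral = isTRUE(s$peripheral), venous = isTRUE(s$venous),
      rectifier = isTRUE(s$rectifier),
      territory = if (is.null(s$territory) || is.na(s$territory))
        NA_character_ else s$territory,
      P_fix = num(s, "P_fix", s$id, NA_real_))
    # volume state may deviate from V0 + C P_init after gravity transforms
    if (!is.null(s$V)) co$V <- as.numeric(s$V)
    if (!is.null(s$V) && is.null(s$P_init)) co$P_init <- (co$V - co$V0) / co$C
    co
  })
  chs <- lapply(doc$chambers, function(s) {
    a <- s$activation
    heart_chamber(id = s$id, E_min = num(s, "E_min", s$id),
                  E_amp = num(s, "E_amp", s$id), V0 = num(s, "V0", s$id),
                  V = num(s, "V", s$id),
                  onset = as.numeric(a$onset), duration = as.numeric(a$duration),
                  peak = as.numeric(a$peak),
                  R_source = num(s, "R_source", s$id, 0))
  })
  vls <- lapply(doc$valves, function(s) {
    v <- valve_state(id = s$id, from = s$from, to = s$to,
                     coeff_pressure = num(s, "coeff_pressure", s$id),
                     coeff_friction = num(s, "coeff_friction", s$id),
                     coeff_blood_motion = num(s, "coeff_blood_motion", s$id),
                     coeff_vortex = num(s, "coeff_vortex", s$id),
                     R_open = num(s, "R_open", s$id),
                     L_blood = num(s, "L_blood", s$id, 5e-4),
                     opening = num(s, "opening", s$id, 0))
    v$omega <- num(s, "omega", s$id, 0)
    v
  })
  b <- doc$baroreflex
  brx <- baroreflex_block(
    setpoint = as.numeric(b$setpoint), hr_baseline = as.numeric(b$hr_baseline),
    gains = lapply(b$gains, as.numeric), taus = lapply(b$taus, as.numeric),
    tau_afferent = as.numeric(b$tau_afferent), slope = as.numeric(b$slope),
    w_aortic = as.numeric(b$w_aortic),
    carotid_site = b$carotid_site, enabled = isTRUE(b$enabled))

  ifaces <- lapply(doc$interfaces, function(i) list(
    segment = i$segment, arteriole = i$arteriole,
    impedance = as.numeric(i$impedance),
    access_resistance = as.numeric(i$access_resistance %||% 0)))
  root <- doc$root
  if (!is.null(root$qin)) root$qin <- as.numeric(root$qin)
  net <- cardiovascular_network(
    segments = segs, compartments = comps, chambers = chs, valves = vls,
    junctions = doc$junctions, interfaces = ifaces,
    root = root %||% list(segment = NULL, mode = "none"),
    baroreflex = brx,
    numerics = lapply(doc$numerics, function(v) if (is.numeric(v)) as.numeric(v) else v),
    meta = doc$meta %||% list(name = "network", gravity = "1g"))

  problems <- validate_network(net)
  if (length(problems) > 0)
    load_error("invalid network:\n  - %s", paste(problems, collapse = "\n  - "))
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a
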