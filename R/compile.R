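# Translate a cv_network into the flat arrays consumed by the compiled core,
# and build the catalog of recordable (site, variable) pairs.

ROOT_MODES <- c(valve = 0L, inflow = 1L, closed = 2L, none = 2L)

compile_network <- function(net, hr = NULL) {
  problems <- validate_network(net)
  if (length(problems) > 0)
    stop("invalid network:\n  - ", paste(problems, collapse = "\n  - "))

  comp_ids <- names(net$compartments)
  ch_ids <- names(net$chambers)
  seg_ids <- names(net$segments)
  node_ids <- c(comp_ids, ch_ids)
  nidx <- setNames(seq_along(node_ids) - 1L, node_ids)   # 0-based
  sidx <- setNames(seq_along(seg_ids) - 1L, seg_ids)

  nc <- length(comp_ids)
  node_kind <- integer(length(node_ids))
  node_C <- node_V0 <- node_V <- node_Pfix <- numeric(length(node_ids))
  node_venous <- logical(length(node_ids))
  node_chamber <- rep(-1L, length(node_ids))

  for (i in seq_along(net$compartments)) {
    co <- net$compartments[[i]]
    if (co$class == "reservoir") {
      node_kind[i] <- 2L
      node_Pfix[i] <- co$P_fix
      node_C[i] <- 1; node_V0[i] <- 0; node_V[i] <- 0
    } else {
      node_kind[i] <- 0L
      node_C[i] <- co$C; node_V0[i] <- co$V0; node_V[i] <- co$V
      node_venous[i] <- isTRUE(co$venous)
    }
  }
  ch_Emin <- ch_Eamp <- ch_onset <- ch_dur <- ch_peak <- ch_Rs <-
    numeric(length(ch_ids))
  ch_ventricle <- logical(length(ch_ids))
  for (j in seq_along(net$chambers)) {
    ch <- net$chambers[[j]]
    i <- nc + j
    node_kind[i] <- 1L
    node_V0[i] <- ch$V0; node_V[i] <- ch$V; node_C[i] <- 1
    node_chamber[i] <- j - 1L
    ch_Emin[j] <- ch$E_min; ch_Eamp[j] <- ch$E_amp
    ch_onset[j] <- ch$activation$onset; ch_dur[j] <- ch$activation$duration
    ch_peak[j] <- ch$activation$peak
    ch_ventricle[j] <- isTRUE(ch$ventricle)
    ch_Rs[j] <- ch$R_source %||% 0
  }

  # edges: compartment outlets first, then valves
  e_from <- e_to <- e_kind <- e_valve <- integer(0)
  e_R <- e_L <- e_Q <- numeric(0)
  e_peri <- logical(0)
  edge_of_comp <- setNames(rep(NA_integer_, nc), comp_ids)
  add_edge <- function(from, to, kind, R, L, peri, valve = -1L) {
    e_from <<- c(e_from, from); e_to <<- c(e_to, to)
    e_kind <<- c(e_kind, kind); e_R <<- c(e_R, R); e_L <<- c(e_L, L)
    e_Q <<- c(e_Q, 0); e_peri <<- c(e_peri, peri); e_valve <<- c(e_valve, valve)
    length(e_from) - 1L
  }
  for (i in seq_along(net$compartments)) {
    co <- net$compartments[[i]]
    if (is.na(co$downstream)) next
    kind <- if (isTRUE(co$rectifier)) 3L else if (co$L > 0) 1L else 0L
    edge_of_comp[co$id] <- add_edge(nidx[[co$id]], nidx[[co$downstream]], kind,
                                    co$R, co$L, isTRUE(co$peripheral))
  }
  v_xi <- v_om <- v_kp <- v_kf <- v_km <- v_kv <- v_Rv <- v_L <-
    numeric(length(net$valves))
  node_outvalve <- rep(-1L, length(node_ids))
  av_edge <- -1L
  edge_of_valve <- setNames(rep(NA_integer_, length(net$valves)), names(net$valves))
  for (j in seq_along(net$valves)) {
    v <- net$valves[[j]]
    v_xi[j] <- v$opening; v_om[j] <- v$omega
    v_kp[j] <- v$coeff_pressure; v_kf[j] <- v$coeff_friction
    v_km[j] <- v$coeff_blood_motion; v_kv[j] <- v$coeff_vortex
    v_Rv[j] <- v$R_open; v_L[j] <- v$L_blood
    to <- if (identical(v$to, "1d_root")) -1L else nidx[[v$to]]
    e <- add_edge(nidx[[v$from]], to, 2L, v$R_open, 0, FALSE, j - 1L)
    edge_of_valve[v$id] <- e
    node_outvalve[nidx[[v$from]] + 1L] <- e
    if (to == -1L) av_edge <- e
  }

  # 1D segments
  segs <- lapply(net$segments, discretize_segment, numerics = net$numerics)
  jun_parent <- vapply(net$junctions, function(j) sidx[[j$parent]], 0L)
  jun_daughters <- lapply(net$junctions,
                          function(j) unname(vapply(j$daughters, function(d) sidx[[d]], 0L)))
  term_seg <- integer(0); term_node <- integer(0); term_Z <- numeric(0)
  term_of_seg <- setNames(rep(NA_integer_, length(seg_ids)), seg_ids)
  for (k in seq_along(net$interfaces)) {
    i <- net$interfaces[[k]]
    term_seg <- c(term_seg, sidx[[i$segment]])
    term_node <- c(term_node, nidx[[i$arteriole]])
    term_Z <- c(term_Z, i$impedance + (i$access_resistance %||% 0))
    term_of_seg[i$segment] <- k - 1L
  }
  root_seg <- if (length(seg_ids) > 0 && !is.null(net$root$segment))
    sidx[[net$root$segment]] else -1L
  root_mode <- ROOT_MODES[[net$root$mode %||% "none"]]
  root_qin <- as.numeric(net$root$qin %||% 0)
  root_P0 <- net$numerics$init_pressure

  # baroreflex
  b <- net$baroreflex
  carotid_seg <- -1L; carotid_cell <- 0L
  if (!is.null(b$carotid_site) && b$carotid_site %in% seg_ids) {
    carotid_seg <- sidx[[b$carotid_site]]
    carotid_cell <- segs[[b$carotid_site]]$n - 1L
  }
  bl <- list(enabled = isTRUE(b$enabled) && length(net$chambers) > 0,
             setpoint = b$setpoint, hr_baseline = b$hr_baseline,
             tau_afferent = b$tau_afferent, slope = b$slope,
             gain_hr = b$gains$hr, gain_e = b$gains$e_amp,
             gain_r = b$gains$resistance, gain_v0 = b$gains$v0_venous,
             gain_c = b$gains$c_venous,
             tau_hr = b$taus$hr, tau_e = b$taus$e_amp, tau_r = b$taus$resistance,
             tau_v0 = b$taus$v0_venous, tau_c = b$taus$c_venous,
             p_filt = b$setpoint, m_hr = 1, m_e = 1, m_r = 1, m_v0 = 1, m_c = 1,
             carotid_seg = carotid_seg, carotid_cell = carotid_cell,
             w_aortic = b$w_aortic)

  cpp <- list(
    node_kind = node_kind, node_C = node_C, node_V0 = node_V0,
    node_V = node_V, node_Pfix = node_Pfix, node_venous = node_venous,
    node_chamber = node_chamber,
    ch_Emin = ch_Emin, ch_Eamp = ch_Eamp, ch_onset = ch_onset,
    ch_dur = ch_dur, ch_peak = ch_peak, ch_ventricle = ch_ventricle,
    ch_Rs = ch_Rs, node_outvalve = node_outvalve,
    edge_from = e_from, edge_to = e_to, edge_kind = e_kind,
    edge_R = e_R, edge_L = e_L, edge_Q = e_Q, edge_valve = e_valve,
    edge_peripheral = e_peri,
    valve_xi = v_xi, valve_omega = v_om, valve_kp = v_kp, valve_kf = v_kf,
    valve_km = v_km, valve_kv = v_kv, valve_Rv = v_Rv, valve_L = v_L,
    segments = unname(segs),
    jun_parent = jun_parent, jun_daughters = jun_daughters,
    term_seg = term_seg, term_node = term_node, term_Z = term_Z,
    root_seg = root_seg, root_mode = root_mode, root_qin = root_qin,
    av_edge = av_edge, root_P0 = root_P0,
    baroreflex = bl)

  # ---- catalog of recordable signals
  rows <- list()
  add <- function(site, var, kind, i1, i2 = 0L)
    rows[[length(rows) + 1L]] <<- data.frame(site = site, var = var,
                                             kind = kind, i1 = i1, i2 = i2)
  for (id in seg_ids) {
    mid <- as.integer(floor(segs[[id]]$n / 2))
    add(id, "P", 0L, sidx[[id]], mid)
    add(id, "Q", 1L, sidx[[id]], mid)
    add(id, "A", 2L, sidx[[id]], mid)
  }
  for (id in comp_ids) {
    co <- net$compartments[[id]]
    if (co$class == "reservoir") next
    add(id, "P", 3L, nidx[[id]])
    add(id, "V", 4L, nidx[[id]])
    iface <- which(vapply(net$interfaces, function(i) identical(i$arteriole, id), TRUE))
    if (length(iface) == 1) {
      add(id, "Q", 10L, iface[1] - 1L)       # terminal interface inflow
    } else if (!is.na(edge_of_comp[id])) {
      add(id, "Q", 5L, edge_of_comp[id])
    }
  }
  for (id in ch_ids) {
    add(id, "P", 3L, nidx[[id]])
    add(id, "V", 4L, nidx[[id]])
    add(id, "E", 7L, nidx[[id]])
  }
  for (id in names(net$valves)) {
    add(id, "open", 6L, match(id, names(net$valves)) - 1L)
    add(id, "Q", 5L, edge_of_valve[id])
  }
  if (root_seg >= 0) add("aortic_root", "P", 8L, 0L)
  catalog <- do.call(rbind, rows)

  list(cpp = cpp, catalog = catalog, nidx = nidx, sidx = sidx,
       edge_of_comp = edge_of_comp, edge_of_valve = edge_of_valve)
}
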