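# Simulation driver: closed-loop runs to steady state, time-series store,
# steady-beat extraction, and fixture generators.

#' Run a closed-loop simulation
#'
#' Advances the coupled 1D/0D/heart/baroreflex system for `n_beats` cardiac
#' periods and records sampled time series at the requested sites.  The
#' physics is fully deterministic: identical configurations produce
#' bit-identical stores.
#'
#' @param net a validated `cv_network`.
#' @param n_beats number of cardiac periods (default 100, after which the
#'   transient dynamics of both configurations are extinguished).
#' @param record_sites character vector of site ids (all recordable variables
#'   of each site), or a data.frame with columns `site`, `var`; `NULL`
#'   records everything.
#' @param dt time step (s); default derived from the CFL condition with
#'   headroom for systolic velocities (see Details).
#' @param cfl Courant number used when `dt` is derived.
#' @param hr heart rate override (bpm); default: baroreflex baseline.
#' @param sample_dt target sampling interval (s) for the store.
#' @param sample_stride explicit sampling stride (overrides `sample_dt`).
#' @param check_convergence logical; when TRUE a run whose final beat-to-beat
#'   convergence metric exceeds `1e-3` is flagged with a warning.
#'
#' @details The explicit scheme requires dt <= dx/(|u| + c) everywhere at all
#' times.  The default dt applies the Courant factor to the initial-state
#' limit with an additional 150 cm/s velocity headroom so that systolic
#' velocities and pressurization-induced wave-speed increases do not violate
#' the condition mid-run (the core checks every step and aborts on violation).
#'
#' @return a `cv_run` store: `time`, `signals` (matrix, columns named
#'   `site.var`), `beat_start`, `beat_RR`, `beat_volume` (total blood volume
#'   at each beat boundary), `convergence` (per-beat relative L2 difference of
#'   the sentinel pressure waveform), `final` state, and `meta` (including
#'   the full network object, sufficient to reproduce the run bit-exactly).
#' @export
run_simulation <- function(net, n_beats = 100L, record_sites = NULL,
                           dt = NULL, cfl = 0.9, hr = NULL,
                           sample_dt = 0.001, sample_stride = NULL,
                           check_convergence = TRUE) {
  stopifnot(n_beats >= 1)
  cm <- compile_network(net)

  if (is.null(dt)) {
    if (length(net$segments) > 0) {
      dts <- vapply(cm$cpp$segments, function(s) {
        c0 <- wave_speed(s$A, s$A0c, s$betac, s$rho)
        s$dx / max(abs(s$Q / s$A) + c0 + 200)
      }, 0)
      dt <- cfl * min(dts)
    } else dt <- 2e-4
  }
  if (is.null(sample_stride)) sample_stride <- max(1L, round(sample_dt / dt))

  cat_all <- cm$catalog
  rec <- if (is.null(record_sites)) cat_all
  else if (is.character(record_sites)) {
    missing <- setdiff(record_sites, cat_all$site)
    if (length(missing) > 0)
      stop("unknown record site(s): ", paste(missing, collapse = ", "))
    cat_all[cat_all$site %in% record_sites, ]
  } else {
    idx <- mapply(function(s, v) {
      w <- which(cat_all$site == s & cat_all$var == v)
      if (length(w) != 1) stop("unknown record signal ", s, ".", v)
      w
    }, record_sites$site, record_sites$var)
    cat_all[idx, ]
  }

  ctrl <- list(dt = dt, n_beats = as.integer(n_beats),
               sample_stride = as.integer(sample_stride),
               rec_kind = as.integer(rec$kind), rec_i1 = as.integer(rec$i1),
               rec_i2 = as.integer(rec$i2),
               hr = if (is.null(hr)) -1 else hr)
  res <- cpp_run(cm$cpp, ctrl)

  colnames(res$signals) <- paste(rec$site, rec$var, sep = ".")
  run <- structure(list(
    time = res$time, signals = res$signals,
    beat_start = res$beat_start, beat_RR = res$beat_RR,
    beat_volume = res$beat_volume,
    dt = dt, sample_stride = sample_stride,
    final = list(node_V = res$node_V, node_P = res$node_P,
                 edge_Q = res$edge_Q, valve_xi = res$valve_xi,
                 seg_state = res$seg_state, root_P = res$root_P,
                 brx_state = res$brx_state),
    catalog = rec,
    meta = list(network = net, n_beats = n_beats, hr = hr, cfl = cfl,
                sample_dt = sample_dt, gravity = net$meta$gravity)
  ), class = "cv_run")
  run$convergence <- beat_convergence(run)
  if (check_convergence && length(run$convergence) > 0) {
    final_metric <- tail(run$convergence, 1)
    attr(run, "converged") <- is.finite(final_metric) && final_metric < 1e-3
    if (!isTRUE(attr(run, "converged")))
      warning(sprintf(
        "run not converged: beat-to-beat metric %.3g at beat %d (threshold 1e-3)",
        final_metric, length(run$convergence) + 1L))
  }
  run
}

#' @export
print.cv_run <- function(x, ...) {
  cat("<cv_run> ", x$meta$network$meta$name, " [", x$meta$gravity, "]: ",
      x$meta$n_beats, " beats, ", length(x$time), " samples, ",
      ncol(x$signals), " signals\n", sep = "")
  if (length(x$convergence) > 0)
    cat("  final beat-to-beat convergence metric:",
        format(tail(x$convergence, 1), digits = 3), "\n")
  cat("  HR of final beat:", format(60 / tail(x$beat_RR, 1), digits = 4),
      "bpm\n")
  invisible(x)
}

# per-beat relative L2 difference of consecutive sentinel waveforms on a
# common phase grid; sentinel = ascending aorta pressure when present
beat_convergence <- function(run, n_grid = 200) {
  cols <- colnames(run$signals)
  sent <- grep("^(ascending_aorta|aortic_root)\\.P$", cols)
  if (length(sent) == 0) sent <- grep("\\.P$", cols)
  if (length(sent) == 0) sent <- 1L
  sent <- sent[1]
  nb <- length(run$beat_start)
  if (nb < 2) return(numeric(0))
  ends <- c(run$beat_start[-1], run$beat_start[nb] + run$beat_RR[nb])
  phase <- seq(0, 1, length.out = n_grid)
  resample <- function(b) {
    tt <- run$beat_start[b] + phase * (ends[b] - run$beat_start[b])
    approx(run$time, run$signals[, sent], xout = tt, rule = 2)$y
  }
  prev <- resample(1)
  out <- numeric(nb - 1)
  for (b in 2:nb) {
    cur <- resample(b)
    out[b - 1] <- sqrt(mean((cur - prev)^2)) / max(sqrt(mean(prev^2)), 1e-12)
    prev <- cur
  }
  out
}

#' Extract the steady-state beat from a run
#'
#' Returns the last full beat of each recorded signal, re-indexed to
#' t in [0, RR].  If the run failed its convergence check the result carries
#' a `stale` attribute (a warning is issued, never silent).
#'
#' @param store a `cv_run`.
#' @param signals optional character vector of `site.var` column names.
#' @return named list of `beat_series` objects (fields `site`, `var`, `t`,
#'   `y`, `RR`), plus attributes `RR` and `HR`.
#' @export
extract_steady_beat <- function(store, signals = NULL) {
  nb <- length(store$beat_start)
  RR <- store$beat_RR[nb]
  t0 <- store$beat_start[nb]
  t1 <- t0 + RR
  keep <- store$time >= t0 - 1e-12 & store$time <= t1 + 1e-12
  cols <- signals %||% colnames(store$signals)
  stale <- FALSE
  if (length(store$convergence) > 0 &&
      !(is.finite(tail(store$convergence, 1)) && tail(store$convergence, 1) < 1e-3)) {
    warning("steady beat extracted from a non-converged run")
    stale <- TRUE
  }
  tt <- store$time[keep] - t0
  out <- lapply(cols, function(cn) {
    parts <- strsplit(cn, ".", fixed = TRUE)[[1]]
    structure(list(site = parts[1], var = parts[2],
                   t = tt, y = store$signals[keep, cn], RR = RR),
              class = "beat_series")
  })
  names(out) <- cols
  attr(out, "RR") <- RR
  attr(out, "HR") <- 60 / RR
  attr(out, "stale") <- stale
  out
}

#' Generate an analytic test fixture network
#'
#' Small networks with closed-form expectations, used by the test-suite and
#' available for experimentation:
#' \describe{
#'   \item{single-tube-windkessel}{one uniform artery driven by a prescribed
#'     inflow, terminated by characteristic impedance + arteriole (R, C) into
#'     a fixed-pressure reservoir; steady mean pressure = Q (Z + R) + P_out.}
#'   \item{two-compartment-loop}{two compartments exchanging flow in a closed
#'     ring; total volume is exactly conserved.}
#'   \item{mini-tree}{one parent bifurcating into two daughters with unequal
#'     terminal resistances; steady flows split as the inverse total
#'     resistances.}
#' }
#'
#' @param kind fixture name.
#' @param ... overrides merged into the fixture parameters: `q_mean` (ml/s),
#'   `Z`, `R`, `C`, `P_out`, `pulsatile` (logical).
#' @return a validated `cv_network`.
#' @export
generate_fixture <- function(kind = c("single-tube-windkessel",
                                      "two-compartment-loop", "mini-tree"),
                             ...) {
  kind <- match.arg(kind)
  par <- modifyList(list(q_mean = 70, Z = 0.1, R = 1.0, C = 1.2, P_out = 5,
                         pulsatile = TRUE), list(...))
  if (kind == "two-compartment-loop") {
    a <- compartment_0d("a", R = 0.5, C = 2, V0 = 100, P = 20, downstream = "b",
                        class = "vein")
    b <- compartment_0d("b", R = 0.8, C = 5, V0 = 200, P = 5, downstream = "a",
                        class = "vein")
    return(cardiovascular_network(
      compartments = list(a, b),
      meta = list(name = "two-compartment-loop", gravity = "1g")))
  }
  mk_seg <- function(id, length, r, c0)
    artery_segment(id, length = length, r_prox = r, r_dist = r,
                   c0_prox = c0, c0_dist = c0, wall_viscosity = 0)
  qin <- if (par$pulsatile) {
    ph <- seq(0, 1, length.out = 65)[-65]
    par$q_mean * (1 + 0.25 * sin(2 * pi * ph))
  } else rep(par$q_mean, 8)
  if (kind == "single-tube-windkessel") {
    seg <- mk_seg("tube", 12, 0.6, 800)
    art <- compartment_0d("wk_arteriole", R = par$R, C = par$C, V0 = 20,
                          P = par$q_mean * par$R + par$P_out,
                          downstream = "sink", class = "arteriole")
    sink <- compartment_0d("sink", R = 0, C = 1, V0 = 0, class = "reservoir",
                           P_fix = par$P_out)
    return(cardiovascular_network(
      segments = list(seg), compartments = list(art, sink),
      interfaces = list(list(segment = "tube", arteriole = "wk_arteriole",
                             impedance = par$Z, access_resistance = 0)),
      root = list(segment = "tube", mode = "inflow", qin = qin),
      meta = list(name = "single-tube-windkessel", gravity = "1g")))
  }
  # mini-tree
  parent <- mk_seg("parent", 10, 0.8, 500)
  d1 <- mk_seg("d1", 8, 0.55, 550)
  d2 <- mk_seg("d2", 8, 0.55, 550)
  a1 <- compartment_0d("art1", R = 2, C = 0.3, V0 = 5, P = 74,
                       downstream = "sink", class = "arteriole")
  a2 <- compartment_0d("art2", R = 4, C = 0.3, V0 = 5, P = 76,
                       downstream = "sink", class = "arteriole")
  sink <- compartment_0d("sink", R = 0, C = 1, V0 = 0, class = "reservoir",
                         P_fix = 0)
  cardiovascular_network(
    segments = list(parent, d1, d2), compartments = list(a1, a2, sink),
    junctions = list(list(parent = "parent", daughters = c("d1", "d2"))),
    interfaces = list(
      list(segment = "d1", arteriole = "art1", impedance = 0.15,
           access_resistance = 0),
      list(segment = "d2", arteriole = "art2", impedance = 0.15,
           access_resistance = 0)),
    root = list(segment = "parent", mode = "inflow", qin = qin),
    meta = list(name = "mini-tree", gravity = "1g"))
}
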