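# Beat-level analysis: statistics, cardiac indexes, normalized waveforms and
# the NSD waveform-similarity metric.
#
# Quadrature convention: signals are resampled by linear interpolation onto a
# common 1000-point-per-beat grid and integrated with the trapezoidal rule;
# standard deviations use the population (1/N) form.

NSD_GRID <- 1000L

trapz_int <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

resample_beat <- function(series, n = NSD_GRID) {
  tt <- seq(0, series$RR, length.out = n)
  y <- approx(series$t, series$y, xout = tt, rule = 2)$y
  list(t = tt, y = y, RR = series$RR)
}

as_beat_series <- function(x, RR = NULL) {
  if (inherits(x, "beat_series")) return(x)
  if (is.list(x) && !is.null(x$t) && !is.null(x$y))
    return(structure(list(site = x$site %||% "signal", var = x$var %||% "y",
                          t = x$t, y = x$y, RR = x$RR %||% RR %||% max(x$t)),
                     class = "beat_series"))
  stop("cannot interpret input as a beat series")
}

#' Beat statistics
#'
#' Mean (trapezoidal quadrature over the beat divided by RR), maximum,
#' minimum and pulse (max - min) of one steady beat.
#'
#' @param series a `beat_series` (or list with `t`, `y`, `RR`).
#' @return list with `mean`, `max`, `min`, `pulse`.
#' @export
beat_statistics <- function(series) {
  s <- as_beat_series(series)
  if (max(s$t) < 0.98 * s$RR || min(s$t) > 0.02 * s$RR)
    stop("coverage error: series does not span a full beat")
  r <- resample_beat(s)
  list(mean = trapz_int(r$t, r$y) / s$RR,
       max = max(r$y), min = min(r$y), pulse = max(r$y) - min(r$y))
}

#' Normalize a beat waveform
#'
#' Maps a beat to dimensionless time t' = t/RR in [0, 1] and normalized value
#' y' = (y - mu)/sigma with mu, sigma the beat mean and (population) standard
#' deviation, so the result has zero mean and unit standard deviation and is
#' invariant under any increasing affine transform of the input.
#'
#' @param series a `beat_series`.
#' @return a `beat_series` with `t` = t' in [0, 1], `y` = y', `RR` = 1, and
#'   attributes `mu`, `sigma`.
#' @export
normalize_waveform <- function(series) {
  s <- as_beat_series(series)
  r <- resample_beat(s)
  mu <- trapz_int(r$t, r$y) / s$RR
  sigma <- sqrt(trapz_int(r$t, (r$y - mu)^2) / s$RR)
  if (sigma <= 1e-12 * max(1, abs(mu)))
    stop("normalization error: constant signal (sigma = 0)")
  out <- structure(list(site = s$site, var = s$var,
                        t = r$t / s$RR, y = (r$y - mu) / sigma, RR = 1),
                   class = "beat_series")
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  out
}

#' Normalized signal difference (NSD)
#'
#' NSD = integral over t' in [0,1] of |y'_ref - y'_alt| dt', where both
#' signals are amplitude-normalized (zero mean, unit SD) and time-normalized
#' beats.  NSD is symmetric, lies in [0, 2] (0 for overlapping signals, 2
#' only for complementary centred step functions), and is bounded by
#' sqrt(2 (1 - rho)) with rho the Pearson correlation of the normalized
#' signals.
#'
#' @param series_ref,series_alt `beat_series` objects (raw beats are
#'   normalized internally; already-normalized beats, RR = 1, are used as-is).
#' @return the NSD value (dimensionless).
#' @export
nsd <- function(series_ref, series_alt) {
  norm1 <- function(s) {
    s <- as_beat_series(s)
    if (!isTRUE(all.equal(s$RR, 1)) || abs(mean(s$y)) > 1e-6 ||
        abs(sd(s$y) - 1) > 0.05)
      s <- normalize_waveform(s)
    resample_beat(s, NSD_GRID)
  }
  a <- norm1(series_ref)
  b <- norm1(series_alt)
  tp <- seq(0, 1, length.out = NSD_GRID)
  ya <- approx(a$t / max(a$t), a$y, xout = tp, rule = 2)$y
  yb <- approx(b$t / max(b$t), b$y, xout = tp, rule = 2)$y
  trapz_int(tp, abs(ya - yb))
}

#' Relative variation between two configurations
#'
#' 100 (x_alt - x_ref) / x_ref, sign preserved.
#'
#' @param x_1G reference value (must be non-zero).
#' @param x_0G altered value.
#' @return percent variation.
#' @export
relative_variation <- function(x_1G, x_0G) {
  if (any(x_1G == 0))
    stop("undefined-variation error: zero baseline value")
  100 * (x_0G - x_1G) / x_1G
}

# Augmentation index from the inflection-point decomposition of the central
# systolic wave: the inflection (shoulder left by the reflected wave) is the
# zero crossing of the second derivative of the smoothed pressure nearest to
# the systolic peak, searched between the mid-upstroke and the end of the
# systolic window; AI = (P_syst - P_inflection) / PP * 100.
augmentation_index <- function(p_series, systole_end_frac = 0.45,
                               smooth_df = 12) {
  s <- as_beat_series(p_series)
  r <- resample_beat(s, 400)
  win <- r$t <= systole_end_frac * s$RR
  tt <- r$t[win]; yy <- r$y[win]
  fit <- smooth.spline(tt, yy, df = min(smooth_df, length(tt) - 2))
  d2 <- predict(fit, tt, deriv = 2)$y
  t_peak <- tt[which.max(yy)]
  zc <- which(d2[-length(d2)] * d2[-1] < 0)
  zc <- zc[tt[zc] >= 0.4 * t_peak]
  p_syst <- max(r$y)
  pp <- max(r$y) - min(r$y)
  if (length(zc) == 0) return(list(AI = NA_real_, P_inflection = NA_real_))
  k <- zc[which.min(abs(tt[zc] - t_peak))]
  p_infl <- predict(fit, tt[k])$y
  list(AI = 100 * (p_syst - p_infl) / pp, P_inflection = p_infl)
}

#' Cardiac indexes from a steady run
#'
#' Computes the full set of beat-level cardiac indexes from a converged run:
#' end-systolic/diastolic LV volumes, SV, EF, CO, stroke work per minute
#' (PV-loop area x beats/min), tension-time index per minute (ascending
#' aortic pressure integrated over the aortic-valve-open interval x
#' beats/min), rate-pressure product (HR x systolic aortic pressure), CVP
#' (mean of the beat-averaged SVC and IVC pressures), MAP, systolic/diastolic
#' aortic pressures, pulse pressure and augmentation index.
#'
#' @param run_store a `cv_run` recording at least `LV.V`, `LV.P`,
#'   `ascending_aorta.P`, `svc.P`, `ivc.P`, `AV.open`.
#' @return object of class `cardiac_indexes` (a named list).
#' @export
cardiac_indexes <- function(run_store) {
  beat <- extract_steady_beat(run_store)
  need <- c("LV.V", "LV.P", "ascending_aorta.P", "svc.P", "ivc.P", "AV.open")
  missing <- setdiff(need, names(beat))
  if (length(missing) > 0)
    stop("dependency error: run store lacks recorded signal(s) ",
         paste(missing, collapse = ", "))
  RR <- attr(beat, "RR"); HR <- 60 / RR
  lvv <- resample_beat(beat[["LV.V"]])
  lvp <- resample_beat(beat[["LV.P"]])
  aap <- resample_beat(beat[["ascending_aorta.P"]])
  av <- resample_beat(beat[["AV.open"]])

  V_lved <- max(lvv$y); V_lves <- min(lvv$y)
  SV <- V_lved - V_lves
  EF <- 100 * SV / V_lved
  CO <- SV * HR / 1000                      # l/min
  # stroke work: area of the PV loop (shoelace on the closed V,P polygon)
  vv <- lvv$y; pp <- lvp$y
  sw_beat <- abs(sum(vv * c(pp[-1], pp[1]) - c(vv[-1], vv[1]) * pp)) / 2
  SW_min <- sw_beat * HR
  sys <- av$y > 0.05
  TTI_min <- trapz_int(aap$t[sys], aap$y[sys]) * HR
  P_syst <- max(aap$y); P_dias <- min(aap$y)
  PP <- P_syst - P_dias
  RPP <- HR * P_syst
  MAP <- trapz_int(aap$t, aap$y) / RR
  svc <- beat_statistics(beat[["svc.P"]])$mean
  ivc <- beat_statistics(beat[["ivc.P"]])$mean
  CVP <- (svc + ivc) / 2
  ai <- augmentation_index(beat[["ascending_aorta.P"]])
  structure(list(
    HR = HR, RR = RR, V_lves = V_lves, V_lved = V_lved, SV = SV, EF = EF,
    CO = CO, SW_min = SW_min, TTI_min = TTI_min, RPP = RPP, CVP = CVP,
    MAP = MAP, P_AA_syst = P_syst, P_AA_dias = P_dias, PP_AA = PP,
    AI_AA = ai$AI), class = "cardiac_indexes")
}

#' @export
print.cardiac_indexes <- function(x, ...) {
  cat("Cardiac indexes (steady beat):\n")
  fmt <- c(HR = "bpm", V_lves = "ml", V_lved = "ml", SV = "ml", EF = "%",
           CO = "l/min", SW_min = "mmHg ml/min", TTI_min = "mmHg s/min",
           RPP = "mmHg bpm", CVP = "mmHg", MAP = "mmHg", P_AA_syst = "mmHg",
           P_AA_dias = "mmHg", PP_AA = "mmHg", AI_AA = "%")
  for (k in names(fmt))
    cat(sprintf("  %-10s %10.2f %s\n", k, x[[k]], fmt[[k]]))
  invisible(x)
}

#' Compare two runs site by site
#'
#' Emits machine-readable tables comparing a reference (1g) and an altered
#' (0g) run: beat-averaged pressure and flow with relative variations,
#' maximum pressure and pulse pressure with relative variations, NSD of the
#' normalized pressure and flow waveforms, and the paired cardiac indexes.
#'
#' @param run_1G,run_0G converged `cv_run` stores recording the same sites.
#' @param site_list character vector of sites; default: all sites recorded in
#'   both runs.
#' @return list of data.frames: `means` (columns site, quantity, ref, alt,
#'   variation_pct), `pressure_extrema`, `nsd`, and `indexes`.
#' @export
comparison_report <- function(run_1G, run_0G, site_list = NULL) {
  b1 <- extract_steady_beat(run_1G)
  b0 <- extract_steady_beat(run_0G)
  sites1 <- unique(vapply(b1, `[[`, "", "site"))
  sites0 <- unique(vapply(b0, `[[`, "", "site"))
  if (is.null(site_list)) site_list <- intersect(sites1, sites0)
  bad <- setdiff(site_list, intersect(sites1, sites0))
  if (length(bad) > 0)
    stop("report error: site(s) not recorded in both runs: ",
         paste(bad, collapse = ", "))
  means <- pex <- nsdtab <- data.frame()
  for (site in site_list) {
    for (v in c("P", "Q", "V")) {
      cn <- paste(site, v, sep = ".")
      if (!cn %in% names(b1) || !cn %in% names(b0)) next
      s1 <- beat_statistics(b1[[cn]]); s0 <- beat_statistics(b0[[cn]])
      means <- rbind(means, data.frame(
        site = site, quantity = v, ref = s1$mean, alt = s0$mean,
        variation_pct = if (s1$mean != 0)
          relative_variation(s1$mean, s0$mean) else NA_real_))
      if (v == "P")
        pex <- rbind(pex, data.frame(
          site = site,
          Pmax_ref = s1$max, Pmax_alt = s0$max,
          Pmax_variation_pct = relative_variation(s1$max, s0$max),
          PP_ref = s1$pulse, PP_alt = s0$pulse,
          PP_variation_pct = if (s1$pulse > 1e-9)
            relative_variation(s1$pulse, s0$pulse) else NA_real_))
      if (v %in% c("P", "Q")) {
        val <- tryCatch(nsd(b1[[cn]], b0[[cn]]), error = function(e) NA_real_)
        nsdtab <- rbind(nsdtab, data.frame(site = site, quantity = v,
                                           NSD = val))
      }
    }
  }
  idx <- tryCatch({
    i1 <- cardiac_indexes(run_1G); i0 <- cardiac_indexes(run_0G)
    ks <- setdiff(names(i1), "RR")
    data.frame(index = ks,
               ref = unlist(i1[ks]), alt = unlist(i0[ks]),
               variation_pct = vapply(ks, function(k)
                 if (is.finite(i1[[k]]) && i1[[k]] != 0)
                   relative_variation(i1[[k]], i0[[k]]) else NA_real_, 0))
  }, error = function(e) NULL)
  list(means = means, pressure_extrema = pex, nsd = nsdtab, indexes = idx)
}

#' Write a comparison report to CSV files
#'
#' One CSV per table plus a JSON summary of the paired cardiac indexes.
#'
#' @param report result of [comparison_report()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_comparison_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("means", "pressure_extrema", "nsd")) {
    df <- report[[nm]]
    utils::write.csv(format(df, digits = 17), file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(report$indexes))
    jsonlite::write_json(report$indexes, file.path(dir, "indexes.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
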