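# Regression harness: the published 1g-supine vs long-term-0g comparison
# encoded as tolerance-checked targets, plus hard direction and
# spatial-pattern checks.
#
# Two tolerance tiers reflect how faithfully the baseline parameter set can
# be expected to reproduce the source model: "tight" (0.5 percentage points
# on relative variations, 0.05 on NSD, 2 mmHg on mean pressures) would apply
# to an exact parameter transcription; "loose" (2 pp, 0.1, 2 mmHg) is the
# default for the packaged reduced-tree baseline, which is independently
# calibrated.  Direction and pattern checks are tier-independent hard
# checks.

#' Published comparison targets
#'
#' Loads the packaged target set: per-site beat-averaged pressure/flow,
#' maximum pressure, pulse pressure (values and relative variations) and NSD
#' for both variables, plus the cardiac-index relative variations.
#'
#' @return list of data.frames `sites` and `indexes`.
#' @export
paper_targets <- function() {
  list(
    sites = utils::read.csv(system.file("extdata", "flight_targets.csv",
                                        package = "cardiodecon")),
    indexes = utils::read.csv(system.file("extdata", "flight_index_targets.csv",
                                          package = "cardiodecon")))
}

tier_tolerances <- function(tier = c("loose", "tight")) {
  tier <- match.arg(tier)
  if (tier == "tight") list(variation = 0.5, nsd = 0.05, pressure = 2)
  else list(variation = 2, nsd = 0.1, pressure = 2)
}

#' Evaluate the published targets against a pair of runs
#'
#' Computes every target quantity from the two runs (beat statistics,
#' relative variations, NSD, cardiac indexes), forms the residual
#' computed - printed, and flags each target pass/fail at its class
#' tolerance.
#'
#' @param run_1G,run_0G converged `cv_run` stores of the supine baseline and
#'   the weightlessness configuration.
#' @param target_set result of [paper_targets()] (default).
#' @param tier tolerance tier: `"loose"` (default, independently calibrated
#'   baseline) or `"tight"`.
#' @return list with data.frames `sites`, `indexes` (columns: id, quantity,
#'   computed, printed, residual, tolerance, pass) and the `tier` used.
#' @export
evaluate_targets <- function(run_1G, run_0G, target_set = paper_targets(),
                             tier = "loose") {
  tol <- tier_tolerances(tier)
  rep <- comparison_report(run_1G, run_0G)
  b1 <- suppressWarnings(extract_steady_beat(run_1G))
  b0 <- suppressWarnings(extract_steady_beat(run_0G))

  rows <- list()
  addrow <- function(id, quantity, computed, printed, tolerance) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, quantity = quantity, computed = computed, printed = printed,
      residual = computed - printed, tolerance = tolerance,
      pass = is.finite(computed) && abs(computed - printed) <= tolerance)
  }
  st <- target_set$sites
  chamber_q <- c(LA = "MV.Q", LV = "AV.Q", RA = "TV.Q", RV = "PV.Q")
  for (i in seq_len(nrow(st))) {
    s <- st$site[i]
    pc <- paste0(s, ".P")
    qc <- if (s %in% names(chamber_q)) chamber_q[[s]] else paste0(s, ".Q")
    if (!pc %in% names(b1) || !qc %in% names(b1)) next
    sp1 <- beat_statistics(b1[[pc]]); sp0 <- beat_statistics(b0[[pc]])
    sq1 <- beat_statistics(b1[[qc]]); sq0 <- beat_statistics(b0[[qc]])
    addrow(s, "mean_P_1g", sp1$mean, st$P1g[i], tol$pressure)
    addrow(s, "mean_P_0g", sp0$mean, st$P0g[i], tol$pressure)
    addrow(s, "var_mean_P", relative_variation(sp1$mean, sp0$mean),
           st$varP[i], tol$variation)
    addrow(s, "var_mean_Q", relative_variation(sq1$mean, sq0$mean),
           st$varQ[i], tol$variation)
    addrow(s, "var_Pmax", relative_variation(sp1$max, sp0$max),
           st$varPmax[i], tol$variation)
    if (sp1$pulse > 0.05)   # pulse variations meaningless for flat signals
      addrow(s, "var_PP", relative_variation(sp1$pulse, sp0$pulse),
             st$varPP[i], tol$variation)
    addrow(s, "nsd_P", tryCatch(nsd(b1[[pc]], b0[[pc]]), error = function(e) NA_real_),
           st$nsdP[i], tol$nsd)
    addrow(s, "nsd_Q", tryCatch(nsd(b1[[qc]], b0[[qc]]), error = function(e) NA_real_),
           st$nsdQ[i], tol$nsd)
  }
  sites <- do.call(rbind, rows)

  i1 <- cardiac_indexes(run_1G); i0 <- cardiac_indexes(run_0G)
  vol_var <- function(site) {
    v1 <- beat_statistics(b1[[paste0(site, ".V")]])$mean
    v0 <- beat_statistics(b0[[paste0(site, ".V")]])$mean
    relative_variation(v1, v0)
  }
  it <- target_set$indexes
  irows <- lapply(seq_len(nrow(it)), function(k) {
    id <- it$index[k]
    computed <- switch(id,
      pulmonary_artery_volume = vol_var("pulmonary_arteries"),
      pulmonary_vein_volume = vol_var("pulmonary_veins"),
      relative_variation(i1[[id]], i0[[id]]))
    data.frame(id = id, quantity = "variation_pct", computed = computed,
               printed = it$variation_pct[k],
               residual = computed - it$variation_pct[k],
               tolerance = tol$variation,
               direction_expected = it$direction[k],
               direction_pass = is.finite(computed) &&
                 ((it$direction[k] == "increase") == (computed > 0)),
               pass = is.finite(computed) &&
                 abs(computed - it$variation_pct[k]) <= tol$variation)
  })
  indexes <- do.call(rbind, irows)
  list(sites = sites, indexes = indexes, tier = tier,
       nsd_table = rep$nsd)
}

#' Hard direction and spatial-pattern checks
#'
#' Tier-independent qualitative checks of the weightlessness response:
#' the cardiac indexes move in the published directions (SV, EF, CO, MAP,
#' pulse pressure, stroke work, tension-time index, rate-pressure product
#' and CVP all decrease; end-systolic LV volume and the pulmonary volumes
#' increase), NSD grows from the proximal to the distal end of the 1D
#' arterial pathway, and flow waveforms are at least as altered as pressure
#' waveforms at most arterial sites.
#'
#' @param run_1G,run_0G converged `cv_run` stores.
#' @return data.frame with columns `check`, `value`, `pass`.
#' @export
direction_checks <- function(run_1G, run_0G) {
  i1 <- cardiac_indexes(run_1G); i0 <- cardiac_indexes(run_0G)
  b1 <- suppressWarnings(extract_steady_beat(run_1G))
  b0 <- suppressWarnings(extract_steady_beat(run_0G))
  out <- list()
  add <- function(check, value, pass)
    out[[length(out) + 1L]] <<- data.frame(check = check, value = value,
                                           pass = pass)
  dec <- c("SV", "EF", "CO", "MAP", "PP_AA", "SW_min", "TTI_min", "RPP", "CVP")
  for (k in dec) {
    v <- relative_variation(i1[[k]], i0[[k]])
    add(paste0(k, " decreases"), v, v < 0)
  }
  v <- relative_variation(i1$V_lves, i0$V_lves)
  add("V_lves increases", v, v > 0)
  for (s in c("pulmonary_arteries", "pulmonary_veins")) {
    v <- relative_variation(beat_statistics(b1[[paste0(s, ".V")]])$mean,
                            beat_statistics(b0[[paste0(s, ".V")]])$mean)
    add(paste0(s, " volume increases"), v, v > 0)
  }
  # proximal -> distal NSD growth along the 1D pathway
  path <- c("ascending_aorta", "thoracic_aorta", "abdominal_aorta_A",
            "abdominal_aorta_E", "external_iliac", "femoral")
  nsds <- vapply(path, function(s)
    nsd(b1[[paste0(s, ".P")]], b0[[paste0(s, ".P")]]), 0)
  add("NSD(P) grows proximal to distal", nsds[length(nsds)] - nsds[1],
      all(diff(nsds) > -0.02) && nsds[length(nsds)] > nsds[1])
  # flow shapes at least as altered as pressure shapes at most 1D sites
  arts <- intersect(unique(vapply(b1, `[[`, "", "site")),
                    c(path, "l_vertebral", "l_internal_carotid",
                      "l_external_carotid", "l_brachial", "intercostals",
                      "gastric", "celiac_A", "l_renal", "inner_iliac",
                      "deep_femoral", "anterior_tibial", "posterior_tibial"))
  frac <- mean(vapply(arts, function(s) {
    np <- nsd(b1[[paste0(s, ".P")]], b0[[paste0(s, ".P")]])
    nq <- nsd(b1[[paste0(s, ".Q")]], b0[[paste0(s, ".Q")]])
    nq >= np - 0.02
  }, TRUE))
  add("NSD(Q) >= NSD(P) at most arterial sites", frac, frac >= 0.5)
  do.call(rbind, out)
}
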