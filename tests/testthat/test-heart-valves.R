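# Elastance chambers and valve dynamics.

test_that("elastance is periodic, bounded and attains its extremes", {
  ch <- heart_chamber("LV", E_min = 0.07, E_amp = 2.5, V0 = 10, V = 120,
                      onset = 0, duration = 0.4, peak = 0.55)
  RR <- 0.8
  t <- seq(0, RR, length.out = 2001)
  E <- elastance(ch, t, RR)
  expect_true(all(E >= ch$E_min - 1e-12))
  expect_true(all(E <= ch$E_min + ch$E_amp + 1e-12))
  expect_equal(min(E), ch$E_min)                       # e attains 0
  expect_equal(max(E), ch$E_min + ch$E_amp, tolerance = 1e-6)  # e attains 1
  # periodicity E(t + RR) = E(t)
  expect_equal(elastance(ch, t + RR, RR), E, tolerance = 1e-12)
  # diastolic instant: E = E_min
  expect_equal(elastance(ch, 0.6 * RR, RR), ch$E_min)
})

test_that("chamber pressure is the elastance law with its reference at V0", {
  ch <- heart_chamber("LV", E_min = 0.07, E_amp = 2.5, V0 = 12, V = 120)
  RR <- 0.8
  expect_equal(chamber_pressure(ch, ch$V0, 0.1, RR), 0)
  # increasing V at fixed t raises P; doubling E_amp raises peak-systolic P
  t_peak <- 0.4 * 0.55 * RR
  expect_gt(chamber_pressure(ch, 130, t_peak, RR),
            chamber_pressure(ch, 110, t_peak, RR))
  ch2 <- ch; ch2$E_amp <- 2 * ch$E_amp
  expect_gt(chamber_pressure(ch2, 120, t_peak, RR),
            chamber_pressure(ch, 120, t_peak, RR))
})

test_that("valves open under forward and close under reverse pressure", {
  v <- valve_state("AV", from = "LV", to = "1d_root", opening = 0)
  for (i in 1:4000) v <- valve_update(v, dP = 10, local_flow = 100, dt = 1e-4)
  expect_equal(v$opening, 1)
  expect_gt(v$flow, 0)
  for (i in 1:4000) v <- valve_update(v, dP = -20, local_flow = -10, dt = 1e-4)
  expect_equal(v$opening, 0)
  expect_identical(v$flow, 0 * v$flow)
  # flow is exactly zero whenever the valve is closed
  v0 <- valve_state("MV", from = "LA", to = "LV", opening = 0)
  v0 <- valve_update(v0, dP = -5, local_flow = 0, dt = 1e-4)
  expect_identical(v0$flow, 0)
})

test_that("the steady beat shows physiological valve timing", {
  pair <- cached_pair()
  b <- suppressWarnings(extract_steady_beat(pair$r1))
  av <- b[["AV.open"]]$y; mv <- b[["MV.open"]]$y
  # aortic valve opens once per beat; its open interval defines systole
  frac_open <- mean(av > 0.5)
  expect_gt(frac_open, 0.15); expect_lt(frac_open, 0.5)
  # mitral and aortic valves are never simultaneously wide open
  expect_lt(max(pmin(av, mv)), 0.5)
  # atrial activation precedes ventricular activation: the LA elastance
  # peak falls in late diastole, before the LV peak of the next beat
  ela <- b[["LA.E"]]$y; elv <- b[["LV.E"]]$y
  t <- b[["LA.E"]]$t; RR <- b[["LA.E"]]$RR
  expect_gt(t[which.max(ela)], 0.7 * RR)
  expect_lt(t[which.max(elv)], 0.4 * RR)
})

test_that("removing the atrial kick reduces end-diastolic ventricular volume", {
  net <- baseline_network_1g()
  nokick <- net
  nokick$chambers$LA$E_amp <- 0
  nokick$chambers$RA$E_amp <- 0
  r_kick <- run_simulation(net, n_beats = 30, check_convergence = FALSE)
  r_nokick <- run_simulation(nokick, n_beats = 30, check_convergence = FALSE)
  edv <- function(r) max(suppressWarnings(extract_steady_beat(r))[["LV.V"]]$y)
  expect_lt(edv(r_nokick), edv(r_kick))
})

test_that("the weightlessness configuration scales ventricular elastance by 0.73", {
  nets <- cached_networks()
  expect_equal(nets$net0$chambers$LV$E_amp / nets$net1$chambers$LV$E_amp, 0.73)
  expect_equal(nets$net0$chambers$RV$E_amp / nets$net1$chambers$RV$E_amp, 0.73)
  # and the realized peak-to-trough elastance excursion follows
  RR <- 0.8
  exc <- function(ch) {
    E <- elastance(ch, seq(0, RR, length.out = 4001), RR)
    max(E) - min(E)
  }
  expect_equal(exc(nets$net0$chambers$LV) / exc(nets$net1$chambers$LV), 0.73,
               tolerance = 1e-9)
})
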