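# Baroreflex: afferent filtering, effector statics/signs, 0g baselines.

test_that("the afferent filter converges to a constant input", {
  blk <- baroreflex_block(setpoint = 93, hr_baseline = 75)
  f <- 70
  for (i in 1:20000) f <- afferent_pressure(93, 93, f, 1e-3, blk)$filtered
  expect_equal(f, 93, tolerance = 1e-4)
  # first-order step response is monotone (no overshoot)
  f <- 80; trace <- numeric(500)
  for (i in 1:500) { f <- afferent_pressure(100, 100, f, 1e-2, blk)$filtered
                     trace[i] <- f }
  expect_true(all(diff(trace) > 0))
  expect_true(all(trace < 100))
})

test_that("beat-averaged afferent equals the beat-averaged input", {
  blk <- baroreflex_block(setpoint = 93, hr_baseline = 75)
  RR <- 0.8; dt <- 1e-4
  t <- seq(0, 400 * RR, by = dt)
  p <- 93 + 18 * sin(2 * pi * t / RR)
  f <- 93
  vals <- numeric(length(t))
  for (i in seq_along(t)) { f <- afferent_pressure(p[i], p[i], f, dt, blk)$filtered
                            vals[i] <- f }
  last_beat <- t > max(t) - RR
  expect_lt(abs(mean(vals[last_beat]) - 93) / 93, 1e-3)
})

test_that("effector multipliers sit at 1 at the setpoint and obey feedback signs", {
  blk <- baroreflex_block(setpoint = 93, hr_baseline = 75)
  st <- c(hr = 1, e_amp = 1, resistance = 1, v0_venous = 1, c_venous = 1)
  for (i in 1:5000) st <- baroreflex_effectors(93, blk, st, dt = 0.01)
  expect_equal(unname(st), rep(1, 5), tolerance = 1e-9)
  # sensed pressure 10% below the setpoint
  lo <- st
  for (i in 1:20000) lo <- baroreflex_effectors(0.9 * 93, blk, lo, dt = 0.01)
  expect_gt(lo[["hr"]], 1)
  expect_gt(lo[["e_amp"]], 1)
  expect_gt(lo[["resistance"]], 1)
  expect_lt(lo[["v0_venous"]], 1)
  expect_lt(lo[["c_venous"]], 1)
  # zero gains: open-loop reduction, multipliers pinned at 1 for any input
  blk0 <- baroreflex_block(setpoint = 93, hr_baseline = 75,
                           gains = list(hr = 0, e_amp = 0, resistance = 0,
                                        v0_venous = 0, c_venous = 0))
  st0 <- c(hr = 1, e_amp = 1, resistance = 1, v0_venous = 1, c_venous = 1)
  for (p in c(50, 93, 140))
    for (i in 1:100) st0 <- baroreflex_effectors(p, blk0, st0, dt = 0.01)
  expect_identical(unname(st0), rep(1, 5))
})

test_that("weightlessness re-baselining scales HR by 1.13 and setpoint by 0.90", {
  blk <- baroreflex_block(setpoint = 100, hr_baseline = 70)
  blk0 <- set_0g_baselines(blk)
  expect_equal(blk0$setpoint, 90)
  expect_equal(blk0$hr_baseline, 70 * 1.13)
  expect_identical(blk0$gains, blk$gains)
  expect_identical(blk0$taus, blk$taus)
  expect_error(set_0g_baselines(blk0), "idempotency")
})

test_that("the closed loop counteracts an acute volume withdrawal", {
  net <- baseline_network_1g()
  # withdraw ~10% of the venous blood volume (stressed share) at t = 0
  for (id in names(net$compartments)) {
    co <- net$compartments[[id]]
    if (isTRUE(co$venous)) {
      co$V <- co$V - 0.10 * co$V
      co$V0 <- co$V0 * 0.90          # keep V = V0 + C P consistent
      co$P_init <- (co$V - co$V0) / co$C
      net$compartments[[id]] <- co
    }
  }
  run <- run_simulation(net, n_beats = 50, check_convergence = FALSE)
  runs_open <- local({
    net_open <- net; net_open$baroreflex$enabled <- FALSE
    run_simulation(net_open, n_beats = 50, hr = 75, check_convergence = FALSE)
  })
  map_of <- function(r) suppressWarnings(
    beat_statistics(extract_steady_beat(r)[["ascending_aorta.P"]])$mean)
  # regulation pulls MAP back towards the setpoint relative to open loop
  expect_gt(map_of(run), map_of(runs_open))
  # and the heart rate rises above its baseline
  expect_gt(60 / tail(run$beat_RR, 1), 75)
})
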