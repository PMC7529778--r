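# Junction coupling and the two 1D<->0D interfaces.

face_state <- function(r = 0.8, c0 = 500, P = 80, rho = 1.06) {
  A0 <- pi * r^2
  beta <- 2 * rho * sqrt(A0) * c0^2 / 1333.22
  A <- (sqrt(A0) + P * A0 / beta)^2
  list(A0 = A0, beta = beta, A = A,
       c = wave_speed(A, A0, beta, rho))
}

test_that("an impedance-matched continuation transmits without reflection", {
  p <- face_state(); d <- face_state()
  eps <- 5   # incident forward-wave velocity perturbation (cm/s)
  res <- solve_junction(
    list(W1 = eps + 4 * p$c, A0 = p$A0, beta = p$beta, A = p$A),
    list(list(W2 = -4 * d$c, A0 = d$A0, beta = d$beta, A = d$A)))
  # transmitted state identical on both sides
  expect_equal(res$A_parent, res$A_daughters[1], tolerance = 1e-12)
  expect_equal(res$u_parent, res$u_daughters[1], tolerance = 1e-12)
  # reflected invariant change below 1e-6 of the incident one
  cpar <- wave_speed(res$A_parent, p$A0, p$beta, 1.06)
  dW2 <- (res$u_parent - 4 * cpar) - (-4 * p$c)
  expect_lt(abs(dW2), 1e-6 * eps)
})

test_that("an abrupt area step reflects like the linear transmission line", {
  rho <- 1.06
  for (r2 in c(0.6, 0.95)) {
    p <- face_state(r = 0.8); d <- face_state(r = r2)
    eps <- 1   # small amplitude for the linear limit
    res <- solve_junction(
      list(W1 = eps + 4 * p$c, A0 = p$A0, beta = p$beta, A = p$A),
      list(list(W2 = -4 * d$c, A0 = d$A0, beta = d$beta, A = d$A)))
    cpar <- wave_speed(res$A_parent, p$A0, p$beta, rho)
    # the backward invariant carries -1 times the pressure-wave amplitude
    R_meas <- -((res$u_parent - 4 * cpar) - (-4 * p$c)) / eps
    Y1 <- p$A / (rho * p$c); Y2 <- d$A / (rho * d$c)   # admittances
    R_lin <- (Y1 - Y2) / (Y1 + Y2)
    expect_lt(abs(R_meas - R_lin), 0.03 * max(abs(R_lin), 0.05))
  }
})

test_that("converged junction solves satisfy the stated residual bounds", {
  p <- face_state(r = 0.9, P = 95)
  d1 <- face_state(r = 0.55, P = 70)
  d2 <- face_state(r = 0.62, P = 88)
  res <- solve_junction(
    list(W1 = 60 + 4 * p$c, A0 = p$A0, beta = p$beta, A = p$A),
    list(list(W2 = 10 - 4 * d1$c, A0 = d1$A0, beta = d1$beta, A = d1$A),
         list(W2 = -5 - 4 * d2$c, A0 = d2$A0, beta = d2$beta, A = d2$A)))
  expect_lt(abs(res$Q_parent - sum(res$Q_daughters)), 1e-10)
  expect_lt(res$residual_ptot, 1e-9)
})

test_that("the arteriolar interface honors the characteristic and the series law", {
  f <- face_state(r = 0.3, c0 = 700, P = 90)
  iface <- list(impedance = 2, access_resistance = 6)
  res <- arteriolar_interface_step(
    list(A = f$A, u = 10, A0 = f$A0, beta = f$beta), iface,
    arteriole_pressure = 70)
  # series element law Q = (P - P_art) / Z at the converged boundary
  expect_equal(res$Q, (res$P - 70) / 8, tolerance = 1e-8)
  # outgoing characteristic preserved
  W1 <- 10 + 4 * f$c
  c_new <- wave_speed(res$A, f$A0, f$beta, 1.06)
  expect_equal(res$u + 4 * c_new, W1, tolerance = 1e-8)
  # Z -> infinity closes the end
  res_inf <- arteriolar_interface_step(
    list(A = f$A, u = 10, A0 = f$A0, beta = f$beta),
    list(impedance = 1e12), arteriole_pressure = 70)
  expect_lt(abs(res_inf$Q), 1e-6)
})

test_that("a matched terminal impedance absorbs an incident pulse", {
  st <- uniform_segment_state(length = 40, r = 0.5, c0 = 550, P0 = 40)
  rho <- 1.06
  c_op <- wave_speed(st$A[1], st$A0c[1], st$betac[1], rho)
  Zc <- rho * c_op / (st$A[1] * 1333.22)
  dt <- 0.8 * st$dx / (c_op + 100)
  n <- round(0.12 / dt)
  tt <- seq_len(n) * dt
  qin <- 8 * exp(-((tt - 0.01) / 0.003)^2)
  r <- advance_segment(st, dt, n_steps = n, bc_in = "flow", value_in = qin,
                       bc_out = "impedance", Z_out = Zc, P_out = 40,
                       sample_cell = 40, sample_stride = 1)
  q <- r$series$Q
  incident <- max(q)
  # a reflection off the terminal would pass the probe again at
  # t ~ 0.01 + (2 L - 2 x_probe)/c ~ 0.13 s; check the window after the
  # incident pulse has fully passed the probe (t > 0.05 s)
  late <- r$series$t > 0.05
  expect_lt(max(abs(q[late])), 0.05 * incident)
})

test_that("the aortic root interface transmits valve flow and reflects when shut", {
  f <- face_state(r = 1.4, c0 = 550, P = 80)
  valve_closed <- valve_state("AV", from = "LV", to = "1d_root", opening = 0)
  inlet <- list(A = f$A, W2 = -4 * f$c, A0 = f$A0, beta = f$beta, P = 80)
  shut <- aortic_root_interface(120, valve_closed, inlet)
  expect_identical(shut$Q, 0)
  expect_equal(shut$u, 0, tolerance = 1e-12)
  valve_open <- valve_state("AV", from = "LV", to = "1d_root", opening = 1,
                            R_open = 0.006)
  open <- aortic_root_interface(120, valve_open, inlet)
  expect_gt(open$Q, 0)
  expect_gt(open$P, 80)  # the inlet pressurizes as flow enters
})
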