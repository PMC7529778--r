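# Beat statistics, normalization, NSD, cardiac indexes, comparison report.

mk_beat <- function(y, RR = 0.8, n = 801, site = "x", var = "P") {
  structure(list(site = site, var = var,
                 t = seq(0, RR, length.out = n), y = y, RR = RR),
            class = "beat_series")
}

test_that("beat statistics match closed-form quadrature", {
  RR <- 0.8; t <- seq(0, RR, length.out = 801)
  const <- mk_beat(rep(7.5, 801))
  s <- beat_statistics(const)
  expect_equal(s$mean, 7.5); expect_equal(s$pulse, 0)
  # y = a sin(2 pi t / RR) + b -> mean b, pulse 2a
  a <- 13; b <- 92
  s2 <- beat_statistics(mk_beat(a * sin(2 * pi * t / RR) + b))
  expect_equal(s2$mean, b, tolerance = 1e-4)
  expect_equal(s2$pulse, 2 * a, tolerance = 1e-4 * 2 * a)
  # cross-check the quadrature against an independent implementation
  y <- 80 + 20 * sin(2 * pi * t / RR)^3 + 5 * cos(6 * pi * t / RR)
  s3 <- beat_statistics(mk_beat(y))
  expect_equal(s3$mean, trapz_ref(t, y) / RR, tolerance = 1e-6)
  # refinement: doubling the sampling changes the mean by < 0.01%
  s4 <- beat_statistics(mk_beat(approx(t, y, n = 1601)$y, n = 1601))
  expect_lt(abs(s4$mean - s3$mean) / abs(s3$mean), 1e-4)
  short <- structure(list(site = "x", var = "P",
                          t = seq(0, 0.3, length.out = 100),
                          y = rep(1, 100), RR = 0.8), class = "beat_series")
  expect_error(beat_statistics(short), "coverage")
})

test_that("waveform normalization has zero mean, unit SD and affine invariance", {
  RR <- 0.8; t <- seq(0, RR, length.out = 1001)
  y <- 90 + 25 * sin(2 * pi * t / RR) + 6 * sin(4 * pi * t / RR + 1)
  n1 <- normalize_waveform(mk_beat(y, RR, 1001))
  expect_lt(abs(cardiodecon:::trapz_int(n1$t, n1$y)), 1e-10)
  expect_equal(sqrt(cardiodecon:::trapz_int(n1$t, n1$y^2)), 1, tolerance = 1e-9)
  expect_equal(range(n1$t), c(0, 1))
  # invariance under y -> 3 y + 5
  n2 <- normalize_waveform(mk_beat(3 * y + 5, RR, 1001))
  expect_equal(n2$y, n1$y, tolerance = 1e-10)
  # idempotence
  n3 <- normalize_waveform(n1)
  expect_equal(n3$y, n1$y, tolerance = 1e-6)
  # constant signal: sigma = 0 guard
  expect_error(normalize_waveform(mk_beat(rep(4, 1001), RR, 1001)), "sigma = 0")
})

test_that("NSD attains its bounds and the closed-form shifted-sine value", {
  RR <- 1; t <- seq(0, 1, length.out = 2001)
  y <- sqrt(2) * sin(2 * pi * t)
  expect_equal(nsd(mk_beat(y, RR, 2001), mk_beat(y, RR, 2001)), 0,
               tolerance = 1e-9)
  # complementary centred unit steps reach the upper bound 2
  step1 <- ifelse(t < 0.5, 1, -1)
  step2 <- -step1
  expect_equal(nsd(mk_beat(step1, RR, 2001), mk_beat(step2, RR, 2001)), 2,
               tolerance = 5e-3)
  # quarter-period shifted unit-SD sine: closed form 4/pi
  y2 <- sqrt(2) * sin(2 * pi * (t - 0.25))
  expect_equal(nsd(mk_beat(y, RR, 2001), mk_beat(y2, RR, 2001)), 4 / pi,
               tolerance = 2e-3)
})

test_that("NSD is symmetric, bounded and below the correlation bound", {
  set.seed(421)
  n <- 400
  t <- seq(0, 1, length.out = n)
  for (k in 1:1000) {
    mk <- function() {
      f <- sample(1:4, 1)
      5 * rnorm(1) + rnorm(1, sd = 3) * sin(2 * pi * f * t + runif(1, 0, 2 * pi)) +
        cumsum(rnorm(n, sd = 0.05)) + rnorm(1, sd = 2) * t
    }
    y1 <- mk(); y2 <- mk()
    if (sd(y1) < 1e-8 || sd(y2) < 1e-8) next
    a <- mk_beat(y1, 1, n); b <- mk_beat(y2, 1, n)
    v <- nsd(a, b)
    expect_gte(v, 0); expect_lte(v, 2)
    expect_equal(nsd(b, a), v, tolerance = 1e-12)
    n1 <- normalize_waveform(a); n2 <- normalize_waveform(b)
    rho <- suppressWarnings(cor(n1$y, n2$y))
    expect_lte(v, sqrt(2 * (1 - rho)) + 1e-6)
  }
})

test_that("relative variation reproduces the printed percentages", {
  expect_equal(relative_variation(92.61, 83.19), -10.17, tolerance = 0.005)
  expect_equal(relative_variation(0.25, 0.11), -56.00, tolerance = 1e-10)
  expect_equal(relative_variation(5, 5), 0)
  expect_error(relative_variation(0, 1), "zero baseline")
})

test_that("cardiac indexes follow their definitions on a synthetic run", {
  # build a minimal synthetic store: rectangular PV loop and flat signals
  RR <- 60 / 75
  tt <- seq(0, 2 * RR, by = 1e-3)
  phase <- (tt %% RR) / RR
  V <- ifelse(phase < 0.25, 120, ifelse(phase < 0.5, 50, ifelse(phase < 0.75, 50, 120)))
  # traverse the rectangle P: 10 <-> 110 at the volume extremes
  P <- ifelse(phase < 0.25, 110, ifelse(phase < 0.5, 110, ifelse(phase < 0.75, 10, 10)))
  aa <- rep(100, length(tt))
  sig <- cbind("LV.V" = V, "LV.P" = P, "ascending_aorta.P" = aa,
               "svc.P" = rep(6.48, length(tt)), "ivc.P" = rep(6.50, length(tt)),
               "AV.open" = as.numeric(phase >= 0.25 & phase < 0.5))
  store <- structure(list(time = tt, signals = sig,
                          beat_start = c(0, RR), beat_RR = c(RR, RR),
                          beat_volume = c(1, 1, 1), convergence = numeric(0),
                          dt = 1e-3, sample_stride = 1,
                          meta = list(network = NULL, n_beats = 2, gravity = "1g")),
                     class = "cv_run")
  idx <- cardiac_indexes(store)
  expect_equal(idx$V_lved, 120); expect_equal(idx$V_lves, 50)
  expect_equal(idx$SV, 70)
  expect_equal(idx$EF, 100 * 70 / 120)             # 58.33%
  expect_equal(idx$CO, 70 * 75 / 1000)
  # CVP: mean of the two beat-averaged caval pressures
  expect_equal(idx$CVP, 6.49)
  # rectangular PV loop area = (110 - 10) (120 - 50) = 7000 mmHg ml per beat
  expect_equal(idx$SW_min / idx$HR, 7000, tolerance = 0.02 * 7000)
  expect_equal(idx$MAP, 100, tolerance = 1e-9)
  expect_equal(idx$RPP, idx$HR * 100)
  # missing recorded site -> dependency error
  store2 <- store; colnames(store2$signals)[4] <- "other.P"
  expect_error(cardiac_indexes(store2), "dependency")
})

test_that("MAP lies between diastolic and systolic pressure on real beats", {
  pair <- cached_pair()
  for (r in pair) {
    i <- suppressWarnings(cardiac_indexes(r))
    expect_lte(i$P_AA_dias, i$MAP)
    expect_lte(i$MAP, i$P_AA_syst)
    expect_equal(i$PP_AA, i$P_AA_syst - i$P_AA_dias)
    expect_gt(i$EF, 0); expect_lt(i$EF, 100)
    expect_lt(i$V_lves, i$V_lved)
  }
})

test_that("the comparison report mirrors the published table structure", {
  pair <- cached_pair()
  rep <- suppressWarnings(comparison_report(pair$r1, pair$r0))
  expect_true(all(c("site", "quantity", "ref", "alt", "variation_pct") %in%
                  names(rep$means)))
  expect_true(all(c("Pmax_ref", "Pmax_alt", "PP_ref", "PP_alt") %in%
                  names(rep$pressure_extrema)))
  expect_true(all(rep$nsd$NSD >= 0 & rep$nsd$NSD <= 2, na.rm = TRUE))
  # identical runs: all variations 0, all NSD 0
  rep0 <- suppressWarnings(comparison_report(pair$r1, pair$r1,
                                             site_list = "ascending_aorta"))
  expect_equal(rep0$means$variation_pct, rep(0, nrow(rep0$means)))
  expect_equal(rep0$nsd$NSD, rep(0, nrow(rep0$nsd)), tolerance = 1e-9)
  # unknown site -> report error
  expect_error(suppressWarnings(comparison_report(pair$r1, pair$r0,
                                                  site_list = "nowhere")),
               "report error")
})
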