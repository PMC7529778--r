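# Gravity configurator: blood shift, volume reduction, cardiac/vascular
# changes, full 0g pipeline.

test_that("the default change set is the published one and shifts sum to zero", {
  d <- gravity_delta()
  expect_equal(sum(d$blood_shift), 0)
  expect_equal(unname(d$blood_shift[c("legs", "lower-abdomen", "head-arms",
                                      "cardiac-thoracic", "upper-abdomen")]),
               c(-235, -234, 133, 202, 134))
  expect_equal(d$volume_reduction_fraction, 0.115)
  expect_equal(d$ventricular_E_amp_factor, 0.73)
  expect_equal(d$chamber_V0_factor, 0.10)
  expect_error(gravity_delta(blood_shift = c("legs" = -100, "lower-abdomen" = 0,
                                             "head-arms" = 50,
                                             "cardiac-thoracic" = 20,
                                             "upper-abdomen" = 0)),
               "sum to 0")
})

test_that("blood shift splits proportionally and preserves V0/V exactly", {
  net <- two_zone_network()
  # region 'legs' holds zones of 100 ml and 300 ml; inject +40 ml
  expect_equal(net$compartments$zone_a$V, 100)
  expect_equal(net$compartments$zone_b$V, 300)
  d <- gravity_delta(blood_shift = c("legs" = 40, "lower-abdomen" = 0,
                                     "head-arms" = -40, "cardiac-thoracic" = 0,
                                     "upper-abdomen" = 0))
  v_before <- total_blood_volume(net)
  ratio_a <- net$compartments$zone_a$V0 / net$compartments$zone_a$V
  shifted <- apply_blood_shift(net, d)
  expect_equal(shifted$compartments$zone_a$V, 110)
  expect_equal(shifted$compartments$zone_b$V, 330)
  expect_lt(abs(shifted$compartments$zone_a$V0 / shifted$compartments$zone_a$V -
                ratio_a), 1e-12)
  # zero-sum: total volume invariant
  expect_equal(total_blood_volume(shifted), v_before, tolerance = 1e-12)
  # a shift exceeding the region's volume is a configuration error
  d_bad <- gravity_delta(blood_shift = c("legs" = -1000, "lower-abdomen" = 0,
                                         "head-arms" = 1000,
                                         "cardiac-thoracic" = 0,
                                         "upper-abdomen" = 0))
  expect_error(apply_blood_shift(net, d_bad), "exceeds region")
})

test_that("volume reduction is exactly multiplicative and order-enforced", {
  net <- two_zone_network()
  expect_error(apply_volume_reduction(net), "ordering error")
  d <- gravity_delta(blood_shift = c("legs" = 40, "lower-abdomen" = 0,
                                     "head-arms" = -40, "cardiac-thoracic" = 0,
                                     "upper-abdomen" = 0))
  shifted <- apply_blood_shift(net, d)
  v_before <- total_blood_volume(shifted)
  reduced <- apply_volume_reduction(shifted, 0.115)
  expect_equal(total_blood_volume(reduced), 0.885 * v_before, tolerance = 1e-12)
  for (id in c("zone_a", "zone_b", "zone_u")) {
    r0 <- shifted$compartments[[id]]$V0 / shifted$compartments[[id]]$V
    r1 <- reduced$compartments[[id]]$V0 / reduced$compartments[[id]]$V
    expect_lt(abs(r1 - r0), 1e-12)
  }
  # fraction 0 is the identity transform
  same <- apply_volume_reduction(shifted, 0)
  expect_equal(same$compartments, shifted$compartments, tolerance = 0)
})

test_that("permuting shift and reduction changes per-zone volumes", {
  net <- baseline_network_1g()
  d <- gravity_delta()
  a <- apply_volume_reduction(apply_blood_shift(net, d),
                              d$volume_reduction_fraction)
  # reversed order, bypassing the guard by re-tagging
  net_rev <- net
  net_rev$meta$shift_applied <- TRUE
  b <- apply_volume_reduction(net_rev, d$volume_reduction_fraction)
  b$meta$shift_applied <- NULL
  b <- apply_blood_shift(b, d)
  expect_equal(total_blood_volume(a), total_blood_volume(b), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(a$compartments$legs_veins$V,
                                b$compartments$legs_veins$V,
                                tolerance = 1e-6)))
})

test_that("cardiac changes scale elastances, pulmonary compliances and chamber V0", {
  net <- baseline_network_1g()
  net$chambers$LV$V0 <- 20
  net$chambers$RV$E_min <- 0.08
  out <- apply_cardiac_changes(net)
  expect_equal(out$chambers$LV$V0, 2)          # x0.10 (90% reduction)
  expect_equal(out$chambers$RV$E_min, 0.0824)  # x1.03
  expect_equal(out$chambers$LV$E_amp, net$chambers$LV$E_amp * 0.73)
  expect_equal(out$compartments$pulmonary_arteries$C,
               net$compartments$pulmonary_arteries$C * 1.04)
  expect_equal(out$compartments$pulmonary_veins$C,
               net$compartments$pulmonary_veins$C * 1.05)
  # atria are not ventricles: elastances untouched, V0 still scaled
  expect_equal(out$chambers$LA$E_amp, net$chambers$LA$E_amp)
  expect_equal(out$chambers$LA$V0, net$chambers$LA$V0 * 0.10)
})

test_that("vascular changes hit the stated territories and nothing else", {
  net <- baseline_network_1g()
  out <- apply_vascular_changes(net)
  expect_equal(out$compartments$legs_veins$C,
               net$compartments$legs_veins$C * 1.27)
  expect_equal(out$compartments$l_internal_carotid_arterioles$R,
               net$compartments$l_internal_carotid_arterioles$R * 1.10)
  expect_equal(out$compartments$l_vertebral_arterioles$R,
               net$compartments$l_vertebral_arterioles$R * 1.10)
  # lower-body beds x0.90
  expect_equal(out$compartments$posterior_tibial_arterioles$R,
               net$compartments$posterior_tibial_arterioles$R * 0.90)
  expect_equal(out$compartments$mesenteric_arterioles$R,
               net$compartments$mesenteric_arterioles$R * 0.90)
  # upper-abdominal organ beds (above the VIP) are untouched
  expect_equal(out$compartments$l_renal_arterioles$R,
               net$compartments$l_renal_arterioles$R)
  expect_equal(out$compartments$gastric_arterioles$R,
               net$compartments$gastric_arterioles$R)
  # venous compliances outside the legs are untouched
  expect_equal(out$compartments$u_abd_veins$C, net$compartments$u_abd_veins$C)
})

test_that("the full 0g pipeline is ordered, tagged, guarded and reported", {
  net <- baseline_network_1g()
  v1 <- total_blood_volume(net)
  net0 <- configure_0g(net)
  expect_identical(net0$meta$gravity, "0g")
  expect_equal(total_blood_volume(net0), 0.885 * v1, tolerance = 1e-9)
  expect_equal(net0$baroreflex$hr_baseline, net$baroreflex$hr_baseline * 1.13)
  expect_equal(net0$baroreflex$setpoint, net$baroreflex$setpoint * 0.90)
  expect_error(configure_0g(net0), "idempotency")
  # the change report lists exactly the published parameter families
  fams <- unique(attr(net0, "changes")$family)
  expect_setequal(fams, c("blood_shift", "volume_reduction",
                          "ventricular_E_amp", "ventricular_E_min",
                          "chamber_V0", "pulmonary_artery_C",
                          "pulmonary_vein_C", "legs_venous_C",
                          "carotid_vertebral_R", "lower_body_R",
                          "hr_baseline", "setpoint"))
  # every change row carries before/after values
  ch <- attr(net0, "changes")
  expect_true(all(is.finite(ch$before)) && all(is.finite(ch$after)))
})

test_that("1D segments participate in shift and reduction via their lumen", {
  net <- baseline_network_1g()
  net0 <- configure_0g(net)
  v1 <- cardiodecon:::segment_volume(net$segments$femoral, net$numerics)
  v0 <- cardiodecon:::segment_volume(net0$segments$femoral, net0$numerics)
  rv <- cardiodecon:::regional_volumes(net)
  f_legs <- (1 - 235 / rv[["legs"]]) * 0.885
  expect_equal(v0 / v1, unname(f_legs), tolerance = 1e-9)
  # wall stiffness expressed as wave speed is preserved
  expect_equal(net0$segments$femoral$c0_prox, net$segments$femoral$c0_prox)
})
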