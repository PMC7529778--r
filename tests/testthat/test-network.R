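# Data model: construction, validation, volume accounting, serialization.

test_that("a minimal two-compartment closed loop is a legal network", {
  net <- generate_fixture("two-compartment-loop")
  expect_length(net$segments, 0)
  expect_length(net$compartments, 2)
  expect_identical(validate_network(net), character(0))
  # loop closure: each compartment drains into the other
  expect_identical(net$compartments$a$downstream, "b")
  expect_identical(net$compartments$b$downstream, "a")
})

test_that("the packaged supine baseline loads, validates and matches the builder", {
  net <- load_network(baseline_document_path())
  expect_identical(validate_network(net), character(0))
  built <- baseline_network_1g()
  expect_equal(net, built, tolerance = 0)
  # regions of the lumped venous return mirror the model scheme:
  # right heart, pulmonary circulation, upper/lower abdomen, head-arms
  # venous return, SVC, IVC, legs
  classes <- vapply(net$compartments, `[[`, "", "class")
  expect_setequal(names(net$chambers), c("LA", "LV", "RA", "RV"))
  expect_true(all(c("pulmonary-artery", "pulmonary-vein", "vena-cava",
                    "arteriole", "vein", "venule", "capillary") %in% classes))
  expect_true(all(c("svc", "ivc", "ha_veins", "u_abd_veins", "l_abd_veins",
                    "legs_veins") %in% names(net$compartments)))
})

test_that("invariant violations are reported and name the offending element", {
  net <- baseline_network_1g()
  bad <- net
  bad$segments$femoral$length <- -1
  expect_error(compile_network <- load_network(
    yaml::yaml.load(write_network(bad))), "femoral")
  report <- validate_network(bad)
  expect_true(any(grepl("femoral.*length", report)))

  bad2 <- net
  bad2$valves$MV$opening <- 1.5
  expect_true(any(grepl("MV", validate_network(bad2))))

  # removing the IVC leaves its tributaries dangling (open loop)
  bad3 <- net
  bad3$compartments$ivc <- NULL
  report3 <- validate_network(bad3)
  expect_true(any(grepl("dangling downstream 'ivc'", report3)))

  # a dangling terminal interface is a load error
  bad4 <- net
  bad4$interfaces[[1]]$arteriole <- "no_such_bed"
  expect_true(any(grepl("no_such_bed", validate_network(bad4))))
})

test_that("total blood volume sums compartments, chambers and 1D segments", {
  # all pressures zero, no segments -> sum of V0
  a <- compartment_0d("a", R = 1, C = 2, V0 = 100, P = 0, downstream = "b")
  b <- compartment_0d("b", R = 1, C = 5, V0 = 250, P = 0, downstream = "a")
  net <- cardiovascular_network(compartments = list(a, b))
  expect_equal(total_blood_volume(net), 350)

  # V = V0 + C P accounting
  a2 <- compartment_0d("a", R = 1, C = 2, V0 = 100, P = 10, downstream = "b")
  net2 <- cardiovascular_network(compartments = list(a2, b))
  expect_equal(total_blood_volume(net2), 370)

  # 1D volume responds to the initialization pressure through the tube law:
  # at zero pressure the tube holds exactly its unstressed volume A0 L
  net3 <- generate_fixture("single-tube-windkessel")
  v80 <- total_blood_volume(net3)
  net3$numerics$init_pressure <- 0
  v0 <- total_blood_volume(net3)
  seg <- net3$segments$tube
  comp_v <- sum(vapply(net3$compartments,
                       function(co) if (co$class == "reservoir") 0 else co$V, 0))
  expect_equal(v0, comp_v + pi * seg$r_prox^2 * seg$length, tolerance = 1e-12)
  expect_gt(v80, v0)
})

test_that("the VIP partition covers every volume-holding element exactly once", {
  net <- baseline_network_1g()
  vv <- cardiodecon:::vip_volumes(net)
  rv <- cardiodecon:::regional_volumes(net)
  expect_equal(unname(sum(vv)), total_blood_volume(net), tolerance = 1e-9)
  expect_equal(unname(sum(rv)), total_blood_volume(net), tolerance = 1e-9)
  upper <- rv[["head-arms"]] + rv[["cardiac-thoracic"]] + rv[["upper-abdomen"]]
  expect_equal(unname(vv[["upper"]]), unname(upper), tolerance = 1e-9)
})

test_that("serialization round-trips every parameter bit-exactly", {
  for (kind in c("single-tube-windkessel", "mini-tree")) {
    net <- generate_fixture(kind)
    txt <- write_network(net)
    net2 <- load_network(yaml::yaml.load(txt))
    expect_equal(net2, net, tolerance = 0)
  }
  net <- baseline_network_1g()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_network(net, path)
  expect_equal(load_network(path), net, tolerance = 0)
})
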