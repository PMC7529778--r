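# Shared fixtures and cached long runs.
#
# The 100-beat supine/weightlessness pair is expensive (~2 min); it is run
# once per session and reused by the heart, metrics, regression and
# acceptance tests.

.run_cache <- new.env(parent = emptyenv())

cached_pair <- function() {
  if (!exists("pair", envir = .run_cache)) {
    net1 <- baseline_network_1g()
    net0 <- configure_0g(net1)
    .run_cache$net1 <- net1
    .run_cache$net0 <- net0
    .run_cache$pair <- list(
      r1 = run_simulation(net1, n_beats = 100),
      r0 = run_simulation(net0, n_beats = 100))
  }
  .run_cache$pair
}

cached_networks <- function() {
  cached_pair()
  list(net1 = .run_cache$net1, net0 = .run_cache$net0)
}

# tiny lumped-only network: compartment discharging through R into a
# fixed-pressure reservoir (closed-form RC decay)
rc_discharge_network <- function(R = 1, C = 2, P0 = 20, P_out = 0) {
  a <- compartment_0d("cap", R = R, C = C, V0 = 100, P = P0,
                      downstream = "sink", class = "vein")
  sink <- compartment_0d("sink", R = 0, C = 1, V0 = 0, class = "reservoir",
                         P_fix = P_out)
  cardiovascular_network(compartments = list(a, sink),
                         meta = list(name = "rc-discharge", gravity = "1g"))
}

# toy two-zone region network used by the gravity-configurator tests
two_zone_network <- function() {
  a <- compartment_0d("zone_a", R = 1, C = 5, V0 = 60, P = 8,
                      downstream = "zone_b", class = "vein",
                      region = "legs", vip_side = "lower", venous = TRUE)
  b <- compartment_0d("zone_b", R = 1, C = 15, V0 = 180, P = 8,
                      downstream = "zone_a", class = "vein",
                      region = "legs", vip_side = "lower", venous = TRUE)
  up <- compartment_0d("zone_u", R = 1, C = 10, V0 = 100, P = 10,
                       downstream = "zone_u", class = "vein",
                       region = "head-arms", vip_side = "upper")
  net <- cardiovascular_network(compartments = list(a, b, up),
                                meta = list(name = "two-zone", gravity = "1g"))
  net
}

# uniform test segment, discretized
uniform_segment_state <- function(length = 40, r = 0.6, c0 = 500, gamma = 0,
                                  P0 = 30, dx = 0.25) {
  seg <- artery_segment("t", length = length, r_prox = r, r_dist = r,
                        c0_prox = c0, c0_dist = c0, wall_viscosity = gamma)
  cardiodecon:::discretize_segment(
    seg, list(rho = 1.06, mu = 0.04, dx_max = dx, init_pressure = P0))
}

trapz_ref <- function(x, y) {
  # independent quadrature for cross-checks
  if (requireNamespace("pracma", quietly = TRUE)) pracma::trapz(x, y)
  else sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}
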