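test_that("segment stiffness and cross-section match the published constants", {
  expect_equal(actin_cross_section(3.5), 38.48, tolerance = 2e-4)
  ## 0.46 N/m at the initial 150-nm rest length (pN/nm -> N/m is /1000)
  expect_equal(effective_segment_stiffness(150) / 1000, 0.46, tolerance = 5e-3)
  ## kappa scales as 1/L0: doubling the rest length halves the stiffness
  expect_equal(effective_segment_stiffness(300) / 1000, 0.231, tolerance = 5e-3)
  expect_equal(effective_segment_stiffness(150) /
               effective_segment_stiffness(300), 2)
  expect_error(effective_segment_stiffness(0))
})

test_that("load-dependent growth follows the exponential velocity-force law", {
  expect_equal(load_dependent_growth_rate(0, 1), 50)
  expect_equal(load_dependent_growth_rate(20, 1), 50 / exp(1),
               tolerance = 1e-12)
  ## more filaments sharing the load strictly speed growth
  v1 <- load_dependent_growth_rate(40, 1)
  v2 <- load_dependent_growth_rate(40, 2)
  expect_gt(v2, v1)
  expect_error(load_dependent_growth_rate(10, 0))
})

test_that("rest lengths grow at the barbed end and shrink at the pointed end", {
  net <- actin_network()
  net <- an_add_filament(net, cbind(0, 0, seq(0, 600, by = 150)))
  net <- update_rest_lengths(net, 1, dt = 1, grow = TRUE, shrink = FALSE,
                             v_g = 20)
  expect_equal(net$filaments[[1]]$L0, c(150, 150, 150, 170))
  net <- update_rest_lengths(net, 1, dt = 1, grow = FALSE, shrink = TRUE)
  expect_equal(net$filaments[[1]]$L0, c(140, 150, 150, 170))
  ## capped filament: barbed end frozen
  net$filaments[[1]]$capped <- TRUE
  L_before <- net$filaments[[1]]$L0
  net <- update_rest_lengths(net, 1, dt = 1, grow = TRUE, shrink = FALSE)
  expect_equal(net$filaments[[1]]$L0, L_before)
})

test_that("net rest-contour growth is exactly v_g - v_s under free growth", {
  net <- actin_network()
  net <- an_add_filament(net, cbind(0, 0, seq(0, 900, by = 150)))
  c0 <- filament_contour(net, 1)
  for (i in 1:40)   # 20 s in 0.5-s control steps, crossing split/merge events
    net <- update_rest_lengths(net, 1, dt = 0.5, grow = TRUE, shrink = TRUE)
  expect_equal(filament_contour(net, 1), c0 + 20 * (20 - 10))
})

test_that("barbed segments split at 300 nm and the filament dies below 2 nodes", {
  net <- actin_network()
  net <- an_add_filament(net, rbind(c(0, 0, 0), c(0, 0, 290)), L0 = 290)
  net <- update_rest_lengths(net, 1, dt = 1, grow = TRUE, shrink = FALSE)
  expect_equal(net$filaments[[1]]$L0, c(155, 155))
  expect_length(net$filaments[[1]]$nodes, 3L)
  ## shrink a 2-node filament to extinction
  net2 <- actin_network()
  net2 <- an_add_filament(net2, rbind(c(0, 0, 0), c(0, 0, 30)), L0 = 30)
  net2 <- update_rest_lengths(net2, 1, dt = 5, grow = FALSE, shrink = TRUE)
  expect_false(net2$filaments[[1]]$alive)
})

test_that("filament elastic force reproduces the hand-computed tension", {
  ## one segment at 165 nm (L0 = 150): kappa * 15 = 6.9 nN
  net <- actin_network()
  net <- an_add_filament(net, rbind(c(0, 0, 0), c(0, 0, 165)), L0 = 150)
  F <- actin_elastic_forces(net)
  expect_equal(sqrt(sum(F[1, ]^2)), effective_segment_stiffness(150) * 15)
  expect_equal(sqrt(sum(F[1, ]^2)) / 1000, 6.9, tolerance = 5e-3)  # nN
  expect_equal(F[1, ] + F[2, ], numeric(3))
  ## straight filament at rest: zero everywhere
  net0 <- actin_network()
  net0 <- an_add_filament(net0, cbind(0, 0, seq(0, 600, by = 150)))
  expect_equal(max(abs(actin_elastic_forces(net0))), 0)
})

test_that("filament and branch forces equal minus the energy gradient", {
  for (seed in 1:3) {
    net <- branched_net(perturb = 8, seed = seed)
    F <- actin_elastic_forces(net) + branch_forces(net)
    G <- num_grad(function(Z) actin_elastic_energy(net, Z) +
                    branch_energy(net, Z), net$X, h = 1e-4)
    expect_lt(grad_mismatch(F, G), 1e-6)
  }
})

test_that("branch equilibrium geometry carries zero force, stretched Arp 100 pN", {
  net <- branched_net(perturb = 0)
  ## construction places the daughter at lambda_arp = 30 nm and 70 degrees
  F <- branch_forces(net)
  expect_lt(max(abs(F)), 1e-9)
  ## displace the daughter base 10 nm along the Arp connector: kappa_arp *
  ## 10 nm = 100 pN spring force (angle terms unchanged by radial motion)
  d1 <- net$filaments[[2]]$nodes[1]
  mj <- net$filaments[[2]]$mother$node_j
  dir <- net$X[d1, ] - net$X[mj, ]
  dir <- dir / sqrt(sum(dir^2))
  net$X[d1, ] <- net$X[d1, ] + 10 * dir
  net$X[net$filaments[[2]]$nodes[2], ] <-
    net$X[net$filaments[[2]]$nodes[2], ] + 10 * dir
  F <- branch_forces(net)
  expect_equal(sqrt(sum(F[mj, ]^2)), 100, tolerance = 1e-6)
})

test_that("ratchet force follows the logarithmic law with its clamps and gate", {
  n <- c(0, 0, 1)
  ## relative normal speed = v0: log(1) = 0
  expect_equal(ratchet_force(c(0, 0, 50), c(0, 0, 0), n), numeric(3))
  ## speed v0/e: F_p * log(e) = 20 pN
  F <- ratchet_force(c(0, 0, 50 / exp(1)), c(0, 0, 0), n)
  expect_equal(F, c(0, 0, 20), tolerance = 1e-12)
  ## zero speed: clamped at F_max
  expect_equal(ratchet_force(c(0, 0, 0), c(0, 0, 0), n)[3], 100)
  ## faster than v0: clamped at zero, never negative
  expect_equal(ratchet_force(c(0, 0, 500), c(0, 0, 0), n), numeric(3))
  ## phase gate: off outside the protrusive phase
  expect_equal(ratchet_force(c(0, 0, 5), c(0, 0, 0), n, phase = "retractile"),
               numeric(3))
})

test_that("the barbed-end lifecycle follows gap, tension and capping rules", {
  p <- invadosim_params()
  X_cc <- matrix(c(0, 0, 250), 1L)
  net <- actin_network()
  net <- an_add_filament(net, cbind(0, 0, seq(0, 200, by = 100)),
                         state = 2L)
  ## gap 50 nm < 100 nm: growth -> adhesion
  net <- state_transition(net, 1, X_cc, "protrusive", 0.5, rng_u = 0.99)
  expect_equal(net$filaments[[1]]$state, 3L)
  expect_equal(net$filaments[[1]]$adhesion$L0, 50)
  ## stretch the adhesion to 25 pN tension (kappa_adh 10 pN/nm, +2.5 nm
  ## would rupture at 25 pN; move the cortex node away by 2.5 nm extra)
  X_cc2 <- matrix(c(0, 0, 252.6), 1L)
  net <- state_transition(net, 1, X_cc2, "protrusive", 0.5, rng_u = 0.99)
  expect_equal(net$filaments[[1]]$state, 5L)   # detach is transient -> ratchet
  expect_null(net$filaments[[1]]$adhesion)
  ## capping probability per step: 1 - exp(-k_cap dt)
  expect_equal(1 - exp(-p$actin$k_cap * 0.01), 0.002996, tolerance = 1e-3)
  net <- state_transition(net, 1, X_cc2, "protrusive", 0.01, rng_u = 0.0001)
  expect_equal(net$filaments[[1]]$state, 6L)
  expect_true(net$filaments[[1]]$capped)
  ## unknown state faults
  net$filaments[[1]]$state <- 99L
  expect_error(state_transition(net, 1, X_cc, "protrusive", 0.5),
               "unknown filament state")
})

test_that("severing partitions filaments into <= 300-nm pieces, conserving contour", {
  mk <- function(total, by = 150) {
    net <- actin_network()
    an_add_filament(net, cbind(0, 0, seq(0, total, by = by)))
  }
  ## 900 nm -> 3 pieces of 300 nm
  net <- sever_filament(mk(900), 1)
  alive <- Filter(function(fl) fl$alive, net$filaments)
  expect_length(alive, 3L)
  expect_equal(vapply(alive, function(fl) sum(fl$L0), numeric(1)),
               rep(300, 3))
  ## 250 nm -> 1 piece (unchanged)
  net <- sever_filament(mk(250, by = 125), 1)
  expect_length(Filter(function(fl) fl$alive, net$filaments), 1L)
  ## 750 nm -> pieces summing to 750
  net <- sever_filament(mk(750), 1)
  alive <- Filter(function(fl) fl$alive, net$filaments)
  expect_equal(sum(vapply(alive, function(fl) sum(fl$L0), numeric(1))), 750)
  expect_true(all(vapply(alive, function(fl) sum(fl$L0), numeric(1)) <= 300))
})
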