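test_that("binding positions are convex combinations of segment endpoints", {
  a <- c(0, 0, 0); b <- c(100, 0, 0)
  expect_equal(binding_position(a, b, 0), a)
  expect_equal(binding_position(a, b, 1), b)
  expect_equal(binding_position(a, b, 0.25), c(25, 0, 0))
})

test_that("crosslinker forces distribute by fraction and obey action-reaction", {
  ## two parallel segments 70 nm apart, alpha-actinin rest 50, kappa 10
  net <- actin_network()
  net <- an_add_filament(net, rbind(c(0, 0, 0), c(150, 0, 0)))
  net <- an_add_filament(net, rbind(c(0, 70, 0), c(150, 70, 0)))
  lk <- one_linker(kind = 3L, alpha = 0.3, beta = 0.3, L0 = 50,
                   filB = 2L, b1 = 3L, b2 = 4L)
  r <- linker_forces(lk, net$X)
  expect_equal(r$tension, 200)                       # 10 pN/nm * 20 nm
  expect_equal(sqrt(sum(r$F_actin[1, ]^2)), (1 - 0.3) * 200)
  expect_equal(sqrt(sum(r$F_actin[2, ]^2)), 0.3 * 200)
  ## filament A total + filament B total = 0
  expect_equal(colSums(r$F_actin[1:2, ]) + colSums(r$F_actin[3:4, ]),
               numeric(3))
  ## at rest length: all four node forces zero
  lk0 <- one_linker(kind = 3L, L0 = 70, alpha = 0.3, beta = 0.3,
                    filB = 2L, b1 = 3L, b2 = 4L)
  expect_equal(max(abs(linker_forces(lk0, net$X)$F_actin)), 0)
  ## gradient oracle at a skew configuration
  set.seed(5)
  X <- net$X + matrix(rnorm(12, 0, 10), ncol = 3)
  F <- linker_forces(lk, X)$F_actin
  G <- num_grad(function(Z) linker_energy(lk, Z), X, h = 1e-5)
  expect_lt(grad_mismatch(F, G), 1e-6)
})

test_that("myosin springs engage only in the retractile phase", {
  net <- actin_network()
  net <- an_add_filament(net, rbind(c(0, 0, 0), c(150, 0, 0)))
  net <- an_add_filament(net, rbind(c(0, 350, 0), c(150, 350, 0)))
  lk <- one_linker(kind = 4L, L0 = 300, alpha = 0.5, beta = 0.5,
                   filB = 2L, b1 = 3L, b2 = 4L)
  on <- linker_forces(lk, net$X, motors_on = TRUE)
  expect_equal(on$tension, 500)                      # 10 pN/nm * 50 nm
  off <- linker_forces(lk, net$X, motors_on = FALSE)
  expect_equal(max(abs(off$F_actin)), 0)
  ## at rest (300 nm) no force either way
  net$X[3:4, 2] <- 300
  expect_equal(max(abs(linker_forces(lk, net$X)$F_actin)), 0)
})

test_that("the Hill force-velocity law hits its published endpoints", {
  expect_equal(hill_sliding_velocity(0), 160)
  expect_equal(hill_sliding_velocity(1240), 0)
  ## half stall: 160 * 0.5 / (1 + 4.761 * 0.5)
  expect_equal(hill_sliding_velocity(620), 23.66, tolerance = 1e-3)
  ## above stall: clamped at zero rather than reversing
  expect_equal(hill_sliding_velocity(2000), 0)
  ## monotone decreasing in load
  v <- hill_sliding_velocity(seq(0, 1240, by = 62))
  expect_true(all(diff(v) < 0))
})

test_that("sliding updates alpha by v dt / segment length and clamps at the barbed end", {
  net <- actin_network()
  net <- an_add_filament(net, cbind(seq(0, 450, by = 150), 0, 0))
  net <- an_add_filament(net, cbind(seq(0, 450, by = 150), 350, 0))
  lk <- one_linker(kind = 4L, L0 = 300, alpha = 0.5, beta = 0.5,
                   filB = 2L, b1 = 5L, b2 = 6L)
  lk$F_prev <- 0   # unloaded: v = 160 nm/s
  r <- advance_sliding(lk, net, dt = 0.01)
  expect_equal(r$alpha, 0.5 + 160 * 0.01 / 150, tolerance = 1e-12) # 0.51067
  ## zero velocity leaves fractions unchanged
  lk$F_prev <- 1240
  r <- advance_sliding(lk, net, dt = 0.01)
  expect_equal(r$alpha, 0.5)
  ## long slide hops segments toward the barbed end, then clamps at 1
  lk$F_prev <- 0
  r <- lk
  for (i in 1:50) r <- advance_sliding(r, net, dt = 0.1)
  expect_equal(r$a2, 4L)     # terminal barbed segment of filament 1
  expect_equal(r$alpha, 1)
  ## alpha is monotone under repeated sliding
  r <- lk; prev <- -Inf
  for (i in 1:10) {
    r <- advance_sliding(r, net, dt = 0.02)
    pos <- match(r$a1, net$filaments[[1]]$nodes) + r$alpha
    expect_gte(pos, prev)
    prev <- pos
  }
})

test_that("the predicted-position identity matches the geometric recomputation", {
  ## alpha* from the expanded identity equals |x* - x_j| / |x_{j+1} - x_j|
  set.seed(9)
  for (i in 1:20) {
    xj <- rnorm(3, 0, 100); xj1 <- xj + rnorm(3, 0, 150)
    alpha <- runif(1, 0, 0.8); v <- runif(1, 0, 200); dt <- 0.01
    that <- (xj1 - xj) / sqrt(sum((xj1 - xj)^2))
    xstar <- (1 - alpha) * xj + alpha * xj1 + v * dt * that
    geom <- sqrt(sum((xstar - xj)^2)) / sqrt(sum((xj1 - xj)^2))
    expanded <- alpha + v * dt / sqrt(sum((xj1 - xj)^2))
    expect_equal(geom, expanded, tolerance = 1e-12)
  }
})

test_that("placement respects parallelism, the leading-edge cone, turnover and knockouts", {
  p <- invadosim_params(linker = list(p_bind = 1))
  set.seed(2)
  net <- actin_network()
  ## two parallel filaments in the +z cone, 40 nm apart (fascin range)
  net <- an_add_filament(net, rbind(c(0, 0, 800), c(0, 0, 950)), pattern = 1L)
  net <- an_add_filament(net, rbind(c(40, 0, 800), c(40, 0, 950)), pattern = 1L)
  ## an 80-degree pair: ineligible for fascin bundling
  net <- an_add_filament(net, rbind(c(200, 0, 800), c(200, 0, 950)),
                         pattern = 1L)
  net <- an_add_filament(net,
    rbind(c(240, 0, 800), c(240 + 150 * sin(80 * pi / 180), 0,
                            800 + 150 * cos(80 * pi / 180))), pattern = 1L)
  X_pal <- matrix(c(0, 0, -5000), 1L)
  lk <- place_and_turnover(linker_table(), net, X_pal, c(0, 0, 1),
                           center = c(0, 0, 0), t = 0, phase = "protrusive",
                           params = p)
  fas <- lk[lk$kind == 1L, ]
  expect_true(all(fas$filA %in% 1:2 & fas$filB %in% 1:2))  # never the 80-deg pair
  expect_gt(nrow(fas), 0)
  ## candidates at 75 degrees from polarity are outside the 60-degree cone
  net2 <- actin_network()
  z <- 1000 * cos(75 * pi / 180); x <- 1000 * sin(75 * pi / 180)
  net2 <- an_add_filament(net2, rbind(c(x, 0, z), c(x, 0, z + 150)))
  net2 <- an_add_filament(net2, rbind(c(x + 40, 0, z), c(x + 40, 0, z + 150)))
  lk2 <- place_and_turnover(linker_table(), net2, X_pal, c(0, 0, 1),
                            center = c(0, 0, 0), t = 0, phase = "protrusive",
                            params = p)
  expect_equal(nrow(lk2[lk2$kind %in% c(1L, 2L), ]), 0L)
  ## turnover: a linker aged past 60 s is removed this step
  lk$birth <- -61
  lk3 <- place_and_turnover(lk, actin_network(), X_pal, c(0, 0, 1),
                            c(0, 0, 0), t = 0, phase = "protrusive",
                            params = p)
  expect_equal(nrow(lk3), 0L)
  ## knockouts suppress placement entirely
  lk4 <- place_and_turnover(linker_table(), net, X_pal, c(0, 0, 1),
                            c(0, 0, 0), t = 0, phase = "protrusive",
                            ko = list(fascin = TRUE, filamin = TRUE,
                                      alpha_actinin = TRUE), params = p)
  expect_equal(nrow(lk4), 0L)
})
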