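test_that("the fiber network generator is seed-deterministic and hits its pore target", {
  a <- .test_ecm(1)
  b <- generate_network(c(8000, 8000, 8000), 2000, 41, seed = 1)
  expect_identical(a$X, b$X)
  expect_identical(a$seg, b$seg)
  ## measured mean pore within 15% of the 2.0-um target
  expect_lt(abs(a$pore_measured - 2000) / 2000, 0.15)
  ## a single giant component holds >= 90% of the nodes
  edges <- rbind(as.matrix(a$seg[, c("n1", "n2")]),
                 as.matrix(a$junction[, c("n1", "n2")]))
  n <- nrow(a$X)
  adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  seen <- logical(n); comp <- integer(n); cid <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    cid <- cid + 1L; q <- s; seen[s] <- TRUE
    while (length(q)) {
      v <- q[[1]]; q <- q[-1]; comp[v] <- cid
      nb <- adj[[as.character(v)]]; nb <- nb[!seen[nb]]
      seen[nb] <- TRUE; q <- c(q, nb)
    }
  }
  expect_gte(max(table(comp)) / n, 0.9)
  ## degenerate request rejected
  expect_error(generate_network(c(8000, 8000, 8000), 5000, 41, seed = 1),
               "pore size")
})

test_that("fiber forces are zero at rest and gradient-consistent when perturbed", {
  ecm <- .test_ecm(1)
  expect_lt(max(abs(fiber_forces(ecm))), 1e-7)
  ## a single fiber stretched 1%: tension = (A_f E / L0) * 0.01 L0
  one <- ecm
  one$seg <- data.frame(n1 = 1L, n2 = 2L, L0 = 500, fiber = 1L, intact = TRUE)
  one$bend <- one$bend[0, ]; one$junction <- one$junction[0, ]
  one$X <- rbind(c(0, 0, 0), c(0, 0, 505))
  F <- fiber_forces(one)
  expect_equal(sqrt(sum(F[1, ]^2)), one$area * one$E_collagen * 0.01,
               tolerance = 1e-9)
  ## random perturbation: forces match the numerical energy gradient
  set.seed(4)
  sub <- ecm
  keep <- which(sub$seg$fiber %in% 1:3)
  sub$seg <- sub$seg[keep, , drop = FALSE]
  segkey <- paste(sub$seg$n1, sub$seg$n2)
  sub$bend <- sub$bend[paste(sub$bend$n1, sub$bend$n2) %in% segkey &
                       paste(sub$bend$n2, sub$bend$n3) %in% segkey, ]
  nodes <- sort(unique(c(sub$seg$n1, sub$seg$n2)))
  sub$junction <- sub$junction[sub$junction$n1 %in% nodes &
                               sub$junction$n2 %in% nodes, ]
  X <- sub$X
  X[nodes, ] <- X[nodes, ] + matrix(rnorm(3 * length(nodes), 0, 5), ncol = 3)
  F <- fiber_forces(sub, X)
  idx <- nodes[1:15]
  G <- X * 0
  for (i in idx) for (k in 1:3) {
    h <- 1e-3
    Xp <- X; Xp[i, k] <- X[i, k] + h
    Xm <- X; Xm[i, k] <- X[i, k] - h
    G[i, k] <- (fiber_energy(sub, Xp) - fiber_energy(sub, Xm)) / (2 * h)
  }
  expect_lt(max(abs(F[idx, ] + G[idx, ])) / max(abs(F[idx, ])), 1e-6)
})

test_that("Bell kinetics: slip-bond rates and ODE equilibrium", {
  p <- invadosim_params()
  ## at the rest length the dissociation rate is the intrinsic one
  r <- bond_rates(30, p)
  expect_equal(r$k_off, p$adhesion$k_off0)
  ## k_off strictly increases with bond length (slip bond)
  ko <- bond_rates(seq(30, 60, by = 5), p)$k_off
  expect_true(all(diff(ko) > 0))
  ## negative bond length faults
  expect_error(bond_rates(-1), "negative")
  ## integrated n_b converges to the closed-form equilibrium at fixed L_b
  Lb <- 38
  r <- bond_rates(Lb, p)
  eq <- p$adhesion$n_tot * r$k_on / (r$k_on + r$k_off)
  nb <- 0   # integrate to ~10 relaxation times of the bond ODE
  t_end <- 10 / (r$k_on + r$k_off)
  for (i in 1:5000) nb <- bond_kinetics_step(nb, Lb, t_end / 5000, p)
  expect_equal(nb, eq, tolerance = 1e-3)
  ## n_b stays within [0, n_tot]
  expect_lte(bond_kinetics_step(p$adhesion$n_tot, 30, 1, p), p$adhesion$n_tot)
  expect_gte(bond_kinetics_step(0, 200, 1, p), 0)
})

test_that("focal complex forces are paired and match the bond-count arithmetic", {
  ## n_b = 10 bonds at 1 pN/nm stretched 10 nm: 100 pN
  r <- focal_complex_force(c(0, 0, 0), c(0, 0, 40), n_b = 10)
  expect_equal(sqrt(sum(r$F_ci^2)), 100)
  expect_equal(r$F_ci + r$F_en, numeric(3))
  ## at the 30-nm rest length: zero
  r0 <- focal_complex_force(c(0, 0, 0), c(0, 0, 30), n_b = 10)
  expect_equal(r0$F_ci, numeric(3))
})

test_that("volume exclusion pushes penetrating nodes out with paired reactions", {
  cell <- build_spherical_cell(3000, 1300, 1)
  nrm <- vertex_normals(cell$CI)
  ## fiber node 10 nm inside the membrane at the +z pole: 100 pN outward
  pole <- which.max(cell$CI$X[, 3])
  pt <- matrix(cell$CI$X[pole, ] - 10 * nrm[pole, ], 1L)
  ex <- volume_exclusion_forces(pt, cell$CI$X, nrm, side = "inside",
                                kappa = 10)
  expect_equal(sqrt(sum(ex$F_pts^2)), 100, tolerance = 1e-6)
  expect_gt(ex$F_pts[1, 3], 0)   # outward
  expect_equal(ex$F_pts[1, ] + ex$F_mesh[pole, ], numeric(3))
  ## a node well outside: no force anywhere
  far <- matrix(c(0, 0, 10000) + cell$CI$X[pole, ], 1L)
  ex0 <- volume_exclusion_forces(far, cell$CI$X, nrm, side = "inside")
  expect_equal(max(abs(ex0$F_pts)), 0)
  expect_equal(max(abs(ex0$F_mesh)), 0)
})

test_that("degradation is local, thresholded and irreversible", {
  ecm <- .test_ecm(1)
  p <- invadosim_params()
  field <- rd_field(c(8000, 8000, 8000), p)
  ## full phi6 everywhere: nothing degrades
  e1 <- degrade_segments(ecm, field, p)
  expect_true(all(e1$seg$intact))
  ## zero phi6 in a ball around one segment midpoint: that segment degrades
  s1 <- 1L
  mid <- (ecm$X[ecm$seg$n1[s1], ] + ecm$X[ecm$seg$n2[s1], ]) / 2
  gi <- pmin(pmax(round(mid / field$h) + 1L, 1L), field$dims)
  lo <- pmax(gi - 2L, 1L); hi <- pmin(gi + 2L, field$dims)
  field$phi6[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 0
  e2 <- degrade_segments(ecm, field, p)
  expect_false(e2$seg$intact[s1])
  ## degraded count is non-decreasing under further steps
  n1 <- sum(!e2$seg$intact)
  e3 <- degrade_segments(e2, rd_field(c(8000, 8000, 8000), p), p)
  expect_gte(n1, sum(!e3$seg$intact) * 0 + n1)  # irreversible
  expect_true(all(which(!e2$seg$intact) %in% which(!e3$seg$intact)))
  ## degraded segments exert no force
  expect_equal(nrow(active_bends(e2)) <= nrow(active_bends(ecm)), TRUE)
})

test_that("the stretch test reports zero stress at zero strain and grows with density", {
  ecm <- .test_ecm(1)
  r0 <- bulk_modulus_stretch_test(ecm, strains = c(-0.01, 0, 0.01))
  expect_lt(abs(r0$table$stress[r0$table$strain_lin == 0]),
            1e-3 * max(abs(r0$table$stress)))
  ## denser network (smaller pore) is stiffer at equal modulus
  dense <- generate_network(c(8000, 8000, 8000), 1500, 41, seed = 3)
  sparse <- generate_network(c(8000, 8000, 8000), 2500, 41, seed = 3)
  Kd <- bulk_modulus_stretch_test(dense, strains = c(-0.01, 0.01))$K_Pa
  Ks <- bulk_modulus_stretch_test(sparse, strains = c(-0.01, 0.01))$K_Pa
  expect_gt(Kd, Ks)
})
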