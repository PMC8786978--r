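test_that("icosphere subdivision gives the closed-mesh node/triangle counts", {
  for (lev in 0:2) {
    ic <- icosphere(1000, lev)
    expect_equal(nrow(ic$X), 10 * 4^lev + 2)
    expect_equal(nrow(ic$tri), 20 * 4^lev)
    ## closed orientable surface: every edge borders exactly two triangles
    ek <- apply(rbind(ic$tri[, 1:2], ic$tri[, 2:3], ic$tri[, c(3, 1)]),
                1L, function(e) paste(sort(e), collapse = "-"))
    expect_true(all(table(ek) == 2L))
    expect_equal(sqrt(rowSums(ic$X^2)), rep(1000, nrow(ic$X)))
  }
})

test_that("a fresh five-layer cell is at rest with 50-nm layer pairing", {
  cell <- build_spherical_cell(3000, 1300, 1)
  expect_equal(max(abs(membrane_elastic_forces(cell$CI))), 0)
  tc <- transduce_and_cortex_forces(cell)
  for (Fm in tc[c("F_I", "F_T", "F_C")])
    expect_lt(max(abs(Fm)), 1e-9)
  gap_IT <- sqrt(rowSums((cell$CI$X - cell$CT$X)^2))
  gap_TC <- sqrt(rowSums((cell$CT$X - cell$CC$X)^2))
  expect_equal(gap_IT, rep(50, nrow(cell$CI$X)))
  expect_equal(gap_TC, rep(50, nrow(cell$CT$X)))
  expect_equal(sqrt(rowSums((cell$PAL$X - cell$NMS$X)^2)),
               rep(50, nrow(cell$PAL$X)))
})

test_that("cell construction rejects impossible geometry", {
  expect_error(build_spherical_cell(-1, 500, 1), "positive")
  expect_error(build_spherical_cell(1500, 1450, 1), "strictly inside")
  ## a 150-nm cell cannot host two 50-nm offsets plus the nucleus
  expect_error(build_spherical_cell(260, 110, 3), "too coarse|too small")
})

test_that("a 10% stretched edge at the published membrane stiffness gives 1 pN", {
  ## kappa_L^I = 5e-5 N/m = 0.05 pN/nm, L0 = 200 nm, stretch 20 nm
  mesh <- list(id = "CI", X = rbind(c(0, 0, 0), c(220, 0, 0), c(110, 500, 0)),
               tri = matrix(c(1L, 2L, 3L), 1L),
               edges = matrix(c(1L, 2L), 1L),
               L0 = 200, A0 = 1, kappa_L = 0.05, kappa_A = 0,
               kappa_L_edge = NULL)
  F <- membrane_elastic_forces(mesh)
  expect_equal(sqrt(sum(F[1, ]^2)), 1.0, tolerance = 1e-12)
  expect_equal(F[1, ], c(1, 0, 0))          # pulls toward the partner
  expect_equal(F[2, ], -F[1, ])             # Newton pair
})

test_that("a 60-nm transduce link at kappa_T = 8e-3 N/m attracts with 80 pN", {
  XA <- matrix(c(0, 0, 0), 1L)
  XB <- matrix(c(0, 0, 60), 1L)
  vf <- vertical_link_forces(XA, XB, kappa = 8, L0 = 50)
  expect_equal(sqrt(sum(vf$FA^2)), 80)
  expect_equal(vf$FA[1, 3], 80)             # attraction: A pulled toward B
  expect_equal(vf$FA + vf$FB, matrix(0, 1L, 3L))
})

test_that("membrane forces equal minus the numerical energy gradient", {
  set.seed(7)
  cell <- build_spherical_cell(3000, 1300, 1)
  for (ly in c("CI", "CC", "PAL")) {
    m <- cell[[ly]]
    X <- m$X + matrix(rnorm(length(m$X), 0, 25), ncol = 3)
    F <- membrane_elastic_forces(m, X)
    G <- num_grad(function(Z) membrane_energy(m, Z), X, h = 1e-3)
    expect_lt(grad_mismatch(F, G), 1e-6)
  }
  ## vertical links too
  XA <- cell$CI$X; XB <- cell$CT$X + matrix(rnorm(length(XA), 0, 20), ncol = 3)
  vf <- vertical_link_forces(XA, XB, 8, 50)
  GA <- num_grad(function(Z) vertical_link_energy(Z, XB, 8, 50), XA, h = 1e-3)
  expect_lt(grad_mismatch(vf$FA, GA), 1e-6)
})

test_that("internal forces of a closed layer sum to zero", {
  set.seed(11)
  cell <- build_spherical_cell(3000, 1300, 1)
  m <- cell$CI
  X <- m$X + matrix(rnorm(length(m$X), 0, 40), ncol = 3)
  F <- membrane_elastic_forces(m, X)
  expect_lt(max(abs(colSums(F))), 1e-8 * max(abs(F)) * nrow(F))
})

test_that("nuclear crosslink force follows the spring law and its gradient", {
  ## alpha-actinin, rest 50 nm, kappa 0.01 N/m stretched to 70 nm -> 200 pN
  r <- nuclear_link_force(c(0, 0, 0), c(70, 0, 0), kappa = 10, L0 = 50)
  expect_equal(sqrt(sum(r$F_nuc^2)), 200)
  expect_equal(r$F_nuc + r$F_attach, numeric(3))
  r0 <- nuclear_link_force(c(0, 0, 0), c(50, 0, 0), kappa = 10, L0 = 50)
  expect_equal(r0$F_nuc, numeric(3))
  ## gradient oracle
  x <- c(3, -4, 12)
  en <- function(z) 0.5 * 10 * (sqrt(sum((z - c(70, 5, -3))^2)) - 50)^2
  G <- vapply(1:3, function(k) {
    h <- 1e-6; xp <- x; xm <- x; xp[k] <- x[k] + h; xm[k] <- x[k] - h
    (en(xp) - en(xm)) / (2 * h)
  }, numeric(1))
  r <- nuclear_link_force(x, c(70, 5, -3), kappa = 10, L0 = 50)
  expect_equal(r$F_nuc, -G, tolerance = 1e-6)
})

test_that("damped relaxation of a perturbed layer never increases its energy", {
  set.seed(3)
  cell <- build_spherical_cell(3000, 1300, 1)
  m <- cell$CI
  m$kappa_A <- 0.1
  X <- m$X + matrix(rnorm(length(m$X), 0, 60), ncol = 3)
  H0 <- H <- membrane_energy(m, X)
  for (i in 1:200) {
    X <- X + 0.5 * membrane_elastic_forces(m, X)   # overdamped descent
    H2 <- membrane_energy(m, X)
    expect_lte(H2, H * (1 + 1e-12))
    H <- H2
  }
  expect_lt(H, 0.5 * H0)   # substantially relaxed
})
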