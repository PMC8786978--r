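test_that("tip position is the maximal-projection node, equivariant and oracle-exact", {
  ic <- icosphere(2000, 1)
  tp <- tip_position(ic$X, c(0, 0, 1))
  expect_equal(tp$pos[3], max(ic$X[, 3]))
  ## translation equivariance
  sh <- sweep(ic$X, 2L, c(100, -50, 300), `+`)
  tp2 <- tip_position(sh, c(0, 0, 1))
  expect_equal(tp2$pos, ic$X[tp$node, ] + c(100, -50, 300))
  ## deformed mesh: equals brute-force argmax over all nodes
  set.seed(12)
  Xd <- ic$X + matrix(rnorm(length(ic$X), 0, 150), ncol = 3)
  pol <- c(1, 2, -0.5); pol <- pol / sqrt(sum(pol^2))
  tp3 <- tip_position(Xd, pol)
  expect_equal(tp3$node, which.max(as.numeric(Xd %*% pol)))
})

test_that("average speed matches direct window computations", {
  t <- seq(0, 600, by = 1)
  ## uniform straight motion at 20 nm/s
  P <- cbind(0, 0, 20 * t)
  expect_equal(average_speed(t, P, window = 180), 20)
  ## stationary path
  expect_equal(average_speed(t, P * 0, window = 180), 0)
  ## zig-zag: compare against a brute-force window loop
  set.seed(3)
  P2 <- apply(matrix(rnorm(length(t) * 3, 0, 30), ncol = 3), 2, cumsum)
  w <- 120
  idx <- seq(1, length(t), by = w)
  d <- sqrt(rowSums((P2[idx[-1], ] - P2[idx[-length(idx)], ])^2))
  brute <- mean(d / diff(t[idx]))
  expect_equal(average_speed(t, P2, window = w), brute)
  expect_error(average_speed(1, matrix(0, 1, 3)))
})

test_that("ordinary least squares reports slope, intercept and r-squared", {
  r <- linear_fit_r2(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$slope, 2)
  expect_equal(r$r2, 1)
  ## hand-computed OLS on an arbitrary fixture
  x <- c(60, 120, 240); y <- c(1.2, 2.3, 4.8)
  n <- 3
  b <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  a <- mean(y) - b * mean(x)
  r2h <- 1 - sum((y - a - b * x)^2) / sum((y - mean(y))^2)
  r <- linear_fit_r2(x, y)
  expect_equal(r$slope, b)
  expect_equal(r$intercept, a)
  expect_equal(r$r2, r2h)
  ## near-zero slope with noise: r2 near 0
  set.seed(5)
  rn <- linear_fit_r2(1:50, rnorm(50))
  expect_lt(rn$r2, 0.2)
  expect_error(linear_fit_r2(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("the tiny fixture builds, mimics the seeding patterns and is deterministic", {
  cfg <- make_fixture("tiny", seed = 4)
  st <- build_scenario(cfg)
  ## pattern-1 filaments are radially aligned: mean alignment of the
  ## filament axis with the radial direction from the cell center > 0.8
  al <- vapply(Filter(function(f) !is.null(f) && f$alive && f$pattern == 1L,
                      st$net$filaments), function(fl) {
    a <- st$net$X[fl$nodes[1], ]; b <- st$net$X[fl$nodes[length(fl$nodes)], ]
    axis <- (b - a) / sqrt(sum((b - a)^2))
    rad <- (b - st$center) / sqrt(sum((b - st$center)^2))
    sum(axis * rad)
  }, numeric(1))
  expect_gt(mean(al), 0.8)
  ## pattern-2 filaments encircle the nucleus: midpoints near the PAL shell
  p2 <- Filter(function(f) !is.null(f) && f$alive && f$pattern == 2L,
               st$net$filaments)
  md <- vapply(p2, function(fl)
    sqrt(sum((colMeans(st$net$X[fl$nodes, ]) - st$center)^2)), numeric(1))
  expect_true(all(md > cfg$radius_nucleus & md < cfg$radius_nucleus + 1500))
  ## determinism of construction
  st2 <- build_scenario(cfg)
  expect_identical(st$net$X, st2$net$X)
  expect_identical(st$ecm$X, st2$ecm$X)
})

test_that("knockout flags honor their contracts", {
  ## Arp2/3 inhibition: zero nucleation events over a protrusive phase
  cfg <- make_fixture("tiny", seed = 6, protrusive = 3, retractile = 1,
                      severing = 1, inhibit_arp23 = TRUE)
  res <- run_scenario(cfg)
  expect_equal(res$counts$nucleation, 0L)
  ## alpha-actinin knockout: no alpha-actinin linker is ever placed
  cfg2 <- make_fixture("tiny", seed = 6, protrusive = 2, retractile = 2,
                       severing = 1, ko_alpha_actinin = TRUE)
  res2 <- run_scenario(cfg2)
  expect_false(any(res2$state$lk$kind == 3L))
  ## MT1-MMP knockout: no secretion, no degradation
  cfg3 <- make_fixture("tiny", seed = 6, protrusive = 3, retractile = 1,
                       severing = 1, ko_mt1mmp = TRUE)
  res3 <- run_scenario(cfg3)
  expect_equal(max(res3$state$field$phi3), 0)
  expect_equal(sum(!res3$state$ecm$seg$intact), 0L)
})

test_that("scenario configs round-trip through YAML", {
  cfg <- scenario_config(protrusive = 120, n_pattern1 = 10, n_pattern2 = 5,
                         seed = 9)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(protrusive = 120, n_pattern1 = 10, n_pattern2 = 5,
                        seed = 9), path)
  cfg2 <- read_scenario_config(path)
  expect_equal(cfg2$protrusive, cfg$protrusive)
  expect_equal(cfg2$n_pattern1, cfg$n_pattern1)
  expect_equal(cfg2$seed, cfg$seed)
  unlink(path)
})

test_that("snapshot writers produce parseable text artifacts", {
  cfg <- make_fixture("tiny", seed = 2)
  st <- build_scenario(cfg)
  td <- tempfile(); dir.create(td)
  fs <- filament_snapshot(st$net, file.path(td, "fil.csv"))
  back <- read.csv(file.path(td, "fil.csv"))
  expect_equal(nrow(back), nrow(filament_snapshot(st$net)))
  ecm_snapshot(st$ecm, file.path(td, "ecm.csv"))
  expect_true(file.exists(file.path(td, "ecm.csv")))
  write_vtk_mesh(st$cell$CI, file.path(td, "ci.vtk"),
                 scalars = rep(0, nrow(st$cell$CI$X)))
  head1 <- readLines(file.path(td, "ci.vtk"), n = 5)
  expect_match(head1[1], "vtk DataFile")
  expect_match(head1[4], "POLYDATA")
  write_vtk_lines(st$net$X, lapply(
    Filter(function(f) f$alive, st$net$filaments), function(f) f$nodes),
    file.path(td, "fil.vtk"))
  expect_true(file.exists(file.path(td, "fil.vtk")))
  unlink(td, recursive = TRUE)
})
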