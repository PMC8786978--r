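## Scenario configuration, the in-silico experiments (phase-duration
## sweeps, crosslinker/MT1-MMP knockouts, Arp2/3 inhibition, the
## stiffness-interface run), trajectory analysis, and the miniature
## fixtures used by the test-suite.

#' Scenario configuration
#'
#' @param protrusive,retractile,severing phase durations (s).  The base
#'   characterization runs use protrusive durations of 60/120/240 s with
#'   retractile and severing fixed at 60 and 20 s; the stiffness-interface
#'   run uses 300/60/20 s.
#' @param n_pattern1 initial radially aligned filaments (barbed ends at the
#'   cortex, pointed ends at the nucleus); 500 in the base case.
#' @param n_pattern2 initial perinuclear filaments encircling the nucleus;
#'   500 in the base case.
#' @param radius_cell,radius_nucleus cell geometry (nm).
#' @param subdivision icosphere level.
#' @param box ECM domain (nm).
#' @param pore_size target ECM pore size (nm).
#' @param ko_alpha_actinin,ko_filamin,ko_fascin,ko_mt1mmp,inhibit_arp23
#'   knockout/inhibition flags.
#' @param stiffness_interface logical: soft/stiff ECM interface scenario
#'   (cell placed 10 um from the interface; MT1-MMP secretion then scales
#'   with local ligand density, which the phi5 factor of the secretion term
#'   already provides).
#' @param seed RNG seed.
#' @param total_time simulated duration (s).
#' @param leading_edge_bias logical: seed the radial filament pattern
#'   within the leading-edge cone only (miniature-fixture default).
#' @param sample_interval trajectory sampling interval (s).
#' @param params parameter list.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(protrusive = 240, retractile = 60, severing = 20,
                            n_pattern1 = 500, n_pattern2 = 500,
                            radius_cell = 8000, radius_nucleus = 3500,
                            subdivision = 2,
                            box = c(45000, 30000, 20000), pore_size = 3000,
                            ko_alpha_actinin = FALSE, ko_filamin = FALSE,
                            ko_fascin = FALSE, ko_mt1mmp = FALSE,
                            inhibit_arp23 = FALSE,
                            stiffness_interface = FALSE,
                            leading_edge_bias = FALSE,
                            seed = 1L, total_time = 600,
                            sample_interval = 1,
                            params = invadosim_params()) {
  stopifnot(n_pattern1 >= 0, n_pattern2 >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "scenario_config"
  cfg
}

#' Read a scenario configuration from a YAML file
#'
#' Keys mirror the arguments of [scenario_config()].
#' @param path YAML file path.
#' @return a `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(scenario_config, y)
}

## ---------------------------------------------------------------------------
## Initial filament seeding

#' Seed the two initial filament patterns
#'
#' Pattern 1: radial filaments whose pointed ends sit just outside the
#' nuclear membrane and barbed ends just inside the actin cortex layer.
#' Pattern 2: filaments randomly distributed to encircle the nucleus
#' (tangent to a shell slightly outside the PAL).
#'
#' @param net `actin_network` to extend.
#' @param n1,n2 filament counts for the two patterns.
#' @param center cell center (nm).
#' @param radius_nucleus,radius_cortex shell radii (nm).
#' @param params parameter list.
#' @param cone optional `list(axis =, angle =)`: restrict pattern-1
#'   directions to the leading-edge cone (used by the miniature fixtures).
#' @return updated network.
#' @export
seed_filaments <- function(net, n1, n2, center, radius_nucleus, radius_cortex,
                           params = invadosim_params(), cone = NULL) {
  L0 <- params$actin$L0_init
  for (i in seq_len(n1)) {
    u <- random_direction()
    if (!is.null(cone)) {      # bias into the leading-edge cone
      while (sum(u * cone$axis) < cos(cone$angle)) u <- random_direction()
    }
    r_in <- radius_nucleus + 150
    r_out <- radius_cortex - 80   # barbed ends start inside the 100-nm
                                  # adhesion range of the cortex
    nseg <- max(2L, floor((r_out - r_in) / L0))
    rr <- r_in + (0:nseg) * L0
    rr <- rr[rr <= r_out]
    if (length(rr) < 3L) rr <- c(r_in, r_in + L0, r_in + 2 * L0)
    P <- t(center + outer(u, rr))        # pointed end inner, barbed outer
    net <- an_add_filament(net, P, L0 = rep(L0, nrow(P) - 1L),
                           state = S_GROWTH, pattern = 1L)
  }
  for (i in seq_len(n2)) {
    u <- random_direction()
    base <- center + u * (radius_nucleus + 200)
    t1 <- random_direction()
    t1 <- t1 - sum(t1 * u) * u           # tangent to the shell
    t1 <- t1 / sqrt(sum(t1 * t1))
    nseg <- 6L
    P <- t(base + outer(t1, (0:nseg) * L0) -
             outer(u, (0:nseg)^2 * L0^2 / (2 * (radius_nucleus + 200))))
    net <- an_add_filament(net, P, state = S_GROWTH, pattern = 2L)
  }
  net
}

#' Build a full simulation state for a scenario
#'
#' Generates the ECM network (pore-size targeted), places the spherical
#' five-layer cell at the domain center, seeds both filament patterns,
#' initializes the reaction-diffusion field (ECM concentration where fibers
#' exist) and clears fibers from the cell interior.
#'
#' @param cfg `scenario_config`.
#' @return an `invadosim_state`.
#' @export
build_scenario <- function(cfg) {
  set.seed(cfg$seed)
  p <- cfg$params
  p$membrane$radius_cell <- cfg$radius_cell
  p$membrane$radius_nucleus <- cfg$radius_nucleus
  center <- cfg$box / 2
  ecm <- generate_network(cfg$box, cfg$pore_size,
                          p$ecm$fiber_diameter,
                          seed = cfg$seed + 1000L, params = p)
  ## remove fiber segments overlapping the initial cell volume
  d1 <- row_norms(sweep(ecm$X[ecm$seg$n1, , drop = FALSE], 2L, center))
  d2 <- row_norms(sweep(ecm$X[ecm$seg$n2, , drop = FALSE], 2L, center))
  ecm$seg <- ecm$seg[pmin(d1, d2) > cfg$radius_cell, , drop = FALSE]
  keepn <- sort(unique(c(ecm$seg$n1, ecm$seg$n2)))
  ecm$junction <- ecm$junction[ecm$junction$n1 %in% keepn &
                               ecm$junction$n2 %in% keepn, , drop = FALSE]
  segkey <- paste(ecm$seg$n1, ecm$seg$n2)
  ecm$bend <- ecm$bend[paste(ecm$bend$n1, ecm$bend$n2) %in% segkey &
                       paste(ecm$bend$n2, ecm$bend$n3) %in% segkey, ,
                       drop = FALSE]
  if (isTRUE(cfg$stiffness_interface)) {
    ## stiffness interface 10 um ahead of the cell along +z: densify
    ## (stiffen) fibers beyond it by doubling the modulus
    ecm$E_interface_z <- center[3] + 1e4
    ecm$E_stiff_factor <- 2
  }
  cell <- build_spherical_cell(cfg$radius_cell, cfg$radius_nucleus,
                               cfg$subdivision, p)
  for (ly in names(cell)) cell[[ly]]$X <- sweep(cell[[ly]]$X, 2L, center, `+`)
  net <- actin_network()
  cone <- if (isTRUE(cfg$leading_edge_bias))
    list(axis = c(0, 0, 1), angle = p$linker$cone_angle) else NULL
  net <- seed_filaments(net, cfg$n_pattern1, cfg$n_pattern2, center,
                        cfg$radius_nucleus,
                        cfg$radius_cell - p$membrane$L_T0 - p$membrane$L_C0,
                        p, cone = cone)
  field <- rd_field(cfg$box, p, phi6_mask = fiber_mask(ecm, cfg$box, p))
  polarity <- c(0, 0, 1)
  simulation_state(cell, net, ecm, field, params = p,
                   schedule = phase_schedule(cfg$protrusive, cfg$retractile,
                                             cfg$severing),
                   polarity = polarity,
                   ko = list(alpha_actinin = cfg$ko_alpha_actinin,
                             filamin = cfg$ko_filamin,
                             fascin = cfg$ko_fascin,
                             mt1mmp = cfg$ko_mt1mmp,
                             arp23 = cfg$inhibit_arp23))
}

## logical voxel mask of fiber-occupied grid cells
fiber_mask <- function(ecm, box, params) {
  h <- params$rd$h
  dims <- pmax(2L, as.integer(ceiling(box / h)) + 1L)
  mask <- array(FALSE, dim = dims)
  act <- ecm$seg$intact
  mid <- (ecm$X[ecm$seg$n1[act], , drop = FALSE] +
          ecm$X[ecm$seg$n2[act], , drop = FALSE]) / 2
  pts <- rbind(ecm$X, mid)
  dmax <- matrix(rep(dims, each = nrow(pts)), ncol = 3L)
  ## mark all 8 voxel corners around every fiber point so trilinear
  ## interpolation at fiber material reads the full initial concentration
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    idx <- pmin(pmax(floor(pts / h) + 1L +
                       matrix(rep(c(dx, dy, dz), each = nrow(pts)), ncol = 3L),
                     1L), dmax)
    mask[idx] <- TRUE
  }
  mask
}

## ---------------------------------------------------------------------------
## Trajectory analysis

#' Invadopodium tip position
#'
#' The CI node with maximal projection on the polarity vector (ties broken
#' by the lowest node index).
#'
#' @param X_ci CI node positions.
#' @param polarity unit polarity vector.
#' @return list with `pos` (length-3) and `node` index.
#' @export
tip_position <- function(X_ci, polarity) {
  proj <- as.numeric(X_ci %*% polarity)
  i <- which.max(proj)   # which.max returns the first (lowest) index on ties
  list(pos = X_ci[i, ], node = i)
}

#' Window-averaged path speed of a trajectory
#'
#' Mean over consecutive windows of displacement magnitude over window
#' duration, mirroring a timelapse-imaging measurement (default window
#' 180 s = the 3-min imaging interval).
#'
#' @param times sample times (s), monotone.
#' @param pos k x 3 position matrix (nm).
#' @param window window length (s).
#' @return speed (nm/s).
#' @export
average_speed <- function(times, pos, window = 180) {
  stopifnot(length(times) >= 2L, all(diff(times) > 0))
  if (!is.matrix(pos)) pos <- matrix(pos, ncol = 1L)
  t0 <- times[1]
  breaks <- seq(t0, times[length(times)], by = window)
  if (length(breaks) < 2L) breaks <- c(t0, times[length(times)])
  idx <- vapply(breaks, function(b) which.min(abs(times - b)), integer(1))
  idx <- unique(idx)
  if (length(idx) < 2L) idx <- c(1L, length(times))
  d <- pos[idx[-1], , drop = FALSE] - pos[idx[-length(idx)], , drop = FALSE]
  dt <- times[idx[-1]] - times[idx[-length(idx)]]
  mean(sqrt(rowSums(d * d)) / dt)
}

#' Ordinary least squares with r-squared
#'
#' @param x,y numeric vectors (>= 3 points, nonzero x variance).
#' @return list with `slope`, `intercept`, `r2`.
#' @export
linear_fit_r2 <- function(x, y) {
  stopifnot(length(x) >= 3L, length(x) == length(y))
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) {
    if (ss_res < 1e-12) 1 else stop("degenerate regression: zero y variance")
  } else 1 - ss_res / ss_tot
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), r2 = r2)
}

#' Run a scenario
#'
#' Builds the state from the configuration and advances it for
#' `total_time`, recording the trajectory at each sampling interval: tip
#' position, nucleus centroid, traction force magnitude summed over the
#' tip cap (nN), intracellular (actin-side) force at the tip-cap cortex
#' nodes (nN), and the adhered-filament count.
#'
#' @param cfg `scenario_config`.
#' @return list with `trajectory` (data.frame), `state` (final), `events`,
#'   `counts`.
#' @export
run_scenario <- function(cfg) {
  st <- build_scenario(cfg)
  rec <- new.env(parent = emptyenv())
  rec$rows <- list()
  rec$t_last <- -Inf
  sampler <- function(s) {
    if (s$time - rec$t_last < cfg$sample_interval - 1e-9) return(invisible())
    rec$t_last <- s$time
    rec$rows[[length(rec$rows) + 1L]] <- trajectory_row(s)
    invisible()
  }
  st <- advance(st, cfg$total_time, on_sample = sampler)
  traj <- do.call(rbind, rec$rows)
  list(trajectory = traj, state = st, events = st$events, counts = st$counts)
}

trajectory_row <- function(st) {
  tp <- tip_position(st$cell$CI$X, st$polarity)
  proj <- as.numeric(st$cell$CI$X %*% st$polarity)
  ncap <- max(1L, ceiling(st$params$rd$tip_frac * nrow(st$cell$CI$X)))
  cap <- order(proj, decreasing = TRUE)[seq_len(ncap)]
  traction <- intracell <- 0
  if (!is.null(st$last_forces)) {
    traction <- sqrt(sum(colSums(
      st$last_forces$traction_I[cap, , drop = FALSE])^2)) / 1000   # nN
    capC <- cap   # CI and CC are index-paired
    intracell <- sqrt(sum(colSums(
      st$last_forces$actin_on_C[capC, , drop = FALSE])^2)) / 1000  # nN
  }
  adhered <- sum(vapply(st$net$filaments, function(fl)
    !is.null(fl) && fl$alive && fl$state == S_ADHESION, logical(1)))
  data.frame(time = st$time,
             tip_x = tp$pos[1], tip_y = tp$pos[2], tip_z = tp$pos[3],
             nuc_x = mean(st$cell$NMS$X[, 1]),
             nuc_y = mean(st$cell$NMS$X[, 2]),
             nuc_z = mean(st$cell$NMS$X[, 3]),
             traction_nN = traction, intracellular_nN = intracell,
             adhered_filaments = adhered)
}

## ---------------------------------------------------------------------------
## Miniature fixtures

#' Miniature simulation fixtures
#'
#' Reduced-scale study systems that exercise every module while running
#' full phase cycles in minutes of wall time: `tiny` uses 30 + 8 filaments
#' and an icosphere-level-1 cell (2.5 um) in a 9-um ECM patch with a
#' 1.5-um pore; `small` uses 40 + 20 filaments at level 2 in a 12-um
#' patch.  Both mimic the two seeding patterns of the full model, with the
#' radial pattern concentrated in the leading-edge cone (a miniature of
#' the invadopodium core), nucleation scaled to the miniature filament
#' count, and the MMP cascade accelerated so short protrusive phases
#' degrade nearby matrix as long full-scale phases do (see the methods
#' vignette).
#'
#' @param scale `"tiny"` or `"small"`.
#' @param seed RNG seed.
#' @param protrusive,retractile,severing phase durations (s) of the
#'   miniature cycle.
#' @param ... overrides passed to [scenario_config()].
#' @return a `scenario_config`.
#' @export
make_fixture <- function(scale = c("tiny", "small"), seed = 1L,
                         protrusive = 12, retractile = 6, severing = 2,
                         ...) {
  scale <- match.arg(scale)
  base <- if (scale == "tiny") {
    ## nucleation scaled with the miniature filament count (k_n is the
    ## cell-wide rate of the full 500-filament model)
    list(n_pattern1 = 30, n_pattern2 = 8, leading_edge_bias = TRUE,
         radius_cell = 2500, radius_nucleus = 1100, subdivision = 1,
         box = c(9000, 9000, 9000), pore_size = 1500,
         total_time = protrusive + retractile + severing,
         ## miniature-cycle chemistry: faster secretion/degradation so the
         ## short protrusive phases degrade matrix as the long full-scale
         ## phases do
         params = invadosim_params(actin = list(k_n = 10),
                                   rd = list(alpha_phi2 = 2, alpha_phi3 = 4,
                                             k_on_34 = 0.2, k_off_4 = 1,
                                             k_deg = 40)))
  } else {
    list(n_pattern1 = 40, n_pattern2 = 20, leading_edge_bias = TRUE,
         radius_cell = 4000, radius_nucleus = 1800, subdivision = 2,
         box = c(12000, 12000, 12000), pore_size = 2500,
         total_time = protrusive + retractile + severing,
         params = invadosim_params(actin = list(k_n = 12),
                                   rd = list(alpha_phi2 = 2, alpha_phi3 = 4,
                                             k_on_34 = 0.2, k_off_4 = 1,
                                             k_deg = 40)))
  }
  args <- modifyList(c(base, list(protrusive = protrusive,
                                  retractile = retractile,
                                  severing = severing, seed = seed)),
                     list(...))
  do.call(scenario_config, args)
}
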