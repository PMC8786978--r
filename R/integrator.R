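## Coupled explicit integration of the five cell layers, the actin network
## and the ECM fiber network under overdamped Kelvin-Voigt dynamics: nodal
## velocities are the explicit quotients (total force plus the lagged
## dissipated force of the previous step, divided by the summed drag
## coefficients), advanced inside an adaptive step-doubling controller.
## Discrete chemistry and topology events (growth, nucleation, capping,
## adhesion, linker turnover, bond kinetics, reaction-diffusion, fiber
## degradation) fire at a fixed control interval; the phase controller
## cycles protrusive -> retractile -> severing.

#' Phase schedule
#'
#' @param protrusive,retractile,severing phase durations (s), all > 0.
#' @return a `phase_schedule`.
#' @export
phase_schedule <- function(protrusive = 240, retractile = 60, severing = 20) {
  stopifnot(protrusive > 0, retractile > 0, severing > 0)
  structure(list(durations = c(protrusive = protrusive,
                               retractile = retractile,
                               severing = severing)),
            class = "phase_schedule")
}

#' Phase at a given time
#'
#' @param schedule a `phase_schedule`.
#' @param t time (s).
#' @return list with `phase` (string), `cycle` (0-based count of completed
#'   cycles) and `t_in_cycle`.
#' @export
phase_at <- function(schedule, t) {
  d <- schedule$durations
  cl <- sum(d)
  cyc <- floor(t / cl + 1e-12)
  tm <- t - cyc * cl
  ph <- if (tm < d[1]) "protrusive" else if (tm < d[1] + d[2]) "retractile"
        else "severing"
  list(phase = ph, cycle = cyc, t_in_cycle = tm)
}

## ---------------------------------------------------------------------------
## Simulation state

#' Assemble a simulation state
#'
#' Bundles the five-layer cell, actin network, ECM, linker and
#' focal-complex tables and the reaction-diffusion field, with the
#' bookkeeping the integrator needs (previous-step velocities for the
#' lagged dissipated-force terms, zero at birth; drag denominators; event
#' log).
#'
#' @param cell from [build_spherical_cell()] (already translated into the
#'   ECM box frame).
#' @param net `actin_network`.
#' @param ecm `ecm_network` or NULL.
#' @param field `rd_field` or NULL.
#' @param params parameter list.
#' @param schedule `phase_schedule`.
#' @param polarity unit migration-direction vector.
#' @param ko named list of knockout flags (`alpha_actinin`, `filamin`,
#'   `fascin`, `mt1mmp`, `arp23`).
#' @return an `invadosim_state`.
#' @export
simulation_state <- function(cell, net, ecm = NULL, field = NULL,
                             params = invadosim_params(),
                             schedule = phase_schedule(),
                             polarity = c(0, 0, 1),
                             ko = list()) {
  ko <- modifyList(list(alpha_actinin = FALSE, filamin = FALSE,
                        fascin = FALSE, mt1mmp = FALSE, arp23 = FALSE), ko)
  st <- list(cell = cell, net = net, ecm = ecm, field = field,
             lk = linker_table(), fc = focal_complex_table(),
             params = params, schedule = schedule,
             polarity = polarity / sqrt(sum(polarity^2)),
             center = colMeans(cell$CI$X),
             time = 0, dt = params$integrator$dt_init,
             ko = ko,
             Vprev = list(I = zmat(cell$CI$X), T = zmat(cell$CT$X),
                          C = zmat(cell$CC$X), A = zmat(net$X),
                          PAL = zmat(cell$PAL$X), NMS = zmat(cell$NMS$X),
                          E = if (is.null(ecm)) NULL else zmat(ecm$X)),
             events = data.frame(time = numeric(0), event = character(0),
                                 detail = character(0)),
             counts = list(nucleation = 0L, capping = 0L, severing = 0L,
                           adhesion = 0L, rupture = 0L, degenerate = 0L))
  st$net$tables <- an_build_tables(net, params)
  st$attach <- build_attach(st$net)
  st$geom <- precompute_geometry(st)
  st$grow <- build_growth_rates(st, phase_at(schedule, 0)$phase)
  structure(st, class = "invadosim_state")
}

## vectorized tables of barbed-end adhesions (S = 3) and ratchet pushers
## (S = 5); rebuilt at every discrete-event boundary
build_attach <- function(net) {
  ab <- ac <- rb <- rc <- integer(0); aL0 <- numeric(0); apl <- logical(0)
  for (f in seq_along(net$filaments)) {
    fl <- net$filaments[[f]]
    if (is.null(fl) || !fl$alive) next
    if (fl$state == S_ADHESION && !is.null(fl$adhesion)) {
      ab <- c(ab, fl$nodes[length(fl$nodes)])
      ac <- c(ac, fl$adhesion$cc)
      aL0 <- c(aL0, fl$adhesion$L0)
      apl <- c(apl, isTRUE(fl$adhesion$plane))
    } else if (fl$state == S_RATCHET && !is.null(fl$ratchet_cc)) {
      rb <- c(rb, fl$nodes[length(fl$nodes)])
      rc <- c(rc, fl$ratchet_cc)
    }
  }
  list(adh_b = ab, adh_c = ac, adh_L0 = aL0, adh_plane = apl,
       rat_b = rb, rat_c = rc)
}

zmat <- function(X) matrix(0, nrow(X), 3L)

## adjacency-derived drag denominators and neighbor edge lists
precompute_geometry <- function(st) {
  dg <- st$params$drag
  layer_geom <- function(mesh, extra) {
    deg <- tabulate(c(mesh$edges[, 1], mesh$edges[, 2]), nbins = nrow(mesh$X))
    list(edges = mesh$edges, denom = deg * dg$C_pair + extra + dg$C0,
         a1 = acc_make(mesh$edges[, 1], nrow(mesh$X)),
         a2 = acc_make(mesh$edges[, 2], nrow(mesh$X)))
  }
  g <- list(
    I = layer_geom(st$cell$CI, dg$C1_T),
    T = layer_geom(st$cell$CT, dg$C1_T + dg$C1_C),
    C = layer_geom(st$cell$CC, dg$C1_C),
    PAL = layer_geom(st$cell$PAL, 0),
    NMS = layer_geom(st$cell$NMS, 0)
  )
  g$A <- actin_geom(st$net, st$params)
  if (!is.null(st$ecm)) g$E <- ecm_geom(st$ecm, st$params)
  g
}

actin_geom <- function(net, params) {
  dg <- params$drag
  tb <- an_tables(net, params)
  n <- nrow(net$X)
  deg <- tabulate(c(tb$seg$n1, tb$seg$n2), nbins = n)
  arp <- tabulate(c(tb$branch$mj, tb$branch$d1), nbins = n)
  n <- nrow(net$X)
  list(edges = cbind(tb$seg$n1, tb$seg$n2),
       arp_edges = cbind(tb$branch$mj, tb$branch$d1),
       denom = pmax(deg, 1L) * dg$C_pair_A + arp * dg$C_arp + dg$C0_A,
       a1 = tb$seg$a1, a2 = tb$seg$a2,
       arp_a1 = acc_make(tb$branch$mj, n), arp_a2 = acc_make(tb$branch$d1, n))
}

ecm_geom <- function(ecm, params) {
  pe <- params$ecm
  segE <- ecm$seg
  degE <- tabulate(c(segE$n1, segE$n2), nbins = nrow(ecm$X))
  mech <- ecm_mech(ecm)
  list(edges = cbind(segE$n1, segE$n2),
       denom = degE * pe$C_pair + pe$C0,
       a1 = acc_make(segE$n1, nrow(ecm$X)), a2 = acc_make(segE$n2, nrow(ecm$X)),
       mech = mech,
       live_nodes = sort(unique(c(segE$n1[segE$intact], segE$n2[segE$intact]))))
}

## sum of previous-step neighbor velocities weighted by the pair drags,
## using the precomputed edge accumulators of a layer's geometry
lag_term <- function(V, geom, C_pair, a1 = geom$a1, a2 = geom$a2) {
  F <- zmat(V)
  if (!is.null(a1)) {
    F <- acc_add(F, a1, C_pair * V[geom$edges[, 2], , drop = FALSE])
    F <- acc_add(F, a2, C_pair * V[geom$edges[, 1], , drop = FALSE])
  }
  F
}

## ---------------------------------------------------------------------------
## Force assembly

#' Assemble all nodal forces
#'
#' Fixed evaluation order: membranes, actin, linkers/motors,
#' adhesion/exclusion, ratchet.  Returns one force matrix per module plus
#' the diagnostic per-node traction (focal-complex force on CI) and
#' cortex-side actin force (adhesion + ratchet on CC).
#'
#' @param st `invadosim_state`.
#' @param phase current phase string.
#' @return list of force matrices `I`, `T`, `C`, `A`, `PAL`, `NMS`, `E`,
#'   and diagnostics `traction_I`, `actin_on_C`.
#' @keywords internal
assemble_forces <- function(st, phase = phase_at(st$schedule, st$time)$phase) {
  p <- st$params
  cell <- st$cell; net <- st$net
  XI <- cell$CI$X; XC <- cell$CC$X
  tc <- transduce_and_cortex_forces(cell, params = p)
  FI <- membrane_elastic_forces(cell$CI) + tc$F_I
  FT <- tc$F_T
  FC_ <- tc$F_C
  ## nuclear envelope: in-plane elasticity + PAL<->NMS vertical links
  nn <- vertical_link_forces(cell$PAL$X, cell$NMS$X,
                             p$membrane$kappa_NN, p$membrane$L_NN0)
  FPAL <- membrane_elastic_forces(cell$PAL) + nn$FA
  FNMS <- membrane_elastic_forces(cell$NMS) + nn$FB
  ## actin internal elasticity + branches
  FA <- actin_elastic_forces(net, params = p)
  Fbr <- branch_forces(net, params = p)
  st$counts$degenerate <- st$counts$degenerate + attr(Fbr, "degenerate")
  FA <- FA + Fbr
  ## crosslinkers and motors
  lf <- linker_forces(st$lk, net$X, cell$PAL$X,
                      motors_on = identical(phase, "retractile"))
  FA <- FA + lf$F_actin
  if (!is.null(lf$F_nuc)) FPAL <- FPAL + lf$F_nuc
  ## barbed-end adhesions to the cortex and ratchet forces (vectorized over
  ## the attachment tables rebuilt at each discrete-event boundary)
  actin_on_C <- zmat(XC)
  normalsI <- vertex_normals(cell$CI)
  normalsC <- vertex_normals(cell$CC)
  at <- st$attach
  if (length(at$adh_b)) {
    pl <- at$adh_plane
    Fsp <- matrix(0, length(at$adh_b), 3L)
    if (any(pl)) {
      nh <- normalsC[at$adh_c[pl], , drop = FALSE]
      g <- rowSums((net$X[at$adh_b[pl], , drop = FALSE] -
                    XC[at$adh_c[pl], , drop = FALSE]) * nh)
      Fsp[pl, ] <- -nh * (p$actin$kappa_adh * (g - at$adh_L0[pl]))
    }
    if (any(!pl)) {
      d <- XC[at$adh_c[!pl], , drop = FALSE] -
        net$X[at$adh_b[!pl], , drop = FALSE]
      L <- pmax(row_norms(d), .Machine$double.eps)
      Fsp[!pl, ] <- d * (p$actin$kappa_adh * (L - at$adh_L0[!pl]) / L)
    }
    FA <- add_at(FA, at$adh_b, Fsp)
    FC_ <- add_at(FC_, at$adh_c, -Fsp)
    actin_on_C <- add_at(actin_on_C, at$adh_c, -Fsp)
  }
  if (length(at$rat_b) && identical(phase, "protrusive")) {
    nh <- normalsI[at$rat_c, , drop = FALSE]
    speed <- abs(rowSums(nh * (st$Vprev$A[at$rat_b, , drop = FALSE] -
                               st$Vprev$C[at$rat_c, , drop = FALSE])))
    mag <- ifelse(speed == 0, p$actin$F_ratchet_max,
                  p$actin$F_p * log(p$actin$v0_poly / pmax(speed, 1e-12)))
    mag <- pmin(pmax(mag, 0), p$actin$F_ratchet_max)
    Fr <- nh * mag
    FC_ <- add_at(FC_, at$rat_c, Fr)
    actin_on_C <- add_at(actin_on_C, at$rat_c, Fr)
  }
  ## focal complexes (CI <-> ECM) and ECM mechanics
  FE <- NULL
  traction_I <- zmat(XI)
  if (!is.null(st$ecm)) {
    FE <- fiber_forces_mech(st$geom$E$mech, st$ecm$X)
    if (nrow(st$fc)) {
      d <- st$ecm$X[st$fc$en, , drop = FALSE] - XI[st$fc$ci, , drop = FALSE]
      dist <- row_norms(d)
      ## bonds span from the membrane to the fiber surface
      Lb <- pmax(dist - st$ecm$fiber_diameter / 2, 0.1)
      ok <- dist > 0 & st$fc$n_b > 0
      if (any(ok)) {
        coef <- st$fc$n_b * p$adhesion$kappa_LR *
          (Lb - p$adhesion$lambda) / pmax(dist, .Machine$double.eps)
        Fm <- d * (coef * ok)
        FI <- add_at(FI, st$fc$ci, Fm)
        traction_I <- add_at(traction_I, st$fc$ci, Fm)
        FE <- add_at(FE, st$fc$en, -Fm)
      }
    }
    ## exclusion: intact fiber nodes out of the cell interior (degraded
    ## segments no longer block the membrane)
    livef <- st$geom$E$live_nodes
    near <- livef[row_norms(sweep(st$ecm$X[livef, , drop = FALSE], 2L,
                                  st$center)) <
                    max(row_norms(sweep(XI, 2L, st$center))) + 2000]
    if (length(near)) {
      ex <- volume_exclusion_forces(st$ecm$X[near, , drop = FALSE],
                                    XI, normalsI, side = "inside",
                                    kappa = p$ecm$kappa_excl)
      FE <- add_at(FE, near, ex$F_pts)
      FI <- FI + ex$F_mesh
    }
  }
  ## exclusion: actin inside the cortex, outside the nuclear surface
  if (nrow(net$X)) {
    exC <- volume_exclusion_forces(net$X, XC, normalsC, side = "outside",
                                   kappa = p$ecm$kappa_excl)
    FA <- FA + exC$F_pts
    FC_ <- FC_ + exC$F_mesh
    normalsN <- vertex_normals(cell$NMS)
    exN <- volume_exclusion_forces(net$X, cell$NMS$X, normalsN,
                                   side = "inside", kappa = p$ecm$kappa_excl)
    FA <- FA + exN$F_pts
    FNMS <- FNMS + exN$F_mesh
  }
  list(I = FI, T = FT, C = FC_, A = FA, PAL = FPAL, NMS = FNMS, E = FE,
       traction_I = traction_I, actin_on_C = actin_on_C)
}

## continuous rest-length evolution (barbed growth, pointed shrinkage)
## applied inside each integration sub-step so the polymerization forcing
## is smooth rather than impulsive; rates are set at control boundaries
apply_growth <- function(st, dt) {
  gr <- st$grow
  if (is.null(gr) || !length(gr$rows)) return(st)
  tb <- st$net$tables
  ## floor keeps the 1/L0 effective stiffness bounded; fully consumed
  ## segments are retired at the next control boundary
  L0 <- pmax(tb$seg$L0[gr$rows] + gr$rates * dt,
             st$params$actin$L_seg_min / 2)
  tb$seg$L0[gr$rows] <- L0
  pa <- st$params$actin
  tb$seg$kappa[gr$rows] <- actin_cross_section(pa$r_A) * pa$E_A / L0
  st$net$tables <- tb
  st
}

## growth-rate table for the coming control interval
build_growth_rates <- function(st, phase) {
  p <- st$params
  tb <- an_tables(st$net, p)
  if (!length(tb$seg$fil)) return(list(rows = integer(0), rates = numeric(0)))
  grow_phase <- identical(phase, "protrusive")
  load <- row_norms(if (!is.null(st$last_forces)) st$last_forces$actin_on_C
                    else zmat(st$cell$CC$X))
  nF <- tabulate(unlist(lapply(st$net$filaments, function(fl) {
    if (is.null(fl) || !fl$alive) return(integer(0))
    if (fl$state == S_ADHESION && !is.null(fl$adhesion)) fl$adhesion$cc
    else if (fl$state == S_RATCHET && !is.null(fl$ratchet_cc)) fl$ratchet_cc
    else integer(0)
  })), nbins = nrow(st$cell$CC$X))
  rows <- integer(0); rates <- numeric(0)
  for (f in seq_along(st$net$filaments)) {
    fl <- st$net$filaments[[f]]
    if (is.null(fl) || !fl$alive) next
    frows <- which(tb$seg$fil == f)
    if (!length(frows)) next
    ## pointed-end depolymerization
    rows <- c(rows, frows[1]); rates <- c(rates, -p$actin$v_s)
    if (grow_phase && !fl$capped) {
      vg <- p$actin$v_g_free
      j <- if (fl$state == S_ADHESION && !is.null(fl$adhesion)) fl$adhesion$cc
           else if (fl$state == S_RATCHET && !is.null(fl$ratchet_cc))
             fl$ratchet_cc else NA_integer_
      if (!is.na(j) && nF[j] >= 1L)
        vg <- load_dependent_growth_rate(load[j], nF[j],
                                         p$actin$v0_poly, p$actin$f0)
      last <- frows[length(frows)]
      if (last == rows[length(rows)])   # 1-segment filament: net rate
        rates[length(rates)] <- rates[length(rates)] + vg
      else { rows <- c(rows, last); rates <- c(rates, vg) }
    }
  }
  list(rows = rows, rates = rates)
}

## one explicit update of all positions; returns new position list and the
## velocities used (which become Vprev)
explicit_update <- function(st, dt, phase) {
  st <- apply_growth(st, dt)
  dg <- st$params$drag
  g <- st$geom
  F <- assemble_forces(st, phase)
  vel <- function(Fm, Vl, geom, C_pair, extra_lag) {
    (Fm + lag_term(Vl, geom, C_pair) + extra_lag) / geom$denom
  }
  VI <- vel(F$I, st$Vprev$I, g$I, dg$C_pair, dg$C1_T * st$Vprev$T)
  VT <- vel(F$T, st$Vprev$T, g$T, dg$C_pair,
            dg$C1_T * st$Vprev$I + dg$C1_C * st$Vprev$C)
  VC <- vel(F$C, st$Vprev$C, g$C, dg$C_pair, dg$C1_C * st$Vprev$T)
  VA <- if (nrow(st$net$X)) {
    arp_lag <- zmat(st$Vprev$A)
    if (!is.null(g$A$arp_a1)) {
      arp_lag <- acc_add(arp_lag, g$A$arp_a1,
                         dg$C_arp * st$Vprev$A[g$A$arp_edges[, 2], ,
                                               drop = FALSE])
      arp_lag <- acc_add(arp_lag, g$A$arp_a2,
                         dg$C_arp * st$Vprev$A[g$A$arp_edges[, 1], ,
                                               drop = FALSE])
    }
    (F$A + lag_term(st$Vprev$A, g$A, dg$C_pair_A) + arp_lag) / g$A$denom
  } else st$Vprev$A
  VPAL <- vel(F$PAL, st$Vprev$PAL, g$PAL, dg$C_pair, 0)
  VNMS <- vel(F$NMS, st$Vprev$NMS, g$NMS, dg$C_pair, 0)
  st$cell$CI$X <- st$cell$CI$X + dt * VI
  st$cell$CT$X <- st$cell$CT$X + dt * VT
  st$cell$CC$X <- st$cell$CC$X + dt * VC
  if (nrow(st$net$X)) st$net$X <- st$net$X + dt * VA
  st$cell$PAL$X <- st$cell$PAL$X + dt * VPAL
  st$cell$NMS$X <- st$cell$NMS$X + dt * VNMS
  if (!is.null(st$ecm)) {
    VE <- (F$E + lag_term(st$Vprev$E, st$geom$E, st$params$ecm$C_pair)) /
      st$geom$E$denom
    st$ecm$X <- st$ecm$X + dt * VE
    st$Vprev$E <- VE
  }
  st$Vprev$I <- VI; st$Vprev$T <- VT; st$Vprev$C <- VC
  st$Vprev$A <- VA; st$Vprev$PAL <- VPAL; st$Vprev$NMS <- VNMS
  st$last_forces <- F[c("traction_I", "actin_on_C")]
  st
}

all_positions <- function(st) {
  rbind(st$cell$CI$X, st$cell$CT$X, st$cell$CC$X, st$net$X,
        st$cell$PAL$X, st$cell$NMS$X,
        if (!is.null(st$ecm)) st$ecm$X)
}

#' Advance the mechanical state by one adaptive step
#'
#' Takes one explicit step of size `dt_try` and two half steps from the
#' same state; accepts the half-step result when the maximum nodal position
#' discrepancy, relative to the 10-um cell length scale, is below the
#' integrator tolerance, otherwise halves the step and retries.  On
#' acceptance the next trial step grows by the configured factor.
#'
#' @param st `invadosim_state`.
#' @param dt_try trial step (s); defaults to the state's current step.
#' @return updated state (fields `time`, `dt`, positions, `Vprev`).
#' @export
step <- function(st, dt_try = st$dt) {
  ig <- st$params$integrator
  phase <- phase_at(st$schedule, st$time)$phase
  L_ref <- 1e4   # nm; error measured relative to the cell scale
  dt <- dt_try
  repeat {
    if (dt < ig$dt_min)
      stop(sprintf("time step underflow (dt = %.2e s) at t = %.3f s",
                   dt, st$time))
    full <- explicit_update(st, dt, phase)
    half <- explicit_update(st, dt / 2, phase)
    half <- explicit_update(half, dt / 2, phase)
    err <- max(abs(all_positions(full) - all_positions(half))) / L_ref
    if (is.finite(err) && err < ig$tol) {
      half$time <- st$time + dt
      half$dt <- min(dt * ig$grow, ig$dt_max)
      return(half)
    }
    dt <- dt / 2
  }
}

## ---------------------------------------------------------------------------
## Discrete events (control interval) and phase transitions

log_event <- function(st, event, detail = "") {
  st$events <- rbind(st$events,
                     data.frame(time = st$time, event = event,
                                detail = detail))
  st
}

#' Apply phase-boundary events
#'
#' On protrusive to retractile: all tip filaments are force-capped, myosin
#' and alpha-actinin activate, ratchet forces and tip secretion switch off.
#' On retractile to severing: buckled filaments are severed into 300-nm
#' pieces.  On severing to protrusive: capped ends uncap, motors
#' deactivate, secretion re-enables, cycle count increments.
#'
#' @param st `invadosim_state`.
#' @param old_phase,new_phase phase strings around the boundary.
#' @return updated state.
#' @export
advance_phase <- function(st, old_phase, new_phase) {
  if (identical(old_phase, new_phase)) return(st)
  if (new_phase == "retractile") {
    ## force-cap filaments at the invadopodium tip
    proj <- as.numeric(st$cell$CI$X %*% st$polarity)
    zcap <- stats::quantile(proj, 1 - st$params$rd$tip_frac)
    for (f in seq_along(st$net$filaments)) {
      fl <- st$net$filaments[[f]]
      if (is.null(fl) || !fl$alive) next
      barbed <- st$net$X[fl$nodes[length(fl$nodes)], ]
      if (sum(barbed * st$polarity) >= zcap - 500) {
        fl$state <- S_CAPPED; fl$capped <- TRUE; fl$adhesion <- NULL
        st$net$filaments[[f]] <- fl
        st$counts$capping <- st$counts$capping + 1L
      }
    }
    st <- log_event(st, "phase", "protrusive->retractile")
  } else if (new_phase == "severing") {
    nf <- length(st$net$filaments)
    for (f in seq_len(nf)) {
      if (filament_buckled(st$net, f, st$params)) {
        st$net <- sever_filament(st$net, f, st$params)
        st$counts$severing <- st$counts$severing + 1L
      }
    }
    st <- log_event(st, "phase", "retractile->severing")
  } else if (new_phase == "protrusive") {
    for (f in seq_along(st$net$filaments)) {
      fl <- st$net$filaments[[f]]
      if (is.null(fl) || !fl$alive || !fl$capped) next
      fl$state <- S_UNCAPPED; fl$capped <- FALSE
      st$net$filaments[[f]] <- fl
    }
    st <- log_event(st, "phase", "severing->protrusive")
  }
  st$net$tables <- an_build_tables(st$net, st$params)
  st$attach <- build_attach(st$net)
  st$geom$A <- actin_geom(st$net, st$params)
  st$Vprev$A <- pad_rows(st$Vprev$A, nrow(st$net$X))
  st
}

pad_rows <- function(M, n) {
  if (nrow(M) >= n) M[seq_len(n), , drop = FALSE]
  else rbind(M, matrix(0, n - nrow(M), 3L))
}

#' Run the discrete-event control update
#'
#' Fires once per control interval: filament lifecycle transitions and
#' capping, rest-length growth/shrinkage with the load-dependent barbed
#' rate, Arp2/3 nucleation (cell-wide Poisson, suppressed by Arp2/3
#' inhibition), crosslinker placement/turnover, myosin sliding, focal
#' complex opening and Bell kinetics, reaction-diffusion sub-stepping and
#' fiber degradation.
#'
#' @param st `invadosim_state`.
#' @param dt control interval actually elapsed (s).
#' @return updated state.
#' @export
control_update <- function(st, dt) {
  p <- st$params
  phase <- phase_at(st$schedule, st$time)$phase
  XC <- st$cell$CC$X
  ## lifecycle transitions
  nC <- vertex_normals(st$cell$CC)
  for (f in seq_along(st$net$filaments)) {
    fl <- st$net$filaments[[f]]
    if (is.null(fl) || !fl$alive) next
    old <- fl$state
    st$net <- state_transition(st$net, f, XC, phase, dt, params = p,
                               normals_cc = nC)
    newS <- st$net$filaments[[f]]$state
    if (newS == S_ADHESION && old != S_ADHESION)
      st$counts$adhesion <- st$counts$adhesion + 1L
    if (newS == S_RATCHET && old == S_ADHESION)
      st$counts$rupture <- st$counts$rupture + 1L
    if (newS == S_CAPPED && old != S_CAPPED)
      st$counts$capping <- st$counts$capping + 1L
  }
  ## rest-length bookkeeping: the continuous growth applied inside the
  ## integration sub-steps is synced back into the filament records, then
  ## segments are split/merged/removed
  tbs <- st$net$tables$seg
  if (!is.null(tbs) && length(tbs$fil)) {
    for (f in unique(tbs$fil))
      st$net$filaments[[f]]$L0 <- tbs$L0[tbs$fil == f]
  }
  for (f in seq_along(st$net$filaments))
    st$net <- an_normalize_segments(st$net, f, p)
  grow_phase <- identical(phase, "protrusive")
  ## nucleation: cell-wide Poisson over eligible leading-edge segments
  if (!isTRUE(st$ko$arp23) && grow_phase) {
    n_events <- stats::rpois(1, p$actin$k_n * dt)
    if (n_events > 0) {
      seg <- collect_segments(st$net)
      if (nrow(seg)) {
        mid <- (st$net$X[seg$n1, , drop = FALSE] +
                st$net$X[seg$n2, , drop = FALSE]) / 2
        relv <- sweep(mid, 2L, st$center)
        elig <- which(safe_acos(relv %*% st$polarity /
                                pmax(row_norms(relv), 1e-9)) <
                        p$linker$cone_angle)
        if (length(elig)) {
          pick <- sample(rep(elig, 2L), min(n_events, length(elig)))
          for (s in pick) {
            fl <- st$net$filaments[[seg$fil[s]]]
            jseg <- match(seg$n1[s], fl$nodes)
            st$net <- nucleate_daughter(st$net, seg$fil[s], jseg, params = p)
            st$counts$nucleation <- st$counts$nucleation + 1L
          }
        }
      }
    }
  }
  ## crosslinkers, motors, sliding (binding sweeps at the 1-s cadence)
  if (is.null(st$last_bind) ||
      st$time - st$last_bind >= p$linker$bind_interval - 1e-9) {
    st$lk <- place_and_turnover(st$lk, st$net, st$cell$PAL$X, st$polarity,
                                st$center, st$time, phase,
                                ko = st$ko, params = p)
    st$last_bind <- st$time
  }
  if (identical(phase, "retractile") && nrow(st$lk)) {
    lf <- linker_forces(st$lk, st$net$X, st$cell$PAL$X, motors_on = TRUE)
    st$lk$F_prev <- pmax(lf$tension, 0)
    st$lk <- advance_sliding(st$lk, st$net, dt, p)
  }
  ## focal complexes
  if (!is.null(st$ecm)) {
    st$fc <- update_focal_complexes(st$fc, st$cell$CI$X, st$ecm, p)
    if (nrow(st$fc)) {
      Lb <- pmax(row_norms(st$ecm$X[st$fc$en, , drop = FALSE] -
                           st$cell$CI$X[st$fc$ci, , drop = FALSE]) -
                   st$ecm$fiber_diameter / 2, 0.1)
      st$fc$n_b <- bond_kinetics_step(st$fc$n_b, Lb, dt, p)
    }
  }
  ## reaction-diffusion and degradation
  if (!is.null(st$field)) {
    tips <- tip_source_nodes(st$cell$CI$X, st$polarity, st$field, p)
    st$field <- rd_step(st$field, dt, phase, tips, p,
                        mt1mmp_ko = isTRUE(st$ko$mt1mmp))
    if (!is.null(st$ecm))
      st$ecm <- degrade_segments(st$ecm, st$field, p)
  }
  ## refresh cached topology-derived quantities
  st$net$tables <- an_build_tables(st$net, p)
  st$attach <- build_attach(st$net)
  st$geom$A <- actin_geom(st$net, p)
  st$Vprev$A <- pad_rows(st$Vprev$A, nrow(st$net$X))
  if (!is.null(st$ecm)) st$geom$E <- ecm_geom(st$ecm, p)
  st$grow <- build_growth_rates(st, phase)
  st
}

#' Advance the full simulation
#'
#' Runs adaptive mechanical steps between control-interval boundaries,
#' firing the discrete-event update at each boundary and phase-transition
#' events whenever a boundary crosses a phase edge.
#'
#' @param st `invadosim_state`.
#' @param duration simulated time to advance (s).
#' @param on_sample optional callback `function(st)` invoked at each control
#'   boundary (used by the trajectory recorder).
#' @return updated state.
#' @export
advance <- function(st, duration, on_sample = NULL) {
  ctrl <- st$params$integrator$control_interval
  t_end <- st$time + duration
  while (st$time < t_end - 1e-9) {
    t_ctrl <- min(st$time + ctrl, t_end)
    old_phase <- phase_at(st$schedule, st$time)$phase
    while (st$time < t_ctrl - 1e-9) {
      rem <- t_ctrl - st$time
      if (rem < 2 * st$params$integrator$dt_min) { st$time <- t_ctrl; break }
      st <- step(st, min(st$dt, rem))
    }
    new_phase <- phase_at(st$schedule, st$time)$phase
    if (!identical(old_phase, new_phase))
      st <- advance_phase(st, old_phase, new_phase)
    st <- control_update(st, ctrl)
    ## warm-start the lagged velocities against the post-event forces so
    ## the step-size controller does not pay a first-order transient
    st <- explicit_update(st, 0, new_phase)
    if (!is.null(on_sample)) on_sample(st)
  }
  st
}
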