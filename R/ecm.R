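## Discrete collagen type 1 fiber network: seeded generation to a target
## pore size, stretch/bend/junction mechanics, volume exclusion, chemical
## degradation, and the volumetric stretch test that measures the network
## bulk modulus.

#' Generate a collagen fiber network
#'
#' Straight fibers with random orientations are seeded sequentially: the
#' first at a uniform random position, each subsequent fiber nucleated
#' through an anchor point within one fiber diameter of a randomly chosen
#' node of the existing network (mimicking fibril bundling during collagen
#' polymerization and guaranteeing a connected network).  Fibers span the
#' box (clipped at the faces) and are discretized into ~0.5 um line
#' elements; junction springs connect node pairs of different fibers closer
#' than the fiber diameter.  The fiber count is iterated until the measured
#' mean pore size (mean nearest-void diameter on a sampling grid) is within
#' `pore_tol` of the target.  Deterministic for a given seed.
#'
#' @param box box dimensions (length-3, nm).
#' @param pore_size target mean pore size (nm).
#' @param fiber_diameter collagen fiber diameter (nm).
#' @param seed integer RNG seed.
#' @param params parameter list.
#' @return an `ecm_network`: node matrix `X`, segment table `seg`
#'   (n1, n2, L0, fiber, intact), bend-triple table, junction table,
#'   `box`, `pore_measured`, plus the mechanical constants.
#' @export
generate_network <- function(box, pore_size = 3000, fiber_diameter = 41,
                             seed = 1L, params = invadosim_params()) {
  pe <- params$ecm
  stopifnot(length(box) == 3L, all(box > 0))
  if (pore_size >= min(box) / 2)
    stop("pore size must be much smaller than the box")
  set.seed(seed)
  ## target length density from the nearest-void statistic of an isotropic
  ## line process: mean pore diameter ~ 1/sqrt(rho)
  rho <- 1 / (pore_size / 1e3)^2              # um / um^3
  V_um3 <- prod(box) / 1e9
  mean_chord <- 4 * V_um3 / (2 * (box[1] * box[2] + box[2] * box[3] +
                                  box[1] * box[3]) / 1e6) # 4V/S um
  n_fib <- max(3L, round(rho * V_um3 / mean_chord))
  best <- NULL
  for (it in seq_len(pe$max_iter)) {
    net <- seed_fibers(n_fib, box, fiber_diameter, pe$seg_length)
    if (is.null(net)) stop("empty box request (zero fibers)")
    pore <- measure_pore_size(net$X, net$seg, box)
    miss <- abs(pore - pore_size) / pore_size
    if (is.null(best) || miss < best$miss)
      best <- list(net = net, pore = pore, miss = miss)
    if (miss <= 0.05) break   # close enough; stop refining the density
    n_new <- max(3L, round(n_fib * (pore / pore_size)^2))
    if (n_new == n_fib) n_new <- n_fib + sign(pore - pore_size)
    n_fib <- n_new
  }
  if (best$miss > pe$pore_tol)
    stop(sprintf(
      "pore-size target unreachable: target %.0f nm, best measured %.0f nm",
      pore_size, best$pore))
  net <- best$net
  net$pore_measured <- best$pore
  net$pore_target <- pore_size
  net$box <- box
  net$fiber_diameter <- fiber_diameter
  net$E_collagen <- pe$E_collagen
  net$kappa_junction <- pe$kappa_junction
  net$area <- pi * (fiber_diameter / 2)^2
  net$I_f <- pi * (fiber_diameter / 2)^4 / 4
  structure(net, class = "ecm_network")
}

## sequentially seed n_fib connected fibers; returns X, seg, bend, junction
seed_fibers <- function(n_fib, box, fiber_diameter, seg_length) {
  if (n_fib < 1L) return(NULL)
  Xl <- list(); fib_of <- integer(0)
  segl <- list(); bendl <- list(); juncl <- list()
  n_nodes <- 0L
  for (f in seq_len(n_fib)) {
    if (f == 1L || n_nodes == 0L) {
      anchor <- stats::runif(3) * box
      anchor_node <- NA_integer_
    } else {
      anchor_node <- sample.int(n_nodes, 1L)
      Xall <- do.call(rbind, Xl)
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      ## offset bounded away from zero so the junction spring has a
      ## well-defined rest length
      anchor <- Xall[anchor_node, ] +
        u * stats::runif(1, 0.2, 1) * fiber_diameter
      anchor <- pmin(pmax(anchor, 0), box)
    }
    d <- random_direction()
    tt <- clip_line_to_box(anchor, d, box)
    if (is.null(tt) || diff(tt) < 2 * seg_length) {
      ## degenerate clip (anchor on a face): retry with a fresh direction
      d <- random_direction()
      tt <- clip_line_to_box(anchor, d, box)
      if (is.null(tt) || diff(tt) < 2 * seg_length) next
    }
    ## nodes at the anchor and every seg_length toward both clip ends
    t_neg <- rev(seq(0, tt[1], by = -seg_length))
    t_pos <- seq(0, tt[2], by = seg_length)[-1]
    tvals <- c(t_neg, t_pos)
    if (length(tvals) < 2L) next
    P <- t(anchor + outer(d, tvals))
    idx <- n_nodes + seq_len(nrow(P))
    n_nodes <- n_nodes + nrow(P)
    Xl[[f]] <- P
    fib_of <- c(fib_of, rep.int(f, nrow(P)))
    k <- nrow(P)
    L0 <- row_norms(P[-1, , drop = FALSE] - P[-k, , drop = FALSE])
    segl[[f]] <- data.frame(n1 = idx[-k], n2 = idx[-1], L0 = L0, fiber = f)
    if (k >= 3L)
      bendl[[f]] <- data.frame(n1 = idx[1:(k - 2L)], n2 = idx[2:(k - 1L)],
                               n3 = idx[3:k], L0 = L0[1:(k - 2L)])
    if (!is.na(anchor_node)) {
      anchor_idx <- idx[which.min(abs(tvals))]
      L0j <- sqrt(sum((P[which.min(abs(tvals)), ] -
                       Xall[anchor_node, ])^2))
      if (L0j > 1)
        juncl[[length(juncl) + 1L]] <-
          data.frame(n1 = anchor_node, n2 = anchor_idx, L0 = L0j)
    }
  }
  if (!length(segl)) return(NULL)
  X <- do.call(rbind, Xl)
  seg <- do.call(rbind, segl)
  seg$intact <- TRUE
  bend <- if (length(bendl)) do.call(rbind, bendl) else
    data.frame(n1 = integer(0), n2 = integer(0), n3 = integer(0),
               L0 = numeric(0))
  junction <- if (length(juncl)) do.call(rbind, juncl) else
    data.frame(n1 = integer(0), n2 = integer(0), L0 = numeric(0))
  ## incidental contacts: node pairs of different fibers within one diameter
  extra <- close_node_pairs(X, fib_of, fiber_diameter)
  extra <- extra[extra$L0 > 1, , drop = FALSE]   # co-located pairs excluded
  if (nrow(extra)) junction <- unique(rbind(junction, extra))
  rownames(seg) <- rownames(junction) <- NULL
  list(X = X, seg = seg, bend = bend, junction = junction, fiber_of = fib_of)
}

random_direction <- function() {
  u <- stats::rnorm(3)
  u / sqrt(sum(u^2))
}

## intersect the line anchor + t*d with the box [0, box]; returns c(tmin, tmax)
clip_line_to_box <- function(anchor, d, box) {
  tmin <- -Inf; tmax <- Inf
  for (k in 1:3) {
    if (abs(d[k]) < 1e-12) {
      if (anchor[k] < 0 || anchor[k] > box[k]) return(NULL)
    } else {
      t1 <- (0 - anchor[k]) / d[k]
      t2 <- (box[k] - anchor[k]) / d[k]
      tmin <- max(tmin, min(t1, t2))
      tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmin >= tmax) return(NULL)
  c(tmin, tmax)
}

## node pairs from different fibers within `cutoff`, via cell binning
close_node_pairs <- function(X, fib_of, cutoff) {
  cs <- max(cutoff, 500)
  key <- floor(t(t(X) / cs))
  kstr <- paste(key[, 1], key[, 2], key[, 3])
  cells <- split(seq_len(nrow(X)), kstr)
  cellkeys <- do.call(rbind, lapply(strsplit(names(cells), " "), as.integer))
  out <- list()
  lookup <- new.env(parent = emptyenv())
  for (i in seq_along(cells)) assign(names(cells)[i], i, envir = lookup)
  for (ci in seq_along(cells)) {
    base <- cellkeys[ci, ]
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      nm <- paste(base[1] + dx, base[2] + dy, base[3] + dz)
      j <- lookup[[nm]]
      if (!is.null(j) && j >= ci) cand <- c(cand, cells[[j]])
    }
    for (a in cells[[ci]]) {
      b <- cand[cand > a & fib_of[cand] != fib_of[a]]
      if (!length(b)) next
      d <- row_norms(sweep(X[b, , drop = FALSE], 2L, X[a, ]))
      hit <- b[d < cutoff]
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(n1 = a, n2 = hit,
                                              L0 = d[d < cutoff])
    }
  }
  if (!length(out))
    return(data.frame(n1 = integer(0), n2 = integer(0), L0 = numeric(0)))
  do.call(rbind, out)
}

#' Mean pore size of a fiber network
#'
#' Mean nearest-void diameter: twice the average distance from points of a
#' regular sampling grid to the nearest fiber segment.
#'
#' @param X node matrix.
#' @param seg segment table.
#' @param box box dimensions (nm).
#' @param spacing sampling grid spacing (nm).
#' @return mean pore size (nm).
#' @export
measure_pore_size <- function(X, seg, box, spacing = 1000) {
  gx <- seq(spacing / 2, box[1], by = spacing)
  gy <- seq(spacing / 2, box[2], by = spacing)
  gz <- seq(spacing / 2, box[3], by = spacing)
  P <- as.matrix(expand.grid(gx, gy, gz))
  dmin <- rep(Inf, nrow(P))
  A <- X[seg$n1, , drop = FALSE]
  B <- X[seg$n2, , drop = FALSE]
  D <- B - A
  DL2 <- pmax(rowSums(D * D), .Machine$double.eps)
  for (s in seq_len(nrow(A))) {
    w <- sweep(P, 2L, A[s, ])
    tpar <- pmin(pmax((w %*% D[s, ]) / DL2[s], 0), 1)
    dd <- w - tpar %*% t(D[s, ])
    dmin <- pmin(dmin, sqrt(rowSums(dd * dd)))
  }
  2 * mean(dmin)
}

## ---------------------------------------------------------------------------
## Mechanics

## flatten the intact mechanics into plain vectors (hot-path cache used by
## the integrator; rebuilt whenever segments degrade)
ecm_mech <- function(ecm) {
  sg <- ecm$seg[ecm$seg$intact, , drop = FALSE]
  bd <- active_bends(ecm)
  jn <- ecm$junction
  n <- nrow(ecm$X)
  list(sn1 = sg$n1, sn2 = sg$n2, sL0 = sg$L0,
       skap = ecm$area * ecm$E_collagen / sg$L0,
       bn1 = bd$n1, bn2 = bd$n2, bn3 = bd$n3, bL0 = bd$L0,
       kb = ecm$E_collagen * ecm$I_f,
       jn1 = jn$n1, jn2 = jn$n2, jL0 = jn$L0, jkap = ecm$kappa_junction,
       n = n,
       as1 = acc_make(sg$n1, n), as2 = acc_make(sg$n2, n),
       ab1 = acc_make(bd$n1, n), ab2 = acc_make(bd$n2, n),
       ab3 = acc_make(bd$n3, n),
       aj1 = acc_make(jn$n1, n), aj2 = acc_make(jn$n2, n))
}

fiber_forces_mech <- function(mech, X) {
  F <- matrix(0, nrow(X), 3L)
  if (length(mech$sn1)) {
    d <- X[mech$sn2, , drop = FALSE] - X[mech$sn1, , drop = FALSE]
    L <- row_norms(d)
    if (any(L == 0)) stop("degenerate fiber segment")
    coef <- mech$skap * (L - mech$sL0) / L
    F <- acc_add(F, mech$as1, d * coef)
    F <- acc_add(F, mech$as2, -d * coef)
  }
  if (length(mech$bn1)) {
    u <- X[mech$bn2, , drop = FALSE] - X[mech$bn1, , drop = FALSE]
    v <- X[mech$bn3, , drop = FALSE] - X[mech$bn2, , drop = FALSE]
    g <- angle_grads(u, v)
    coef <- mech$kb * g$theta / mech$bL0
    F <- acc_add(F, mech$ab1, coef * g$du)
    F <- acc_add(F, mech$ab2, -coef * (g$du - g$dv))
    F <- acc_add(F, mech$ab3, -coef * g$dv)
  }
  if (length(mech$jn1)) {
    d <- X[mech$jn2, , drop = FALSE] - X[mech$jn1, , drop = FALSE]
    L <- pmax(row_norms(d), .Machine$double.eps)
    coef <- mech$jkap * (L - mech$jL0) / L
    F <- acc_add(F, mech$aj1, d * coef)
    F <- acc_add(F, mech$aj2, -d * coef)
  }
  F
}

#' ECM fiber elastic energy
#'
#' Stretch energy of intact segments with per-segment stiffness
#' \eqn{A_f E_c / L_0}, bending energy \eqn{E_c I_f \theta^2 / (2 L_0)} over
#' intact consecutive-segment triples, and junction-spring energy.  Degraded
#' segments store no energy.
#'
#' @param ecm `ecm_network`.
#' @param X optional replacement coordinates.
#' @return scalar energy (pN*nm).
#' @export
fiber_energy <- function(ecm, X = ecm$X) {
  fiber_energy_mech(ecm_mech(ecm), X)
}

fiber_energy_mech <- function(mech, X) {
  H <- 0
  if (length(mech$sn1)) {
    L <- row_norms(X[mech$sn2, , drop = FALSE] - X[mech$sn1, , drop = FALSE])
    H <- H + sum(0.5 * mech$skap * (L - mech$sL0)^2)
  }
  if (length(mech$bn1)) {
    u <- X[mech$bn2, , drop = FALSE] - X[mech$bn1, , drop = FALSE]
    v <- X[mech$bn3, , drop = FALSE] - X[mech$bn2, , drop = FALSE]
    th <- safe_acos(rowSums(u * v) / (row_norms(u) * row_norms(v)))
    H <- H + sum(0.5 * mech$kb * th^2 / mech$bL0)
  }
  if (length(mech$jn1)) {
    L <- row_norms(X[mech$jn2, , drop = FALSE] - X[mech$jn1, , drop = FALSE])
    H <- H + sum(0.5 * mech$jkap * (L - mech$jL0)^2)
  }
  H
}

## bend triples whose two supporting segments are both intact
active_bends <- function(ecm) {
  bd <- ecm$bend
  if (!nrow(bd)) return(bd)
  segkey <- paste(ecm$seg$n1, ecm$seg$n2)
  intact <- ecm$seg$intact
  ok1 <- intact[match(paste(bd$n1, bd$n2), segkey)]
  ok2 <- intact[match(paste(bd$n2, bd$n3), segkey)]
  bd[which(ok1 & ok2), , drop = FALSE]
}

#' ECM fiber forces
#'
#' Analytic gradient of [fiber_energy()]; degraded segments contribute
#' nothing.
#'
#' @inheritParams fiber_energy
#' @return n x 3 matrix of forces (pN).
#' @export
fiber_forces <- function(ecm, X = ecm$X) {
  fiber_forces_mech(ecm_mech(ecm), X)
}

#' Degrade fiber segments below the local MMP-2-eroded ECM threshold
#'
#' A segment becomes (irreversibly) degraded when the ECM concentration
#' phi6, sampled at its midpoint, falls below `deg_threshold` of the initial
#' value.
#'
#' @param ecm `ecm_network`.
#' @param field `rd_field` (see [rd_field()]).
#' @param params parameter list.
#' @return updated `ecm_network`.
#' @export
degrade_segments <- function(ecm, field, params = invadosim_params()) {
  act <- which(ecm$seg$intact)
  if (!length(act)) return(ecm)
  mid <- (ecm$X[ecm$seg$n1[act], , drop = FALSE] +
          ecm$X[ecm$seg$n2[act], , drop = FALSE]) / 2
  phi6 <- sample_field(field, mid, species = "phi6")
  gone <- phi6 < params$rd$deg_threshold * params$rd$phi6_init
  ecm$seg$intact[act[gone]] <- FALSE
  ecm
}

#' Volume-exclusion penalty forces
#'
#' (i) ECM fiber nodes penetrating the invadopodial membrane receive an
#' outward penalty force, with the reaction on the nearest CI node;
#' (ii) actin nodes outside the actin cortex layer or inside the nuclear
#' membrane surface are pushed back, with reactions on the nearest mesh
#' node.  Penetration is measured against the local outward normal of the
#' nearest mesh node.
#'
#' @param X_pts positions to test (k x 3).
#' @param mesh_X mesh node positions.
#' @param mesh_normals outward unit normals at mesh nodes.
#' @param side `"inside"` forbids points inside the surface (fibers vs CI,
#'   actin vs NMS); `"outside"` forbids points outside it (actin vs CC).
#' @param kappa penalty stiffness (pN/nm).
#' @return list `F_pts` (k x 3), `F_mesh` (forces accumulated on mesh
#'   nodes), `depth` (penetration depths, 0 when not penetrating).
#' @export
volume_exclusion_forces <- function(X_pts, mesh_X, mesh_normals,
                                    side = c("inside", "outside"),
                                    kappa = 10) {
  side <- match.arg(side)
  k <- nrow(X_pts)
  F_pts <- matrix(0, k, 3L)
  F_mesh <- matrix(0, nrow(mesh_X), 3L)
  depth <- numeric(k)
  if (k == 0L) return(list(F_pts = F_pts, F_mesh = F_mesh, depth = depth))
  D2 <- outer(rowSums(X_pts^2), rep(1, nrow(mesh_X))) +
    outer(rep(1, k), rowSums(mesh_X^2)) - 2 * X_pts %*% t(mesh_X)
  nn <- max.col(-D2, ties.method = "first")
  rel <- X_pts - mesh_X[nn, , drop = FALSE]
  s <- rowSums(rel * mesh_normals[nn, , drop = FALSE])
  pen <- if (side == "inside") pmax(-s, 0) else pmax(s, 0)
  hit <- which(pen > 0)
  if (length(hit)) {
    dir <- mesh_normals[nn[hit], , drop = FALSE] *
      (if (side == "inside") 1 else -1)
    Fp <- dir * (kappa * pen[hit])
    F_pts[hit, ] <- Fp
    F_mesh <- add_at(F_mesh, nn[hit], -Fp)
    depth[hit] <- pen[hit]
  }
  list(F_pts = F_pts, F_mesh = F_mesh, depth = depth)
}

## ---------------------------------------------------------------------------
## Stretch test

#' Bulk modulus of the fiber network by a simulated stretch test
#'
#' Applies small volumetric strain steps to the network: boundary nodes
#' (within half a segment length of a box face) are pinned at their affine
#' images, interior nodes relax to mechanical equilibrium (L-BFGS-B on the
#' elastic energy with the analytic gradient), and the boundary stress is
#' recorded as the virial of the pinned-node reaction forces.  The bulk
#' modulus is the slope of the linear fit of stress against volumetric
#' strain.
#'
#' @param ecm `ecm_network`.
#' @param strains linear strain levels per axis (default +/-1%, +/-2%).
#' @param maxit relaxation iteration cap.
#' @return list with `K_Pa` (bulk modulus, Pa), `table` (strain/stress
#'   data.frame) and the fit.
#' @export
bulk_modulus_stretch_test <- function(ecm, strains = c(-0.02, -0.01, 0.01, 0.02),
                                      maxit = 400) {
  box <- ecm$box
  X0 <- ecm$X
  margin <- 600
  onb <- (X0[, 1] < margin | X0[, 1] > box[1] - margin |
          X0[, 2] < margin | X0[, 2] > box[2] - margin |
          X0[, 3] < margin | X0[, 3] > box[3] - margin)
  if (!any(onb) || all(onb)) stop("degenerate boundary split for stretch test")
  center <- box / 2
  free <- which(!onb)
  V0 <- prod(box)
  mech <- ecm_mech(ecm)
  rows <- lapply(strains, function(eps) {
    Xa <- sweep(sweep(X0, 2L, center) * (1 + eps), 2L, center, `+`)
    X <- Xa
    par0 <- as.numeric(X[free, ])
    fn <- function(p) {
      X[free, ] <- matrix(p, ncol = 3L)
      fiber_energy_mech(mech, X)
    }
    gr <- function(p) {
      X[free, ] <- matrix(p, ncol = 3L)
      -as.numeric(fiber_forces_mech(mech, X)[free, ])
    }
    op <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                       control = list(maxit = maxit, factr = 1e4))
    if (op$convergence > 1)
      stop("stretch-test relaxation did not converge: ", op$message)
    X[free, ] <- matrix(op$par, ncol = 3L)
    Fb <- fiber_forces_mech(mech, X)[onb, , drop = FALSE]
    rel <- sweep(X[onb, , drop = FALSE], 2L, center * (1 + eps))
    V <- V0 * (1 + eps)^3
    stress <- -sum(Fb * rel) / (3 * V)        # pN/nm^2; positive in dilation
    data.frame(strain_lin = eps, strain_vol = (1 + eps)^3 - 1,
               stress = stress, energy = op$value)
  })
  tab <- do.call(rbind, rows)
  fit <- stats::lm(stress ~ strain_vol, data = tab)
  K <- unname(stats::coef(fit)[2])
  list(K_Pa = pN_per_nm2_to_Pa(K), table = tab, fit = fit)
}
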