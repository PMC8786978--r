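## Branched actin network: filament representation, growth/shrinkage of rest
## lengths, the seven-state lifecycle, severing, and all filament-side
## elastic forces (stretch, bend, Arp2/3 spring, branch angle, dihedral,
## Brownian-ratchet polymerization force).

## Filament states
S_NUCLEATED <- 1L; S_GROWTH <- 2L; S_ADHESION <- 3L; S_DETACH <- 4L
S_RATCHET <- 5L; S_CAPPED <- 6L; S_UNCAPPED <- 7L

#' Create an empty actin network
#'
#' The network stores a shared node-position matrix plus one record per
#' filament: ordered node indices (pointed end first, barbed end last),
#' per-segment rest lengths, lifecycle state `S` (1 nucleated, 2 growth,
#' 3 adhesion, 4 detach, 5 ratchet, 6 capped, 7 uncapped), Arp2/3 mother
#' link, cortex adhesion target, and seeding pattern (1 radial leading-edge,
#' 2 perinuclear).
#'
#' @return an `actin_network` object.
#' @export
actin_network <- function() {
  structure(list(X = matrix(numeric(0), 0L, 3L),
                 filaments = list(),
                 tables = NULL),
            class = "actin_network")
}

## append nodes, return updated net and new row indices
an_add_nodes <- function(net, P) {
  n0 <- nrow(net$X)
  net$X <- rbind(net$X, P)
  list(net = net, idx = n0 + seq_len(nrow(P)))
}

#' Add a filament to the network
#'
#' @param net an `actin_network`.
#' @param P ordered node positions (k x 3, pointed to barbed, k >= 2).
#' @param L0 per-segment rest lengths (length k-1); defaults to current
#'   segment lengths.
#' @param state lifecycle state (1..7).
#' @param pattern seeding pattern tag (1 or 2).
#' @param mother optional list(fil =, node_j =, node_j1 =) Arp2/3 parentage
#'   (global node indices of the mother segment).
#' @return updated network (the new filament id is `length(net$filaments)`).
#' @export
an_add_filament <- function(net, P, L0 = NULL, state = S_GROWTH,
                            pattern = 1L, mother = NULL) {
  stopifnot(nrow(P) >= 2L)
  r <- an_add_nodes(net, P)
  net <- r$net
  if (is.null(L0)) L0 <- row_norms(P[-1, , drop = FALSE] -
                                   P[-nrow(P), , drop = FALSE])
  stopifnot(length(L0) == nrow(P) - 1L, all(L0 > 0))
  net$filaments[[length(net$filaments) + 1L]] <-
    list(nodes = r$idx, L0 = L0, state = as.integer(state),
         capped = state == S_CAPPED, pattern = as.integer(pattern),
         mother = mother, adhesion = NULL, alive = TRUE)
  net$tables <- NULL
  net
}

## Flatten live topology into vectorized force tables.  Rebuilt after every
## discrete event (growth bookkeeping, nucleation, severing, deletion).
an_build_tables <- function(net, params = invadosim_params()) {
  pa <- params$actin
  s1 <- integer(0); s2 <- integer(0); sL0 <- numeric(0); sfil <- integer(0)
  b1 <- integer(0); b2 <- integer(0); b3 <- integer(0); bL0 <- numeric(0)
  mj <- integer(0); mj1 <- integer(0); d1 <- integer(0); d2 <- integer(0)
  for (f in seq_along(net$filaments)) {
    fl <- net$filaments[[f]]
    if (!fl$alive) next
    nd <- fl$nodes; k <- length(nd)
    s1 <- c(s1, nd[-k]); s2 <- c(s2, nd[-1]); sL0 <- c(sL0, fl$L0)
    sfil <- c(sfil, rep.int(f, k - 1L))
    if (k >= 3L) {
      b1 <- c(b1, nd[1:(k - 2L)]); b2 <- c(b2, nd[2:(k - 1L)])
      b3 <- c(b3, nd[3:k]); bL0 <- c(bL0, fl$L0[1:(k - 2L)])
    }
    if (!is.null(fl$mother)) {
      mo <- net$filaments[[fl$mother$fil]]
      if (!is.null(mo) && mo$alive &&
          fl$mother$node_j %in% mo$nodes && fl$mother$node_j1 %in% mo$nodes) {
        mj <- c(mj, fl$mother$node_j); mj1 <- c(mj1, fl$mother$node_j1)
        d1 <- c(d1, nd[1]); d2 <- c(d2, nd[2])
      }
    }
  }
  n <- nrow(net$X)
  list(seg = list(n1 = s1, n2 = s2, L0 = sL0, fil = sfil,
                  kappa = if (length(sL0)) effective_segment_stiffness(
                    sL0, pa$E_A, pa$r_A) else numeric(0),
                  a1 = acc_make(s1, n), a2 = acc_make(s2, n)),
       bend = list(n1 = b1, n2 = b2, n3 = b3, L0 = bL0,
                   a1 = acc_make(b1, n), a2 = acc_make(b2, n),
                   a3 = acc_make(b3, n)),
       branch = list(mj = mj, mj1 = mj1, d1 = d1, d2 = d2,
                     amj = acc_make(mj, n), amj1 = acc_make(mj1, n),
                     ad1 = acc_make(d1, n), ad2 = acc_make(d2, n)))
}

an_tables <- function(net, params = invadosim_params()) {
  if (is.null(net$tables)) an_build_tables(net, params) else net$tables
}

## ---------------------------------------------------------------------------
## Energies and analytic forces

#' Filament elastic energy (stretch + bend)
#'
#' \eqn{H_L = 1/2 \sum_j \kappa_{L,j} (L_j - L_j^0)^2} with
#' \eqn{\kappa_{L,j} = A_A E_A / L_j^0}, plus
#' \eqn{H_B = 1/2 \kappa_b \sum_j \theta_j^2 / L_j^0} over consecutive
#' tangent angles (unstressed angle zero), \eqn{\kappa_b = E_A I_A}.
#'
#' @param net actin network.
#' @param X optional replacement coordinates.
#' @param params parameter list.
#' @return scalar energy (pN*nm).
#' @export
actin_elastic_energy <- function(net, X = net$X, params = invadosim_params()) {
  tb <- an_tables(net, params)
  H <- 0
  sg <- tb$seg
  if (length(sg$n1)) {
    L <- row_norms(X[sg$n2, , drop = FALSE] - X[sg$n1, , drop = FALSE])
    H <- H + sum(0.5 * sg$kappa * (L - sg$L0)^2)
  }
  bd <- tb$bend
  if (length(bd$n1)) {
    kb <- actin_bending_modulus(params$actin$E_A, params$actin$r_A)
    t1 <- X[bd$n2, , drop = FALSE] - X[bd$n1, , drop = FALSE]
    t2 <- X[bd$n3, , drop = FALSE] - X[bd$n2, , drop = FALSE]
    th <- safe_acos(rowSums(t1 * t2) / (row_norms(t1) * row_norms(t2)))
    H <- H + sum(0.5 * kb * th^2 / bd$L0)
  }
  H
}

## gradient pieces for the angle between u = p2-p1 and v = p3-p2 (shared
## middle point); returns -dtheta/dp as force-direction gradients
angle_grads <- function(u, v) {
  Lu <- row_norms(u); Lv <- row_norms(v)
  t1 <- u / Lu; t2 <- v / Lv
  c0 <- rowSums(t1 * t2)
  c_cl <- pmin(pmax(c0, -1 + 1e-12), 1 - 1e-12)
  s <- pmax(sqrt(1 - c_cl^2), 1e-3)  # sine floor bounds the force at
                                     # degenerate (collinear) angles
  gu <- (t2 - c_cl * t1) / Lu      # d c / d u
  gv <- (t1 - c_cl * t2) / Lv      # d c / d v
  fac <- -1 / s                    # d theta / d c
  list(theta = acos(c_cl), du = gu * fac, dv = gv * fac)
}

#' Filament elastic forces (stretch + bend)
#'
#' Analytic virtual-work gradient of [actin_elastic_energy()]: each node
#' receives stretch contributions from its adjacent segments and bending
#' contributions from adjacent tangent-angle triples (with the 1/L0
#' normalization of the bending energy).  Collinear triples are handled with
#' an epsilon-clamped arccos gradient.
#'
#' @inheritParams actin_elastic_energy
#' @return n x 3 matrix of forces (pN) over all network nodes.
#' @export
actin_elastic_forces <- function(net, X = net$X, params = invadosim_params()) {
  tb <- an_tables(net, params)
  F <- matrix(0, nrow(X), 3L)
  sg <- tb$seg
  if (length(sg$n1)) {
    d <- X[sg$n2, , drop = FALSE] - X[sg$n1, , drop = FALSE]
    L <- row_norms(d)
    coef <- sg$kappa * (L - sg$L0) / L
    Fc <- d * coef
    F <- acc_add(F, sg$a1, Fc)
    F <- acc_add(F, sg$a2, -Fc)
  }
  bd <- tb$bend
  if (length(bd$n1)) {
    kb <- actin_bending_modulus(params$actin$E_A, params$actin$r_A)
    u <- X[bd$n2, , drop = FALSE] - X[bd$n1, , drop = FALSE]
    v <- X[bd$n3, , drop = FALSE] - X[bd$n2, , drop = FALSE]
    g <- angle_grads(u, v)
    coef <- kb * g$theta / bd$L0           # dH/dtheta
    ## dtheta/dp1 = -du, dp2 = du - dv, dp3 = dv ; force = -coef * dtheta/dp
    F <- acc_add(F, bd$a1, coef * g$du)
    F <- acc_add(F, bd$a2, -coef * (g$du - g$dv))
    F <- acc_add(F, bd$a3, -coef * g$dv)
  }
  F
}

#' Branch (Arp2/3) energy
#'
#' Arp2/3 spring energy \eqn{1/2\,\kappa_{arp}(L_{arp}-\lambda_{arp})^2}
#' plus branch-angle energy \eqn{1/2\,\kappa_{ang}(\phi-\phi_0)^2/\lambda_{arp}}
#' (equilibrium 70 degrees between mother and daughter tangents) and
#' dihedral energy \eqn{1/2\,\kappa_{dihed}(\psi-\psi_0)^2/\lambda_{arp}}
#' between the two planes spanned by the Arp connector and each filament.
#'
#' @inheritParams actin_elastic_energy
#' @return scalar energy (pN*nm).
#' @export
branch_energy <- function(net, X = net$X, params = invadosim_params()) {
  br <- an_tables(net, params)$branch
  if (!length(br$mj)) return(0)
  pa <- params$actin
  xmj <- X[br$mj, , drop = FALSE]; xmj1 <- X[br$mj1, , drop = FALSE]
  xd1 <- X[br$d1, , drop = FALSE]; xd2 <- X[br$d2, , drop = FALSE]
  r <- xmj - xd1
  Larp <- row_norms(r)
  H <- sum(0.5 * pa$kappa_arp * (Larp - pa$lambda_arp)^2)
  u <- xmj1 - xmj; v <- xd2 - xd1
  phi <- safe_acos(rowSums(u * v) / (row_norms(u) * row_norms(v)))
  H <- H + sum(0.5 * pa$kappa_br_ang * (phi - pa$phi0)^2 / pa$lambda_arp)
  a <- cross3(r, u); b <- cross3(r, v)
  na <- row_norms(a); nb <- row_norms(b)
  ## skip near-collinear plane vectors (sin of the spanning angle < 5%)
  ok <- na > 0.05 * Larp * row_norms(u) & nb > 0.05 * Larp * row_norms(v)
  if (any(ok)) {
    psi <- safe_acos(rowSums(a[ok, , drop = FALSE] * b[ok, , drop = FALSE]) /
                     (na[ok] * nb[ok]))
    H <- H + sum(0.5 * pa$kappa_br_dihed * (psi - pa$psi0)^2 / pa$lambda_arp)
  }
  H
}

#' Branch (Arp2/3) forces
#'
#' Analytic gradient of [branch_energy()] distributed over the four
#' participating nodes (mother segment j, j+1 and daughter nodes 1, 2).
#' Undefined dihedrals (collinear plane vectors) contribute zero for the
#' step and are counted in the `degenerate` attribute.
#'
#' @inheritParams actin_elastic_energy
#' @return n x 3 matrix of forces (pN).
#' @export
branch_forces <- function(net, X = net$X, params = invadosim_params()) {
  br <- an_tables(net, params)$branch
  F <- matrix(0, nrow(X), 3L)
  ndeg <- 0L
  if (!length(br$mj)) { attr(F, "degenerate") <- 0L; return(F) }
  pa <- params$actin
  xmj <- X[br$mj, , drop = FALSE]; xmj1 <- X[br$mj1, , drop = FALSE]
  xd1 <- X[br$d1, , drop = FALSE]; xd2 <- X[br$d2, , drop = FALSE]
  ## Arp2/3 spring between mother node j and daughter node 1
  r <- xmj - xd1
  Larp <- row_norms(r)
  Lsafe <- pmax(Larp, .Machine$double.eps)
  coef <- pa$kappa_arp * (Larp - pa$lambda_arp) / Lsafe
  ## branch angle phi between mother tangent u and daughter tangent v
  u <- xmj1 - xmj; v <- xd2 - xd1
  g <- angle_grads(u, v)    # here the two segments share no point
  coefp <- pa$kappa_br_ang * (g$theta - pa$phi0) / pa$lambda_arp
  ## dphi/dmj = -du, dmj1 = +du, dd1 = -dv, dd2 = +dv
  F <- acc_add(F, br$amj, -r * coef + coefp * g$du)
  F <- acc_add(F, br$ad1, r * coef + coefp * g$dv)
  F <- acc_add(F, br$amj1, -coefp * g$du)
  F <- acc_add(F, br$ad2, -coefp * g$dv)
  ## dihedral psi between plane normals a = r x u and b = r x v
  a <- cross3(r, u); b <- cross3(r, v)
  na <- row_norms(a); nb <- row_norms(b)
  ## undefined dihedral (collinear plane vectors): term zero for this step
  ok <- na > 0.05 * Larp * row_norms(u) & nb > 0.05 * Larp * row_norms(v)
  ndeg <- sum(!ok)
  if (any(ok)) {
    ah <- a[ok, , drop = FALSE] / na[ok]
    bh <- b[ok, , drop = FALSE] / nb[ok]
    c0 <- rowSums(ah * bh)
    c_cl <- pmin(pmax(c0, -1 + 1e-12), 1 - 1e-12)
    s <- pmax(sqrt(1 - c_cl^2), 1e-3)
    psi <- acos(c_cl)
    ga <- (bh - c_cl * ah) / na[ok]       # dc/da
    gb <- (ah - c_cl * bh) / nb[ok]       # dc/db
    ## dc w.r.t. the difference vectors r, u, v via triple products
    g_r <- cross3(u[ok, , drop = FALSE], ga) + cross3(v[ok, , drop = FALSE], gb)
    g_u <- cross3(ga, r[ok, , drop = FALSE])
    g_v <- cross3(gb, r[ok, , drop = FALSE])
    fac <- -1 / s                          # dpsi/dc
    coefd <- pa$kappa_br_dihed * (psi - pa$psi0) / pa$lambda_arp
    cc <- coefd * fac
    ## r = mj - d1, u = mj1 - mj, v = d2 - d1
    F <- add_at(F, br$mj[ok], -cc * (g_r - g_u))
    F <- add_at(F, br$mj1[ok], -cc * g_u)
    F <- add_at(F, br$d1[ok], cc * (g_r + g_v))
    F <- add_at(F, br$d2[ok], -cc * g_v)
  }
  attr(F, "degenerate") <- ndeg
  F
}

#' Brownian-ratchet polymerization force
#'
#' Force exerted on an actin cortex node by a filament in the ratchet state:
#' \eqn{F_P = F_p \log(v_0 / \|\hat n_R (v_b - v_a)\|)} along the outward
#' membrane normal.  Active only during the protrusive phase; the magnitude
#' is clamped to `[0, F_ratchet_max]` (the logarithm diverges at zero
#' relative speed and turns negative above `v0`).
#'
#' @param v_b barbed-end velocity (length-3, nm/s).
#' @param v_a cortex-node velocity (length-3, nm/s).
#' @param n_hat outward unit normal at the membrane node.
#' @param phase current phase string.
#' @param params parameter list.
#' @return length-3 force vector (pN) on the cortex node.
#' @export
ratchet_force <- function(v_b, v_a, n_hat, phase = "protrusive",
                          params = invadosim_params()) {
  if (!identical(phase, "protrusive")) return(numeric(3))
  pa <- params$actin
  speed <- abs(sum(n_hat * (v_b - v_a)))
  mag <- if (speed == 0) pa$F_ratchet_max else pa$F_p * log(pa$v0_poly / speed)
  mag <- min(max(mag, 0), pa$F_ratchet_max)
  mag * n_hat
}

## ---------------------------------------------------------------------------
## Growth, severing, state machine

#' Update filament rest lengths (polymerization bookkeeping)
#'
#' Grows the barbed-end segment rest length at the supplied rate and shrinks
#' the pointed-end segment at `v_s`.  The barbed segment is subdivided when
#' its rest length exceeds the 300-nm split threshold (inserting the spatial
#' midpoint, conserving rest contour); a pointed segment consumed to zero
#' removes its node, carrying any residual shrinkage into the next segment;
#' pointed segments below the merge threshold are merged into their
#' neighbor.  A filament left with fewer than 2 nodes is deleted.
#'
#' @param net actin network.
#' @param f filament index.
#' @param dt time increment (s).
#' @param grow logical: barbed-end growth active (protrusive phase, uncapped).
#' @param shrink logical: pointed-end depolymerization active.
#' @param v_g barbed growth rate (nm/s); defaults to the free rate.
#' @param params parameter list.
#' @return updated network.
#' @export
update_rest_lengths <- function(net, f, dt, grow = TRUE, shrink = TRUE,
                                v_g = NULL, params = invadosim_params()) {
  stopifnot(dt > 0)
  pa <- params$actin
  fl <- net$filaments[[f]]
  if (is.null(fl) || !fl$alive) return(net)
  if (is.null(v_g)) v_g <- pa$v_g_free
  if (grow && !fl$capped) {
    k <- length(fl$L0)
    fl$L0[k] <- fl$L0[k] + v_g * dt
    if (fl$L0[k] > pa$L_seg_max) {
      ## subdivide: insert spatial midpoint, halve the rest length
      nd <- fl$nodes
      mid <- (net$X[nd[k], ] + net$X[nd[k + 1L], ]) / 2
      r <- an_add_nodes(net, matrix(mid, 1L, 3L))
      net <- r$net
      fl$nodes <- c(nd[seq_len(k)], r$idx, nd[k + 1L])
      fl$L0 <- c(fl$L0[seq_len(k - 1L)], fl$L0[k] / 2, fl$L0[k] / 2)
    }
  }
  if (shrink) {
    rem <- pa$v_s * dt
    while (rem > 0 && length(fl$L0) >= 1L) {
      if (fl$L0[1] > rem) {
        fl$L0[1] <- fl$L0[1] - rem
        rem <- 0
      } else {
        rem <- rem - fl$L0[1]
        fl$nodes <- fl$nodes[-1]
        fl$L0 <- fl$L0[-1]
      }
    }
    ## merge a too-short pointed segment into its neighbor
    if (length(fl$L0) >= 2L && fl$L0[1] < pa$L_seg_min) {
      fl$L0 <- c(fl$L0[1] + fl$L0[2], fl$L0[-(1:2)])
      fl$nodes <- fl$nodes[-2]
    }
    if (length(fl$nodes) < 2L) {
      fl$alive <- FALSE
      fl$adhesion <- NULL
    }
  }
  net$filaments[[f]] <- fl
  net$tables <- NULL
  net
}

## Split/merge/remove segments after continuous rest-length evolution:
## barbed segments past the split threshold are subdivided, pointed
## segments consumed to (near) zero lose their node, short pointed
## segments merge into their neighbor; a filament below 2 nodes dies.
an_normalize_segments <- function(net, f, params = invadosim_params()) {
  pa <- params$actin
  fl <- net$filaments[[f]]
  if (is.null(fl) || !fl$alive) return(net)
  k <- length(fl$L0)
  if (fl$L0[k] > pa$L_seg_max) {
    nd <- fl$nodes
    mid <- (net$X[nd[k], ] + net$X[nd[k + 1L], ]) / 2
    r <- an_add_nodes(net, matrix(mid, 1L, 3L))
    net <- r$net
    fl$nodes <- c(nd[seq_len(k)], r$idx, nd[k + 1L])
    fl$L0 <- c(fl$L0[seq_len(k - 1L)], fl$L0[k] / 2, fl$L0[k] / 2)
  }
  while (length(fl$L0) >= 2L && fl$L0[1] < pa$L_seg_min) {
    ## merge the short pointed segment into its neighbor (conserves rest
    ## contour and bounds the 1/L0 stiffness)
    fl$L0 <- c(fl$L0[1] + fl$L0[2], fl$L0[-(1:2)])
    fl$nodes <- fl$nodes[-2]
  }
  if (length(fl$nodes) < 2L ||
      (length(fl$L0) == 1L && fl$L0[1] <= pa$L_seg_min / 2 + 1)) {
    fl$alive <- FALSE
    fl$adhesion <- NULL
  }
  net$filaments[[f]] <- fl
  net$tables <- NULL
  net
}

#' Sever a filament into 300-nm pieces
#'
#' Partitions the node chain at existing nodes so that no piece exceeds the
#' 300-nm rest-contour segmentation length (cut boundaries duplicate the
#' shared node so each piece is a complete filament).  Total rest contour is
#' conserved at the severing instant.  Filaments at or below one piece are
#' returned unchanged.  Daughter pieces lose the Arp2/3 parentage and start
#' uncapped in the growth state with the original pattern tag.
#'
#' @param net actin network.
#' @param f filament index.
#' @param params parameter list.
#' @return updated network (new pieces appended; original shortened to the
#'   first piece).
#' @export
sever_filament <- function(net, f, params = invadosim_params()) {
  pa <- params$actin
  fl <- net$filaments[[f]]
  if (is.null(fl) || !fl$alive) return(net)
  L0 <- fl$L0
  cuts <- integer(0)   # segment index after which to cut
  acc <- 0
  for (j in seq_along(L0)) {
    if (acc > 0 && acc + L0[j] > pa$L_seg_max + 1e-9) {
      cuts <- c(cuts, j - 1L)
      acc <- 0
    }
    acc <- acc + L0[j]
  }
  if (!length(cuts)) return(net)
  bounds <- c(0L, cuts, length(L0))
  nd <- fl$nodes
  first <- TRUE
  for (p in seq_len(length(bounds) - 1L)) {
    segs <- (bounds[p] + 1L):bounds[p + 1L]
    nodes_p <- nd[c(segs, segs[length(segs)] + 1L)]
    if (first) {
      fl$nodes <- nodes_p
      fl$L0 <- L0[segs]
      fl$adhesion <- NULL
      fl$state <- S_GROWTH
      fl$capped <- FALSE
      net$filaments[[f]] <- fl
      first <- FALSE
    } else {
      ## duplicate the boundary node so pieces are independent
      P <- net$X[nodes_p, , drop = FALSE]
      net <- an_add_filament(net, P, L0 = L0[segs], state = S_GROWTH,
                             pattern = fl$pattern, mother = NULL)
    }
  }
  net$tables <- NULL
  net
}

#' Rest contour length of a filament
#' @param net actin network.
#' @param f filament index.
#' @return total rest contour (nm), 0 for dead filaments.
#' @export
filament_contour <- function(net, f) {
  fl <- net$filaments[[f]]
  if (is.null(fl) || !fl$alive) return(0)
  sum(fl$L0)
}

## is a filament buckled (end-to-end below buckle_ratio * contour)?
filament_buckled <- function(net, f, params = invadosim_params()) {
  fl <- net$filaments[[f]]
  if (is.null(fl) || !fl$alive) return(FALSE)
  ee <- sqrt(sum((net$X[fl$nodes[length(fl$nodes)], ] -
                  net$X[fl$nodes[1], ])^2))
  contour <- sum(row_norms(net$X[fl$nodes[-1], , drop = FALSE] -
                           net$X[fl$nodes[-length(fl$nodes)], , drop = FALSE]))
  contour > 0 && ee < params$actin$buckle_ratio * contour
}

#' Single-filament lifecycle transition
#'
#' Applies the discrete state network of a filament barbed end for one
#' control interval: growth enters adhesion when the gap to the actin cortex
#' layer falls below 100 nm; adhesion ruptures above 20 pN tension (detach,
#' then immediately ratchet); growth/ratchet ends cap stochastically at
#' `k_cap` during any phase; capped ends uncap at the protrusive-phase
#' restart (handled by the phase controller).
#'
#' @param net actin network.
#' @param f filament index.
#' @param X_cc actin cortex layer node positions.
#' @param phase current phase string.
#' @param dt control interval (s).
#' @param normals_cc optional outward unit normals of the cortex mesh; when
#'   supplied the gap is measured along the nearest node's normal
#'   (tangent-plane gap, robust to coarse triangulations), otherwise as the
#'   nearest-node distance.
#' @param rng_u optional uniform deviate (for reproducible tests); default
#'   drawn from the session RNG.
#' @param params parameter list.
#' @return updated network.
#' @export
state_transition <- function(net, f, X_cc, phase, dt,
                             rng_u = stats::runif(1),
                             params = invadosim_params(),
                             normals_cc = NULL) {
  pa <- params$actin
  fl <- net$filaments[[f]]
  if (is.null(fl) || !fl$alive) return(net)
  S <- fl$state
  if (!S %in% 1:7) stop("unknown filament state: ", S)
  if (S == S_NUCLEATED) S <- S_GROWTH
  if (S == S_UNCAPPED) { S <- S_GROWTH; fl$capped <- FALSE }
  barbed <- net$X[fl$nodes[length(fl$nodes)], ]
  ## gap to the cortex surface: with mesh normals available, the distance
  ## along the local outward normal of the nearest cortex node (robust to
  ## coarse triangulations); otherwise the nearest-node distance
  if (S == S_GROWTH) {
    d2 <- colSums((t(X_cc) - barbed)^2)
    j <- which.min(d2)
    if (is.null(normals_cc)) {
      hp <- sqrt(d2[j])
      if (hp < pa$h_adh) {
        S <- S_ADHESION
        fl$adhesion <- list(cc = j, L0 = hp, plane = FALSE)
      }
    } else {
      g <- sum((barbed - X_cc[j, ]) * normals_cc[j, ])  # signed, <0 inside
      if (abs(g) < pa$h_adh) {
        S <- S_ADHESION
        fl$adhesion <- list(cc = j, L0 = g, plane = TRUE)
      }
    }
  } else if (S == S_ADHESION) {
    ad <- fl$adhesion
    g <- if (isTRUE(ad$plane) && !is.null(normals_cc))
      sum((barbed - X_cc[ad$cc, ]) * normals_cc[ad$cc, ])
    else sqrt(sum((X_cc[ad$cc, ] - barbed)^2))
    tension <- pa$kappa_adh * abs(g - ad$L0)
    if (tension > pa$F_detach) {
      fl$ratchet_cc <- ad$cc   # cortex node the ratchet keeps pushing
      fl$adhesion <- NULL
      S <- S_RATCHET    # detach (S=4) is transient: polymerization resumes
    }
  }
  if (S %in% c(S_GROWTH, S_RATCHET)) {
    p_cap <- 1 - exp(-pa$k_cap * dt)
    if (rng_u < p_cap) { S <- S_CAPPED; fl$capped <- TRUE; fl$adhesion <- NULL }
  }
  fl$state <- S
  net$filaments[[f]] <- fl
  net
}

#' Nucleate a daughter filament from a mother segment
#'
#' Places the daughter's first node one Arp2/3 rest length from the chosen
#' mother node, oriented 70 degrees from the mother tangent at a supplied
#' (or random) azimuth, with a short initial segment.
#'
#' @param net actin network.
#' @param f mother filament index.
#' @param jseg mother segment index.
#' @param azimuth branching azimuth (rad) about the mother tangent.
#' @param params parameter list.
#' @return updated network.
#' @export
nucleate_daughter <- function(net, f, jseg, azimuth = stats::runif(1, 0, 2 * pi),
                              params = invadosim_params()) {
  pa <- params$actin
  fl <- net$filaments[[f]]
  if (is.null(fl) || !fl$alive || jseg >= length(fl$nodes)) return(net)
  nj <- fl$nodes[jseg]; nj1 <- fl$nodes[jseg + 1L]
  tvec <- net$X[nj1, ] - net$X[nj, ]
  th <- tvec / sqrt(sum(tvec^2))
  ## orthonormal frame around the tangent
  ref <- if (abs(th[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * th) * th
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(th[2] * e1[3] - th[3] * e1[2],
          th[3] * e1[1] - th[1] * e1[3],
          th[1] * e1[2] - th[2] * e1[1])
  dir <- cos(pa$phi0) * th +
    sin(pa$phi0) * (cos(azimuth) * e1 + sin(azimuth) * e2)
  p1 <- net$X[nj, ] + pa$lambda_arp * dir
  p2 <- p1 + pa$L_seg_min * dir
  an_add_filament(net, rbind(p1, p2), L0 = pa$L_seg_min, state = S_NUCLEATED,
                  pattern = fl$pattern,
                  mother = list(fil = f, node_j = nj, node_j1 = nj1))
}
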