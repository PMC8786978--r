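## Six-species reaction-diffusion system on a regular 3D grid:
## MMP-2 (phi1), TIMP-2 (phi2), MT1-MMP (phi3), the ternary
## MT1-MMP:TIMP-2:proMMP-2 complex (phi4), ligand / collagen molecules
## (phi5) and ECM (phi6).  phi1, phi2 and phi5 diffuse (7-point stencil,
## zero-flux boundaries); phi3, phi4 and phi6 are immobile.  Secretion of
## TIMP-2 and MT1-MMP happens at invadopodium-tip grid nodes, only during
## the protrusive phase, at rates proportional to the local ligand
## concentration.

#' Create a reaction-diffusion field
#'
#' @param box domain dimensions (length-3, nm).
#' @param params parameter list (grid spacing `rd$h` and all rate
#'   constants).
#' @param phi6_mask optional logical array marking voxels containing ECM
#'   fibers (phi6 initialized to `phi6_init` there, 0 elsewhere); default
#'   everywhere.
#' @return an `rd_field`: list of six 3D arrays plus grid metadata.
#' @export
rd_field <- function(box, params = invadosim_params(), phi6_mask = NULL) {
  h <- params$rd$h
  dims <- pmax(2L, as.integer(ceiling(box / h)) + 1L)
  z <- array(0, dim = dims)
  phi6 <- array(params$rd$phi6_init, dim = dims)
  if (!is.null(phi6_mask)) {
    stopifnot(all(dim(phi6_mask) == dims))
    phi6[!phi6_mask] <- 0
  }
  structure(list(phi1 = z, phi2 = z, phi3 = z, phi4 = z,
                 phi5 = array(params$rd$phi5_init, dim = dims),
                 phi6 = phi6,
                 h = h, dims = dims, box = box),
            class = "rd_field")
}

## 7-point-stencil Laplacian with zero-flux (reflecting) boundaries
laplacian3 <- function(A, h) {
  d <- dim(A)
  shift <- function(axis, by) {
    idx <- rep(list(quote(expr = )), 3L)
    n <- d[axis]
    src <- pmin(pmax(seq_len(n) + by, 1L), n)  # reflect at the faces
    idx[[axis]] <- src
    do.call(`[`, c(list(A), idx))
  }
  (shift(1, -1) + shift(1, 1) + shift(2, -1) + shift(2, 1) +
     shift(3, -1) + shift(3, 1) - 6 * A) / h^2
}

#' Advance the reaction-diffusion field
#'
#' One (sub-stepped) explicit update of all six species: diffusion for
#' phi1/phi2/phi5, mass-action reactions exactly as written in the model
#' table (including MMP-2 production via the ternary complex,
#' \eqn{+k^{on}_{\phi3:\phi4}\phi_3\phi_4}), first-order decay, ECM
#' degradation \eqn{-k^{deg}\phi_1\phi_6} releasing ligand into phi5, and
#' tip-source secretion \eqn{\alpha_{\phi2}\phi_5, \alpha_{\phi3}\phi_5}
#' active only during the protrusive phase.  In the stiffness-directed
#' scenario the MT1-MMP secretion coefficient already scales with local
#' ligand density through the \eqn{\phi_5} factor.  Concentrations are
#' clipped at zero; the requested `dt` is split into sub-steps satisfying
#' the diffusion stability bound `h^2/(6 max D)`.
#'
#' @param field `rd_field`.
#' @param dt time increment (s).
#' @param phase current phase string (secretion gate).
#' @param tip_idx integer matrix (k x 3) of tip-source grid indices, or
#'   NULL.
#' @param params parameter list.
#' @param mt1mmp_ko logical: knock out all secretion.
#' @return updated field.
#' @export
rd_step <- function(field, dt, phase = "protrusive", tip_idx = NULL,
                    params = invadosim_params(), mt1mmp_ko = FALSE) {
  pr <- params$rd
  h <- field$h
  Dmax <- max(pr$D_phi1, pr$D_phi2, pr$D_phi5)
  dt_stab <- h^2 / (6 * Dmax)
  nsub <- max(1L, ceiling(dt / dt_stab))
  hdt <- dt / nsub
  if (hdt > dt_stab * (1 + 1e-9)) stop("rd_step: stability bound violated")
  secrete <- identical(phase, "protrusive") && !mt1mmp_ko &&
    !is.null(tip_idx) && nrow(tip_idx) > 0
  src2 <- src3 <- NULL
  for (s in seq_len(nsub)) {
    p1 <- field$phi1; p2 <- field$phi2; p3 <- field$phi3
    p4 <- field$phi4; p5 <- field$phi5; p6 <- field$phi6
    r12 <- pr$k_on_12 * p1 * p2
    r23 <- pr$k_on_23 * p2 * p3
    r34 <- pr$k_on_34 * p3 * p4
    roff <- pr$k_off_4 * p4
    rdeg <- pr$k_deg * p1 * p6
    d1 <- pr$D_phi1 * laplacian3(p1, h) - r12 + r34 - pr$k_decay_1 * p1
    d2 <- pr$D_phi2 * laplacian3(p2, h) - r12 - r23 + roff
    d3 <- -r23 + roff - pr$k_decay_3 * p3
    d4 <- r23 + r34 - roff
    d5 <- pr$D_phi5 * laplacian3(p5, h) - pr$k_decay_5 * p5 + rdeg
    d6 <- -rdeg
    if (secrete) {
      lig <- p5[tip_idx]
      d2[tip_idx] <- d2[tip_idx] + pr$alpha_phi2 * lig
      d3[tip_idx] <- d3[tip_idx] + pr$alpha_phi3 * lig
    }
    field$phi1 <- pmax(p1 + hdt * d1, 0)
    field$phi2 <- pmax(p2 + hdt * d2, 0)
    field$phi3 <- pmax(p3 + hdt * d3, 0)
    field$phi4 <- pmax(p4 + hdt * d4, 0)
    field$phi5 <- pmax(p5 + hdt * d5, 0)
    field$phi6 <- pmax(p6 + hdt * d6, 0)
  }
  field
}

#' Grid nodes forming the invadopodium tip source
#'
#' The tip cap is the top `tip_frac` of CI nodes by projection on the
#' polarity vector; the source set is every grid node within one grid
#' spacing of a tip-cap membrane node.
#'
#' @param X_ci invadopodial membrane node positions.
#' @param polarity unit polarity vector.
#' @param field `rd_field`.
#' @param params parameter list.
#' @param frac cap fraction; 0 yields an empty set.
#' @return integer matrix (k x 3) of grid indices.
#' @export
tip_source_nodes <- function(X_ci, polarity, field, params = invadosim_params(),
                             frac = params$rd$tip_frac) {
  if (frac <= 0) return(matrix(integer(0), 0L, 3L))
  proj <- as.numeric(X_ci %*% polarity)
  ncap <- max(1L, ceiling(frac * nrow(X_ci)))
  cap <- order(proj, decreasing = TRUE)[seq_len(ncap)]
  h <- field$h
  idx <- unique(do.call(rbind, lapply(cap, function(i) {
    g0 <- X_ci[i, ] / h + 1      # fractional grid coordinate
    lo <- pmax(floor(g0), 1)
    hi <- pmin(ceiling(g0), field$dims)
    as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  })))
  colnames(idx) <- NULL
  storage.mode(idx) <- "integer"
  idx
}

#' Sample the field by trilinear interpolation
#'
#' @param field `rd_field`.
#' @param pos positions (k x 3 matrix or length-3 vector, nm); positions
#'   outside the box take the boundary value.
#' @param species one of `"phi1"`..`"phi6"`, or `"all"` for a k x 6 matrix.
#' @return numeric vector (or matrix for `"all"`).
#' @export
sample_field <- function(field, pos, species = "phi1") {
  if (!is.matrix(pos)) pos <- matrix(pos, 1L, 3L)
  h <- field$h; dims <- field$dims
  g <- pos / h + 1
  g <- pmin(pmax(g, 1), matrix(rep(dims, each = nrow(pos)), ncol = 3L))
  i0 <- pmin(floor(g), matrix(rep(dims - 1L, each = nrow(pos)), ncol = 3L))
  fr <- g - i0
  interp1 <- function(A) {
    v <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (ifelse(dx == 1, fr[, 1], 1 - fr[, 1]) *
            ifelse(dy == 1, fr[, 2], 1 - fr[, 2]) *
            ifelse(dz == 1, fr[, 3], 1 - fr[, 3]))
      v <- v + w * A[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
    }
    v
  }
  if (identical(species, "all")) {
    sapply(paste0("phi", 1:6), function(s) interp1(field[[s]]))
  } else interp1(field[[species]])
}
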