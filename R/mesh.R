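## Triangulated sphere meshes: icosphere construction and the generic
## triangle-mesh container used by every membrane layer.

#' Icosphere triangulation
#'
#' Subdivided icosahedron projected onto a sphere.  Level `n` has
#' `10 * 4^n + 2` vertices and `20 * 4^n` triangles; the topology is fixed
#' for the lifetime of a simulation (no remeshing).
#'
#' @param radius sphere radius (nm).
#' @param level subdivision level (integer >= 0).
#' @return list with `X` (n x 3 vertex matrix), `tri` (t x 3 index matrix,
#'   outward winding) and `edges` (m x 2, each row sorted).
#' @export
icosphere <- function(radius, level = 2) {
  stopifnot(radius > 0, level >= 0)
  t <- (1 + sqrt(5)) / 2
  X <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1)
  )
  tri <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  X <- X / sqrt(rowSums(X^2))
  if (level > 0) {
    for (lv in seq_len(level)) {
      midkey <- new.env(parent = emptyenv())
      Xl <- vector("list", 0L)
      nX <- nrow(X)
      midpoint <- function(a, b) {
        key <- paste(min(a, b), max(a, b))
        id <- midkey[[key]]
        if (!is.null(id)) return(id)
        m <- (X[a, ] + X[b, ]) / 2
        m <- m / sqrt(sum(m^2))
        Xl[[length(Xl) + 1L]] <<- m
        id <- nX + length(Xl)
        midkey[[key]] <- id
        id
      }
      newtri <- matrix(0L, nrow(tri) * 4L, 3L)
      for (i in seq_len(nrow(tri))) {
        a <- tri[i, 1]; b <- tri[i, 2]; c <- tri[i, 3]
        ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
        newtri[(i - 1L) * 4L + 1:4, ] <- rbind(
          c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
      }
      X <- rbind(X, do.call(rbind, Xl))
      X <- X / sqrt(rowSums(X^2))
      tri <- newtri
    }
  }
  edges <- unique(t(apply(rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)]),
                          1L, sort)))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  list(X = X * radius, tri = tri, edges = edges)
}

## build one membrane layer container from an icosphere; the accumulation
## maps over the (fixed) edge/triangle topology are precomputed once
new_layer <- function(ico, id, kappa_L, kappa_A = 0) {
  X <- ico$X
  e <- ico$edges
  L0 <- row_norms(X[e[, 2], ] - X[e[, 1], ])
  A0 <- triangle_areas(X, ico$tri)
  stopifnot(all(L0 > 0), all(A0 > 0))
  n <- nrow(X)
  list(id = id, X = X, tri = ico$tri, edges = e, L0 = L0, A0 = A0,
       kappa_L = kappa_L, kappa_A = kappa_A,
       kappa_L_edge = NULL,   # optional per-edge stiffness (ACL)
       acc = list(e1 = acc_make(e[, 1], n), e2 = acc_make(e[, 2], n),
                  t1 = acc_make(ico$tri[, 1], n),
                  t2 = acc_make(ico$tri[, 2], n),
                  t3 = acc_make(ico$tri[, 3], n)))
}

triangle_areas <- function(X, tri) {
  u <- X[tri[, 2], , drop = FALSE] - X[tri[, 1], , drop = FALSE]
  v <- X[tri[, 3], , drop = FALSE] - X[tri[, 1], , drop = FALSE]
  n <- cross3(u, v)
  row_norms(n) / 2
}

## row-wise cross product of n x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Outward unit normals at mesh vertices
#'
#' Area-weighted average of adjacent (outward-wound) triangle normals.
#'
#' @param mesh a layer as built by [build_spherical_cell()].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  X <- mesh$X; tri <- mesh$tri
  u <- X[tri[, 2], , drop = FALSE] - X[tri[, 1], , drop = FALSE]
  v <- X[tri[, 3], , drop = FALSE] - X[tri[, 1], , drop = FALSE]
  fn <- cross3(u, v)   # 2*area-weighted normal
  N <- matrix(0, nrow(X), 3L)
  if (!is.null(mesh$acc)) {
    N <- acc_add(N, mesh$acc$t1, fn)
    N <- acc_add(N, mesh$acc$t2, fn)
    N <- acc_add(N, mesh$acc$t3, fn)
  } else for (k in 1:3) N <- add_at(N, tri[, k], fn)
  nr <- row_norms(N)
  nr[nr == 0] <- 1
  N / nr
}

#' Build the five-layer spherical cell
#'
#' Constructs five concentric closed triangulated surfaces sharing the
#' icosphere topology: the invadopodial membrane (CI), force transduction
#' layer (CT, 50 nm inside CI), actin cortex layer (CC, 50 nm inside CT),
#' and the nuclear envelope as perinuclear actin layer (PAL) with the
#' nuclear membrane surface (NMS) 50 nm inside it.  CI/CT/CC share node
#' count and index-wise pairing, as do PAL/NMS.  All layers are built at
#' rest: every edge at its rest length, every triangle at its rest area,
#' every vertical link at 50 nm, so the total elastic force is zero.
#'
#' @param radius_cell outer cell radius (nm).
#' @param radius_nucleus PAL radius (nm); must leave the nucleus strictly
#'   inside the cortex.
#' @param subdivision icosphere level for the three cell layers (the nuclear
#'   layers use `max(subdivision - 1, 1)`).
#' @param params parameter list from [invadosim_params()].
#' @return list of layers `CI`, `CT`, `CC`, `PAL`, `NMS` plus the vertical
#'   link table.
#' @export
build_spherical_cell <- function(radius_cell, radius_nucleus,
                                 subdivision = 2,
                                 params = invadosim_params()) {
  pm <- params$membrane
  if (radius_cell <= 0 || radius_nucleus <= 0)
    stop("radii must be positive")
  off <- pm$L_T0 + pm$L_C0
  if (radius_nucleus - pm$L_NN0 <= 0)
    stop("nucleus too small to host both nuclear layers")
  if (radius_cell - off <= radius_nucleus)
    stop("nucleus must lie strictly inside the actin cortex layer")
  ## reject subdivisions too coarse to offset layers without
  ## self-intersection: the 50-nm offsets must stay well below the edge length
  probe <- icosphere(radius_cell, subdivision)
  min_edge <- min(row_norms(probe$X[probe$edges[, 2], ] -
                            probe$X[probe$edges[, 1], ]))
  if (min_edge < 2 * max(pm$L_T0, pm$L_C0))
    stop("subdivision too coarse: edge length below twice the layer offset")

  ci <- new_layer(probe, "CI", pm$kappa_L_I, pm$kappa_A_I)
  ct <- new_layer(icosphere(radius_cell - pm$L_T0, subdivision),
                  "CT", pm$kappa_L_T, 0)
  cc <- new_layer(icosphere(radius_cell - off, subdivision), "CC", NA, 0)
  ## ACL edges carry the filament-bundle stiffness A_A E_A / L0 per edge
  cc$kappa_L_edge <- effective_segment_stiffness(cc$L0,
                                                 params$actin$E_A,
                                                 params$actin$r_A)
  sub_n <- max(subdivision - 1L, 1L)
  pal <- new_layer(icosphere(radius_nucleus, sub_n),
                   "PAL", pm$kappa_L_N, pm$kappa_A_N)
  nms <- new_layer(icosphere(radius_nucleus - pm$L_NN0, sub_n),
                   "NMS", pm$kappa_L_N, pm$kappa_A_N)
  structure(list(CI = ci, CT = ct, CC = cc, PAL = pal, NMS = nms),
            class = "invadosim_cell")
}

## ---------------------------------------------------------------------------
## Elastic energies and analytic forces (virtual-work gradients)

#' Membrane elastic energy
#'
#' Line energy \eqn{H_L = \kappa_L/2 \sum_i (L_i - L_i^0)^2} (per-edge
#' stiffness when the layer carries one, as the ACL does) plus area energy
#' \eqn{H_A = \kappa_A/2 \sum_i ((A_i - A_i^0)/A_i^0)^2 A_i^0}.
#'
#' @param mesh a membrane layer.
#' @param X optional replacement coordinates (defaults to `mesh$X`).
#' @return scalar energy (pN*nm).
#' @export
membrane_energy <- function(mesh, X = mesh$X) {
  e <- mesh$edges
  L <- row_norms(X[e[, 2], , drop = FALSE] - X[e[, 1], , drop = FALSE])
  kL <- if (!is.null(mesh$kappa_L_edge)) mesh$kappa_L_edge else mesh$kappa_L
  H <- sum(0.5 * kL * (L - mesh$L0)^2)
  if (!is.null(mesh$kappa_A) && mesh$kappa_A > 0) {
    A <- triangle_areas(X, mesh$tri)
    H <- H + sum(0.5 * mesh$kappa_A * ((A - mesh$A0) / mesh$A0)^2 * mesh$A0)
  }
  H
}

#' Membrane elastic forces
#'
#' Analytic gradient \eqn{-\partial(H_L + H_A)/\partial x_i} of
#' [membrane_energy()] at every node: stretched edges pull their endpoints
#' together, compressed edges push them apart, and the area term restores
#' each triangle toward its rest area.
#'
#' @inheritParams membrane_energy
#' @return n x 3 matrix of forces (pN).
#' @export
membrane_elastic_forces <- function(mesh, X = mesh$X) {
  e <- mesh$edges
  d <- X[e[, 2], , drop = FALSE] - X[e[, 1], , drop = FALSE]
  L <- row_norms(d)
  if (any(L == 0)) stop("degenerate edge (zero length)")
  kL <- if (!is.null(mesh$kappa_L_edge)) mesh$kappa_L_edge else mesh$kappa_L
  coef <- kL * (L - mesh$L0) / L      # dH/dL * dL/dx2 direction
  Fc <- d * coef                      # force on node e1 (pull toward e2 when stretched)
  F <- matrix(0, nrow(X), 3L)
  if (!is.null(mesh$acc)) {
    F <- acc_add(F, mesh$acc$e1, Fc)
    F <- acc_add(F, mesh$acc$e2, -Fc)
  } else {
    F <- add_at(F, e[, 1], Fc)
    F <- add_at(F, e[, 2], -Fc)
  }
  if (!is.null(mesh$kappa_A) && mesh$kappa_A > 0) {
    tri <- mesh$tri
    a <- X[tri[, 1], , drop = FALSE]
    b <- X[tri[, 2], , drop = FALSE]
    c <- X[tri[, 3], , drop = FALSE]
    n <- cross3(b - a, c - a)
    nn <- row_norms(n)
    if (any(nn == 0)) stop("degenerate triangle (zero area)")
    A <- nn / 2
    nh <- n / nn
    ## grad_a A = ((b - c) x n_hat)/2 etc.
    gA_a <- cross3(b - c, nh) / 2
    gA_b <- cross3(c - a, nh) / 2
    gA_c <- cross3(a - b, nh) / 2
    coefA <- mesh$kappa_A * (A - mesh$A0) / mesh$A0
    if (!is.null(mesh$acc)) {
      F <- acc_add(F, mesh$acc$t1, -gA_a * coefA)
      F <- acc_add(F, mesh$acc$t2, -gA_b * coefA)
      F <- acc_add(F, mesh$acc$t3, -gA_c * coefA)
    } else {
      F <- add_at(F, tri[, 1], -gA_a * coefA)
      F <- add_at(F, tri[, 2], -gA_b * coefA)
      F <- add_at(F, tri[, 3], -gA_c * coefA)
    }
  }
  F
}

#' Vertical (inter-layer) link forces
#'
#' Spring forces between index-paired nodes of two layers (CI-CT transduce
#' links, CT-CC cortex links, PAL-NMS nuclear links).  Forces are equal and
#' opposite across each pair.
#'
#' @param XA,XB node coordinate matrices of the two paired layers.
#' @param kappa link stiffness (pN/nm).
#' @param L0 rest length (nm), scalar or per-pair vector.
#' @return list with `FA`, `FB` (forces on each layer) and `L` (current
#'   lengths).
#' @export
vertical_link_forces <- function(XA, XB, kappa, L0) {
  d <- XB - XA
  L <- row_norms(d)
  L[L == 0] <- .Machine$double.eps
  coef <- kappa * (L - L0) / L
  FA <- d * coef
  list(FA = FA, FB = -FA, L = L)
}

## energy of the vertical links (for gradient oracles)
vertical_link_energy <- function(XA, XB, kappa, L0) {
  L <- row_norms(XB - XA)
  sum(0.5 * kappa * (L - L0)^2)
}

#' Transduce and cortex coupling forces over the three outer layers
#'
#' Assembles the CI-CT transduce springs and CT-CC cortex springs, plus the
#' in-plane elastic forces of CT and CC.
#'
#' @param cell five-layer cell from [build_spherical_cell()].
#' @param XI,XT,XC optional replacement coordinates for CI, CT, CC.
#' @param params parameter list.
#' @return list of n x 3 force matrices `F_I`, `F_T`, `F_C` and the raw
#'   transduce/cortex pair forces `F_T_pair`, `F_C_pair` acting on CI and CT.
#' @export
transduce_and_cortex_forces <- function(cell, XI = cell$CI$X, XT = cell$CT$X,
                                        XC = cell$CC$X,
                                        params = invadosim_params()) {
  pm <- params$membrane
  tr <- vertical_link_forces(XI, XT, pm$kappa_T, pm$L_T0)
  co <- vertical_link_forces(XT, XC, pm$kappa_C, pm$L_C0)
  F_I <- tr$FA
  F_T <- tr$FB + co$FA + membrane_elastic_forces(cell$CT, XT)
  F_C <- co$FB + membrane_elastic_forces(cell$CC, XC)
  list(F_I = F_I, F_T = F_T, F_C = F_C,
       F_T_pair = tr$FA, F_C_pair = co$FA)
}

#' Nuclear crosslink force
#'
#' Spring force exerted on a nuclear-layer node by a filamin or
#' alpha-actinin crosslinker anchored on an actin segment at fractional
#' position beta.
#'
#' @param x_nuc nuclear node position (length-3).
#' @param x_attach actin-side attachment position (length-3).
#' @param kappa crosslinker stiffness (pN/nm).
#' @param L0 rest length (nm).
#' @return list with `F_nuc` (force on the nuclear node), `F_attach`
#'   (reaction at the attachment point) and `L`.
#' @export
nuclear_link_force <- function(x_nuc, x_attach, kappa, L0) {
  d <- x_attach - x_nuc
  L <- sqrt(sum(d * d))
  if (L == 0) return(list(F_nuc = numeric(3), F_attach = numeric(3), L = 0))
  Fn <- kappa * (L - L0) * d / L
  list(F_nuc = Fn, F_attach = -Fn, L = L)
}
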