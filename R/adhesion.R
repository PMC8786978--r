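## Integrin-collagen focal complexes with Bell slip-bond kinetics.

#' Create an empty focal-complex table
#'
#' One row per focal complex: the invadopodial membrane node, the bonded
#' fiber node, and the continuous bond count `n_b` integrating the Bell
#' kinetics.
#' @return zero-row data.frame.
#' @export
focal_complex_table <- function() {
  data.frame(ci = integer(0), en = integer(0), n_b = numeric(0))
}

#' Bell association and dissociation rates
#'
#' Association \eqn{k_{on} = k_{on}^0 (l_{bind}/Z_0)
#' \exp[-\kappa_{LR}(L_b-\lambda)^2/(2 k_B T)]} with the harmonic partition
#' function \eqn{Z_0}; dissociation by Bell's slip-bond equation
#' \eqn{k_{off} = k_{off}^0 \exp[\kappa_{LR}(L_b-\lambda) x_b / k_B T]},
#' with the intrinsic force scale \eqn{k_B T / x_b} of about 200 pN.
#'
#' @param L_b mean bond length (nm), >= 0.
#' @param params parameter list.
#' @return list with `k_on` and `k_off` (1/s), vectorized over `L_b`.
#' @export
bond_rates <- function(L_b, params = invadosim_params()) {
  ad <- params$adhesion
  if (any(L_b < 0)) stop("negative bond length")
  stretch <- L_b - ad$lambda
  a <- sqrt(ad$kappa_LR / (2 * ad$kBT))
  Z0 <- sqrt(pi * ad$kBT / (2 * ad$kappa_LR)) *
    (erf(stretch * a) + erf(ad$lambda * a))
  k_on <- ad$k_on0 * (ad$l_bind / Z0) *
    exp(-ad$kappa_LR * stretch^2 / (2 * ad$kBT))
  ## x_b = kBT / F_intrinsic, so the exponent is force / F_intrinsic
  k_off <- ad$k_off0 * exp(ad$kappa_LR * stretch / ad$F_intrinsic)
  list(k_on = k_on, k_off = k_off)
}

#' Integrate the bond-count ODE of a focal complex
#'
#' Explicit integration of \eqn{dn_b/dt = k_{on}(n_{tot} - n_b) -
#' k_{off} n_b} at fixed mean bond length over `dt`, sub-stepped so the
#' update stays stable; `n_b` is clamped to `[0, n_tot]`.
#'
#' @param n_b current bond count.
#' @param L_b mean bond length (nm).
#' @param dt time increment (s).
#' @param params parameter list.
#' @return updated bond count (vectorized).
#' @export
bond_kinetics_step <- function(n_b, L_b, dt, params = invadosim_params()) {
  ad <- params$adhesion
  r <- bond_rates(L_b, params)
  ktot <- r$k_on + r$k_off
  nsub <- max(1L, ceiling(max(ktot) * dt / 0.1))
  h <- dt / nsub
  for (s in seq_len(nsub))
    n_b <- n_b + h * (r$k_on * (ad$n_tot - n_b) - r$k_off * n_b)
  pmin(pmax(n_b, 0), ad$n_tot)
}

#' Focal complex force
#'
#' \eqn{F = n_b \kappa_{LR} (L_b - \lambda) \hat n} on the membrane node,
#' directed toward the bonded fiber node, with the equal-and-opposite
#' reaction on the fiber node (the route by which protruding cells remodel
#' and densify the surrounding matrix).
#'
#' @param x_ci membrane node position.
#' @param x_en fiber node position.
#' @param n_b bond count.
#' @param params parameter list.
#' @return list `F_ci`, `F_en` (pN), `L_b`.
#' @export
focal_complex_force <- function(x_ci, x_en, n_b, params = invadosim_params()) {
  ad <- params$adhesion
  d <- x_en - x_ci
  L_b <- sqrt(sum(d * d))
  if (L_b == 0 || n_b <= 0)
    return(list(F_ci = numeric(3), F_en = numeric(3), L_b = L_b))
  Fm <- n_b * ad$kappa_LR * (L_b - ad$lambda) * d / L_b
  list(F_ci = Fm, F_en = -Fm, L_b = L_b)
}

#' Open and close focal complexes against the fiber network
#'
#' A membrane node without a complex opens one to the nearest intact fiber
#' node whose surface gap (center distance minus the fiber radius and the
#' bond rest length) is within the binding radius; ties break by distance
#' then lowest node index.  Complexes detach when the bond count decays
#' below 1e-3 or the fiber node's segments have all been degraded.
#'
#' @param fc focal-complex table.
#' @param X_ci membrane node positions.
#' @param ecm `ecm_network`.
#' @param params parameter list.
#' @return updated table.
#' @export
update_focal_complexes <- function(fc, X_ci, ecm, params = invadosim_params()) {
  ad <- params$adhesion
  r_f <- ecm$fiber_diameter / 2
  live_nodes <- sort(unique(c(ecm$seg$n1[ecm$seg$intact],
                              ecm$seg$n2[ecm$seg$intact])))
  if (nrow(fc)) {
    keep <- fc$en %in% live_nodes & fc$n_b >= 1e-3
    fc <- fc[keep, , drop = FALSE]
  }
  if (!length(live_nodes)) return(fc)
  unbonded <- setdiff(seq_len(nrow(X_ci)), fc$ci)
  Xe <- ecm$X[live_nodes, , drop = FALSE]
  capture <- ad$lambda + ad$l_bind + r_f
  for (i in unbonded) {
    d2 <- colSums((t(Xe) - X_ci[i, ])^2)
    j <- which.min(d2)   # smallest distance; which.min takes the lowest index
    if (sqrt(d2[j]) <= capture)  # complex opens with a single nucleating bond
      fc <- rbind(fc, data.frame(ci = i, en = live_nodes[j], n_b = 1))
  }
  rownames(fc) <- NULL
  fc
}
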