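## Crosslinkers (fascin, filamin, alpha-actinin) and bipolar myosin
## minifilaments: fractional binding positions on filament segments, spring
## forces distributed to the supporting nodes, Hill force-velocity sliding,
## placement rules and turnover.

#' Binding position on a filament segment
#'
#' Convex combination \eqn{x = (1-\alpha) x_j + \alpha x_{j+1}} of the
#' segment endpoints at fractional position alpha.
#'
#' @param x_j,x_j1 segment endpoint positions (length-3 vectors or k x 3
#'   matrices).
#' @param alpha fraction in `[0, 1]` (scalar or length-k).
#' @return position(s), same shape as the inputs.
#' @export
binding_position <- function(x_j, x_j1, alpha) {
  if (is.matrix(x_j)) (1 - alpha) * x_j + alpha * x_j1
  else (1 - alpha) * x_j + alpha * x_j1
}

#' Create a linker/motor table
#'
#' Columns: kind (1 fascin, 2 filamin, 3 alpha-actinin, 4 myosin,
#' 5 filamin/actinin-to-nucleus), endpoint A (filament, segment nodes, alpha),
#' endpoint B (filament or nuclear node, segment nodes, beta), stiffness,
#' rest length, birth time, previous-step tension (for the Hill law).
#' @return zero-row linker table (data.frame).
#' @export
linker_table <- function() {
  data.frame(kind = integer(0),
             filA = integer(0), a1 = integer(0), a2 = integer(0),
             alpha = numeric(0),
             filB = integer(0), b1 = integer(0), b2 = integer(0),
             beta = numeric(0),
             kappa = numeric(0), L0 = numeric(0),
             birth = numeric(0), F_prev = numeric(0),
             nuc_node = integer(0))
}

LK_FASCIN <- 1L; LK_FILAMIN <- 2L; LK_ACTININ <- 3L; LK_MYOSIN <- 4L
LK_NUCLEAR <- 5L

#' Linker and motor spring forces
#'
#' Spring force \eqn{\kappa (L - L^0)} along the connector between the two
#' fractional binding positions, distributed to the supporting segment nodes
#' with weights \eqn{(1-\alpha, \alpha)} and \eqn{(1-\beta, \beta)};
#' action equals reaction across the two filaments.  Nuclear linkers
#' (kind 5) connect endpoint A on a filament to a nuclear-layer node held in
#' `nuc_node` of `X_nuc`.  Myosin motors exert force only when `motors_on`.
#'
#' @param lk linker table.
#' @param X actin node positions.
#' @param X_nuc nuclear-layer (PAL) node positions.
#' @param motors_on logical: retractile phase active.
#' @return list with `F_actin` (forces on actin nodes), `F_nuc` (forces on
#'   nuclear nodes), `tension` (signed connector tension magnitudes,
#'   positive = stretched) and `L` (current lengths).
#' @export
linker_forces <- function(lk, X, X_nuc = NULL, motors_on = TRUE) {
  F <- matrix(0, nrow(X), 3L)
  Fn <- if (is.null(X_nuc)) NULL else matrix(0, nrow(X_nuc), 3L)
  if (nrow(lk) == 0L)
    return(list(F_actin = F, F_nuc = Fn,
                tension = numeric(0), L = numeric(0)))
  pa <- binding_position(X[lk$a1, , drop = FALSE],
                         X[lk$a2, , drop = FALSE], lk$alpha)
  isnuc <- lk$kind == LK_NUCLEAR
  pb <- matrix(0, nrow(lk), 3L)
  if (any(!isnuc))
    pb[!isnuc, ] <- binding_position(X[lk$b1[!isnuc], , drop = FALSE],
                                     X[lk$b2[!isnuc], , drop = FALSE],
                                     lk$beta[!isnuc])
  if (any(isnuc)) pb[isnuc, ] <- X_nuc[lk$nuc_node[isnuc], , drop = FALSE]
  d <- pb - pa
  L <- row_norms(d)
  Ls <- pmax(L, .Machine$double.eps)
  active <- rep(TRUE, nrow(lk))
  if (!motors_on) active <- active & lk$kind != LK_MYOSIN
  coef <- ifelse(active, lk$kappa * (L - lk$L0) / Ls, 0)
  Fa <- d * coef          # force at binding position A (toward B if stretched)
  F <- add_at(F, lk$a1, Fa * (1 - lk$alpha))
  F <- add_at(F, lk$a2, Fa * lk$alpha)
  ii <- which(!isnuc)
  if (length(ii)) {
    F <- add_at(F, lk$b1[ii], -Fa[ii, , drop = FALSE] * (1 - lk$beta[ii]))
    F <- add_at(F, lk$b2[ii], -Fa[ii, , drop = FALSE] * lk$beta[ii])
  }
  jj <- which(isnuc)
  if (length(jj)) Fn <- add_at(Fn, lk$nuc_node[jj], -Fa[jj, , drop = FALSE])
  list(F_actin = F, F_nuc = Fn,
       tension = lk$kappa * (L - lk$L0) * as.numeric(active), L = L)
}

## energy for the gradient oracle
linker_energy <- function(lk, X, X_nuc = NULL, motors_on = TRUE) {
  if (nrow(lk) == 0L) return(0)
  pa <- binding_position(X[lk$a1, , drop = FALSE],
                         X[lk$a2, , drop = FALSE], lk$alpha)
  isnuc <- lk$kind == LK_NUCLEAR
  pb <- matrix(0, nrow(lk), 3L)
  if (any(!isnuc))
    pb[!isnuc, ] <- binding_position(X[lk$b1[!isnuc], , drop = FALSE],
                                     X[lk$b2[!isnuc], , drop = FALSE],
                                     lk$beta[!isnuc])
  if (any(isnuc)) pb[isnuc, ] <- X_nuc[lk$nuc_node[isnuc], , drop = FALSE]
  L <- row_norms(pb - pa)
  active <- rep(TRUE, nrow(lk))
  if (!motors_on) active <- active & lk$kind != LK_MYOSIN
  sum(0.5 * lk$kappa[active] * (L[active] - lk$L0[active])^2)
}

#' Hill force-velocity law for bipolar myosin
#'
#' \eqn{v = v_0 (F_{stall} - F_{ext}) / (F_{stall} + c_m F_{ext})} with the
#' sensed contractile load of the previous time step; velocity clamps to 0
#' above stall.
#'
#' @param F_ext load magnitude (pN), >= 0.
#' @param params parameter list.
#' @return sliding velocity (nm/s).
#' @export
hill_sliding_velocity <- function(F_ext, params = invadosim_params()) {
  pl <- params$linker
  stopifnot(all(F_ext >= 0))
  v <- pl$v_slide0 * (pl$F_stall - F_ext) / (pl$F_stall + pl$c_m * F_ext)
  pmax(v, 0)
}

#' Advance myosin sliding along both filaments
#'
#' Updates the fractional positions \eqn{\alpha^* = \alpha + v\,\Delta t /
#' \|x_{j+1}-x_j\|} toward each filament's barbed end (both endpoints slide
#' simultaneously).  When a fraction passes 1 the endpoint hops to the next
#' segment toward the barbed end, or clamps at 1 on the terminal barbed
#' segment.  The sliding speed comes from the Hill law at the motor tension
#' recorded on the previous step.
#'
#' @param lk linker table (myosin rows are advanced; others untouched).
#' @param net actin network (for segment lengths and barbed-end hopping).
#' @param dt time step (s).
#' @param params parameter list.
#' @return updated linker table.
#' @export
advance_sliding <- function(lk, net, dt, params = invadosim_params()) {
  my <- which(lk$kind == LK_MYOSIN)
  if (!length(my)) return(lk)
  v <- hill_sliding_velocity(pmax(lk$F_prev[my], 0), params)
  for (side in c("A", "B")) {
    n1c <- if (side == "A") "a1" else "b1"
    n2c <- if (side == "A") "a2" else "b2"
    frc <- if (side == "A") "alpha" else "beta"
    filc <- if (side == "A") "filA" else "filB"
    seglen <- row_norms(net$X[lk[[n2c]][my], , drop = FALSE] -
                        net$X[lk[[n1c]][my], , drop = FALSE])
    newfrac <- lk[[frc]][my] + v * dt / pmax(seglen, .Machine$double.eps)
    for (q in seq_along(my)) {
      i <- my[q]
      fr <- newfrac[q]
      fl <- net$filaments[[lk[[filc]][i]]]
      if (is.null(fl) || !fl$alive) next
      nd <- fl$nodes
      while (fr > 1) {
        pos <- match(lk[[n2c]][i], nd)
        if (is.na(pos) || pos >= length(nd)) { fr <- 1; break }
        ## hop to the next segment toward the barbed end
        lk[[n1c]][i] <- nd[pos]
        lk[[n2c]][i] <- nd[pos + 1L]
        fr <- fr - 1
      }
      lk[[frc]][i] <- min(fr, 1)
    }
  }
  lk
}

#' Place crosslinkers and motors, apply turnover
#'
#' Binding rules: fascin bundles near-parallel filament pairs in the
#' leading-edge cone; filamin links parallel-or-orthogonal pairs in the cone
#' and also tethers cone filaments to the perinuclear actin layer;
#' alpha-actinin and bipolar myosin bind near-parallel perinuclear
#' (pattern 2) pairs and are active during the retractile phase.  Each
#' eligible pair binds with probability `p_bind` per control interval at a
#' random fractional position; linkers older than the turnover time are
#' removed (rebinding allowed on later calls).  Knockout flags suppress
#' placement of the corresponding species entirely.
#'
#' @param lk linker table.
#' @param net actin network.
#' @param X_pal perinuclear actin layer node positions.
#' @param polarity unit migration-direction vector.
#' @param center cell center (origin for the leading-edge cone test).
#' @param t current time (s).
#' @param phase current phase string.
#' @param ko named logical list: `alpha_actinin`, `filamin`, `fascin`.
#' @param params parameter list.
#' @return updated linker table.
#' @export
place_and_turnover <- function(lk, net, X_pal, polarity, center, t, phase,
                               ko = list(alpha_actinin = FALSE,
                                         filamin = FALSE, fascin = FALSE),
                               params = invadosim_params()) {
  pl <- params$linker
  ## turnover: drop linkers past their lifetime
  if (nrow(lk)) lk <- lk[t - lk$birth <= pl$turnover, , drop = FALSE]
  ## drop linkers whose filaments died or whose segments were consumed
  if (nrow(lk)) {
    keep <- vapply(seq_len(nrow(lk)), function(i) {
      okA <- segment_live(net, lk$filA[i], lk$a1[i], lk$a2[i])
      okB <- lk$kind[i] == LK_NUCLEAR ||
        segment_live(net, lk$filB[i], lk$b1[i], lk$b2[i])
      okA && okB
    }, logical(1))
    lk <- lk[keep, , drop = FALSE]
  }
  ## candidate segments: midpoints, tangents, cone membership, pattern
  seg <- collect_segments(net)
  if (!nrow(seg)) return(lk)
  mid <- (net$X[seg$n1, , drop = FALSE] + net$X[seg$n2, , drop = FALSE]) / 2
  tg <- net$X[seg$n2, , drop = FALSE] - net$X[seg$n1, , drop = FALSE]
  tg <- tg / pmax(row_norms(tg), .Machine$double.eps)
  relv <- sweep(mid, 2L, center)
  cone <- safe_acos(relv %*% polarity / pmax(row_norms(relv), 1e-9)) <
    pl$cone_angle
  newrows <- list()
  ## occupancy: at most one linker of each kind per segment, bounding the
  ## crosslinker population by the segment count
  occupied <- new.env(parent = emptyenv())
  if (nrow(lk)) {
    for (i in seq_len(nrow(lk))) {
      assign(paste(lk$kind[i], lk$a1[i]), TRUE, envir = occupied)
      if (lk$kind[i] != LK_NUCLEAR)
        assign(paste(lk$kind[i], lk$b1[i]), TRUE, envir = occupied)
    }
  }
  is_free <- function(kind, n1) is.null(occupied[[paste(kind, n1)]])
  add_pairs <- function(cand, kind, L0, kappa) {
    if (length(cand) < 2L) return()
    for (ii in seq_along(cand)) {
      i <- cand[ii]
      if (!is_free(kind, seg$n1[i])) next
      rest <- cand[cand > i]
      if (!length(rest)) next
      d <- row_norms(sweep(mid[rest, , drop = FALSE], 2L, mid[i, ]))
      ang <- safe_acos(abs(tg[rest, , drop = FALSE] %*% tg[i, ]))
      gate <- d > L0 * (1 - pl$dist_slack) & d < L0 * (1 + pl$dist_slack) &
        seg$fil[rest] != seg$fil[i]
      gate <- gate & switch(as.character(kind),
        "1" = ang < pl$parallel_angle,
        "2" = ang < pl$parallel_angle |
              (ang > pl$orth_band[1] & ang < pl$orth_band[2]),
        "3" = ang < pl$parallel_angle,
        "4" = ang < pl$parallel_angle)
      hits <- rest[gate & stats::runif(length(rest)) < pl$p_bind]
      for (h in hits) {
        if (!is_free(kind, seg$n1[i]) || !is_free(kind, seg$n1[h])) next
        assign(paste(kind, seg$n1[i]), TRUE, envir = occupied)
        assign(paste(kind, seg$n1[h]), TRUE, envir = occupied)
        newrows[[length(newrows) + 1L]] <<- data.frame(
          kind = kind, filA = seg$fil[i], a1 = seg$n1[i], a2 = seg$n2[i],
          alpha = stats::runif(1),
          filB = seg$fil[h], b1 = seg$n1[h], b2 = seg$n2[h],
          beta = stats::runif(1),
          kappa = kappa, L0 = L0, birth = t, F_prev = 0, nuc_node = 0L)
      }
    }
  }
  lead <- which(cone)
  peri <- which(seg$pattern == 2L)
  if (!isTRUE(ko$fascin))
    add_pairs(lead[seg$pattern[lead] == 1L], LK_FASCIN, pl$L0_fascin, pl$kappa)
  if (!isTRUE(ko$filamin))
    add_pairs(lead, LK_FILAMIN, pl$L0_filamin, pl$kappa)
  if (!isTRUE(ko$alpha_actinin) && identical(phase, "retractile")) {
    add_pairs(peri, LK_ACTININ, pl$L0_actinin, pl$kappa)
    add_pairs(peri, LK_MYOSIN, pl$L0_myosin, pl$kappa_myosin)
  }
  ## nuclear tethers: filamin (any phase) and alpha-actinin (retractile)
  ## from filament segments near the PAL to the nearest PAL node
  if (nrow(X_pal) && length(peri)) {
    for (i in peri) {
      if (!is_free(LK_NUCLEAR, seg$n1[i])) next
      d2 <- colSums((t(X_pal) - mid[i, ])^2)
      j <- which.min(d2)
      dn <- sqrt(d2[j])
      use_fil <- !isTRUE(ko$filamin)
      use_act <- !isTRUE(ko$alpha_actinin) && identical(phase, "retractile")
      L0n <- if (use_act) pl$L0_actinin else pl$L0_filamin
      if ((use_fil || use_act) &&
          dn > L0n * (1 - pl$dist_slack) && dn < L0n * (1 + pl$dist_slack) &&
          stats::runif(1) < pl$p_bind) {
        assign(paste(LK_NUCLEAR, seg$n1[i]), TRUE, envir = occupied)
        newrows[[length(newrows) + 1L]] <- data.frame(
          kind = LK_NUCLEAR, filA = seg$fil[i], a1 = seg$n1[i],
          a2 = seg$n2[i], alpha = stats::runif(1),
          filB = 0L, b1 = 0L, b2 = 0L, beta = 0,
          kappa = pl$kappa, L0 = L0n, birth = t, F_prev = 0, nuc_node = j)
      }
    }
  }
  if (length(newrows)) lk <- rbind(lk, do.call(rbind, newrows))
  rownames(lk) <- NULL
  lk
}

## all live segments as a data.frame (fil, n1, n2, pattern)
collect_segments <- function(net) {
  tb <- an_tables(net)
  pats <- vapply(net$filaments, function(fl)
    if (is.null(fl) || !fl$alive) NA_integer_ else fl$pattern, integer(1))
  data.frame(fil = tb$seg$fil, n1 = tb$seg$n1, n2 = tb$seg$n2,
             pattern = if (length(tb$seg$fil)) pats[tb$seg$fil]
                       else integer(0))
}

segment_live <- function(net, f, n1, n2) {
  if (f < 1L || f > length(net$filaments)) return(FALSE)
  fl <- net$filaments[[f]]
  if (is.null(fl) || !fl$alive) return(FALSE)
  i <- match(n1, fl$nodes)
  !is.na(i) && i < length(fl$nodes) && fl$nodes[i + 1L] == n2
}
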