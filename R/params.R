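#' @keywords internal
"_PACKAGE"

## Internal unit system: lengths in nm, forces in pN, time in s.
## Derived units: stiffness pN/nm (1 pN/nm = 1e-3 N/m), energy pN*nm,
## pressure / Young's modulus pN/nm^2 (1 pN/nm^2 = 1e6 Pa = 1 MPa),
## drag pN*s/nm.  Published values in SI are converted once, here.

#' Unit conversion helpers
#'
#' The simulator works in nanometres, piconewtons and seconds.  These helpers
#' convert the published SI values into that system:
#' 1 N/m = 1000 pN/nm, 1 GPa = 1000 pN/nm^2, 1 Pa = 1e-6 pN/nm^2.
#'
#' @param x numeric value in the source unit.
#' @return numeric value in the internal unit.
#' @name units
NULL

#' @rdname units
#' @export
N_per_m_to_pN_per_nm <- function(x) x * 1e3

#' @rdname units
#' @export
GPa_to_pN_per_nm2 <- function(x) x * 1e3

#' @rdname units
#' @export
Pa_to_pN_per_nm2 <- function(x) x * 1e-6

#' @rdname units
#' @export
pN_per_nm2_to_Pa <- function(x) x * 1e6

#' Default simulation parameters
#'
#' Returns the full nested parameter list of the model with all published
#' constants converted to the internal nm/pN/s unit system, plus documented
#' defaults for quantities the model leaves configurable (drag coefficients,
#' branch-bending moduli, reaction-diffusion rate constants, the collagen
#' Young's modulus calibrated against the 2,558 Pa network bulk modulus).
#' Any entry can be overridden via `...` using nested lists, e.g.
#' `invadosim_params(actin = list(v_g_free = 25))`.
#'
#' @param ... named nested lists overriding individual entries.
#' @return nested list of parameters.
#' @export
#' @examples
#' p <- invadosim_params()
#' p$actin$E_A          # 1800 pN/nm^2 == 1.8 GPa
#' p$membrane$kappa_T   # 8 pN/nm == 8.0e-3 N/m
invadosim_params <- function(...) {
  p <- list(
    membrane = list(
      kappa_L_I  = 0.05,   # invadopodial membrane line stiffness, 5.0e-5 N/m
      kappa_A_I  = 0.1,    # membrane area stiffness; printed 1.0e-4 (see vignette on units)
      kappa_L_T  = 8,      # FTL line stiffness, 8.0e-3 N/m
      kappa_T    = 8,      # CI<->CT vertical link stiffness, 8.0e-3 N/m
      L_T0       = 50,     # CI<->CT rest length (nm)
      kappa_C    = 10,     # CT<->CC vertical link stiffness, 1.0e-2 N/m
      L_C0       = 50,     # CT<->CC rest length (nm)
      kappa_L_N  = 5,      # nuclear membrane line stiffness, 5.0e-3 N/m
      kappa_A_N  = 0.1,    # nuclear area stiffness (same reading as kappa_A_I)
      kappa_NN   = 10,     # PAL<->NMS vertical link stiffness (reuses kappa_C)
      L_NN0      = 50,     # PAL<->NMS rest length (nm)
      radius_cell    = 8000,
      radius_nucleus = 3500,
      subdivision    = 2
    ),
    actin = list(
      E_A        = 1800,        # Young's modulus of F-actin, 1.8 GPa
      r_A        = 3.5,         # filament radius (nm)
      L0_init    = 150,         # initial segment rest length (nm)
      L_seg_max  = 300,         # split threshold (nm)
      L_seg_min  = 75,          # merge threshold (nm); keeps A_A E_A/L0 bounded
      v_g_free   = 20,          # free barbed-end growth rate (nm/s)
      v_s        = 10,          # pointed-end shrinkage rate (nm/s)
      v0_poly    = 50,          # zero-load polymerization speed (nm/s)
      f0         = 20,          # load-sensitivity force scale (pN)
      F_p        = 20,          # ratchet force scale (pN)
      F_ratchet_max = 100,      # clamp on ratchet magnitude (pN)
      kappa_arp  = 10,          # Arp2/3 spring, 0.01 N/m
      lambda_arp = 30,          # Arp2/3 rest length (nm)
      phi0       = 70 * pi / 180,  # equilibrium branch angle (rad)
      psi0       = 0,           # equilibrium dihedral (rad)
      kappa_br_ang   = 30,      # branch-angle modulus (pN*nm^2): 1 pN*nm per nm of Arp rest length
      kappa_br_dihed = 30,      # dihedral modulus (pN*nm^2)
      k_n        = 50,          # cell-wide nucleation rate (1/s)
      k_cap      = 0.3,         # stochastic capping rate (1/s)
      h_adh      = 100,         # barbed-end/ACL gap for adhesion (nm)
      F_detach   = 20,          # adhesion rupture tension (pN)
      kappa_adh  = 10,          # barbed-end/ACL adhesion spring (pN/nm)
      buckle_ratio = 0.9        # end-to-end/contour ratio defining buckling
    ),
    linker = list(
      kappa      = 10,    # crosslinker stiffness, 0.01 N/m
      L0_actinin = 50,    # alpha-actinin rest length (nm)
      L0_fascin  = 40,    # fascin rest length (nm)
      L0_filamin = 150,   # filamin rest length (nm)
      L0_myosin  = 300,   # bipolar myosin minifilament rest length (nm)
      kappa_myosin = 10,  # myosin stiffness, 0.01 N/m
      turnover   = 60,    # crosslinker turnover time (s)
      v_slide0   = 160,   # unloaded myosin sliding speed (nm/s)
      F_stall    = 1240,  # myosin stall force (pN), 1.24 nN
      c_m        = 4.761, # Hill curvature parameter (dimensionless)
      parallel_angle = 20 * pi / 180,   # "parallel" filament-pair threshold
      orth_band  = c(70, 110) * pi / 180, # filamin orthogonal band
      cone_angle = 60 * pi / 180,       # leading-edge cone half-angle
      p_bind     = 0.1,   # binding probability per eligible pair per interval
      bind_interval = 1,  # s between binding-attempt sweeps
      dist_slack = 0.5    # distance gate: rest length +/- 50%
    ),
    ecm = list(
      fiber_diameter = 41,     # collagen type 1 fiber diameter (nm)
      seg_length     = 500,    # fiber discretization (nm)
      pore_size      = 3000,   # target mean pore size (nm)
      box            = c(45000, 30000, 20000), # full ECM domain (nm)
      E_collagen     = 200,    # collagen fiber Young's modulus (pN/nm^2 = MPa);
                               # calibrated once against the 2,558 Pa network
                               # bulk modulus (scripts/calibrate_ecm.R)
      kappa_junction = 50,     # inter-fiber junction spring (pN/nm)
      pore_tol       = 0.15,   # relative tolerance on measured pore size
      max_iter       = 12,     # generator density iterations
      kappa_excl     = 10,     # volume-exclusion penalty stiffness, 0.01 N/m
      C_pair         = 1.0,    # fiber Kelvin-Voigt pair drag (pN*s/nm)
      C0             = 8.0     # fiber ground drag (pN*s/nm)
    ),
    adhesion = list(
      kappa_LR = 1,      # single integrin-collagen bond stiffness (pN/nm)
      lambda   = 30,     # bond rest length (nm)
      l_bind   = 30,     # binding radius (nm)
      kBT      = 4.11,   # thermal energy (pN*nm)
      F_intrinsic = 200, # kBT/x_b, intrinsic slip-bond force scale (pN)
      k_on0    = 1,      # zero-force association rate (1/(molecule*s))
      k_off0   = 0.05,   # zero-force dissociation rate (1/s)
      n_tot    = 50      # integrin capacity per membrane node
    ),
    rd = list(
      h      = 500,      # grid spacing (nm)
      D_phi1 = 1e7,      # MMP-2 diffusivity (nm^2/s = 10 um^2/s)
      D_phi2 = 1e7,      # TIMP-2 diffusivity
      D_phi5 = 1e7,      # ligand diffusivity
      k_on_12 = 1,       # MMP-2 + TIMP-2 association
      k_on_34 = 0.05,    # MMP-2 activation via ternary complex (kept well
                         # below k_off_4: the phi4 production term is
                         # autocatalytic as written and must stay bounded)
      k_on_23 = 1,       # TIMP-2 + MT1-MMP association
      k_off_4 = 0.5,     # ternary complex dissociation
      k_decay_1 = 2,     # MMP-2 decay (localizes degradation to ~sqrt(D/k))
      k_decay_3 = 1,     # MT1-MMP decay
      k_decay_5 = 0.01,  # ligand decay
      k_deg     = 0.5,   # ECM degradation rate constant
      alpha_phi2 = 0.5,  # TIMP-2 tip secretion coefficient
      alpha_phi3 = 1,    # MT1-MMP tip secretion coefficient
      tip_frac   = 0.05, # fraction of CI nodes forming the tip cap
      phi5_init  = 1,    # initial ligand concentration (normalized)
      phi6_init  = 1,    # initial ECM concentration where fibers exist
      deg_threshold = 0.2 # fiber segment degraded below this phi6 fraction
    ),
    drag = list(        # cell-side dissipation coefficients (pN*s/nm)
      C_pair = 0.2,     # membrane Kelvin-Voigt dashpot between mesh neighbors
      C0     = 1.3,     # ground (cytosol) drag per node
      C1_T   = 0.2,     # CI<->CT dashpot
      C1_C   = 0.2,     # CT<->CC dashpot
      C_pair_A = 1.0,   # actin segment dashpot
      C0_A   = 5.0,     # actin ground drag (keeps the stiff 0.46 N/m line
                        # elements overdamped at the working step size)
      C_arp  = 0.5      # mother<->daughter dashpot at Arp2/3 links
    ),
    integrator = list(
      tol      = 1e-4,  # relative position error tolerance (step doubling)
      dt_init  = 5e-3,  # initial time step (s)
      dt_max   = 2e-2,
      dt_min   = 1e-6,
      grow     = 1.25,  # step growth factor on acceptance
      control_interval = 0.5 # s between discrete-event updates
    ),
    phases = list(
      protrusive = 240, # s
      retractile = 60,
      severing   = 20
    )
  )
  ov <- list(...)
  modifyList(p, ov)
}

## derived actin quantities -------------------------------------------------

#' Cross-sectional area of an actin filament
#'
#' @param r_A filament radius (nm), default 3.5.
#' @return area in nm^2 (38.48 nm^2 at the default radius).
#' @export
actin_cross_section <- function(r_A = 3.5) pi * r_A^2

#' Effective stiffness of an actin line element
#'
#' Axial stiffness of a discretized filament segment,
#' \eqn{\kappa = A_A E_A / L_0}, with \eqn{A_A = \pi r_A^2}.
#'
#' @param L0 segment rest length (nm), must be > 0.
#' @param E_A Young's modulus (pN/nm^2), default 1800 (1.8 GPa).
#' @param r_A filament radius (nm), default 3.5.
#' @return stiffness in pN/nm. Divide by 1000 for N/m:
#'   460 pN/nm = 0.46 N/m at L0 = 150 nm.
#' @export
effective_segment_stiffness <- function(L0, E_A = 1800, r_A = 3.5) {
  stopifnot(all(L0 > 0))
  actin_cross_section(r_A) * E_A / L0
}

#' Bending modulus of an actin filament
#'
#' \eqn{\kappa_b = E_A I_A} with \eqn{I_A = \pi r_A^4/4}.
#' @inheritParams effective_segment_stiffness
#' @return bending modulus in pN*nm^2.
#' @export
actin_bending_modulus <- function(E_A = 1800, r_A = 3.5) E_A * pi * r_A^4 / 4

#' Load-dependent barbed-end growth rate
#'
#' Concave-up velocity-force relation for a barbed end polymerizing against
#' the actin cortex: \eqn{v_g = v_0 \exp(-f_{cortex}/(n_F f_0))}.
#'
#' @param f_cortex tension at the cortex node (pN), >= 0.
#' @param n_F number of filaments sharing the node, >= 1.
#' @param v0 zero-load polymerization speed (nm/s).
#' @param f0 force scale (pN).
#' @return growth rate in nm/s.
#' @export
load_dependent_growth_rate <- function(f_cortex, n_F, v0 = 50, f0 = 20) {
  stopifnot(all(n_F >= 1), all(f_cortex >= 0))
  v0 * exp(-f_cortex / (n_F * f0))
}

## small numeric helpers used across modules --------------------------------

## row-wise Euclidean norms of an n x 3 matrix
row_norms <- function(M) sqrt(rowSums(M * M))

## clamp acos argument away from +/-1 (degenerate-angle guard)
safe_acos <- function(x, eps = 1e-12) acos(pmin(pmax(x, -1 + eps), 1 - eps))

## error function via pnorm (used by the Bell-kinetics partition function)
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

## Precomputed accumulator for a fixed index pattern: scatter-adds k x 3
## contributions into an n x 3 force matrix via one sparse multiply.  Used
## on the hot path (mesh edges/triangles, filament tables, lag terms) where
## the index pattern is reused for thousands of force evaluations.
acc_make <- function(idx, n) {
  if (length(idx) == 0L) return(NULL)
  ui <- sort.int(unique(idx))
  list(A = Matrix::sparseMatrix(i = match(idx, ui), j = seq_along(idx),
                                x = 1, dims = c(length(ui), length(idx))),
       rows = ui)
}

acc_add <- function(F, acc, contrib) {
  if (is.null(acc)) return(F)
  S <- acc$A %*% contrib             # dgeMatrix; read its data slot directly
  F[acc$rows, ] <- F[acc$rows, ] + matrix(S@x, length(acc$rows), 3L)
  F
}

## accumulate rows of `contrib` (k x 3) into `F` (n x 3) at (possibly
## duplicated) row indices `idx`
add_at <- function(F, idx, contrib) {
  if (length(idx) == 0L) return(F)
  S <- rowsum(contrib, group = idx)          # groups in sorted order
  rows <- sort.int(unique(idx))              # same order, no string parsing
  F[rows, ] <- F[rows, ] + S
  F
}
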