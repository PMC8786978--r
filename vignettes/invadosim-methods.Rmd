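---
title: "invadosim: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{invadosim: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(invadosim)
```

## The model

`invadosim` simulates a cancer cell pushing invadopodia — actin-rich membrane
protrusions — into a three-dimensional collagen type 1 fiber network.  Three
coupled subsystems are evolved together:

1. **Cell mechanics.**  Five closed triangulated surfaces — the invadopodial
   membrane (CI), force transduction layer (CT, 50 nm inside it), actin
   cortex layer (CC, another 50 nm inside), and a double nuclear envelope
   (perinuclear actin layer, PAL, and nuclear membrane surface, NMS) — plus a
   discrete branched actin network.  Every line element is a Kelvin–Voigt
   unit: a linear spring in parallel with a dashpot.  Membrane layers carry
   edge-spring energy $\tfrac{\kappa_L}{2}\sum_i (L_i-L_i^0)^2$ and an
   area-strain energy $\tfrac{\kappa_A}{2}\sum_i ((A_i-A_i^0)/A_i^0)^2
   A_i^0$; actin filaments carry axial energy with per-segment stiffness
   $\kappa_{L,j} = A_A E_A / L_j^0$ ($E_A$ = 1.8 GPa, $A_A = \pi r_A^2$ =
   38.48 nm², so 0.46 N/m at the initial 150-nm discretization) and a
   discrete bending energy $\tfrac{\kappa_b}{2}\sum_j \theta_j^2/L_j^0$ with
   $\kappa_b = E_A I_A$.  Arp2/3 branches add a connector spring (0.01 N/m,
   rest 30 nm), a branch-angle term with 70° equilibrium, and a dihedral
   term.  All forces are exact analytic gradients of these energies
   (virtual-work forces); the test-suite verifies every term against
   central-difference gradients to below $10^{-6}$ relative error.

2. **ECM mechanics and adhesion.**  Collagen fibers are straight node chains
   (0.5-µm elements, 41-nm diameter) with the same stretch/bend mechanics,
   crosslinked by junction springs where fibers touch.  Integrin
   adhesions follow Bell kinetics: the per-node bond count obeys
   $dn_b/dt = k_{on}(n_{tot}-n_b) - k_{off}n_b$ with a Gaussian-in-extension
   association rate (harmonic-well partition function with the error
   function) and the slip-bond dissociation rate
   $k_{off} = k_{off}^0\exp[\kappa_{LR}(L_b-\lambda)x_b/k_BT]$, intrinsic
   force scale $k_BT/x_b \approx 200$ pN.  The focal-complex force
   $n_b\,\kappa_{LR}(L_b-\lambda)$ acts on the membrane node with its
   reaction on the fiber — the route by which the cell remodels the matrix.

3. **Reaction–diffusion chemistry.**  Six normalized species on a regular
   grid (0.5-µm spacing): MMP-2 ($\phi_1$), TIMP-2 ($\phi_2$), MT1-MMP
   ($\phi_3$), the ternary MT1-MMP:TIMP-2:proMMP-2 complex ($\phi_4$),
   ligand ($\phi_5$) and ECM ($\phi_6$).  $\phi_1,\phi_2,\phi_5$ diffuse
   (7-point stencil, zero-flux boundaries); $\phi_3,\phi_4,\phi_6$ are
   immobile.  MT1-MMP and TIMP-2 are secreted at invadopodium-tip grid
   nodes, only during the protrusive phase, at rates proportional to the
   local ligand concentration; ECM is degraded by
   $-k^{deg}\phi_1\phi_6$, which also releases ligand.  A fiber element is
   retired (irreversibly, exerting no further force and accepting no bonds)
   once the local $\phi_6$ falls below 20% of its initial value.

The protrusion cycle has three phases: **protrusive** (barbed ends grow at
20 nm/s free, or with the load-dependent law
$v_g = v_0\exp(-f_{cortex}/(n_F f_0))$, $v_0$ = 50 nm/s, $f_0$ = 20 pN;
Brownian-ratchet forces $F_p\log(v_0/\|\hat n\cdot(v_b-v_a)\|)$ push the
cortex; MT1-MMP secretion on), **retractile** (barbed ends force-capped;
α-actinin and bipolar myosin minifilaments engage perinuclear filament
pairs; myosin slides toward both barbed ends at the Hill force–velocity
rate $v = v_0(F_{stall}-F)/(F_{stall}+c_m F)$, $v_0$ = 160 nm/s,
$F_{stall}$ = 1.24 nN, $c_m$ = 4.761), and **severing** (buckled filaments
— end-to-end distance below 0.9 of contour — are cut into ≤300-nm pieces
that depolymerize in parallel at 10 nm/s).  A barbed end follows the
seven-state lifecycle: nucleated → growth → adhesion (cortex gap below
100 nm) → detach (adhesion tension above 20 pN) → ratchet, with stochastic
capping at 0.3 s⁻¹, forced capping of tip filaments at the protrusive-phase
end, and uncapping at the next protrusive phase.

## Integration

Nodal dynamics are overdamped: the velocity of each node is the quotient of
its total force (plus the dissipated-force lag term built from the
previous step's neighbor velocities through the Kelvin–Voigt pair dashpots)
and the sum of its drag coefficients.  These explicit quotients are advanced
inside an adaptive step-doubling controller: each trial step is computed
once at $\Delta t$ and twice at $\Delta t/2$; the half-step result is
accepted when the maximum nodal discrepancy, measured against the 10-µm
cell scale, is below the $10^{-4}$ tolerance, otherwise the step is halved.
Lagged velocities are zero at birth and warm-started after every
discrete-event boundary so the controller does not pay a first-order
transient.  Discrete chemistry and topology (lifecycle transitions,
nucleation, capping, linker placement and turnover, myosin sliding, bond
kinetics, reaction–diffusion sub-stepping, fiber degradation,
split/merge of filament segments) fire on a fixed 0.5-s control grid;
binding sweeps run at a 1-s cadence.  Rest-length growth and shrinkage are
applied continuously inside the integration sub-steps rather than as
impulses at control boundaries — polymerization forcing is smooth, which
the step-size controller rewards.  The reaction–diffusion field is
sub-cycled within each control interval at the explicit diffusion
stability bound $h^2/(6\max D)$.

## Parameters and unit conventions

Lengths are in nm, forces in pN, time in s; 1 pN/nm = $10^{-3}$ N/m and
1 pN/nm² = 1 MPa.  All published constants are converted once in
`invadosim_params()`.  Choices worth noting:

* **Membrane area stiffness.**  The printed value $1.0\times10^{-4}$ is
  dimensionally inconsistent with the area-strain energy it accompanies
  (that energy form requires N/m, i.e. surface-tension units).  We keep the
  printed number and read it in N/m; the area term is in any case a weak
  regularizer next to the edge springs.
* **PAL–NMS coupling.**  No stiffness is published for the nuclear-envelope
  pair; the two layers are linked index-wise by 50-nm vertical springs
  reusing the cortex coupling value ($1.0\times10^{-2}$ N/m).
* **Dissipation coefficients** are free parameters chosen so the system is
  overdamped and stable at working step sizes of $10^{-3}$–$10^{-2}$ s.
  Weight is deliberately placed on the ground (cytosol) drag rather than
  the pair dashpots: the pair dashpots enter the explicit scheme through
  lagged neighbor velocities, and large pair/ground ratios degrade the
  step-doubling error estimate.  Actin and ECM carry larger drags than the
  membranes because their line elements are three orders of magnitude
  stiffer.
* **Segment management.**  Filament segments split above 300 nm and merge
  below 75 nm.  The merge threshold bounds the $1/L_0$ effective stiffness
  (a fully depolymerized pointed segment would otherwise become arbitrarily
  stiff); single-segment filaments are retired once consumed below half the
  merge threshold.
* **Branch moduli.**  The angular and dihedral branch moduli are not
  published numerically; the default is 1 pN·nm per nm of Arp2/3 rest
  length (30 pN·nm²), configurable.  The dihedral is undefined when the
  Arp connector is collinear with either filament — exactly the geometry a
  fresh daughter is born in — so dihedral terms are skipped (and counted)
  while the spanning angle is below ~3°, and all angle gradients carry a
  sine floor of $10^{-3}$.
* **Ratchet clamp.**  The logarithmic ratchet force diverges at zero
  relative speed and turns negative above $v_0$; it is clamped to
  [0, 100 pN].
* **Myosin stall.**  The stall force is printed with an ambiguous unit
  ("1.24 Nn"); it is read as 1.24 nN, consistent with a ~100-head
  minifilament of ~10-pN heads.
* **Nucleation bookkeeping.**  The nucleation rate (50 s⁻¹) is read as a
  cell-wide Poisson rate distributed uniformly over eligible mother
  segments in the leading-edge cone (the per-entity basis is not
  published).
* **Crosslinker geometry.**  Fascin and filamin rest lengths default to 40
  and 150 nm; "parallel" means a mutual angle below 20°, filamin also
  accepts 70–110° pairs; candidate pairs bind with probability 0.1 per 1-s
  sweep within ±50% of the rest length, at most one linker of a kind per
  segment (which bounds the crosslinker population by the segment count).
  Turnover removes linkers after 60 s; rebinding is allowed.
* **Bell kinetics defaults.**  $k_{off}^0$ = 0.05 s⁻¹ (the measured
  α-actinin/actin rupture scale), $n_{tot}$ = 50 integrins per membrane
  node.  A focal complex opens when the membrane-to-fiber-surface gap
  (center distance minus the 20.5-nm fiber radius) is within the 30-nm
  binding radius of the 30-nm bond rest length; the bond length entering
  the force and the rates is likewise measured to the fiber surface.
* **Reaction–diffusion constants** are unpublished in the main text; the
  defaults are dimensionless-stable magnitudes ($k\phi\,\Delta t \ll 1$).
  As printed, the ternary-complex equation contains the autocatalytic
  production $+k^{on}_{\phi_3:\phi_4}\phi_3\phi_4$; that constant is kept
  well below the complex dissociation rate so the system stays bounded.
  The secretion terms multiply the local ligand concentration, so a ligand
  initial condition of zero would silence secretion forever; the ligand
  field is therefore initialized at 1 throughout the domain.
* **ECM generation.**  Fibers are seeded sequentially with random
  orientations, each nucleated through a point within one fiber diameter
  of the existing network; this mimics fibril bundling during collagen
  polymerization and guarantees a single connected component, which
  independently seeded lines at a 3-µm pore size would not give.  The
  fiber count is iterated until the measured mean pore size (twice the mean
  sampling-grid distance to the nearest fiber) is within 5% of target if
  possible, 15% at worst.
* **Collagen modulus calibration.**  The fiber Young's modulus is not
  published; it is calibrated once (scripts/calibrate_ecm.R) so that the
  simulated volumetric stretch test on the standard network (pore 3.0 µm,
  41-nm fibers, 16-µm cube) reproduces the 2,558 Pa network bulk modulus.
  Because the relaxed configuration is invariant under uniform stiffness
  scaling, the bulk modulus is exactly linear in the fiber modulus and the
  calibration is a single division: the default ships as 200 MPa, squarely
  in the measured range for hydrated collagen fibrils.  Network-to-network
  (seed) variability of the measured modulus is about 10%.

## The stretch test

`bulk_modulus_stretch_test()` pins the boundary nodes of a generated
network at affine images under small volumetric strains (linear strains
±1%, ±2% per axis), relaxes the interior to mechanical equilibrium with
L-BFGS-B on the elastic energy (analytic gradients), records the boundary
stress as the virial of the pinned-node reactions,
$\sigma = -\tfrac{1}{3V}\sum_b F_b\cdot(x_b - x_c)$, and reports the slope
of stress against volumetric strain in Pa.

## The miniature fixtures and what they do (and do not) show

`make_fixture()` builds reduced-scale study systems that exercise every
module in seconds: a 2.5-µm cell (icosphere level 1) in a 9-µm ECM patch
with a 1.5-µm pore, 30 + 8 filaments, short phase cycles, and chemistry
accelerated so that a ~10-s protrusive phase degrades nearby matrix the
way a 240-s phase does at full scale (faster MMP-2 activation and
degradation constants, nucleation scaled to the miniature filament count,
radial filaments seeded within the leading-edge cone — a miniature of the
invadopodium core rather than of the whole cell).  At this scale the
protrusion machinery moves the tip by nanometres to tens of nanometres per
cycle, not the micrometres of the full-scale model, because a handful of
20–100-pN pushers work against the cortex elasticity.  Fixture-based tests
therefore assert *orderings and trends* — tip advance increasing with
protrusive duration, knockouts reducing advance, degradation absent under
MT1-MMP knockout — never absolute magnitudes.  Passing them shows the
coupled machinery transduces forces and chemistry in the right directions;
it does not validate quantitative full-scale behavior, which requires runs
at the published population sizes (500–3000 filaments, hours of simulated
time).

## Known limitations

* The membrane topology is fixed; very narrow protrusions that would
  require remeshing cannot form.
* The explicit integrator pays a first-order accuracy penalty through the
  lagged dissipation terms; the step controller compensates with small
  steps after discrete events.
* Volume exclusion and the cortex-gap test use the nearest-node tangent
  plane; at coarse subdivisions the surface between nodes is approximated.
* Crosslinker unbinding is a fixed turnover time, not load-dependent.
* Concentrations are normalized (dimensionless); only ratios of the
  reaction-diffusion constants are meaningful.
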