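---
title: "memfield: models, numerics and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{memfield: models, numerics and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memfield)
```

This vignette is the package's own account of what it computes, which
knobs matter, what the synthetic-data generators do and do not emulate, and
where genuinely open design choices were resolved.

## 1. The mean-field adsorption model

A peripheral protein such as a StarT-domain sterol transporter is treated
as a rigid set of fixed partial charges in an ionic solution above a planar
membrane. The membrane is a two-dimensional charged surface at $z = 0$:
its neutral lipids (PC, PE, cholesterol) form an inert background, while
the anionic species (PS at $-1\,e$, or a bis-phosphorylated
phosphoinositide at $-4\,e$ per headgroup) is laterally mobile, described
by an area-fraction field $\phi(x, y)$ on a lattice of sites. The surface
charge density is $\sigma = z_l e\,\phi/a$ with $a$ the area per lipid
(default $65\ \mathrm{\AA^2}$).

The potential (reduced units $\tilde\psi = e\psi/k_BT$) obeys the
linearized Poisson–Boltzmann (Debye–Hückel) equation in the half-space
above the membrane,
$$\nabla^2\tilde\psi - \tilde\psi/\lambda^2 = -4\pi l_B \rho_z,$$
with Bjerrum length $l_B$ and Debye length
$\lambda = \sqrt{\varepsilon_0\varepsilon_r k_B T / (2 N_A e^2 I)}$
($8.09\ \mathrm{\AA}$ at $I = 0.15$ M, $T = 310$ K,
$\varepsilon_r = 80$ — `debye_length()`). The membrane is impermeable:
ions exist only at $z > 0$, and the surface charge enters through the flux
condition $\partial_z\tilde\psi|_{0^+} = -4\pi l_B \tilde\sigma$.

The free energy balanced by the lipid redistribution is
$$F = F_{el} + F_{ion} + F_{lip},$$
with $F_{el}$ the electrostatic field energy, $F_{ion}$ the
translational-entropy penalty of the mobile ions (to second order
$k_BTc_0\int\tilde\psi^2\,dV$, the form consistent with the linearized ion
profiles $c_\pm = c_0(1 \mp \tilde\psi)$), and the lattice-gas mixing
entropy
$$F_{lip} = \frac{k_BT}{a}\int\big[\phi\ln\phi + (1-\phi)\ln(1-\phi)\big]\,dA.$$
At fixed potential the constrained minimizer of $F$ over $\phi$ is the
Langmuir relation
$$\frac{\phi'}{1-\phi'} = e^{-(z_l\tilde\psi - \mu)},$$
with the chemical potential $\mu$ set so the total anionic amount is
conserved (`langmuir_update()`, conservation to the rounding floor). The
self-consistency loop alternates field solves with damped Langmuir updates
until $\phi$ is a fixed point.

**Assumptions worth stating.** Uniform dielectric
($\varepsilon_r = 80$ everywhere — no low-dielectric protein cavity); this
is what makes the printed $\lambda$ exactly reproducible and matches the
smooth-charged-surface abstraction of the membrane. Linearized ions: the
single reported screening length is the signature of the linear regime; a
nonlinear-Boltzmann option is config-gated (`nonlinear_ions`) but
deliberately not implemented. Protein rigidity during the scan. Charges
default to a coarse rule (Arg/Lys $+1$ on the terminal sidechain N-group
center, Asp/Glu $-1$ split over the carboxylate oxygens, His 0) because no
charge set is part of the model's definition; a CSV charge table or a
PQR-style column overrides it.

## 2. The numerical scheme

Three choices differ from the most naive discretization, each forced by a
measurable failure of the simpler option.

**Direct solve instead of relaxation.** The lateral directions are
periodic (an infinite membrane), so the grid operator diagonalizes by
lateral FFT into independent tridiagonal systems in $z$, solved exactly by
a Thomas sweep. There are no iteration-order effects and no convergence
parameters for the linear solve. Periodic lateral boundaries are also what
make a uniform membrane exactly self-consistent — with lateral Dirichlet
walls a uniform $\phi$ is not a fixed point near the walls and the
protein-at-infinity reference loses its meaning.

**Compact fourth-order operator with exponentially fitted screening.**
A plain 7-point Laplacian at the standard resolution $h = \lambda/2$
mis-screens by 3–4% at $r = 4\lambda$ (lattice dispersion), which is
outside the 2% agreement we demand against the closed forms. The
19-point compact (Mehrstellen) operator with the screening mass fitted to
$2[\cosh(h/\lambda) - 1]/h^2$ reproduces the one-dimensional Gouy–Chapman
profile $\tilde\psi(z) = 4\pi l_B\tilde\sigma\lambda\,e^{-z/\lambda}$ to
machine precision and keeps the point-charge field within 2% everywhere in
$\lambda \le r \le 4\lambda$, with a per-mode flux factor making the
surface boundary condition exact for pure decay modes.

**Singularity splitting.** Protein point charges are never put on the
grid: their free-space screened-Coulomb (Yukawa) field
$l_B z_i e^{-r/\lambda}/r$ is analytic, and the grid carries only the
smooth remainder — the membrane charge and the flux correction that builds
the protein's image response in the impermeable wall. Consequences: no
grid self-energy, so adsorption energies need no sub-grid alignment
tricks; `potential_at()` is accurate arbitrarily close to the charges; and
the genuinely grid-borne part of the solution (the image response) can be
validated against the exact direct-plus-image closed form, where its error
decreases from ~1.8% at $h = \lambda/2$ to ~0.5% at $h = \lambda/4$.

**Free-energy bookkeeping.** Reported components satisfy
$F_{total} = F_{el} + F_{ion} + F_{lip}$ exactly, with $F_{el}$ the field
energy obtained from the equilibrium identity
$F_{el} = \tfrac12\sum q\psi - F_{ion}$. The charging functional
$\tfrac12\sum q\psi + F_{lip}$ is the quantity the density iteration
descends on; counting the protein–membrane cross term once, through the
surface-side path, makes the Langmuir update the *exact* gradient of the
discrete functional. This is what guarantees the observed monotone descent
(to $10^{-14}\,k_BT$ in the tests) — an energy evaluated through a
different numerical path than the update's driving force would stall a few
$10^{-4}\,k_BT$ above the fixed point.

**Reference state.** All docking energies are relative to the
protein-at-infinity, uniform-membrane state: the membrane-only fixed point
reached from uniform $\phi$ (identical to the uniform state whenever the
lipid lattice is commensurate with the solver grid) plus the protein's
translation-invariant pairwise self energy in bulk, including the part of
its screening cloud that the wall excludes. A neutral protein therefore
scores exactly zero in every pose, and any pose farther than
$\sim 10\lambda$ scores zero within $10^{-4}\,k_BT$.

**Self-consistency iteration.** Damped fixed-point iteration with
backtracking (the free energy never increases) plus depth-1 Anderson
(secant) acceleration, whose mixing weights sum to one so the anionic
amount stays conserved; accelerated steps are accepted only if they keep
$\phi$ strictly inside $(0,1)$ and decrease $F$. For a PS membrane the
loop converges in $\sim$20 iterations; for the $-4\,e$ phosphoinositide
the coupling is stiff (sites saturate) and several hundred iterations are
normal — the default `max_iter` (1000) and `phi_tol` ($10^{-9}$, i.e.
fixed-point residuals well under the $10^{-8}$ we assert) reflect that.

**Tunable parameters.** `box_edge_A` (256), `grid_points` (64, giving
$h = 4\ \mathrm{\AA} \approx \lambda/2$; a warning fires when
$h > \lambda/2$), `ionic_strength_M` (0.15), `temperature_K` (310),
`relative_permittivity` (80), `area_per_lipid_A2` (65), `clearance_A` (2 —
every atom at least this high in a scan pose), `n_directions` ×
`n_azimuths` (72 × 12), `mixing` (0.5, the initial damping). Anionic
headgroup charge defaults: PS $-1$, PIP₂ $-4$ (the common assignment near
pH 7.2); both are fields of the species table, not constants.

## 3. Trajectory analytics

**Orientation.** The membrane plane is a least-squares (principal
component) fit through upper-leaflet phosphate positions, outward normal
toward the protein. The helix axis uses the rotation-axis construction
(cross products of successive second differences of the CA trace): exact
for an ideal helix, defined from 4 CAs up. Plain PCA of the CA cloud is
available (`method = "pca"`) but is biased by $\sim0.1^\circ$ for
non-integer turn counts, which would swamp the $10^{-6}$-degree recovery
we require of the generator/analyzer round trip. *Tilt* is measured from
the outward normal — $0^\circ$ means the helix points away from the
membrane, larger tilt means it leans down toward the plane. *Rotation* is
the signed angle about the helix axis from the projected normal to the
projected reference-selection centroid (default: the Ω1 loop); it is
undefined when the axis is parallel to the normal and reported as 0 with a
degeneracy flag. Orientation maps are plain normalized 2D histograms.

**Contacts.** A lipid binds a residue when any of its headgroup oxygens
lies within 4.0 Å (inclusive — boundary unit tests pin `<=`) of any
sidechain N/O atom of the residue; backbone atoms are excluded. Default
atom lists cover Arg (NE/NH1/NH2), Lys (NZ), Ser (OG), His, the PS and
PIP₂ phosphate/inositol oxygens, and the single-oxygen fixture beads.
Probabilities are fractions of frames (also reported as % occurrence);
multiplicity counts distinct lipid molecules; a shared-site probability is
the fraction of frames in which one lipid simultaneously engages both
residues of a pair (the R46/R58 groove geometry, where R58 is occluded and
every lipid it binds is shared with R46, is the motivating case).
Replicas are pooled with equal frame weights, not averaged per replica.

**Embedding.** Buried contact area is half the solvent-accessible surface
area lost on forming the complex, $(A_P + A_M - A_{PM})/2$, from a
deterministic Shrake–Rupley implementation (golden-spiral points, probe
1.4 Å, 960 points/atom, bundled element radii). A frame is
membrane-embedded iff the Ω1-loop area exceeds 200 Å² *and* the
β-sheet/C-term-helix area exceeds 150 Å², both strictly; there is no
hysteresis or persistence requirement. The analysis window keeps the last
720 ns; frames strictly after $t_{end} - 720$ ns are retained, with one
documented convention: a trajectory whose duration equals the window
exactly keeps all its frames (the two natural readings of the boundary
conflict only in that measure-zero case).

## 4. Transfer kinetics

FRET traces are fit by a single exponential with endpoint/log-linear
initialization and Gauss–Newton refinement (strictest convergence
tolerance first, relaxed stepwise for noisy traces whose relative-offset
criterion bottoms out at the rounding floor); standard errors are the
asymptotic values from the fit covariance. The fitted rate constant
converts to a transport rate by the initial-rate convention
$$\mathrm{rate} = k \cdot f_{eq} \cdot [\mathrm{DHE}]_0 /
[\mathrm{transporter}],$$
molecules per transporter per minute. $f_{eq}$ is the fraction of the
sterol pool on acceptor membranes at equilibrium; 0.5 is the natural
default for equal donor and acceptor lipid amounts and is configurable,
since the published quantifications defer this constant to their methods
references. With $k = 0.6087\ \mathrm{min}^{-1}$, 23 µM DHE and 1 µM
transporter this gives 7.0 molecules/min, the magnitude of the
PS-control assay. Fold changes propagate uncertainty to first order.
Replicates are fit independently and summarized as mean ± SE.

## 5. What the synthetic generators do (and do not) emulate

`make_bilayer()` allocates per-leaflet species counts by largest-remainder
(Hamilton) rounding — deterministic and fraction-faithful, so the default
200-site leaflet at 44:23:23:10 gives exactly 88/46/46/20 and a 400-lipid
symmetric bilayer — and scatters species over the lattice under a seed.
`make_bead_protein()` builds an ideal CA helix (rise 1.5 Å/residue, twist
100°, radius 2.3 Å, residues 203–224 by default), an Ω1-loop and a
β-sheet bead cluster, and named charged sites (R46, R58, S215, R218) at
mutually spaced offsets. `make_trajectory()` poses that protein at
scheduled (tilt, rotation) — computed with the same conventions the
analyzer measures, so round trips are exact — and realizes binding plans
by moving single-oxygen headgroup beads to 3.5 Å (bound) or 5.5 Å
(unbound) from the named residues' polar atoms, comfortably clear of the
4.0 Å criterion on both sides; the protein floats 8 Å above the plane so
no unplanned contact is possible. Orientation schedules support fixed
lists, reflected/wrapped Gaussians and two-component mixtures (to emulate
bimodal orientation maps without claiming their values).

These fixtures have no acyl chains, no realistic lipid packing, no forces
and no thermal motion. A green round-trip test therefore establishes that
the *bookkeeping* — angle conventions, criterion boundaries, probability
aggregation, windowing, file IO — is exact, and nothing about whether a
real force field would produce such configurations. Likewise the
mean-field tests establish agreement with the model's own closed forms and
variational structure, not the accuracy of the mean-field abstraction
itself. Published per-residue binding probabilities and orientation maps
derive from tens of microseconds of all-atom sampling and are explicitly
out of reach at desk scale; the package reproduces the printed
desk-recomputable quantities (screening length, composition bookkeeping,
aggregate sampling arithmetic, rate conversion) and validates everything
else by construction oracles.

## 6. Degenerate inputs and tie-breaking

Collinear plane fits, sub-4-CA helices, empty trajectories, constant FRET
traces, zero density maps, and over-concentrated placement maps
(a site whose inclusion probability would exceed 1) are errors with
specific messages. Orientation-scan ties are broken by (direction index,
azimuth) for determinism; poses whose relaxation fails are flagged,
excluded from the ranking and kept in the output table. Anionic placement
uses systematic probability-proportional-to-size sampling, so inclusion
probabilities are exactly proportional to the density map — the property
the goodness-of-fit test relies on — while drawing exactly the requested
number of distinct sites under a seed.

## 7. Known limitations

- The mean-field stage is strictly linear-response; strongly charged
  surfaces (high PIP₂ fractions) push $|\tilde\psi|$ past 1 near the
  plane, where the linearized ion profiles are a documented approximation.
- The membrane is rigid and flat: no curvature, deformation energetics, or
  protein-induced remodeling.
- One mobile anionic species at a time; mixed PS/PIP competition is not
  modeled.
- The PDB reader covers the fixed-width ATOM/HETATM subset the package
  writes (plus 4-character residue names in columns 18–21); exotic PDB
  features (altLocs, insertion codes) are ignored.
- SASA is cutoff-free Shrake–Rupley in pure R: adequate for bead fixtures
  and small selections, not tuned for $10^5$-atom systems.
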