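---
title: "Mesoscale models of polymer-linked nanobody dimers: methods and design choices"
author: "diabodysim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesoscale models of polymer-linked nanobody dimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The system and the question

A *diabody* is a pair of nanobodies (single-domain antibody fragments)
joined by a flexible polymer linker, e.g. (Gly4Ser)n or PEG.  When one
nanobody is bound to an epitope on a surface, the second one explores the
neighbourhood of the wall, and the kinetics of its encounters with the
surface governs the cooperative affinity gain (avidity) of bivalent
binding.  `diabodysim` provides the full mesoscale tool chain for this
problem:

* coarse-grained model building (`buildSphDiabody()`, `buildSbcgDiabody()`),
* equilibrium and dynamical sampling (`sampleEquilibriumMC()`,
  `runTrajectory()`),
* free-energy profiles along collective variables by umbrella sampling and
  WHAM (`runUmbrella()`, `wham()`),
* flight/residence decomposition of paratope trajectories and the
  survival-probability estimators of the second-binding rate constants
  (`decomposeEvents()`, `ratesFromSurvival()`),
* analytic tethered Gaussian-polymer references (`tetheredEndPdf()`,
  `tailConstantsTheory()`, `fitEffectiveNk()`).

## Units

Everything is expressed in reduced Lennard-Jones units: the unit of length
is one linker monomer, $\sigma = 3.5$ Å; energies are expressed in $k_BT$
(the underlying LJ energy unit is $\epsilon = 100$ K, so at room
temperature $k_BT = 3\epsilon$; `unitSystem()` records both); times are in
Brownian units $\tau_B = \gamma\sigma^2/k_BT$ of a unit-diameter bead.  No
mapping from $\tau_B$ to nanoseconds is claimed anywhere: all kinetic output
is dimensionless or in $\tau_B$, because such a mapping would require a
physical friction constant that is not part of the model.

## The two coarse-grained representations

**SPH.** Each nanobody is a rigid sphere of diameter $10\sigma$ decorated
with a connector bead (diameter 1) and a paratope bead (diameter 1.6) at
diametrically opposite poles; sphere + connector + paratope move as one
rigid body.  Pole beads are placed at tangent contact (centre distance =
sphere radius + bead radius); the alternative, half-embedded placement
changes tethered-geometry observables by well under a bead radius.

**SBCG.** Each nanobody is a shape-based coarse-grained network of ~40
beads obtained from a topology-representing neural-gas map of the residue
coordinates (`buildSbcgNanobody()`): bead positions are converged codebook
vectors, bead masses are the summed masses of the points in each Voronoi
domain, radii follow the mass-proportional volume rule
$r_i = 0.5\,\sigma\,(m_i/m_\mathrm{ref})^{1/3}$ against a PEG monomer
(44 Da), and the network is wired from supplied point-level connectivity
when available, else from the competitive-Hebbian rule (first and second
best-matching units).  Intra-body WCA repulsion preserves the shape.  Since
no protein structure ships with the package, `syntheticNanobodyCloud()`
provides a synthetic 126-point ellipsoidal cloud whose axes bracket the
$10\sigma$ SPH diameter; real input enters through `readPdbCoords()`.

**Linker.** A freely-jointed bead-spring chain of N unit beads: harmonic
bonds at $r_0 = 1\sigma$ with $k_b = 1597\,k_BT/\sigma^2$ (54 N/m converted
at 300 K in the $\frac12 k(r-r_0)^2$ convention; bond-length fluctuations
~2.5%), harmonic bending at $\theta_0 = 180^\circ$, and WCA excluded
volume.

### The bending coefficient

The bending coefficient deserves a note.  The engine convention here is
$V = \frac12 k_\theta (\theta - \theta_0)^2$ with $k_\theta$ in $k_BT$.
The package default is `kTheta = 1.2`, i.e. a bending weight of
$0.6\,k_BT\,\varphi^2$ per joint.  This value is chosen so that the chain's
local persistence length is $\ell_p \approx 1.5\sigma$ (Kuhn length
$b = 2\ell_p = 3\sigma$), the stiffness scale of the PEG-like linkers these
models target: it corresponds to reading the conventional coefficient
"1.8" as a LAMMPS-style angle constant in LJ energy units
($1.8\,\epsilon = 0.6\,k_BT$ at room temperature, no $\frac12$).  Reading
the same number as $1.8\,k_BT$ in the $\frac12 k$ convention gives a
noticeably stiffer chain ($\ell_p \approx 2\sigma$ by exact transfer-matrix
evaluation of $\langle\cos\varphi\rangle$), inconsistent with
$b = 3\sigma$.  `buildLinker(kTheta = )` exposes the choice.

### Persistence-length estimation

`persistenceLength()` fits $\langle u_i\cdot u_{i+s}\rangle =
e^{-s b_0/\ell_p}$ by weighted log-linear regression through the origin.
The persistence length is a *local* property: for a self-avoiding chain the
bond correlation is exponential only at short contour separations and
crosses over to a slower, swelling-dominated decay, so the fit uses only
separations with $C(s) \ge e^{-1}$ (at least two).  Fitting far into the
tail (e.g. 15 bonds) returns a swollen effective value ~30% larger, which
is a statement about excluded volume, not about local stiffness.

## Walls, tether and restraints

The box is periodic in x and y; the z walls are LJ 12-6 surfaces acting on
each bead's centre with per-bead parameters (`wallSetTable()`): cut at
$2^{1/6}s_\mathrm{wall}$ they are purely repulsive (WCA), cut at
$2.5\,s_\mathrm{wall}$ attractive with well depth 1.5 or 2.5 $k_BT$
(nanobody and paratope beads only; linker and connector beads always see a
repulsive $s = 0.8\sigma$ wall).  For the SPH nanobody $s_\mathrm{wall}$
(4.5 or 3.0 $\sigma$) is smaller than the sphere radius, so the sphere can
partially sink into the wall — this is deliberate, as it controls how much
the tethered unit can bend.  SBCG nanobody beads see the wall individually
with $s = 0.8\sigma$, which is what lets the flexible body approach the
wall much more closely than the sphere.  All truncated LJ terms (pairs,
walls, tether) are energy-shifted to zero at their cutoff so that the
Metropolis sampler sees a continuous energy; an unshifted truncation would
insert a spurious $-\epsilon$ step at the cutoff and corrupt the Boltzmann
measure (the unshifted form is available via
`wallPotential(shifted = FALSE)`).

The molecule is tethered by a deep attractive LJ well (20 $k_BT$, range
$2.5\,s$) between the paratope P2 and a fixed epitope bead on the lower
wall; at this depth no detachment occurs at thermal energies.  Straightening
restraints ($\theta_0 = 180^\circ$, ten times the linker bending constant)
keep the linker take-off aligned with each nanobody's polar axis, and for
the SBCG model one harmonic dihedral per nanobody (10 $k_BT/\mathrm{rad}^2$)
prevents rotation about its long axis.

Default box: $L_x = L_y = 5(N+12)\sigma$, $L_z = 2(N+12)\sigma$ — wide
enough that periodic images never interact and tall enough that the upper
(container) wall is not visited at equilibrium.

## Samplers

**Brownian dynamics.** Overdamped Langevin with the Leimkuhler–Matthews
(BAOAB-limit) update: the noise added per step is the average of the
current and previous Gaussian draws, which gives second-order
configurational accuracy at Euler cost — with a plain Euler–Maruyama step
the steep wall regions are measurably overheated at usable time steps.
Rigid groups translate by their net force and rotate by their net torque
(quaternion update; internal geometry is exact to machine precision).  The
default time step $10^{-4}\tau_B$ resolves the stiff bond; pair and wall
forces are magnitude-capped (500 $k_BT/\sigma$) purely as an integration
safeguard — the capped region starts hundreds of $k_BT$ up the repulsive
core and is never visited at equilibrium.

Two friction models are provided.  `drag = "stokes"` (default) scales bead
drag with diameter and rigid-body rotational drag with diameter cubed.
`drag = "uniform"` gives every bead and body unit drag; it exists because
with Stokes drag the $10\sigma$ sphere's rotational time is
$\mathcal{O}(300\,\tau_B)$ and wall-visit statistics at desk scale become
unaffordable, while every *dimensionless* kinetic quantity studied here
(short-time exponents, flight/residence ratios, trends across linker
length and wall attraction) is friction-independent.  Absolute rates are
reported in $\tau_B$ of whichever model was used, with no physical-time
claim.

**Monte Carlo.** Metropolis sampling of the same Boltzmann measure with a
move mixture: single-bead displacements, rigid-group translations and
rotations, crankshaft rotations of chain beads, pivot rotations of the
chain tail, and — for tethered systems — a global tilt move that rotates
every mobile bead about the fixed epitope.  The tilt move is what makes
equilibrium sampling of the tethered assembly practical: its slowest
physical mode is the collective tilt about the anchor, which local moves
relax only over thousands of sweeps.  All proposals are symmetric, so
detailed balance holds by construction.  Equilibrium observables of
tethered diabodies (height distributions, effective-polymer fits) use the
MC sampler; kinetics uses Brownian dynamics, with replica ensembles
(`runKineticsReplicas()`) whose starting configurations are drawn by MC so
that the slow tilt mode is sampled through the initial conditions — the
same role the 5x5 lattice of non-interacting tethered copies plays in a
single large simulation.

## Umbrella sampling and WHAM

The collective variables are $\rho_z$ (height of the centre of mass of the
free nanobody above the tethering wall) and $\rho_{xy}$ (in-plane distance
from the tethering point to that centre of mass, sampled with $\rho_z$
restrained, default $50\,k_BT/\sigma^2$ at $5\sigma$).  Windows are laid on
an inclusive arithmetic grid (`generateWindows()`; $0.5\sigma$ spacing is
the production default), starting structures are generated by dragging the
system from window to window with a stiff bias, and each window is sampled
by MC under a harmonic bias (default $10\,k_BT/\sigma^2$) with the series
subsampled at its integrated autocorrelation time.  `wham()` iterates the
standard self-consistent equations to $10^{-7}\,k_BT$ on the window free
energies (bin width $0.25\sigma$), aborts with a diagnostic if the pooled
histogram has an interior gap, and returns the PMF shifted to zero at its
minimum with Poisson per-bin uncertainties.  `pmfFlatMetric()` reports the
mean normalized coordinate over the region within 1 $k_BT$ of the minimum
and the extent of that region — the flatness measure used to compare
models.

## Flight/residence kinetics

The z series of the free paratope P1 is split at a threshold
$z_0 = 3.5\sigma$ into flights ($z \ge z_0$) and residences ($z < z_0$).
Stretches shorter than a minimum duration are *absorbed into the enclosing
event* (shortest first), which removes rapid recrossings while preserving
strict alternation and total duration; events truncated by the trajectory
ends are censored and excluded from means.  The survival curves
$S_f, S_r$ are empirical complementary cumulatives; their exact integrals
equal the mean durations, and $k_{on} = 1/\langle t_f\rangle$,
$k_{off} = 1/\langle t_r\rangle$ with bootstrap errors.  The short-time
regime of $S_f$ follows the $t^{-1/2}$ law of free diffusive recrossing
(`fitShorttimePowerlaw()`, with a log-log curvature diagnostic that flags
non-power-law data), while the tails are exponential
(`fitExponentialTail()`; the reported confidence interval uses the number
of surviving tail events as the effective sample size, since
survival-curve points are serially correlated).  The analytic counterparts
$\tau_f = \Delta t_c/P_<$, $\tau_r = \Delta t_c/P_>$ and the geometric
run-length laws are in `tailConstantsTheory()` and
`runLengthDistribution()`; $\Delta t_c$ defaults to the integrated
autocorrelation time of the below-threshold indicator when not supplied.

## The tethered-Gaussian reference and effective-polymer fits

`tetheredEndPdf()` implements the reflected-wall (image-construction)
height density of the free end of a Gaussian chain tethered at height
$z_t$, normalized by its erf factor; as $z_t \to 0$ it reduces to
$P(z) = (3z/\langle d^2\rangle) e^{-3z^2/2\langle d^2\rangle}$.
`fitEffectiveNk()` least-squares fits this law to an empirical paratope
height histogram with Kuhn length and tether height fixed, returning the
effective Kuhn-segment number alongside the naive geometric guess
$(N + 2r)/b$.  The gap between the two quantifies how strongly the bulky
end groups and the wall's entropic repulsion stretch the composite
molecule relative to a bare polymer.

## What the synthetic generators do and do not emulate

The built-in generators (`fixtureTwoStateChain()`,
`fixtureOuHeightSeries()`, `fixtureIdealTetheredChain()`,
`fixtureClusterCloud()`) realize exactly the idealized processes the
analysis modules assume: uncorrelated two-state frames, Gaussian
mean-reverting heights, ideal reflected-Gaussian end distributions,
separated mass clusters.  Tests against them validate the estimators, not
the physics of real diabodies: real paratope trajectories have correlated
frames, non-Gaussian near-wall statistics and composite-molecule
corrections that the ideal references deliberately lack — measuring those
deviations is the scientific point of the package.

## Numerical choices and degenerate inputs

* WHAM tolerance $10^{-7}\,k_BT$, bin width $0.25\sigma$, bias spring
  $10\,k_BT/\sigma^2$ — all config keys.
* Angle forces use the analytic $\theta\to\pi$ limit so that straightening
  restraints at $\theta_0 = 180^\circ$ are smooth at their equilibrium.
* A height series exactly equal to the threshold everywhere is rejected as
  degenerate; a single event of a kind yields a rate with an infinite
  error flag; an unnormalized histogram passed to `fitEffectiveNk()` is
  renormalized with a warning; a non-decaying bond correlation returns a
  lower bound on $\ell_p$ with a warning.
* MC move amplitudes (displacement $0.06\sigma$, group translation
  $0.2\sigma$, rotations 0.2–0.5 rad) target 20–70% acceptance for the
  stiff-bond chain; they affect efficiency only, never the sampled
  measure.

## Problem sizes used by the test suite and acceptance script

Equilibrium observables use MC runs of $1.2\times10^5$–$1.5\times10^5$
sweeps (30–40-mer tethered diabodies, seconds to tens of seconds);
persistence length uses a 100-bond chain over $2.4\times10^4$ sweeps;
kinetic quantities pool 3–6 BD replicas of $2.5\times10^6$–$4\times10^6$
steps at $dt = 2\times10^{-4}\tau_B$ with uniform drag; PMF comparisons
use 16–23 windows of ~1200 production sweeps.  These sizes give
convergence adequate for the qualitative and percent-level quantitative
statements made in the tests (means stable across run halves and seeds);
production studies should scale window counts and trajectory lengths up
by an order of magnitude.

## Known limitations

* The wall is flat and rigid; no membrane curvature, deformability or
  surface charge.  No hydrodynamic interactions, no electrostatics, no
  inertial dynamics.
* Binding is represented by a generic deep LJ well, not by
  paratope–epitope chemistry; "residence" means proximity, not a bound
  state.
* The equilibrium tilt of the wall-tethered rigid-sphere unit is governed
  by the isotropic rigid-body orientation measure restricted by the wall;
  with the parameter sets implemented here its mean connector height
  equilibrates near $10\sigma$ (verified independently by MC, BD and
  direct Boltzmann integration of the isolated unit).  Reports of lower
  values for comparable sphere models imply an additional
  orientation-aligning ingredient (or much stiffer effective anchoring)
  that is not part of this package's Hamiltonian.
* Absolute kinetic rates depend on the friction model and are reported in
  $\tau_B$ only.
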