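---
title: "Nanoparticle transport in topologically defined network cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nanoparticle transport in topologically defined network cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellhop)
```

# The physical problem

A hard spherical nanoparticle of diameter $d$ is trapped in a permanently
cross-linked macromolecular network.  The elementary unit of such a network is
a *cell*: a closed cage of strands (edges) meeting at cross-links (vertices).
`cellhop` models a family of cells shaped like Platonic and Archimedean
polyhedra, labelled by their face count $g \in \{4, 6, 8, 12, 20, 32\}$
(tetrahedron through truncated icosahedron), with all strands of equal mesh
size $a_x$, the root-mean-square end-to-end distance of a strand.  $a_x$ is
the length unit; energies are in $k_BT$ and times in the Langevin unit
$\tau$, with particle mass $m = 1$.

Three spheres characterize a cell's geometry: the insphere (radius $r_{in}$,
tangent to the faces), the midsphere ($r_{mid}$, tangent to the edges) and
the circumsphere ($r_{out}$, through the vertices).  They are the critical
particle radii for deforming faces, strands, and cross-links, and define
four confinement regimes for the particle radius $R = d/2$:

* **Regime I**, $R > r_{out}$: the particle dilates the cross-links,
* **Regime II**, $r_{mid} < R < r_{out}$: it deforms strands but not vertices,
* **Regime III**, $r_{in} < R < r_{mid}$: it feels the faces only,
* **Regime IV**, $R < r_{in}$: the cell is invisible to it.

For the regular (Platonic) cells, closed forms give the radii from the face
degree $n$ and dihedral angle $\theta$:
$r_{in} = \tfrac{a_x}{2}\cot(\pi/n)\tan(\theta/2)$,
$r_{mid} = \tfrac{a_x}{2}\cot(\pi/n)\sec(\theta/2)$,
$r_{out} = \tfrac{a_x}{2}\cot(\pi/n)\sqrt{\sec^2(\theta/2) + \tan^2(\pi/n)}$.
`radii_geometric()` recomputes all three directly from the coordinates and is
the authoritative route for the truncated icosahedron, whose two face
classes (pentagons and hexagons) break the single-$(n, \theta)$ assumption.
Note two exact geometric facts that soften the folklore "anisotropy decreases
with $g$": dual pairs (cube/octahedron, dodecahedron/icosahedron) share
$r_{out}/r_{in}$ exactly, and the truncated icosahedron's $r_{mid}/r_{in}$
equals the icosahedron's to seven digits.  The aspheric ratios are therefore
*non-increasing*, not strictly decreasing, across the catalog.

# The free-energy landscape

## Model

The network is a set of Gaussian strands of $N$ bonds with Kuhn length $b$,
$\sqrt{N} b = a_x$, joined at cross-links; a strand between cross-links at
$r_i, r_j$ contributes the entropic-spring energy
$\tfrac{3}{2} k_BT\, |r_i - r_j|^2 / (N b^2)$, and the particle excludes all
network material from a sphere of radius $R$.  The Helmholtz free energy of
the particle-network system at particle position $r$ is
$F(r) = -k_BT \ln Z(r)$ with the partition sum running over cross-link
positions and strand paths outside the sphere.

`cellhop` evaluates $F$ at the **saddle point** of this sum:

1. Each strand's path integral is dominated by its shortest sphere-avoiding
   path.  For endpoints outside the sphere this is either the straight
   segment or the taut tangent-arc-tangent detour, with length
   $L_{geo} = \sqrt{d_a^2 - R^2} + \sqrt{d_b^2 - R^2} + R(\gamma - \alpha - \beta)$,
   giving strand energy $\tfrac{3}{2} L_{geo}^2 / a_x^2$ (the equipartitioned
   discrete chain attains exactly $L_{geo}^2/N$ as its minimal
   sum-of-squares).
2. The cross-links are relaxed by projected gradient descent over this
   energy, with the hard constraint $|r_k - r| \ge R$ enforced by radial
   projection.  Gradients of $L_{geo}$ are analytic (unit tests check them
   against finite differences to $10^{-6}$).

The environment of the cell is its first shell of mirror-image cells, one
per face, whose outer (image-only) cross-links are pinned at their rest
positions; the home cell's cross-links are free.  We experimented with a
second, softer shell: it produces a non-monotone path profile with an
interior maximum, whereas the published profiles for these systems rise
monotonically to the face, so the single-shell boundary is retained.  The
face-center free-energy minimum is transverse: within the face plane the
face centroid is a minimum (tests verify this), while along the path it is
the barrier top.

Two numerical details matter.  First, a perfectly symmetric start is a
*saddle* of the descent: the relaxation therefore applies a fixed,
deterministic symmetry-breaking displacement of amplitude $10^{-3} a_x$
to cold starts.  Second, `mep_profile()` runs three passes over the path
points — cold starts plus forward and backward warm-start continuation — and
keeps the lowest energy per point, eliminating hysteresis between competing
local minima.  The estimator is exactly deterministic; no Monte-Carlo noise
enters the default landscape.

## Strand-fluctuation entropy

The survival probability of a Gaussian bridge against the hard sphere
(`bridge_survival()`, a seeded Brownian-bridge Monte Carlo with a
closed-form $\chi^2_3$ oracle at $N = 2$) quantifies the fluctuation entropy
a strand loses near the particle, and `strand_free_energy()` combines it
with the stretching term.  This term is deliberately **not** added to the
default landscape estimator: evaluating it at the saddle of the energetic
objective is inconsistent (the center and face configurations are relaxed
under a different functional, and the combination can even produce negative
barriers), while the package's own Wang-Landau simulations of the $N = 4$
bead-spring world — the stated accuracy gauge — agree with the pure saddle
estimator to within the Monte-Carlo error scale of $0.3\,k_BT$.

## What the desk-scale model does and does not reproduce

The saddle landscape reproduces, deterministically: a flat profile in
Regime IV ($\Delta F \equiv 0$ exactly), the delayed, "nonconsecutive" rise
of Regime III, the quadratic small-$z$ growth of Regime II (fitted exponent
$\eta = 2.00$), the shrinkage of Regimes II and III with increasing $g$, and
point-group symmetry of the 3-D field.  It is cross-validated pointwise
against Wang-Landau Monte Carlo on the same bead-spring world.

It does **not** reproduce two published magnitudes.  With harmonic vertex
tethers and a single pinned image shell, the cube's barrier saturates near
$2\,k_BT$ for $d > 2 r_{out}$ instead of growing quadratically, and the
outer-half path exponent fits at $\eta \approx 1.5$ rather than 1 (in this
model $\eta \to 1$ only when the pre-contact compression $R - r_{out}$
exceeds the half-path length, which lies outside the feasible range of the
one-shell environment).  Both behaviors are confirmed independently by the
Wang-Landau route, i.e. the theory and the simulation of this model class
agree with each other; the larger published magnitudes must come from
modeling details (far-field stiffness, strand-exclusion resolution) that the
available text does not pin down.  The corresponding acceptance checks are
left failing rather than re-tuned, and the package reports what it computes.

# Wang-Landau Monte Carlo

`wang_landau_profile()` samples a bead-spring realization (`to_bead_network()`,
interior beads at $b = a_x/\sqrt{N}$) with the particle confined to the path
axis.  A penalty $f$ is deposited in the current $z$-bin at every attempt;
moves are accepted with probability
$\min\{1, e^{-\Delta E - \Delta f}\}$, where $\Delta E$ is the spring-energy
change and hard-sphere overlaps reject outright.  When every bin's count
reaches 80% of the mean, $f$ halves and the histogram resets; the run ends
at $f < 10^{-4} k_BT$ (13 stages from $f_0 = 0.5$).  The free energy is the
negative of the accumulated bias, shifted to $F(0) = 0$.  The penalty
increment $f_0 = 0.5\,k_BT$ and the at-least-fifty-runs error protocol follow
the production recipe; the halving schedule and 0.8 flatness are the standard
flat-histogram choices.  A configurational-integral prefactor linear in $z$
can be read into the bias bookkeeping; it would only tilt the profile by a
constant slope and is not treated as a physical field here.

Runs are deterministic given a seed; `multi_run_error()` derives distinct
seeds from a base seed, excludes (and counts) runs that hit the sweep cap,
and reports per-bin means and standard errors.  At the reference settings
(tetrahedron, $N = 4$, $d = a_x$, 32 bins, 50 runs) the maximum standard
error is $\approx 0.06\,k_BT$, comfortably inside the $0.3\,k_BT$ budget.

# Langevin dynamics

`simulate_nle()` integrates the underdamped nonlinear Langevin equation
$m\ddot z = -\Delta F'(z) - \gamma \dot z + \xi(t)$,
$\langle\xi(t)\xi(t')\rangle = 2\gamma k_BT \delta(t - t')$, by
Euler-Maruyama at $\Delta t = 0.01\tau$ with $\gamma/m = 10\,\tau^{-1}$ as
defaults, on the path profile periodized by even reflection
(`periodic_potential()`; period $2 z_{face}$, periodic cubic spline).  The
initial velocity is Maxwellian; trajectories are thinned for storage.  The
production run length is $10^7\tau$; the package default is a scaled-down
$10^5\tau$, and the tests use $10^4$–$3\times10^4\tau$ — every stochastic
tolerance in the tests is set for these scaled lengths.

`diffusion_coefficient()` integrates the velocity autocorrelation (Green-Kubo)
with a decay-based cutoff and cross-checks against half the long-time MSD
slope; at $dt = 0.01\tau$ the Euler-Maruyama discretization bias and the
trapezoidal quadrature bias cancel to well under 1%.  Two friction models
are provided: Stokes ($\gamma \propto d$) and the default Rouse coupling
($\gamma \propto d^3/a_x^2$), normalized to $\gamma(a_x) = \gamma_{ref}$;
the latter makes the bare diffusivity scale as $(d/a_x)^{-3}$, which is what
collapses the small-particle branch of the master curve.

`detect_events()` coarse-grains a trajectory into cell-index jumps with a
hysteresis rule (an index change is committed only when the trajectory
reaches the new cell's core, within a quarter period of its center),
suppressing barrier-top recrossings.  `classify_motion()` labels ensembles
Brownian / hopping / trapped from the local log-log MSD slope after the
ballistic regime plus the event count.  The slope window starts at
$2\tau \approx 20\,m/\gamma$: the intra-cell caging window at desk scale is
roughly $[2.5, 15]\tau$, so a later start would miss it.  Classification is
reliable only on ensemble MSDs (single-trajectory slopes at long lags are
too noisy); in this desk-scale world the barrier magnitudes cap out near
$2\,k_BT$, so truly trapped dynamics (no escape over the full run) only
occurs for synthetic high-barrier potentials, not for the reconstructed cube
landscape — see the acceptance notes above.

# Regime-resolved MSD theory

With $U_b$ the path barrier and $t_w$ the measured waiting time,
`params_from_landscape()` builds the parameter bundle (natural units
$m = k_BT = 1$, which closes the printed formulas dimensionally):
$\rho = U_b / r_{in}$ (V-potential slope), $\omega = \sqrt{2U_b}/r_{in}$
(harmonic frequency), $\beta_1 = \sqrt{(\gamma/m)^2 - 8\omega^2}$,
$\omega_1 = \sqrt{\omega^2 - (\gamma/m)^2/8}$,
$\Delta_0 = \sqrt{1 + 4D_0/(\rho^2 t_w)}$.  $D_0$ defaults to
$k_BT/\gamma$, the bare diffusivity of the 1-D Langevin model actually
simulated (the Stokes form $k_BT/6\pi\gamma R$ differs only by the absorbed
constant).  The intra-cell MSDs are:

* **Regime I** (V potential): numerical inverse Laplace (fixed Talbot,
  32 nodes, gated by a closed-form-pair self-test to $10^{-6}$) of the
  Laplace-domain MSD; it saturates at
  $2 D_0 t_w - \rho^2 t_w^2 (\Delta_0 - 1)$, and its transient decays at the
  complex characteristic root $s_1$ — an underdamped mode.
* **Regime II** (harmonic): closed forms on either side of the damping
  boundary $\gamma = \sqrt{8}\, m\omega$, evaluated in an overflow-safe
  exponential form; the branches join continuously and both saturate at
  $k_BT/m\omega^2$.
* **Regime III** (reflected walk between $\pm r_{in}$):
  $\tfrac{r_{in}^2}{6}(1 - e^{-t/\tau_0})$ with plateau exactly
  $r_{in}^2/6$.  The relaxation time $\tau_0$ is not fixed by the published
  formulas; the package defaults to $\tau_0 = r_{in}^2 / 12 D_0$ so that the
  short-time expansion matches free diffusion $2 D_0 t$ ($\tau_0$ is a
  config override).  Note the printed plateau is half the textbook value
  $r_{in}^2/3$ for a walker started at the center of reflecting walls at
  $\pm r_{in}$; the package reproduces the printed constant and records the
  discrepancy rather than resolving it.

`compose_total_msd()` splices the intra-cell MSD with the jump-waiting
picture $\langle N(t)\rangle = t/t_w$: below $t_w$ the intra-cell curve,
above it $(t/t_w)\langle\delta z^2(t)\rangle$, which is continuous at
$t_w$ and linear (normal diffusion) for $t \gg t_w$.  `oscillation_mode()`
returns underdamped for Regime I, the $\gamma \lessgtr \sqrt{8} m\omega$
branch for Regime II, overdamped for Regime III; the intermediate
"oscillated" label sometimes used for Regime II is resolved into that same
two-way criterion, which is the only printed inequality.  Regime IV has no
landscape and is labelled "none".

# Scaling analyses

`fit_exponent()` is an ordinary least-squares log-log slope on a stated
window; it is exact on power laws and invariant under axis rescaling.  The
fit windows follow the structure of the path: outer half
$[z_{face}/2, z_{face}]$ for the Regime-I exponent, inner quarter
$(0, z_{face}/4]$ for the Regime-II small-$z$ exponent (the published plots
show but do not state their windows).  `barrier_scan()`, `regime_diagram()`,
`eta_heatmap()` and `master_curve()` assemble the derived tables; the master
curve normalizes per cell at $d = 2r_{in}$ (or $2r_{out}$), interpolating
log-log with edge-pair extrapolation when the normalization diameter was not
sampled (exact on power laws), fits the small-particle slope (expected $-3$
under Rouse-coupling friction; the acceptance run measures $-3.00$) and the
exponential-law $R^2$ on the large-particle branch.

# Synthetic data and seeds

There are no external data: every input is generated by the package (cell
geometries are exact closed forms; dynamics and MC configurations default to
the stated production parameters $\Delta t = 0.01\tau$,
$\gamma/m = 10\tau^{-1}$, $f_0 = 0.5$, 50-run error protocol, with run
lengths scaled down as documented).  All randomness flows from a base seed
through `derive_seed()` (a Lehmer-style mix kept below $2^{31}$); equal
seeds reproduce byte-identical trajectories, Monte-Carlo profiles and CLI
outputs.  A green stochastic test therefore certifies the scaled-down world
it runs in — statistical tolerances (3 standard errors, $\chi^2$ and KS
thresholds at $p > 0.01$) are calibrated to those lengths, not to the
production $10^7\tau$ runs.

# Known limitations

* Single first-shell mirror-image environment; no periodic bulk tiling, no
  second shell (see the boundary-condition discussion above).
* Barrier magnitudes saturate near $2\,k_BT$ in this model class, so
  published behaviors that require $U_b \gg k_BT$ at moderate $d$ (trapping
  at $d/a_x = 1.9$, quadratic $U_b(d)$ growth, $\eta = 1$) are outside the
  desk-scale world; the corresponding checks are reported failing by design.
* Dynamics are 1-D along the path on a quenched landscape; no hydrodynamic
  memory, no network motion coupled to the particle, no entanglements,
  regular cells only, hard spheres only.
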