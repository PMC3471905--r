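---
title: "Elastic-network mechanics of a two-domain protein: model, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic-network mechanics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
model and its assumptions, the parameters that matter and their defaults,
what the synthetic generator does and does not emulate, and the numerical
decisions a maintainer would otherwise have to reverse-engineer.

## The model

### Network construction

A protein is reduced to one bead per residue at the Cα position. Every
bead pair whose reference distance is *strictly* below a cutoff $d_c$ is
joined by a harmonic spring with natural length equal to that distance,
so the reference conformation is by construction the state of lowest
(zero) elastic energy:

$$E \;=\; \frac{\kappa}{2}\sum_{(i,j):\,r^{(0)}_{ij}<d_c}
\bigl(r_{ij}-r^{(0)}_{ij}\bigr)^2 .$$

All springs share one stiffness $\kappa$; sequence neighbours get no
special treatment. Ties at exactly $d_c$ are excluded — the rule is
"smaller than", and `build_network()` implements it with `<`.

The cutoff itself is selected by a spectral criterion
(`select_cutoff()`): scan an increasing ladder of candidates and take the
smallest whose Hessian has **exactly six** eigenvalues at zero. Fewer
than six is impossible for a 3-D network (rigid translations and
rotations are exact null vectors); more than six signals disconnected
components or free internal rotations, i.e. a cutoff too small to make
the molecule one rigid unit. Zero is judged relative to the largest
eigenvalue, $|\lambda| < 10^{-8}\lambda_{\max}$; no absolute tolerance
survives a change of units, and the per-candidate counts plus the gap to
the first retained eigenvalue are returned so the 6-vs-7 decision is
auditable. For the synthetic structure the gap is enormous
($\lambda_7 \approx 10^{-2}$ against null-vector residuals of
$10^{-15}$), so the count is not tolerance-sensitive.

### Rescaled overdamped dynamics

On the timescales of interest inertia is negligible and the dynamics is
a dissipative gradient flow with additive forces:

$$\dot R_i \;=\; -\frac{\partial E}{\partial R_i} \;+\; F_i \;+\; \xi_i(t).$$

Time has been rescaled so that both the friction coefficient and
$\kappa$ drop out. Two consequences worth internalizing: a force of
magnitude 1 stretches an isolated link by 1 Å, and Hessian eigenvalues
are relaxation *rates* — the slowest modes relax like
$e^{-\lambda_k t}$. A stretched dumbbell (one spring) relaxes its
extension as $e^{-2t}$, because the relative coordinate feels both
beads' mobility; this closed form is one of the package's standing
checks.

Integration is explicit Euler with default `dt = 0.01`. The stability
limit is $2/\lambda_{\max}$; for the synthetic network
$\lambda_{\max} \approx 11$, so 0.01 sits an order of magnitude below
it, and `check_timestep()` (integrate to stationarity at `dt` and at a
smaller step, compare final states node-wise) is provided as the guard
the protocol calls for. Very stiff engaged contacts raise
$\lambda_{\max}$ — a breakable-link strength of 1.5 at the default
geometry already pushes the engaged-pair curvature past the limit and
the integrator reports non-finite coordinates with a step-size
diagnostic rather than silently oscillating.

### Stationarity

A relaxation is declared stationary when, per integration step, the sum
of the six pairwise subdomain-COM distances changes by less than
`eps_dist` (default $10^{-6}$ Å) *and* the dihedral angle by less than
`eps_angle` (default $10^{-6}$ degrees). The criterion is evaluated over
single steps spaced ten steps apart — same thresholds, same per-step
semantics, a tenth of the bookkeeping cost. Networks without the four
subdomain labels (dumbbells, blobs) fall back to the maximum per-bead
displacement per step. Non-convergence within `max_steps` is reported,
never fatal, and ensemble protocols count and list such runs rather than
dropping them.

One practical note: the defaults resolve endpoints to roughly
$10^{-2}$ Å along the softest mode (residual amplitude
$\approx$ `eps_dist` $/(\lambda_{\text{slow}}\,dt)$). Where endpoints
feed the cluster classifier, whose default tolerance is of the same
order, the ensemble protocols tighten both epsilons to $10^{-8}$ so that
classification never hinges on convergence slack.

### Immobilization

A static external field would otherwise translate and spin the molecule.
`immobilizing_forces()` adds the unique rigid-body generator field — a
uniform translation plus a linear rotation field about the center of
mass — that cancels the external field's total force and torque. Because
the correction *is* a rigid-body generator, it causes no internal strain
to first order; nothing is pinned, so no artificial deformations appear
near anchor points. The translation part is $-\sum_i F_i/N$; the
rotation vector solves $M b = -\tau$ with
$M=\sum_i(\lVert d_i\rVert^2 I - d_i d_i^{\mathsf T})$, $d_i$ the offset
from the COM. $M$ is singular only for collinear geometries, which are
rejected. Residual force and torque sit at machine precision
($\sim10^{-14}$). Immobilization is applied automatically whenever a
nonzero external field is present, and not in thermal runs — noise has
zero mean and balancing it step by step would correlate the increments.

### Breakable links

When two domains approach, residues that are far apart in the reference
can come into contact; a pure ANM has no way to notice. The expanded
model adds, on a designated pair list, the truncated Lennard-Jones
potential built on

$$u(r) \;=\; A\left[\left(\frac{r_0}{r}\right)^{12}
  - 2\left(\frac{r_0}{r}\right)^{6}\right],$$

with minimum $-A$ at $r_0$ and curvature $u''(r_0)=72A/r_0^2$. The
truncation is *shifted-force*: below $d_t$ the pair feels
$u(r)-u(d_t)-(r-d_t)u'(d_t)$, beyond $d_t$ nothing. Both the energy and
the radial force are continuous and exactly zero at $d_t$ — a plain
energy shift would leave a finite force step there, which the
requirement "the potential becomes flat" rules out. The linear term
moves the minimum slightly off $r_0$ but leaves the curvature untouched.

`add_breakable_links()` enforces the three parameter requirements at
construction: (i) zero force at the truncation length (guaranteed by the
shifted-force form, still measured); (ii) $r_0$ inside the
[min, max] natural-length range of the host network's elastic links — a
contact should equilibrate at a distance the network itself considers
bonded; (iii) the curvature ratio $72A/(r_0^2\kappa)$ is computed and
stored so the "how much stiffer than a regular link" factor is always
reportable. The candidate pair list comes from
`find_emergent_contacts()`: pairs from two chosen subdomains that are
within the cutoff in a second conformation but unlinked in the
reference, sorted by ascending contact distance so a closest-$n$ subset
is a `head()` away. For actin the second conformation is the filament
model, the subset convention is the five closest pairs
(62–204, 63–203, 63–204, 66–203, 67–203) of the eleven S2×S4 contacts;
for the synthetic structure the default subset is the three aligned
pairs (see below).

### Ligands

ADP is one extra node, placed at a reference position (for actin, the
ribose–adenine bridging carbon of the bound nucleotide, read from the
HETATM record by `nucleotide_center()`), connected to every protein bead
within $d_c$ by ordinary springs at natural length. Insertion therefore
changes neither the equilibrium nor, to first order, the slow dynamics.
The printed neighbour lists in the literature for this construction
contain an obvious range typo; the package regenerates the neighbour set
from the cutoff rule, which is the authoritative definition, and treats
any printed list as a cross-check.

ATP is the ADP node plus a phosphate (Pi) node at the unweighted
centroid of three designated "sensitive" residues and the ADP node,
linked to those four partners with natural lengths equal to
`prestrain` × insertion distance. The default `prestrain = 0.2` states
the "80% shorter" rule as a retained-length fraction to avoid
sign/percentage ambiguity. The links are born stretched; their
contraction mimics the pocket shrinkage seen on ATP binding, and because
the Pi node sits at the centroid the initial pulls cancel at the node
itself — the drive acts on the pocket, not on the ligand. Hydrolysis and
release are `release_pi()`: remove the node and its links, change
nothing else; it exactly inverts `add_atp()`. Ligand nodes obey the same
overdamped dynamics as residue beads.

### Order parameters

$d_{13}$ and $d_{24}$ are the distances between unweighted subdomain
centers of mass (all beads are identical particles); $\varphi$ is the
signed dihedral of the point sequence C2–C1–C3–C4 about the C1→C3 axis,
computed with the two-normal `atan2` formula, reported in
$(-180°, 180°]$. The sign convention is right-handed about C1→C3;
only consistency matters (published comparisons use magnitudes), so the
convention is frozen and tested: the triple is invariant under rigid
motions to $10^{-9}$ and $\varphi$ flips sign under mirror reflection.
Sensitivity tables report $\max|\Delta\varphi|$ and relative distance
changes, matching the usual max-response convention.

### Thermal fluctuations

Noise enters per coordinate as independent Gaussian increments of
variance $2D\,dt$ per step (Euler–Maruyama). $D$ is kept as a single
scalar; its temperature reading is not needed for anything the package
computes. The standing calibration check is the one closed form the
model admits: for a single spring the extension
$x = r - r_0$ obeys an Ornstein–Uhlenbeck equation
$\dot x = -2x + \sqrt{4D}\,\eta(t)$ — rate 2 because two beads move,
noise doubled for the same reason — so $\mathrm{var}(x) = D$
stationarily. At $10^5$ samples taken every 100 steps the estimate lands
within ~1–2% (the residual bias is the first-order Euler correction
$\sim\theta\,dt/2$). `thermal_distribution()` follows the standard
protocol shape — burn-in, then strided sampling of the order parameters
(defaults 20 000 steps discarded, 10 000 samples every 400 steps) — with
all sizes configurable downward for desk-scale work.

## The synthetic two-domain structure

`make_two_domain_toy()` builds, deterministically from a seed, a 60-bead
analogue of the two-domain architecture the analysis assumes:

* **S1 + S3**: halves of one rigid two-layer slab (5×3×2 unit lattice).
  The lower-domain separation $d_{13}$ is consequently inert, matching
  the observation that the lower subdomains barely move.
* **S2, S4**: 15-bead clusters — 3×3 face up, 2×2 middle, two-bead
  stalk down — standing on their stalks above the slab ends. The stalk
  hinge is the soft direction; `hinge_gap = 0.45` sets how many
  hinge links form and hence the tilt stiffness.
* **Open vs closed**: the open (reference) form leans both upper
  clusters outward by `open_angle = 0.35` rad, putting the inner faces
  ~2.3 units apart (> cutoff 1.6, no S2×S4 links). The closed form is
  the same beads with the clusters upright: seven S2×S4 pairs fall
  inside the cutoff, the three *aligned* ones at 1.1–1.2.
* **Pocket and nucleotide site**: three cleft-facing beads (top-inner of
  S2 and S4, top-inner of S3) play the sensitive residues; the ADP site
  sits between them on the slab top.
* **Jitter**: every template bead is displaced by Gaussian noise
  (sd 0.05, same in both forms) so spectra and responses are generic
  rather than lattice-degenerate.

Design choices that took iteration, recorded here because they are easy
to break: the lower domain must be a *single* slab — two separate
clusters bridged by coplanar links leave near-mechanisms
($\lambda \sim 10^{-5}$) that masquerade as extra zero modes and make
every relaxation glacial. The stalk beads carry small $y$-offsets so the
hinge resists torsion. And `hinge_gap` is the knob that separates the
strong-link from the soft-link regime: the tilt restoring force at the
engaged-contact distance must exceed the total soft-LJ pull but not the
strong-LJ pull.

`make_bistable_toy()` attaches breakable links on the closest `n_pairs`
(default 3) designed contacts with `strength = 0.6`, `r0 = 1.1`,
`d_t` = cutoff, then *verifies* the two-basin structure — relax from
open stays open, relax from the closed geometry stays closed with
engaged links — and refuses to return an unverified network. The default
strength gives curvature ratio $72 \cdot 0.6/1.1^2 \approx 36$: engaged
contacts are much stiffer than regular links, compensating (as in the
actin parameterization) for the small number of pairs. The aligned trio
is the default because the diagonal pairs admit twist-shifted locked
registers — additional metastable states that are physically legitimate
but obscure the clean two-basin picture the fixture exists to provide.
`toy_soft_strength()` returns 0.01, below the locking threshold
(~0.015 at the default geometry): with soft links the closed basin is
absent — a relaxation from the closed geometry reopens — yet the
pre-strained Pi dimer still drives and holds closure, and its release
reopens the cleft. That is the strong/soft contrast in miniature.

Force scales are matched to the fixture: the toy's links are ~1 Å, a
quarter of typical Cα–Cα link lengths, so ensemble protocols on the toy
use magnitudes in [0, 0.3] where the actin-facing defaults use
magnitude 1 and [0, 2]. Same strain regime, different units.

**What passing the desk-scale suite does and does not show.** The toy
shares the actin analysis's mechanical skeleton — rigid base, hinged
domains, closable cleft, emergent contacts, pocket-coupled ligand — so
it exercises every code path: network building, spectra, nonlinear
relaxation, immobilized response ensembles, endpoint classification,
ligand cycles, thermal sampling. It does *not* emulate actin's geometry,
connectivity heterogeneity, or any quantitative response value
(sensitivity magnitudes, the specific 15%/15° response ranges, the
measured variance reduction). Conclusions about real actin require the
real structures through the same pipeline.

## Parameters at a glance

| Parameter | Default | Units | Why |
|---|---|---|---|
| `kappa` | 1 | energy/Å² | rescaled out; all rates relative to it |
| `cutoff` (toy) | 1.6 | Å | smallest lattice-compatible value with 6 zero modes |
| `dt` | 0.01 | rescaled time | ~10× below the Euler stability limit; guarded by `check_timestep()` |
| `eps_dist`, `eps_angle` | 1e-6 | Å, deg per step | stationarity; tightened to 1e-8 inside ensemble classification |
| LJ `strength` (strong/soft) | 0.6 / 0.01 | energy | locks / fails to lock the toy's closed basin; curvature ratios 36 / 0.65 |
| LJ `r0` | 1.1 | Å | inside the toy's natural-length range (requirement ii) |
| LJ `truncation` | = cutoff | Å | flat exactly where an elastic link would have been drawn |
| `prestrain` | 0.2 | fraction | Pi links born at 20% of insertion length ("80% shorter") |
| sensitive residues (actin) | 16, 73, 159 | ids | one per pocket loop (S-, H-, G-loop) |
| sensitivity thresholds | 6.9°, 0.11 | deg, relative | flags the large-response residues in the scan |
| noise `D` (toy thermal) | 2e-4 | Å²/time | fluctuation sd ~0.03 Å on d24: visible, basin-preserving |
| endpoint cluster `tol` | (0.005, 0.005, 0.5°) | rel, rel, deg | far below basin separation (~0.23, ~5°), stable under halving |

## Slow-mode labelling

The two slowest internal modes of a two-domain network are a
propeller-like counter-twist and a scissor-like opening/closing, but
their eigenvalue *order* is not something to hard-code — reasonable
descriptions disagree, and it can flip with construction details.
`label_slow_modes()` therefore assigns the labels empirically: displace
along each slow mode, project onto $(\Delta\varphi, \Delta d_{24})$, and
call the mode whose normalized dihedral response dominates "propeller",
the other "scissor", orienting each so its dominant parameter increases.
The empirical order is reported, never assumed.

## Known limitations

* Chemistry is absent by design: identical beads, identical springs, no
  hydrolysis kinetics, no Mg²⁺, no solvent structure; hydrodynamic
  interactions are neglected. The model isolates mechanics.
* Closed-state geometry depends on the ligand-interaction parameters;
  only the qualitative open/closed distinction is robust, and the
  package's checks are phrased accordingly.
* The explicit Euler integrator is first-order; all quantitative checks
  carry an $O(dt)$ bias (~1–2% at the defaults), visible in the
  dumbbell and OU validations and accounted for in their tolerances.
* Endpoint classification is a reporting device (complete-linkage in
  tolerance-scaled order-parameter space), not a free-energy analysis;
  basins separated by less than the tolerance merge silently.

## Problem sizes used by the tests and the validation script

The test suite and `scripts/acceptance.R` run entirely on the 60-bead
synthetic structure and 2–10-bead fixtures: 100 finite-difference
configurations, 40-realization response ensembles, $10^5$-sample OU
runs, 4 000-sample thermal comparisons. These sizes give sampling errors
comfortably below the asserted tolerances (e.g. variance SE ~0.5% against
a 5% band) while keeping a full run in minutes on one core.
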