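---
title: "Loop extrusion as an active unknotting machine: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Loop extrusion as an active unknotting machine: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(loopex)
```

This vignette documents the models behind `loopex`: what is simulated, which
parameters matter, where the design was genuinely open and how those choices
were made, and what the synthetic systems do and do not say about real
chromatin.

## The physical picture

Interphase chromatin is crowded enough that free topoisomerase-mediated
strand passage would drive it to a topological equilibrium of complex knots
and pervasive inter-chromosomal catenation — yet Hi-C-era experiments show
chromosomes that are essentially unknotted and demixed into territories.
`loopex` simulates the candidate active mechanism: cohesin-mediated loop
extrusion. A cohesin handcuff threads chromatin through itself; because
neither the cohesin rings nor the fibre can be crossed, every entanglement
ahead of the rings is swept toward the TAD border. There, a short region
with excluded volume switched off stands in for Top2B-mediated strand
passage, and the concentrated knot escapes. The extruded loop behind the
rings can never acquire new entanglements.

## The polymer model

Chains are standard Kremer–Grest-style beaded self-avoiding rings in reduced
Lennard-Jones units: bead diameter $\sigma = 1$, thermal energy
$k_BT = 1$, bead mass $m = 1$. One bead represents 400 bp of chromatin
fibre, 10 nm across. Rings are closed (the last bead bonds to the first) —
loop closure both mirrors the looped state of TADs and keeps the knots from
slipping off the ends.

| term | form | default | why |
|---|---|---|---|
| backbone bond | FENE, $k = 30\,k_BT/\sigma^2$, $r_{max}=1.5\sigma$ | — | diverges before two bonded beads can separate enough to let another chain slip through: together with the WCA core this makes chain crossing impossible |
| bond core | WCA between the two bonded beads, always on | $\epsilon=1$ | keeps contour length ~$0.97\sigma$/bond even for phantom chains |
| excluded volume | WCA (purely repulsive 12-6, cutoff $2^{1/6}\sigma$), non-bonded pairs | $\epsilon = 1\,k_BT$ | self-avoidance; skipped whenever either bead is phantom |
| bending | $\kappa(1-\cos\varphi)$ | $\kappa = 0$ | the unknotting mechanism does not depend on persistence length; exposed as a knob |
| wall | harmonic inward beyond $R$, $k_w = 100\,k_BT/\sigma^2$ | — | soft spherical container; excursions are $\sim\sqrt{k_BT/k_w} \approx 0.1\sigma$ |

The integrator is BAOAB-split Langevin dynamics with $\Delta t = 0.01\tau$,
$\gamma = 1/\tau$, $T = 1$ — a standard stable choice for this force field.
Thermal noise comes from a self-contained counter-seeded generator, so a
run is reproducible bit-for-bit from `(configuration, seed)` regardless of
R's RNG state. Freshly generated configurations may overlap; a *push-off*
phase caps the per-bead force (50 $k_BT/\sigma$, preceded by a gentler
10 $k_BT/\sigma$ stage) until the cores have separated. Near-coincident
pairs are reported as clashes with a capped force, never an exception.

**Phantom semantics.** `phantom` is a per-bead flag; a non-bonded pair
interaction is skipped if *either* bead is phantom. This reproduces "short
chain sections without excluded volume": other fibres pass freely through a
phantom segment, which is exactly the licensed strand-passage of a
topoisomerase-rich region.

## The two extruders

**Cohesin handcuff** (single-TAD and three-TAD experiments). Two 7-bead
rings threaded around adjacent fibre beads, joined by two bonds between
neighbouring beads of each ring. Each ring walks by three springs
($k = 20\,k_BT/\sigma^2$, rest length $1\sigma$, formed at up to $2\sigma$)
from three nonconsecutive cohesin beads to one shifting chromatin bead; when
all three have shrunk to the replacement threshold the springs re-anchor one
bead further and the anchor advances. A 7-bead ring with unit bonds has
circumradius $0.5/\sin(\pi/7) \approx 1.152\sigma$, a hard floor on the
walk-spring length, so the threshold is $1.25\sigma$ — just above the floor,
i.e. "about the rest length". Geometric threading (the fibre pierces each
ring's disc exactly once) is verified at load time and guarantees, together
with impassable bead cores, that the handcuff cannot be lost. A side whose
next bead is CTCF-flagged halts permanently; the other side continues.

**Migrating bond** (melt experiment). One strong spring
($k = 100\,k_BT/\sigma^2$) between two beads; whenever the anchors come
within $1.2\sigma$ the bond steps one bead outward on each unstopped side.
This reproduces the handcuff's entanglement-herding at a fraction of the
cost — the bond junction is a moving clamp no entanglement can pass.

Handcuffs are threaded while the ring is still in its smooth parametric
shape (locally clash-free by construction); thermalisation follows with the
handcuff in place. The three-TAD construct is deliberately not
pre-equilibrated, preserving its quasi-symmetric starting geometry.

## Knot identification

The analysis stage answers "what knot is this ring?" from coordinates
alone:

1. **Simplify** the closed polygon by removing any vertex whose removal
   triangle is pierced by no other segment (randomised passes under a
   seed). This is conservative — borderline contacts block removal — so the
   knot type provably survives; a parametric trefoil of 120 beads reduces
   to ~7 vertices.
2. **Project** along a set of directions: the three principal axes of the
   gyration tensor plus `n_directions` seeded random unit vectors (10 by
   default). Symmetric knots (torus knots especially) attain their minimal
   diagrams along symmetry axes, which random directions alone find slowly.
   Non-generic projections are perturbed deterministically, and directions
   that stay degenerate (an in-plane view of a planar curve) are skipped.
3. **Reduce** each diagram by Reidemeister R1/R2 moves on the signed Gauss
   code and keep the minimal diagram; its crossing count is an upper bound
   on the crossing number.
4. **Classify** by the Alexander polynomial, computed exactly from the
   Wirtinger presentation (fraction-free 128-bit integer elimination at
   integer nodes, Lagrange interpolation, normalisation to lowest degree 0
   and positive leading coefficient) and the determinant $|\Delta(-1)|$.
   Names come from a bundled table of all prime knots to 8 crossings (plus
   $9_1$); composite knots are detected by exact polynomial factorisation
   into table entries, filtered by the crossing-count bound (this is how a
   granny knot at 6 crossings is reported as `3_1#3_1` rather than the
   8-crossing prime with the same polynomial). Anything beyond the table —
   including every diagram past 12 crossings — is `"unclassified"` with its
   invariants recorded. Because the Alexander polynomial is blind to
   chirality and to a few knot pairs, genuinely ambiguous matches return a
   candidate list with `ambiguous = TRUE` instead of a guessed name.

Catenation uses the Gauss linking number, computed as half the signed
inter-curve crossing sum in a generic projection and cross-checked over
independent directions; the test suite validates it against a discrete
Gauss double-sum oracle.

## Voronoi demixing metric

Each bead's Voronoi cell is built by half-space clipping (as in cell-based
tessellation codes): bisector planes of all other beads in increasing
distance order with a security-radius early exit. The spherical wall is
realised by tangent planes derived from the configuration itself — first
the bisector with the bead's own mirror image across the sphere surface,
then adaptive tangent planes wherever a cell vertex still protrudes beyond
the sphere (radial tolerance $10^{-3}R$). Two consequences, both tested:
cell volumes sum to the sphere volume within a few tenths of a percent, and
the whole construction rotates rigidly with the configuration. The area of
a shared facet is averaged over its two per-cell computations (they differ
only by wall-discretisation round-off at the rim), making the
envelope identity $\sum_c \text{envelope}_c = 2\times\text{total}$ exact.
The inter-chain interfacial area counts each facet between beads of
different rings once; wall facets are excluded. Beads are unweighted points
— with monodisperse beads the radical tessellation coincides with the
ordinary one.

## The three experiments and their synthetic inputs

**Single TAD** — a 133-bead ring tied into a $(2,3)$ torus knot (trefoil;
$(3,7)$, 14 crossings, for the complex-knot variant), with a border of 5
phantom beads flanked by one CTCF bead on each side, extrusion starting
diametrically opposite. Expected outcome: unknotting; the no-phantom
control must conserve the knot exactly (non-crossing contract).

**Three TADs** — a 400-bead ring laid out as one global trefoil, cut into
three equal TADs (within one bead) by three borders; three handcuffs start
mid-TAD and run concurrently or sequentially. The knot, too delocalised to
live in any single TAD, concentrates in the borders and escapes there.

**Melt** — $8$ rings ($300$ beads each at desk scale, $4000$ at paper
scale) in a sphere sized by $R = (n/8\phi)^{1/3}$ for volume fraction
$\phi = 0.30$, the chromatin concentration of eukaryotic nuclei. The start
is a stack of planar annular double spirals, one per z-slab — unknotted and
unlinked *by construction* (a plane cannot hold $n$ beads of contour at
unit spacing, so spacing shrinks to keep a $0.55\sigma$ gap between spiral
arms; the push-off restores bond lengths). Topological equilibration then
runs with *every* bead phantom, in windows of $6\times10^4$ steps until the
binned knot-determinant spectrum of the last three windows is chi-square
homogeneous (4–10 windows); excluded volume returns through the capped
push-off, borders stay phantom, and the equilibrated state is reported
(knot per ring, pairwise linking matrix). Extrusion starts simultaneously
in all rings at the site most distant from each ring's border.

Step budgets default to $2\times10^6$ (TAD experiments) and $5\times10^6$
(melt); desk-scale runs complete far earlier (a single-TAD run finishes in
$\sim4\times10^4$ steps) and budget exhaustion yields an `"incomplete"`
outcome rather than an error. Knot identification is sampled every $10^4$
steps, not every step; outcomes are always recomputed from the final frame
by the topology module, never cached.

## What passing tests do and do not show

The generators emulate the *topological* content of the study conditions:
ring sizes, knot types, border layout, confinement density and the
equilibration protocol. They do not model nucleosome-scale structure,
hydrodynamics, cohesin loading/unloading kinetics, CTCF orientation logic,
transcription-driven supercoiling, or repeated extrusion rounds with
intra-TAD topoisomerase action (the knotting/unknotting steady state such
rounds would produce has no published protocol to follow). Desk-scale melt
rings (300 beads) equilibrate to milder knot spectra than 4000-bead rings
would, so the melt acceptance checks are directional (fewer linked pairs,
lower interfacial area), not quantitative reproductions of the full-size
spectrum.

## Numerical choices worth knowing

- Projection degeneracies (collinear crossings, equal depths, near-endpoint
  intersections) are detected and resolved by deterministic perturbation of
  the direction; 100 failures in a row raise a projection error.
- Alexander polynomials are exact for diagrams to ~20 crossings; beyond
  that only the determinant is reported (long-double LU), and such rings
  are `"unclassified"` anyway.
- The simplification pass order is seeded; results are deterministic given
  the seed, and the polynomial-invariance property is tested over 100
  randomised fixtures.
- Integration blow-up (non-finite or diverging coordinates) aborts with the
  step number; it is prevented in normal use by the default timestep and
  the push-off phase.
- `tessellate()` requires beads strictly inside the sphere;
  `demixing_series()` radially clamps the soft wall's $\sim0.1\sigma$
  excursions before tessellating.
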