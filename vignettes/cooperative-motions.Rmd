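---
title: "Probing cooperative domain motions in homodimeric enzymes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing cooperative domain motions in homodimeric enzymes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerflex)
library(dplyr)
```

Many enzymes work as homodimers whose two active sites sit in clefts between
a large, stable core and a small mobile domain. Whether the two clefts open
and close together (symmetric cooperativity), in opposition (anti-symmetric
cooperativity: one closes as the other opens), or independently is a
functional property of the structure that a single crystal form cannot
reveal. `dimerflex` probes it with three ingredients that each cost seconds
to minutes rather than the days of explicit-solvent molecular dynamics:

1. **Elastic-network normal modes** supply candidate directions of
   collective motion.
2. **Pebble-game rigidity analysis** of the bonding constraint network
   decomposes the structure into rigid clusters and flexible joints.
3. **Template-based geometric simulation** drives the structure along a
   mode direction — parallel and antiparallel — while maintaining local
   bonding geometry and steric exclusion, until the motion *jams* against
   the constraints.

Cleft measures evaluated along the resulting trajectories, and the
trajectory statistics layer (PCA projections, windowed correlations,
cosine contents, clustering), then classify the motion.

## The elastic network model

One site per residue is placed at the Cα position and uniform springs of
constant `k` connect every pair of sites within a distance cutoff
(default **12 Å**, the standard coarse-grained choice; `k` defaults to 1 and
sets only the eigenvalue scale — only mode shapes and ordering are
meaningful). The Hessian of the harmonic network energy is the usual
isotropic second-derivative matrix: each spring contributes the rank-1
block $k\,\hat e \hat e^{\mathsf T}$ on the unit bond vector $\hat e$.
Diagonalization of the $3N \times 3N$ matrix yields six zero-frequency
modes (rigid-body motions) for a connected network; modes are numbered from
1 including these, so the first informative mode is **mode 7**.

Composite bias directions are normalized linear combinations,
e.g. $\mathbf e_{8+7} = (\mathbf e_8 + \mathbf e_7)/\sqrt2$, built with
`combine_modes()`. Two numerical points deserve care:

* **Eigenvector sign is arbitrary.** The pipeline therefore always runs
  both parallel and antiparallel biases and no sign convention is imposed.
* **Near-degenerate eigenvalues can swap mode order** under small changes
  of cutoff or coordinates. Single-mode overlaps with a conformational
  transition are correspondingly basis-sensitive: on the synthetic dimer
  the best single nontrivial mode carries roughly half of the open/closed
  transition vector while the lowest dozen nontrivial modes (about 2% of
  the spectrum) jointly carry the large majority. This is exactly why
  composite modes are useful, and why `transition_overlap()` reports the
  full per-mode profile rather than one number.

## Rigidity: constraint networks and the pebble game

Bonding constraints come in four kinds: covalent bonds (element-distance
rules), peptide/partial-double bonds (locked), hydrogen bonds and salt
bridges (kept when their energy is at or below a cutoff, default
**−2.0 kcal/mol** — the regime appropriate for exploring flexible motion,
as opposed to the −0.5..−1.0 kcal/mol range used for static rigidity
studies), and hydrophobic tethers (C/S pairs within the van der Waals sum
plus 0.25 Å). Hydrogen-bond energies use a Mayo-style distance–angle well:
equilibrium donor–acceptor distance 2.8 Å, well depth 8 kcal/mol, and a
$\cos^2$ penalty on the deviation of the donor–H–acceptor angle from
linearity (zero beyond 90°). Without explicit hydrogens a heavy-atom frame
is substituted and a warning is issued; salt bridges receive a fixed
favourable offset (−2 kcal/mol by default). All of these live in function
arguments, not hard-coded constants.

Two resolutions are supported:

* **All-atom (body-bar)**: atoms are 3D bodies; a rotatable covalent bond
  contributes 5 bars, peptide bonds and bonds to terminal atoms 6 (locked;
  a terminal atom has no meaningful torsion), hydrogen bonds 5, hydrophobic
  tethers 2. With $l+1 = 7 \le 2k = 12$ the pebble game is the standard
  matroidal one: a bar is independent iff 7 free pebbles can be gathered on
  its endpoints, the result is provably independent of insertion order, and
  the stalled search region of a locked pair is its rigid component.
* **Coarse Cα (bar-joint points)**: chain bonds, next-neighbour angle bars
  and tethers are single distance constraints between point sites
  (3 degrees of freedom each). Here $l+1 = 7$ exceeds the $2k = 6$ pebbles
  two points can hold; after pinning 3+3 the game hunts the seventh pebble
  in the pair's constraint neighbourhood. This is the molecular-framework
  variant of the game: exact on bond-bending-style networks (the class the
  coarse networks belong to) and on the Henneberg-construction frameworks
  used as oracle fixtures in the tests, where the floppy count provably
  equals $3N - 6 - \mathrm{rank}$ of the distance Jacobian. General
  three-dimensional bar-joint rigidity has **no exact combinatorial
  test** (the double-banana counterexample); on dense, highly redundant
  coarse networks the floppy count can deviate from the numerical rank by
  roughly one part in several hundred, and insertion order can shift it
  similarly. Rigid components in point mode are built constructively
  instead of from search regions: a constraint triangle is rigid, a site
  attached by ≥3 bars to a rigid set is generically rigidly attached
  (0-extension), rigid sets sharing ≥3 sites merge, and only components of
  ≥4 sites are reported — so a covalent bond is *locked* exactly when it is
  interior to a component large enough to block torsion about its axis.

## Geometric simulation of flexible motion

Rigid clusters become rigid *templates* extended by the covalent
neighbours of their members (so adjacent templates share the junction
atoms); every joint atom with a variable bond contributes a local template
of itself plus its bonded neighbours, which maintains bond lengths and
angles while leaving torsions free. Each step:

1. displaces every atom along the fixed per-atom bias field (RMS
   displacement `bias_step`, default **0.01 Å**) plus an isotropic random
   step (uniform in a sphere of radius `random_step`, default **0.01 Å**,
   independent per atom, seeded);
2. relaxes positions by iteratively fitting each template with a
   least-squares rigid superposition, moving every atom to the average of
   its templates' proposals, and separating sterically overlapping
   nonbonded pairs symmetrically (hard-sphere radii scaled by 0.85;
   1–2 and 1–3 bonded pairs excluded), until the worst mismatch drops to
   `relax_tolerance` (default **0.125 Å**) or `max_relax_iters` (200) is
   exhausted.

Steps whose relaxation fails are rejected and the coordinates revert;
`jam_patience` (default 20) consecutive failures set the jam flag and end
the trajectory, so every emitted frame satisfies the tolerance. Two
properties of this jamming criterion are worth knowing. It fires for
*wedging* motions — driving the cleft closed past steric contact jams
reliably, because no nearby configuration reconciles the hinge templates
with the steric wall. It does *not* fire for free rigid-body translations,
which the relaxation can always undo; such motion simply stops progressing.
The bias field is recomputed from the fixed mode eigenvector, not from the
moving structure, so the constraint network converts the linear bias into a
curving trajectory: on long runs the fixed direction eventually becomes
unproductive and the structure drifts off the closing path, which is why
each mode is explored with a few hundred to a few thousand steps in both
directions rather than one long run.

## Measures and statistics

All measures are data-driven site specs (chain, residue, atom name):
intersite distances `d(AB)`/`d(BA)` (the DcpS convention: Cα Trp175 of one
chain to Cα Asp111 of the other; the "A-B" site pairs Trp175 of chain A
with Asp111 of chain B), per-chain hinge angles (Tyr143–Arg145–Arg149 with
Arg145 the hinge centre), the citrate-synthase tip–hinge–hinge–tip quartet
giving the cleft-closing angles ABC and BCD plus the signed inter-domain
dihedral ABCD (Gly312 tip, Gly386 hinge), and dRMS. Conventions chosen
where the sources were open:

* **dRMS is the raw root-mean-square of the six cross-cleft distances**,
  not an RMS deviation from a reference structure's distances; the
  alternative is a one-line change of the spec and both correlate equally
  with the single intersite distance on closing sweeps.
* For the CS quartet, **B and C are the hinges of chains A and B
  respectively** (tips pair with their own chain's hinge); the assignment
  is configurable in `cleft_spec()`.
* Dihedrals are signed with the IUPAC convention. Note the reversal
  identity $\chi(D,C,B,A) = \chi(A,B,C,D)$: exchanging the two chain labels
  reverses the quartet and therefore exchanges ABC with BCD but leaves the
  dihedral unchanged; only a mirror reflection flips its sign.
* **Cosine content** uses the essential-dynamics definition: the squared
  normalized inner product of the centered series with
  $\cos(i\pi t/T)$, sampled at half-offset points so a pure half-period
  cosine scores exactly 1. (A full-period cosine is orthogonal to the
  half-period probe and scores 0 at index 1, 1 at index 2; a half-period
  *sine* is not orthogonal to it.)
* Windowed Pearson correlations use the sample convention; zero-variance
  windows are reported missing, never as 0. Window and stride are in
  frames; map them to nanoseconds via your trajectory's saving interval.

PCA aligns every frame on the first frame over the alignment selection
(e.g. the stable core domains) before accumulating the mass-unweighted
Cartesian covariance over the analysis selection (e.g. the mobile
domains). Frame clustering is average-linkage agglomeration on the
pairwise RMSD matrix with medoid representatives.

## The synthetic dimer: what it does and does not emulate

`make_toy_dimer()` builds a C2-symmetric, Cα-resolution dimer: two
interlocked rigid core domains (60 residues each, lattice-packed at
3.8 Å spacing and cross-tethered at the dimer interface), one 25-residue
mobile domain per chain on a 3-residue zig-zag linker, hovering over the
partner core so that two equivalent binding clefts form. The linker's bond
directions alternate out of plane so its torsion axes are generic and the
mobile domain has real tipping freedom; the designated pre-hinge site,
hinge centre and cleft tip lie in the plane perpendicular to the hinge
axis, so a rigid rotation of the mobile domain by θ changes the hinge-angle
measure by exactly θ — exact ground truth for the open/closed pair
generator. The chains are offset along the dimer axis normal so the two
mobile domains sit outside each other's elastic cutoff: their hinge motions
couple only through the cores, which keeps the symmetric and anti-symmetric
cleft modes both among the lowest nontrivial modes. Small seeded jitter
keeps the lattice generic (applied to one chain, then mirrored, so C2
symmetry is exact to machine precision).

What passing tests on the toy *do* show: the whole pipeline — network
construction, rigidity decomposition (the designed cores form one rigid
cluster, each mobile domain another, linker bonds variable), mode-biased
simulation, jamming, measures, statistics — behaves correctly on a system
with known ground truth, and the designed anti-symmetric/symmetric
cooperativity is recovered as strongly anticorrelated/correlated cleft
measures. What they do *not* show: anything about real secondary structure,
side-chain packing, hydrogen-bond networks, or solvent; amplitudes and
jamming depths on real proteins depend on all-atom packing that a
Cα lattice cannot represent. The all-atom code paths are exercised on a
synthetic idealized helical peptide (`make_toy_peptide()`, ideal backbone
internal coordinates with amide hydrogens) whose i, i+4 hydrogen-bond
ladder rigidifies it in the body-bar decomposition.

## Problem sizes and run lengths

The shipped tests and the acceptance script run the toy dimer (176
residues) with 300-step biased runs saved every 20 steps in both
directions per mode, an 800-step closing drive for the jamming check,
600-frame planted-direction trajectories for PCA recovery, series of
10⁴ points for correlation recovery, and 50 random frameworks of 6–12
sites against the Jacobian rank oracle. These sizes were chosen so the
full validation cycle completes in a few minutes on one core while every
qualitative regime (easy motion, curving, jamming) is reached; production
runs on real structures would use the paper-scale defaults
(0.01 Å steps, several thousand iterations per mode).

## Known limitations

* The point-mode pebble game inherits the theoretical limits of 3D
  bar-joint rigidity (see above); treat coarse floppy counts as exact on
  molecular-style networks and as tight estimates elsewhere. The body-bar
  mode is matroidal and exact.
* Side-chain partial double bonds (arginine guanidinium, carboxylates,
  aromatic rings) are modelled as rotatable unless terminal; FIRST locks
  some of these. This shifts all-atom floppy counts slightly but not
  cluster topology in the cases tested.
* Jamming detection is tied to relaxation failure; motions that stall
  without wedging end at `max_steps` instead of raising the jam flag.
* The geometric simulation explores feasibility, not thermodynamics: it
  deliberately sacrifices the conformational energy landscape for speed,
  so amplitudes are upper bounds on constraint-compatible motion, not
  free-energy-weighted predictions.
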