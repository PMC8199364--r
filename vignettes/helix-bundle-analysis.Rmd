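---
title: "Analysing the structure and thermal response of alpha-helical bundles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing the structure and thermal response of alpha-helical bundles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixtraj)
```

## The problem

Four-alpha-helical bundles are among the most regular protein folds: four
amphipathic helices packed in parallel or antiparallel fashion around a
hydrophobic core.  Two archetypes bracket the family: a homodimer of
helical hairpins (each chain two antiparallel helices joined by a short
loop, 63 residues per chain) and its "loopless" relative, a tetramer of
four long single helices (58 residues per chain) obtained by deleting loop
residues so the heptad repeat runs uninterrupted.  Comparing the two —
and tracking how each degrades as the simulation temperature rises — asks
for a fixed battery of trajectory measures: deviation from the native
state, per-residue flexibility, hydrogen bonding, hydrophobic packing,
backbone torsion statistics and helix dimensions.

`helixtraj` implements that battery as composable functions over a small
set of containers (`molecular_system`, `trajectory`, `region_annotation`,
`atom_selection`), plus a synthetic builder that produces ideal bundles
and noisy trajectories with exactly known ground truth so every stage can
be validated analytically.

## Deviation metrics

For a selected atom set (conventionally C-alpha, with the flexible
7-residue C-tails excluded, and additionally the first 4 residues for the
tetramer whose termini are unresolved in the crystal),

$$\mathrm{rmsd}(t) = \sqrt{\tfrac1N \sum_{i=1}^N \lVert r_i(t) - r_i^{\mathrm{ref}}\rVert^2},$$

computed by `rmsd_series()` after least-squares (Kabsch) superposition of
each frame onto the reference over the same selection.  The superposition
protocol is not uniquely dictated by the definition; fitting on the metric
selection is the common tool convention and `fit = FALSE` is available.
The thermal contrast between a hotter series and a reference series is

$$\%D(t_i) = \frac{\lvert \mathrm{rmsd}_T(t_i) - \mathrm{rmsd}_{\mathrm{ref}}(t_i)\rvert}{\mathrm{rmsd}_{\mathrm{ref}}(t_i)},$$

in `percent_increase()`.  Points with a zero reference are undefined;
they are excluded from the average and counted rather than clamped, which
would bias the mean.  Per-residue flexibility uses the same quadratic
form per C-alpha over time (`rmsf_per_residue()`), with the reference
either the time-mean structure (default; the lower-bound fluctuation) or
the first frame, and optional averaging of equivalent residues across
chains.

One algebraic identity ties the two metrics together and is asserted in
the tests: with `fit = FALSE` and a shared reference, the frame-average of
rmsd² equals the atom-average of rmsf² exactly.

## Hydrogen bonds

Detection is geometric: donors are backbone amide N–H groups and water
O–H; acceptors are backbone carbonyl O and water O.  A pair is bonded
when the donor–acceptor distance is at most 0.35 nm and the
H–donor–acceptor angle at most 30° — the convention of the common MD
analysis tools, which the source studies in this area use without stating
it.  Both cutoffs are configurable (`hbond_criterion()`).  When the
input lacks hydrogens (crystal structures), the amide H is reconstructed
0.10 nm from N in the C(i−1)–N–CA plane, opposite the bisector — standard
planar amide geometry.  Covalently adjacent pairs (N with its own or the
preceding carbonyl O) are excluded.

`hbond_census()` partitions counts into protein–protein (split interchain
/ intrachain), protein–water, and water–water per water molecule; the
last attributes each W–W bond to both partners (2·N~WW~/N~waters~), the
bookkeeping used when comparing against bulk-water coordination numbers.
`helix_i_to_i4()` counts the defining helical O(i)→N–H(i+4) pattern per
annotated helix, and `loop_bridge_table()` tabulates bonds between each
loop residue and each helix, flagging "bridge" residues bonded to both
helices of their own chain (threshold 0.05 mean bonds per frame,
configurable).  Since the builder produces backbone + C-beta only,
synthetic tests exercise backbone and water donor/acceptor classes;
side-chain donors present in real inputs participate only through atoms
actually present in the file.

## Hydrophobic contacts

`rdf()` computes the cross-set radial distribution function between the
C-beta atoms of hydrophobic residues of different chains (dimer) or chain
pairs AB vs CD (tetramer), with minimum-image distances in periodic
boxes, normalised by the ideal-gas expectation
$N_A N_B\,4\pi r^2 \Delta r / V$.  The hydrophobic classification
defaults to {Ala, Val, Leu, Ile, Met, Phe, Trp} and can be overridden per
residue through the annotation.  `cm_distance()` gives the distance
between the (geometric, since all atoms are identical C-beta carbons)
centres of the two sets, a proxy for the extension of the hydrophobic
core.

## Backbone torsions and Ramachandran regions

φ(i) = C(i−1)–N(i)–CA(i)–C(i) and ψ(i) = N(i)–CA(i)–C(i)–N(i+1) in the
IUPAC sign convention (verified against an independent torsion
implementation and against L-residue improper torsions of deposited
structures, which measure about −122° for N–CA–C–CB).  Classification
uses simple disjoint rectangles standing in for the density-derived
regions of crystallographic survey tools: ALPHA φ∈[−180,0), ψ∈[−120,50);
BETA φ∈[−180,−20), ψ∈[50,180]∪[−180,−150); LEFT_ALPHA φ∈[0,180],
ψ∈[−20,90); OTHER the remainder.  Rectangles are checked for disjointness
at construction, classification is total, and the reported percentages
sum to 100 exactly.  Because the regions are definitional, absolute
percentages are comparable only within one region definition; the
package's value is the *contrast* across thermal tiers.  Mean per-helix
torsions use two-stage averaging — circular mean along the helix per
frame, then block averaging — because arithmetic means are wrong at the
±180° wrap.

## Helix geometry

`fit_axis()` takes the principal axis of the centred C-alpha cloud
(oriented N→C); a global straight axis suits short, straight bundle
helices, and the radius formula presumes a single axis frame.  With the
axis as z: rise d = mean |Δz| of sequential residues; radius
r = RMS distance of C-alphas from the axis; twist θ = mean absolute
rotation about the axis between consecutive projections; and L = d·n
(the stated rise-times-count convention, deliberately kept even though
d·(n−1) is the geometric span).  `end_to_end()` measures the first atom
of the first helical residue to the last atom of the last.

A geometric fact worth stating: with the standard peptide geometry used
by the builder (N–CA–C = 111.2°, trans ω), a chain built at
(φ,ψ) = (−57,−47) measures d = 0.156 nm, θ = 99.4°, r = 0.227 nm.  The
textbook 0.150 nm rise at 100°/residue corresponds to a slightly smaller
N–CA–C angle (≈109–110°); rise is sensitive to that angle at fixed
torsions.  We keep the standard 111.2° default and note the ~4%
difference rather than bending the geometry to match the textbook pair.

## Block averaging

Every trajectory-level summary flows through `block_average()`: the
trailing analysis window is split into contiguous equal-duration blocks,
the result is the mean of block means and the error bar the population
standard deviation across them.  Defaults are 5 blocks over the full
series (analyses of long production runs conventionally use the trailing
segment where the rmsd has plateaued — e.g. the last 100 ns of a 200+ ns
run; the block count is rarely stated in the literature, so 5 is a
documented default, not a derived one).  For i.i.d. samples the spread
across block means scales as √(n_blocks/N) at a fixed window — the error
bar of the overall mean, spread/√n_blocks, is what stabilises.

## The synthetic generator

`build_chain()` grows N, CA, C, O (and C-beta) positions from bond
lengths, bond angles and (φ,ψ) torsions by
natural-extension-reference-frame placement, so measured torsions equal
the inputs to machine precision (a property test, and the round-trip
anchor for everything else).  `build_bundle()` assembles either topology
— for the hairpin dimer the default layout is N-tail 1–2, helix1 3–24,
loop 25–33, helix2 34–56, C-tail 57–63.  The native helix assignment for
this fold ends helix2 near residue 52 with a partly helical stretch to
56; since region labels must partition the chain, the synthetic default
extends HELIX2 to the tail boundary.  The loop's default torsions were
chosen once (by a search over turn motifs, then frozen) so the two
helices of a chain fold back antiparallel, as in the real hairpin.
Chains sit on a square lattice with antiparallel alternation at 1 nm
spacing.

`generate_trajectory()` adds i.i.d. per-frame Gaussian displacements with
per-residue amplitude σ_i (optionally on a slow linear drift towards a
target conformation), reproducible bit-for-bit under a fixed seed.
`sigma_profile()` maps regions to amplitudes (defaults 0.01 / 0.03 /
0.05 nm for helix / loop / tail), emulating the observation that tails
and loops fluctuate most; "temperature" tiers are labels on σ multipliers,
with no thermodynamics implied.  For isotropic noise the per-residue rmsf
is σ√3 — the analytic oracle for the fluctuation tests.  What the
generator deliberately omits: time-correlated dynamics, anharmonic
transitions, side chains beyond C-beta, explicit-solvent structure and
real hydrogen positions.  Passing tests therefore certify the measurement
machinery against known ground truth, not the physics of any particular
force field; real trajectories enter through multi-model PDB input.

`place_waters()` scatters rigid 3-site waters (O–H 0.1 nm, H–O–H
109.47°) with a minimum O–O spacing to exercise the protein–water and
water–water bond classes; random orientations mean the bond counts per
water are far below liquid-water coordination, which is intended — the
code path, not the liquid, is under test.

## Numerical choices and degenerate inputs

* Superposition excludes reflections (determinant correction); collinear
  point sets are rejected.
* Fitting frames onto a noisy reference with strongly heterogeneous σ
  leaks apparent motion into quiet residues at long lever arms; the
  fluctuation-recovery validation therefore measures about the static
  time mean without superposition (`superpose = FALSE`), while real-data
  analyses keep the fit to remove genuine rigid-body drift.
* Axis fitting requires ≥5 points and a unique principal direction;
  straight-line traces (radius < 1e−6 nm) have undefined twist and error
  out explicitly.
* Torsions of collinear quadruples are NA and excluded from averages;
  angular averaging is circular throughout and invariant under adding
  360°.
* The rdf requires r_max ≤ half the box edge under periodicity;
  non-periodic runs need an explicit normalisation volume.
* Analyses at desk scale use tens to a few hundred frames per tier and
  bundles of 2 × 63 or 4 × 58 residues; the validation suite's largest
  run is 2000 frames of the dimer for the fluctuation oracle.

## Limitations

The package measures structures; it does not simulate them.  Absolute
hydrogen-bond counts depend on the donor/acceptor inventory present in
the input (backbone-only synthetic systems undercount relative to
all-atom force-field trajectories, e.g. intrachain bonds per residue
≈0.65 here versus ≈0.9 for all-atom inputs), Ramachandran percentages
depend on the region definition, and the L = d·n length convention
slightly overstates the geometric span.  All are documented conventions,
chosen for comparability rather than universality.
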