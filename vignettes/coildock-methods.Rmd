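---
title: "Modelling oligomeric coiled-coil subcomplexes with coilDock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling oligomeric coiled-coil subcomplexes with coilDock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coilDock)
```

## The problem

The bacterial divisome recruits a periplasmic subcomplex of three bitopic
membrane proteins — FtsB, FtsL and FtsQ — whose stoichiometry is not known
experimentally. FtsB and FtsL carry leucine-heptad (coiled-coil) periplasmic
segments and associate before FtsQ joins. coilDock implements a desk-scale,
fully testable version of the computational strategy used to weigh competing
stoichiometries: build parametric coiled-coil bundles for each candidate
chain ratio, score them with a family-specific residue-pair contact
potential, dock the globular partner by rigid-body shape complementarity
under membrane-orientation and mutation-derived distance restraints, and
characterize every resulting interface quantitatively.

All inputs can be synthesized in code (module `makeBundle()`,
`makeTrainingSet()`, `makeGrooveReceptor()`/`makeRodLigand()`,
`makeChargedBundle()`), so the whole pipeline runs and is tested without any
external file. A crystal structure of the partner can be supplied as a PDB
file but is never required.

## Coiled-coil construction

Bundles are generated on Crick coil-of-coils geometry: each chain's backbone
atoms follow minor helices wound on a common superhelical axis (z), chains
offset by $360^\circ/n$. The parameters, all exposed through
`CrickParams()`:

* superhelix radius $R_0$ — 4.9 Å (dimer), 6.7 Å (trimer), 7.6 Å
  (tetramer); canonical GCN4-family values,
* pitch $P = -148$ Å (negative sign = left-handed supercoil),
* axial rise 1.51 Å/residue,
* relative minor-helix frequency $\omega_1 = 2\pi\cdot 2/7$ per residue, so
  the packing core repeats exactly every seven residues and heptad positions
  *a*/*d* face the bundle axis.

The cylindrical offsets of N, C and O relative to the CA helix (radius,
phase, axial shift) were derived once from an internal-coordinate (NeRF)
build of an ideal $\alpha$-helix at $\phi=-57.8^\circ$, $\psi=-47^\circ$,
$\omega=180^\circ$ and frozen as package constants; CB is placed
tetrahedrally from N/CA/C. Side chains are an idealized extension along the
CA→CB vector with declared per-residue lengths, blended with the outward
radial direction (splay factor 0.6) so that long charged side chains do not
interpenetrate across the interface; there is no rotamer sampling. Contact
and surface calculations are tolerant of this approximation at the
tolerances the tests declare, but absolute packing energetics are outside
what this geometry can support.

Helix breaks (e.g. the GDHS turn candidate in the FtsL-like chain) are
rendered as extended non-helical stretches: the declared turn residues
advance 2.1× the helical rise along the chain axis at reduced minor-helix
radius, joining two Crick segments whose registers restart independently.
This is a declared simple geometry for a connector, not a loop model. The
break is applied by default only in the 2:2 bundle, where the second helix
must be repositioned; straight helices suffice for the dimer and trimers.

Only parallel bundles are supported: the chains are membrane-anchored at
their N-termini on the same side, and antiparallel topologies are rejected
with an error. The 2:2 tetramer is assembled as two heterodimers with A/B
identities alternating around the axis. The pentamer is excluded by rule
(`pentamerAdmissible()`): five-helix cores need bulky aromatics (Trp/Tyr) at
*a*/*d* positions in at least half the chains.

## The residue-pair potential

`derivePairPotential()` computes a 20×20 symmetric log-odds matrix

$$S(i,j) = \ln\frac{O(i,j) + p}{E(i,j) + p}, \qquad
  E(i,j) = T f_i f_j (2 - \delta_{ij}),$$

where $O$ counts unordered interchain residue-pair contacts over a training
set of two-chain interfaces, $f$ are the marginal residue frequencies at
those interfaces and $T$ the total contact count. The Laplace pseudocount
$p = 1$ guarantees finiteness. The default contact rule is a minimum
heavy-atom distance of 4.5 Å; a CB–CB 6.5 Å rule is offered as the
alternative used throughout the synthetic experiments. Intrachain contacts
are excluded by default. Scores of candidate complexes are sums of $S$ over
interchain contacts, and `rankModels()` orders models by score with ties
broken by fewer interchain clashes (< 2.5 Å), then input order.

### Controlled training sets

`makeTrainingSet()` generates interfaces whose contact-type statistics are
known by construction: isolated residue pairs placed across the interface at
CB–CB 5.0 Å, 20 Å apart from one another, with types drawn from a calibrated
joint distribution. Two design points deserve explanation:

* **Calibration.** Sampling pair types as $e_{ij} f_i f_j$ does *not* make
  the derived $S$ converge to $\ln e$: enriching a cell shifts the realized
  marginals, which enter the denominator of the ratio the derivation
  computes. The generator therefore solves, by fixed-point iteration, for
  sampling weights under which the *realized* observed/expected ratio (with
  expectation from realized marginals) equals the declared factor. The
  iteration also reveals infeasibility: for a diagonal cell with background
  frequency $f$, the attainable ratio has a finite supremum (about 1.56 at
  $f = 0.25$), so an enrichment of 2 or 4 over a 4-letter uniform background
  is mathematically unrealizable and raises a generation error. Recovery
  experiments therefore keep the enriched type rare
  (`enrichmentBackground()`, $f = 0.05$–0.1).
* **Background composition.** The default background is uniform over a
  4-residue alphabet (L, E, K, S). With ~10^4 contacts this puts several
  hundred counts in every populated cell, so a null training set yields
  $\max|S| \lesssim 0.1$ — sampling noise, not signal. A 20-letter uniform
  background at the same budget would put ~25–50 counts per cell and produce
  spurious log-odds of ±0.4. The composition was fixed from this
  expected-count analysis before any test was run.

The generator records its realized counts, so tests can verify the derived
matrix against generator bookkeeping rather than against itself.

## Docking

`generatePoses()` implements grid-based rigid-body docking with the
Katchalski-Katzir surface/interior encoding: cells within a van der Waals
radius are molecule, the layer within `surface_thickness` of open space
scores 1, the receptor interior scores −15 and the ligand interior +1. The
translation scan is an FFT cross-correlation over a zero-padded lattice,
bit-identical (to numerical precision) to direct spatial correlation — a
property the test suite asserts on random grids.

Rotations come from a deterministic ZYZ Euler lattice at the requested
angular step with duplicate-orientation pruning: at the gimbal poles only
$\alpha + \gamma$ matters, and near the poles the $\alpha$ count is scaled
by $\sin\beta$ because neighbouring $\alpha$ values there differ by much
less than the nominal step. No randomness enters anywhere in docking. The
default test settings (15°, 1.5 Å) resolve a rod-in-groove recovery problem
in about two minutes on one CPU; production-quality settings are a
configuration change, not a code change.

Two biological restraints filter poses (`applyRestraints()`): a distance
restraint — minimum heavy-atom distance between declared receptor and ligand
residue sets at most 6 Å by default, mirroring the mutation-derived contact
between the partner's recruitment surface and the bundle — and a
coplanarity (membrane-orientation) restraint requiring the N-terminal
main-chain atoms of all chains to lie within one slab (default thickness
8 Å; neither the slab thickness nor the axis convention is fixed by prior
work, so both are configuration) normal to the bundle axis. Filtering is
idempotent, order-preserving and purely subtractive. A second partner copy
can be docked sequentially with the first accepted pose frozen into the
receptor (`n_copies = 2` in the pipeline configuration).

Note on discretization: a shape interference smaller than the surface-layer
thickness (1.5 Å by default) is absorbed by the surface encoding — a groove
1 Å narrower than the rod still scores well. The negative docking control
therefore uses a groove clearly narrower than the ligand (5 Å vs 10 Å).

## Interface analysis

* **SASA** — Shrake-Rupley with a deterministic 960-point Fibonacci sphere
  and probe 1.4 Å. An isolated atom reproduces $4\pi(r+1.4)^2$ exactly up to
  the point-set quantization (< 1%).
* **Interface area** — $[\mathrm{SASA}(1) + \mathrm{SASA}(2) -
  \mathrm{SASA}(\mathrm{complex})]/2$; the percentage uses the complex ASA
  as denominator (declared convention; configurable to the monomer sum).
* **Interface residues** — ASA loss > 1.0 Å² between isolated side and
  complex.
* **Hydrogen bonds** — heavy-atom geometric criteria (hydrogens are not
  modelled): donor-acceptor ≤ 3.9 Å and angle at the donor (antecedent =
  nearest bonded heavy atom) ≥ 90°; N/O-H donors, O and His ring-N
  acceptors.
* **Salt bridges** — oppositely charged side-chain atoms *within* 4 Å, one
  bridge per residue pair. The source convention we follow is ≤ 4 Å; the
  phrase "at least 4 Å apart" that sometimes accompanies it contradicts all
  structural practice and the cited definition, and is read as "within".
  His counts as positively charged at both ring nitrogens (configurable via
  the shipped chemistry table).
* **Composition** — percentages of polar / nonpolar / charged residues over
  interface residues and, separately, over solvent-exposed residues
  (relative SASA > 5% of the residue-type maximum). The classification
  scheme (His charged, Gly polar) is itself a declared convention shipped as
  an editable table: published interface statistics rarely state their
  scheme, and percentages are only comparable when the scheme is explicit.
* **Dimensions** — bounding-box extents after aligning the principal axis
  to z.

`classifyStability()` compares six fields (interface ASA %, three interface
composition percentages, and the two interaction densities) against a
shipped mean-stable-complex reference row (11.2 / 32.2 / 39.5 / 28.2 / 1 /
2–6). A field is within its band when it lies within a factor 1.5 of the
reference (range-valued references extend the band from both ends); 5 of 6
within ⇒ consistent, 4 ⇒ borderline, otherwise inconsistent, and an empty
interface is always inconsistent. The multiplicative band was chosen over an
additive ±50% because it treats shortfalls and excesses symmetrically on a
ratio scale — e.g. an interface share of 6.1% against a reference of 11.2%
is correctly flagged as outside.

## Hotspots and charged patches

`alanineScan()` truncates each interface residue to CB and recomputes the
pair-potential score, interchain hydrogen bonds and salt bridges; the proxy
$\Delta\Delta G = \Delta S + w_{HB}\,\Delta n_{HB} + w_{SB}\,\Delta n_{SB}$
(weights default 1) ranks hotspot candidates. The proxy is dimensionless and
deliberately *not* comparable to physical kJ/mol alanine-scanning energies —
a declared ranking device, with interaction types annotated at precedence
SB > HB > VW. Gly/Ala are reported unscanned with a proxy of 0.

`coulombPotential()` replaces a Poisson-Boltzmann map with a screened
Coulomb sum $\phi(p) = \sum_q \mathrm{sign}(q)\, e^{-d/\lambda}/d$ (distance
floored at 1 Å, $\lambda = 8$ Å ≈ 150 mM ionic strength; arbitrary units,
meaningful sign). `findChargePatches()` single-links exposed charged
residues of one sign through their charged-atom distances (≤ 10 Å) and
reports patches of at least 2 residues; this is how the negative band on
the bundle's mid-section is detected in the synthetic reproduction
(`makeChargedBundle()` seeds acidic bands at FtsB-like residues 50–70 and
FtsL-like 85–95).

## Pipeline

`runPipeline()` chains the stages per stoichiometry (1:1, 2:1, 1:2, 2:2) and
writes, per candidate: the bundle PDB, pose manifests before and after
restraint filtering, the interface and surface tables in the layout of the
published comparison tables (with the reference row appended by
`renderTables()`), the hotspot table, and the stability classification. The
summary ranks stoichiometries by restraint-passing pose count, then
stability verdict, then pair-potential score — a declared synthesis of a
qualitative selection narrative, labelled *static-analysis only* because the
molecular-dynamics stability evidence that complements it is out of scope
here. Runs are deterministic: same configuration and seed ⇒ byte-identical
outputs. A stage failure is logged, the stoichiometry is marked failed, and
later independent stages still run.

## What the synthetic data do and do not show

The generators emulate ideal geometry: exact Crick bundles, isolated
contact pairs with controlled statistics, rectangular grooves and rods.
Passing tests therefore demonstrate that the *algorithms* are correct —
FFT = brute force, potentials recover known enrichments, detectors equal
O(n²) scans, the builder hits its declared geometry — not that the
biological conclusions about any particular complex are right. Real
structures add conformational variability, rotamer packing, solvation and
crystal-quality coordinates that no test here exercises. The shipped
FtsB/FtsL periplasmic sequences are constructed stand-ins labelled
synthetic (the natural sequences can be dropped in as a FASTA file); they
carry the documented features — leucine heptads, no core Trp/Tyr, a GDHS
turn candidate, acidic bands — so every sequence-dependent rule in the
package is exercised honestly.

## Numerical choices and problem sizes

Tolerances and sizes used by the shipped tests, chosen as the package's own
desk-scale defaults: FFT-vs-direct agreement to 1e−6 relative on 8³/12³
grids; SASA checks at 960 sphere points; enrichment recovery at 10⁴
contacts per training set against 3 count-based standard errors; docking
recovery at 15°/1.5 Å on a 40×30×14 Å receptor; pipeline determinism at
60°/2.0 Å with 8 training interfaces. Degenerate inputs are defined
errors: empty structures, overlapping partitions, selectors resolving to no
atoms, infeasible enrichments, non-parallel bundles, chains past PDB
numbering capacity. Ties are broken deterministically everywhere (input
order for equal scores, altloc 'A' at equal occupancy, earliest frame for
register ties).

## Known limitations

* Backbone and side-chain geometry is idealized; no rotamer library, no
  loop modelling, no refinement. Interface metrics on built bundles are
  meaningful relatively (between stoichiometries), not absolutely.
* The pair potential is family-specific by construction and is not intended
  to reproduce any published matrix numerically.
* The electrostatics is a screened-Coulomb screen, not a Poisson-Boltzmann
  solution; patch detection depends on sign patterns only.
* Docking scores shape complementarity only; no electrostatic or
  desolvation term inside the FFT score.
* The hexamer route docks the second partner copy greedily (first accepted
  pose frozen); no joint two-body optimization.
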