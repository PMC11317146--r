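---
title: "Measuring and classifying polymorphic DNA base-pair geometries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and classifying polymorphic DNA base-pair geometries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpgeom)
```

`bpgeom` annotates nucleic-acid crystal structures in which a single
base pair may exist as several alternate-location conformers with
fractional occupancies.  The motivating system is the methylated mC:G
pair at a non-CpG step, which can refine simultaneously as a
Watson–Crick-like major form and a minority *water-mediated cis
Watson–Crick/Hoogsteen* form, (w)cWH: guanosine *syn*, a direct
N4···O6 bond, a bifurcated N3···O6 bond, and the pyrimidine O2 reaching
the purine N7 only through a bridging water.  This vignette documents
the measurement conventions, the classification rules, the synthetic
fixture generator used for validation, and the package's numerical
choices and limitations.

## Conformer model: occupancy as first-class data

A structure is stored as a flat atom table (altloc label, occupancy and
B-factor preserved verbatim).  `expand_conformers()` produces one
self-consistent model per altloc label: blank-altloc atoms are shared
into every model, and the model's occupancy is the common occupancy of
its altloc group (a warning is raised if occupancies within one group
spread by more than 0.05).  A structure without altlocs yields one
model at occupancy 1.  `enumerate_pair_conformers()` then reports each
base pair once if its nucleosides are single-conformer, and once per
conformer — with that conformer's occupancy — if they are not.  An
alternate *linking phosphate* alone does not split a pair: pair
identity is judged on nucleoside atoms.

## Geometric parameters

**Base reference frames.** Each base is fitted by least squares (SVD
Kabsch) onto an embedded standard-geometry table (ring plus exocyclic
heavy atoms of A, G, C, T, U; inosine is guanine without N2;
5-methylcytosine is cytosine plus an in-plane C7 at 1.50 Å from C5).
The standard frames place x toward the major-groove edge, y along the
pairing axis, z along the base normal, so that Watson–Crick pairing is
a rotation of π about x.  The fit residual (Å RMSD) is reported; under
isotropic coordinate noise of σ = 0.05 Å the frame orientation is
stable to ~1° on average.

**Glycosidic torsion.** χ is the signed IUPAC dihedral O4′–C1′–N9–C4
(purines) / O4′–C1′–N1–C2 (pyrimidines), computed from the raw atoms;
the *syn* call is χ ∈ (−90°, +90°], *anti* otherwise.  A missing
defining atom yields "undefined", never a guess.

**λ angles and C1′–C1′.** λ is the angle at C1′ between the glycosidic
bond and the C1′–C1′ line (λY pyrimidine, λR purine).  Both λ and
C1′–C1′ are computed from *frame-implied* atom positions — the standard
base coordinates carried through the fitted frame — rather than from
the raw C1′/N atoms.  The frame fit averages coordinate noise over the
whole base; raw-atom λ would inherit an ~3°/0.05 Å error from the
1.5 Å glycosidic-bond lever arm, which is larger than the asymmetry
threshold separating WC from aWC.  At zero noise the two conventions
coincide exactly.

**Rigid-body pair parameters.** Shear, stretch, stagger (Å) and buckle,
propeller, opening (°) come from the standard mid-frame decomposition:
the second base's frame is flipped (y, z negated), the
buckle–propeller hinge rotation is split symmetrically between the two
frames, opening is the residual in-plane rotation, and the
translational components are the origin displacement expressed in the
mid-frame.  When the two normals are antiparallel (a Hoogsteen flip
makes γ ≈ 180°) the hinge direction is degenerate; the package then
uses base A's x axis as the hinge, which keeps the decomposition
deterministic (the WC-family thresholds are never applied to such
pairs, so the arbitrary choice does not affect classification).  The
builder implements the exact inverse map, which is what makes
generator → analyzer round trips exact to machine precision.

**Superposition.** `superpose_rmsd()` matches atoms by (chain, residue
number, insertion code, atom name), optionally through a chain map,
and computes the optimal rigid-body RMSD with a full-precision SVD
Kabsch.  The default selection is nucleotide heavy atoms; waters, ions
and ligands are excluded unless requested, since duplex comparisons
concern the DNA.

## Hydrogen bonds, bridges, ions

Deposited structures at 1.6–2.5 Å rarely contain hydrogens, so a
hydrogen bond is a heavy-atom criterion: a donor–acceptor pair from a
hard-coded polar-atom table within a cutoff (default 3.5 Å,
configurable; pairs under 2.0 Å are treated as covalent/clash and
excluded, as is the O3′–P linkage).  Cytosine N3 is admitted as a
donor to represent a protonated-N3 bond; such bonds are flagged
`protonation_assumed` — the package reports rather than decides
protonation.  Ligand N/O atoms participate generically by element.
Bonds sharing a terminus with ≥ 2 partners on the same residue receive
a common bifurcation group id.  A water bridge is a water oxygen
within the cutoff of polar atoms of two different residues; both leg
distances and the water B-factor are kept.  Ion shells collect O/N
atoms within 2.8 Å of an ion and are labelled octahedral when exactly
six ligands have all cis angles within 90 ± 15°.

## Pair detection and classification

Candidate pairs need ≥ 1 inter-base hydrogen bond or qualifying water
bridge between base atoms, C1′–C1′ ∈ [8, 12.5] Å, and base-normal
angle ≤ 65° (folded to [0, 90°], so Hoogsteen flips pass).  Matching is
greedy: most bonds first, ties broken by shorter C1′–C1′; a residue
joins at most one pair (triplexes are out of scope).  Classification
applies ordered rules on the stored evidence:

1. **WC** — both *anti*, the canonical bond set for the base
   combination (C:G: ≥ 2 of {N4···O6, N3···N1, O2···N2} including
   N3···N1; T:A: both of {N3···N1, O4···N6}), |λY − λR| ≤ 8° and
   |shear| ≤ 0.8 Å.
2. **aWC** — canonical bonds, *anti*–*anti*, but asymmetry beyond
   either threshold.
3. **cWH / (w)cWH** — purine *syn*, pyrimidine WC edge bonded to the
   purine Hoogsteen edge (N7/O6), *cis* orientation; `(w)cWH` when the
   O2···N7 contact is a water bridge rather than direct.
4. **nonWC** — *anti*–*anti* with WC-edge bonding that is not the
   canonical set (the C:I pair, inosine lacking N2, lands here).
5. **other** — anything else, evidence retained.

The aWC thresholds (8°, 0.8 Å) are package defaults, exposed in the
threshold list; they cleanly separate the built WC and aWC exemplars
and are deliberately tunable because different refinement conventions
shift λ by degrees.  Cis/trans is operationalized as: both C1′ atoms on
the same side of the line through the two glycosidic nitrogens,
projected on the base plane.  Labels are a pure function of stored
evidence: re-running `classify_geometry()` on a serialized pair
reproduces them exactly.

Duplexes are maximal chains of pairs consecutive by backbone
connectivity (O3′→P ≤ 2.0 Å) with the two strands advancing in
opposite directions; branching connectivity is an error naming the
residues.

## The synthetic generator

`build_pair()`/`build_duplex()` produce idealized fixtures that stand
in for the crystal structures during validation:

* **WC-family pairs** place standard bases by the exact inverse of the
  mid-frame decomposition, so requested parameters are recovered to
  10⁻³ (machine precision in practice).  Sugar and a minimal backbone
  (P, OP1/OP2, O5′, C5′, C4′, C3′, O3′, C2′, C1′, O4′) are built from
  internal coordinates with χ set exactly; the backbone is geometrically
  plausible but not energy-minimized — only connectivity, C1′ and χ
  matter downstream, and phosphates are repositioned so O3′→P
  connectivity holds (splitting the linking phosphate into altloc
  copies when the preceding residue exists only as alternate
  conformers, as deposited structures do).
* **Hoogsteen pairs** solve the in-plane purine placement against
  target distances N4···O6 = 2.9 Å, N3···O6 = 3.2 Å and O2···N7 = 4.6 Å
  (water-mediated; 2.9 Å direct for dry cWH) by multi-start BFGS,
  rejecting distance-feasible but physically overlapping branches
  (inter-base separation < 2.5 Å).  The resulting (w)cWH exemplar
  reproduces the expected signatures without being told them: C1′–C1′
  elongates to 10.8 Å (8.5 Å for the dry Hoogsteen pair), λR drops to
  ~23°, and the orientation is *cis*.  The bridging water is placed at
  the requested leg distances (2.8/2.9 Å) by circle intersection in the
  pair plane, on the minor-groove side; an infeasible triangle is an
  error stating the violated inequality.
* **Duplexes** stack pairs at rise 3.4 Å / twist 36° with the default
  sequence d(ACGmCCGT/ACGGCGT) and the central pair overridable by a
  spec or an altloc plan; the plans used throughout validation are the
  occupancy splits of the studied crystals (0.9/0.1 and 0.6/0.4
  unliganded, 0.7/0.3 drug-bound).  The default aWC exemplar shears the
  pyrimidine by −1.2 Å, i.e. toward the helix interior, the
  displacement direction reported for methylated cytosines; with this
  sign the central mC4–C5 π–π centroid distance contracts (3.82 Å vs
  4.10 Å unmethylated in the ideal fixture), mirroring the tighter
  stacking seen in methylated structures.
* **Noise** is i.i.d. Gaussian per atom and axis with a caller-supplied
  seed (σ = 0 is the identity); generation is byte-deterministic in the
  seed, and the caller's RNG state is restored.
* **Intercalator stand-ins** are generic planar six-rings (two ring
  nitrogens) stacked between steps — enough to exercise
  ligand-as-partner bonding, deliberately not a real drug geometry.

What the fixtures do **not** emulate: sequence-dependent helical fine
structure (roll/slide/tilt are zero), exact sugar ring closure and
pucker, solvent beyond requested bridging waters, real ligand
chemistry, and crystal-symmetry contacts.  Passing the synthetic suite
therefore demonstrates that the *measurement and classification
machinery* is correct and noise-robust under controlled conditions; it
does not by itself validate absolute agreement with any particular
refinement's printed λ/shear values, which can differ by
convention-level offsets.

## Validation problem sizes and numerical choices

The test suite and `scripts/acceptance.R` use: 7-bp duplexes; a
parameter-recovery grid of 27 combinations plus χ targets; a taxonomy
suite of 5 exemplar classes × 100 random rigid motions with σ = 0.05 Å
noise (accuracy is 100% there; at σ = 0.1 Å individual bond distances
begin to cross the 3.5 Å cutoff stochastically and per-class accuracy
drops to 94–98%, which is why the suite validates at 0.05); a
four-duplex asymmetric-unit fixture with σ = 0.1 Å per-copy noise, the
coordinate-uncertainty scale of a ~2 Å map, giving pairwise duplex
RMSDs of ~0.25 Å.  Superposition uses the package's own SVD Kabsch at
full precision; `bio3d` backs file parsing and PDB writing, and its
fitted RMSD (printed at three decimals) is kept as an independent
cross-check in the tests.

Degenerate inputs are reported, not repaired: missing frame atoms give
"insufficient ring atoms", missing χ atoms give an undefined state,
undefined parameters give `unclassified(reason)` labels, and unmatched
residues in superposition are listed by name.

## Known limitations

* Crystal symmetry mates are not generated; contacts across asymmetric
  units are seen only if the deposited file contains the partner atoms.
* Protonation states are asserted by table, not computed.
* λ/shear conventions may differ from other annotation tools by fixed
  offsets; the package guarantees internal consistency and oracle
  agreement, not convention identity.
* Only two-residue pairs are detected (greedy matching); triplexes,
  quadruplexes and RNA-specific families are out of scope.
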