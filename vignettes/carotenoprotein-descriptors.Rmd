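---
title: "Structural descriptors of protein-bound carotenoids: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural descriptors of protein-bound carotenoids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carotenostruct)
```

## The problem

Carotenoproteins shift the absorption maximum of their bound pigment far to
the red — an orange carotenoid can appear blue inside a protein. The
photophysics of that shift is encoded in structure: how far the conjugated
polyene's bond lengths equalise (bond length alternation, BLA), whether the
end rings rotate into the plane of the chain and extend conjugation
(*s-cis* versus *s-trans*), how two pigments are stacked at a heterodimer
interface, and how each subunit contacts and buries the chromophore. This
package computes those descriptors from atomic coordinates, with a
synthetic-structure generator that provides exact ground truth for every
descriptor so the pipeline can be validated end to end without any
deposited data.

## Data model

A structure is a tibble with one row per atom (`chain`, `resid`, `resname`,
`atom`, `element`, `x`, `y`, `z`, `b`, `occ`, `alt`, `is_polymer`,
`is_water`). Author chain identifiers and residue numbering are used
everywhere, because that is how binding-site residues are reported in the
literature (e.g. "Ser133 of the alpha-subunit"). Reading a file resolves
alternate locations by keeping the highest-occupancy conformer, ties broken
by file order — a single-conformer model is what descriptor analyses assume,
and deposition order is the only reproducible tie-break. Waters are kept but
flagged, and excluded from contact, hydrogen-bond and SASA analyses by
default; glycans and other heterogroups are kept as non-polymer residues.
Hydrogens are absent from typical crystallographic models at this
resolution, so every geometric criterion in the package is defined on heavy
atoms only.

Ligands are identified against *templates* — declarative descriptions of a
carotenoid chemotype: heavy-atom names, a bond list with formal orders, the
ordered polyene path, end-ring atom sets and named torsion quadruples.
Built-ins cover astaxanthin (AXT) and mytiloxanthin (MXT, with its C7–C8
triple bond, order 3, and kappa-type primed end ring). The MXT template is a
reconstruction following standard carotenoid numbering with primes; a
deposition that uses different atom names can supply its own template via
`carotenoid_template()`. A residue matches a template when at least 90% of
the template's atom names are present — tolerant of a few unmodelled atoms,
strict enough that a fragment does not match.

## Geometric descriptors

**BLA.** `bla()` averages formal single-bond lengths minus formal
double-bond lengths along the polyene path. Two choices matter. First, the
single/double classification comes from the template's formal bond orders,
never from the observed lengths — the crystal lengths are the measurement,
and classifying by length would bias BLA toward zero by construction.
Second, the path runs between the end rings (the ring-to-chain single bond
included, ring-internal bonds excluded), and a triple bond contributes to
neither class. Half-path scopes split at the central bond; with an odd
number of path bonds the central bond is assigned to neither half, so the
two halves are symmetric.

**Torsions and ring conformation.** `dihedral()` uses the IUPAC sign
convention (validated against an independent projection-formula oracle and
against biotite), range (−180°, 180°]. End-ring conformation about the
chain–ring single bond is *s-trans* iff |torsion| > 90°; the boundary at
exactly 90° goes to *s-cis* by the strict inequality. That threshold is
consistent with how the field labels observed geometries: ring torsions
near −40° are called *s-cis*, near 165–171° *s-trans*.

**Planes and pairs.** Polyene planes are total-least-squares fits (smallest
principal direction of the centred scatter); the normal's sign is fixed
toward +z (ties toward +x, then +y) purely for reproducibility. For a
carotenoid pair, the interplanar angle is the acute angle between normals;
the minimum distance is taken over polyene-chain heavy atoms only, not end
rings, because "plane separation" is a statement about the stacked
chromophores, not about ring substituents that splay outward; and the
crossing dihedral is an ordinary signed dihedral over a named quadruple
spanning the two ligands.

**Pseudo-twofold axes.** The dimer axis is the rotation axis of the
alpha-to-beta chain superposition (a warning is raised if that rotation is
under 120°, where "twofold" stops being meaningful). The pigment-pair axis
is the rotation axis of the better of the two rigid maps of one polyene
onto the other (forward or reversed atom order — antiparallel pairs need
the reversal). The angle between the axes is classified coincident below
30° and perpendicular above 60°; the field uses these labels qualitatively,
and the 30°/60° split leaves a clear oblique band so neither label is ever
assigned marginally.

## Interactions

**Contact shells** use the minimum heavy-atom distance per residue at a
4.0 Å default cutoff — the conventional shell for describing a binding
site. Only polymer residues are listed; the partner pigment and glycans are
never "contact residues".

**Hydrogen bonds** are heavy-atom N/O–N/O pairs within 3.5 Å. No
criterion was available from the structure this convention targets, so
3.5 Å — the common heavy-atom donor–acceptor ceiling — is the default and a
parameter. With `require_geometry = TRUE` an antecedent–donor–acceptor
angle ≥ 90° is additionally required on at least one side: with no
hydrogens in the model this is a proxy that removes head-on artefacts
without pretending to know the proton position. Hydroxyl–hydroxyl pairs are
donor/acceptor-ambiguous and reported once, ligand atom first.

**SASA** is Shrake–Rupley with probe 1.4 Å and a deterministic spherical
Fibonacci lattice of 960 points per atom — no RNG, so areas are exactly
reproducible run to run, which matters when fractions of areas become
reported percentages. Van der Waals radii are a fixed, versioned Bondi-type
table (C 1.70, N 1.55, O 1.52, S 1.80 Å). The isolated-sphere closed form
is reproduced to well under 0.5% at 960 points; the lattice is not
mirror-symmetric, so exactly symmetric environments can differ in the
fourth significant figure.

**SASA partition.** The fraction of a ligand's isolated surface buried by
partner X is (SASA alone − SASA beside X alone) / SASA alone, with protein
chains keyed by chain id and every other non-water residue (partner
pigment, glycans) under its own key. Pairwise burial double-counts regions
occluded by two partners at once; the partition is reported as-is with the
discrepancy in `overlap`, because pairwise accounting is how subunit shares
are quoted in the literature (two subunits sharing 48% and 45% of a surface
sum below 100%).

**Fragment B-factors** are unweighted means/SDs over template-defined
end-ring atom sets — a direct, resolution-honest measure of which end of
the pigment is loosely held.

## Superposition

Chain superposition is sequence-guided: a global BLOSUM62 alignment (gap
open 10, extend 0.5 — standard protein defaults) supplies Cα pairs, Kabsch
(SVD, reflection never chosen) fits the rigid transform, and pairs
deviating more than `trim_sigma` (default 2) times the current RMSD are
removed and the fit repeated until stable. Trimming is how "RMSD over N
matched Cα" numbers with N below the alignment length arise in practice.
Identity is counted over aligned columns excluding terminal gaps, matching
conventional percent-identity reporting. Dimer superposition concatenates
the per-chain alignments under the chain pairing that minimises the final
RMSD and fits one transform over all pairs. The Kabsch route is validated
against an independent quaternion eigen-decomposition oracle to 1e-9 on
1000 random point sets.

## Sequences, masses, spectra

The sequon scanner defaults to the strict Asn-x-Thr pattern (x ≠ Pro), with
Asn-x-Ser/Thr behind a flag; positions are reported in both precursor and
mature numbering once a signal-cleavage position is supplied (cleavage
positions are user-supplied facts, typically from Edman sequencing —
prediction is out of scope). Cysteine profiling always returns exact
positions and counts; the shipped profile table (profile-1/2/3 keyed to
conserved-cysteine counts 4/6/5) is a reconstruction of the published
ependymin-family classification and its labels are advisory.

Monoisotopic masses come from a pinned IUPAC/CODATA table; charged adducts
are electron-corrected. For C40H52O4, [M+H]+ computes to 597.3938 Da —
within 0.0003 Da of high-resolution LC–MS assignments of astaxanthin.

λmax calls smooth the spectrum with a centred moving average (default 5 nm)
and take the argmax, then refine it to sub-grid precision as the vertex of
a quadratic fitted to the smoothed curve within ±25 nm of the argmax. Both
steps are unbiased for a symmetric band, and the quadratic averages noise
across the peak top. For noisy broad bands the smoothing window should be
widened toward the band's FWHM (a matched filter); at a signal-to-noise
ratio of 20 on a 25 nm-sigma band, that recovers the band centre to within
1 nm across 200 noise realisations. A maximum on the search boundary (ramp
or flat trace) is a no-peak error, not a call. Shoulders are reported at
second-derivative sign changes on the long-wavelength flank, without a
wavelength-accuracy claim. Bathochromic shifts are signed bound-minus-free
differences of λmax.

## The synthetic generator: what it does and does not emulate

`make_polyene()` builds a planar zig-zag chain with *exactly* alternating
single/double bond lengths and 120° angles, end-ring stubs rotated to
requested torsions (placed by internal-coordinate construction, so the
requested dihedral is exact), and a hydroxyl oxygen on each stub so
hydrogen-bond code paths see ligand oxygens. `make_complex()` stacks two
copies in parallel planes (pure translation by default, so the plane
separation is exactly the requested offset; optionally a 180° rotation
about x, the relation real pigment pairs show) and surrounds the first with
shell pseudo-residues using real amino-acid atom naming (SER with OG), each
placed twice, mirrored through the polyene plane — one copy per chain — so
the two chains bury the ligand identically by construction. Far-away
filler residues keep the chains superposable. `make_c2_dimer()` adds exact
C2-symmetric pseudo-protein chains about a chosen axis, giving known
dimer-axis/pair-axis relations. All randomness flows from explicit seeds
and the generators restore the session RNG state.

What this validates: every descriptor's arithmetic, sign conventions,
cutoff semantics, and invariances (rigid-motion invariance to 1e-6 over
100 random transforms; exact parameter recovery of BLA, torsions and plane
separation). What it does not: real protein folds, crystallographic noise,
partial occupancy disorder, or genuinely ambiguous density — a passing
suite says the descriptors are computed correctly, not that any particular
deposition is well-modelled. Accession-based analyses
(`bcp_structure_report()` on a deposited mmCIF) run the identical code
path and carry those caveats.

## Numerical choices and degenerate inputs

* Alt-loc resolution: highest occupancy, ties by file order.
* Plane-fit normals: sign fixed (+z, then +x, then +y); collinear point
  sets are a degenerate-fit error.
* Dihedrals: collinear mid-bond triples are an undefined-torsion error.
* s-cis/s-trans boundary at exactly 90°: *s-cis* (strict inequality for
  *s-trans*).
* Kabsch: fewer than 3 pairs or collinear sets are errors; trimming stops
  when the fit is already exact (RMSD < 1e-8), so perfect matches are never
  trimmed.
* Interplanar angles are folded to [0°, 90°]; axis-relation thresholds
  30°/60°.
* JSON/TSV reports round floats to 4 decimals and use a fixed field order,
  so identical inputs give byte-identical files.

## Problem sizes

The shipped tests use 14–22-atom polyene paths, two-chain complexes of
~140 atoms, 15-residue pseudo-chains, 1000-point-set superposition oracle
checks, 100 random rigid motions, and 200 seeded noise realisations for
spectral recovery — sizes chosen so the whole suite exercises every code
path in well under a minute on one core while keeping the statistical
properties (oracle agreement at 1e-9, recovery at 1e-6) meaningful.

## Known limitations

* SASA subunit shares are radii- and probe-sensitive; compare shares only
  across runs with the same table (the defaults are pinned and logged).
* Hydrogen-bond detection is a heavy-atom proxy; donor/acceptor roles for
  hydroxyl pairs are not assigned.
* Pairwise burial fractions double-count triple overlaps (reported in
  `overlap`).
* No quantum chemistry: excitation energies, geometry optimisation, ring
  conformational energetics, and predicted λmax values are explicitly out
  of scope; BLA here is a descriptor of the coordinates you give it, not of
  an optimised geometry.
* Phylogenetic inference and signal-peptide prediction are out of scope;
  cysteine profile labels are advisory reconstructions.
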