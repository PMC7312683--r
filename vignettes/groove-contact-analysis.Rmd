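---
title: "Minor-groove contact analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minor-groove contact analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groovescan)
```

## The problem

Proteins read DNA sequence both directly, through base-specific hydrogen
bonds, and indirectly, through the local shape of the double helix.  The
width of the minor groove is the workhorse descriptor of that shape: narrow
grooves concentrate negative electrostatic potential and attract arginine,
while widened grooves -- up to the extreme of A-form-like geometry -- have
been associated with hydrophobic side chains.  `groovescan` implements a
complete, testable pipeline for quantifying this association in 3D
structures of protein--DNA complexes: it finds every amino acid residue
whose closest approach to the DNA is into the minor groove, attaches the
local groove width at that position, and derives composition,
secondary-structure, interaction-mode and sequence statistics from the
resulting residue--dinucleotide-step table.

## The contact algorithm

Each nucleobase carries two *reference atoms*, one near the floor of each
groove:

| base | minor groove | major groove |
|------|--------------|--------------|
| dA   | N3           | N6           |
| dG   | N3           | O6           |
| dT   | O2           | O4           |
| dC   | O2           | N4           |

For every amino acid residue, the distance to a reference atom is the
minimum Euclidean distance over the residue's non-hydrogen atoms.  The
residue is *minor-groove-contacting* iff its globally nearest reference
atom (over all duplex nucleotides in the structure) is a minor-groove atom
**and** that distance is strictly below 6.0 Å.  Both the cutoff and the
strictness matter: a residue whose nearest reference atom is a major-groove
atom is discarded even if some minor-groove atom is also within range.

Each contact is then assigned a *dinucleotide step*: the contacted
nucleotide plus the closer of its two sequence-adjacent neighbours on the
same strand (closeness again measured to the neighbours' minor-groove
reference atoms; an exact tie goes to the 5' neighbour, a terminal
nucleotide has only one choice).  The step's minor groove width and width
category complete one record of the dataset table.  Residues can share a
step; a residue never contributes two records for the same step.

Manual curation of mis-assigned residues is represented only as a blacklist
input -- no geometric heuristic tries to reproduce visual inspection.
Family-based pruning (`ds_prune`) removes records annotated to excluded
protein families; the defaults, PF00505 (high-mobility-group proteins) and
PF00352 (TATA-box binding proteins), are the two archetypal wide-groove
binder families.

## Groove width convention

Widths are computed from the structure itself, as cross-strand
phosphorus--phosphorus distances in the style of El Hassan & Calladine: for
step *s* (pairs *s*, *s+1*, 0-based) the width is the minimum P--P distance
over the level combinations (*s+1*, *s-1*), (*s+2*, *s-1*) and (*s+2*, *s*)
of strand-1/strand-2 phosphates flanking the step.  No van der Waals
subtraction is applied; the category thresholds below are calibrated for
raw P--P distances.  Steps whose window reaches past either duplex end are
undefined, as are steps with a missing phosphate; undefined widths are
never imputed.  An importer for externally computed per-step width tables
(plain TSV) is provided for users who prefer another engine's widths.

Width categories partition the positive axis: **narrow** ≤ 11.0 Å <
**standard** < 17.0 Å ≤ **wide**.  The boundaries sit near the 15th/85th
percentiles of typical protein-bound groove width distributions
(`percentile_thresholds` recomputes them for any table, using R's default
type-7 linear-interpolation quantile).  On the package's ideal fiber
models, the B-form helix falls in the standard category and the A-form
helix (18.5 Å central width) in the wide category -- the canonical
structural anchor for "wide like A-DNA".

## Interfaces, hexamers and sequence features

A protein--DNA interface is a maximal run of contacted steps in which
breaks of at most 2 consecutive non-contacted steps are bridged; bridged
steps count as part of the interface, so windows may be centred on them.
Interfaces spanning at least 6 nucleotides are scanned with a 6-nucleotide
sliding window (stride 1; a segment of L nucleotides yields L−5 windows).
Each window takes the width of its central dinucleotide step (windows with
an undefined central width are skipped and logged), a GC content in {0,
1/6, ..., 1} counted on strand 1, and the union of residues contacting any
of its five internal steps.  Width distributions are tabulated per GC level
both pooled and per amino-acid type.  Dinucleotide sequence preferences are
reported over the 10 complement-pooled step classes (ApA/TpT, ApT, TpA,
...), with strand-2 contacts mapped to their strand-1 representation.

## Statistics

**Composition and relative entropy.**  Amino-acid frequency distributions
are tabulated per width category.  Differences between categories are
summarized by the Kullback--Leibler divergence in bits,
D(p‖q) = Σ pᵢ log₂(pᵢ/qᵢ), with the first-named category as p.  When q has
zero mass at an amino acid where p does not, q's counts are smoothed with a
pseudocount of 0.5 before normalization; otherwise both distributions are
used exactly, so D = 0 holds if and only if p = q.

**Width tests.**  For the one-sided Mann--Whitney U scheme the amino acids
are split into a hydrophobic group (Leu, Ala, Ile, Val, Gly, Phe, Trp, Tyr,
Met) and a non-hydrophobic group (Asp, His, Glu, Gln, Asn, Thr, Ser, Lys,
Cys, Pro); arginine is excluded from every comparison population because
its abundance and narrow-groove preference would dominate the pooled
distributions.  Each hydrophobic amino acid's width distribution is tested
against the pooled non-hydrophobic widths; each non-hydrophobic amino acid
against the pooled widths of the other non-hydrophobic amino acids.  The
alternative hypothesis is always "greater median".  U uses midranks for
ties.  The p-value is exact -- full enumeration of all C(n₁+n₂, n₁)
labelings -- whenever that count is at most 50 000 (which covers every case
with min(n₁,n₂) ≤ 8 and n₁+n₂ ≤ 16); otherwise a tie-corrected normal
approximation with continuity correction is used.  In a null simulation
(1000 replicates of 19 amino acids × 8 records each, widths i.i.d. normal;
the acceptance suite runs exactly this) the per-test rejection rate at
α = 0.05 stays within 0.05 ± 0.02.  No multiple-testing correction is
applied; the number of tests is reported for transparency.

**Secondary structure.**  Rather than depending on DSSP, residues are
classified from their backbone dihedrals by fixed φ/ψ regions, applied in
precedence order: α-helix (φ ∈ [−100,−30], ψ ∈ [−80,−5]); 3-10 helix
(φ ∈ [−100,−30], ψ ∈ (−5,45]); polyproline-II (φ ∈ [−90,−55],
ψ ∈ [120,180]); β-strand (φ ∈ [−170,−70], ψ ∈ [90,180] ∪ [−180,−170]).
Putting polyproline-II before β resolves the overlap of those two boxes in
favour of the more specific region.  Residues outside all boxes are
labelled bend when the Cα virtual angle over five residues exceeds 70°,
turn between 45° and 70°, and "others" otherwise; missing dihedrals (chain
termini and breaks) give "unassigned".  These regions approximate, but do
not reproduce, DSSP's hydrogen-bond-energy-based classes; the "others"
membership in particular will differ.

**Interaction modes.**  Hydrogen bonds use geometric criteria: donor--
acceptor heavy-atom distance ≤ 3.5 Å and donor-antecedent--donor--acceptor
angle ≥ 90°, evaluated without hydrogens from packaged per-residue donor/
acceptor tables, in both directions across the interface.  Bonds are
classified by protein side (backbone vs side chain) and DNA target (base,
deoxyribose O4', or phosphate OP1/OP2/O5'/O3').  Heavy-atom pairs within
4.0 Å that are not hydrogen-bonded count as van der Waals contacts.  All
three thresholds are configurable arguments, not constants in the logic.
Residue--step superpositions for interaction-geometry pooling use the
closed-form Kabsch algorithm (proper rotation; degenerate/collinear input
is an error), and a set of steps is represented by the member minimizing
the summed pairwise RMSD, with ties (within 1e-9 Å, absorbing
floating-point noise) going to the lowest index.

## The synthetic generator: what it does and does not emulate

Because the statistics above are only trustworthy if every stage is
testable, the package ships a deterministic generator of fully ledgered
synthetic complexes.

*Fiber duplexes.*  `generate_fiber_duplex` builds all-heavy-atom A- and
B-form duplexes from a packaged repeating unit: an idealized planar
Watson--Crick pair template (procedural ring geometry; C1'--C1' ≈ 11 Å,
purine N1--pyrimidine N3 2.85/2.88 Å) propagated helically (A: 32.7°/2.56 Å
per step; B: 36.0°/3.38 Å), with deoxyribose rings built at the form's
canonical pucker (C3'-endo for A, C2'-endo for B) and phosphates placed at
per-form cylindrical coordinates.  The phosphate placement was calibrated
once so that the implemented width convention reproduces the canonical
ideal-form anchors -- 18.5 Å for A-form, ≈11.7 Å for B-form -- while
keeping phosphate--sugar distances chemically plausible.  Deliberate
idealizations: base pairs are planar and perpendicular to the helix axis
(no inclination, roll or propeller, although real A-DNA is inclined
~19°); backbone linkage geometry is approximate (the O3'--P bridge can be
stretched by a few tenths of an Å); there is no sequence dependence of the
geometry whatsoever.  Consequently, passing tests demonstrate the
correctness of the *algorithms* on controlled geometry, not the biological
realism of fiber models; real crystal structures have heterogeneous widths,
modified residues, and missing atoms that only the validation and logging
layers address.

*Perturbations.*  `perturb_groove` displaces the phosphate groups of a
step's width window radially (optionally with seeded Gaussian jitter) and
re-derives the O5'/O3' bridge atoms; a bond guard (derived P--C5'
separation within [1.6, 4.5] Å, O3' bridge within [1.6, 4.8] Å) rejects
displacements that would sever the backbone.  Width responds monotonically
to the displacement, which is what the category tests exercise.

*Probes.*  `plant_probe_residues` places complete heavy-atom amino-acid
residues (idealized internal geometry from small internal z-matrices) so
that the nearest probe atom sits *exactly* at the requested distance from
the requested reference atom -- a deterministic direction scan plus a 1-D
root solve -- while staying ≥ 0.5 Å farther from every other reference atom
and ≥ 2 Å from existing atoms.  The ledger records the expected detection
outcome of every probe, making 100%-precision/recall claims checkable.
Probes are isolated residues: they exercise contact detection, not
secondary structure (peptides with exact target dihedrals are built
separately by `build_peptide_with_dihedrals`).

*Defects.*  `make_defect_mutant` introduces exactly one documented defect
(missing atom, non-standard residue name, displaced base) for negative
tests of validation and pairing.

## Dataset-level filters and file handling

`parse_structure` reads PDB via bio3d (first MODEL only; highest-occupancy
altloc conformer, ties to file order; nucleotide naming dialects normalized
to dA/dC/dG/dT; hydrogens ignored throughout).  DNA chains are validated
against a packaged heavy-atom inventory (5'-terminal phosphates optional,
matching deposition practice); chains failing validation are excluded with
logged reasons.  Structure-level filters retain X-ray entries at resolution
≤ 3.5 Å (inclusive); missing resolution metadata excludes a structure with
a logged reason.  Non-redundancy is represented only as an optional chain
allowlist -- no sequence clustering is performed.  Base pairs are detected
geometrically (complementary bases, N1--N3 ≤ 3.5 Å, C1'--C1' ∈ [9.5, 11.5]
Å, greedy one-pair-per-nucleotide) and chained into antiparallel duplexes
of at least 3 pairs.

## Reproducibility and problem sizes

The pipeline (`run_synth` → `run_build` → `run_analyze`) is deterministic
for a fixed configuration and seed; two runs produce byte-identical TSV
outputs, and the run manifest logs a reason for every dropped record.  The
test and acceptance suites use desk-scale problem sizes chosen to exercise
every code path while remaining quick: 10--14 bp duplexes, ~200 planted
probes across 50 complexes for the recovery study, 200 enumeration cases
for the Mann--Whitney oracle, 1000 replicates for the type-I calibration,
and 100 randomized sugars for the pseudorotation cross-check.

## Known limitations

- Fiber-model geometry is idealized (above); the generator is a test
  harness and a source of anchors, not a DNA mechanics model.
- The φ/ψ classifier approximates DSSP; cross-study comparisons of
  secondary-structure counts should expect differences in the turn/bend
  and "others" classes.
- Hydrogen-bond detection is heavy-atom geometric; it does not place
  hydrogens or score energies.
- Groove widths are raw P--P distances; conventions that subtract 5.8 Å
  for phosphate van der Waals radii report values lower by that constant.
- Only minor-groove datasets are constructed; residues failing the
  minor-groove test are discarded, not analyzed as major-groove binders.
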