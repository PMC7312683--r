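# groovescan

Protein–DNA minor groove contact and width analysis in R.

## The problem

Proteins recognize DNA not only through base-specific hydrogen bonds but
also through the local *shape* of the double helix — indirect (shape)
readout. The width of the DNA minor groove is the central descriptor of
that shape: narrow grooves attract arginine through focused electrostatic
potential, while widened, A-form-like grooves have been associated with
hydrophobic side chains. `groovescan` is for structural bioinformaticians
who want to quantify this association in 3D structures of protein–DNA
complexes without stitching together half a dozen external programs.

## What it computes

For each amino acid residue in a complex, the pipeline finds the nearest
*groove reference atom* over all duplex nucleotides — N3/N6 for adenine,
N3/O6 for guanine, O2/O4 for thymine, O2/N4 for cytosine (minor/major
respectively), distances taken as the minimum over the residue's heavy
atoms. A residue is minor-groove-contacting iff its nearest reference atom
is a minor-groove atom **and** lies at *d* < 6.0 Å. Each contact is
assigned a dinucleotide step (the contacted nucleotide plus its closer
sequence neighbour) carrying the local minor groove width

  *w*(s) = min cross-strand P–P distance over the levels flanking step *s*

(no van der Waals subtraction), and a category: **narrow** (≤ 11 Å),
**standard**, or **wide** (≥ 17 Å). On the resulting residue–step table
the package derives per-category amino-acid compositions and their
relative entropies (bits), one-sided Mann–Whitney width tests per amino
acid (hydrophobic residues vs the pooled non-hydrophobic group, arginine
excluded), interface segmentation with ≤ 2-step gaps, 6-nucleotide sliding
windows with central-step widths and GC content, complement-pooled
dinucleotide preferences, a φ/ψ-region secondary-structure classifier,
and geometric hydrogen-bond / van der Waals interaction tables.

A deterministic synthetic-structure generator (fiber-model A/B-form
duplexes, groove perturbations, probe residues planted at exact distances
with a ground-truth ledger) makes every stage testable offline; the
A-form unit is calibrated so its central minor groove width is the
canonical 18.5 Å.

## Worked example

```r
library(groovescan)

# 1. synthesize a small ledgered study set (3 complexes, 11 probe residues)
bundles <- run_synth(demo_synth_spec(), tempfile("synth"), seed = 1)

# 2. build the contact dataset
cfg <- default_config(outdir = tempfile("reports"), seed = 1)
cfg$models <- lapply(bundles, function(b) b$model)
built <- run_build(cfg)
built$manifest$counts
#>   models_in models_kept    contacts     records
#>           3           3           9           9
head(as.data.frame(built$table)[, c("structure_id", "residue_type",
                                    "step_sequence", "distance", "width",
                                    "category")])
#>   structure_id residue_type step_sequence distance width category
#> 1        demo1          ARG            CA      4.0  11.7 standard
#> 2        demo1          LEU            AT      5.0  11.7 standard
#> 3        demo2          PHE            GC      4.5  18.5     wide
#> 4        demo2          ALA            CA      5.0  18.5     wide
#> 5        demo2          GLY            AT      5.5  18.5     wide
#> 6        demo2          TYR            TG      4.8  18.5     wide
```

Nine of the eleven planted probes are true contacts and all nine are
recovered, at exactly their planted distances; the two planted negatives
(6.5 Å from a minor atom; nearest atom in the major groove) are rejected.
The B-form complex shows the standard-category fiber width (11.7 Å), the
A-form complex the wide 18.5 Å.

```r
rep <- run_analyze(built$table, cfg, models = cfg$models)
rep$entropies
#>           comparison entropy_bits computable
#> 1 narrow_to_standard     4.700440       TRUE
#> 2   wide_to_standard     2.378512       TRUE
#> 3     wide_to_narrow     2.137504       TRUE
subset(rep$width_tests, amino_acid %in% c("PHE", "ALA", "THR"))
#>   amino_acid           group n1 n2 U         p            method significant
#> 2        ALA     hydrophobic  1  2 2 0.3333333 exact-permutation       FALSE
#> 5        PHE     hydrophobic  1  2 2 0.3333333 exact-permutation       FALSE
#> 8        THR non-hydrophobic  1  1 1 0.5000000 exact-permutation       FALSE
```

The entropies quantify how differently composed the narrow/standard/wide
contact sets are (in bits; here inflated by the tiny demo counts), and the
width tests report the exact one-sided Mann–Whitney p-value per amino acid
(nothing is significant at this size — the demo is an API tour, not a
study). `run_analyze` also writes the full report bundle (composition,
hexamer/GC, sequence-preference, secondary-structure, H-bond and vdW
tables) as TSV files into `cfg$outdir`.

The structural anchor in one line:

```r
g <- generate_fiber_duplex("A", "GCGCATGCATGCGC")
dup <- build_duplexes(detect_base_pairs(g$model), g$model)[[1]]
compute_minor_groove_width(dup, g$model, 6)
#> [1] 18.5
```

Real structures enter through `parse_structure("file.pdb")` (bio3d-backed;
first MODEL, highest-occupancy altlocs, naming dialects normalized),
`validate_dna_chain()` and `apply_dataset_filters()` (X-ray, ≤ 3.5 Å,
optional chain allowlist), with every exclusion logged in the run
manifest.

## Design notes

See the methods vignette (`vignettes/groove-contact-analysis.Rmd`) for the
model assumptions, parameter defaults with units, what the synthetic
generator does and does not emulate, and known limitations.
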