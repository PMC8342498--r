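# ptmfam

Site-specific PTM quantification by peptide-family normalization for
DIA/SWATH proteomics of fermented beverages.

## The problem

Bottom-up proteomics of beer (and similar malt-fermented beverages) sees
three pervasive post-translational modification classes that standard
protein-centric summaries ignore:

- **physiological proteolysis** — barley proteins clipped by malt
  proteases during mashing, detected as semi- or non-tryptic peptide
  termini;
- **glycation** — non-enzymatic Maillard attachment of
  maltooligosaccharides (oligohexose, Hex1–Hex10) to Lys residues of
  barley proteins;
- **O-/N-glycosylation** — oligomannose-type Hex1–Hex10 on Ser/Thr and
  HexNAc1–2(Hex0–10) at N-X-S/T sequons of secreted yeast proteins.

Because ionization efficiency differs across peptide forms, absolute
intensities of modified peptides are not comparable across samples.
`ptmfam` instead normalizes every modified or clipped peptide form to
its **peptide family**: the set of forms sharing one full-tryptic anchor
peptide. For family *F* in sample *s* with member intensities
*I(f, s)*, the proportion of form *f* is

    p(f, s) = I(f, s) / Σ_{g ∈ F} I(g, s)

and the **occupancy** of a PTM kind in family *F* is the summed
proportion of its modified members. Per-sample summaries are the
unweighted **total** (Σ over families of occupancy) and **average**
(mean over families) — two numbers that move independently, e.g. dark
beers show high average proteolysis but few detected clipped families.

Around that core the package provides: in-silico tryptic digestion with
missed cleavages and cleavage-class assignment; a validated modification
grammar; 1% peptide-FDR refiltering; protein abundance normalized to
total protein or to trypsin self-digest peptides; PCA; hierarchical
clustering with **uncentered correlation** (Cluster 3.0 semantics,
`d = 1 − Σxy/√(Σx²Σy²)`) and complete linkage; Welch-t /
Benjamini–Hochberg differential abundance; OLS regression of
protein-class abundance (NLTPs, serpins, seripauperins) against foam
measurements; and a fully seeded synthetic-data generator with ground
truth so the whole pipeline is testable without any raw MS data.

## Worked example

```r
library(ptmfam)
b   <- generate_dataset(synth_config(seed = 1))   # 23 beers, 224 families
res <- analyze_bundle(b)                          # parse -> FDR -> families
subset(res$occupancy, kind == "glycation" & startsWith(sample_id, "A-"))
```

```
    sample_id      kind total average n_families
   A-AmberAle glycation  2.75  0.0654         42
  A-GoldenAle glycation 10.75  0.2621         41
        A-IPA glycation 11.09  0.2640         42
    A-PaleAle glycation 10.84  0.2644         41
     A-Porter glycation  2.61  0.0621         42
 A-SessionAle glycation 10.72  0.2551         42
```

The two dark styles (Amber Ale, Porter) carry ~4x less glycation than
the pale styles of the same brewery — the planted dark-beer rule,
recovered by the pipeline. Checking estimates against the generator's
ground truth and the planted foam coupling:

```r
tc <- truth_check(b, res)
tc$occupancy$glycation$rmse   # 0.0280  (per-family occupancy RMSE)
tc$foam                       # slope -445.6, R^2 0.58 (planted target 0.7)

m <- as_feature_matrix(res$protein_abundance, "accession", "sample_id",
                       "log10_norm")
pca(m[rowSums(!is.na(m)) > 0, ])$explained_pct[1:2]
# "29.59%" "21.57%"
```

A negative seripauperin–foam-lifetime slope with R² within sampling
error of the planted 0.7 reproduces the qualitative finding that low
seripauperin levels accompany long-lived foam.

## Command line

```sh
Rscript inst/exec/ptmfam generate --seed 1 --out demo
Rscript inst/exec/ptmfam run --fasta demo/proteins.fasta \
    --quant demo/quant.tsv --metadata demo/metadata.tsv \
    --foam demo/foam.tsv --out demo_results
```

Subcommands `occupancy`, `cluster`, `compare`, `foamreg` expose single
stages with the same flags (`--fdr`, `--mode`, `--kind`, `--groups`).
Every run writes a `provenance.json` echoing all thresholds.

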