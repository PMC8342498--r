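---
title: "Peptide-family normalization of PTMs: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide-family normalization of PTMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmfam)
```

## The model

`ptmfam` analyses long-format peptide-level DIA/SWATH quantification of
beverages brewed from malted grain and fermented with yeast. Every
quantified row is a *peptide form*: a backbone span in a protein plus an
optional glyco/glycation modification and a cleavage class. Forms are
grouped into *peptide families*, each anchored on a full-tryptic
peptide, and all quantitative statements about modification are made
*within* a family:

$$p(f,s) \;=\; \frac{I(f,s)}{\sum_{g \in F} I(g,s)},\qquad
\mathrm{occ}_k(F,s) \;=\; \sum_{f \in F \,:\, \mathrm{kind}(f)=k} p(f,s).$$

The ratio cancels per-family ionization efficiency and per-sample
loading, which is what makes occupancies comparable across samples. The
assumptions are the usual ones for label-free XIC ratios: members of a
family co-elute from the same protein pool, intensities are
proportional to amount within a family, and a missing XIC means
"not detected", i.e. contributes zero to the family denominator rather
than being censored at random.

Three PTM kinds are distinguished. *Glycation* is oligohexose on Lys
(Maillard adducts of maltooligosaccharides; compositions Hex1–Hex10
accepted, Hex1–Hex7 emitted by the generator with Hex1/Hex2 dominant).
*Glycosylation* covers Ser/Thr oligohexose (O-mannosylation-like,
Hex1–Hex10) and N-glycans (HexNAc1–2, optionally Hex1–10, restricted to
N-X-S/T sequons). *Proteolysis* is any semi- or non-tryptic terminus —
physiological clipping by malt proteases, not an annotation on the
modification string.

### Cleavage classes and family anchoring

Trypsin cleaves C-terminal to Lys/Arg. A terminus is tryptic when the
preceding residue is K/R (N-side) or the last residue is K/R (C-side);
protein termini count as tryptic, otherwise every protein-terminal
peptide would be spuriously "clipped". The anchor of a form is the
*minimal* full-tryptic span containing it: fewest missed cleavages,
then shortest, then smallest start. The minimal-anchor rule makes
families disjoint and deterministic; it is our generalization of
"matched to each full tryptic peptide", and it is idempotent (the
anchor of an anchor is itself), which the tests verify against a
brute-force span search.

Glycated peptides typically *are* missed-cleavage peptides (the adduct
blocks cleavage at the modified Lys), so glycation families anchor on
one-missed-cleavage spans containing an internal Lys; their unmodified
counterpart is the same missed-cleavage backbone.

### Occupancy summaries

For each kind, *eligible* families are those with at least one member
form of that kind anywhere in the dataset; summaries run over eligible
families *detected* (family total > 0) in the sample. `total` is the
unweighted sum of per-family occupancies — the literal reading of
"sum of all modified peptides normalised to their peptide family" — and
`average` is their mean. An intensity-weighted total is available via
`occupancy_summary(..., weighted = TRUE)` but is not the default. The
two summaries deliberately decouple: a sample can have high average
occupancy (strong clipping within detected families) and low total
(few clipped families detected), which is exactly the dark-beer
signature the package is designed to expose.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `fdr_cutoff` | 0.01 | q-value | the emulated study's 1% peptide FDR refilter |
| `max_missed` | 2 | cleavages | the emulated search setting |
| `collapse` | mean | — | technical replicates averaged *before* normalization; family proportions are ratio statistics and ratios of sparse replicates are unstable |
| `mode` | total | — | protein abundance as fraction of summed (non-contaminant, non-trypsin) protein signal; `trypsin` divides by trypsin self-digest signal instead |
| `alpha` | 0.05 | — | significance flag for volcano and regression outputs |
| proline rule | off | — | the emulated search states plain C-terminal K/R cleavage with no proline exception; `proline_rule = TRUE` restores the convention |
| sequon rule | X = P allowed | — | the motif is stated as N-X-S/T without exclusions; `allow_proline = FALSE` gives the conventional rule |

Normalization modes differ in what they are invariant to: `norm_total`
is invariant to global per-sample intensity scaling; `norm_trypsin` is
invariant only if trypsin peptides scale with the rest, but unlike
`norm_total` it is not compositional (one protein's change does not
mechanically move the others).

## Numerical choices

- **Missing vs zero.** Missing intensities are explicit (`NA`), count 0
  in family denominators and protein sums, and a family is detected in
  a sample iff its total is positive. Undefined families carry `NA`
  proportions and are excluded from averages.
- **log10 floor.** `log10` is taken only of strictly positive
  normalized abundances; zeros become `NA` with no pseudo-count.
  Before PCA/clustering, `NA` cells are imputed with the feature
  minimum (i.e. "at the detection limit"); a row-mean alternative is
  available. The choice is recorded in provenance.
- **PCA.** Column-centered, unscaled (`prcomp`), samples as
  observations; explained variance reported to two decimals as
  percentages.
- **Clustering.** Uncentered correlation distance
  \(d = 1 - \sum x_iy_i / \sqrt{\sum x_i^2 \sum y_i^2}\) (no mean
  centering, range 0–2, scale-free per vector) with complete linkage.
  Ties in the minimum inter-cluster distance break on the lowest pair
  of cluster indices in creation order, making dendrograms
  byte-reproducible. The agglomeration returns a standard `hclust`
  object and is checked against an \(O(n^3)\) re-derivation including
  heights.
- **Differential abundance.** Welch t-test per feature on per-beer
  means (beers, not injections, are the experimental unit), BH
  adjustment across tested features, positive log2FC = higher in the
  first-named group. The emulated study never names its test; this
  choice is flagged in provenance output.
- **Collapsed common modifications.** Deamidation/oxidation variants of
  a form are summed into the parent form (minimum q-value kept), since
  family analysis concerns glyco/glycation/clipping states only.

## What the generator emulates — and what it does not

`generate_dataset()` emits a FASTA (synthetic accessions, species tags
in headers), a long quant TSV, beer metadata, and a foam table, with
complete ground truth. The default world: 23 beers across 7 breweries
(two flagged multinational), technical triplicate with 20% lognormal
CV, log10 protein base abundance N(4.5, 0.6) with brewery (SD 0.30) and
style (SD 0.15) effects, yeast proteins shifted +0.4 log10 in
independent-brewery beers, glycation Hex weights proportional to
52:37:… (Hex1/Hex2 dominant), O-glycan weights decaying over Hex1–Hex8,
exactly one HexNAc1 sequon event on one yeast protein, and a dark-beer
rule: glycated-form proportions ×0.25, clipped-form proportions ×2.5,
clipped-family abundance ×0.02 so most clipped families fall below the
detection limit (10^3 intensity units) in dark styles. Foam lifetime
and small-bubble counts are linear in the seripauperin class sum with
negative slopes; the noise SD is calibrated against the realized
predictor variance so the planted coefficients of determination are
0.70 and 0.38 — targets the recovery tests then re-estimate, not
asserted equalities. Values not stated by the emulated study (protein
counts, effect SDs, detection limit, dark factors) were chosen once as
field-realistic and are not tuned against test outcomes.

Deliberately *not* simulated: spectra, retention time, m/z,
chromatographic interference, shared peptides across proteins,
between-batch drift, hop/bacterial proteins, and biological (as opposed
to technical) replication. A green recovery test therefore establishes
that the estimators are correct and well-calibrated under the stated
noise model — not that real DIA data meet that model. Detection is
modeled at the family level (a family below the limit vanishes
entirely); real XIC dropout can be form-specific, which would bias
occupancy in ways the generator cannot expose.

## Open design decisions, resolved

- *Anchor on 0-missed peptides only?* No: minimal anchor over ≤
  `max_missed` spans, so glycated missed-cleavage backbones form proper
  families. Deterministic tie-breaks keep families disjoint.
- *Normalize before or after replicate collapse?* Mean-collapse first
  (default); both orders are available through the API
  (`family_normalize` accepts any per-sample table).
- *Weighted or unweighted total occupancy?* Unweighted by default —
  the literal reading of the figure-caption definition; weighted
  behind a flag.
- *Shared peptides.* A row is credited to the accession given in the
  row; cross-protein deduplication is out of scope.

## Known limitations

Occupancies are ratios of noisy sums and slightly biased at small
family totals (the recovery tests bound the effect at CV 20%,
triplicate). Proteins quantified only by decoy-like or
FDR-failing rows vanish rather than being imputed. The volcano stage
assumes exactly two groups; nested designs (styles within breweries)
get no mixed-effects treatment. `norm_total` is compositional, so
strong changes in one abundant protein induce anti-correlated apparent
changes elsewhere — the trypsin-reference mode exists precisely to
check robustness of any conclusion against this.
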