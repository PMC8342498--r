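Package: ptmfam
Title: Site-Specific PTM Quantification by Peptide-Family Normalization
    for DIA/SWATH Proteomics
Version: 0.1.0
Authors@R:
    person("ptmfam", "developers", email = "ptmfam@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of peptide-level DIA/SWATH-MS
    quantification tables for beverages fermented from malted grain:
    in-silico tryptic digestion and cleavage-class assignment,
    parsing of glycated (oligohexose on Lys), O-/N-glycosylated and
    physiologically clipped (semi/non-tryptic) peptide forms, grouping
    of forms into peptide families anchored on full-tryptic peptides,
    FDR refiltering, within-family proportion and site-occupancy
    summaries, protein abundance with total- or trypsin-reference
    normalization, principal component analysis, hierarchical
    clustering with uncentered correlation and complete linkage,
    differential abundance (Welch t + Benjamini-Hochberg), linear
    regression of protein-class abundance against foam measurements,
    and a seeded synthetic-data generator with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
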