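Package: hlacpep
Title: HLA-C C1/C2 Dimorphism Analysis of Immunopeptidomes and
    Peptide-Binding-Groove Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how the HLA-C C1/C2 dimorphism (residues 77 and
    80 of the heavy chain) shapes the peptide repertoire at the C-terminal
    anchor (pOmega) and the penultimate position (pOmega-1). Reads, merges
    and deduplicates per-allotype eluted-peptide lists, classifies allotypes
    into C1/C2 by the Ser77/Asn80 vs Asn77/Lys80 rule, computes
    position-specific amino-acid frequency matrices and group-level
    enrichment statistics (Fisher's exact test on anchor counts,
    Student/Welch t volcano tables, position-wise Pearson correlations,
    side-chain-volume correlation), and extracts a panel of
    peptide-binding-groove geometry descriptors (position-77 Cbeta to
    pOmega-1 Calpha distance, Tyr171 hydroxyl to peptide N-terminus
    distance, pOmega-1/Val76 side-chain contact distance, terminal
    peptide-bond torsion) from peptide-MHC crystal structures in PDB or
    mmCIF format. Includes seed-controlled synthetic peptide panels and toy
    coordinate fixtures with analytically known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
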