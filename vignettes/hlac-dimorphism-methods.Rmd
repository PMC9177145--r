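---
title: "Methods: C1/C2 dimorphism analysis of HLA-C immunopeptidomes and groove geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: C1/C2 dimorphism analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlacpep)
```

## The question the package answers

HLA-C allotypes divide into the C1 group (Ser77/Asn80) and the C2 group
(Asn77/Lys80). Residue 77 points into the peptide-binding groove next to
the F pocket that buries the peptide C-terminal anchor (pΩ), so the
dimorphism is positioned to shape both *which* C-terminal and penultimate
(pΩ-1) residues are presented and *where* the pΩ-1 backbone sits. The
package quantifies both effects: position-specific amino-acid statistics
over per-allotype eluted-ligand sets, and a panel of four geometric
descriptors over peptide–MHC crystal structures.

## Sequence arm

### Peptide sets

A `peptide_set` holds one allotype's eluted ligands: upper-cased,
validated against the 20-letter alphabet (B/J/O/U/X/Z rejected with the
offending line reported, never silently dropped), restricted to the 8–15
length range, deduplicated by exact string equality and stored sorted.
Merging lists from independent studies is a set union, so it is idempotent
and order-independent; source labels accumulate per sequence. Analyses run
on length strata — 9mers are the primary set, 10mers a secondary one —
because position indices are only comparable at fixed length.

Datasets raised in C1R cells carry a background of peptides bound by the
cell line's endogenous HLA-B\*35:03/HLA-C\*04:01. The published peptide
lists had such motif-matching background removed without a stated
algorithm, so the filter here is an explicit stand-in: a position-frequency
matrix per length scores each peptide by log-likelihood and peptides at or
above a per-motif threshold are removed, each removal logged with the motif
responsible. The filter is off unless motifs are supplied; the bundled
default motif's threshold sits one self-score standard deviation below the
expected self log-likelihood (≈85% recall on motif draws), and real uses
should tune it because the false-positive rate depends entirely on how
similar the true motif is to the contaminant.

### Frequency and enrichment statistics

`position_frequency_matrix` counts residues per position (via
`Biostrings::consensusMatrix`) and normalises to frequencies. The
group-level comparison in `group_enrichment` follows three deliberate
choices:

* **Allotypes are the unit of replication.** Group means are unweighted
  means of per-allotype frequencies, not pooled counts: allotype set sizes
  differ by more than tenfold, and pooling would let the largest sets
  dominate. The t-tests run across the allotype-level frequencies, on the
  percent scale.
* **Folds are pseudocounted.** C2/C1 fold differences are formed on means
  of `(count + 0.5) / (n + 10)` per allotype (Haldane–Anscombe), so a
  residue absent from one group yields a finite fold; raw means and
  standard deviations are reported alongside.
* **Both t variants are exposed.** The volcano flag (fold ≥ 2 or ≤ 0.5 and
  p < 0.05) uses the equal-variance Student test by default; the
  Welch-corrected p is always reported as a column, and either can drive
  the flag. Degenerate cells are defined explicitly: two zero-variance
  groups with equal means give t = 0, p = 1; with different means, p = 0.
  No multiple-testing correction enters the flag — the fold threshold plays
  that role — but a Benjamini–Hochberg column is emitted for transparency.

`fisher_count_test` is the exact two-sided comparison for a single residue
count in two sets. Two-sidedness follows the probability-mass convention
(sum of all tables with the same margins whose hypergeometric probability
does not exceed the observed table's), matching `stats::fisher.test`;
this is documented because mid-p and central conventions differ in the
third significant figure.

`volume_correlation` relates log2(C2/C1) enrichment to side-chain volume
on the Zamyatnin (1972) scale. The published analysis does not name its
volume scale; Zamyatnin is the common default and any complete scale can
be substituted. An open question we settled the same way: whether the
volcano t-test ran on percent or proportion scale is immaterial for t and
p (scale-invariant), and percent matches the reported standard deviations,
so percent is used throughout.

## Structure arm

`load_structure` parses PDB/mmCIF through bio3d, keeps the first model,
drops hydrogens, and resolves altlocs to the highest-occupancy conformer
(ties to the first letter). Chain auto-detection takes the shortest 8–11
residue chain as the peptide (ties are an error demanding explicit ids)
and a ≥100-residue chain containing residues 76/77/171 — preferring Tyr at
171 — as the heavy chain; author numbering is used, with an integer offset
option for shifted files.

Descriptor conventions:

* `d77_pOmega1` uses the Cβ of residue 77 — the first side-chain carbon —
  and the Cα of the *penultimate* peptide residue, which generalises p8 of
  a 9mer to p9 of a 10mer.
* `d_tyr171_nterm`: tyrosine's side-chain oxygen is the η-hydroxyl, PDB
  atom name `OH` (sometimes loosely called Oγ); `OH` is what is measured.
* `d_val76_side` is the minimum over side-chain heavy-atom pairs (Cβ and
  beyond); backbone N/Cα/C/O/OXT are excluded, glycine makes the
  descriptor undefined (reported as NA, excluded pairwise from group
  statistics with a log message). Residue 76 is the contact partner —
  the conserved Val76 of the α1 helix.
* `terminal_torsion` reports ω of the pΩ-1→pΩ bond,
  dihedral(Cα,C,N',Cα'), signed IUPAC convention in (−180, 180], with
  ψ(pΩ-1) as an auxiliary: a terminal-bond torsion could denote either
  dihedral, and ω is the default because it is the torsion of the bond
  itself. Group means of torsions
  are arithmetic on the signed values, which is only meaningful away from
  the ±180° wrap; panels near the wrap should be inspected directly.

Group comparisons (`group_geometry_stats`) use unweighted means, sample
standard deviations and two-sided Welch t-tests, with a hard error when a
descriptor is constant in both groups rather than a silent NA.

## Synthetic data: what it emulates and what it does not

`sample_peptide_panel` draws peptides position-independently from a
group-specific frequency matrix. Its defaults are the study conditions:
14 C1 and 7 C2 allotypes (reusing the study allotype names), 9mers, group
pΩ-Ala rates of 1.45% and 0.27% (the reported group means), and a pΩ-1
volume tilt of 0.7 per volume-SD, which makes a residue one standard
deviation above mean volume about twofold C2-enriched — the magnitude of
the reported p8 effect. The default 1000 peptides per allotype matches
the scale used in the recovery analyses; the acceptance script uses 1300,
the study's average per-allotype count. The generator supports planted
pΩ-1 multipliers (for detectability experiments), an optional
pΩ-conditional pΩ-1 distribution (emulating the observation that small
pΩ-1 residues are preferred more strongly in pΩ-Ala peptides), and a
contaminant admixture.

What it deliberately does not emulate: positional coupling beyond the one
optional conditional, between-allotype motif heterogeneity within a group
(all allotypes of a group share one matrix, so between-allotype variance
is pure multinomial noise — real allotypes vary far more, e.g. the
reported 1.45% ± 1.4% across C1 allotypes), peptide abundance, and
proteome-derived sequence statistics. Passing recovery tests therefore
show the estimators are correct under the stated model, not that real
immunopeptidomes satisfy the model.

`build_toy_structure` writes a heavy-chain stub plus peptide whose four
descriptors equal their targets *exactly* at zero noise, by analytic
placement (natural-extension frame construction for the terminal
torsions; axis-aligned contact geometry for the distances). It is a
geometric fixture, not a folded MHC: only the atoms the descriptors touch
are meaningful. mmCIF output carries full floating-point precision and is
what the 1e-6 round-trip tests use; PDB output is limited by the format's
3-decimal coordinate fields (~2×10⁻³ Å).

## Numerical and testing choices

* Multinomial recovery is asserted two ways: mean absolute error < 0.01
  per cell at 2000 peptides/allotype, and ≥99% of cells within 3
  multinomial standard errors (with a hard 6-SE cap). Per-cell 3σ coverage
  is 99.73%, so demanding *every* cell inside 3 SE would fail by chance in
  panels of hundreds of cells; the coverage form is the statistically
  meaningful statement of the same bound.
* Planted-effect detectability uses a 2.5× pΩ-1 multiplier against the
  fold ≥ 2 flag. A planted fold exactly at the flag threshold would make
  the flag a fair coin by construction (the estimated fold straddles 2),
  so the detectability experiments plant a clearly super-threshold effect
  and verify ≥18/20 seeded detections, with ≤2/20 flags on null panels.
* Problem sizes in the default suite — panels of 2–6 allotypes × 200–2000
  peptides, 20-seed power runs, toy structures with 180-residue stubs —
  were chosen to exercise every code path at sampling errors small enough
  for the stated bounds.
* Determinism: every stochastic step takes a seed (`withr::with_seed`, so
  the caller's RNG state survives); identical config and seed reproduce
  report files byte-for-byte, with timestamps confined to the run log.

## Known limitations

* The contaminant filter is a stand-in for an unpublished procedure; the
  published peptide totals (e.g. 3182 nonredundant C\*08 9mers in the
  methods vs 1986 in the pΩ-Ala result) cannot be reconciled exactly, so
  full reconstruction of the published merged dataset is an integration
  goal, not something the offline tests claim.
* Structure analyses assume class-I author numbering (76/77/171); heavily
  renumbered files need the offset option or explicit chains.
* Torsion group statistics are non-circular (see above).
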