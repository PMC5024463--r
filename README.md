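# indelstruct

Structure-aware triage of small in-frame insertions and deletions
(indels) detected by gene-panel sequencing, built for the situation
faced in inherited eye disease diagnostics (childhood cataract,
retinal dystrophy): a cohort yields dozens of rare in-frame indels —
a gain or loss of ≤21 nt, hence 1–7 amino acids — and sequence-based
predictors return damaging/neutral calls without mechanistic
justification. `indelstruct` annotates the indels, classifies their
slippage-prone sequence contexts, selects a homologous structure
template per affected protein, reads the likely disruption mechanism
off the structural context of the affected residues, and scores
prediction–clinical concordance.

## What it computes

* **Variant annotation** — VCF parsing, left alignment to the minimal
  anchored representation, strand-aware projection onto transcript
  CDS, frame classification (`in_frame` ⟺ |Δlen| mod 3 = 0), HGVS
  `c.`/`p.` names with the protein change placed at its 3'-most
  equivalent position, splice-proximity flags (±2 bp of intron–exon
  boundaries), and the cohort filters: read support < 0.1 discarded,
  population allele frequency > 1 % deemed benign, samples kept when
  ≥ 99.5 % of the target reaches 50×.
* **Sequence context** — homopolymer runs (≥ 6 identical bases) and
  tandem repeats (≥ 2 consecutive copies of a 1–21 nt unit covering
  the altered bases), smallest unit reported.
* **Template selection** — Smith–Waterman/BLOSUM62 local alignment
  (gap open 11, extend 1), bit score
  `b = (λS − ln K)/ln 2` (λ = 0.267, K = 0.041), E-value
  `E = m·n·2⁻ᵇ`, candidates at `E ≤ 10⁻³` that show strictly more
  than 5/11 identity in the alignment window covering the variant
  residues ± 5 columns; target residues mapped column-by-column onto
  the template's ATOM records.
* **Structural context** — Kabsch–Sander secondary structure
  (H-bond when `0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) < −0.5`
  kcal/mol), Shrake–Rupley accessibility (960 points, probe 1.4 Å),
  edge/central strand topology, inter-chain contacts ≤ 4.5 Å and salt
  bridges ≤ 4.0 Å (DNA phosphate OP1/OP2 included), and the helix
  register shift `(n × 100°) mod 360°` from 3.6 residues per turn.
* **Verdict** — first matching rule: strand residue → *probably*
  (β-sheet disruption); interface helix with shift ≥ 60° → *probably*
  (register shift); inter-chain salt bridge/contact → *probably*
  (binding-site disruption); remote surface loop → *unlikely*;
  otherwise *unclear* (packing loss).
* **Evaluation** — three-tool agreement, confusion-matrix statistics
  against clinical labels (clinical *possibly* excluded; structural
  *unclear* counted damaging-side), and cohort rates.
* **Synthetic data** — seeded generators for genomes/transcripts/VCFs
  with planted homopolymer and tandem-repeat indels, and ideal
  protein geometries (helix, β-sheets, two-helix dimer, protein–DNA
  complex) on which every structural operation is exercisable offline.

## Worked example

```r
library(indelstruct)

# 1. normalize an indel in a homopolymer run
normalize_indel(raw_variant("chr22", 4, "TT", "T"), "GATTTTC", 1)
#> <raw_variant> chr22:2 AT>A

# 2. verdict for deleting one residue from an edge strand of an
#    ideal three-strand sheet
pdb <- build_geometry(geometry_spec("beta_sheet", n_residues = 10,
                                    n_strands = 3, connect = TRUE))
ann <- annotate_structure(parse_structure(pdb))
classify_mechanism(ann, data.frame(chain = "A", resno = 5),
                   n_changed_residues = 1)
#> <mechanism_verdict> probably [beta_sheet_disruption]

# 3. concordance of predictors with the clinical assessment on the
#    packaged eight-variant table
evaluate_against_clinical(make_table1_fixture())
#>    predictor n_evaluated TP FP TN FN accuracy sensitivity specificity
#> 1    ddig_in           7  5  1  0  1     0.71        0.83           0
#> 2 sift_indel           7  6  1  0  0     0.86        1.00           0
#> 3    provean           7  6  1  0  0     0.86        1.00           0
#> 4 structural           7  6  0  1  0     1.00        1.00           1

# 4. cohort-level rates from the packaged count table
summarize_cohort(eye_cohort_counts())[3, ]
#>      group carrier_rate_pct reported_per_tested modelable_pct agreement_pct
#> 3 combined             16.8                  37          14.5          61.8
```

Reading the output: the single-base deletion in the `TTTT` run shifts
to its left-most anchored form (`chr22:2 AT>A`). The edge-strand
deletion is called *probably* disruptive because β-sheets are
cooperative hydrogen-bond networks. On the packaged table, one indel
per ~37 probands tested is clinically reported, 16.8 % of probands
carry a small in-frame indel, the three sequence tools agree on
61.8 % of variants, and 14.5 % of indels fall in regions with a
usable structure template.

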