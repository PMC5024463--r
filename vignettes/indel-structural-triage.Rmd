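---
title: "Structural triage of small in-frame indels: models, rules and design choices"
author: "indelstruct"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Small insertions and deletions — defined here as a gain or loss of at
most 21 nucleotides at a single locus — are the second most common form
of coding variation, and the in-frame subset (net change a multiple of
3, so 1–7 amino acids gained or lost) is notoriously hard to interpret
in diagnostic settings. Sequence-based predictors return a single
damaging/neutral call without saying *why*. This package implements a
complementary, structure-aware triage: normalize and annotate the
indels from a panel-sequenced cohort, classify their slippage-prone
sequence contexts, select a homologous structure template for each
affected protein, and read the likely disruption mechanism directly off
the structural context of the affected residues — ending in a
three-level verdict (*probably* / *unclear* / *unlikely* disruptive)
with machine-readable evidence, plus concordance statistics against the
clinical assessment.

# Variant annotation

Indels are parsed from VCF and left-aligned to the minimal anchored
representation (the canonical VCF convention); the brute-force
equivalence class over the local reference window defines the target
representation, and a property test checks the implementation against
that enumeration. Protein-level names instead follow the HGVS
convention of the *most C-terminal* equivalent position. Both
representations are stored; this asymmetry (5'-shifted DNA, 3'-shifted
protein) is deliberate and matches how diagnostic laboratories report
variants.

Consequence calling projects the altered bases through the transcript's
CDS intervals, strand-aware. The design keeps edge cases *typed* rather
than forced: purely intronic changes return `non_coding`,
changes straddling an exon/intron junction return `junction_spanning`
with no fabricated protein change, deletions touching the initiator or
stop codon return `terminal_codon`, and a non-codon-aligned deletion
whose junction codon happens to be a stop is named `p.(Xaa#Ter)`.
Records longer than 21 nt are kept and flagged out of scope rather than
silently dropped, so the small-indel definition remains auditable.

Cohort filters mirror the study design and are applied in a fixed
order with the first failing rule recorded: read support (discard below
0.1 of reads — strictly below, so exactly 0.1 is kept), population
allele frequency (above 1% is deemed benign), then size. Missing
metrics pass their rule; the filters only act where the evidence
exists. Sample-level coverage uses the inclusion rule of at least
99.5% of the target covered to 50x. Changes within 2 bp of an
intron–exon boundary are flagged splice-proximal (boundary bases
inclusive), not excluded.

# Sequence context

Two contexts are classified on the reference around each normalized
indel: a homopolymer run (HR) when the altered bases lie within, or an
insertion of the run base immediately extends, a maximal run of six or
more identical bases; and a tandem repeat (TR) when some unit of 1–21
nt has at least two consecutive reference copies containing the altered
bases, with the net change a whole number of units or the indel itself
a rotation of unit copies. The smallest qualifying unit is reported
(CAGCAG is two copies of CAG, not one of CAGCAG), and a homopolymer is
by construction also a 1-mer tandem repeat, so HR and TR are emitted
as independent flags plus a combined label (`HR`, `TR`, `HR+TR`,
`other`) — both readings of the category scheme stay available. The
search is bounded to units of 21 nt within a ±30 nt flank, which covers
every in-scope indel; detection is checked against a brute-force
unit-enumeration oracle on random sequences with planted arrays.

# Template selection

Template search scores a Smith–Waterman local alignment (Gotoh affine
gaps) of the affected protein against each library sequence under
BLOSUM62 with gap open 11 / extend 1 — the classic protein-BLAST
parameterization — and converts the raw score $S$ to a bit score
$b = (\lambda S - \ln K)/\ln 2$ with the gapped Karlin–Altschul
constants $\lambda = 0.267$, $K = 0.041$, then
$E = m\,n\,2^{-b}$ for target length $m$ and library size $n$
residues. Candidates must reach $E \le 10^{-3}$ and pass the
variant-window rule: strictly more than 5/11 identity over the
alignment columns holding the affected residues plus five flanking
columns on each side. Gap columns count as mismatches and `X` never
counts as an identity. At sequence termini, or for multi-residue
variants whose window exceeds 11 columns, the strict threshold scales
proportionally (`count > 5·len/11`); truncated windows are flagged.
Ranking among qualifying hits is a documented tie-break cascade —
window identity fraction, then global identity, then E-value, then
identifier — chosen to be order-invariant because "closest match" has
no canonical definition. The target is then mapped residue-by-residue
onto the template's ATOM records by walking alignment columns; rather
than building an explicit homology model, all structural reasoning is
performed on the selected template at the mapped positions, which is
the information the verdicts operationally rest on.

# Structural annotation and mechanism rules

Secondary structure follows the Kabsch–Sander convention: amide
hydrogens are imputed 1.0 Å from N opposite the preceding carbonyl,
the electrostatic hydrogen-bond energy
$E = 0.084 \cdot 332 \cdot (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
kcal/mol defines a bond at $E < -0.5$, helix requires two consecutive
$i \to i+4$ turns, and strands come from parallel/antiparallel bridge
patterns (bridges may span chains). Solvent accessibility is
Shrake–Rupley quadrature with 960 golden-spiral points per atom, probe
1.4 Å and radii C 1.70 / N 1.55 / O 1.52 / S 1.80 / P 1.80 Å; relative
accessibility divides by a theoretical per-residue maximum and a
residue is "surface" at RSA ≥ 0.25. A strand is *central* when it has
bridge partners in two distinct neighbouring strands and *edge* with
one. Inter-chain interface contacts use a 4.5 Å heavy-atom cutoff;
salt bridges require a charged side-chain atom within 4.0 Å of an
opposite charge, DNA phosphate OP1/OP2 included.

The verdict is the first matching rule, in order: (1) any affected
residue in a strand → *probably*, β-sheet disruption — sheets are
cooperative hydrogen-bond networks, and both edge and central strands
qualify; (2) any affected residue in a helix whose segment packs
against another chain, when the register shift $(100°$ per
residue$) \bmod 360°$ reaches 60° → *probably*, register shift — at
3.6 residues per turn, one deleted residue rotates every downstream
side chain by 100°, moving interface residues to the surface; (3) any
affected residue contacting another chain (salt bridge or interface)
→ *probably*, binding-site disruption; (4) affected residues all in
surface coil, contact-free and at least 3 residues from the nearest
helix/strand → *unlikely*; (5) otherwise → *unclear*, packing loss.
"Unclear" is therefore produced structurally, not by abstention: a
loop deletion adjacent to a sheet, or a buried packing change away
from any interface, is genuinely ambiguous at this level of modelling.

All numeric cutoffs in the two preceding paragraphs are the package's
own calibration: the underlying biological reasoning is qualitative,
so each threshold is a named field of `structure_thresholds()` with
the qualitative behaviour of the six canonical scenarios as its fixed
point, and each is exercised by tests on ideal geometry where the
correct answer is known by construction.

# Evaluation conventions

Concordance statistics take the clinical report as the standard.
Records whose clinical call is *possibly* are excluded; tools map D →
positive, N → negative; the structural verdict maps *probably* and
*unclear* to positive and *unlikely* to negative, with *unassessable*
excluded for the structural predictor only. Treating an inconclusive
structural call as damaging-side parallels how the sequence tools'
D calls are read, and is applied uniformly — the packaged
prediction table is evaluated under exactly this convention, and the
resulting confusion-matrix cells are printed alongside the rounded
metrics (2 decimals for metrics, 1 for percentages, centralised in
`round_metric()`/`round_percent()`). Specificity with no clinical
negatives is reported `NA`, never 0/0. Cohort rates divide the
transcribed count table directly; the packaged combined row keeps the
published headline numerator (112 carriers of 667) even though the
per-group counts sum to 111 — the table documents this rather than
silently reconciling it.

# What the synthetic data emulate — and what they do not

`generate_cohort()` plants a configurable mixture of in-frame and
frameshift indels into synthetic multi-exon genes on both strands, one
variant per 33-nt codon-aligned CDS slot kept clear of exon junctions.
Defaults encode the study conditions: 667 probands, 55 in-frame
indels, a 63.6% tandem-repeat fraction, and an affected-residue size
distribution with mean ≈ 2.2 and median 1.5 over the 1–7 range.
Quantities the study does not report are fixed once at realistic
values and documented here: a 20% homopolymer fraction (HR variants
are a subset of TR under the 1-mer reading), a 70:30
deletion:insertion ratio, read support drawn mostly from a balanced
heterozygous-like Beta(30,30) with a 10% low-support artifact
component Beta(2,30), and allele frequencies mostly rare with a 15%
common component reaching 5%. Planted contexts are verified by
re-detection at generation time, "other" loci by rejection sampling,
so the truth table is exact. What the generator does **not** emulate:
read-level errors, alignment artifacts, imperfect/degenerate repeats,
population structure in allele frequencies, or multi-transcript genes
— so a passing round-trip shows the annotation and context machinery
is internally correct, not that it is robust to noisy real-world
calls.

`build_geometry()` produces ideal structures from internal
coordinates (N–CA 1.46, CA–C 1.52, C–N 1.33 Å): an α-helix at
φ = −57°, ψ = −47° (carbonyl–amide i→i+4 distances ≈ 3.06 Å),
antiparallel sheets whose strand placement is refined over a
deterministic grid by maximizing cross-strand hydrogen-bond counts —
either as separate chains or as a single-chain meander joined by
glycine loops (the monomeric topology, used for the loop-adjacent
scenarios), a parallel two-helix dimer with leucines packing the
interface, and a protein–DNA complex with exactly one arginine–
phosphate pair at 3.2 Å. Ideal geometry is the point: the
secondary-structure and accessibility code can be validated against an
independent implementation (mdtraj) where agreement is expected to be
near-perfect; distorted or low-resolution experimental structures will
be messier than anything these fixtures show.

The end-to-end fixture (`generate_structural_cohort()`) closes the
loop: synthetic genes encode exactly the fixture chain sequences, so
each planted deletion maps through alignment onto the structure it
came from and the verdict distribution is known in advance.

# Numerical choices and degenerate inputs

Alignment tracebacks break ties deterministically toward the earliest
target position, so selection is reproducible; `select_template()` is
invariant under permutation of its input. Sphere quadrature uses a
fixed golden-spiral point set, making SASA exactly reproducible and
the isolated-atom case quadrature-exact ($4\pi(r+1.4)^2$). Residues
with missing backbone atoms are assigned coil with a warning flag
rather than dropped. AltLoc conformers resolve to highest occupancy,
ties toward `A`; waters and hydrogens are dropped on parsing. Empty
VCFs exit cleanly with empty outputs. Problem sizes in the test suite
and acceptance script (a 5,000-variant synthetic cohort, 10–34-residue
fixtures) were chosen as the smallest scales at which the binomial
sampling bounds and interior-residue agreement statistics are
meaningful.

# Known limitations

The verdict rules are first-match-wins and qualitative; they encode
one defensible reading of how structural context separates "away from
functional sites" from "loss of packing interactions", and borderline
residues near rule boundaries (e.g. RSA near 0.25, loops exactly 3
residues from an element) flip categories discontinuously. Template
assessment analyses the *wild-type* template at mapped positions; it
does not model the mutant conformation, estimate stability changes, or
repack side chains. The alignment is pairwise only — no profiles or
iterated search — so remote homologs that a profile method would find
are reported as having no usable template. Finally, the three-level
verdict is an interpretive aid, not a clinical classifier: the
evaluation module exists precisely to quantify how often it agrees
with clinical judgement on labelled data.
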