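---
title: "Methods: characterizing PKS and hybrid NRPS-PKS genes at desk scale"
author: "dinoPKS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing PKS and hybrid NRPS-PKS genes at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dinoPKS)
```

## The problem

Dinoflagellates such as the coral symbiont *Symbiodinium minutum* synthesize
large, bioactive polyketides through polyketide synthases (PKS). Type I PKS
proteins are assembly lines: an ordered series of catalytic domains —
ketosynthase (KS), acyltransferase (AT), acyl carrier protein (PP-binding),
ketoreductase (KR), dehydratase (DH), enoylreductase (ER) — each of which
performs one step of a chain-extension cycle. Genome surveys of these genes
ask several small, linked questions:

1. Does a predicted protein carry the catalytic residues that make a KS
   domain functional?
2. Is a gene a monofunctional single-KS gene, a multifunctional PKS, or a
   hybrid NRPS-PKS that interleaves non-ribosomal peptide synthetase
   modules?
3. Do spliced-leader (SL) tagged transcriptome reads support expression,
   and do some gene models produce several trans-spliced transcripts?
4. Do observed high-resolution mass-spectrometry ions correspond to a known
   polyketide metabolite?
5. Into which evolutionary group does a KS domain fall?

dinoPKS implements each question as a small, tested operation, plus
synthetic-data generators so the whole pipeline can be exercised and
validated without any external downloads.

## Motif scanning and active-site verification

Signature motifs are written in a compact grammar: uppercase literals,
`x` wildcards, and bracketed alternative sets (`[DEG]`). For nucleotide
patterns, IUPAC degeneracy letters compile to alternative sets. Matching
semantics are deliberately asymmetric:

* *literal* positions tolerate up to `maxSubstitutions` mismatches in
  total — this is how near-variants of a conserved motif are picked up;
* *set* positions are strict: they encode known biological variability
  (e.g. the SL's first base) and a residue outside the set is a
  disqualification, not a substitution;
* `x` positions never constrain anything.

The ambiguity residue `X` in scanned input never satisfies a literal or a
set (it is unknown, not wildcard), but does satisfy `x`.

The packaged motif set covers KS (`DTACSS`), AT (`GHSLG`), KR
(`GxGxxGxxxA`), DH (`HxxxGxxxx`), ER (`LxHxxxGGVG`) and the N-terminal
signature (`ExExGYLG`). It ships as a plain-text table
(`inst/extdata/pks_motifs.tsv`) that users can extend.

`verifyKSActiveSite()` checks the three residues required for condensation
activity. The catalytic cysteine is position 4 of `DTACSS` and must be a
literal `C` even when the motif match itself used substitutions — a
substitution budget must not be allowed to excuse the loss of the catalytic
residue. The companion histidine and lysine lie downstream of the motif but
their exact offsets vary between enzymes; we search windows of 200 aa (His)
and 250 aa (Lys) downstream of the motif end. These windows are generous by
design — canonical KS His/Lys residues fall well within them — and both are
arguments, so a user with an alignment in hand can tighten them. The DTACSS
match allows 2 substitutions by default, reflecting the near-variants seen
across real KS collections.

The DH signature nominally carries two active residues (histidine and
proline), but the proline has no fixed position inside the motif.
`verifyDHSite()` therefore reports the His at motif position 1 and,
separately, a heuristic flag for a proline within 30 aa downstream.

The N-terminal signature `ExExGYLG` is scored per 8-residue window in the
first 150 residues: +1 for each matching literal (the two `E`s and the
`G`,`Y`,`L`,`G` core), best score wins, ties to the smallest position. A
window must score at least 4 of 6 to be accepted; below that the protein is
reported `OTHER(----)`. The threshold, limit and scoring are explicit
package choices — the signature is described in the literature without
coordinates — and all are arguments. The core tetrapeptide is labelled
`GYLG`, `DYLG`, `EYLG`, `GYMG` or `OTHER(<tetra>)`.

## Architecture classification and module decomposition

Domain architectures are hyphen-separated code strings over a closed
vocabulary (`KS`, `AT`, `PP`, `KR`, `DH`, `ER`, `AM`, `C`, `A`, `MT`, `TE`,
`HXXPF`); unknown tokens are rejected naming the token and its ordinal.
Classification is a total function:

* `HYBRID_NRPS_PKS` — at least one KS plus at least one NRPS domain
  (C or A);
* `MULTI_PKS` — KS together with a companion PKS code
  (AT, PP, KR, DH, ER, AM, MT, TE);
* `SINGLE_KS` — exactly the one-domain architecture `KS`;
* `NON_PKS` — everything else.

Two corners deserve a note. AM (AMP-binding) alone does **not** open an
NRPS module and does not make a gene a hybrid: AM appears in PKS-only
architectures (e.g. `AM-PP-KS-AT`), so only the condensation domain C
anchors NRPS modules. And a degenerate architecture of repeated KS with no
second code class (`KS-KS`) falls through to `NON_PKS` under the literal
rules; such strings do not occur in the packaged survey table.

Module decomposition follows standard assembly-line convention, applied
greedily left to right: each C opens an NRPS module, each KS opens a PKS
module, domains before the first anchor form a loading module (flagged,
kind following the first anchor), an NRPS module containing `HXXPF` is
relabelled `NRPS_LIKE`, and trailing domains — the thioesterase in
particular — stay in the final module. Concatenating the module members
always reproduces the architecture; this partition property is tested on
random architectures.

The packaged survey table (`ksGeneSurvey()`) lists the 25 KS-containing
gene models with their printed architecture strings. The hybrid NRPS-PKS
gene `symbB1.v1.2.012436.t1` is published only as a schematic, so its row
carries a reconstructed string chosen to reproduce the schematic's module
content exactly — 8 modules, 3 NRPS-type (one of them the `C-HXXPF-A`
NRPS-like assembly), 5 PKS, terminal TE — with the AT placed inside the
first PKS module. Classification of the printed strings yields 15
`SINGLE_KS` genes and 10 multifunctional ones (including the hybrid); the
original survey text says eleven multifunctional genes, but only ten of the
printed architectures contain more than one domain code, so the package
reports its own count and notes the discrepancy here rather than adjusting
data to match prose.

Adenylation-domain specificity codes (Stachelhaus-type) are extracted by
aligning the packaged reference A-domain to the query
(`Biostrings::pairwiseAlignment`, BLOSUM62, affine gaps: open 10,
extend 1; global in the reference, local in the query so flanking sequence
is harmless) and reading the query residues opposite the eight annotated
binding-pocket positions; a pocket aligned to a gap reads `x`. If fewer
than 50% of reference positions align to query residues the code is
refused with a diagnostic rather than reported. The shipped reference is a
**synthetic** GrsA-type stand-in (the real reference sequence is not
redistributable here): a fixed A-domain-sized sequence with eight annotated
pocket positions spelling `DAWTIAAI`. What the tests guarantee is
planted-residue recovery and gap/padding robustness, not agreement with any
external predictor.

## Spliced-leader trimming and TSS clustering

The dinoflagellate SL consensus `DCCGTAGCCATTTTGGCTCAAG` (22 nt, first base
D = A/G/T) marks trans-spliced mRNA 5' ends. Trimming is exact by default
(`maxMismatch = 0`): a 99-nt TSS read with the leader yields a 77-nt
residual; the realized degenerate first base is recorded per read. Reads
shorter than the consensus go to a too-short stream, non-matching reads to
an untrimmed stream, and the stream counts always sum to the input — a
conservation invariant the tests check on 10,000 random reads.

Placement is an exact, full-length substring search on both strands
(minus-strand hits reported at their leftmost genomic coordinate), chosen
for desk-scale determinism over spliced alignment; placements from a real
aligner can be supplied directly to `detectTransSpliceSites()` instead.
Multi-mapping reads are excluded from clustering and counted. Reads are
assumed sense-stranded after SL removal, so antisense placements are
reported but not clustered.

Trans-splice sites are called per gene by single-linkage clustering of the
5' positions of unique, sense-strand placements inside the gene interval
extended 500 nt upstream; clusters within a 50-nt gap merge, and clusters
with at least 2 supporting reads are reported. The number of reported
clusters is the predicted transcript count. The gap, support and margin
defaults are package choices (read pileups at genuine SL acceptor sites are
sharp, so 50 nt comfortably merges micro-heterogeneity while separating
distinct starts); all three are arguments, and the monotonicity properties
(more required support never increases transcript counts; a larger gap
never increases cluster counts) are tested.

## Monoisotopic masses and adduct matching

Formulas are parsed Hill-style with subscript markup tolerated
(`C_54_H_84_O_19_N` and `C54H84O19N` are the same formula). Masses are sums
of packaged standard monoisotopic constants (C = 12 exactly,
H = 1.0078250319, N = 14.0030740052, O = 15.9949146221, Na = 22.98976928;
electron 0.00054857990).

For a cation adduct, the m/z is

$$ m/z = \frac{M_\text{neutral} + M_\text{added} - z\,m_e}{z} $$

The electron-mass subtraction matters at the tolerance this package works
at: omitting it biases every theoretical m/z upward by ~0.55 mmu per
charge, a fifth of the default 3-mmu matching tolerance. The packaged
positive-mode adducts are [M+H]+, [M+NH4]+ and [M+Na]+; higher charge
states divide by z. Matching reports every (observed, candidate, adduct)
pair within tolerance, sorted by |delta| in mmu, preserving ambiguity.
Printed-value comparisons round half away from zero at 4 decimal places.
Compound-table screening (`screenCompoundTable()`) is a direct
m/z-to-m/z lookup in mmu or ppm against reported values for known
*Symbiodinium* metabolites.

## Distance-based clade assignment

The survey question for KS phylogeny is classification into three groups
(dinoflagellate single-domain, protist multi-domain, bacterial), not tree
inference. dinoPKS therefore assigns clades by distance: p-distances over a
pre-aligned reference (columns with a gap in either row excluded; pairs
with no comparable columns get distance 1 and are flagged; an optional
Poisson correction $-\ln(1-p)$ is available), and the query goes to the
clade with the smallest mean distance, with the runner-up margin as a
confidence measure. Ties break alphabetically and are flagged; queries
overlapping fewer than half the non-gap columns of every reference row are
`UNASSIGNED`. This is explicitly a desk-scale stand-in for Bayesian/ML
phylogenetics: no model correction beyond Poisson, no support values, and
queries must already be in the reference coordinate system.

The accompanying neighbor-joining implementation uses the standard Saitou-
Nei Q-criterion with deterministic tie-breaking (smallest index pair) and
clamps negative branch lengths to zero, transferring the remainder to the
sibling so the joined pair still spans its distance. On additive matrices
NJ provably recovers the generating topology; the tests verify this for
n ≤ 6 against exhaustive topology enumeration with least-squares fits, and
against an independent NJ implementation (`ape::nj`) on random matrices.

## Synthetic data: what it does and does not show

Each generator is deterministic given (parameters, seed) and emits a
machine-readable truth record; round-trip tests read only the truth.

* `simulatePKSProtein()` — uniform i.i.d. background residues with
  signature motifs planted at recorded positions (KS also gets its His at
  +20 and Lys at +45 downstream, inside the default windows). Uniform
  background is a deliberate simplification: motif recovery at these
  lengths does not depend on background composition, but real proteomes
  have biased composition and homologous context that this generator does
  not emulate.
* `simulateSLReadSet()` — 99-nt reads from planted TSS positions on a
  random scaffold, SL-prefixed with probability `slFraction` and the
  degenerate base drawn uniformly from T/A/G. No sequencing errors, no
  quality scores, no introns: recovery results on this generator show the
  trimming/clustering logic is correct, not that it is robust to noisy
  alignment.
* `simulateIonList()` — theoretical adduct m/z plus Gaussian error of a
  few mmu (the error scale of a modern orbitrap), with optional uniform
  decoys over the m/z 400–2000 scan range. At tolerance 3σ the expected
  true-ion recovery is 99.73%; the acceptance suite requires ≥ 99% over
  1000 simulated spectra.
* `simulateCladeAlignment()` — a root sequence mutated into clade
  ancestors (`betweenDiv` per site) and leaves (`withinDiv` per site),
  235 columns by default (a trimmed KS domain), no indels. With
  within = 0.1 and between = 0.4 assignment is expected to be perfect;
  the degenerate control within = between collapses margins toward zero.

## Numerical and interface choices

* All coordinates in the R API are 1-based inclusive (the R/Bioconductor
  convention); BED output alone is 0-based half-open.
* Ties everywhere break deterministically (smallest position, smallest
  index pair, alphabetical clade), so identical inputs give identical
  bytes; the survey writer sorts rows and fixes float formats for the same
  reason.
* Problem sizes in the tests and acceptance script (random-sequence
  lengths of a few hundred residues, 10,000 reads for conservation, 1000
  simulated spectra, trees to n = 6, 10 alignment seeds) were chosen as
  the smallest sizes at which each property is statistically meaningful.

## Known limitations

* No HMM/profile domain detection: architectures come from strings or
  coordinate annotations, not from scanning the protein itself.
* The exact-match micro-mapper does not tolerate mismatches or splicing;
  real read data should be aligned externally and imported.
* Clade assignment requires pre-aligned queries and gives no support
  values.
* The headline counts of the original genome survey (65 KS-domain genes,
  21/25 intact active sites, and so on) require the real genome and are
  out of scope here; the package reproduces the string-level and
  mass-spectrometric results and validates everything else on synthetic
  data.
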