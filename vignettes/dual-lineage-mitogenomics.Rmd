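---
title: "Dual-lineage comparative mitogenomics with mitopair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-lineage comparative mitogenomics with mitopair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitopair)
```

# The problem

Under doubly uniparental inheritance (DUI), bivalve species carry a
maternally transmitted F-type and a paternally transmitted, faster-evolving
M-type mitogenome. Because the F/M split predates the family-level
radiation of freshwater mussels, each species contributes two deeply
divergent ~16–18 kb circular genomes that share one species tree. That
makes the system a natural experiment: reconstruct the phylogeny from each
lineage independently and ask whether topology and node heights agree.
`mitopair` provides the comparative plumbing around that question —
annotated-genome I/O, composition and divergence profiles, alignment
curation that is robust to database frameshift errors, supermatrix
assembly, tree-congruence statistics, structural comparison, and a
simulator that generates fully annotated F/M pairs for end-to-end
validation.

# Coordinates and genome I/O

Internally every feature is a set of 0-based half-open `[start, end)`
segments in transcription order; GenBank I/O converts to and from the
1-based inclusive convention. A feature crossing the origin of a circular
genome is stored as two segments, which keeps all arithmetic exact and
makes rotation (`rotateGenome()`) a pure bookkeeping operation — feature
transcripts are invariant under it, and the test suite checks this
property for arbitrary shifts.

Only `A, C, G, T, N` are accepted: the study system's genomes are
Sanger-finished and unambiguous, so any other IUPAC code more likely
signals a corrupted record than real ambiguity, and is rejected at parse
time. Gene labels are normalized on read (`COI`/`COX1` → `cox1`,
`16S` → `rrnL`, `MT-ORF` → `m-ORF`, three-letter tRNA names → one-letter),
because public records for this family label the same genes
inconsistently; this mapping also stands in for the manual annotation
harmonization a curator would apply to older records.

Translation uses the invertebrate mitochondrial code (NCBI table 5) by
default: `AGA`/`AGG` = Ser, `ATA` = Met, `TGA` = Trp. A trailing 1–2 nt
remainder (incomplete stop codons are common in mitochondrial
annotations) is dropped with a flag rather than an error, and internal
stops are preserved as `*` and flagged — downstream curation wants to see
them, not have them silently removed.

# Composition and divergence profiles

`windowedComposition()` computes AT skew `(A − T)/(A + T)` and GC content
in sliding windows (defaults 300 bp / 25 bp, the scale at which local
compositional bias is usually drawn on mitogenome maps). Windows are
anchored at position 0 of the record as deposited; the anchor is
configurable since it is a presentation choice, not a biological one. On
circular genomes windows wrap, so every position is covered by exactly
`window/step` windows — the coverage identity the tests verify. `N` bases
are excluded from numerators and denominators alike; a window without
`A`/`T` has undefined skew and is flagged `NA` rather than raising.

Divergence uses the uncorrected p-distance, mismatches over compared
sites, with pairwise deletion (columns containing `-` or `N` in either
row are excluded). For two sequences pairwise and complete deletion
coincide except in their treatment of `N`, so the simpler rule is used.
For whole mitogenomes of the same lineage — which differ by a few percent
at most — the pair is first rotated to start at `cox1` (removing the
arbitrary origin offset of circular records) and aligned with a banded
affine-gap global aligner (match +1, mismatch −1, gap open −8, extend −1,
band half-width 400, widened automatically by the length difference). The
band keeps a 17 kb × 17 kb alignment cheap while being far wider than any
realistic indel offset in near-identical genomes; the aligner is verified
against `Biostrings::pairwiseAlignment()` scores on smaller instances.
With non-overlapping tiling (`step = window`) the site-weighted mean of
window p-distances equals the global p exactly — a partition identity the
acceptance suite checks on random fixtures.

# Alignment curation and frameshift-aware recovery

Database mitogenome CDSs sometimes contain single-nucleotide frameshifts
(sequencing or annotation errors). Translating such a CDS garbles
everything downstream, which silently poisons amino-acid supermatrices.
The curation procedure works gene by gene and lineage by lineage:

1. **Dual-space screening** (`dualSpaceConsistency()`): each taxon's
   amino-acid row is back-mapped onto its raw CDS nucleotides (one codon
   per non-gap residue), re-translated, and compared column by column. A
   taxon is `suspicious` when the nucleotide length cannot be reconciled
   with the ungapped amino-acid length (difference outside 0–3 nt, the
   slack for a complete or incomplete terminal stop), or when at least 5
   columns disagree. The threshold is a declared design choice: one or
   two disagreements are what isolated ambiguous residues or a mutated
   terminal codon produce, whereas a frameshift ≥ 60 nt from the gene's
   3′ end garbles ≥ 20 codons and lands far above it. The screen compares
   the *deposited protein row* against the *re-translation of the
   deposited nucleotides* — exactly the database-error situation, where
   the protein row reflects the intended conserved protein while the
   nucleotides carry the error. In-frame indels keep the two spaces
   consistent and are correctly left alone.
2. **Profile building** (`buildProfile()`): curated rows become a
   position-specific scoring profile — per-column log-odds
   `log2(((count + pc·bg) / (n + pc)) / bg)` with pseudocount 1 and a
   uniform 1/20 background by default, consensus by count argmax with
   alphabetical tie-break. Columns with ≥ 50% gaps are treated as insert
   regions and dropped. This PSSM (plus affine gap penalties) is a
   deliberately transparent stand-in for a full profile HMM: per-state
   transition training is out of scope, and every quantity in the profile
   is inspectable.
3. **Frameshift-aware recovery** (`frameshiftAwareAlign()`): a global
   dynamic program over (DNA position × profile column) recovers a
   protein row directly from raw nucleotides. Moves: match (3 nt against
   one column, scored by the column log-odds of the translated codon),
   column deletion and 3-nt DNA insertion (affine penalties, default
   open −11 / extend −1), and frameshift moves consuming 4 nt (`+1`,
   first three translated) or 2 nt (`−1`, residue `X`) against one column
   at `fs_penalty` (default −12). Internal stop codons score −8; codons
   containing `N` score 0. Co-optimal paths resolve
   match > delete > insert > frameshift, so frameshifts are only reported
   when the score demands them; with `fs_penalty = -Inf` the program
   reduces exactly to codon-level profile alignment. The defaults make a
   single frameshift cheaper than mistranslating the ≥ 5 columns that
   typically follow one, without letting frameshifts absorb ordinary
   mismatches. The DP is verified against an independent brute-force
   enumeration of all move sequences on every instance up to 18 nt × 5
   columns.

Finally `stripGapColumns()` removes every column containing a gap —
mirroring how gap columns are excluded from phylogenetic reconstruction —
and reports the effective alignment length alongside the removal mask.

# Supermatrices and tree congruence

`concatenateAlignments()` concatenates per-gene alignments into a
partitioned supermatrix, mapping row names through a species-level key so
the M and F records of one species can share a single taxon set. The
strict policy errors on missing taxa (naming taxon and partition); `pad`
fills with gaps. Exports use 1-based inclusive coordinates throughout:
NEXUS with `charset` lines (mixed nt + aa matrices get a
`datatype=mixed(...)` format line), relaxed PHYLIP (refused for mixed
datatypes, which the format cannot express), and RAxML-style partition
files. NEXUS export/import is an exact round trip. Tree inference itself
is consumed, not performed — the package prepares inputs for and
normalizes outputs of external BI/ML software.

For congruence, node heights are defined as the maximum root-to-leaf path
length minus node depth, which reduces to the usual height for
ultrametric (time-calibrated) trees and degrades gracefully for
non-ultrametric ones. `normalizeToMrca()` divides all heights by the
height of a named clade's MRCA — putting both lineages' trees on a common
relative time scale without assuming either is correctly calibrated; the
operation is idempotent and scale-invariant. Robinson–Foulds distances
are computed on trees viewed as unrooted (the standard definition, robust
to different rooting choices by BI/ML consumers), with shared and
tree-specific bipartitions reported by name so a conflicting placement is
immediately attributable; the implementation is cross-checked against
`phangorn::RF.dist()` and its metric axioms are verified exhaustively on
all 105 rooted 5-leaf topologies. `matchedCladeHeights()` pairs clades
between two normalized trees by identical leaf sets and reports height
ratios, listing clades without counterparts (e.g. conspecific M
haplogroup cherries absent from the F data) separately.

# Structural comparison

`geneOrder()` produces a canonical signed gene order: rotate to the
anchor gene (`cox1`) and reverse-complement the whole order if the anchor
lies on the minus strand. The result is invariant under genome rotation
and full reverse-complementation, so two records can be compared no
matter how they were linearized. `detectExtraFeatures()` compares feature
names as multisets (duplicated-copy suffixes collapse onto the base
name), reporting gains, losses and whether the shared gene order is
rearranged. Feature identity is by normalized name, not sequence
similarity — duplication detection should not depend on how far the
copies have diverged. `classifyTrn()` assigns a tRNA's amino acid through
its anticodon (reverse-complemented to the codon it decodes; `TAT`
decodes `ATA` = Met under table 5) and ranks reference tRNAs by
global-alignment identity. The anticodon comes from the annotation when
present; the alignment-based fallback (reading the 3-mer aligned with the
nearest reference's anticodon) is a clearly labelled heuristic, since
authoritative anticodon placement requires secondary-structure
inspection.

# The simulator

`simulateMitogenomes()` generates the study conditions the pipeline
assumes. A root genome is drawn from target base frequencies following a
template layout (13 protein-coding genes, 2 rRNAs, 22 tRNAs, one
supernumerary `m-ORF` adjacent to `trnD`, mixed strands, ~15.6 kb). The
defaults encode the system's characteristic features:

* base frequencies `A = 0.2295, C = 0.1642, G = 0.1642, T = 0.4421` —
  the composition implied by an M-type mitogenome with AT skew −0.3166
  and GC content 0.3284, with GC split evenly in the absence of a stated
  GC skew;
* an F/M stem of 0.25 substitutions/site (M side scaled by `rate_m`),
  modelling the deep lineage split that predates the radiation;
* `rate_m = 3`: the M lineage evolves three times faster;
* `kappa = 3`: a typical mitochondrial transition:transversion ratio.

Along each branch of length `b` every site substitutes with probability
`1 − exp(−b · rate)`, the replacement drawn with weight
`π(y) · κ^[transition]` — an HKY-flavoured kernel that provides
controllable divergence without the machinery of the inference-side
models (mtREV, GTR+Γ), which the package deliberately does not fit. Three
numerical details matter:

* **Composition control.** The target frequencies apply to the deposited
  (plus) strand, so minus-strand transcripts are drawn from complemented
  frequencies; CDS codons are conditioned on not being a stop, and start/
  stop codons are fixed. The residual deviation of the root's global AT
  skew from the target is below 0.01 systematic plus binomial noise,
  within ±0.02 at L ≥ 15 kb. Note the control applies to the *root*: the
  jump-chain replacement kernel is not exactly stationary at π, so
  composition drifts measurably over deep stems — visible, and realistic
  in spirit, when simulating the highly divergent M lineage.
* **No implicit indels.** Substitutions never move coordinates, so
  annotations are carried through unchanged and every round-trip test is
  exact. Indels and duplications exist only as explicit, seeded
  injections (`injectFrameshift()`, `injectDuplication()`), which also
  makes them perfect ground truth for the curation and
  structure-comparison tests.
* **Reproducibility.** Every random stream is derived by hashing a stable
  branch identity (the sorted leaf set below the branch, plus lineage)
  with the master seed, so outputs are byte-identical for a given seed
  and independent of traversal order.

What the simulator does *not* emulate: rate heterogeneity across sites
(optional in principle, off by default), selection, recombination or
F-to-M gene conversion (masculinization), real tRNA secondary structure,
and indel accumulation. Tests passing on synthetic data therefore
demonstrate the pipeline's correctness — coordinate handling, screening
sensitivity/specificity, statistical recovery of simulated parameters —
not that real mitogenomes satisfy the simulator's assumptions.

# Problem sizes and verification

The shipped test and acceptance runs use a compact ~1.2 kb template for
most pipeline round trips and the full ~15.6 kb template where length
matters (composition control, binomial substitution recovery at
L = 15 000), 50-replicate batches for rate-ratio recovery
(`rate_m = 3` recovered as ≈ 2.8–2.9; the small shortfall is the expected
saturation of p-distances at finite branch lengths, since
`(1−e^{−6b})/(1−e^{−2b}) < 3`), 100 screening trials, and exhaustive DP
verification up to 18 nt × 5 columns. The regression checks against the
published *U. pictorum* / *S. woodiana* records
(`accessionRegressionChecks()`) run whenever the GenBank records have
been fetched into `inst/extdata/accessions/` with
`scripts/fetch_accessions.R`.

# Known limitations

* GenBank parsing targets well-formed flat files of the kind NCBI emits;
  exotic location operators beyond `join`/`order`/`complement` are not
  supported.
* BEAST-style square-bracket node annotations (height intervals) are
  stripped on parsing, not retained; congruence therefore works from
  point estimates.
* The PSSM profile has no per-state transition training; genuinely
  hypervariable regions (e.g. m-ORFs across distant taxa) are better
  aligned in nucleotide space, as the supermatrix module permits.
* `locusPDistance()` and `genomePDistance()` assume the two sequences are
  globally alignable; between F and M lineages (p ≈ 0.5) a global
  nucleotide alignment of whole genomes is not meaningful, which is
  precisely why the analysis works in amino-acid space per lineage.
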