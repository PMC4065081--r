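---
title: "Methods: annotating venom-gland transcriptomes with venomics"
author: "venomics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating venom-gland transcriptomes with venomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomics)
```

## The problem

Spider venom glands express large families of short, disulfide-rich peptide
toxins. Each toxin gene encodes a precursor with a conserved tripartite
architecture — a hydrophobic signal peptide, an (often) acidic propeptide,
and a hypervariable mature peptide whose cysteine scaffold is strongly
conserved within a gene superfamily. Deep cDNA sequencing of a venom gland
therefore produces a mixture of highly expressed canonical precursors and a
long tail of rare mutated isoforms (point substitutions, small indels,
premature stops, stop read-through), and the analysis task is to assemble,
classify, segment and group these sequences, and to quantify the selective
regime acting on each superfamily.

`venomics` implements that full analysis as a reusable pipeline over plain
FASTA input, together with a ground-truthed simulator so every stage can be
validated without external data.

## The synthetic data generator

The generator is first-class, tested code: it defines the study conditions
under which the pipeline's recovery guarantees are stated.

* **Templates.** One precursor template per catalog superfamily (16 in
  total) is built deterministically from the bundled catalog: the catalog
  signal peptide, a propeptide ending in a processing quadruplet motif
  (PQM; `X[ED][ED]R`, e.g. GEER/SEER) for superfamilies that have one, and
  a synthetic mature peptide realising the superfamily's cysteine
  framework (patterns I–XI, 4–12 cysteines). Template precursors span
  56–116 aa, matching the 60–120 aa range typical of these toxins. The
  stretch of mature sequence before the first cysteine excludes E/D/R so a
  spurious PQM cannot precede the scaffold.
* **Reverse translation** uses a fixed, versioned single-codon-per-residue
  table (`inst/extdata/codon_table.tsv`); any fixed table would do, and
  fixing it makes every run byte-reproducible.
* **Mutations.** Each variant draws each mutation class independently:
  point substitutions anywhere in the CDS interior (redrawn if they would
  create a stop — stop creation is its own class), insertions/deletions of
  1–6 nt and premature stops in the mature-coding region (C-terminal
  variability dominates the observed isoform diversity), and stop-loss
  substitutions at the terminal stop. Applied specs are recorded
  right-to-left so every recorded position refers to the unmutated CDS;
  the truth ledger is therefore exact.
* **Design.** The default allocation of variants over superfamilies is
  strongly skewed (66/44/38/22/13/… down to 1, totalling 208), mirroring
  the observed dominance of a few superfamilies over a long tail; a uniform
  design would make the per-superfamily abundance regression degenerate.
* **Abundance.** The read budget (default 5,000) is split across
  superfamilies in proportion to their variant counts — each superfamily
  hosts its own expression hierarchy, which is what makes read totals track
  precursor counts. Within a superfamily, one third of the variants share a
  Zipf head (exponent 1.5) and the remaining two thirds are fixed at a
  single read. This reproduces the empirical shape of venom-gland EST
  abundance — a few dominant isoforms, a majority of singletons, and read
  totals that scale with superfamily size — without claiming any particular
  dataset's numbers.
* **Read model.** Read lengths are lognormal (`sdlog = 0.35`), truncated
  to [40, 836] nt with the location chosen so the truncated mean is 327 nt
  (454-style pyrosequencing lengths). With probability 0.9 a read is
  anchored at the cDNA 5' end, emulating a full-length-enriched library —
  the premise that long reads span whole precursors is what makes
  single-read precursor discovery possible at all. Reads are error-free
  exact substrings: the downstream assembler demands 100% identity, and
  sequencing-error simulation is out of scope.
* **Background.** Non-toxin transcripts are generated in four classes:
  residue-shuffled housekeeping-style ORFs (shuffling guarantees no
  similarity hits while keeping composition), random sequence with no ORF
  of 40+ codons, lightly mutated copies of bundled "hypothetical"
  proteins (which hit the unannotated reference database), and lightly
  mutated toxin precursors (decoys that should classify as toxin-like).
  All bundled reference proteins are synthetic stand-ins written for this
  package, marked `_synthetic` in their identifiers.

What the simulator does **not** emulate: sequencing error (and hence
error-induced isoform inflation), homopolymer artefacts, quality scores,
strand-specific library biases, chimeric reads, and real database
heterogeneity. Passing recovery tests on synthetic data therefore
demonstrates the correctness of the pipeline's logic under its stated
assumptions, not its accuracy on raw 454 data.

## Assembly

Reads are merged only on perfectly identical suffix–prefix overlaps of at
least 50 nt (containment counts as a full-length overlap), the stringency
appropriate for separating closely related isoforms. The algorithm is
greedy longest-overlap-first with a fully deterministic tie-break
(lexicographically smaller merged sequence, then smaller member read id);
reverse-complement overlaps are considered, and the contig keeps the
orientation of its first-merged read. Exact assembly (`identity = 1.0`) is
the only supported mode — approximate assembly is explicitly rejected.
Candidate pairs are prefiltered by requiring one sequence's leading 50-mer
to occur in the other, which makes the greedy search practical at tens of
thousands of reads without changing its result.

Singletons pass through to annotation by default (the analysis pools raw
reads and contigs); singletons shorter than 120 nt — the minimum length
that can contain a 40-codon ORF — are dropped, since no open reading frame
can be recovered from them.

## Annotation

* **Similarity search** is Smith–Waterman under BLOSUM62 with affine gaps
  (open 11, extend 1). Raw scores are converted to a bits-equivalent and an
  e-value-like quantity \(K m n e^{-\lambda S}\) with fixed constants
  (\(\lambda = 0.267\), \(K = 0.041\)); these are versioned calibration
  constants, not fitted Karlin–Altschul statistics. A hit is significant
  only if the e-value-like quantity is ≤ 1e−5 **and** the bit score
  exceeds 40.
* **Five categories**, applied in strict order: significant toxin hit →
  `Toxin_like`; significant hit to an annotated non-toxin reference →
  `Cellular_Proteins`; significant hit to an unannotated reference →
  `Unknown_function`; a cysteine-rich ORF (30–130 aa, post-signal region
  with ≥4 cysteines at ≥6% frequency) → `Putative_toxin`; otherwise
  `No_Hit`. The cysteine-richness thresholds are documented package
  defaults: the length bounds follow the observed 30–60 residue matures
  and 4–12 cysteine scaffolds, the 6% fraction is a free choice.
* **ORF choice.** All six frames are scanned; complete ORFs are preferred
  over 3'-partial and then 5'-partial spans, because shifted frames of
  low-entropy coding sequence can produce long stop-free spans. The ORF
  actually segmented is the one carrying the best toxin hit, and its start
  is refined against the signal-peptide catalog: among N-terminal
  methionines, the one whose following residues best match a catalog
  signal (≤2 mismatches) wins, which corrects for in-frame ATGs in the
  5' UTR.
* **Segmentation.** The signal-peptide end comes from the best catalog
  match (≤2 mismatches over the catalog signal length). Failing that, a
  heuristic stands in for neural-network signal prediction: a 15–30
  residue N-terminal window with ≥50% hydrophobic residues, ending at a
  small residue (A/G/S/C) within the last five positions of the window —
  the classic tripartite signal-peptide shape. Catalog entries without a
  signal peptide (superfamily XXV) are matched by their stored propeptide.
  The propeptide ends at the **rightmost** PQM match after the signal and
  before the first post-signal cysteine; without a PQM the propeptide is
  empty. With no signal evidence at all the precursor is flagged
  (`signal_evidence = "missing"`) and the mature peptide defaults to the
  whole sequence — unless a PQM is present, which still segments a
  propeptide (this is what makes signal-less, propeptide-anchored
  precursors segmentable). Segmentation always conserves length:
  |signal| + |propeptide| + |mature| equals the precursor length.
* **Frameworks.** The cysteine scaffold is rendered left-to-right with
  `CC` for adjacent cysteines and `-C-` otherwise, then looked up against
  the eleven catalog patterns; anything else is `NOVEL`. A mature with no
  cysteines yields scaffold `-`, class `NOVEL`.

## Taxonomy

Superfamilies are assigned by global-alignment identity of the signal
peptide against the catalog (threshold 0.70); precursors without signal
evidence fall back to local-identity nearest-neighbour matching of the
mature peptide against the reference templates (flagged in the output),
and signal-less catalog entries match by propeptide. Whatever remains is
clustered into `NEW-k` superfamilies by single linkage at the same
threshold, numbered in input order. Families then subfamilies are nested
single-linkage clusterings on full-precursor identity (0.60) and
mature-peptide identity (0.90). All three thresholds are configuration
values: the source analyses never state theirs, so these defaults are
chosen to reproduce the nested structure qualitatively, and identity is
defined as matches over alignment length under the package's global
aligner. Raising a threshold can only split clusters, so the partitions
are monotone in their thresholds and always nest.

## Variant events and expression tiers

Within each family the member with the highest read support (ties: longer
CDS, then smaller id) acts as the reference. Each other member is globally
aligned to it at the nucleotide level (match +2, mismatch −3, gap open 5,
extend 2 — mismatches are strictly cheaper than gaps, and the traceback is
deterministic). Mismatches and gaps map to events on reference
coordinates: synonymous/nonsynonymous points (cysteine loss/gain emitted
alongside), in-frame indels (length divisible by 3), frameshifts
(everything downstream of the first frameshift collapses into that single
event, annotated with the variant's new stop), premature stops (with the
truncated cysteine framework re-extracted), and stop-loss elongation.
Pairs below 30% alignment identity are flagged and produce no events; a
3-nt indel is always in-frame by arithmetic. Expression tiers are `rare`
(1 read), `low` (2–10), `high` (>10) — a total, piecewise-constant
function with breakpoints exactly at 1/2 and 10/11.

## Selection analysis

`ng_counts()` implements the original Nei–Gojobori method: per-codon
synonymous-site fractions (changes to stops count as nonsynonymous, so
N + S = 3 per codon) averaged across the two sequences, and differences
resolved by equal-weight averaging over all minimal substitution pathways,
excluding pathways through stop codons. Codons containing gaps or N, stop
codons, and codon pairs whose pathways are all blocked are removed
pairwise. Proportions are corrected with Jukes–Cantor,
\(D = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)\); a proportion ≥ 3/4 yields an
undefined distance (a flag, not an error), and the ratio is undefined when
Ds = 0. Selection zones follow the conventional thresholds — Dn/Ds > 1
positive, 0.27 < Dn/Ds ≤ 1 lack of constraints, ≤ 0.27 purifying — with
boundary values assigned to the lower zone, since the published zone
definitions use strict inequalities on all three sides and leave the
boundaries unassigned. The one-sided Fisher exact test for positive
selection builds its 2×2 table {Nd, N−Nd; Sd, S−Sd} by rounding the
fractional NG counts to the nearest integer (ties to even); degenerate
margins give p = 1.

Phylogenies are neighbor-joining (Saitou–Nei Q criterion) with ties broken
by the smallest row/column index pair; negative branch lengths are clamped
to zero on output with the raw values kept as an attribute. Bootstrap
support resamples alignment columns with a mandatory seed, 500 replicates
by default. Multiple alignments inside the pipeline are reference-anchored:
every member is codon-aligned to the family reference and insertions
relative to the reference are dropped. This is a deliberate simplification
— it biases columns toward the reference and ignores member-specific
insertions — acceptable here because members are close isoforms of one
reference; for distant sequences a proper MSA should be supplied instead.

## Pipeline, determinism and problem sizes

`run_pipeline()` chains simulate → assemble → annotate → taxonomy →
variants → evolve → report. Every stage writes a manifest (parameter echo
plus MD5 checksums of inputs and outputs) and is skipped when up-to-date,
so runs resume after interruption; any failure halts with an error naming
the stage and preserves partial outputs. All randomness flows from the
single mandatory seed, and a fixed seed yields byte-identical FASTA,
tables and reports.

The default synthetic configuration — 16 templates × 13 variants (208
precursors), a 5,000-read budget, 300 background transcripts, 500
bootstrap replicates — runs in about a minute on one CPU and is the size
at which the package's recovery claims are tested: ≥95% of variants
assigned to their true superfamily, ≥99% recovery of single injected
mutation events (position exact for substitutions, within a placement
window for indels, since gap placement is only defined up to the repeat
structure of the context), and exact segmentation of all mutation-free
precursors. Known residual failure modes, visible in the truth-ledger
evaluation, are variants whose only read is too short to contain a
40-codon ORF and variants whose frameshift destroys most of the mature
peptide — both are genuine information loss, not classifier defects.

## Known limitations

* The e-value-like statistic is a calibrated convenience, not a fitted
  BLAST statistic; absolute e-values should not be compared with BLAST's.
* The signal-peptide heuristic is a coarse stand-in for dedicated
  predictors and is only exercised when the catalog misses.
* Reference-anchored pseudo-alignment (above) in the evolution stage.
* The taxonomy thresholds are qualitative defaults; on real data the
  family/subfamily structure is threshold-sensitive and should be tuned
  against curated families.
* The assembler is exact-overlap only and will fragment data containing
  sequencing errors; it is not a general-purpose transcriptome assembler.
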