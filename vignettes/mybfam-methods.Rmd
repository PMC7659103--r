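---
title: "Methods and design notes for mybfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mybfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`mybfam` re-implements, as a reusable and tested pipeline, the standard
genome-wide workflow for mining a MYB transcription-factor family from a
plant genome: detect the ~52-residue MYB DNA-binding repeat in every
protein, classify genes by repeat count into the 1R / 2R (R2R3-MYB) /
3R (R1R2R3-MYB) / 4R subfamilies, name members by chromosomal order, call
tandem and segmental duplications, estimate Ka/Ks for duplicate pairs,
build neighbor-joining trees with bootstrap support, and screen
stress-responsive members from TPM expression matrices. The motivating
application is hexaploid wheat (subgenomes A, B, D; chromosomes 1–7), but
nothing in the code is wheat-specific beyond the chromosome-label
convention `chr<number><subgenome letter>`.

Genome-scale inputs (a full proteome, public RNA-seq) are deliberately out
of scope for validation. Instead the package ships generators that build
synthetic genomes and expression matrices with machine-readable planted
truth, and the test suite measures recovery of that truth. A green suite
therefore establishes that the algorithms recover what they claim under
the generators' statistical assumptions — not that any biological
conclusion about a real genome is correct.

## Repeat detection

The repeat scanner is a log-odds position score matrix (PSSM) over a
52-column consensus, scored in bits against a uniform background (1/20 per
residue). Column probabilities model a noisy consensus copy: the consensus
residue with probability $1 - \nu$, every other residue $\nu/19$, plus a
pseudocount of 0.01, with $\nu = 0.1$ by default. Every window scoring at
least `bit_threshold` is reported; overlapping windows are merged into
repeats when their gap is below `min_separation` (5 residues), and the
subfamily class is the merged repeat count (counts of 0 or >4 are flagged
`"none"`, never dropped).

The default `bit_threshold = 30` was calibrated once with
`scripts/calibrate_threshold.R`: across ~5 × 10^5 random uniform-composition
windows the maximum observed score was about −32 bits (hit rate 0 at any
threshold ≥ 0), while planted repeats at substitution noise 0.1 scored
127–204 bits. The threshold sits far above random and far below planted
scores, so classification is insensitive to its exact value across tens of
bits; it was fixed before the acceptance suite was run and not revisited.

An alternative ingest path accepts HMMER3 `--domtblout` tables (envelope
coordinates, independent E-values), so a profile-HMM search against
PF00249 can replace the internal scanner without changing anything
downstream. Full Forward/Viterbi profile scoring is a non-goal.

Within-protein repeat identity (which repeat is R1 vs R2 vs R3) is not
assigned; only the count matters for classification. Representative
transcripts are chosen by longest CDS with lexicographic tie-break — the
redundancy rule is this package's choice, since tools differ and the
convention is rarely stated.

## Naming

Each subfamily class gets an independent name series ordered by
(chromosome number 1–7, subgenome letter A < B < D, start coordinate, gene
id). The 2R series is the bare `prefix + ordinal` series (mirroring the
field's `TaMYB1…` convention); other classes interpose the class tag
(`prefix3R1…`). Genes on unparseable chromosome labels are appended after
all placed genes in input order. Naming is a bijection and is invariant
under permutation of the input rows.

## Duplication calling

Evidence is a table of pairwise hits (query, subject, percent identity,
alignment length, E-value, score), either ingested from 12-column BLAST
tabular output or computed internally with affine-gap alignment
(nucleotide match +1 / mismatch −1, BLOSUM62 for proteins, gap open 10,
extend 0.5) behind a shared-k-mer prefilter. Internal hits carry no
E-value; wherever a criterion asks for E-value < 1e−10 the internal path
substitutes a raw-score threshold (default 100) and the output flags
`evidence = "score"`.

Tandem criteria follow the classic four rules: (1) alignment length ≥ 80%
of the *longer* gene's sequence — the stricter symmetric reading, which
prevents a short fragment from passing on its own length; (2) identity
> 80%; (3) adjacency in the all-genes positional order of the chromosome,
i.e. *no annotated gene of any kind* between the two — the literal reading
of "no genes inserted"; (4) E-value < 1e−10. Clusters are connected
components of passing links, so membership is order-independent and no
gene can appear in two clusters. Tandem links are computed from CDS-level
hits, segmental anchors from protein-level hits — common practice where
published survey protocols are silent.

Segmental blocks chain non-adjacent anchor pairs (identity ≥ 90%,
significant) that are collinear — consistent order and orientation, with
inter-anchor gaps bounded by `max_gap` — and report a block when both
chained regions span at least `min_span` and contain at least
`min_anchors` anchors. The genome-scale span criterion (600 kb) cannot be
meant as a single gene alignment length, so it is operationalized as the
chained block's genomic span; `min_span` is a configuration knob and the
synthetic tests scale it to their chromosome sizes (blocks are planted at
1.0–1.2 × `segmental_span` and called with `min_span = segmental_span/2`).

Homoeolog groups are reciprocal best hits per subgenome pair, merged into
components; the completeness fraction is the share of groups with all
three subgenomes present. Translocation/inversion detection is a non-goal
(no published procedure to mirror).

## Ka/Ks (Nei–Gojobori 1986)

Site counts use the classic convention: at each codon position the
synonymous fraction is (synonymous one-step changes)/(one-step changes
that do not create a stop), summed over the three positions; S is the
average of the two sequences' totals and N = 3·(codons compared) − S,
exactly. Pairwise differences are partitioned by averaging over all
orderings of the differing positions that avoid stop-codon intermediates
(≤ 3! paths). If *every* ordering is stop-blocked — possible only for a
handful of sense-codon pairs — each differing position is classified by
applying it alone to the first codon (stop-creating counts as
nonsynonymous) and the pair is flagged; this keeps the partition total
equal to the nucleotide difference count. Proportions are Jukes–Cantor
corrected ($K = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$); a proportion at or
beyond 0.75 leaves the corresponding rate, and the ratio, undefined rather
than propagating NaN. Ratios are labeled purifying (< 1), neutral (= 1
within 1e−9), or positive (> 1); Ks = 0 gives an undefined ratio.

The 61×61 difference tables are verified in the acceptance suite against
an independent exhaustive path-enumeration oracle for all 3721 sense-codon
pairs.

The divergence simulator inverts the correction: targets are converted to
raw proportions, scaled by the sequence's own site counts, and planted as
single-nucleotide substitutions (preferring untouched codons, rejecting
stops). Because nearly all mutated codons carry a single change, NG86
counting recovers the targets; 200 replicates of 500 codons at
(Ks, Ka) = (0.2, 0.05) recover means within a few percent.

## Phylogeny

Distances are p-distances over pairwise-ungapped columns of a protein
alignment (a Poisson-corrected option would be a one-line change but
p-distance is the default and the one tested). NJ is the
classic Saitou–Nei agglomeration with the Q-criterion; ties break to the
first minimal pair in row-major order of the current matrix, and negative
branch lengths clamp to zero. On additive matrices the generating tree is
recovered exactly (cophenetic distances within 1e−9), which the acceptance
suite checks on 100 random 8-leaf trees.

Bootstrap resamples alignment *columns* (protein, not codons — matching a
protein-based tree), rebuilds the NJ tree per replicate, and scores each
internal edge of the original tree by the percentage of replicates
containing the same bipartition; supports land on internal node labels in
the Newick output. Degenerate replicates (a pair with zero comparable
columns) fall back to distance 0 instead of aborting. The classic
replicate count (1000) is the default; desk-scale runs use fewer via
configuration.

For the pipeline's tree stage a trivial right-pad "alignment" backs the
synthetic fixtures (pairwise-ungapped p-distance ignores the padding); real
analyses should supply a proper MSA (ClustalX/MAFFT are upstream,
out of scope).

## Expression screening

Z-scores standardize log2(TPM + 1) per gene to mean 0, sample-sd 1
(the +1 offset keeps zero TPM at 0; the n−1 sd form is configurable in
principle but fixed here and documented). Zero-variance genes become
all-zero rows with a flag. Differential status per contrast uses
log2FC = log2((mean treated + 1)/(mean control + 1)) with a Welch t-test
on log2(TPM + 1) replicates: up iff log2FC > 1 and p < 0.05, down iff
log2FC < −1 and p < 0.05; genes with zero TPM across the whole contrast
are "undetected" (mirroring deletion from published heatmaps). Welch is
the default because survey protocols rarely state more than "t-test"; pooled
variance is available via `var_equal = TRUE`. No multiple-testing
correction is applied by default (classic surveys apply none); a
Benjamini–Hochberg column is available but off.

Profile clustering is average-linkage agglomeration on 1 − Pearson
correlation of z-rows, cut at k (5 groups in the motivating analysis).
qPCR relative expression is the Livak 2^−ΔΔCt rule with the mean ΔCt of
the calibrator samples as baseline.

The expression generator draws negative-binomial counts (dispersion 0.1
by default — a typical bulk RNA-seq value; `size = 1/dispersion`) around
log-normal gene means, multiplies treated-condition means by 2^log2FC for
planted genes, and rescales each sample to one million, reproducing TPM's
compositional structure without read-level simulation. Planted effects
default to |log2FC| = 3 with a default planted fraction of 0.1. At these
settings the Welch screen has type-I error within [0.03, 0.07] and power
≥ 0.9 at n = 3, which the acceptance suite measures on 10,000 null
gene-contrasts.

## Synthetic genome: the stated world

Defaults: 3 subgenomes × 7 chromosomes × 300 kb; 90 family genes (mix
5/80/10/5% across 1R/2R/3R/4R — 2R-heavy, as in plant MYB families) and
200 background genes; 3 tandem clusters of 2–4 members; 2 segmental blocks
of 5 genes spanning ~60 kb with the copy on another chromosome of the same
subgenome; 85% of homoeolog groups planted as complete A/B/D triads;
repeat substitution noise 0.1; minimum intergenic gap 200 bp. Genes get
1–4 exons (weights 0.15/0.30/0.30/0.25, matching the modal 1–3 introns of
real family surveys), GT…AG introns of 60–300 bp, and random strand.
Tandem copies diverge at pairwise (Ks, Ka) ≈ (0.16, 0.04), segmental
copies (0.10, 0.025), homoeologs (0.5, 0.1) — all comfortably inside the
classic 80%/90% identity criteria and all purifying, so every planted
duplicate pair should be recovered and labeled Ka/Ks < 1. Promoter
cis-elements are spliced into the intergenic DNA upstream of family genes
(within the near half of the flanking gap, so neighbouring promoters
cannot collide), on either strand, and recorded in the truth record.

One deliberate deviation from an early design sketch: repeat linkers are
5–10 residues, not 1–10. A linker shorter than the repeat-merge
separation (5) would fuse two genuine repeats into one and misclassify the
gene by construction, contradicting the recovery requirement; real R2R3
linkers are short but the merge rule, not biology, sets the floor here.

What the generator does **not** emulate: indels (so coverage criteria are
exercised only through alignment length, not gapped structure), UTRs and
alternative isoforms (the dedupe rule is tested on hand-built fixtures
instead), base-composition bias, low-complexity DNA, read-level noise, and
realistic chromosome sizes. Green recovery tests therefore validate the
algorithms' logic, not robustness to those phenomena.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout (GFF3 convention); promoter
  offsets count from the promoter's 5′ end; BED exports are 0-based
  half-open.
* Isoelectric point: bisection on (0, 14) to 1e−3 pH with the Bjellqvist
  pKa set used by the ExPASy tools (residue-specific N-terminal pKa,
  C-terminal D/E specials); the charge function is strictly monotone so
  the root is unique. Molecular weight uses ExPASy average residue masses
  plus one water; X contributes the mean residue mass.
* Promoters truncated by a chromosome edge are returned shorter with a
  warning flag; a gene at position 1 yields an empty promoter.
* All generators take integer seeds and restore the caller's RNG state;
  identical seeds give byte-identical outputs, which the pipeline report
  inherits (no timestamps in artifacts).
* The pipeline's per-stage artifacts are plain TSV/FASTA/GFF3/Newick/JSON;
  every stage re-reads its inputs from disk, so any suffix of the pipeline
  can be rerun after deleting downstream outputs and reproduces them
  byte-identically under a fixed seed.

## Known limitations

* The internal aligner path has no E-value theory; its score threshold is
  a calibrated stand-in, flagged in outputs.
* The segmental chainer is a greedy single-pass scan, adequate for planted
  collinear runs but not a general synteny finder (no inversions within
  blocks, no gap scoring).
* `stack_alignment` is a fixture device, not an aligner.
* NG86 only; ML/YN00 Ka/Ks variants and ML/Bayesian trees are non-goals.
* Subcellular-localization prediction, intron-phase analysis, figure
  rendering, and translocation/inversion detection are out of scope.
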