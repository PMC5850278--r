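---
title: "Methods: ortholog-based completeness assessment in microbusco"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ortholog-based completeness assessment in microbusco}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The assessment model

`microbusco` measures completeness of a genome assembly, gene set, or
transcriptome as the recovery of benchmarking universal single-copy
orthologs (BUSCOs): genes that evolve under single-copy control and are
therefore expected once, and only once, in any complete representative of
their lineage. The evolutionary expectation does the work here — absence
or fragmentation of such a gene is evidence about the data set, not about
the organism. The caveats are the usual ones: a duplicated call can be an
uncollapsed heterozygous region rather than a true duplication (the short
summary carries a note to this effect), and a missing call can be a
genuinely divergent ortholog rather than an assembly gap.

An assessment has four stages:

1. **Candidate extraction.** Protein mode takes records verbatim (terminal
   `*` stripped; internal `*` kept with a warning rather than silently
   splitting a record the user supplied). Genome and transcriptome modes
   extract all six-frame stop-to-stop open reading frames; an initial Met
   is not required, because assembly fragments routinely truncate genes.
2. **Profile search.** Every candidate is scored against every ortholog
   profile with a local Viterbi alignment; non-positive bit scores are
   discarded. A pre-filter skips candidates shorter than 0.2× or longer
   than 5× the ortholog's expected length — such candidates cannot reach
   complete grade and carry essentially no classification signal.
3. **Assignment.** Each candidate is consumed by at most one ortholog: its
   highest-bits pairing, with deterministic tie-breaks (ortholog id, then
   candidate id). Without this rule a single repetitive sequence could
   inflate the completeness of many orthologs at once.
4. **Grading.** A hit is complete-grade when its bits reach the ortholog's
   score cutoff *and* its aligned length falls inside the expected length
   window; fragment-grade when the score passes but the length does not.
   Two or more complete-grade hits on distinct loci give
   `complete_duplicated`; exactly one gives `complete_single`;
   fragment-grade evidence only gives `fragmented`; otherwise `missing`.
   All boundaries are inclusive: a hit exactly at the cutoff or at the
   window edge counts as complete, so the cutoffs themselves define the
   accepted set.

## Profile HMMs and scoring

Profiles are built from the amino-acid alignment of each ortholog group.
Columns with gap fraction < 0.5 become match states (the conventional
majority heuristic; the choice only matters for ragged alignments).
Match emissions are observed frequencies mixed with the alignment-wide
background by a pseudocount, `(counts + w·background) / (n + w)` with
`w = 1` by default — enough to guarantee strictly positive probabilities
without washing out the signal of small alignments. The background is the
pooled residue frequency of the alignment, floored at 1e-4 per residue and
renormalized, so rare residues never produce infinite log-odds. Members
are weighted equally; sequence weighting schemes (e.g. Henikoff) would
matter for phylogenetically clumped alignments but add a second layer of
tuning, so the package leaves counts unweighted and documents the choice.

Transitions among match/insert/delete states are counted from each row's
path through the alignment with +1 Laplace smoothing; delete→delete is
allowed. Transitions are stored for positions 0..k (position 0 is the
begin state; the row at position k feeds the terminal insert state), and
exit from any position-k state is free. Scores are log2-odds (bits)
against the background; insert states emit the background, so inserted
residues are score-neutral and only pay their transition cost. Residues
outside the 20-letter alphabet (including `X`) emit the background and
contribute zero bits. Local mode grants free entry and exit at any match
state and free flanking target residues — the simplest defensible local
model, with no length-dependent entry penalty.

The dynamic-programming kernel (C++) is verified *exactly* — to 1e-9 —
against an independent oracle that enumerates every legal state path for
all profiles of ≤ 3 match states and all targets of length ≤ 5 over a
3-letter alphabet (~10⁴ cases), in both modes.

## Cutoff calibration

For each ortholog, the members themselves calibrate the expectations:

* **Score cutoff = 0.25 × mean member score** (local mode). The design
  requirement is that the cutoff separate two populations: genuine
  orthologs *including truncated copies* (a fragment covering 40% of the
  gene scores roughly 40% of the full score) versus unrelated sequences
  (best local score near zero bits). A fraction-of-mean rule sits cleanly
  between them. The alternative of `mean − 2·sd` over member scores was
  rejected after implementation: within a lineage the member-score spread
  is a few percent of the mean, so a 2σ rule lands near 0.9× the mean
  score, above every truncated copy — fragmented orthologs would be
  indistinguishable from missing ones, and even held-out complete copies
  would fail a few percent of the time. The rule is isolated in
  `derive_cutoffs()` so alternative calibrations can be swapped in.
* **Length window = mean ± max(2σ, 0.15 × mean)** of ungapped member
  lengths (n−1 standard deviation). The floor keeps the window from
  collapsing to zero width for length-invariant groups. The length that is
  compared against the window is the *profile-aligned region* of the
  candidate, not the whole candidate: six-frame ORFs routinely run past
  the true gene into flanking sequence, and penalizing a gene for its
  neighborhood would misgrade complete genes as too long.

Ortholog sets are delineated from an orthology table at **universality
0.9**: a group qualifies when ≥ 90% of species carry it in exactly one
copy. "Near-universal" is deliberately not 100% — requiring perfection
would discard good markers over a single annotation error in one species.

## Genome mode and its central trade-off

Genome mode finds genes by six-frame ORF extraction and direct profile
scoring, with `min_aa = 50` (30 in transcriptome mode, where partial ORFs
at transcript edges are common). This makes the whole pipeline
self-contained and exactly testable, at a stated cost: **spliced genes are
recovered only as fragments**, because no intron model is applied. The
fixture generator therefore plants intronless genes when exercising genome
mode, and genome assessments of intron-rich organisms should be read as
lower bounds on completeness. Duplicate resolution treats two hits on the
same record as distinct loci when their nucleotide overlap is below 50% of
the shorter span — a symmetric rule with no free parameters beyond the
threshold.

Gene models of complete orthologs can be exported (GFF3, GenBank-flavored
flat file, coding-orientation FASTA) as training input for ab initio gene
predictors; only complete-grade matches are exported since fragmented
models would teach a predictor truncated gene structures.

## Phylogenomic markers

Orthologs classified `complete_single` in *every* assessed species form
the marker set. Each marker is aligned by center-star progressive
alignment (the center maximizes summed pairwise global-alignment score;
BLOSUM62, affine gap open −10 / extend −1, via `pairwiseAlignment`), the
merge following "once a gap, always a gap". Center-star is a deliberate
desk-scale stand-in for a full progressive aligner; it is exact for the
gapless alignments the simulator produces and adequate for closely related
sequences, and the interface allows swapping in an external aligner.
Columns with gap fraction > 0.5 are trimmed (the filter is idempotent),
markers are concatenated in sorted order, and the partition table tiles
the supermatrix exactly — partition bookkeeping is what lets users run
maximum-likelihood inference externally (a RAxML-style partition file is
emitted). The built-in tree is neighbor joining on p-distances (gap/`X`
positions excluded pairwise; negative branch lengths clamped to zero),
which is a guide tree, not a substitute for ML: no bootstrap, no model
selection, no rooting logic.

## The synthetic-data generator

`simulate_lineage()` draws one random ancestral protein per ortholog
(uniform residues, leading Met, length uniform in `gene_length_range`,
default 150–250 residues) and evolves one copy per species, either i.i.d.
per site at the stated divergence (star model) or along a supplied species
tree with per-branch substitution probability equal to branch length.
`plant_targets()` then builds a target set with known truth:
complete single-copy = one freshly diverged copy; duplicated = k copies on
distinct records (default k = 2); fragmented = the N-terminal fraction
(default 0.4 — the N-terminus, because ORF extraction naturally finds
prefixes); missing = omitted. Genome mode codon-encodes each peptide with
random synonymous codons, appends a stop, and embeds it on a random strand
in uniform-ACGT background (200–400 nt flanks per side), recording true
coordinates. The generator refuses fragment fractions that would fall
inside the length window, since such a "fragment" would correctly classify
as complete and the truth table would be wrong, not the classifier.

By default the simulator introduces no indels, so the per-group alignments
are trivially exact and profile lengths match gene lengths; an optional
indel rate adds gaps. What the simulator does **not** emulate — and what
passing its tests therefore does not demonstrate — includes: realistic
amino-acid composition and substitution matrices (mutations are uniform
over the 19 alternatives), codon usage bias, introns, sequencing error,
assembly artifacts, and phylogenetically uneven species sampling. The
fixtures establish that the machinery is correct under its own model, not
that classification accuracy on real genomes matches the simulated rates.

## Numerical and reproducibility choices

* Scores in bits (log base 2) throughout; comparisons at boundaries
  inclusive.
* Internal coordinates are 0-based half-open only transiently; every
  emitted file is 1-based inclusive (GFF3/full-table convention), and ORF
  spans include the terminating stop codon when present.
* Percentages are one-decimal, rounded half away from zero; the summary
  string re-parses to the counts.
* All simulation is seed-deterministic: identical fixture specs produce
  byte-identical FASTA output, and repeated assessments of the same input
  produce byte-identical full tables.
* Test problem sizes were chosen as the smallest that exercise every code
  path with comfortable statistical margins: the end-to-end fixture uses
  50 orthologs × 10 species at divergence 0.1 (planted 40/3/4/3); the
  conservation property runs 200 assessments of 6-ortholog lineages; tree
  recovery uses 50 replicates of an 8-marker, 5-species lineage on a fixed
  tree with branch lengths 0.05–0.12 substitutions/site.

## Known limitations

* Spliced genes are found only as fragments (no gene prediction).
* No E-values or forward-algorithm statistics; bit scores and calibrated
  cutoffs only. Profile files use the package's own text format, not the
  HMMER3 format.
* The coverage score aligns predicted against reference globally
  (BLOSUM62, −10/−1) and counts identical aligned positions over the
  reference length; for near-full-length predictions this agrees with a
  local-search definition, but heavily truncated predictions pay end-gap
  penalties a local search would not impose.
* Duplicated status cannot distinguish true paralogs from uncollapsed
  alleles; the report says so rather than guessing.
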