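# microbusco

Completeness assessment of genomic data in terms of expected gene content.

Technical sequencing metrics (contiguity, N50) say nothing about whether a
genome assembly, annotated gene set, or transcriptome actually contains the
genes it should. `microbusco` quantifies completeness against the
evolutionary expectation carried by **benchmarking universal single-copy
orthologs (BUSCOs)**: genes under single-copy control that are present, and
present exactly once, in essentially every genome of a lineage. It is
aimed at genome assembly and annotation groups (quality control and
like-for-like comparisons of assembly versions), at gene-prediction
pipelines (exporting complete gene models as training input), and at
phylogenomics studies (extracting shared single-copy markers into a
supermatrix).

Every ortholog of a lineage set is classified in the familiar scheme

* **C** complete (score and length within expectation) = **S** single-copy + **D** duplicated,
* **F** fragmented (score passes, length outside the expected window),
* **M** missing,

reported as `C:98.0%[S:96.0%,D:2.0%],F:1.0%,M:1.0%,n:100`.

## The model

Each ortholog group is represented by a **profile hidden Markov model**
built from the multiple sequence alignment of its members. Alignment
columns with gap fraction < 0.5 become match states; match emissions are
pseudocounted residue frequencies (`(counts + w·background)/(n + w)`,
default `w = 1`); transitions among match/insert/delete states are counted
from each row's path with Laplace smoothing. Candidate sequences are scored
by the **Viterbi algorithm** in log2-odds (bits) against the alignment-wide
background; local mode allows free entry/exit at any match state with free
flanking residues. The implementation is validated exactly against
exhaustive path enumeration on small models.

Per ortholog, a **score cutoff** (one quarter of the mean member score, so
truncated genes remain detectable while unrelated sequences stay far below)
and an **expected length window** (mean ± max(2σ, 0.15·mean) of ungapped
member lengths) grade each hit; one candidate is consumed by at most one
ortholog (greedy by bits). Genome and transcriptome inputs are reduced to
candidates by six-frame stop-to-stop ORF extraction, so intron-containing
genes surface as fragments — the genome mode is exact for intronless gene
structures (see the methods vignette).

## Worked example

Everything below is reproducible offline: the fixture simulator generates a
lineage of 50 ortholog families over 10 species (per-site divergence 0.1)
and a target proteome in which 40 orthologs are planted complete
single-copy, 3 duplicated, 4 fragmented, and 3 missing.

```r
library(microbusco)

spec    <- fixture_spec(50, 10, divergence = 0.1, seed = 42,
                        planted = planted_statuses(40, 3, 4, 3))
lineage <- simulate_lineage(spec)
ds      <- build_dataset(lineage$table, lineage$msas, name = "demo")
targets <- plant_targets(spec, lineage)

run <- run_assessment(targets$targets, mode = "proteins", ds = ds,
                      out_dir = "demo_out")
run$summary
#> C:86.0%[S:80.0%,D:6.0%],F:8.0%,M:6.0%,n:50

evaluate_recovery(run, targets$truth)$agreement
#> [1] 1
```

All 50 planted statuses are recovered (86% complete = the 40 + 3 planted
complete orthologs out of 50; the 8% fragmented and 6% missing are exactly
the planted fragments and omissions). `demo_out/` contains
`full_table.tsv` (per-match coordinates and bit scores),
`short_summary.txt`, and per-status FASTA files. A genome-mode run on
planted contigs additionally supports `export_training_models()` (GFF3 +
GenBank-flavored gene models + coding FASTA for gene-predictor training),
and several runs can be combined with `select_universal_markers()` →
`build_supermatrix()` → `nj_tree()` for phylogenomics.

A thin command-line wrapper with `run`, `phylo`, and `fixtures`
subcommands is installed at `inst/cli/microbusco`.

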