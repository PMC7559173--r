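---
title: "Resolving multi-mapped translated reads: model, simulation and benchmarking"
author: "cdsem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving multi-mapped translated reads: model, simulation and benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Shotgun metagenomic reads translated and aligned against a protein
reference database recruit far more coding sequences (CDS) than are truly
present: proteins evolve by duplication and domain shuffling, so a 250 bp
read (~83 aa) frequently aligns equally well to tens or hundreds of
distinct reference peptides that share a conserved domain. Accepting every
aligned reference ("mapping all-hits") therefore has dismal precision,
while demanding uniquely mapping reads throws away most of the signal.
`cdsem` assigns each multi-mapped read to a single reference by combining
two observations:

1. A reference that is truly present is covered *evenly* along its length
   by randomly fragmented reads; a reference recruited only through a
   shared domain shows a hot spot and is empty elsewhere.
2. Among references that pass the evenness test, the sample-wide read
   support of each reference tells us where a tied read most likely came
   from.

## The algorithm

Input is a blastx-style tabular alignment file (12 columns, optional 13th
with the subject length). Per read, alignments within `tolerance_pct` of
the best (percent identity points; `accept_best()`) are retained -- the
"top-hit" rule at 0, the "top-10" rule at 10.

**Coverage evenness.** For each candidate reference, the per-position
amino-acid coverage depth vector $CD$ is accumulated from the alignment
intervals. With $\mathrm{CV} = CD_{SD} / CD_{Mean}$ (population SD and
mean over the *full* reference length, uncovered positions counted as
zeros), a reference is removed when

$$\frac{CD_{SD}}{CD_{Mean}} > 1.0 .$$

The criterion is scale-free, so sequencing depth does not change the
decision; a reference covered only across a domain that occupies a
fraction $p$ of its length has $\mathrm{CV} \approx \sqrt{(1-p)/p}$ and is
removed whenever $p < 1/2$. Ties at exactly the threshold are retained
(the filter fires on strictly greater). Subjects with zero coverage are
removed.

**Score initialization.** Each surviving read--reference candidacy gets
$s_0(q, r) = B(q, r) / \sum_{r'} B(q, r')$, where $B$ is the alignment
bitscore, so scores sum to 1 per read.

**Iterative weighting and pruning.** Until an iteration prunes nothing or
`max_iterations` (default 10) is reached:

* *weight and renormalize*: $W(r) = \sum_q s(q, r)$ over the whole sample;
  $s'(q, r) \propto s(q, r)\, W(r)$, renormalized per read;
* *prune*: drop candidates with $s'(q, r) < \rho \cdot \max_{r'} s'(q, r')$
  (default $\rho = 0.5$), renormalize. The per-read maximum, and ties with
  it, always survive, so no read ever loses all candidates here.

**Final assignment and re-filter.** Each read is assigned to its
highest-scoring candidate (ties broken by larger $W(r)$, then
lexicographically smallest reference id -- determinism matters more than
the particular rule). Coverage is then rebuilt from the deduplicated
one-reference-per-read alignments with unit weights and the evenness
filter is applied once more; reads whose final reference fails it are
reported in an `unassigned` count rather than silently dropped.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `tolerance_pct` | 10 | acceptance band below the per-read best alignment, in percent-identity points (`accept_best`); a bitscore-relative variant is available via `by = "bitscore"` |
| `evenness_threshold` | 1.0 | coverage-CV cutoff (dimensionless) |
| `prune_ratio` | 0.5 | relative per-read pruning threshold in (0, 1] |
| `max_iterations` | 10 | iteration cap; the loop stops earlier when stable |
| `weighted_first_filter` | FALSE | use bitscore-normalized weights already in the first coverage pass |

`prune_ratio = 0.5` is scale-free, guarantees the per-read maximum
survives, and in our experiments reproduces the gradual per-iteration
culling of candidates rather than an abrupt collapse; larger values prune
more aggressively. The first evenness pass uses unweighted counts and the
final one unit-weight deduplicated alignments; bitscore influence enters
only through the initialization, not through per-iteration re-weighting by
alignment quality.

### Read pairs

The two mates of a pair share one query id (mate suffixes are stripped),
so a pair is resolved jointly to one reference. Within a (query,
reference) pair, alignment records whose subject intervals overlap are
redundant local alignments of the same evidence and only the best-bitscore
one is kept; records on disjoint intervals -- typically the two mates --
are independent coverage evidence and all contribute to the coverage
vector. The score model still tracks one candidacy per (query, reference),
with the summed bitscore of the retained records as its evidence. Keeping
both mates' intervals matters: with ~1 kb fragments and ~250 bp reads, the
two mates of a pair cover disjoint parts of a gene, and discarding one of
them would make genuinely present genes look half-covered and uneven.

## The synthetic-data generator

All tests run against simulated communities with known ground truth; no
external databases or aligners are needed.

**Community model.** 20 genomes, each a chain of protein-coding genes
(uniform 150--450 aa) separated by 50--150 bp random spacers -- roughly
250 kb per genome and ~5 Mb per community at the defaults. Per-genome
sequencing depth is drawn log-normally: $d = \min(100, 10^{N(\mu, 1)})$
with $10^\mu = 5$, i.e. "median 5x, 1 log SD, capped at 100x". We read
the location parameter as the median; an arithmetic-mean convention is
available via `depth_mean_is = "mean"` (the cap two SDs above the median
only makes sense under the log10 reading).

**Homology structure.** Real protein databases make multi-mapping
pervasive: most reads from a real community tie across many entries that
share conserved sequence. The generator emulates this regime structurally:
90% of community CDS (`conserved_fraction`) consist of a conserved core
(80% of the length, `core_fraction`) flanked by member-specific termini.
For each such family the reference database additionally contains two
reference-only full-length homologs sharing the identical core
(`n_orthologs`) and one decoy sharing only a 70 aa slice of it
(`n_domain_decoys`); 10% of the conserved CDS occur as core-sharing pairs
placed in two community genomes (`paired_fraction`). Reads from a core
therefore genuinely tie across 3--5 references, reads from termini map
uniquely, and short-domain decoys recruit hot-spot coverage -- the three
behaviors the algorithm exists to separate. Peptides are reverse-translated
with random synonymous codons, so identical peptide cores differ at the
nucleotide level, as homologous genes in distinct genomes do.

**Reads.** Paired-end 250 bp, fragment length $N(1000, 300)$ truncated to
[read length, sequence length], mate 2 reverse-complemented, optional
uniform substitution errors (default 0), constant quality strings. Each
pair is labelled with its true origin CDS (largest overlap; pairs touching
no CDS by at least one codon stay unlabelled). The pair count per genome
is `round(depth * length / (2 * read_length))`.

**What the generator does not emulate.** Platform-specific error and
quality profiles, indels, strain-level SNP structure, GC and coverage
biases, mobile elements, and the size and domain granularity of real
protein databases (a real database recruits hundreds of relatives per
read, not a handful). Passing tests therefore demonstrate the algorithm's
behavior under its own model assumptions -- even coverage of present
genes, domain-restricted coverage of absent relatives -- not performance
on any particular real dataset.

**The emulated translated aligner.** `emulate_alignment()` six-frame
translates every mate, seeds candidate (frame, reference) pairs with
exact amino-acid 6-mers, requires two seeds on nearby diagonals (the
classic two-hit rule, which suppresses chance single-k-mer hits), and
runs affine-gap Smith--Waterman (BLOSUM62, gap open 11 / extend 1) banded
around the seed diagonals. Raw scores are converted to bits with the
standard gapped Karlin--Altschul parameters ($\lambda = 0.267$,
$K = 0.041$), and rows below `min_bitscore` (default 30, ~14 exactly
matching residues) are not reported. An error-free read's true origin is
always among its best-scoring hits. Because the floor and the two-hit rule
discard marginal alignments a real aligner might report, absolute
recruitment counts are not comparable to a real database search; the
multi-mapping *structure* is what is emulated.

## Benchmark evaluation

Detected and truly present CDS sets are each clustered at 90% amino-acid
identity (greedy longest-first clustering, global identity = matches over
alignment columns -- the CD-HIT strategy, implemented internally so no
external tool is needed). Detections are then classified by all-vs-all
local alignment against the truth:

* **TP** -- the detected CDS is the mutual best hit of a truth;
* **DUP** -- it aligns to a truth (at least 50% identity over at least
  50% of the shorter sequence) without being its best hit;
* **FP** -- it aligns to no truth at that floor;
* **FN** -- a truth with no TP.

Sensitivity = TP/(TP+FN), PPV = TP/(TP+FP), uniqueness = TP/(TP+DUP);
empty denominators are reported as `NA`, never 0. With per-truth depths,
sensitivity and uniqueness are additionally reported for depth strata
(default 0--5x and >5x); PPV is not stratified because false positives
carry no truth depth. Cluster depth is the sum of its members' depths,
since their reads pool. Best-hit ordering is raw score, then identity,
then id -- again for determinism. The alignment floor (50%/50%) and the
clustering threshold are configurable; the mutual-best-hit test is applied
to cluster representatives.

The two baselines are defined on the same accepted alignment set:
*all-hits* reports every reference with at least one alignment;
*unique-hits* reports references supported by at least one read whose
top-hit candidate set (ties with its best alignment) contains exactly that
single reference.

## Problem sizes and numerical choices

The packaged experiments use a 3-truth/30-decoy fixture with 360 read
pairs (`convergence_experiment()`), and one full 20-genome, ~5 Mb
community with roughly 200,000 read pairs and ~18,000 reference peptides
(`benchmark_strategies()`); both run in minutes on one CPU. Score sums
per read are maintained at 1 within 1e-9 throughout; the iterative update
on small instances matches a dense-matrix recurrence to 1e-12. All
randomness flows through a single integer seed per experiment; reruns are
bit-identical. Population (not sample) SD is used for coverage because the
vector is the complete profile, not a sample. Ties are never broken by
hash or pointer order anywhere in the package.

## Known limitations

* The evenness filter removes genuinely present genes at very low depth
  (roughly below 0.5x, where random fragmentation cannot cover a gene
  evenly); they are counted as unassigned/missed, which is visible in the
  low-depth sensitivity stratum.
* One EM pass with a single final re-filter: the re-filter does not
  trigger further reassignment rounds, and reads unassigned by it are not
  redistributed.
* The emulated aligner reports one best local alignment per mate and
  reference (no secondary HSPs) and does not model indel sequencing
  errors.
* Detection is presence/absence plus read counts; no abundance
  normalization, taxonomic profiling, or functional annotation.
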