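---
title: "Methods: prime-encoded SSR mining and group-differential screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prime-encoded SSR mining and group-differential screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrmine)
```

## The detection model

A perfect simple sequence repeat (SSR) is an uninterrupted tandem array of
one motif: `(AT)5` is five copies of `AT` covering 10 bp. `ssrmine`
detects these by numeric encoding: each base maps to a prime (A=2, C=3,
G=5, T=7) and every other symbol to 1. For motif length $m$, the product
of each length-$m$ window of the encoded list is constant across a
period-$m$ repeat, so repeats are maximal runs of equal window products.
A repeat of $E$ copies produces a run of exactly $mE - (m-1)$ windows,
which is the run-length threshold applied for a configured minimum
exponent.

Two implementation paths coexist in the compiled scanner. The literal
path materializes the products (exact 64-bit arithmetic; with values at
most 7 this is exact for $m \le 22$). The default path materializes
nothing: since no encoded value is zero, adjacent products are equal if
and only if the residue leaving the window equals the residue entering
it, giving an $O(n)$ scan per motif length whose memory does not grow
with $m$. The two paths are asserted identical in the test suite —
exhaustively for all strings up to length 5 over {A, C, G, T, N} and on
3000 random strings up to length 10, for $m \in \{1,2,3\}$ (the full
exhaustive space up to length 10 is ~12 million strings; the sampled
check covers the same collision structure, in particular windows
containing 1s). Because the default path is exact for any $m$, motif
length is unbounded: minisatellites ($m > 6$) use the same machinery.

Decisions in corner cases:

- **Prime assignment.** Any assignment of distinct primes is equivalent;
  A=2, C=3, G=5, T=7 is fixed for reproducibility.
- **Ambiguous bases.** All non-ACGT symbols share the encoded value 1, so
  windows differing only in which ambiguity symbol they contain would
  compare equal. Detected regions containing any position encoded as 1
  are therefore discarded: runs of Ns are not biologically meaningful
  repeats, and a repeat interrupted by an N is reported only on the
  unambiguous side of the interruption.
- **Trimming.** A maximal run often ends mid-copy; the region is trimmed
  to whole motif copies ($E = \lfloor \text{len}/m \rfloor$) so reported
  exponents are integers and `end - start + 1 = mE` always holds.
- **Maximality.** Runs are extended as far as equality holds before
  thresholding, so reported repeats cannot be extended on either side.
- **Coordinates.** 1-based inclusive, the convention of the standard SSR
  mining tools whose output format this package follows.

## Post-processing

Per-motif-length scans emit records unsorted across lengths, so records
are sorted by start (ties: smaller motif first, then longer region
first). Redundancy then arises because a repeat at period $m$ is also a
repeat at every multiple of $m$ it fits: `(AC)4` re-detects as
`(ACAC)2`, and a mononucleotide run satisfies every period. The smaller
motif wins. The rule is containment plus motif periodicity — B is dropped
when a kept A has smaller motif length dividing B's, A's motif repeated
equals B's motif, and B's region lies inside A's. A literal
same-coordinates rule would fail here, because trimming gives records at
different periods different ends (an `(A)13` run traps `(AA)6` at
[1, 12], not [1, 13]).

Compound SSRs chain greedily left to right: with gap defined as
`start(next) - end(previous)`, consecutive records with gap ≤ `int`
(default 10 bp, configurable in the parameters file) form one tract.
Adjacent records have gap 1 and overlapping records have gap ≤ 0, so both
always merge. The internal marker-matrix convention negates every
boundary interior to a chain, keeping magnitudes intact; the sign pattern
alone reconstructs the tract boundaries, which the tests verify by round
trip.

## Inputs and outputs

Parameters use a `motif:repetitions` dialect (`2:5` = at least five
copies of any dinucleotide), one pair per line, with an optional
`int:` line for the merge gap. FASTA input (single, multi-record, or a
folder) yields the SSR table — columns ID, per-sequence SSR number, type
(`p1`…`pN` perfect, `c` compound), SSR string, size, start, end.
GenBank input additionally yields the genome FASTA, a protein table, and
the coding-SSR table (Start, End, SSR, Gene, Strand, Synonym, Product,
ID). GenBank parsing is a minimal flat-file reader (accession, CDS
features, ORIGIN); multi-interval `join(...)` locations are reduced to
their envelope and flagged — adequate for prokaryotes, where CDS features
are almost always single intervals. The writer/parser pair is
cross-checked against Biopython in the test suite.

A repeat belongs to a coding region only if fully contained in the CDS
interval (partial overlaps are ambiguous for marker design and are
excluded). Motifs are reported in genome forward orientation for both
strands; the strand is a column, so reverse-complementing is left to the
user. Flank extraction for primer design defaults to 200 bp a side
(typical for Sanger-scale marker assays), clipped at chromosome bounds.

## Group-differential screening

The abundance table counts occurrences of each exact SSR string (motif
plus exponent) per gene per genome — not the exponent value itself. This
is what makes repeat-length polymorphism visible as a group difference:
a gene carrying `(CGG)5` in one group and `(CGG)4` in the other produces
two complementary rows, each perfectly separated between groups. Genomes
lacking a gene score 0, keeping the matrix rectangular.

Each row is screened with Shapiro–Wilk on the pooled counts (one W per
row; per-group normality is a reasonable alternative the interface does
not currently expose), one-way ANOVA with Tukey HSD contrasts, a
tie-corrected Kruskal–Wallis test, and per-group count sums. Counts are
small integers with heavy ties and are rarely normal, so the
Kruskal–Wallis p-value at a strict raw threshold (default 0.001) drives
marker selection; no multiple-testing correction is applied to the
selection by design, though a Benjamini–Hochberg column is emitted for
users who want it. Rows with zero variance overall get NA statistics
rather than errors, and groups with fewer than two genomes produce NA
with a warning. Under complete separation of two groups of $n_1$ and
$n_2$ constant counts, the tie-corrected statistic equals $N - 1$
($N = n_1 + n_2$); the tests assert this exactly for 51 + 51 and verify
the ~5% null rejection rate at $\alpha = 0.05$ by simulation (1000
replicates of iid Poisson(8) counts over 51 + 51 genomes — a null chosen
once to mimic cohort-scale count data).

## The synthetic-data generator

`synth_genome()` plants specified repeats into random ACGT background and
rejection-samples the background until a naive reference scan (an
independent implementation: direct residue-vs-residue-one-period-ahead
comparison plus an exhaustive redundancy rule) finds exactly the planted
set. The returned truth is therefore exhaustive, making end-to-end tests
exact rather than statistical. `synth_cohort()` builds two-group GenBank
cohorts in which selected genes carry different planted exponents per
group (the repeat-length polymorphism scenario), optional jittered genes
provide null rows with variance, and a configurable fraction of genomes
can lack a gene entirely. The default simulated cohort uses 20 genomes
per group with one differential gene — small enough to mine in seconds,
large enough that complete separation passes the 0.001 screen
(chi-squared 39 ≈ p of 4 × 10⁻¹⁰).

What the generator does not emulate: imperfect repeats (mismatches or
indels inside the array — outside the detection model altogether),
GC-content and oligomer biases of real genomes, repeat clustering, and
evolutionary relatedness between cohort genomes (counts are independent
across synthetic genomes, while real strains are phylogenetically
correlated, which can inflate apparent group differences). Passing tests
demonstrate algorithmic correctness on the stated model, not robustness
to those properties of real data.

## Problem sizes and limitations

The validation battery uses: 500 random 1–5 kb sequences against the
naive oracle for motif lengths 1–8; planted repeats over $m \in 1..10$,
$E \in 2..8$ for the run-length identity; 1000-replicate null
simulations; and a 20 + 20 cohort of ~2 kb annotated genomes end to end.
These sizes make the suite run in about a minute while exercising every
code path; the scanner itself is linear-time and handles megabase
genomes.

Known limitations: no imperfect-SSR detection; no cyclic-rotation motif
normalization (the motif is read at the tract start, so `(GGT)4` and a
rotated `(GTG)4` at shifted coordinates are different names for
overlapping arrays); GenBank parsing covers the common flat-file layout,
not every esoteric location type; and the group screen treats genomes as
independent samples.
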