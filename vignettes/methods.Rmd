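---
title: "Graph-based genotyping of structural variants: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based genotyping of structural variants: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svgt)
```

## The problem

Structural variants (SVs, events of 50 bp and larger) are routinely
*discovered* with long reads but must be *genotyped* in large short-read
cohorts. Naive approaches — counting reads from the linear alignment around a
candidate breakpoint — suffer from reference bias: reads carrying the
alternative allele misalign or soft-clip near the junction. `svgt` instead
builds, for every candidate SV, a local sequence graph containing both
alleles, realigns nearby reads to that graph, and genotypes each junction
("breakpoint") from the reads that unambiguously support one allele path.

## The allele graph

A deletion graph has a left flank node, the deleted-sequence node and a right
flank; the reference allele is the path through all three, the alternative
allele the direct flank-to-flank edge. Insertions are symmetric (the inserted
sequence is a middle node on the alternative path) and blockwise sequence
swaps have two parallel middle nodes. Edges carry allele labels; a
*breakpoint* is any node side with two or more connected edges, so deletion,
insertion and swap graphs each have exactly two.

Flank nodes default to one read length (150 bp): reads informative about a
junction overlap it by less than one read length, so longer flanks add
alignment cost without adding evidence. For the same reason, any node longer
than twice the read length is replaced by its first and last read-length
bases (`split_long_nodes()`). The two halves are joined by an edge carrying
the original allele labels, so every allele path still runs source to sink;
the spelled interior sequence is intentionally shortened. Keeping the bridge edge
preserves the path invariants; reads from the omitted interior simply fail
to align, which is the desired behavior.

Coordinates are 0-based half-open everywhere inside the package; the 1-based
closed VCF convention exists only in the I/O layer. This removes a whole
class of off-by-one errors from the dynamic programming and interval
arithmetic.

## Read realignment

Reads are extracted from one read length upstream of the SV start to one read
length downstream of its end, together with their mates (duplicates and
secondary/supplementary alignments excluded — counting the same fragment
twice would bias the Poisson model below). Each read is realigned to the
graph with an affine-gap local aligner whose recurrence crosses junctions:
the first column of a node takes its predecessor cells from the last column
of every in-neighbor. Scores are therefore identical to the best linear
Smith–Waterman score over all allele paths, which is what the test suite
asserts against an independent oracle. The kernel is plain (non-striped)
dynamic programming in C++; SIMD striping is an optimization, not part of the
contract.

Scoring defaults are match/mismatch/gap-open/gap-extend = 1/−4/−6/−1,
standard short-read local-alignment values (a gap of length $k$ costs
$6 + k$). Base qualities are not used. Mates are aligned independently; pair
information is deliberately ignored in alignment and genotyping.

Two filters gate the reads used for genotyping:

* **unique mapping** — exactly one graph location (strand, start, node path)
  attains the best score; co-optimal alignments are collected precisely to
  decide this;
* **unique k-mer** — the read (either strand) contains at least one k-mer
  (default k = 16) occurring exactly once among the graph's node k-mers and
  edge-spanning k-mers. Edge-spanning k-mers are included — the more
  conservative reading — so a read bridging a junction inside a repeat does
  not count as informative.

A read supports a node when its alignment overlaps it by at least
`min(ceil(0.10 × read length), node length)` bases, and supports an edge when
the edge is on its path and both endpoint nodes are supported. The k-mer
filter is applied before alignment as a pure optimization (it does not depend
on the alignment), which leaves the retained read set identical to the
unique-mapping-then-unique-kmer order.

## The Poisson genotype model

At a breakpoint with connecting haplotypes $h_1, h_2$, let $R_{h}$ be the
count of reads supporting haplotype $h$ and $R_{\neq h_1,h_2}$ the
breakpoint-overlapping reads supporting neither. With genome-average depth
$d$, read length $l$ and minimum supporting overlap $m$ (default $0.1\,l$),
the expected breakpoint-spanning read count is

$$\lambda = d\,(l - m)/l .$$

Likelihoods per unordered genotype:

$$P(R \mid G_{h_1/h_2}) = \mathrm{Pois}(R_{h_1};\lambda\mu_{h_1})\,
  \mathrm{Pois}(R_{h_2};\lambda\mu_{h_2}) \qquad (h_1 \ne h_2),$$
$$P(R \mid G_{h/h}) = \mathrm{Pois}(R_{h};\lambda(1-\varepsilon)),$$

each multiplied by the error term
$\mathrm{Pois}(R_{\neq};\lambda\varepsilon)$, where $R_{\neq}$ counts the
reads supporting no haplotype *of the genotype under evaluation* (for a
homozygote, reads on the other edge count here — that is what separates
hom from het). Defaults: haplotype fractions $\mu = 0.5/0.5$ for a
heterozygote, error rate $\varepsilon = 0.01$ (the order of combined base +
local mismapping error at junction resolution; configurable), uniform
genotype priors. Posteriors are normalized products of prior × likelihood
(log-space); genotype quality is $-10\log_{10}(1 - \max \text{posterior})$
capped at 100.

Everything is computed with `stats::dpois(log = TRUE)`; the tests verify the
whole grid $\lambda \in \{1..50\}$, counts $\in \{0..100\}$,
$\varepsilon \in \{0, 0.01, 0.05\}$ against an independent factorial-formula
pmf to $10^{-9}$ relative error. $\varepsilon = 0$ with a positive error
count yields probability 0 (log $-\infty$), not an exception.

### Confidence filters

A breakpoint is *passing* when all four hold:

1. more than one read aligned, regardless of allele;
2. total depth not significantly different from the genomic average:
   two-sided Z test of $R$ against mean $\lambda$, variance $\lambda$
   (Poisson), $p \ge 0.01$;
3. genotype quality $\ge 10$;
4. the Fisher strand-bias criterion on the 2×2 allele-by-strand table of
   breakpoint-overlapping reads.

Strand-bias filters are sometimes stated with inverted polarity — a
breakpoint "passes" when the Phred-scaled p-value is at least 30. Taken
literally, a perfectly strand-balanced breakpoint (Phred 0) would always
fail and the PASS label would be unreachable on clean data. `svgt` defaults
to the conventional semantics — **pass iff Phred < 30** (high Phred = strong
bias = fail) — and offers `genotyping_params(fisher_verbatim = TRUE)` for the
inverted reading.

### Combining two breakpoints

The SV genotype comes from a decision tree over the two breakpoint statuses:
both passing and agreeing (branch 1a) — that genotype, filter PASS; both
passing but disagreeing (1b) — re-genotype on pooled reads; exactly one
passing (2) — the passing breakpoint's genotype; both failing and agreeing
(3a) — that genotype; both failing and disagreeing (3b) — pooled re-genotype.
Pooling sums the two count vectors (a read spanning both junctions was
counted at each, hence twice) and doubles the depth parameter $d$. PASS is
reserved for branch 1a; pooled results always carry a non-PASS label, and
branch 3b inherits the failing label explicitly. For benchmarking parity an
evaluation mode reports SVs whose breakpoints failed criteria 1 or 2 as
homozygous reference; criteria-3/4-only failures keep their called genotype
(the to-reference rule is tied to criteria 1 and 2 only).

## Population helpers

* **EM genotype priors.** Given per-sample genotype likelihoods, the
  alternative allele frequency $q$ is estimated by EM under Hardy–Weinberg
  equilibrium (E-step: posterior weights under priors $p^2, 2pq, q^2$;
  M-step: $q$ = weighted allele count / $2N$). The observed-data
  log-likelihood is asserted non-decreasing at every step.
* **HWE filtering.** The exact conditional test of the heterozygote count
  given the allele counts; implementation via the standard recurrence between
  adjacent heterozygote counts, verified in tests against a closed-form
  factorial enumeration. SVs with $p < 10^{-4}$ fail.
* **Merging.** Two deletions are the same variant at ≥ 80% reciprocal
  overlap; two insertions when ≤ 150 bp apart *and* sharing ≥ 80% matching
  bases under local alignment (we normalize matches by the longer sequence —
  the symmetric, stricter choice). Clustering is by
  transitive closure, so merging is order-invariant; representatives are the
  first cluster member in genomic order.
* **Singleton selection.** An SV with any other SV strictly within 150 bp is
  "clustered"; a gap of exactly 150 bp stays a singleton ("within 150 bp"
  read exclusively).
* **Benchmarking.** A call matches a truth record when both breakpoints are
  ≤ 500 bp apart (applied to both the start and the end breakpoint — the
  stricter of the possible readings) and, for deletions, reciprocal overlap
  ≥ 80%.
  Recall = TP / truth alternative genotypes; precision = TP/(TP+FP); genotype
  concordance is reported separately over the TPs.
* **Breakpoint deviation** uses the long-read comparison rule — ≤ 500 bp and
  overlap ≥ 60% of the union length, inclusive — and reports absolute start
  and end differences (mean as the scalar summary) plus, for insertions, the
  pairwise-alignment edit distance of the inserted sequences.

## The simulator: a stated world

`simulate_truth()` + `simulate_reads()` emulate the evaluation design of a
typical short-read SV study: 150 bp paired-end reads at 30× on a 1 Mb random
genome carrying 100 singleton SVs of 50–1000 bp (half deletions, half
insertions), insert size 400 ± 50 bp, 0.5% substitution error, and a quarter
of SV loci embedded in tandem-repeat (TR) arrays of 2–6 bp units with the SV
length rounded to a unit multiple — the breakpoint-ambiguous case that
dominates real genotyping errors. Genotypes default to 0/0 : 0/1 : 1/1 =
0.2 : 0.4 : 0.4 so hom-ref calls are also exercised. SV spans are placed with
at least 1 kb between them: the singleton regime requires > 150 bp, and 1 kb
additionally keeps the ±150 bp extraction windows and ~550 bp fragment reach
of neighboring loci disjoint, so per-locus results are independent. Reads are
placed in the BAM at their *true origin* with exact M/I/D/S CIGARs (reads
entirely inside novel insertions are stored as placed-but-unmapped at the
insertion anchor), so the mapping layer is noise-free and any genotyping
error is attributable to the genotyper.

What the simulator does **not** emulate: platform-specific error profiles,
indel sequencing errors, coverage waves (GC bias), real mismapping from
genome-wide repeats, or clustered/overlapping SVs. A green end-to-end test
therefore establishes correctness of the graph/alignment/model machinery
under the stated world, not performance on real data.

`corrupt_breakpoints()` shifts every SV's breakpoints by exactly ±s bp
(direction random, lengths preserved for deletions) to emulate an imprecise
input VCF; genotyping recall as a function of s ∈ {0, 5, 10, 20, 30} is the
robustness experiment, run on 200 deletion loci (the larger of the two
sample sizes stated for it).

## Numerical and design choices

* Likelihoods in log space; posteriors normalized by max-subtraction; ties in
  the posterior argmax resolve to the first genotype in enumeration order
  (REF/REF first) — with zero reads the model itself already prefers hom-ref
  by a factor $e^{\lambda\varepsilon}$.
* The depth Z-test uses variance $\lambda$ — the model-consistent (Poisson)
  choice for a two-sided Z test against the expected count.
* Node overlap counts aligned read bases (diagonal moves) only; graph bases
  spanned by a deletion gap keep the node on the path but do not count
  toward the overlap threshold.
* "Graph location" for the uniqueness test is the identity
  (strand, start column, node path).
* The per-side retained sequence in `split_long_nodes()` is exactly one read
  length: reads informative for a breakpoint overlap it by less than one
  read length, so nothing farther from the junction can matter.
* Multi-allelic VCF records are decomposed into one biallelic graph per ALT;
  the likelihood model itself handles any number of connecting edges (all
  unordered pairs).
* A read at a breakpoint counts as "neither" if it crosses a connecting edge
  without meeting the overlap threshold, or if its alignment stops exactly at
  the junction with at least the minimum overlap left unaligned (a clipped
  read that *should* have continued but matched no allele).

## Known limitations

* One SV per locus; nested or overlapping SVs are out of scope.
* Ploidy 2 only; no mapping- or base-quality weighting of likelihoods.
* The aligner returns at most `max_alignments` co-optimal alignments
  (default 8); uniqueness only needs 2, but a read with dozens of co-optimal
  placements reports only the first few.
* Breakpoint-shift robustness is demonstrated on deletions (the shift
  preserves deletion length; shifted insertions change only their anchor).
* `extract_reads()` fetches mates by position + name lookup; a mate whose
  record cannot be found is skipped with no error, matching the tolerant
  behavior expected of batch genotyping.
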