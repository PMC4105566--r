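---
title: "Consistency-based evaluation of de novo transcriptome assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consistency-based evaluation of de novo transcriptome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(unigeneqc)
library(dplyr)
```

## The problem

De novo transcriptome projects on non-model organisms — the motivating case
is long single-end pyrosequencing reads from an invasive freshwater mussel —
have no reference genome against which to judge an assembly. Different
assemblers (overlap-layout clusterers such as CAP3, MIRA or Newbler) produce
very different unigene sets from the same reads, and the choice among them
needs a reference-free yardstick. unigeneqc implements the two consistency
indexes used for that decision, together with the gene-discovery bookkeeping
that follows it: adapter clipping, best-hit annotation summaries, coverage
based full-length gene calling, and microsatellite (SSR) discovery.

A *unigene* is either a *contig* (a consensus built from two or more
overlapping reads) or a *singleton* (a read that clustered with nothing).

## The consistency indexes

**Internal Consistency Index (ICI).** For a read $r$ assigned to a contig
with consensus $c$, let $A$ be the best local alignment of $r$ against $c$
(both strands considered) and $\mathrm{ident}(A)$ its number of identically
matched bases. Then

$$\mathrm{ICI}(r) = 100 \cdot \frac{\mathrm{ident}(A)}{|r|}.$$

The denominator is the full read length, not the aligned span: a read scores
100 exactly when the *entire* read maps at 100% identity, and both partial
mapping and substitutions pull the score down. The assembly-level ICI is the
arithmetic mean over all clustered reads. Singletons are excluded — a
singleton trivially aligns to itself at 100 and, since singletons usually
outnumber clustered reads several-fold, including them would flatten the
differences between assemblers that the metric exists to expose.

**External Consistency Index (ECI).** For two distinct contigs $a, b$ with
best local alignment $A$ spanning $\mathrm{cols}(A)$ alignment columns,

$$\mathrm{ECI}(a,b) = 100 \cdot \frac{\mathrm{ident}(A)}{\mathrm{cols}(A)}
  \cdot \frac{\mathrm{cols}(A)}{\min(|a|, |b|)},$$

identity times the fraction of the *shorter* contig covered by the overlap.
A contig aligned against an identical copy of itself scores 100; a short
contig wholly contained in a longer one at perfect identity also scores 100,
which is exactly the redundancy case the metric is after ("the assembler
separated sequences that represent the same gene"). Each contig is reported
with its best-scoring partner; contigs whose best ECI exceeds 75 are flagged
as likely fragments of one gene, and pairs with no positive-scoring
alignment contribute 0 to the mean — which is why realistic assembly-level
means sit far below 100.

The exact formulas behind the published index names are described only in
earlier work that is not always at hand; the definitions above are this
package's reconstruction and satisfy every constraint the index semantics
impose (the 100-anchors for perfect mapping and self-alignment, the
meaning of the 75 threshold, and "average overlap size and identity"
behavior). The mean ECI is taken per contig (over best partners), not per
pair; that choice is stated here because the alternative is equally
defensible.

**Ranking.** `evaluate_assemblies()` ranks candidates by mean ICI, breaking
ties by the number of annotated unigenes and then by lower mean ECI — the
same two-key rule (consistency first, annotation second) used to choose
CAP3 in the motivating study, with ECI as a final deterministic tiebreak.
All three criteria are reported so a user can override the ranking.

```{r example}
tx  <- sim_transcriptome(6, len_range = c(500, 900), seed = 1)
sim <- sim_reads(tx, 36, mean_len = 300, coverage_mode = "even", seed = 2)
vars <- sim_assembly_variants(tx, sim$reads, sim$truth,
                              mutation_rate = 0.05, seed = 3)
evaluate_assemblies(list(
  truth   = list(assembly = vars$truth$assembly,   reads = sim$reads),
  mutated = list(assembly = vars$mutated$assembly, reads = sim$reads),
  split   = list(assembly = vars$split$assembly,   reads = sim$reads)
))
```

## The alignment engine

Both indexes need only identity counts and overlap fractions, so any exact
local aligner serves. The engine is an affine-gap local alignment
(Gotoh/Smith-Waterman semantics, computed by `Biostrings::pairwiseAlignment()`)
with match $+1$, mismatch $-2$, gap open $-3$ and gap extension $-1$; a gap
of length $L$ costs $3 + L$. The original workflow delegated this step to a
heuristic search tool whose defaults are not part of the index definitions;
an exact aligner makes the metrics deterministic and testable, and the
scoring scheme is exposed as arguments on every function that aligns. `N`
bases score as mismatches and never count as identities, not even against
another `N`. The test suite holds the engine to an independently coded
pure-R dynamic program on hundreds of random pairs.

An optional 11-mer prefilter (`assembly_eci(kmer_prefilter = TRUE)`) skips
contig pairs sharing no 11-mer word on either strand. A skipped pair can
only have hidden an alignment of fewer than 11 matched bases — an ECI
contribution of a few points on contigs of realistic length — but because
it can alter those near-zero scores it is off by default.

## Read cleaning

Library adapters are masked by a bounded-mismatch sliding scan: every
occurrence of an adapter (or its reverse complement) matching at least 90%
over at least 10 bases is masked, including occurrences hanging off the
read ends. The original pipeline used a repeat-masking tool with unstated
parameters; a windowed scan with an explicit mismatch budget is
deterministic and sufficient for known library adapters. Clipping then
keeps the longest contiguous unmasked run per read (ties resolved toward
the 5' end, for determinism), dropping reads whose best run is shorter
than `min_len = 20` bases — permissive on purpose, since the motivating
dataset lost only 2 of 95,219 reads at this step. Clipping is idempotent,
and on simulated reads with end-attached adapters it recovers every
planted insert base.

## Annotation and full-length calling

Tabular homology hits (the standard 12- or 14-column tab-separated layout)
are filtered at e-value $\le 10^{-5}$ — the cutoff is *inclusive*, and
where the motivating text wavers between two spellings of the threshold
the superscript form $10^{-5}$ is adopted. Best hits take the highest bit
score, with ties broken by lower e-value and then subject id. Subject
coverage merges the subject-side intervals of all HSPs of one
query/subject pair (internally half-open; emitted 1-based inclusive) and a
reference protein is called *full-length* when a **single** query covers at
least 90% of it — threshold inclusive, per "90% or more". Merging coverage
across queries is available behind `union_queries = TRUE` but off by
default: two half-covering unigenes are not evidence of one full-length
transcript.

## SSR discovery

`find_ssrs()` reports maximal perfect tandem repeats of primitive 2-6 base
motifs with minimum unit counts `c(di = 6, tri = 4, tetra = 3, penta = 3,
hexa = 3)` — the conventional MISA-style defaults, adopted because the
repeat-scanner the motivating study used does not document its own in the
text; the thresholds are arguments. Mononucleotide runs are excluded both
by the di-to-hexa scope and because 454 homopolymer over/undercalls make
them unreliable. Overlapping candidate repeats are resolved leftmost-first,
then longest. Motifs are grouped under a canonical label: the
lexicographically smallest rotation over both strands (so `TA`, `AT` and
`GT` on the reverse strand all report as one group). Published repeat-class
tables from other scanners may canonicalize differently; the rule here is
stated rather than assumed to match any particular tool. Marker candidates
are the annotated SSR-bearing sequences — an SSR inside a sequence with a
credible protein hit is unlikely to be a sequencing artifact.

## The synthetic-data generator

The generator is first-class, tested code; it emulates the study conditions
at roughly 1/100 scale so that every metric can be validated without
external downloads:

* transcripts: i.i.d. sequences, 300-2000 bases, GC 0.40, with pairs
  resampled until they share at most 5 canonical 11-mers (so the
  "unrelated contigs" ECI null holds);
* reads: substrings on either strand with mean insert 554 bases (the clean
  mean read length of the motivating dataset), optional end adapters, and a
  454-style error model — per-homopolymer ±1-base over/undercall plus
  i.i.d. substitutions;
* assembly variants with known defects: `truth`, `mutated(p)`,
  `shuffled`, and `split`, which emits each transcript as the full
  consensus plus its contained middle half so every sibling pair has ECI
  exactly 100 (a stronger, exactly-checkable version of the
  one-gene-in-two-contigs defect);
* hit tables with planted per-subject coverage exact to one residue, and
  SSR panels with planted loci whose flanks are rejection-sampled —
  against an internal scanner independent of `find_ssrs()` — so they
  neither contain qualifying repeats nor extend or re-phase the plant.

What the generator does **not** emulate: real coverage unevenness,
chimeric/CAFIE hybrid reads, quality values, paralogy and alternative
splicing, or BLAST e-value statistics. Passing tests therefore demonstrate
the correctness of the computations, not the field performance of any
assembler.

All generators are deterministic under an integer seed and restore the
caller's RNG state.

## Numerical choices and degenerate inputs

* ICI/ECI are capped into $[0, 100]$; reads or pairs with no
  positive-scoring alignment score 0.
* An assembly with a single contig has no ECI; the result is 0 with a
  warning. An assembly with no contigs is an error for ICI ("nothing to
  score").
* Alignment problem sizes in the tests (pairs up to 200 bases against the
  DP oracle; 60 reads x ~554 bases for the ICI anchors; 6-10 contigs for
  ECI sweeps) were chosen as the smallest scales at which the stochastic
  anchors have comfortable statistical margins — e.g. at 2,000+ scored
  read-bases per contig the binomial standard error of mean ICI under
  substitution rate 0.10 is well under 0.5 points, against a tolerance of
  1.5.
* Mean-ICI anchors under consensus mutation rate $p$ target $100(1-p)$:
  local alignment trims mismatching read ends, but a trimmed terminal
  mismatch was not an identity anyway, so the expectation is unbiased to
  first order (the second-order effect — a lone terminal match stranded
  behind a mismatch — is below 0.05 points at $p \le 0.1$).

## Limitations

The indexes reward internal consistency, not biological truth: an assembler
that refuses to merge anything scores a perfect ICI on its (many, short)
contigs. That is why the ranking also weighs annotation counts, and why
the package reports all criteria rather than a single score. ECI means
depend on the per-contig-best convention stated above and are not directly
comparable to numbers produced under a per-pair convention. The SSR
canonicalization is one of several in field use; compare class tables only
within one convention.
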