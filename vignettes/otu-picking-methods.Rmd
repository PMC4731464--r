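---
title: "Closed-reference OTU picking over a concatenated reference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-reference OTU picking over a concatenated reference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otupick)
```

This vignette explains the model behind `otupick`, the parameters that
matter, the numerical choices made where the design was genuinely open, and
what the package's synthetic-data tests do and do not demonstrate about
real sequencing data.

## The procedure

Closed-reference OTU picking assigns each amplicon read to its acceptable
match in a fixed database of reference marker genes, discarding reads with
no acceptable match. `otupick` organises this as four stages.

**Prep.** All references are concatenated end to end into a single
artificial chromosome, with a sorted offset index recording where each gene
starts. No separator characters are inserted: separators would perturb the
Burrows-Wheeler transform's character statistics, and boundary safety is
handled entirely by the junction test at parse time. Coordinates are
0-based and half-open everywhere inside the package; the single conversion
from SAM's 1-based `POS` happens in the SAM parser, so no other component
can accumulate off-by-one drift.

**Filter.** Reads are parsed from demultiplexed FASTA (sample id = header
token before the last underscore, the common `SampleID_ReadNumber`
convention), optionally trimmed to a fixed length, and deduplicated into a
sample dictionary mapping each distinct sequence to its per-sample
occurrence counts. Deduplication is lossless: the dictionary expands back
to the original read multiset. Two optional lossy steps follow.
*Read compaction* (`d_level >= 1`, the default) treats a read that is a
prefix of a longer read as a copy of that longer read; amplicon reads share
a primer-anchored start, so length variation is usually technical, not
biological. *Multiplicity filtering* (`d_level >= 2`) drops sequences whose
total count falls below `d_level` — singletons at level 2, also doubletons
at level 3, and so on — on the premise that a sequence observed once is
disproportionately likely to carry a sequencing error.

**Align.** Dictionary sequences (not raw reads — this is where
deduplication pays) are aligned against the concatenated reference under a
percent-identity criterion. The embedded aligner is an FM-index over the
concatenated text: suffix array by prefix doubling, full (unsampled)
suffix-array offsets — a deliberate desk-scale simplicity over memory
fidelity — and backward search for exact queries. Alignment tries an exact
whole-read backward search first; on failure it takes fixed-length seeds
spread across the read, backward-searches each, and extends every candidate
location with the semi-global scorer against a padded reference window.
The first candidate meeting the threshold wins, in seed order and then by
leftmost reference position, which makes the "first acceptable hit"
behaviour deterministic. Only the forward strand is searched; antisense
data is handled by reverse-complementing at the filter stage
(`rc = TRUE`). Alternatively, the package emits a complete bowtie2-style
command line implementing the same criterion, and consumes the resulting
headerless SAM.

**Parse.** Each surviving hit is mapped back to an OTU by binary search
over the offset index. A hit whose alignment end (exclusive) extends past
the next gene's start offset spans a junction between concatenated genes
and is discarded; an alignment ending exactly flush at the boundary is a
legitimate full-length match and is kept. The matched entry's full
per-sample counts are added to the OTU's row; the result is a sparse
sample-by-OTU table, optionally taxonomy-annotated, written as BIOM 1.0
JSON or legacy tab-delimited text.

## The identity criterion and its dynamic program

Identity is defined as matching columns divided by total alignment length,
over an alignment that must cover the whole query but may start and end
anywhere on the reference (free reference end gaps). Matches weigh 1,
mismatches 0, matches to IUPAC-ambiguous reference bases are free, and
gaps carry no affine component — a run of gaps costs one per base, the
same as isolated gaps.

Because identity is a ratio of two alignment-dependent quantities
(matches, and query length plus reference-gap bases), a single linear DP
does not directly optimize it. `semi_global_identity()` therefore uses
Dinkelbach iteration: maximize `matches - lambda * ref_gap_bases` by a
standard DP, set `lambda` to the identity achieved, and repeat until the
identity stops improving. The sequence of `lambda` values is
non-decreasing and converges to the optimum in a handful of iterations;
the test suite checks exact agreement with a brute-force enumeration that
stratifies alignments by deletion count on all small instances. Traceback
prefers diagonal over insertion over deletion moves, which among co-optimal
alignments picks one with the fewest reference gaps — a determinism choice,
not a scoring one.

For an external aligner the same criterion is expressed through the score
function: with match bonus 0, mismatch and per-base gap cost 1, a read of
length L passes a threshold `t` exactly when its score is at least
`L * (t - 1)`, hence the emitted `--score-min "L,0,-0.03"` at `t = 0.97`.
The third argument is formatted with two decimals to match the conventional
spelling of that option.

## K-mer denoising

The optional k-mer filter packs each k-mer into 2k bits (A=00, C=01, G=10,
T=11, leftmost base most significant) and builds a counter array of length
`4^k` over all reads — the empirical k-mer frequency distribution. A read
is discarded when any of its k-mers occurs in fewer than
`denoise_fraction * n_reads` reads' worth of counts. Three semantics were
open and are fixed as follows:

* **Denominator.** The threshold is a per-read prevalence: a k-mer is rare
  when its count is below `fraction × number of reads profiled`. (An
  alternative — fraction of all k-mer instances — gives nearly identical
  behaviour at amplicon read lengths but is less interpretable as
  "appearing in under X% of the data".)
* **Ambiguous characters.** Windows containing non-ACGT characters are
  skipped entirely: never counted, never a cause for discard. The 2-bit
  code has no slot for them, and penalizing Ns here would double-count the
  aligner's ambiguity handling.
* **Profiling set.** Counts are built over the raw (post-trim, pre-dedup)
  read multiset, so abundance information is not flattened before the
  frequency distribution is formed.

The operational range for 16S data is k = 8 (the default; 65536 counters)
to k = 14, with thresholds around `1e-4`; tests also use smaller k where
only the arithmetic is at stake. Memory is `4 * 4^k` bytes of counters.

## Compaction semantics

"Reads that are subsets of longer reads" is implemented as *prefix*
containment, matching the uniform-start amplicon setting that motivates
compaction; general substring containment would also capture chimeric and
frame-shifted relationships that should not be merged silently. The merge
target is the longest entry having the sequence as a prefix (prefix runs
are contiguous in the lexicographically sorted dictionary, and the longest
extension itself has no further extension, so one pass suffices). Two
equal-length distinct extensions can tie for "longest"; the
lexicographically smallest wins — a determinism tie-break with no effect on
totals.

## The synthetic-data generator

`simulate_community()` emulates a small marker-gene study: by default 5
references of 200–280 bp (rejection-sampled until all pairs are below 97%
identity, so closed-reference assignment has an unambiguous truth), 3
samples of 100 reads each with geometrically decaying abundances
(ratio 0.5, each sample with its own preference order — amplicon data is
typically dominated by a few taxa), and 150 bp reads taken as reference
prefixes, reflecting primer-anchored amplicons. Errors are flat per-base
substitution and indel rates; a manifest records every read's true
reference and edit counts. A shotgun mode with uniform random start
positions exists solely to manufacture junction-spanning alignments for
testing the junction discard rule, which amplicon-mode reads essentially
never trigger.

What this does **not** emulate: quality-correlated and homopolymer error
structure, chimeras, length-heterogeneous marker regions, reference
databases with near-duplicate entries above the identity threshold, and
primer/adapter contamination. Passing tests therefore demonstrate the
correctness of the pipeline's contracts (conservation, determinism,
threshold behaviour, format fidelity), not field accuracy on real MiSeq
data.

## Numerical and degenerate-input choices

* Dictionary entry order, and hence tags (0-based ordinals), follow byte
  (C-locale) lexicographic order of sequences — a testable contract; the
  internal sort algorithm is free.
* The junction test keeps alignments ending exactly at a boundary
  (half-open end equal to the next start): a flush full-length match to the
  end of a gene is legitimate.
* Empty read files, empty tables (shape `[0, 0]`), and reads shorter than
  k all flow through without special-casing by the caller.
* Ambiguity codes in references pass into the concatesome unmodified, are
  replaced by `A` only inside the FM-index text, and every candidate hit is
  re-scored against the original text where ambiguity matches are free —
  so the index substitution can suppress a seed but never corrupt an
  accepted alignment's score.
* The BIOM `date` field is configurable and pinned to a fixed value by the
  pipeline so identical inputs yield byte-identical outputs; pass
  `date = NULL` to `write_biom()` for wall-clock timestamps.
* Aligner presets (`fast` / `default` / `max`) trade seed count, seed
  length, and window padding for sensitivity; the preset *names* mirror
  the conventional fast/very-sensitive vocabulary, the parameter values
  are this package's own and are documented in `align_read()`.

## Problem sizes used in the tests

The test and acceptance suites run entirely on generated data at desk
scale, chosen as the smallest sizes that exercise each contract: 300-read,
5-reference communities for end-to-end recovery; 5 kb texts and 500
patterns for search-oracle equivalence; 1000 small read sets for
deduplication-oracle equivalence; strings up to length 7 for exhaustive
alignment enumeration (the enumeration is exponential); 10^4 reads for the
k-mer-threshold construction. These sizes are stated here as the package's
own choices so results are interpretable and quick to reproduce.

## Known limitations

* The embedded aligner is written for correctness and auditability at desk
  scale (pure R, full suffix array, full occurrence table); for
  multi-million-read studies, use the emitted external-aligner command and
  feed the SAM back in.
* Paired-end merging, FASTQ input, and quality-aware trimming are upstream
  of this tool; BIOM 2.x (HDF5) output and de novo clustering of unmatched
  reads are out of scope (the unmatched FASTA is the hand-off point for
  open-reference hybrid pipelines).
* `-k 1`-style "first acceptable hit" semantics are inherently
  order-dependent; this package makes the order explicit and deterministic,
  which is a contract choice, not a claim that external aligners visit
  candidates in the same order.
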