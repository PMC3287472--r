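---
title: "Calling structural variants from soft-clipped reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling structural variants from soft-clipped reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipsv)
```

## The method

A read that straddles a structural-variant (SV) junction cannot be aligned
end-to-end: a production aligner maps the part that matches the reference
and records the rest as a terminal *soft clip* (`S` in the CIGAR string,
e.g. `31S69M`). The boundary between the aligned anchor and the clipped
fragment is a putative **breakpoint**, known to the base. When the clipped
bases precede the anchor we speak of an *L-breakpoint*; when they follow it,
an *R-breakpoint*. `clipsv` turns this observation into a five-type SV
caller:

1. **Clip extraction** (`extract_clipped_reads()`): primary mapped records
   with exactly one terminal soft-clip run become clipped reads. Records
   clipped at both ends (e.g. `14S54M36S`) carry no directional information
   and are dropped. Hard clips (`H`), produced by aligners that discard the
   clipped bases, are first rehydrated from the original FASTQ
   (`soften_hard_clips()`).
2. **Breakpoint clustering** (`cluster_breakpoints()`): per contig and
   handedness, sorted breakpoint positions are chained single-linkage; a
   gap above the tolerance (default 5 bases) starts a new cluster. The
   cluster representative is the lower median of member positions and the
   member count is the cluster's support.
3. **Fragment remapping** (`excise_windows()`, `remap_fragments()`):
   clipped fragments longer than 10 bases are re-aligned against reference
   windows of ±1000 bases around every cluster representative — restricting
   the search space keeps short fragments off spurious genome-wide matches.
   The built-in re-aligner tries an exact substring scan, then a
   mismatch-tolerant full-length match, then a seeded Smith–Waterman local
   alignment with unit mismatch/gap costs; a placement must cover ≥ 90 % of
   the fragment with at most `max(2, 10 %)` edits. The single best placement
   wins (score, then lowest coordinate, then forward orientation).
   "Unmapped" is a valid and informative outcome.
4. **Typed classification** (`classify_fragments()`): with `b` the anchor
   cluster position and `[m1, m2)` the fragment placement,
   * opposite orientation → inversion `[min(b, m1), max(b, m2))`;
   * R-anchor with `m1 > b` → deletion `[b, m1)` (the fragment resumes
     beyond the deleted segment); L-anchor with `m2 < b` mirrors it;
   * R-anchor with `m2 ≤ b` → tandem duplication `[m1, b)` (the fragment
     re-enters the repeated segment); L-anchor with `m1 ≥ b` mirrors it;
   * unmapped fragment whose anchor has an opposite-handed cluster within
     10 bases → insertion at `b`;
   * mapped but inconsistent with every rule above, with such an opposite
     cluster → translocation (the placement is reported as the source).
   A placement that merely continues the anchor is uninformative.
5. **Calls** (`aggregate_calls()`, `score_calls()`, `resolve_overlaps()`,
   `filter_zero_score()`): same-type evidence whose interval endpoints agree
   within 10 bases merges single-linkage; merged endpoints are lower medians
   of member endpoints. Support counts follow breakpoint handedness:
   `B_L`/`B_R` are the clipped-read supports of the L-/R-handed clusters
   involved, `C_L`/`C_R` the remapped fragments anchored on each side. The
   reliability score is

   \[ \mathrm{score} = \sqrt{(B_L + C_L)\,(B_R + C_R)}, \]

   which grows with support, is maximal for balanced sides at fixed total,
   and is exactly zero for one-sided calls
   (\((B_L,B_R,C_L,C_R) = (n,0,m,0)\) or \((0,n,0,m)\)). Among overlapping
   same-type calls only the highest-scoring survives, and zero-score calls
   are removed by default — the method's entire noise control; no minimum
   read-count threshold is applied.

The scoring formula is a package design choice: it satisfies every property
required of the reliability score (monotonicity, balance, the one-sided
zero rule) and is exposed as a swappable strategy (`score_fun` argument of
`call_svs()`), so an alternative can be dropped in without touching the
pipeline.

## Coordinates and breakpoint normalization

All internal coordinates are 0-based, half-open; SAM's 1-based `POS` and
VCF output are converted at the I/O boundary. An R-breakpoint sits at the
first reference position *after* the last aligned base, which makes
deletion/duplication interval arithmetic exact.

When the two flanks of a junction share bases (microhomology), several
intervals produce byte-identical donor genomes and no caller can
distinguish them. Both the caller and the simulator therefore **normalize**
DEL/INV/DUP intervals (`normalize_sv_interval()`): deletions and tandem
duplications are shifted one base left as long as the shifted event yields
the same donor sequence (the VCF left-alignment convention), while
inversions — whose ambiguity is palindromic trimming of the interval's two
ends — are shrunk while equivalence holds, which is the representation a
split-read caller's maximally extended anchors naturally produce. Without
this, roughly a quarter of simulated junctions would disagree with their
truth records by the homology length despite describing the same variant.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `bp_tol` | 5 bases | max gap between chained breakpoint positions |
| `min_frag_len` | 11 bases | fragments longer than 10 bases are remapped |
| `window_elong` | 1000 bases | half-width of remap windows around clusters |
| `call_tol` | 10 bases | max per-endpoint difference when merging evidence |
| `same_pos_tol` | 10 bases | L/R cluster distance counting as "same position" for INS/TRA |
| `min_mapq` | 0 | anchors are not filtered by mapping quality by default |
| `zero_filter` | TRUE | drop score-zero (one-sided) calls |

The clustering tolerance is read as *chained* (single-linkage) distance:
fixed-width windows would make results depend on input order and absolute
offsets, while chaining is deterministic and order-independent (a property
the test suite checks). Likewise the insertion/translocation "same
position" rule uses the call-clustering tolerance; both are configurable.

Multi-mapping is resolved to a single best placement per fragment with a
deterministic tie-break rather than discarding ambiguous fragments, and a
fragment counts toward `C` on the side of its *anchor*, not of its remap
target.

## The simulator

`simulate_dataset()` reproduces the evaluation conditions the package is
validated under: a configurable number of SVs (default 200) of types drawn
uniformly from DEL/INS/INV/DUP, event lengths `N(mean, mean/10)`,
single-nucleotide alterations at rate 1/10 000, tandem-duplication copy
numbers `N(40, 20)` truncated above 1, error-free paired-end reads at a
mean depth (default 40×) with read length 108 and template lengths
`N(400, 50)`; the pair count is `round(depth × genome / (2 × read_len))`.
Events are placed uniformly, rejecting layouts where two events come closer
than twice the mean insert so truth intervals stay well defined. Truth
records are reported in reference coordinates and, together with the
recorded inserted sequences and copy numbers, rebuild the donor genome
byte-for-byte (`apply_truth()`), which the suite verifies across 100 seeds.

Reads are error-free by design: the SNV rate already injects mismatches,
and error-free reads make the single-base-resolution checks exact. The
generator therefore does *not* emulate base-quality decay, indel sequencing
errors, GC or coverage bias, chimeric fragments, or multi-mapping repeat
structure of real genomes — passing tests demonstrate the geometric logic
of the caller, not robustness to every artefact of real libraries.

`map_reads()` is a deterministic exact-seed (20-mer) mapper with base-wise
extension and terminal soft-clipping, anchoring the longer matching side of
each read, used so the test data need no external aligner. Real data should
be mapped with any production aligner that emits soft clips; the caller
consumes standard SAM.

## Evaluation

`evaluate_calls()` scores a callset against truth with two rates computed
over type- and contig-matched records. The *discovery rate* is the mean
over truth records of the best overlap fraction achieved by any call
(sensitivity-like); the *true call rate* is the mean over calls of the best
overlap fraction achieved by any truth record (specificity-like); the
fraction is measured in the first record of each pair, so the two rates are
exact duals. Insertions carry only a point, which is widened to ±100 bases
on both sides before overlap. Best-match aggregation (max, then mean) is
used rather than one-to-one assignment; calls may therefore be matched by
the same truth record, which the duplication-invariance test pins down.

## Numerical choices and degenerate inputs

* Cluster and call representatives use the *lower* median, keeping
  representatives on observed positions and resolving even-count ties
  deterministically.
* Overlap resolution orders by score, then total support, then start.
* Empty inputs (no clips, no clusters, no evidence) yield an empty callset
  with a complete stage-count manifest rather than an error; rates over
  empty sets are reported as `NA`, never 0/0.
* `"*"` CIGARs and sequences, unmapped, secondary and supplementary
  records are skipped with counters; multi-line FASTA and missing quality
  strings are tolerated.

## Problem sizes

The validation suite runs entirely on simulated genomes chosen to exercise
every code path at comfortable scale: single-event runs on 100 kb genomes
at depth 30, and a study of 20 SVs on 1 Mb genomes at depths 5–40 and read
lengths 50–108 across several seeds (up to roughly 800 000 reads per run).
These sizes are the package's own choice of test conditions; the caller
itself is linear in the number of reads and windows and has no intrinsic
genome-size limit.

## Known limitations

* Insertion length is not estimated — only the insertion point is called
  (the clipped fragments alone cannot measure it).
* Translocations are classified and reported but not simulated, so their
  accuracy is not benchmarked here.
* One anchor placement per read is used; alternative placements of
  multi-mapping reads are ignored.
* Discordant-pair and read-depth signals are not used; very short reads or
  very low depth starve the method of clipped fragments (the test suite
  checks that rates at depth 20 and read length 100 are at least those at
  depth 5 and read length 50 under the simulated conditions).

## A worked example

```{r example, eval = FALSE}
set.seed(7)
ref <- random_genome(1e5, "chr1")
cfg <- sim_config(n_svs = 1, sv_types = "DEL", sv_len_mean = 500,
                  sv_len_sd = 50, snv_rate = 0, depth = 30, read_len = 100,
                  seed = 7)
sim <- simulate_dataset(ref, cfg)
reads <- c(sim$reads$seq1, sim$reads$seq2)
names(reads) <- c(paste0(sim$reads$ids, ".1"), paste0(sim$reads$ids, ".2"))
aln <- map_reads(reads, ref)
calls <- call_svs(aln, ref)
calls[, c("ref", "start", "end", "sv_type", "B_L", "B_R", "C_L", "C_R",
          "score")]
evaluate_calls(sim$truth, calls)
```
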