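---
title: "Primer-anchored amplicon variant calling: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Primer-anchored amplicon variant calling: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(amplicall)
```

## The problem and the model

Targeted amplicon sequencing reads a small set of PCR-amplified exon
regions at high depth. Every read begins at a known primer, which makes
two shortcuts available that a whole-genome pipeline cannot use: reads
can be *demultiplexed* to their amplicon by reading a few primer
positions rather than aligned to a genome, and the enormous redundancy of
amplicon data can be removed *before* alignment by collapsing identical
spliced read pairs. `amplicall` builds a variant caller around exactly
these two shortcuts.

The library structure assumed throughout is, in R2's reading direction:

    index | forward primer | target (exon) | reverse primer

R2 reads this strand from the index end; R1 reads the opposite strand,
so it starts at the reverse primer. The panel-wide *public* sequence is a
capture oligo: when target capture fails it is sequenced instead of the
target, so pairs containing it (R1 forward, R2 reverse-complemented) are
discarded outright rather than repaired.

## Pipeline stages and their parameters

1. **Public cleaning** (`clean_public`). Exact substring containment;
   either mate hitting drops the pair. Idempotent by construction.
2. **Index trimming** (`clean_index`). The first `|index| + 2` bases of
   R2 are scanned for the index allowing up to `index_max_mismatch = 3`
   substitutions (no gaps); the leftmost hit wins, preserving the most
   read. When the target is shorter than the read length (150 bp), R1 is
   truncated to the target length so index read-through at its 3' end
   cannot masquerade as variation. The pipeline applies this truncation
   per amplicon *after* assignment, since it needs the target length.
   A single-sample library is assumed: the pipeline requires one shared
   index across the panel, because signatures are read from the start of
   the trimmed R2 and a per-amplicon index could not be removed before
   the amplicon is known.
3. **Collapse** (`collapse_pairs`). Key = `R2 + revcomp(R1)`; counts per
   distinct key; entries below `phi` dropped. Default `phi = 1` keeps
   every sequence — the all-inclusive setting; raising φ trades
   sensitivity at low allele fractions for speed and noise suppression.
   Ties in the frequency ordering are broken lexicographically so output
   order is reproducible across platforms.
4. **Signature selection** (`select_positions`). The canonical method
   enumerates position subsets of the primers' common prefix in
   increasing cardinality and takes the lexicographically smallest
   discriminating set; panels are small (tens of primers), so exhaustive
   search is cheap and gives a well-defined, minimal answer. The greedy
   variant ("add the position separating the most colliding pairs") is
   provided as a fast path but is not guaranteed minimal. Primers of
   unequal length are compared over their common prefix.
5. **Assignment** (`assign_reads`). Exact signature match. A variant at
   a signature position would mis-route a read; the optional `rescue`
   mode re-examines unassigned sequences by banded alignment of their
   primer prefix against all primers (unique best hit with `k <= 2`).
   It is off by default because it is an extension of the exact model.
6. **Alignment** (`align_local`). Scoring is +1 match, 0 mismatch, −1
   per gap character, floored at 0, inside a band `|i − j| <= ε` with
   `ε = |m − n| + 1` by default (overridable via `epsilon`). The
   k-statistic `k = min(m, n) − matched` drives acceptance at
   `k_max = 2`.
7. **Calling** (`pileup_amplicon`, `call_snps`, `call_indels`).
   Frequency-weighted base counts per position; the five-way denominator
   includes N. A SNP is called when the reference fraction falls below
   `snp_ref_fraction = 0.90`; the interval [90%, 100%) is deliberately
   conservative — only "exactly 100%" and "below 90%" have defined
   behaviour in the underlying rule, and no call is made anywhere at or
   above the threshold. `min_depth = 10` (package choice) suppresses
   calls where the frequency ratio is statistically meaningless.
   Indels come from gap operations on accepted paths, left-shift
   normalised before aggregation so repeat-region placements agree.

## Numerical and geometric choices

**Band anchoring.** The band is centred on the main diagonal, i.e. on
alignments that share their start. The R2 fragment is a target *prefix*
(offset 0); the R1 fragment is a target *suffix*, whose natural offset
`n − m` sits exactly at the band edge, where an insertion-shifted path
would leave the band. The R1 fragment is therefore aligned in its native
orientation against the reverse-complemented target — again a prefix
alignment — and its coordinates mapped back. This is purely a coordinate
frame choice; the recurrence and the ε rule are unchanged.

**Why k tolerates insertions asymmetrically.** When the read fragment is
shorter than the target, an inserted run of length L leaves L fragment
characters unmatched, so `k = L` and a strict `k <= 2` rule would reject
every read carrying an insertion longer than 2 bp. Alignments are
therefore admitted as indel evidence when `k − inserted <= k_max`, while
the SNP pileup keeps the strict rule (an alignment with many unmatched
characters should not vote on base frequencies).

**Gap coalescing.** Because a mismatch costs 0 and a gap −1, the optimal
path splits a long gap around any accidental interior match: a 6 bp
deletion with one matching base inside scores one point better as 3+3
with a match between. `call_indels` therefore coalesces same-kind gap
runs separated by at most `merge_gap = 10` aligned columns and re-derives
the composite event exactly from the read and target strings; the merge
is only kept when one contiguous event reproduces the read, so a generous
window cannot fabricate events.

**Primer stripping.** Primer bases are removed from fragments by length,
not by matching: reads begin at the primers by construction, and
aligning primer bases against the target would inflate k for every read.

**Indel anchoring.** Records are VCF-style left-anchored (one shared
reference base); an event touching target position 1 is right-anchored
instead. Truth matching in the evaluator compares left-shift-normalised
events, so equivalent placements in repeats count as the same call.

## The simulator: what it emulates and what it does not

`sim_panel` / `sim_truth` / `sim_reads` generate a synthetic study:
20 amplicons with 160–190 bp targets, 7 bp primers, an 8 bp shared index,
error-free 150 bp paired reads at depth 50, 30 spiked SNPs and 20 indels
of 2–10 bp at allele fraction 0.5 — a 1/100-scale analogue of a
high-throughput spike-in experiment (3000 SNP / 2000 indel sites at
10⁸-read scale), with each variant carried per read independently with
probability equal to its allele fraction. Target lengths are kept at or
above the read length so that no target is fully traversed by a read
(which would append reverse-primer bases to the R2 fragment) and the
automatic band always spans indel-shifted paths; variant sites keep a
12 bp margin from target ends and 24 bp separation from each other.

Deliberately *not* emulated: base-quality error models (errors, when
requested, are uniform substitutions), adapter read-through on short
inserts, PCR chimeras and polymerase slippage, strand bias, and germline
variant databases. Passing tests on this simulator therefore demonstrate
the algorithmic correctness of cleaning, demultiplexing, alignment and
calling — not robustness to platform-specific noise on real data.

```{r study, eval = FALSE}
# the default scaled study (runs in seconds; also exercised by the tests)
panel <- sim_panel(n_amplicons = 20, seed = 1121)
truth <- sim_truth(panel, n_snps = 30, n_indels = 20, seed = 1121)
pairs <- sim_reads(panel, truth, depth = 50, capture_fail_rate = 0.05,
                   seed = 1121)
res <- call_pipeline(pairs, panel)
run_evaluate(tidy(res), truth, panel)
```

Evaluation counts true negatives positionally — target positions with
neither a spiked variant nor a call — because per-site negatives are
otherwise ill-defined for a variant caller; FPR and accuracy should be
read with that definition in mind.

## Known limitations

* **Edge-proximal long deletions.** A deletion whose flank on one side
  is barely longer than the gap can be outscored by a free-mismatch path
  (the flank gain barely exceeds the gap cost), leaving no alignment
  that carries the event. Across seeded replicates of the default study
  this keeps indel recall in the 0.90–1.00 range while SNP recall stays
  at 1.00; deletions more than ~25 bp from a target end are unaffected.
* **Dense SNPs.** A fragment spanning more than `k_max` true mismatches
  is rejected wholesale, so a region with 3+ clustered SNPs loses the
  mate that sees all of them; a variant covered by only that mate is
  then missed. This is inherent to the k acceptance rule.
* **No quality awareness.** Base qualities are carried through cleaning
  but ignored by the caller; the frequency model treats every read
  equally. Germline-database filtering and CNV detection are out of
  scope.
* **Multi-sample indices.** One index per run; demultiplexing multiple
  samples by index is not implemented.
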