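---
title: "Leader-end CRISPR genotyping: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leader-end CRISPR genotyping: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and its model

A subtype I-D CRISPR locus is an alternation of a conserved direct repeat
(here ~20–40 bp) and variable spacers acquired from phages and plasmids,
with new spacers inserted adjacent to the leader. Amplifying the
leader-end fragment (forward primer in the leader, reverse primer in the
repeat) and sequencing it deeply turns a natural population into a sample
of ordered leader-end spacer arrays. Two assumptions carry the whole
analysis:

* **Order is identity.** A CRISPR genotype (CT) is defined by the shared
  order of leader-end spacers, and spacer repertoires are disjoint across
  CTs. An amplicon showing spacers of one CT in the catalog's relative
  order belongs to that CT; spacers of two CTs in one amplicon signal a
  chimera or a catalog fault and are reported as ambiguous, never voted
  on.
* **Substitutions dominate errors.** Short-read amplicon errors are
  overwhelmingly substitutions, so every matching step in the package —
  repeat detection, spacer unification, clustering, protospacer search —
  is ungapped (Hamming). Indel-containing variants deliberately fall out
  as new spacer identities rather than being glued back probabilistically.

Within a CT, each array is classified against the CT's *origin*
repertoire $O = (o_1, o_2, \dots)$ (leader-end first) by splitting it
into a maximal leading block of novel spacers followed by a remainder:

| class | leading novel | remainder |
|---|---|---|
| `origin` | 0 | $o_1..o_k$, a contiguous prefix |
| `new_plus` | ≥ 1 | $o_1..o_k$ |
| `proto` | 0 | $o_j..o_{j+k-1}$ with $j \ge 2$ |
| `others` | anything else (deletions, internal novelties, novel-only) | |

`proto` is biologically the ancestral state — the repertoire as it was
before the newest spacers were acquired — and its persistence alongside
`origin` and `new_plus` subpopulations is the signature of an incomplete
selective sweep. The classes are exhaustive and mutually exclusive; a
brute-force enumerator in the test suite checks the classifier against
the literal definitions over every array of length ≤ 4 built from a
length-5 origin plus two novel IDs.

## Parameters that matter

All thresholds live in one `pipeline_config()` object; no stage has
hidden constants. Units and defaults:

| key | default | unit | why |
|---|---|---|---|
| `window_size` | 4 | bases | trimming window; cut at the first window whose mean quality drops below the threshold |
| `q_threshold_r1` / `q_threshold_r2` | 10 / 20 | Phred | the reverse read of this chemistry is much worse, so it is trimmed harder |
| `min_len_r1` / `min_len_r2` | 200 / 70 | bases | post-trim length floors per mate |
| `qual_floor`, `qual_fraction` | 20, 0.80 | Phred, fraction | keep a read only if ≥ 80% of bases reach Q20 (exactly 80% passes) |
| `min_overlap` / `max_overlap` | 60 / 301 | bases | admissible merge overlaps |
| `merge_identity` | 0.90 | fraction | a pair merges iff the best overlap's mismatch fraction is ≤ 0.10 (exactly 0.10 passes) |
| `cluster_identity` / `cluster_coverage` | 0.95 / 0.90 | fraction | greedy clustering thresholds (see below for the coverage denominator) |
| `repeat_sequence` | 22-bp stand-in | DNA | the repeat is organism-specific and **must be overridden for real data**; the default is the reverse complement of a repeat-anchored reverse primer with degeneracy collapsed, and the simulator shares it through the config |
| `repeat_max_mismatch` | 5 | count | tolerant enough to survive realistic error rates; spurious hits on a ≥ 20-bp repeat are negligible (≈ binomial tail of ≥ 17/22 matches at p = 0.25) |
| `min_partial_repeat` | 15 | bases | a 3'-truncated terminal repeat still anchors the last spacer |
| `spacer_min_len` / `spacer_max_len` | 20 / 60 | bases | observed leader-end spacers run ~30–40 bp; 20–60 covers them with margin while rejecting fused or truncated segments |
| `spacer_max_mismatch` | 6 | count | spacer unification tolerance (equal length only) |
| `new_ct_min_novel` | 3 | count | arrays with ≥ 3 novel spacers found new CTs; arrays with 1–2 novel spacers and no catalog spacer are unclassifiable and discarded |
| `dominance_threshold` | 0.01 | fraction | a CT is "dominant" if it exceeds 1% of all amplicon weight, computed on the pooled data |
| `shannon_base` | e | — | Shannon in nats; a config option |
| `chao1_bias_corrected` | TRUE | — | $S_{obs} + F_1(F_1-1)/(2(F_2+1))$; never divides by zero, classic form available |

## Numerical and procedural choices

* **Trimming dialect.** The window scan cuts at the *start* of the first
  failing window (the named trimmer's documented behaviour). Reads
  shorter than the window pass unchanged; an empty read stays empty.
* **Merging.** Among overlap lengths in `[60, 301]` the merge picks the
  lowest mismatch fraction, breaking ties toward the longer overlap (a
  deterministic reading of the usual merge heuristic). At disagreeing
  overlap positions the higher-quality base wins, ties to the forward
  read, and the kept quality is the max of the two — qualities are only
  used upstream of this point, so the choice is inert downstream.
* **Ungapped "alignments" everywhere.** `pairwise_identity()` reports the
  best ungapped offset alignment (max matches; ties to the longer
  overlap). A literal semi-global alignment with internal gaps would make
  "aligned columns" ambiguous and buy nothing in a substitution-only
  stack; this is a deliberate simplification, stated here once.
* **Clustering coverage denominator.** Identity is matches / aligned
  columns of the best alignment. For *membership* the length-coverage
  test divides by the **longer** sequence (the representative), not the
  shorter. With a shorter-sequence denominator every one-spacer amplicon
  (the majority of reads) has coverage 1.0 against *any* longer array
  sharing its leading spacer, so such reads would be absorbed into
  whichever same-prefix cluster was founded first — sometimes a deletion
  variant — and per-CT variant fractions would be mixtures by
  construction. With the longer-sequence denominator clusters correspond
  to whole array types, which is the property the variant tables require.
  `pairwise_identity()` itself still reports coverage over the shorter
  sequence (containment), which is the informative quantity for a
  reporting function.
* **First-fit greedy clustering.** Sequences processed longest-first
  (ties: lexicographic id); each joins the first qualifying cluster in
  founding order or founds one. Exact duplicates are collapsed
  beforehand; because duplicates make identical membership decisions and
  new clusters are appended at the tail, collapsing cannot change the
  outcome. A slow all-pairs reference implementation in the tests
  reproduces the clustering exactly.
* **Dictionary order.** Spacer sequences are unified greedily in
  decreasing abundance (ties: lexicographic), star-shaped around the
  canonical: members match the canonical only, never each other, so
  unification cannot chain two sequences 12 mismatches apart through an
  intermediate. Abundance-first ordering makes the canonical the likely
  error-free form and makes the result independent of input file order.
  Cross-length matching is disallowed (an indel is not a sequencing
  substitution); catalog-seeded IDs keep reference numbering stable and
  new IDs continue after the catalog maximum.
* **New-CT grouping.** Candidates (all-novel arrays with ≥ 3 spacers) are
  agglomerated in a fixed order (longest, then heaviest, then by id): a
  candidate sharing spacer IDs with no group founds one, with exactly one
  group joins it, with two or more groups is flagged
  `unassigned_ambiguous` and modifies nothing — merging two established
  groups through a bridge read would violate cross-CT spacer
  disjointness, and a bridge is more plausibly a chimera. Each group's
  origin repertoire is its longest array (ties: weight, then id); the
  extended catalog is re-validated for disjointness.
* **Singletons.** Any distinct ID array with total weight 1 across the
  whole pooled dataset is relabelled `discarded_singleton` before new-CT
  definition; one observation cannot be distinguished from an error.
* **Denominators.** Relative abundances are reported against total
  amplicon weight (assigned + discarded + unassigned), with
  assigned-only fractions alongside; dominance uses the pooled total.
  Diversity statistics are computed over assigned CT labels weighted by
  read-weighted (cluster-size) abundances.
* **Degenerate inputs.** Empty FASTQ samples produce a flagged,
  zero-weight profile and do not abort the run; empty count vectors are
  a domain error for the Shannon index; rarefaction rejects subsample
  sizes outside `[1, N]`; `chao1` falls back to the bias-corrected form
  at `F2 = 0`.

## What the simulator emulates — and what it does not

`simulation_config()` defaults describe the stated world of a bloom
season: 16 reference CTs with 10-spacer repertoires of 32–40-bp spacers,
7 samples, one dominant CT at 32% pooled abundance with variant mix
origin 0.50 / new_plus 0.45 / proto 0.004 / others 0.046 (other CTs
origin-heavy at 0.90/0.08/0.005/0.015), 1–5 spacers per amplicon with
probabilities ≈ 0.63/0.28/0.046/0.031/0.015 (the field's typical
observation: ~62% one-spacer, ~27% two-spacer amplicons), 20,000
read pairs of 300 bases, substitution rates 0.001 (R1) / 0.005 (R2), and
R2 qualities that start lower and decay toward the 3' end so the
trimming and filtering thresholds are actually exercised. Per-sample CT
proportions follow a Dirichlet around the base composition
(concentration 200); a log-normal random walk and a founder-effect
bottleneck (resampling a few surviving CTs mid-series) are available for
sweep/bottleneck scenarios.

Fixed choices a scientist must know:

* **Leader tail = 140 bp.** The amplicon's leader fragment is long
  enough that a one-spacer template (140 + 22 + ~36 + 22 ≈ 220 bp)
  passes the 200-bp forward-read length filter — required for a world in
  which the majority of accepted amplicons carry one spacer — while the
  longest five-spacer template (~472 bp) still leaves ≥ 60 bp of overlap
  for merging at 2 × 300 cycles.
* **`new_plus`/`others` amplicons carry ≥ 2 spacers.** A single novel
  spacer with nothing after it is exactly the unclassifiable
  "one-or-two novel spacers" discard class; emitting it as a labelled
  variant would make the zero-error recovery target unreachable for any
  implementation, so the generator draws at least two spacers for these
  variants.
* **One `new_plus` spacer per CT**, drawn from a reserved novel pool
  that respects the same pairwise-distance constraint as the catalog
  (> 6 mismatches between equal-length spacers), so "novel" is
  detectable only by dictionary lookup failure, not by annotation; and
  `others` is realised as a deletion of the second origin spacer.
* **Qualities are independent of errors.** The quality model shapes
  trimming/filter attrition; the substitution process is a flat per-base
  rate. Real base-callers correlate the two; this simulator does not.

Not emulated: PCR chimeras, amplification bias, indels, adapter
read-through, real *Microcystis* repeat/leader sequences. A green test
therefore establishes that the pipeline inverts its own generative
model — catalog recovery, order-preserving typing, variant arithmetic,
diversity algebra, determinism — not that it reproduces any particular
wet-lab dataset; thresholds tuned for real data (above all
`repeat_sequence`) must come from the organism at hand.

## Known limitations

* Clustering is all-pairs against representatives (no k-mer prefilter):
  intended for desk-scale inputs (≤ a few ×10⁵ reads), not HiSeq lanes.
* One CRISPR locus per genome; amplicons must be leader-anchored.
* The 6-mismatch spacer unification is a hard rule, not an error model;
  at much higher error rates than simulated it will oversplit.
* Protospacer search is exact ungapped matching against user-supplied
  references — a desk-scale stand-in for a remote gapped search, not a
  homology tool.
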