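---
title: "Auditing nuMT-induced reference bias: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing nuMT-induced reference bias: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(numtaudit)
```

## The mechanism under audit

Mitochondrial short-read analysis against a whole-genome reference is a
competition: every read is placed at whichever locus it matches best, and
nuMTs (nuclear copies of mitochondrial sequence) sit only a few mismatches
away from their chrM source. The quantity that decides a read's fate is its
mismatch count to each candidate locus. A mitochondrial SNV changes that
count by exactly one — *down* at a nuMT whose sequence carries the
alternative allele, *up* at chrM. Reads covering the variant can therefore
flip loci, and because the flip is allele-specific, it removes alternative
allele reads only. Everything this package computes — coverage loss,
observed minor allele frequency (MAF), background-SNP deltas — is a
bookkeeping of that one mechanism.

The pipeline is: synthesise references with planted nuMTs → fragment the
mitochondrial contig exhaustively → align by best hit → compare per-position
depth and pileups between reference and mutated fragment sets.

## Model assumptions

* **Error-free, substitution-only reads.** Fragments are exact windows of
  the (possibly mutated) genome at uniform Q40. There is no sequencing-error
  or quality model: the audit isolates alignment behaviour, and with exact
  reads a counting pileup is an exact allele-frequency estimator, so any MAF
  deficit is attributable to alignment, not calling.
* **Gapless (Hamming) scoring.** Since simulated reads contain no indels,
  gapless scoring is *exact* for this study, and it removes production
  aligner heuristics (soft-clipping, gap penalties, seeding stochasticity)
  as confounders while preserving the decisive mismatch-count competition.
  The SAM bridge exists to rerun the same audit under real aligners.
* **Exhaustive, deterministic sampling.** Sliding windows at 1 bp step make
  depth a census, not an estimate: with read length `r`, interior depth is
  exactly `r`× (single-end) or `2r`× (paired-end with both mates counted),
  so a change of even one read is visible and all results are exact integers
  over known denominators.
* **Exact copy-count heteroplasmy.** Mixtures concatenate whole fragment
  sets (`c_ref` : `c_mut` copies), not binomial samples; the nominal MAF is
  exact by construction and observed MAF obeys the closed form
  `(d_mut c_mut)/(d_mut c_mut + d_ref c_ref)` with `d_ref`, `d_mut` the
  retained depths. Stochastic downsampling would only blur the quantity
  under study.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `read_length` | 100 bp | canonical short-read lengths 100/150/300 bp; depth maxima 100/150/300× |
| `insert_size` | 2×`read_length` | total template length; 200 bp with 100 bp mates means abutting mates, reproducing the 200/300/600× paired maxima exactly; a range (e.g. 200–205) models aligners requiring nonzero insert SD |
| `step` | 1 bp | exhaustive census; larger steps trade resolution for speed |
| `k` (seed length) | 19 | with non-overlapping seeds at offsets 0, k, 2k, …, a read with *m* mismatches keeps ≥ ⌊r/k⌋ − m exact seeds; k = 19 gives 5 seeds per 100 bp read |
| `max_mismatch` | 4 | < ⌊100/19⌋ = 5, so candidate recovery is *guaranteed* for every mappable 100 bp read — the seeded aligner provably equals the brute-force scan (and is tested to) |
| `mito_first` | TRUE | tie-break order; see ambiguity policy below |
| detection `threshold` | 0.01 | observed-MAF cutoff below which a call counts as undetected, modelling pipelines that screen out low-frequency calls |
| mixture copies | 1:1, 95:5 | 50% and 5% heteroplasmy, the two regimes where bias is respectively visible and fatal |

## What the synthetic references emulate — and what they do not

`make_mito_genome()` draws i.i.d. uniform A/C/G/T and rejects any draw
containing a duplicated k-mer (either strand). This guarantees that without
nuMTs every fragment maps uniquely to its origin, so *any* loss is
nuMT-driven — the premise of the audit. `plant_numt()` then paints a copied
mitochondrial segment, with specified point mismatches, onto random nuclear
background; only homology to chrM matters, so background structure is not
modelled.

The emulated properties of the real system are the ones that drive the
mechanism: genome length (16,569 bp default), nuMT length and divergence,
and the placement of divergence sites relative to a focal variant. What is
*not* emulated: real mitochondrial base composition and repeat structure,
the true GRCh38 nuMT catalog (hundreds of copies with a broad divergence
spectrum), the rCRS placeholder N at position 3107, or production aligner
scoring. Consequently a green test establishes that the package computes the
confounding mechanism correctly — it does **not** reproduce
reference-genome-specific counts (how many of the 49,707 variants are
affected depends on the nuMT catalog, and on synthetic references the answer
is whatever was planted). Auditing a real reference requires the external
mode: align real FASTQ output of `write_fastq()` with a real aligner and
ingest the SAM via `read_sam()`.

### The one-mismatch fixture

`one_mismatch_fixture()` realises the minimal total-loss scenario: a nuclear
copy of the segment around a focal position, identical except for one
mismatch *at* the focal position, with the focal SNV's alternative allele
equal to the nuclear base. The copy extends `flank = 150` bp on each side.
The flank choice is deliberate: it exceeds the 100 bp read length (every
100 bp or 150 bp read covering the focal base lies wholly inside the copy,
hence total loss), while 300 bp reads necessarily overhang the 301 bp copy
into nuclear background and anchor back to chrM, giving the strictly partial
loss that demonstrates the benefit of longer fragments. Pairing helps the
same way: a mate outside the copy rescues its confounded partner through
proper-pair scoring.

### The two-mismatch fixture and the background-scan denominator

`background_scan()` measures, for every SNV within ±100 bp of a background
(haplogroup-defining) SNP, its loss with and without that SNP. The loss
*with* background uses the background genome's **own** reference alignment
as denominator. This is a genuine design choice (the convention is not
forced by the problem): it isolates the *incremental* effect of the focal
variant from the background's solo loss, at the price of excluding — from
both numerator and denominator — reads the background alone already
removed.

That convention has a sharp geometric consequence, which drove the fixture
design. If the nuMT differs from chrM at the background site only, the
background strips *all* reads covering it in the denominator alignment, and
no focal variant can add loss: deltas are identically zero. Exacerbation
requires a second nuMT divergence site within one read length of the first:
reads covering both sites survive the background (1 mismatch to each locus;
ties retained on chrM) and are lost only when a focal variant *completes*
the match to the nuclear copy. `two_mismatch_fixture()` therefore places
its second divergence site 60 bp from the background site. Per-read
accounting is fully analytic: a read carrying background + focal has 2
mismatches to chrM and `2 − (number of its alt alleles matching the nuclear
copy)` to the nuMT.

## Numerical and policy choices

* **Loss definition.** `loss = 100 × (1 − d_mut/d_ref)`, unclamped
  (negative if coverage rises), undefined (error) at `d_ref = 0`. A fully
  confounded variant scores exactly 100%, consistent with "no fragments
  covering the mutated position". Threshold binning uses *strict*
  inequalities (>0%, >10%, …); paired-end sweeps apply a >3% floor before
  binning to absorb insert-size jitter.
* **Tie-breaking and ambiguity.** Ties on mismatch count set
  `ambiguous = TRUE` and are broken deterministically: contig order in the
  `reference_set` (chrM first by default — conservative, understating nuMT
  capture), then position, then + before −. MAPQ is not modelled; the
  ambiguity flag is its analog (exported as MAPQ 0/60 in SAM). Depth counts
  ambiguous reads at their tie-break winner; `drop_ambiguous = TRUE`
  switches to the stricter convention, and `mito_first = FALSE` reverses
  the contig order for sensitivity analysis.
* **Paired-end policy.** FR orientation, template length within the insert
  range ± 10 bp, joint mismatch minimisation; an unpaired combination
  replaces a proper pair only when better by ≥ 2 mismatches (`pair_bonus`).
  Mates are counted independently over their own spans in depth (abutting
  mates at insert 200 tile the template without double-counting).
* **Sweep locality.** Only fragments overlapping the variant position differ
  from the reference set, so each of the 3L variants realigns ≤ `r` (single
  end) or ≤ 2 templates' worth of reads, against a cached reference
  alignment. The result is proven equal to full realignment in the test
  suite, and is independent of sweep order and chunking.
* **Circular genomes and the breakpoint.** Fragmentation is linear by
  default (matching the coverage ramps real pipelines show at the ends of a
  linearised circular genome); `breakpoint_scan()` audits variants within
  ±100 bp of the junction on a rotated genome, reporting in original
  coordinates. On nuMT-free references this scan is uniformly zero.
* **Degenerate inputs.** Genomes are strict upper-case ACGT (position-3107-
  style Ns are out of scope); SNV application checks the reference allele
  (guarding coordinate bugs); zero-depth pileups return MAF 0 with an
  explicit `zero_depth` flag rather than NaN; reads shorter than k, inserts
  shorter than reads, overlapping nuMT plants and linear-genome rotations
  are rejected with messages.
* **Seeding.** Every stochastic step (genome draw, background sequence,
  range-insert sampling) derives a private stream from one user seed via
  hashing; nothing touches the caller's RNG state, and regenerating any
  subset of templates reproduces the full run's draws.

## Limitations

* Synthetic references cannot reproduce catalog-dependent counts from any
  real genome build; those require the SAM external mode.
* The full 49,707-variant sweep is supported but takes on the order of an
  hour at default scale in plain R; the test suite instead proves the
  locality optimisation exact and sweeps representative subsets.
* mitoCaller-style likelihood calling is intentionally replaced by exact
  counting (correct for error-free reads); calibrating against a real
  caller's thresholds is out of scope.
* Indels, multi-nucleotide variants and more than two variants per read are
  not modelled; haplotypes enter only via the background scan's two-variant
  genomes.
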