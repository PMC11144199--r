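---
title: "Models and methods behind stitchpairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stitchpairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, rules and numerical choices implemented
by the package: the preprocessing and pair-extraction procedure, the
generative model of the read simulator, and the evaluation statistics. It is
the reference for *why* each default is what it is; the README shows how to
run things.

## Why stitch reads

A proximity-ligation library molecule is either a plain genomic fragment or
a *chimera*: two loci joined at a ligation junction. A chimeric molecule
shorter than twice the read length is fully covered by its two mates, whose
3' ends are reverse-complementary over the uncovered middle. Merging
("stitching") such mates produces a single-end fragment that contains the
junction in its interior, which a local aligner resolves as two split
segments — one chimeric alignment problem instead of two, on a longer query.
Libraries differ widely in how many molecules are stitchable (MNase-digested
Micro-C libraries with mononucleosomal inserts are at the high end), which
is why the stitch decision is automatic by default.

## Preprocessing

The stage order is fixed: **trim → dedup → stitch**. Input/output counts of
each stage satisfy `input = kept + dropped` and are reported in the run log.

**Trimming.** For each mate the 3' adapter is located as the longest
suffix-anchored match of the adapter prefix: the matched region is a suffix
of the read and a prefix of the adapter, allowing one mismatch per 8 matched
bases; matches shorter than 8 bp (minimum 3 bp, at the extreme 3' end) must
be exact. Defaults are the Illumina TruSeq adapter pair. Trailing cycles
with Phred quality below 20 are then removed. Mates keep their own lengths;
a pair is dropped when either trimmed mate is shorter than 36 bp.

**Duplicate removal.** Two pairs are PCR duplicates when the first 16 bp of
read 1 *and* of read 2 agree; the first occurrence is kept. The key is taken
*after* trimming (the stage order above); reads shorter than 16 bp
contribute their full sequence with an explicit length tag, so prefixes of
different lengths never collide. The operation is idempotent by
construction.

**Stitching.** Candidate overlaps `o` between read 1 and the
reverse-complemented read 2 run from `min(l1, l2)` down to 10 bp; the
candidate minimising the mismatch fraction wins, with ties broken toward the
larger overlap; it is accepted when the fraction is at most 0.1. The overlap
search is exhaustive (no k-mer seeding) — correctness over speed at the
scales this package targets; the inner loops are C++. Each overlap position
takes the base of the higher-quality mate (tie: read 1) and the maximum of
the two qualities. A merged fragment has length `l1 + l2 − o`, strictly less
than `l1 + l2` and at least `max(l1, l2)`.

The 0.1 mismatch ceiling is deliberately stricter than FLASH's published
0.25: at 150 bp cycles a permissive ceiling produces occasional false merges
between unrelated reads, and a false merge corrupts the downstream pair,
whereas a missed merge only moves one molecule to the (still handled)
unstitched path.

**Auto mode.** The first 10,000 post-trim, post-dedup pairs are probed;
stitch mode turns on iff *strictly more than* 10% of them stitch. The
strict inequality is a contract, and tested at the boundary.

## Alignment contract

Alignment is delegated to an external local aligner; the package consumes
SAM text. The contract: split reads appear as supplementary (flag 0x800,
not secondary 0x100) records, and output is name-grouped. The bundled
templates drive `bwa mem` with `-S -P` (no mate rescue, no pairing) so that
mates are scored independently, and with `-k 15 -T 19` so that junction
arms as short as 20 bp — the shortest arm the library model can produce —
are still emitted as split segments instead of being silently soft-clipped.
Lowering the score threshold to 19 admits essentially no spurious records:
a spurious local alignment of that score requires a ~19 bp exact repeat,
which random or high-complexity sequence does not supply. Secondary records
are discarded at parse time; supplementary records are kept. A MAPQ of 255
(STAR's "unavailable" convention for unique alignments) is remapped to 60 so
the MAPQ filter treats both supported aligners alike.

Query intervals are reported on the *original read* coordinate system:
leading/trailing clip lengths are mirrored for minus-strand records, which
makes clip accounting strand-free.

## Classification and outermost-end extraction

Records with MAPQ < 10 are removed first (strict threshold). Records of the
same read and source whose query intervals reciprocally overlap by more than
50% describe the same read region (e.g. an alternative supplementary
placement) and are merged into one region, represented by the higher-MAPQ
record. Then the segment-count whitelist applies:

| source | configuration | category |
|---|---|---|
| stitched | 1 region | `stitched_1seg` (non-chimeric) |
| stitched | 2 regions | `stitched_2seg` (chimeric) |
| unstitched | 1 region per mate | `unstitched_2loci` |
| unstitched | 2 + 1 regions, pairing predicate holds | `unstitched_3rec` |
| anything else | — | rejected |

The three-record pairing predicate declares a split segment and the lone
mate products of the same fragment when they share a chromosome, have
opposite strands, face each other, and the implied outermost-to-outermost
span is at most 1000 bp. The span ceiling has to exceed any plausible
sequenced fragment while staying below genuine short-range contacts; 1 kb
does both, and the package reports which of the two segments paired when
both qualify (the smaller span wins). Groups with more than two loci
(multi-way concatemers) are rejected rather than decomposed into pairwise
contacts — the segment-count whitelist above is the governing rule.

After classification, any source read with more than 50% of its cycles
outside the *union* of its kept query intervals is rejected as overclipped
(union, not sum, so overlapping split alignments are not double-counted;
the boundary is strict: exactly 50% clipped is kept).

**Outermost ends.** Each locus contributes the mapped coordinate of its
query base most distal from the ligation junction:

* the end covering query base 1 reports the segment's 5' mapped coordinate
  with the segment's strand;
* the end covering the last query base reports the segment's 3'-in-read
  coordinate with the strand flipped.

For a one-segment fragment this yields its two fragment ends as
`(ref_start, +) / (ref_end, −)`; for a conventional unstitched pair it
degenerates to each mate's 5' coordinate — i.e. the familiar conventions
fall out of one rule. In the three-record case the reported locus A is the
*free* segment (the one not paired with the lone mate) and locus B is the
lone mate's 5' coordinate, the outermost of the joined fragment by
construction. Finally the two ends are swapped if needed into
upper-triangle order (chromosome rank, then position), strands travelling
with their ends. Short cis pairs are reported (they are informative for
coverage and assembly uses); an optional `minSpan` filter can drop them
post hoc and is off by default.

## The simulator's generative model

The simulator emulates sim3C-style proximity-ligation reads, with the knobs
that matter for exercising this pipeline; it is deliberately *not* a full
re-implementation of sim3C (no spurious-ligation class, no WGS background,
no empirical insert distribution, no indels or quality profiles).

Per molecule, with all variates drawn in a fixed order from the configured
seed (identical configurations give byte-identical outputs):

* **Chimeric?** probability 0.8. Non-chimeric molecules are plain fragments;
  in restriction mode their start is snapped to the nearest cut site, and
  the truth records their two actual ends.
* **Partner locus.** Trans with probability 0.1 (uniform over the other
  chromosomes); otherwise cis at distance `d` with density `∝ d^(−1)`
  truncated to [1 kb, 10 Mb] (inverse-CDF sampling). Both loci snap to the
  nearest restriction cut (ties toward the lower coordinate); MNase mode
  (Micro-C) skips snapping — any position is a legal breakpoint.
* **Insert.** Length `ℓ ~ Normal(300, 50)` truncated (by rejection) to
  `[40, 2·read_length + 400]`; split into two arms uniformly with a 20 bp
  minimum arm, so junctions land at variable read cycles and exercise the
  split-read paths. Arm A runs *into* cut A (either side, reverse
  complemented as needed), arm B runs *out of* cut B; the junction sits
  between them, and the truth records the cut coordinates.
* **Reads.** 150 bp from each end of the insert (read 2
  reverse-complemented; for the rare `ℓ <` read-length draw the read is the
  whole insert), substitution errors at 0.001 per base, constant Q30.
  With probability `duplicateFraction` (default 0) the pair is re-emitted
  under a new read id with the same truth loci.

Chromosomes shorter than the insert ceiling (700 bp at default settings)
are excluded from sampling. Cut-site discovery scans the forward strand
only; MboI's GATC is its own reverse complement, so the scan is exhaustive
for the default enzyme.

**What passing tests do and do not show.** The simulator's uniform-random
genomes are near-uniquely mappable; real genomes add repeats, low MAPQ
regions and reference bias, so the measured ~99.9% accuracy characterises
the *extraction logic*, not mappability on real data. Similarly the error
model is substitution-only, so indel robustness of the trimming/stitching
stages is untested by design.

## Evaluation statistics

* **Accuracy vs truth** (default tolerance **< 500 bp**, strict): a reported
  pair is correct when, under either end assignment, both ends match the
  truth chromosome and position within tolerance. The tolerance absorbs the
  distance between a fragment end and its cut site. Pairs whose read id is
  missing from the truth are binned separately (`n_unmatched`), not counted
  as incorrect; the denominator is the truth-matched pairs. A recall-like
  fraction (truth records recovered within tolerance) is reported alongside,
  and every fraction is printed with its integer numerator/denominator.
* **Concordance** (default **< 200 bp**, strict — different aligners clip
  differently and report slightly different endpoints): two runs joined on
  read id; consistent when chromosome pairs agree and both end distances are
  within tolerance; exclusive counts reported both ways.
* **Stitch yield**: pairs reported per preprocessing class (stitched vs
  unstitched) with the overall stitched fraction.

## Problem sizes and runtime choices

The test suite validates the full pipeline on 50,000 simulated pairs over a
1.5 Mb two-chromosome random genome, and the acceptance script uses 60,000
pairs over 2 Mb — sizes chosen so the whole validation runs on a laptop in
minutes while keeping binomial noise on the accuracy estimate well below
the 0.1% margin of interest. The pairs writer's external-merge sort is
exercised with deliberately small chunk sizes to force multi-way merges and
is required to be byte-identical to an in-memory sort.

## Known limitations

* Multi-way (>2 locus) concatemers are rejected, not decomposed.
* BAM/CRAM input is out of scope; decompress to SAM text externally.
* The duplicate key is sequence-prefix based; alignment-based duplicate
  marking (optical duplicates, UMIs) is not implemented.
* `.hic`/`.cool` files are not written; the juicer short-format export
  exists precisely to hand off to external converters.
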