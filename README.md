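# stitchpairs

An upstream pipeline for 3D-genomics sequencing data (Hi-C, Micro-C and
derivative proximity-ligation protocols): it turns raw paired-end FASTQ into
a sorted, header-complete [4DN pairs](https://github.com/4dn-dcic/pairix/blob/master/pairs_format_specification.md)
file of chromatin contacts, and ships a read simulator plus the evaluation
statistics needed to validate every stage without external data.

It is aimed at people who build or benchmark Hi-C/Micro-C processing
pipelines and want a self-contained, testable implementation of the
*read-stitching* upstream strategy.

## The method

Modern sequencers read 150 bp per mate while Micro-C (MNase) libraries have
short inserts, so for a large share of molecules the two mates overlap. The
pipeline exploits this:

1. **Preprocess** (streamed, fixed order trim → dedup → stitch):
   - adapter and 3' quality trimming (suffix-anchored adapter match, one
     mismatch allowed per 8 matched bases);
   - PCR-duplicate removal on the dual 16 bp sequence prefix key
     (read 1 prefix + read 2 prefix, first occurrence kept);
   - FLASH-style stitching: the overlap *o* between read 1 and the reverse
     complement of read 2 is chosen to minimise the mismatch fraction over
     `o ∈ [min(l1,l2), 10]`, accepted when ≤ 0.1, merging the pair into one
     single-end fragment of length `l1 + l2 − o`. In `auto` mode the first
     10,000 pairs are probed and stitching is enabled iff > 10% of them
     stitch.
2. **Align** with any SAM-emitting local aligner that reports split reads as
   supplementary records (bundled templates drive `bwa mem` with pairing
   heuristics disabled).
3. **Classify and extract.** Alignment records with MAPQ < 10 are removed;
   a stitched fragment is kept when it maps to one (non-chimeric) or two
   (chimeric) regions; an unstitched pair is kept when each mate maps to one
   region, or when one mate splits in two segments one of which pairs
   face-to-face with the other mate within 1 kb (three-record case). Reads
   with more than 50% of their cycles clipped across all kept records are
   discarded. The two **outermost ends** — the junction-distal mapped
   coordinates of the two loci — are reported as the contact pair.
4. **Write pairs**: upper-triangle order (chromosome rank, then position),
   sorted with a bounded-memory external merge, with `#chromsize` header
   lines following the reference order. A juicer short-format writer is
   included for `.hic` conversion.

The package also implements a **proximity-ligation simulator** (restriction
mode with cut-site snapping, e.g. MboI `GATC`, or MNase mode where any
position can break): each molecule is chimeric with probability 0.8, trans
with probability 0.1, cis distances follow a truncated `d^-1` decay, insert
lengths are truncated-normal (default 300 ± 50 bp), and the ligation
coordinates of every molecule are recorded as truth. `accuracyVsTruth()`
scores reported pairs at the standard < 500 bp tolerance,
`concordance()` compares two runs at < 200 bp.

## Worked example

```r
library(stitchpairs)
dir <- tempfile("example"); dir.create(dir)
genome <- randomGenome(c(chr1 = 600000, chr2 = 400000), seed = 1)
ref <- file.path(dir, "ref.fa")
Biostrings::writeXStringSet(genome, ref)

sim <- simulateDataset(genome, SimConfig(nPairs = 5000, seed = 2),
                       outPrefix = file.path(dir, "sim"))
run <- runPipeline(sim$fq1, sim$fq2, ref, file.path(dir, "run"))

run$prep$counts
#>      input  too_short  duplicate   stitched unstitched
#>       5000          0          0       2087       2913

run$pairs
#> ContactPairs with 5000 pairs on 2 chromosomes
#>   cis 4587 (91.7%), trans 413
#>   categories: stitched_1seg=447, stitched_2seg=1640, unstitched_2loci=1096, unstitched_3rec=1817
#>       readID chr1   pos1 chr2   pos2 strand1 strand2      category
#> 1 SIM0000005 chr1 560552 chr1 560749       +       - stitched_1seg
#> ...

accuracyVsTruth(run$pairs, sim$truth, tol = 500)
#> Accuracy vs truth (tol < 500 bp):
#>   4998 / 5000 reported pairs correct (accuracy 0.9996)
#>   recall-like: 0.9996 of 5000 truth records; 0 unmatched pairs
```

Reading the output: 2087 of 5000 pairs overlapped enough to be stitched into
single-end fragments (the probe therefore switched stitching on); every
input molecule yielded a contact pair; and 99.96% of the reported pairs
place both ends within 500 bp of the simulated ligation coordinates.
`run$pairsFile` points at the sorted `.pairs.gz` output.

A command-line wrapper with `simulate`, `preprocess`, `run`, `evaluate` and
`concordance` subcommands is installed at
`system.file("scripts/stitchpairs", package = "stitchpairs")`.

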