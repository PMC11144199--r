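Package: stitchpairs
Title: Read Stitching and Contact-Pair Extraction for Hi-C and Micro-C Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An upstream pipeline for proximity-ligation (Hi-C, Micro-C and
    derivative protocols) sequencing data. Implements streaming FASTQ
    preprocessing (adapter and quality trimming, PCR-duplicate removal by
    dual 16 bp sequence prefix, FLASH-style overlap merging of paired-end
    reads into single-end fragments with an automatic stitch-mode decision),
    ingestion of split-read alignments from any SAM-emitting local aligner,
    chimeric-alignment classification and filtering (mapping-quality,
    segment-count and clip-fraction rules), extraction of the outermost
    fragment ends into sorted 4DN pairs format, a restriction/MNase
    proximity-ligation read simulator with ligation-junction truth records,
    and the accuracy and concordance statistics used to evaluate such
    pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    Biostrings,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: bwa (or any SAM-emitting local aligner) for the
    alignment step of the full pipeline
Config/testthat/edition: 3
RoxygenNote: 7.3.3
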