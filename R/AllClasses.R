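#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib stitchpairs, .registration = TRUE
NULL

## Default Illumina TruSeq adapter read-through sequences (as seen at the 3'
## end of read 1 and read 2, respectively).
TRUSEQ_ADAPTERS <- c("AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                     "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT")

#' Simulation configuration
#'
#' Parameters of the proximity-ligation read simulator. `mode = "restriction"`
#' emulates a Hi-C library produced with a restriction enzyme (loci snapped to
#' enzyme cut sites); `mode = "mnase"` emulates a Micro-C library where MNase
#' digestion makes every position a legal breakpoint.
#'
#' @slot mode `"restriction"` or `"mnase"`.
#' @slot enzymeSite recognition sequence, e.g. `"GATC"` for MboI.
#' @slot readLength sequencing read length in bp.
#' @slot insertMean,insertSd mean and standard deviation of the (truncated
#'   normal) insert-size distribution, bp.
#' @slot nPairs number of read-pair molecules to simulate.
#' @slot junctionFraction probability that a molecule carries a ligation
#'   junction (is chimeric).
#' @slot transFraction probability that a chimeric contact is
#'   inter-chromosomal.
#' @slot cisDecayExponent exponent of the d^(-a) cis contact-distance decay.
#' @slot cisRange minimum and maximum cis contact distance, bp.
#' @slot errorRate per-base substitution error probability.
#' @slot baseQuality constant Phred quality assigned to every base.
#' @slot duplicateFraction probability a finished pair is re-emitted as a PCR
#'   duplicate under a new read id.
#' @slot seed integer seed; identical configurations give byte-identical
#'   output files.
#' @export
setClass("SimConfig", representation(
    mode = "character", enzymeSite = "character",
    readLength = "integer", insertMean = "numeric", insertSd = "numeric",
    nPairs = "integer", junctionFraction = "numeric",
    transFraction = "numeric", cisDecayExponent = "numeric",
    cisRange = "numeric", errorRate = "numeric", baseQuality = "integer",
    duplicateFraction = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (!object@mode %in% c("restriction", "mnase"))
        msg <- c(msg, "mode must be 'restriction' or 'mnase'")
    probs <- c(object@junctionFraction, object@transFraction,
               object@errorRate, object@duplicateFraction)
    if (any(probs < 0 | probs > 1))
        msg <- c(msg, "all probabilities must lie in [0, 1]")
    if (object@insertMean <= 0) msg <- c(msg, "insertMean must be > 0")
    if (object@readLength <= 0) msg <- c(msg, "readLength must be > 0")
    if (length(object@cisRange) != 2L || object@cisRange[1] >= object@cisRange[2])
        msg <- c(msg, "cisRange must be (min, max) with min < max")
    if (object@mode == "restriction" &&
        (nchar(object@enzymeSite) == 0L ||
         grepl("[^ACGT]", object@enzymeSite)))
        msg <- c(msg, "enzymeSite must be a non-empty A/C/G/T string")
    if (length(msg)) msg else TRUE
})

#' @param mode,enzymeSite,readLength,insertMean,insertSd,nPairs,junctionFraction,transFraction,cisDecayExponent,cisRange,errorRate,baseQuality,duplicateFraction,seed
#'   see the corresponding slots.
#' @return `SimConfig()` returns a validated \linkS4class{SimConfig} object.
#' @examples
#' SimConfig(nPairs = 1000, seed = 1)
#' @rdname SimConfig-class
#' @export
SimConfig <- function(mode = c("restriction", "mnase"), enzymeSite = "GATC",
                      readLength = 150L, insertMean = 300, insertSd = 50,
                      nPairs = 10000L, junctionFraction = 0.8,
                      transFraction = 0.1, cisDecayExponent = 1.0,
                      cisRange = c(1000, 10000000), errorRate = 0.001,
                      baseQuality = 30L, duplicateFraction = 0,
                      seed = 1L) {
    mode <- match.arg(mode)
    new("SimConfig", mode = mode, enzymeSite = enzymeSite,
        readLength = as.integer(readLength), insertMean = insertMean,
        insertSd = insertSd, nPairs = as.integer(nPairs),
        junctionFraction = junctionFraction, transFraction = transFraction,
        cisDecayExponent = cisDecayExponent, cisRange = as.numeric(cisRange),
        errorRate = errorRate, baseQuality = as.integer(baseQuality),
        duplicateFraction = duplicateFraction, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@mode,
        if (object@mode == "restriction") sprintf("(site %s)", object@enzymeSite)
        else "(no site snapping)", "\n")
    cat(sprintf("  %d pairs, PE%d, insert %g +/- %g bp, junction %.2f, trans %.2f\n",
                object@nPairs, object@readLength, object@insertMean,
                object@insertSd, object@junctionFraction, object@transFraction))
    cat(sprintf("  error %.4g, Q%d, dup %.2f, seed %d\n", object@errorRate,
                object@baseQuality, object@duplicateFraction, object@seed))
})

#' Preprocessing configuration
#'
#' Parameters of the trim / dedup / stitch preprocessing stages.
#'
#' @slot adapters length-2 character: 3' adapter of read 1 and read 2
#'   (defaults: Illumina TruSeq).
#' @slot qualityFloor Phred score below which trailing cycles are trimmed.
#' @slot minReadLen pairs with either trimmed mate shorter than this are
#'   dropped.
#' @slot dedupPrefixLen length of the per-mate sequence prefix forming the
#'   PCR-duplicate key.
#' @slot stitchMinOverlap minimum mate overlap considered for stitching, bp.
#' @slot stitchMaxMismatchFrac maximum mismatch fraction accepted in the
#'   overlap.
#' @slot stitchMode `"auto"`, `"on"` or `"off"`.
#' @slot autoProbeReads number of leading pairs probed in auto mode.
#' @slot autoThreshold stitched fraction strictly above which auto mode turns
#'   stitching on.
#' @export
setClass("PreprocessConfig", representation(
    adapters = "character", qualityFloor = "integer", minReadLen = "integer",
    dedupPrefixLen = "integer", stitchMinOverlap = "integer",
    stitchMaxMismatchFrac = "numeric", stitchMode = "character",
    autoProbeReads = "integer", autoThreshold = "numeric"))

setValidity("PreprocessConfig", function(object) {
    msg <- character()
    lens <- c(object@qualityFloor, object@minReadLen, object@dedupPrefixLen,
              object@stitchMinOverlap, object@autoProbeReads)
    if (any(lens <= 0)) msg <- c(msg, "all lengths/counts must be positive")
    if (object@stitchMaxMismatchFrac < 0 || object@stitchMaxMismatchFrac > 1 ||
        object@autoThreshold < 0 || object@autoThreshold > 1)
        msg <- c(msg, "fractions must lie in [0, 1]")
    if (!object@stitchMode %in% c("auto", "on", "off"))
        msg <- c(msg, "stitchMode must be 'auto', 'on' or 'off'")
    if (length(object@adapters) != 2L)
        msg <- c(msg, "adapters must have length 2")
    if (length(msg)) msg else TRUE
})

#' @param adapters,qualityFloor,minReadLen,dedupPrefixLen,stitchMinOverlap,stitchMaxMismatchFrac,stitchMode,autoProbeReads,autoThreshold
#'   see the corresponding slots.
#' @return `PreprocessConfig()` returns a validated
#'   \linkS4class{PreprocessConfig} object.
#' @examples
#' PreprocessConfig(stitchMode = "on")
#' @rdname PreprocessConfig-class
#' @export
PreprocessConfig <- function(adapters = TRUSEQ_ADAPTERS, qualityFloor = 20L,
                             minReadLen = 36L, dedupPrefixLen = 16L,
                             stitchMinOverlap = 10L,
                             stitchMaxMismatchFrac = 0.1,
                             stitchMode = c("auto", "on", "off"),
                             autoProbeReads = 10000L, autoThreshold = 0.10) {
    stitchMode <- match.arg(stitchMode)
    new("PreprocessConfig", adapters = adapters,
        qualityFloor = as.integer(qualityFloor),
        minReadLen = as.integer(minReadLen),
        dedupPrefixLen = as.integer(dedupPrefixLen),
        stitchMinOverlap = as.integer(stitchMinOverlap),
        stitchMaxMismatchFrac = stitchMaxMismatchFrac,
        stitchMode = stitchMode, autoProbeReads = as.integer(autoProbeReads),
        autoThreshold = autoThreshold)
}

setMethod("show", "PreprocessConfig", function(object) {
    cat("PreprocessConfig: stitch", object@stitchMode, "\n")
    cat(sprintf("  Q floor %d, min len %d, dedup prefix %d bp\n",
                object@qualityFloor, object@minReadLen, object@dedupPrefixLen))
    cat(sprintf("  overlap >= %d bp, mismatch <= %.2f, probe %d (> %.0f%% => on)\n",
                object@stitchMinOverlap, object@stitchMaxMismatchFrac,
                object@autoProbeReads, 100 * object@autoThreshold))
})

#' Pair-extraction configuration
#'
#' Parameters of the alignment filtering and pair-inference rules.
#'
#' @slot minMapq records with mapping quality strictly below this are removed.
#' @slot maxClipFrac reads with a clipped cycle fraction strictly above this
#'   are rejected.
#' @slot mateJoinMaxSpan maximum implied fragment span (bp) for declaring a
#'   split segment and the opposite mate products of the same fragment.
#' @slot minSpan optional post-hoc filter: cis pairs spanning fewer bp are
#'   dropped (0 = keep everything, the default).
#' @export
setClass("ExtractConfig", representation(
    minMapq = "integer", maxClipFrac = "numeric",
    mateJoinMaxSpan = "integer", minSpan = "integer"))

setValidity("ExtractConfig", function(object) {
    msg <- character()
    if (object@minMapq < 0) msg <- c(msg, "minMapq must be >= 0")
    if (object@maxClipFrac < 0 || object@maxClipFrac > 1)
        msg <- c(msg, "maxClipFrac must lie in [0, 1]")
    if (object@mateJoinMaxSpan <= 0) msg <- c(msg, "mateJoinMaxSpan must be > 0")
    if (object@minSpan < 0) msg <- c(msg, "minSpan must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @param minMapq,maxClipFrac,mateJoinMaxSpan,minSpan see the corresponding
#'   slots.
#' @return `ExtractConfig()` returns a validated \linkS4class{ExtractConfig}
#'   object.
#' @examples
#' ExtractConfig()
#' @rdname ExtractConfig-class
#' @export
ExtractConfig <- function(minMapq = 10L, maxClipFrac = 0.5,
                          mateJoinMaxSpan = 1000L, minSpan = 0L) {
    new("ExtractConfig", minMapq = as.integer(minMapq),
        maxClipFrac = maxClipFrac, mateJoinMaxSpan = as.integer(mateJoinMaxSpan),
        minSpan = as.integer(minSpan))
}

setMethod("show", "ExtractConfig", function(object) {
    cat(sprintf("ExtractConfig: MAPQ >= %d, clip <= %.2f, mate-join span <= %d bp",
                object@minMapq, object@maxClipFrac, object@mateJoinMaxSpan))
    if (object@minSpan > 0) cat(sprintf(", min span %d bp", object@minSpan))
    cat("\n")
})

#' Chromosome order
#'
#' The ordered chromosome table that defines genome-wide coordinate ranking
#' (and hence upper-triangle order of contact pairs). The order follows the
#' chrom-sizes table / reference FASTA, not lexicographic sorting, matching
#' aligner-index order.
#'
#' @slot seqnames chromosome names, in rank order.
#' @slot seqlengths chromosome lengths in bp, parallel to `seqnames`.
#' @export
setClass("ChromOrder",
         representation(seqnames = "character", seqlengths = "numeric"))

setValidity("ChromOrder", function(object) {
    msg <- character()
    if (length(object@seqnames) != length(object@seqlengths))
        msg <- c(msg, "seqnames and seqlengths must be parallel")
    if (anyDuplicated(object@seqnames))
        msg <- c(msg, "chromosome names must be unique")
    if (length(object@seqlengths) && any(object@seqlengths <= 0))
        msg <- c(msg, "chromosome lengths must be positive")
    if (length(msg)) msg else TRUE
})

#' @param seqnames,seqlengths chromosome names and lengths (named numeric also
#'   accepted as `seqlengths` with `seqnames` missing).
#' @return `ChromOrder()` returns a \linkS4class{ChromOrder} object.
#' @examples
#' co <- ChromOrder(c("chr1", "chr2"), c(1e6, 5e5))
#' chromRank(co, c("chr2", "chr1"))
#' @rdname ChromOrder-class
#' @export
ChromOrder <- function(seqnames, seqlengths) {
    if (missing(seqnames) && !is.null(names(seqlengths))) {
        seqnames <- names(seqlengths)
        seqlengths <- unname(seqlengths)
    }
    new("ChromOrder", seqnames = as.character(seqnames),
        seqlengths = as.numeric(seqlengths))
}

setMethod("show", "ChromOrder", function(object) {
    cat("ChromOrder with", length(object@seqnames), "chromosomes\n")
    n <- min(length(object@seqnames), 5L)
    for (i in seq_len(n))
        cat(sprintf("  %d. %s (%s bp)\n", i - 1L, object@seqnames[i],
                    format(object@seqlengths[i], big.mark = ",")))
    if (length(object@seqnames) > n) cat("  ...\n")
})

setMethod("length", "ChromOrder", function(x) length(x@seqnames))

#' @describeIn ChromOrder-class 0-based rank of chromosomes under the genome
#'   order (`NA` for unknown names).
#' @param x a `ChromOrder`.
#' @param chrom character vector of chromosome names.
#' @export
chromRank <- function(x, chrom) match(chrom, x@seqnames) - 1L

#' @describeIn ChromOrder-class chromosome names, in order.
#' @export
seqNames <- function(x) x@seqnames

#' @describeIn ChromOrder-class named vector of chromosome lengths.
#' @export
seqLengths <- function(x) stats::setNames(x@seqlengths, x@seqnames)

#' Contact pairs
#'
#' The extracted two-ended contacts of one run, in upper-triangle order:
#' end 1 precedes end 2 under chromosome rank then position. Backed by a
#' data.frame with columns `readID`, `chr1`, `pos1`, `chr2`, `pos2`,
#' `strand1`, `strand2` and (optionally recorded) `category`.
#'
#' @slot pairs the pair table (one row per contact).
#' @slot chromOrder the \linkS4class{ChromOrder} authority used for ranking.
#' @export
setClass("ContactPairs",
         representation(pairs = "data.frame", chromOrder = "ChromOrder"))

setValidity("ContactPairs", function(object) {
    need <- c("readID", "chr1", "pos1", "chr2", "pos2", "strand1", "strand2")
    p <- object@pairs
    if (!all(need %in% names(p)))
        return(paste("pair table must have columns:", paste(need, collapse = " ")))
    if (!nrow(p)) return(TRUE)
    msg <- character()
    r1 <- chromRank(object@chromOrder, p$chr1)
    r2 <- chromRank(object@chromOrder, p$chr2)
    if (anyNA(r1) || anyNA(r2))
        msg <- c(msg, "all pair chromosomes must appear in the chromOrder")
    else {
        if (any(r1 > r2 | (r1 == r2 & p$pos1 > p$pos2)))
            msg <- c(msg, "pairs must be in upper-triangle order")
        len <- seqLengths(object@chromOrder)
        if (any(p$pos1 < 1 | p$pos2 < 1 | p$pos1 > len[p$chr1] |
                p$pos2 > len[p$chr2]))
            msg <- c(msg, "positions must lie within chromosome bounds")
    }
    if (!all(c(p$strand1, p$strand2) %in% c("+", "-")))
        msg <- c(msg, "strands must be '+' or '-'")
    if (length(msg)) msg else TRUE
})

#' @param pairs a data.frame of pair rows (see slots).
#' @param chromOrder a \linkS4class{ChromOrder}.
#' @return `ContactPairs()` returns a validated \linkS4class{ContactPairs}.
#' @rdname ContactPairs-class
#' @export
ContactPairs <- function(pairs, chromOrder) {
    pairs <- as.data.frame(pairs)
    rownames(pairs) <- NULL
    new("ContactPairs", pairs = pairs, chromOrder = chromOrder)
}

setMethod("show", "ContactPairs", function(object) {
    p <- object@pairs
    cat("ContactPairs with", nrow(p), "pairs on",
        length(object@chromOrder), "chromosomes\n")
    if (nrow(p)) {
        cis <- sum(p$chr1 == p$chr2)
        cat(sprintf("  cis %d (%.1f%%), trans %d\n", cis, 100 * cis / nrow(p),
                    nrow(p) - cis))
        if ("category" %in% names(p) && !all(is.na(p$category))) {
            tab <- table(p$category)
            cat("  categories:",
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
        }
        print(utils::head(p, 3L))
        if (nrow(p) > 3L) cat("  ...", nrow(p) - 3L, "more rows\n")
    }
})

setMethod("length", "ContactPairs", function(x) nrow(x@pairs))

#' @describeIn ContactPairs-class the pair table as a data.frame.
#' @param x a `ContactPairs`.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "ContactPairs",
          function(x, ...) x@pairs)

#' @describeIn ContactPairs-class the chromosome order used for ranking.
#' @export
chromOrder <- function(x) x@chromOrder
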