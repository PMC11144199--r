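## FASTQ preprocessing: adapter/quality trimming, prefix-based PCR-duplicate
## removal, FLASH-style read stitching, and the automatic stitch-mode probe.
## Fixed stage order: trim -> dedup -> stitch.

#' Trim adapters and low-quality 3' cycles
#'
#' For each mate the 3' adapter is located as the longest suffix-anchored
#' match of the adapter prefix (at most one mismatch per 8 matched bases;
#' matches under 8 bp, minimum 3 bp at the extreme 3' end, must be exact) and
#' removed; trailing cycles with quality below `qualityFloor` are then
#' clipped. Mates keep their own lengths. Pairs with either trimmed mate
#' shorter than `minReadLen` are dropped with reason `too_short`.
#'
#' @param pairs data.frame with columns `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`.
#' @param config a \linkS4class{PreprocessConfig}.
#' @return list with `pairs` (the surviving trimmed pairs) and `dropped`
#'   (data.frame of dropped ids with `reason`).
#' @export
trimReadPairs <- function(pairs, config = PreprocessConfig()) {
    stopifnot(all(c("id", "seq1", "qual1", "seq2", "qual2") %in% names(pairs)))
    if (!nrow(pairs))
        return(list(pairs = pairs,
                    dropped = data.frame(id = character(),
                                         reason = character())))
    t1 <- .trim_reads_cpp(pairs$seq1, pairs$qual1, config@adapters[1],
                          config@qualityFloor)
    t2 <- .trim_reads_cpp(pairs$seq2, pairs$qual2, config@adapters[2],
                          config@qualityFloor)
    out <- data.frame(id = pairs$id, seq1 = t1$seq, qual1 = t1$qual,
                      seq2 = t2$seq, qual2 = t2$qual)
    keep <- nchar(out$seq1) >= config@minReadLen &
        nchar(out$seq2) >= config@minReadLen
    list(pairs = out[keep, , drop = FALSE],
         dropped = data.frame(id = out$id[!keep],
                              reason = rep("too_short", sum(!keep))))
}

#' Remove PCR duplicates by dual sequence prefix
#'
#' Pairs whose first `dedupPrefixLen` bases of read 1 *and* of read 2 both
#' match an earlier pair are dropped as PCR duplicates; the first occurrence
#' is kept and order is otherwise preserved. Reads shorter than the prefix
#' contribute their full sequence, with an explicit length tag in the key so
#' that prefixes of different lengths never collide.
#'
#' @inheritParams trimReadPairs
#' @return list with `pairs` (duplicates removed) and `dropped`.
#' @export
dedupReadPairs <- function(pairs, config = PreprocessConfig()) {
    k <- config@dedupPrefixLen
    p1 <- substr(pairs$seq1, 1L, k)
    p2 <- substr(pairs$seq2, 1L, k)
    key <- paste0(nchar(p1), ":", p1, "|", nchar(p2), ":", p2)
    dupe <- duplicated(key)
    list(pairs = pairs[!dupe, , drop = FALSE],
         dropped = data.frame(id = pairs$id[dupe],
                              reason = rep("duplicate", sum(dupe))))
}

#' Stitch overlapping mate pairs into single-end fragments
#'
#' Compares the 3' end of read 1 with the reverse complement of read 2 over
#' every overlap length from `min(len1, len2)` down to `stitchMinOverlap`,
#' picks the overlap minimising the mismatch fraction (ties broken by the
#' larger overlap), and accepts it when the fraction is at most
#' `stitchMaxMismatchFrac`. Overlap bases take the higher-quality mate's base
#' (tie: read 1) and the maximum quality.
#'
#' @inheritParams trimReadPairs
#' @return data.frame with one row per input pair: `id`, `stitched` (logical),
#'   and for stitched pairs `seq`/`qual` of the merged fragment (NA
#'   otherwise), plus the surviving `seq1/qual1/seq2/qual2`.
#' @export
stitchReadPairs <- function(pairs, config = PreprocessConfig()) {
    if (!nrow(pairs))
        return(data.frame(id = character(), stitched = logical(),
                          seq = character(), qual = character(),
                          seq1 = character(), qual1 = character(),
                          seq2 = character(), qual2 = character()))
    st <- .stitch_reads_cpp(pairs$seq1, pairs$qual1, revComp(pairs$seq2),
                            revString(pairs$qual2), config@stitchMinOverlap,
                            config@stitchMaxMismatchFrac)
    data.frame(id = pairs$id, stitched = st$overlap > 0L,
               seq = st$seq, qual = st$qual,
               seq1 = pairs$seq1, qual1 = pairs$qual1,
               seq2 = pairs$seq2, qual2 = pairs$qual2)
}

#' Decide the stitch mode from a leading probe
#'
#' Runs the stitcher on the first `autoProbeReads` (post-trim, post-dedup)
#' pairs and returns `"on"` iff strictly more than `autoThreshold` of them
#' stitch. Manual modes bypass the probe.
#'
#' @inheritParams trimReadPairs
#' @return `"on"` or `"off"`.
#' @export
decideStitchMode <- function(pairs, config = PreprocessConfig()) {
    if (config@stitchMode != "auto") return(config@stitchMode)
    if (!nrow(pairs)) {
        warning("empty input: stitch mode set to 'off'")
        return("off")
    }
    probe <- pairs[seq_len(min(config@autoProbeReads, nrow(pairs))), ,
                   drop = FALSE]
    frac <- mean(stitchReadPairs(probe, config)$stitched)
    if (frac > config@autoThreshold) "on" else "off"
}

#' Run the full preprocessing stage
#'
#' Reads one or more FASTQ pairs (multiple pairs are concatenated before
#' duplicate removal: the "biological replicates" mode), applies
#' trim -> dedup -> stitch, and writes the stitched fragments and surviving
#' unstitched pairs to separate FASTQ streams for the aligner.
#'
#' @param fq1,fq2 character vectors of mate-1 / mate-2 FASTQ paths (parallel;
#'   more than one pair activates replicates mode).
#' @param outPrefix when non-NULL, writes `<outPrefix>.stitched.fq.gz`,
#'   `<outPrefix>.unstitched_1.fq.gz`, `<outPrefix>.unstitched_2.fq.gz`, a
#'   per-read class table `<outPrefix>.readclass.tsv.gz` and a JSON run log
#'   `<outPrefix>.preprocess.json`.
#' @param config a \linkS4class{PreprocessConfig}.
#' @return list with `stitched` (FASTQ table), `unstitched` (pair table),
#'   `readClass` (data.frame `id`, `class`), `stitchMode` (the decision),
#'   `counts` (named integer run log: input, too_short, duplicate, stitched,
#'   unstitched) and any output paths.
#' @export
preprocessFastq <- function(fq1, fq2, outPrefix = NULL,
                            config = PreprocessConfig()) {
    stopifnot(length(fq1) == length(fq2), length(fq1) >= 1L)
    r1 <- do.call(rbind, lapply(fq1, readFastq))
    r2 <- do.call(rbind, lapply(fq2, readFastq))
    if (nrow(r1) != nrow(r2) || any(r1$id != r2$id))
        stop("mate FASTQ files disagree on read ids")
    pairs <- data.frame(id = r1$id, seq1 = r1$seq, qual1 = r1$qual,
                        seq2 = r2$seq, qual2 = r2$qual)
    nIn <- nrow(pairs)

    tr <- trimReadPairs(pairs, config)
    dd <- dedupReadPairs(tr$pairs, config)
    kept <- dd$pairs

    mode <- decideStitchMode(kept, config)
    if (mode == "on" && nrow(kept)) {
        st <- stitchReadPairs(kept, config)
    } else {
        st <- data.frame(id = kept$id,
                         stitched = rep(FALSE, nrow(kept)),
                         seq = rep(NA_character_, nrow(kept)),
                         qual = rep(NA_character_, nrow(kept)),
                         seq1 = kept$seq1, qual1 = kept$qual1,
                         seq2 = kept$seq2, qual2 = kept$qual2)
    }
    stitched <- data.frame(id = st$id[st$stitched], seq = st$seq[st$stitched],
                           qual = st$qual[st$stitched])
    un <- st[!st$stitched, c("id", "seq1", "qual1", "seq2", "qual2"),
             drop = FALSE]
    counts <- c(input = nIn, too_short = nrow(tr$dropped),
                duplicate = nrow(dd$dropped), stitched = nrow(stitched),
                unstitched = nrow(un))
    stopifnot(counts["input"] == sum(counts[-1]))
    readClass <- data.frame(id = st$id,
                            class = ifelse(st$stitched, "stitched",
                                           "unstitched"))

    res <- list(stitched = stitched, unstitched = un, readClass = readClass,
                stitchMode = mode, counts = counts)
    if (!is.null(outPrefix)) {
        res$stitchedFq <- writeFastq(stitched,
                                     paste0(outPrefix, ".stitched.fq.gz"))
        res$unstitchedFq1 <- writeFastq(
            data.frame(id = un$id, seq = un$seq1, qual = un$qual1),
            paste0(outPrefix, ".unstitched_1.fq.gz"))
        res$unstitchedFq2 <- writeFastq(
            data.frame(id = un$id, seq = un$seq2, qual = un$qual2),
            paste0(outPrefix, ".unstitched_2.fq.gz"))
        res$readClassFile <- paste0(outPrefix, ".readclass.tsv.gz")
        con <- gzfile(res$readClassFile, "wb")
        utils::write.table(readClass, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        close(con)
        res$logFile <- paste0(outPrefix, ".preprocess.json")
        jsonlite::write_json(c(as.list(counts), list(stitch_mode = mode)),
                             res$logFile, auto_unbox = TRUE, pretty = TRUE)
    }
    res
}
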