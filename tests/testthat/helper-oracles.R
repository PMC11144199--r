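## Independent oracles and fixture builders shared across test files.

## naive substring scan: every start i with genome[i..i+k-1] == site
naiveSiteScan <- function(seqchar, site) {
    k <- nchar(site)
    hits <- integer()
    for (i in seq_len(nchar(seqchar) - k + 1L))
        if (substr(seqchar, i, i + k - 1L) == site) hits <- c(hits, i)
    hits
}

## independent CIGAR replay: walk the ops one by one
replayCigar <- function(cigar, pos, minus) {
    toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
    len <- as.integer(sub("[A-Z=]", "", toks))
    op <- sub("\\d+", "", toks)
    ref <- pos - 1L
    aligned <- 0L
    lead <- 0L
    trail <- 0L
    seen_aln <- FALSE
    for (j in seq_along(op)) {
        if (op[j] %in% c("M", "=", "X")) {
            ref <- ref + len[j]; aligned <- aligned + len[j]; seen_aln <- TRUE
        } else if (op[j] %in% c("D", "N")) {
            ref <- ref + len[j]
        } else if (op[j] == "I") {
            aligned <- aligned + len[j]; seen_aln <- TRUE
        } else if (op[j] %in% c("S", "H")) {
            if (seen_aln) trail <- trail + len[j] else lead <- lead + len[j]
        }
    }
    if (minus) { tmp <- lead; lead <- trail; trail <- tmp }
    list(ref_end = ref, query_start = lead + 1L,
         query_end = lead + aligned, clipped = lead + trail,
         read_len = lead + aligned + trail)
}

## one SAM body line (only the first six fields matter downstream)
samLine <- function(qname, flag, rname, pos, mapq, cigar) {
    paste(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, "*", "*",
          sep = "\t")
}

## an alignment-record row in readSam() layout
makeRec <- function(read_id, source, chrom, ref_start, ref_end, strand,
                    mapq = 60L, query_start = 1L, query_end = 150L,
                    read_len = 150L) {
    data.frame(read_id = read_id, source = source, chrom = chrom,
               ref_start = ref_start, ref_end = ref_end, strand = strand,
               mapq = mapq, query_start = query_start,
               query_end = query_end,
               clipped = read_len - (query_end - query_start + 1L),
               read_len = read_len, supplementary = FALSE)
}

## brute-force re-implementation of the filtering/classification rules,
## with the clip union computed by literal position enumeration
oracleClassify <- function(recs, minMapq = 10L, maxClipFrac = 0.5,
                           maxSpan = 1000L) {
    kept <- recs[recs$mapq >= minMapq, , drop = FALSE]
    if (any(recs$source == "stitched")) {
        n <- nrow(kept)
        cat <- if (n == 1L) "stitched_1seg"
               else if (n == 2L) "stitched_2seg" else NA_character_
    } else {
        n1 <- sum(kept$source == "mate1")
        n2 <- sum(kept$source == "mate2")
        if (n1 == 1L && n2 == 1L) {
            cat <- "unstitched_2loci"
        } else if ((n1 == 2L && n2 == 1L) || (n1 == 1L && n2 == 2L)) {
            segs <- kept[kept$source == ifelse(n1 == 2L, "mate1", "mate2"), ]
            lone <- kept[kept$source == ifelse(n1 == 2L, "mate2", "mate1"), ]
            ok <- FALSE
            for (i in 1:2) {
                s <- segs[i, ]
                if (s$chrom == lone$chrom && s$strand != lone$strand) {
                    plus <- if (s$strand == "+") s else lone
                    minus <- if (s$strand == "+") lone else s
                    if (plus$ref_start <= minus$ref_end &&
                        minus$ref_end - plus$ref_start + 1 <= maxSpan)
                        ok <- TRUE
                }
            }
            cat <- if (ok) "unstitched_3rec" else NA_character_
        } else cat <- NA_character_
    }
    if (!is.na(cat)) {
        for (src in unique(recs$source)) {
            rr <- kept[kept$source == src, , drop = FALSE]
            len <- recs$read_len[recs$source == src][1]
            covered <- rep(FALSE, len)
            for (j in seq_len(nrow(rr)))
                covered[rr$query_start[j]:rr$query_end[j]] <- TRUE
            if ((len - sum(covered)) / len > maxClipFrac)
                return(NA_character_)
        }
    }
    cat
}

## write a pair of FASTQ files from parallel read tables, return paths
## (under tempdir(), removed with the session)
writeFastqPair <- function(reads1, reads2) {
    dir <- tempfile("fqpair")
    dir.create(dir)
    list(fq1 = writeFastq(reads1, file.path(dir, "r1.fq.gz")),
         fq2 = writeFastq(reads2, file.path(dir, "r2.fq.gz")))
}

## random DNA as a plain string
randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

Q30 <- function(n) strrep("?", n)  # '?' is Phred 30
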