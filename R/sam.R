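## SAM ingestion: decompose aligner output into per-read genomic segments
## with query-interval and clip accounting. The aligner contract is any
## SAM-emitting local aligner that reports split reads as supplementary
## (0x800, not secondary 0x100) records and emits name-grouped output.

#' @importFrom data.table data.table := setorder rbindlist fread as.data.table
NULL

## parse CIGAR strings into reference/query consumption and clip lengths
parseCigars <- function(cigars) {
    toks <- regmatches(cigars, gregexpr("\\d+[MIDNSHP=X]", cigars))
    bad <- which(vapply(toks, function(t) sum(nchar(t)), 0) != nchar(cigars) |
                 nchar(cigars) == 0L)
    if (length(bad))
        stop("malformed CIGAR at alignment line ", bad[1], ": ",
             cigars[bad[1]])
    n <- length(cigars)
    refc <- aligned <- lead <- trail <- integer(n)
    for (i in seq_len(n)) {
        t <- toks[[i]]
        len <- as.integer(substr(t, 1L, nchar(t) - 1L))
        op <- substr(t, nchar(t), nchar(t))
        refc[i] <- sum(len[op %in% c("M", "D", "N", "=", "X")])
        aligned[i] <- sum(len[op %in% c("M", "I", "=", "X")])
        clip <- op %in% c("S", "H")
        k <- length(op)
        lead[i] <- if (clip[1]) len[1] else 0L
        trail[i] <- if (k > 1L && clip[k]) len[k] else
            if (k == 1L && clip[1]) 0L else 0L
        if (k > 1L && clip[1] && clip[2])
            stop("malformed CIGAR at alignment line ", i, ": ", cigars[i])
    }
    list(refConsumed = refc, aligned = aligned, lead = lead, trail = trail)
}

#' Read alignment records from a SAM file
#'
#' Parses SAM text into the per-record segment table used by classification:
#' reference interval, strand, MAPQ, and the aligned interval on the
#' *original* read (clip lengths mirrored for minus-strand records so clip
#' accounting is strand-free). Unmapped and secondary (0x100) records are
#' skipped; supplementary (0x800) records are kept and flagged. Single-end
#' records are tagged `source = "stitched"`, paired records `mate1`/`mate2`
#' from flags 0x40/0x80. A MAPQ of 255 ("unavailable", used by STAR for
#' unique alignments) is remapped to 60 so the MAPQ filter treats the two
#' supported aligners alike.
#'
#' @param path a SAM file, or a character vector of SAM lines.
#' @return a data.frame with columns `read_id`, `source`, `chrom`,
#'   `ref_start`, `ref_end`, `strand`, `mapq`, `query_start`, `query_end`,
#'   `clipped`, `read_len`, `supplementary`.
#' @export
readSam <- function(path) {
    lines <- if (length(path) == 1L && file.exists(path)) {
        con <- file(path, "rt"); on.exit(close(con)); readLines(con)
    } else as.character(path)
    lines <- lines[!startsWith(lines, "@")]
    if (!length(lines)) return(emptySamTable())
    ## keep only the six leading mandatory fields: the variable number of
    ## optional tags must not influence the table shape
    lines <- sub("^((?:[^\t]*\t){5}[^\t]*).*", "\\1", lines)
    f <- data.table::fread(text = lines, sep = "\t", header = FALSE,
                           col.names = c("qname", "flag", "rname", "pos",
                                         "mapq", "cigar"),
                           colClasses = list(character = c(1, 3, 6),
                                             integer = c(2, 4, 5)))
    keep <- bitwAnd(f$flag, 0x4L) == 0L & bitwAnd(f$flag, 0x100L) == 0L
    f <- f[keep]
    if (!nrow(f)) return(emptySamTable())
    cg <- parseCigars(f$cigar)
    minus <- bitwAnd(f$flag, 0x10L) != 0L
    lead <- ifelse(minus, cg$trail, cg$lead)   # mirrored to original read
    trail <- ifelse(minus, cg$lead, cg$trail)
    paired <- bitwAnd(f$flag, 0x1L) != 0L
    source <- ifelse(!paired, "stitched",
                     ifelse(bitwAnd(f$flag, 0x40L) != 0L, "mate1", "mate2"))
    mapq <- ifelse(f$mapq == 255L, 60L, f$mapq)
    out <- data.frame(read_id = f$qname, source = source, chrom = f$rname,
                      ref_start = f$pos,
                      ref_end = f$pos + cg$refConsumed - 1L,
                      strand = ifelse(minus, "-", "+"), mapq = mapq,
                      query_start = lead + 1L,
                      query_end = lead + cg$aligned,
                      clipped = cg$lead + cg$trail,
                      read_len = cg$lead + cg$aligned + cg$trail,
                      supplementary = bitwAnd(f$flag, 0x800L) != 0L)
    groupReads(out)
}

emptySamTable <- function() {
    data.frame(read_id = character(), source = character(),
               chrom = character(), ref_start = integer(),
               ref_end = integer(), strand = character(), mapq = integer(),
               query_start = integer(), query_end = integer(),
               clipped = integer(), read_len = integer(),
               supplementary = logical())
}

#' Validate name-grouped record order
#'
#' The aligner contract guarantees name-grouped output (all records of a read
#' adjacent). This checks the property and errors on interleaved ids, e.g.
#' the order A, B, A.
#'
#' @param records a segment table from [readSam()].
#' @return `records`, unchanged, invisibly usable downstream.
#' @export
groupReads <- function(records) {
    if (nrow(records)) {
        r <- rle(records$read_id)
        if (anyDuplicated(r$values))
            stop("SAM input is not grouped by read id (interleaved ids)")
    }
    records
}

#' Clipped-cycle fraction per source read
#'
#' For each (read, source) the fraction of read cycles not covered by the
#' *union* of its records' query intervals, so overlapping split alignments
#' are not double-counted. A read with no surviving records has fraction 1.
#'
#' @param records a segment table from [readSam()].
#' @return data.frame with columns `read_id`, `source`, `read_len`,
#'   `covered`, `clip_frac`.
#' @export
clipFractions <- function(records) {
    if (!nrow(records))
        return(data.frame(read_id = character(), source = character(),
                          read_len = integer(), covered = integer(),
                          clip_frac = numeric()))
    dt <- data.table::as.data.table(records)
    data.table::setorder(dt, read_id, source, query_start, query_end)
    res <- dt[, {
        hi <- cummax(query_end)
        prev <- c(0L, hi[-.N])
        cov <- sum(pmax(0L, query_end - pmax(query_start - 1L, prev)))
        list(read_len = max(read_len), covered = cov)
    }, by = .(read_id, source)]
    res[, clip_frac := (read_len - covered) / read_len]
    as.data.frame(res)
}
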