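## 4DN pairs format I/O: header-complete, sorted output via a bounded-memory
## external merge sort; tolerant reader with sortedness validation. Positions
## are 1-based (pairs convention, inherited from SAM). Chromosome order
## follows the chrom-sizes table, not lexicographic order.

PAIRS_COLUMNS <- c("readID", "chr1", "pos1", "chr2", "pos2",
                   "strand1", "strand2")

pairsHeader <- function(order) {
    c("## pairs format v1.0",
      "#sorted: chr1-chr2-pos1-pos2",
      "#shape: upper triangle",
      sprintf("#chromsize: %s %s", seqNames(order), fmtPos(order@seqlengths)),
      paste("#columns:", paste(PAIRS_COLUMNS, collapse = " ")))
}

formatPairRows <- function(p) {
    if (!nrow(p)) return(character())
    paste(p$readID, p$chr1, fmtPos(p$pos1), p$chr2, fmtPos(p$pos2),
          p$strand1, p$strand2, sep = "\t")
}

pairsOrder <- function(p, order) {
    order(chromRank(order, p$chr1), chromRank(order, p$chr2),
          p$pos1, p$pos2, method = "radix")
}

#' Write contact pairs in 4DN pairs format
#'
#' Emits a header-complete pairs file (`## pairs format v1.0`, one
#' `#chromsize:` line per chromosome in order, `#columns:`) with the body
#' sorted by (chr1 rank, chr2 rank, pos1, pos2). Sorting uses a
#' bounded-memory external merge: rows are sorted in chunks of `chunkSize`,
#' spilled to temporary files, and k-way merged; the result is byte-identical
#' to a full in-memory sort.
#'
#' @param x a \linkS4class{ContactPairs}.
#' @param path output path; a `.gz` suffix selects gzip.
#' @param chunkSize rows sorted in memory at a time.
#' @return `path`, invisibly.
#' @export
writePairs <- function(x, path, chunkSize = 500000L) {
    stopifnot(methods::is(x, "ContactPairs"))
    ord <- x@chromOrder
    p <- x@pairs
    if (nrow(p) && (anyNA(chromRank(ord, p$chr1)) ||
                    anyNA(chromRank(ord, p$chr2)))) {
        bad <- which(is.na(chromRank(ord, p$chr1)) |
                     is.na(chromRank(ord, p$chr2)))[1]
        stop("unknown chromosome in pair of read ", p$readID[bad])
    }
    out <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(out), add = TRUE)
    writeLines(pairsHeader(ord), out)
    n <- nrow(p)
    if (n == 0L) return(invisible(path))

    starts <- seq(1L, n, by = chunkSize)
    if (length(starts) == 1L) {            # single chunk: sort directly
        writeLines(formatPairRows(p[pairsOrder(p, ord), , drop = FALSE]), out)
        return(invisible(path))
    }
    ## spill sorted chunks to temporary files
    chunkFiles <- character(length(starts))
    for (k in seq_along(starts)) {
        idx <- starts[k]:min(starts[k] + chunkSize - 1L, n)
        ck <- p[idx, , drop = FALSE]
        chunkFiles[k] <- tempfile(fileext = ".pairs-chunk")
        writeLines(formatPairRows(ck[pairsOrder(ck, ord), , drop = FALSE]),
                   chunkFiles[k])
    }
    on.exit(unlink(chunkFiles), add = TRUE)
    ## k-way merge: keep one parsed line per chunk, emit the minimum
    cons <- lapply(chunkFiles, file, open = "rt")
    on.exit(lapply(cons, close), add = TRUE)
    rank <- stats::setNames(seq_along(seqNames(ord)) - 1L, seqNames(ord))
    heads <- character(length(cons))
    live <- rep(TRUE, length(cons))
    keys <- matrix(NA_real_, nrow = length(cons), ncol = 4L)
    pull <- function(k) {
        line <- readLines(cons[[k]], n = 1L)
        if (!length(line)) {
            live[k] <<- FALSE
            keys[k, ] <<- NA_real_
        } else {
            f <- strsplit(line, "\t", fixed = TRUE)[[1]]
            heads[k] <<- line
            keys[k, ] <<- c(rank[[f[2]]], rank[[f[4]]],
                            as.numeric(f[3]), as.numeric(f[5]))
        }
    }
    for (k in seq_along(cons)) pull(k)
    while (any(live)) {
        cand <- which(live)
        best <- cand[do.call(order, as.data.frame(keys[cand, , drop = FALSE]))[1]]
        writeLines(heads[best], out)
        pull(best)
    }
    invisible(path)
}

#' Read a 4DN pairs file
#'
#' Parses header and body into a \linkS4class{ContactPairs}. Requires the
#' `#columns:` declaration; tolerates extra columns (ignored) and both the
#' tab and multi-space column dialects (tab is canonical on write). When the
#' header carries a `#sorted:` tag and `strict` is TRUE, sortedness is
#' validated and a violation is an error.
#'
#' @param path a pairs file (gzip transparent).
#' @param strict validate claimed sortedness (default TRUE).
#' @return a \linkS4class{ContactPairs}; write -> read -> write round-trips
#'   are byte-identical.
#' @export
readPairs <- function(path, strict = TRUE) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    lines <- readLines(con)
    isHead <- startsWith(lines, "#")
    nHead <- match(FALSE, isHead, nomatch = length(lines) + 1L) - 1L
    if (any(isHead[-seq_len(nHead)]))
        stop("header line after body start in ", path)
    header <- lines[seq_len(nHead)]
    body <- lines[-seq_len(nHead)]

    colLine <- grep("^#columns:", header, value = TRUE)
    if (!length(colLine)) stop("missing #columns line in ", path)
    cols <- strsplit(sub("^#columns:\\s*", "", colLine[1]), "\\s+")[[1]]
    need <- setdiff(PAIRS_COLUMNS, cols)
    if (length(need))
        stop("pairs file lacks required columns: ", paste(need, collapse = " "))
    csLines <- grep("^#chromsize:", header, value = TRUE)
    if (!length(csLines)) stop("missing #chromsize lines in ", path)
    cs <- do.call(rbind, strsplit(sub("^#chromsize:\\s*", "", csLines), "\\s+"))
    ord <- ChromOrder(cs[, 1], as.numeric(cs[, 2]))

    if (length(body)) {
        f <- strsplit(body, "[\t ]+")
        nf <- lengths(f)
        if (any(nf < length(cols)))
            stop("too few columns at pairs body line ", which(nf < length(cols))[1])
        get <- function(name) vapply(f, `[[`, "", match(name, cols))
        posChr <- function(name) {
            v <- get(name)
            bad <- grepl("[^0-9]", v)
            if (any(bad))
                stop("non-integer position at pairs body line ", which(bad)[1])
            as.integer(v)
        }
        p <- data.frame(readID = get("readID"), chr1 = get("chr1"),
                        pos1 = posChr("pos1"), chr2 = get("chr2"),
                        pos2 = posChr("pos2"), strand1 = get("strand1"),
                        strand2 = get("strand2"))
    } else {
        p <- data.frame(readID = character(), chr1 = character(),
                        pos1 = integer(), chr2 = character(),
                        pos2 = integer(), strand1 = character(),
                        strand2 = character())
    }
    if (strict && any(grepl("^#sorted:", header)) && nrow(p) > 1L) {
        if (!identical(pairsOrder(p, ord), seq_len(nrow(p))))
            stop("pairs file claims sortedness but body is not sorted: ", path)
    }
    ContactPairs(p, ord)
}

#' Write pairs in juicer "short with score"-free short format
#'
#' Eight columns `str1 chr1 pos1 frag1 str2 chr2 pos2 frag2` with strands
#' encoded 0 (+) / 16 (-) and dummy fragment fields 0/1, accepted by
#' external `.hic` converters.
#'
#' @param x a \linkS4class{ContactPairs}.
#' @param path output path; `.gz` selects gzip.
#' @return `path`, invisibly.
#' @export
writeJuicerShort <- function(x, path) {
    stopifnot(methods::is(x, "ContactPairs"))
    p <- x@pairs[pairsOrder(x@pairs, x@chromOrder), , drop = FALSE]
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    if (nrow(p))
        writeLines(paste(ifelse(p$strand1 == "+", 0L, 16L), p$chr1,
                         fmtPos(p$pos1), 0L,
                         ifelse(p$strand2 == "+", 0L, 16L), p$chr2,
                         fmtPos(p$pos2), 1L, sep = "\t"), con)
    invisible(path)
}
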