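## Alignment filtering and pair inference: MAPQ filter, segment-count
## classification for stitched and unstitched reads, clip-fraction filter,
## and outermost-end pair reporting.
##
## "Outermost end" is formalised as the junction-distal mapped coordinate of
## each locus: the reference position of the query base most distal from the
## ligation junction. For the end covering the first query base that is the
## segment's 5' mapped coordinate with the segment's strand; for the end
## covering the last query base it is the segment's 3'-in-read coordinate
## with the strand flipped (so a single-segment fragment reports its two
## fragment ends as +/-).

flipStrand <- function(s) ifelse(s == "+", "-", "+")

#' Remove low-quality alignment records
#'
#' Drops records with mapping quality strictly below `minMapq` (default 10).
#'
#' @param records a segment table from [readSam()].
#' @param config an \linkS4class{ExtractConfig}.
#' @return the filtered segment table (possibly empty per read).
#' @export
filterMapq <- function(records, config = ExtractConfig()) {
    records[records$mapq >= config@minMapq, , drop = FALSE]
}

## Merge records of one (read, source) whose query intervals reciprocally
## overlap by more than 50%: they describe the same read region (e.g. an
## alternative supplementary placement) and count as one region. The
## higher-MAPQ record represents the region (tie: first).
mergeSplitRegions <- function(records) {
    if (!nrow(records)) return(records)
    dt <- data.table::as.data.table(records)
    dt[, .spOrd := .I]
    dt[, .spN := .N, by = .(read_id, source)]
    singles <- dt[.spN == 1L]
    multi <- dt[.spN > 1L]
    if (nrow(multi)) {
        data.table::setorder(multi, read_id, source, query_start, query_end)
        keepRow <- multi[, {
            k <- rep(TRUE, .N)
            rep_i <- 1L
            for (j in seq_len(.N)[-1]) {
                ov <- min(query_end[rep_i], query_end[j]) -
                    max(query_start[rep_i], query_start[j]) + 1L
                w1 <- query_end[rep_i] - query_start[rep_i] + 1L
                w2 <- query_end[j] - query_start[j] + 1L
                if (ov > 0.5 * w1 && ov > 0.5 * w2) {
                    if (mapq[j] > mapq[rep_i]) { k[rep_i] <- FALSE; rep_i <- j }
                    else k[j] <- FALSE
                } else rep_i <- j
            }
            list(.spOrd = .spOrd[k])
        }, by = .(read_id, source)]
        multi <- multi[.spOrd %in% keepRow$.spOrd]
    }
    out <- rbind(singles, multi)
    data.table::setorder(out, .spOrd)
    out[, c(".spOrd", ".spN") := NULL]
    as.data.frame(out)
}

## Core classification shared by classifyGroups() and extractPairs().
## Returns the merged post-filter records plus a per-read table.
classifyCore <- function(records, config) {
    allIds <- unique(records$read_id)
    kept <- filterMapq(records, config)
    clip <- clipFractions(kept)
    merged <- mergeSplitRegions(kept)
    dt <- data.table::as.data.table(merged)

    grp <- data.table::data.table(read_id = allIds)
    if (nrow(dt)) {
        cnt <- dt[, list(n_st = sum(source == "stitched"),
                         n_m1 = sum(source == "mate1"),
                         n_m2 = sum(source == "mate2")), by = read_id]
    } else {
        cnt <- data.table::data.table(read_id = character(), n_st = integer(),
                                      n_m1 = integer(), n_m2 = integer())
    }
    grp <- merge(grp, cnt, by = "read_id", all.x = TRUE, sort = FALSE)
    for (cc in c("n_st", "n_m1", "n_m2"))
        grp[is.na(get(cc)), (cc) := 0L]

    ## a read's stitched/unstitched nature comes from the unfiltered records
    ## (it must survive even when every record is filtered away)
    srcTab <- unique(records[, c("read_id", "source")])
    isStitchedSrc <- tapply(srcTab$source == "stitched", srcTab$read_id, any)
    grp[, stitched_src := as.logical(isStitchedSrc[read_id])]

    category <- rep(NA_character_, nrow(grp))
    reason <- rep(NA_character_, nrow(grp))

    st <- grp$stitched_src
    category[st & grp$n_st == 1L] <- "stitched_1seg"
    category[st & grp$n_st == 2L] <- "stitched_2seg"
    reason[st & grp$n_st == 0L] <- "unmapped"
    reason[st & grp$n_st > 2L] <- "multi_segment"

    un <- !st
    category[un & grp$n_m1 == 1L & grp$n_m2 == 1L] <- "unstitched_2loci"
    reason[un & (grp$n_m1 == 0L | grp$n_m2 == 0L)] <- "unmapped_mate"
    threeCand <- un & is.na(category) & is.na(reason) &
        ((grp$n_m1 == 2L & grp$n_m2 == 1L) |
         (grp$n_m1 == 1L & grp$n_m2 == 2L))
    reason[un & is.na(category) & is.na(reason) & !threeCand] <- "multi_segment"

    ## 3-record case: one mate split in two segments, one of which pairs
    ## with the lone mate (same chrom, opposite strands, face-to-face,
    ## implied outermost-to-outermost span within mateJoinMaxSpan)
    pairedFirst <- rep(NA, nrow(grp))
    splitMate <- rep(NA_character_, nrow(grp))
    if (any(threeCand)) {
        ids3 <- grp$read_id[threeCand]
        sub <- dt[read_id %in% ids3]
        data.table::setorder(sub, read_id, source, query_start, query_end)
        ib <- seq(1L, nrow(sub), 3L)            # 3 rows per candidate read
        sm1 <- sub$source[ib] == sub$source[ib + 1L]
        seg1 <- ifelse(sm1, ib, ib + 1L)
        seg2 <- seg1 + 1L
        lone <- ifelse(sm1, ib + 2L, ib)
        spanOf <- function(s) {
            okOrient <- sub$chrom[s] == sub$chrom[lone] &
                sub$strand[s] != sub$strand[lone]
            plusStart <- ifelse(sub$strand[s] == "+", sub$ref_start[s],
                                sub$ref_start[lone])
            minusEnd <- ifelse(sub$strand[s] == "+", sub$ref_end[lone],
                               sub$ref_end[s])
            span <- minusEnd - plusStart + 1
            ifelse(okOrient & span >= 1 & span <= config@mateJoinMaxSpan,
                   span, NA_real_)
        }
        sp1 <- spanOf(seg1)
        sp2 <- spanOf(seg2)
        ok3 <- !is.na(sp1) | !is.na(sp2)
        m <- match(sub$read_id[ib], grp$read_id)
        category[m[ok3]] <- "unstitched_3rec"
        reason[m[!ok3]] <- "no_mate_pairing"
        pairedFirst[m] <- !is.na(sp1) & (is.na(sp2) | sp1 <= sp2)
        splitMate[m] <- ifelse(sm1, "mate1", "mate2")
    }

    ## clip filter on reads that passed classification
    if (nrow(clip)) {
        maxClip <- tapply(clip$clip_frac, clip$read_id, max)
        over <- !is.na(category) &
            as.numeric(maxClip[grp$read_id]) > config@maxClipFrac
        over[is.na(over)] <- FALSE
        reason[over] <- "overclipped"
        category[over] <- NA_character_
    }

    groups <- data.frame(read_id = grp$read_id, category = category,
                         reason = reason, pairedFirst = pairedFirst,
                         splitMate = splitMate)
    list(groups = groups, records = as.data.frame(dt))
}

#' Classify read groups by segment counts
#'
#' Applies the MAPQ filter and the segment-count rules: stitched reads are
#' kept when they map to one (non-chimeric) or two regions; unstitched reads
#' when each mate maps to exactly one region, or when one mate splits into
#' two segments one of which pairs with the lone mate (same chromosome,
#' opposite strands, face-to-face, implied fragment span at most
#' `mateJoinMaxSpan`). Reads with more than `maxClipFrac` of their cycles
#' outside the union of kept alignments are then rejected as overclipped.
#'
#' @param records a segment table from [readSam()].
#' @param config an \linkS4class{ExtractConfig}.
#' @return data.frame with one row per read: `read_id`, `category` (NA when
#'   rejected) and `reason` (NA when accepted).
#' @export
classifyGroups <- function(records, config = ExtractConfig()) {
    classifyCore(groupReads(records), config)$groups[
        , c("read_id", "category", "reason")]
}

#' Extract contact pairs from classified alignments
#'
#' Runs MAPQ filtering, classification and outermost-end extraction, and
#' returns the contacts in upper-triangle order. Per-category and
#' per-rejection-reason counts are attached as `attr(x, "counts")`.
#'
#' @param records a segment table from [readSam()] (name-grouped).
#' @param chromOrder a \linkS4class{ChromOrder}; the chromosome-order
#'   authority for upper-triangle sorting.
#' @param config an \linkS4class{ExtractConfig}.
#' @return a \linkS4class{ContactPairs}.
#' @export
extractPairs <- function(records, chromOrder, config = ExtractConfig()) {
    cls <- classifyCore(groupReads(records), config)
    groups <- cls$groups
    dt <- data.table::as.data.table(cls$records)
    acc <- groups[!is.na(groups$category), , drop = FALSE]

    ends <- list()
    if (nrow(acc)) {
        dt <- dt[read_id %in% acc$read_id]
        data.table::setorder(dt, read_id, source, query_start, query_end)
        cat1 <- acc$category[match(dt$read_id, acc$read_id)]

        ## helper vectors: 5' coordinate and query-end-side coordinate
        p5 <- ifelse(dt$strand == "+", dt$ref_start, dt$ref_end)
        p3 <- ifelse(dt$strand == "+", dt$ref_end, dt$ref_start)

        one <- which(cat1 == "stitched_1seg")
        if (length(one))
            ends$s1 <- data.frame(readID = dt$read_id[one],
                                  chr1 = dt$chrom[one], pos1 = p5[one],
                                  strand1 = dt$strand[one],
                                  chr2 = dt$chrom[one], pos2 = p3[one],
                                  strand2 = flipStrand(dt$strand[one]),
                                  category = "stitched_1seg")

        two <- which(cat1 == "stitched_2seg")
        if (length(two)) {
            sub <- dt[two]
            o <- order(sub$read_id, sub$query_start, sub$query_end)
            sub <- sub[o]
            a <- seq(1L, nrow(sub), 2L)
            b <- a + 1L
            ends$s2 <- data.frame(readID = sub$read_id[a],
                                  chr1 = sub$chrom[a],
                                  pos1 = ifelse(sub$strand[a] == "+",
                                                sub$ref_start[a],
                                                sub$ref_end[a]),
                                  strand1 = sub$strand[a],
                                  chr2 = sub$chrom[b],
                                  pos2 = ifelse(sub$strand[b] == "+",
                                                sub$ref_end[b],
                                                sub$ref_start[b]),
                                  strand2 = flipStrand(sub$strand[b]),
                                  category = "stitched_2seg")
        }

        loc2 <- which(cat1 == "unstitched_2loci")
        if (length(loc2)) {
            sub <- dt[loc2]   # ordered read_id, source => mate1 then mate2
            a <- seq(1L, nrow(sub), 2L)
            b <- a + 1L
            pp <- ifelse(sub$strand == "+", sub$ref_start, sub$ref_end)
            ends$u2 <- data.frame(readID = sub$read_id[a],
                                  chr1 = sub$chrom[a], pos1 = pp[a],
                                  strand1 = sub$strand[a],
                                  chr2 = sub$chrom[b], pos2 = pp[b],
                                  strand2 = sub$strand[b],
                                  category = "unstitched_2loci")
        }

        r3 <- which(cat1 == "unstitched_3rec")
        if (length(r3)) {
            sub <- dt[r3]   # ordered (read_id, source, query_start): 3 rows/read
            ids <- unique(sub$read_id)
            info <- acc[match(ids, acc$read_id), ]
            ib <- seq(1L, nrow(sub), 3L)
            sm1 <- info$splitMate == "mate1"
            seg1 <- ifelse(sm1, ib, ib + 1L)
            seg2 <- seg1 + 1L
            lone <- ifelse(sm1, ib + 2L, ib)
            free <- ifelse(info$pairedFirst, seg2, seg1)
            coversStart <- !info$pairedFirst
            fs <- sub$strand[free]
            posA <- ifelse(coversStart,
                           ifelse(fs == "+", sub$ref_start[free],
                                  sub$ref_end[free]),
                           ifelse(fs == "+", sub$ref_end[free],
                                  sub$ref_start[free]))
            strA <- ifelse(coversStart, fs, flipStrand(fs))
            ls <- sub$strand[lone]
            ends$u3 <- data.frame(readID = info$read_id,
                                  chr1 = sub$chrom[free], pos1 = posA,
                                  strand1 = strA,
                                  chr2 = sub$chrom[lone],
                                  pos2 = ifelse(ls == "+",
                                                sub$ref_start[lone],
                                                sub$ref_end[lone]),
                                  strand2 = ls,
                                  category = "unstitched_3rec")
        }
    }

    pairs <- if (length(ends)) do.call(rbind, ends) else
        data.frame(readID = character(), chr1 = character(),
                   pos1 = integer(), strand1 = character(),
                   chr2 = character(), pos2 = integer(),
                   strand2 = character(), category = character())
    rownames(pairs) <- NULL

    ## upper-triangle ordering of the two ends (strands travel with ends)
    if (nrow(pairs)) {
        r1 <- chromRank(chromOrder, pairs$chr1)
        r2 <- chromRank(chromOrder, pairs$chr2)
        if (anyNA(r1) || anyNA(r2))
            stop("pair chromosome missing from chromOrder, e.g. read ",
                 pairs$readID[which(is.na(r1) | is.na(r2))[1]])
        sw <- r1 > r2 | (r1 == r2 & pairs$pos1 > pairs$pos2)
        if (any(sw)) {
            tmp <- pairs[sw, c("chr1", "pos1", "strand1")]
            pairs[sw, c("chr1", "pos1", "strand1")] <-
                pairs[sw, c("chr2", "pos2", "strand2")]
            pairs[sw, c("chr2", "pos2", "strand2")] <- tmp
        }
        if (config@minSpan > 0L) {
            drop <- pairs$chr1 == pairs$chr2 &
                pairs$pos2 - pairs$pos1 < config@minSpan
            pairs <- pairs[!drop, , drop = FALSE]
        }
    }
    pairs <- pairs[, c("readID", "chr1", "pos1", "chr2", "pos2",
                       "strand1", "strand2", "category")]
    rownames(pairs) <- NULL

    out <- ContactPairs(pairs, chromOrder)
    rej <- table(groups$reason[!is.na(groups$reason)])
    out@pairs$pos1 <- as.integer(out@pairs$pos1)
    out@pairs$pos2 <- as.integer(out@pairs$pos2)
    attr(out, "counts") <- list(
        groups_in = nrow(groups),
        pairs_out = nrow(pairs),
        by_category = as.list(table(pairs$category)),
        rejected = as.list(rej))
    out
}
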