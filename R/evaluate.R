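## Evaluation statistics: simulation accuracy (reported vs truth coordinates
## within a bp tolerance), cross-run concordance, and stitch-yield tables.
## Tolerances are strict inequalities (< tol).

asPairTable <- function(x) {
    if (methods::is(x, "ContactPairs")) return(x@pairs)
    if (is.character(x)) return(readPairs(x)@pairs)
    as.data.frame(x)
}

asTruthTable <- function(truth) {
    if (is.character(truth))
        truth <- utils::read.table(truth, header = TRUE, sep = "\t",
                                   colClasses = c("character", "character",
                                                  "numeric", "character",
                                                  "numeric", "logical"))
    truth <- as.data.frame(truth)
    stopifnot(all(c("read_id", "chrom1", "pos1", "chrom2", "pos2",
                    "is_chimeric") %in% names(truth)))
    truth
}

## both-end match under either end assignment, strict < tol
bothEndsWithin <- function(c1a, p1a, c2a, p2a, c1b, p1b, c2b, p2b, tol) {
    direct <- c1a == c1b & c2a == c2b &
        abs(p1a - p1b) < tol & abs(p2a - p2b) < tol
    swapped <- c1a == c2b & c2a == c1b &
        abs(p1a - p2b) < tol & abs(p2a - p1b) < tol
    direct | swapped
}

#' Score reported pairs against simulation truth
#'
#' A reported pair is correct when, after trying both end assignments, each
#' end's chromosome equals the truth chromosome and its position is within
#' `tol` bp (strict) of the truth position. Reported pairs whose read id is
#' absent from the truth table are binned separately as `n_unmatched`, not
#' counted as incorrect.
#'
#' @param pairs a \linkS4class{ContactPairs}, pairs file path, or pair table.
#' @param truth truth table (data.frame or TSV path) with columns
#'   `read_id chrom1 pos1 chrom2 pos2 is_chimeric`.
#' @param tol tolerance in bp (default 500).
#' @return an `AccuracyReport` list: `n_pairs_reported`, `n_correct`,
#'   `accuracy`, `n_unmatched`, `n_truth`, `recall_like`, and a
#'   `per_category` breakdown when categories are recorded.
#' @export
accuracyVsTruth <- function(pairs, truth, tol = 500) {
    p <- asPairTable(pairs)
    tr <- asTruthTable(truth)
    m <- match(p$readID, tr$read_id)
    matched <- !is.na(m)
    pm <- p[matched, , drop = FALSE]
    tm <- tr[m[matched], , drop = FALSE]
    correct <- bothEndsWithin(pm$chr1, pm$pos1, pm$chr2, pm$pos2,
                              tm$chrom1, tm$pos1, tm$chrom2, tm$pos2, tol)
    perCat <- NULL
    if ("category" %in% names(pm) && nrow(pm) && !all(is.na(pm$category))) {
        perCat <- do.call(rbind, lapply(split(correct, pm$category),
                                        function(v) data.frame(
                                            n = length(v),
                                            n_correct = sum(v),
                                            accuracy = mean(v))))
        perCat <- cbind(category = rownames(perCat), perCat)
        rownames(perCat) <- NULL
    }
    matchedTruth <- unique(pm$readID[correct])
    rep <- list(n_pairs_reported = nrow(pm),
                n_correct = sum(correct),
                accuracy = if (nrow(pm)) sum(correct) / nrow(pm) else NA_real_,
                n_unmatched = sum(!matched),
                n_truth = nrow(tr),
                recall_like = if (nrow(tr)) length(matchedTruth) / nrow(tr)
                              else NA_real_,
                per_category = perCat,
                tol = tol)
    class(rep) <- "AccuracyReport"
    rep
}

#' @export
print.AccuracyReport <- function(x, ...) {
    cat(sprintf("Accuracy vs truth (tol < %g bp):\n", x$tol))
    cat(sprintf("  %d / %d reported pairs correct (accuracy %.4f)\n",
                x$n_correct, x$n_pairs_reported, x$accuracy))
    cat(sprintf("  recall-like: %.4f of %d truth records; %d unmatched pairs\n",
                x$recall_like, x$n_truth, x$n_unmatched))
    if (!is.null(x$per_category)) print(x$per_category)
    invisible(x)
}

#' Concordance between two pair sets
#'
#' Joins two runs on read id; a common read is consistent when both runs
#' report the same chromosome pair and both end distances are strictly below
#' `tol` bp (either end assignment). Duplicate read ids within one input keep
#' their first occurrence.
#'
#' @param pairsA,pairsB \linkS4class{ContactPairs}, file paths, or tables.
#' @param tol tolerance in bp (default 200).
#' @return a `ConcordanceReport` list: `n_common_read_ids`, `n_consistent`,
#'   `consistency`, `n_only_A`, `n_only_B`.
#' @export
concordance <- function(pairsA, pairsB, tol = 200) {
    a <- asPairTable(pairsA)
    b <- asPairTable(pairsB)
    dupA <- sum(duplicated(a$readID))
    dupB <- sum(duplicated(b$readID))
    if (dupA) message(dupA, " duplicate read ids in A: first kept")
    if (dupB) message(dupB, " duplicate read ids in B: first kept")
    a <- a[!duplicated(a$readID), , drop = FALSE]
    b <- b[!duplicated(b$readID), , drop = FALSE]
    m <- match(a$readID, b$readID)
    common <- !is.na(m)
    am <- a[common, , drop = FALSE]
    bm <- b[m[common], , drop = FALSE]
    cons <- bothEndsWithin(am$chr1, am$pos1, am$chr2, am$pos2,
                           bm$chr1, bm$pos1, bm$chr2, bm$pos2, tol)
    rep <- list(n_common_read_ids = nrow(am),
                n_consistent = sum(cons),
                consistency = if (nrow(am)) mean(cons) else NA_real_,
                n_only_A = nrow(a) - nrow(am),
                n_only_B = nrow(b) - nrow(am),
                tol = tol)
    class(rep) <- "ConcordanceReport"
    rep
}

#' @export
print.ConcordanceReport <- function(x, ...) {
    cat(sprintf("Concordance (tol < %g bp):\n", x$tol))
    cat(sprintf("  %d / %d common reads consistent (%.4f)\n", x$n_consistent,
                x$n_common_read_ids, x$consistency))
    cat(sprintf("  only in A: %d; only in B: %d\n", x$n_only_A, x$n_only_B))
    invisible(x)
}

#' Pair yield by stitch class
#'
#' Cross-tabulates the preprocessing read classes (stitched / unstitched)
#' with the reported pairs: per class, the number of input reads, the number
#' that yielded a pair, and the yield fraction; plus the overall stitched
#' fraction of the input.
#'
#' @param pairs a \linkS4class{ContactPairs}, path, or table.
#' @param readClass data.frame `id`, `class` as produced by
#'   [preprocessFastq()] (or its `.readclass.tsv.gz` file).
#' @return list with `table` (per-class data.frame) and `stitched_fraction`.
#' @export
stitchYield <- function(pairs, readClass) {
    p <- asPairTable(pairs)
    if (is.character(readClass))
        readClass <- utils::read.table(readClass, header = TRUE, sep = "\t",
                                       colClasses = "character")
    unknown <- setdiff(p$readID, readClass$id)
    if (length(unknown)) {
        warning(length(unknown),
                " reported pairs missing from the read-class log: excluded")
        p <- p[p$readID %in% readClass$id, , drop = FALSE]
    }
    hasPair <- readClass$id %in% p$readID
    tab <- do.call(rbind, lapply(split(hasPair, readClass$class),
                                 function(v) data.frame(n_input = length(v),
                                                        n_pairs = sum(v),
                                                        yield = mean(v))))
    tab <- cbind(class = rownames(tab), tab)
    rownames(tab) <- NULL
    list(table = tab,
         stitched_fraction = mean(readClass$class == "stitched"))
}
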