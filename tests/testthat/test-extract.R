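co2 <- ChromOrder(c("chr1", "chr2", "chr3", "chr5"),
                  c(1e6, 1e6, 1e6, 1e6))

test_that("MAPQ filter removes scores strictly below the threshold", {
    recs <- rbind(makeRec("r", "stitched", "chr1", 1, 150, "+", mapq = 9L),
                  makeRec("r", "stitched", "chr1", 1, 150, "+", mapq = 10L),
                  makeRec("r", "stitched", "chr1", 1, 150, "+", mapq = 60L))
    expect_identical(filterMapq(recs)$mapq, c(10L, 60L))
    expect_identical(nrow(filterMapq(recs, ExtractConfig(minMapq = 100))), 0L)
    expect_identical(filterMapq(recs, ExtractConfig(minMapq = 0)), recs)
})

test_that("segment-count classification follows the whitelist", {
    ## stitched fragment in one region
    one <- makeRec("a", "stitched", "chr3", 5001, 5200, "+",
                   query_start = 1, query_end = 200, read_len = 200)
    expect_identical(classifyGroups(one)$category, "stitched_1seg")

    ## stitched read split into three regions: rejected
    three <- rbind(
        makeRec("b", "stitched", "chr1", 1000, 1069, "+", query_start = 1,
                query_end = 70, read_len = 210),
        makeRec("b", "stitched", "chr2", 2000, 2069, "+", query_start = 71,
                query_end = 140, read_len = 210),
        makeRec("b", "stitched", "chr3", 3000, 3069, "+", query_start = 141,
                query_end = 210, read_len = 210))
    cl <- classifyGroups(three)
    expect_true(is.na(cl$category))
    expect_identical(cl$reason, "multi_segment")

    ## the spec'd 3-record configuration: mate 1 split across chr1/chr5,
    ## second segment face-to-face with mate 2 within 1 kb
    r3 <- rbind(
        makeRec("c", "mate1", "chr1", 1000, 1079, "+", query_start = 1,
                query_end = 80),
        makeRec("c", "mate1", "chr5", 9280, 9349, "-", query_start = 81,
                query_end = 150),
        makeRec("c", "mate2", "chr5", 9100, 9249, "+"))
    expect_identical(classifyGroups(r3)$category, "unstitched_3rec")

    ## same but the split segment 2 kb away: no pairing
    far <- r3
    far[far$chrom == "chr5" & far$source == "mate1",
        c("ref_start", "ref_end")] <- c(11150, 11219)
    cl <- classifyGroups(far)
    expect_identical(cl$reason, "no_mate_pairing")
})

test_that("overclipped reads are rejected at a strict 50% boundary", {
    ## exactly half the cycles aligned: kept
    half <- makeRec("r", "stitched", "chr1", 1000, 1074, "+",
                    query_start = 1, query_end = 75, read_len = 150)
    expect_identical(classifyGroups(half)$category, "stitched_1seg")
    ## one base fewer: clip fraction > 0.5, rejected
    over <- makeRec("r", "stitched", "chr1", 1000, 1073, "+",
                    query_start = 1, query_end = 74, read_len = 150)
    cl <- classifyGroups(over)
    expect_identical(cl$reason, "overclipped")
})

test_that("classification agrees with a brute-force oracle on random groups", {
    set.seed(41)
    chroms <- c("chr1", "chr2")
    nAgree <- 0L
    for (k in 1:400) {
        stitched <- runif(1) < 0.5
        mk <- function(src, n) {
            if (n == 0L) return(NULL)
            ## non-overlapping query intervals on a 150 bp read
            bounds <- sort(sample(seq(10, 140, 10), n - 1L))
            qs <- c(1L, bounds + 1L)
            qe <- c(bounds, sample(145:150, 1))
            do.call(rbind, lapply(seq_len(n), function(i) {
                w <- qe[i] - qs[i] + 1L
                st <- sample(1000:20000, 1)
                makeRec("g", src, sample(chroms, 1), st, st + w - 1L,
                        sample(c("+", "-"), 1),
                        mapq = sample(c(0L, 9L, 10L, 60L), 1),
                        query_start = qs[i], query_end = qe[i],
                        read_len = 150L)
            }))
        }
        recs <- if (stitched) mk("stitched", sample(1:3, 1))
                else rbind(mk("mate1", sample(1:2, 1)),
                           mk("mate2", sample(1:2, 1)))
        got <- classifyGroups(recs)$category
        want <- oracleClassify(recs)
        expect_identical(got, want)
        if (!is.na(got)) nAgree <- nAgree + 1L
    }
    expect_gt(nAgree, 50L)   # the fixture space hits accepted categories too
})

test_that("classification is invariant to record order within a group", {
    set.seed(42)
    recs <- rbind(
        makeRec("x", "mate1", "chr1", 1000, 1079, "+", query_start = 1,
                query_end = 80),
        makeRec("x", "mate1", "chr2", 9280, 9349, "-", query_start = 81,
                query_end = 150),
        makeRec("x", "mate2", "chr2", 9100, 9249, "+"))
    base <- classifyGroups(recs)
    for (k in 1:5) {
        perm <- recs[sample(nrow(recs)), , drop = FALSE]
        expect_identical(classifyGroups(perm), base)
    }
})

test_that("overlapping supplementary placements merge into one region", {
    recs <- rbind(
        makeRec("m", "stitched", "chr1", 1000, 1149, "+", mapq = 60,
                query_start = 1, query_end = 150, read_len = 150),
        makeRec("m", "stitched", "chr2", 5000, 5139, "+", mapq = 20,
                query_start = 11, query_end = 150, read_len = 150))
    ## reciprocal query overlap 140/150 and 140/140 > 50%: one region
    expect_identical(classifyGroups(recs)$category, "stitched_1seg")
    pr <- as.data.frame(extractPairs(recs, co2))
    expect_identical(pr$chr1, "chr1")   # the higher-MAPQ record represents it
})

test_that("outermost ends are reported with the documented strands", {
    ## single-segment stitched fragment: its two fragment ends
    one <- makeRec("a", "stitched", "chr3", 5001, 5200, "+",
                   query_start = 1, query_end = 200, read_len = 200)
    pr <- as.data.frame(extractPairs(one, co2))
    expect_identical(pr[, c("chr1", "pos1", "strand1")],
                     data.frame(chr1 = "chr3", pos1 = 5001L, strand1 = "+"))
    expect_identical(pr[, c("chr2", "pos2", "strand2")],
                     data.frame(chr2 = "chr3", pos2 = 5200L, strand2 = "-"))

    ## conventional pair: each mate's 5' coordinate, flipped to upper triangle
    conv <- rbind(makeRec("b", "mate1", "chr2", 800, 949, "-"),
                  makeRec("b", "mate2", "chr1", 100, 249, "+"))
    pr <- as.data.frame(extractPairs(conv, co2))
    expect_identical(pr$chr1, "chr1"); expect_identical(pr$pos1, 100L)
    expect_identical(pr$strand1, "+")
    expect_identical(pr$chr2, "chr2"); expect_identical(pr$pos2, 949L)
    expect_identical(pr$strand2, "-")

    ## two-segment stitched chimera: ends distal to the junction
    two <- rbind(
        makeRec("c", "stitched", "chr2", 10000, 10119, "+", query_start = 1,
                query_end = 120, read_len = 300),
        makeRec("c", "stitched", "chr1", 20000, 20179, "+",
                query_start = 121, query_end = 300, read_len = 300))
    pr <- as.data.frame(extractPairs(two, co2))
    ## end of segment 1 at query base 1 -> chr2:10000 (+); end of segment 2
    ## at the last query base -> chr1:20179, strand flipped; then swapped
    ## into upper-triangle order
    expect_identical(pr$chr1, "chr1"); expect_identical(pr$pos1, 20179L)
    expect_identical(pr$strand1, "-")
    expect_identical(pr$chr2, "chr2"); expect_identical(pr$pos2, 10000L)
    expect_identical(pr$strand2, "+")
    expect_identical(pr$category, "stitched_2seg")
})

test_that("3-record pairs report the free segment and the lone mate's 5' end", {
    r3 <- rbind(
        makeRec("c", "mate1", "chr1", 1000, 1079, "+", query_start = 1,
                query_end = 80),
        makeRec("c", "mate1", "chr5", 9280, 9349, "-", query_start = 81,
                query_end = 150),
        makeRec("c", "mate2", "chr5", 9100, 9249, "+"))
    pr <- as.data.frame(extractPairs(r3, co2))
    expect_identical(pr$category, "unstitched_3rec")
    ## free segment covers the query start: mate 1's 5' coordinate
    expect_identical(pr[, c("chr1", "pos1", "strand1")],
                     data.frame(chr1 = "chr1", pos1 = 1000L, strand1 = "+"))
    expect_identical(pr[, c("chr2", "pos2", "strand2")],
                     data.frame(chr2 = "chr5", pos2 = 9100L, strand2 = "+"))
})

test_that("every emitted pair respects upper-triangle order and accounting", {
    set.seed(43)
    recs <- do.call(rbind, lapply(1:200, function(i) {
        st <- sample(1000:900000, 2)
        rbind(makeRec(sprintf("p%03d", i), "mate1", sample(co2@seqnames, 1),
                      st[1], st[1] + 149L, sample(c("+", "-"), 1)),
              makeRec(sprintf("p%03d", i), "mate2", sample(co2@seqnames, 1),
                      st[2], st[2] + 149L, sample(c("+", "-"), 1)))
    }))
    pairs <- extractPairs(recs, co2)
    p <- as.data.frame(pairs)
    r1 <- chromRank(co2, p$chr1); r2 <- chromRank(co2, p$chr2)
    expect_true(all(r1 < r2 | (r1 == r2 & p$pos1 <= p$pos2)))
    cnt <- attr(pairs, "counts")
    expect_identical(cnt$groups_in,
                     cnt$pairs_out + sum(unlist(cnt$rejected)))
})

test_that("the optional minimum-span filter drops short cis pairs only", {
    conv <- rbind(makeRec("b", "mate1", "chr1", 800, 949, "-"),
                  makeRec("b", "mate2", "chr1", 100, 249, "+"),
                  makeRec("t", "mate1", "chr1", 101000, 101149, "-"),
                  makeRec("t", "mate2", "chr1", 100000, 100149, "+"))
    all <- extractPairs(conv, co2)
    expect_identical(length(all), 2L)
    flt <- extractPairs(conv, co2, ExtractConfig(minSpan = 1000L))
    expect_identical(as.data.frame(flt)$readID, "t")
})
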