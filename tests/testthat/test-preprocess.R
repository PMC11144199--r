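adapter1 <- stitchpairs:::TRUSEQ_ADAPTERS[1]
adapter2 <- stitchpairs:::TRUSEQ_ADAPTERS[2]

test_that("adapter read-through is trimmed and short pairs dropped", {
    set.seed(1)
    insert <- randSeq(30)
    seqs <- paste0(insert, adapter1)
    pairs <- data.frame(id = "r1", seq1 = seqs, qual1 = Q30(nchar(seqs)),
                        seq2 = paste0(randSeq(30), adapter2),
                        qual2 = Q30(63))
    tr <- trimReadPairs(pairs)   # default min length 36
    expect_identical(nrow(tr$pairs), 0L)
    expect_identical(tr$dropped$reason, "too_short")

    tr2 <- trimReadPairs(pairs, PreprocessConfig(minReadLen = 20))
    expect_identical(tr2$pairs$seq1, insert)
    expect_identical(nchar(tr2$pairs$qual1), 30L)
})

test_that("adapter-free high-quality reads pass unchanged", {
    set.seed(2)
    pairs <- data.frame(id = "r1", seq1 = randSeq(150), qual1 = Q30(150),
                        seq2 = randSeq(150), qual2 = Q30(150))
    tr <- trimReadPairs(pairs)
    expect_identical(tr$pairs, pairs)
})

test_that("trailing low-quality cycles are trimmed", {
    set.seed(3)
    pairs <- data.frame(id = "r1", seq1 = randSeq(150),
                        qual1 = paste0(Q30(145), strrep("#", 5)),
                        seq2 = randSeq(150), qual2 = Q30(150))
    tr <- trimReadPairs(pairs)
    expect_identical(nchar(tr$pairs$seq1), 145L)
    expect_identical(nchar(tr$pairs$seq2), 150L)  # mates keep own lengths
})

test_that("partial 3' adapter matches follow the mismatch budget", {
    set.seed(4)
    insert <- randSeq(120)
    ## 16 bp adapter prefix carries a 2-mismatch budget (one per 8 bases):
    ## 1 mismatch is still recognised, 3 mismatches are not
    ad <- adapter1
    mut <- function(s, at, to) { substr(s, at, at) <- to; s }
    one <- mut(substr(ad, 1, 16), 8, "T")
    threeMm <- mut(mut(one, 12, "C"), 16, "G")
    okread <- paste0(insert, one)
    badread <- paste0(insert, threeMm)
    pairs <- data.frame(id = c("a", "b"), seq1 = c(okread, badread),
                        qual1 = Q30(136), seq2 = randSeq(136),
                        qual2 = Q30(136))
    tr <- trimReadPairs(pairs)
    expect_identical(nchar(tr$pairs$seq1), c(120L, 136L))
})

test_that("dual-prefix deduplication keeps first occurrences in order", {
    set.seed(5)
    p1 <- randSeq(16); p2 <- randSeq(16)
    pairs <- data.frame(
        id = c("a", "b", "c"),
        seq1 = c(paste0(p1, randSeq(100)), paste0(p1, randSeq(100)),
                 paste0(p1, randSeq(100))),
        qual1 = Q30(116),
        seq2 = c(paste0(p2, randSeq(100)), paste0(p2, randSeq(100)),
                 paste0(substr(p2, 1, 15), "A", randSeq(100))),
        qual2 = Q30(116))
    ## b duplicates a (identical 16+16 prefix, different tails);
    ## c differs from a at base 16 of read 2
    dd <- dedupReadPairs(pairs)
    expect_identical(dd$pairs$id, c("a", "c"))
    expect_identical(dd$dropped$id, "b")
    expect_identical(dd$dropped$reason, "duplicate")

    ## idempotence and identity on distinct streams
    dd2 <- dedupReadPairs(dd$pairs)
    expect_identical(dd2$pairs, dd$pairs)
    distinct <- data.frame(id = as.character(1:50),
                           seq1 = vapply(1:50, function(i) randSeq(40), ""),
                           qual1 = Q30(40),
                           seq2 = vapply(1:50, function(i) randSeq(40), ""),
                           qual2 = Q30(40))
    expect_identical(nrow(dedupReadPairs(distinct)$pairs), 50L)
})

test_that("short reads with equal prefixes of different lengths never collide", {
    pairs <- data.frame(id = c("a", "b"), seq1 = c("AAA", "AAAA"),
                        qual1 = c("III", "IIII"), seq2 = c("CCC", "CCCC"),
                        qual2 = c("III", "IIII"))
    expect_identical(nrow(dedupReadPairs(pairs)$pairs), 2L)
})

test_that("overlapping mates stitch back to the exact insert", {
    set.seed(6)
    insert <- randSeq(200)
    pairs <- data.frame(id = "m", seq1 = substr(insert, 1, 150),
                        qual1 = Q30(150),
                        seq2 = revComp(substr(insert, 51, 200)),
                        qual2 = Q30(150))
    st <- stitchReadPairs(pairs)
    expect_true(st$stitched)
    expect_identical(nchar(st$seq), 200L)
    expect_identical(st$seq, insert)

    ## a 400 bp insert leaves no overlap
    insert2 <- randSeq(400)
    pairs2 <- data.frame(id = "n", seq1 = substr(insert2, 1, 150),
                         qual1 = Q30(150),
                         seq2 = revComp(substr(insert2, 251, 400)),
                         qual2 = Q30(150))
    expect_false(stitchReadPairs(pairs2)$stitched)
})

test_that("stitching is orientation-consistent under mate swap", {
    set.seed(7)
    for (k in 1:10) {
        insert <- randSeq(sample(180:280, 1))
        l <- nchar(insert)
        fwd <- data.frame(id = "x", seq1 = substr(insert, 1, 150),
                          qual1 = Q30(150),
                          seq2 = revComp(substr(insert, l - 149, l)),
                          qual2 = Q30(150))
        swp <- data.frame(id = "x", seq1 = fwd$seq2, qual1 = fwd$qual2,
                          seq2 = fwd$seq1, qual2 = fwd$qual1)
        a <- stitchReadPairs(fwd)
        b <- stitchReadPairs(swp)
        expect_true(a$stitched && b$stitched)
        expect_identical(b$seq, revComp(a$seq))
    }
})

test_that("mismatching overlap bases take the higher-quality mate's base", {
    set.seed(8)
    insert <- randSeq(200)
    r1 <- substr(insert, 1, 150)
    ## corrupt read 1 at cycle 100 (inside the overlap) with low quality
    substr(r1, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                    substr(r1, 100, 100))[1]
    q1 <- paste0(Q30(99), "#", Q30(50))
    pairs <- data.frame(id = "q", seq1 = r1, qual1 = q1,
                        seq2 = revComp(substr(insert, 51, 200)),
                        qual2 = Q30(150))
    st <- stitchReadPairs(pairs)
    expect_true(st$stitched)
    expect_identical(st$seq, insert)          # read 2's base wins
})

test_that("auto stitch mode uses a strict >10% probe threshold", {
    set.seed(9)
    mkStitchable <- function(n) {
        ins <- vapply(seq_len(n), function(i) randSeq(200), "")
        data.frame(id = paste0("s", seq_len(n)), seq1 = substr(ins, 1, 150),
                   qual1 = Q30(150), seq2 = revComp(substr(ins, 51, 200)),
                   qual2 = Q30(150))
    }
    mkUnstitchable <- function(n) {
        data.frame(id = paste0("u", seq_len(n)),
                   seq1 = vapply(seq_len(n), function(i) randSeq(150), ""),
                   qual1 = Q30(150),
                   seq2 = vapply(seq_len(n), function(i) randSeq(150), ""),
                   qual2 = Q30(150))
    }
    cfg <- PreprocessConfig(autoProbeReads = 1000)
    exact10 <- rbind(mkStitchable(100), mkUnstitchable(900))
    expect_identical(decideStitchMode(exact10, cfg), "off")
    just_over <- rbind(mkStitchable(101), mkUnstitchable(899))
    expect_identical(decideStitchMode(just_over, cfg), "on")
    expect_identical(decideStitchMode(mkUnstitchable(100), cfg), "off")
    expect_identical(decideStitchMode(exact10,
                                      PreprocessConfig(stitchMode = "on")),
                     "on")
    expect_warning(off <- decideStitchMode(exact10[0, ], cfg), "empty")
    expect_identical(off, "off")
})

test_that("stitched fraction matches the truth-derived stitchable fraction", {
    g <- randomGenome(c(chr1 = 500000), seed = 10)
    sim <- simulateDataset(g, SimConfig(nPairs = 10000L,
                                        junctionFraction = 0, seed = 88L))
    fq <- writeFastqPair(sim$reads1, sim$reads2)
    prep <- preprocessFastq(fq$fq1, fq$fq2)
    len <- sim$truth$pos2 - sim$truth$pos1 + 1
    ## stitchable: insert at most 2 * read length - minimum overlap
    p <- mean(len <= 2 * 150 - 10)
    got <- prep$counts[["stitched"]] / sum(prep$counts[c("stitched",
                                                         "unstitched")])
    expect_lt(abs(got - p), 3 * sqrt(p * (1 - p) / 10000))
})

test_that("preprocessing counts balance and replicates mode concatenates", {
    g <- randomGenome(c(chr1 = 300000), seed = 11)
    sim <- simulateDataset(g, SimConfig(nPairs = 1500L, seed = 33L,
                                        duplicateFraction = 0.1))
    d <- withr::local_tempdir()
    half <- 1:(nrow(sim$reads1) %/% 2)
    fqA <- list(writeFastq(sim$reads1[half, ], file.path(d, "a1.fq.gz")),
                writeFastq(sim$reads2[half, ], file.path(d, "a2.fq.gz")))
    fqB <- list(writeFastq(sim$reads1[-half, ], file.path(d, "b1.fq.gz")),
                writeFastq(sim$reads2[-half, ], file.path(d, "b2.fq.gz")))
    prep <- preprocessFastq(c(fqA[[1]], fqB[[1]]), c(fqA[[2]], fqB[[2]]),
                            outPrefix = file.path(d, "p"))
    expect_identical(prep$counts[["input"]], nrow(sim$reads1))
    expect_identical(prep$counts[["input"]],
                     sum(prep$counts[c("too_short", "duplicate", "stitched",
                                       "unstitched")]))
    expect_gt(prep$counts[["duplicate"]], 50)  # planted PCR duplicates found
    expect_true(file.exists(prep$stitchedFq))
    expect_identical(sort(unique(prep$readClass$class)),
                     sort(unique(c("stitched", "unstitched"))))
})
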