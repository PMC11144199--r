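## Proximity-ligation read simulator: restriction (Hi-C) or MNase (Micro-C)
## libraries with per-molecule ligation-junction truth records, so the
## downstream preprocessing / extraction / evaluation stages are testable
## without external data.

#' Generate a uniform-random synthetic genome
#'
#' Builds a synthetic reference with i.i.d. uniform A/C/G/T bases. Random
#' genomes of megabase scale are near-uniquely mappable, which makes them a
#' convenient substrate for end-to-end accuracy checks.
#'
#' @param seqlengths named numeric vector of chromosome lengths, e.g.
#'   `c(chr1 = 1e6, chr2 = 5e5)`.
#' @param seed optional integer seed (set before drawing when non-NULL).
#' @return a named `DNAStringSet`.
#' @examples
#' g <- randomGenome(c(chrA = 10000), seed = 1)
#' @export
randomGenome <- function(seqlengths, seed = NULL) {
    if (is.null(names(seqlengths)) || any(names(seqlengths) == ""))
        stop("seqlengths must be named by chromosome")
    if (!is.null(seed)) set.seed(seed)
    seqs <- vapply(seqlengths, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = ""), "")
    Biostrings::DNAStringSet(stats::setNames(seqs, names(seqlengths)))
}

#' Digest a reference into cut-site lists
#'
#' Finds all occurrences of the enzyme recognition site on the forward strand
#' of each chromosome (MboI's GATC is its own reverse complement, so a
#' forward-strand scan is exhaustive for palindromic sites) and adds virtual
#' terminal cuts at positions 1 and L+1. In MNase mode every position is a
#' legal cut and no list is materialised: the function returns `NULL`.
#'
#' @param genome FASTA path or `DNAStringSet`.
#' @param config a \linkS4class{SimConfig}, or a bare site string such as
#'   `"GATC"` (implying restriction mode).
#' @return named list of sorted 1-based cut positions per chromosome, or
#'   `NULL` in MNase mode.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr = "AAGATCAA"))
#' digestReference(g, "GATC")  # cuts at 1, 3, 9
#' @export
digestReference <- function(genome, config) {
    genome <- loadGenome(genome)
    if (methods::is(config, "SimConfig")) {
        if (config@mode == "mnase") return(NULL)
        site <- config@enzymeSite
    } else site <- config
    if (!is.character(site) || length(site) != 1L || nchar(site) == 0L)
        stop("enzyme site must be a single non-empty string")
    if (grepl("[^ACGT]", site))
        stop("enzyme site contains non-ACGT characters: ", site)
    hits <- Biostrings::vmatchPattern(site, genome)
    L <- Biostrings::width(genome)
    out <- lapply(seq_along(genome), function(i)
        sort(unique(c(1, Biostrings::start(hits[[i]]), L[i] + 1))))
    stats::setNames(out, names(genome))
}

## snap positions to the nearest cut site of their chromosome;
## ties broken toward the lower coordinate
snapToCuts <- function(chromIdx, pos, cutList) {
    out <- pos
    for (ci in unique(chromIdx)) {
        cuts <- cutList[[ci]]
        sel <- which(chromIdx == ci)
        p <- pos[sel]
        i <- findInterval(p, cuts)
        lo <- cuts[i]
        hi <- cuts[pmin(i + 1L, length(cuts))]
        out[sel] <- ifelse(hi - p < p - lo, hi, lo)
    }
    out
}

## inverse-CDF sampler for the d^(-a) cis-distance decay, truncated
## to [dmin, dmax] (both may be vectors parallel to u)
sampleCisDistance <- function(u, a, dmin, dmax) {
    if (abs(a - 1) < 1e-9) {
        d <- exp(log(dmin) + u * (log(dmax) - log(dmin)))
    } else {
        b <- 1 - a
        d <- (dmin^b + u * (dmax^b - dmin^b))^(1 / b)
    }
    pmax(round(d), 1)
}

## substitution errors at a per-base rate; bases mutate to a different base
injectErrors <- function(seqs, rate) {
    if (rate <= 0 || !length(seqs)) return(seqs)
    lens <- nchar(seqs)
    ne <- stats::rbinom(length(seqs), lens, rate)
    bases <- c("A", "C", "G", "T")
    for (i in which(ne > 0L)) {
        s <- strsplit(seqs[i], "")[[1]]
        at <- sample.int(lens[i], ne[i])
        for (j in at) s[j] <- sample(bases[bases != s[j]], 1L)
        seqs[i] <- paste(s, collapse = "")
    }
    seqs
}

#' Simulate a proximity-ligation read set with truth records
#'
#' Generates `nPairs` library molecules. With probability `junctionFraction` a
#' molecule is chimeric: two loci are drawn (inter-chromosomal with
#' probability `transFraction`, else a cis partner at a distance following a
#' truncated d^(-a) decay), snapped to the nearest enzyme cut site in
#' restriction mode, and two arms totalling a truncated-normal insert length
#' are joined at the junction. Otherwise the molecule is a plain genomic
#' fragment. `readLength` bases are then read from each end of the insert
#' (read 2 reverse-complemented), substitution errors injected, and the pair
#' written out together with a truth record holding the junction (or
#' fragment-end) coordinates. Identical configurations (including `seed`)
#' yield byte-identical outputs.
#'
#' @param genome FASTA path or `DNAStringSet`.
#' @param config a \linkS4class{SimConfig}.
#' @param outPrefix when non-NULL, files `<outPrefix>_1.fq.gz`,
#'   `<outPrefix>_2.fq.gz`, `<outPrefix>.truth.tsv` and
#'   `<outPrefix>.chrom.sizes` are written.
#' @return list with elements `reads1`, `reads2` (FASTQ tables), `truth`
#'   (data.frame `read_id chrom1 pos1 chrom2 pos2 is_chimeric`), `chromOrder`,
#'   and when written, the file paths `fq1`, `fq2`, `truthFile`,
#'   `chromSizesFile`.
#' @examples
#' g <- randomGenome(c(chrA = 60000, chrB = 40000), seed = 3)
#' sim <- simulateDataset(g, SimConfig(nPairs = 50, insertMean = 250, seed = 7))
#' head(sim$truth)
#' @export
simulateDataset <- function(genome, config, outPrefix = NULL) {
    stopifnot(methods::is(config, "SimConfig"))
    methods::validObject(config)
    genome <- loadGenome(genome)
    chromStr <- as.character(genome)
    L <- Biostrings::width(genome)
    n <- config@nPairs
    if (n < 1L) stop("nPairs must be >= 1")
    rl <- config@readLength
    minArm <- 20L
    ceilIns <- 2L * rl + 400L
    eligible <- which(L >= ceilIns)
    if (!length(eligible))
        stop("no chromosome is at least the insert ceiling (",
             ceilIns, " bp) long")
    restriction <- config@mode == "restriction"
    cuts <- if (restriction) digestReference(genome, config) else NULL

    set.seed(config@seed)
    ## fixed draw order: all per-molecule variates are drawn up front
    chim <- stats::runif(n) < config@junctionFraction
    len <- round(stats::rnorm(n, config@insertMean, config@insertSd))
    bad <- len < 2L * minArm | len > ceilIns
    while (any(bad)) {
        len[bad] <- round(stats::rnorm(sum(bad), config@insertMean,
                                       config@insertSd))
        bad <- len < 2L * minArm | len > ceilIns
    }
    chromA <- eligible[sample.int(length(eligible), n, replace = TRUE,
                                  prob = L[eligible])]
    posA <- floor(stats::runif(n) * L[chromA]) + 1
    trans <- chim & stats::runif(n) < config@transFraction &
        length(eligible) > 1L
    uB <- stats::runif(n)
    dU <- stats::runif(n)
    signU <- stats::runif(n) < 0.5
    armU <- stats::runif(n)
    sideAU <- stats::runif(n) < 0.5
    sideBU <- stats::runif(n) < 0.5

    ## partner locus
    chromB <- chromA
    if (any(trans)) {
        others <- lapply(seq_along(genome), function(i)
            eligible[eligible != i])
        k <- lengths(others)[chromA[trans]]
        pick <- floor(uB[trans] * k) + 1L
        chromB[trans] <- mapply(function(ci, p) others[[ci]][p],
                                chromA[trans], pick)
        posB <- posA
        posB[trans] <- floor(dU[trans] * L[chromB[trans]]) + 1
    } else posB <- posA
    cis <- chim & !trans
    if (any(cis)) {
        dmax <- pmin(config@cisRange[2], L[chromA[cis]] - 1)
        dmin <- pmin(config@cisRange[1], dmax)
        d <- sampleCisDistance(dU[cis], config@cisDecayExponent, dmin, dmax)
        s <- ifelse(signU[cis], 1, -1)
        p <- posA[cis] + s * d
        flip <- p < 1 | p > L[chromA[cis]]
        p[flip] <- posA[cis][flip] - (s * d)[flip]
        posB[cis] <- pmin(pmax(p, 1), L[chromA[cis]])
    }
    if (restriction) {
        posA[chim] <- snapToCuts(chromA[chim], posA[chim], cuts)
        posB[chim] <- snapToCuts(chromB[chim], posB[chim], cuts)
    }

    ## arms (chimeric) / fragment (non-chimeric)
    armA <- minArm + floor(armU * (len - 2L * minArm + 1))
    armA <- pmin(armA, len - minArm)
    armB <- len - armA

    insert <- character(n)
    if (any(chim)) {
        i <- which(chim)
        cA <- posA[i]; cB <- posB[i]
        lA <- L[chromA[i]]; lB <- L[chromB[i]]
        aA <- armA[i]; aB <- armB[i]
        ## arm A runs INTO cut A: either the upstream side read forward, or
        ## the downstream side reverse-complemented; room clamps arm length
        upOkA <- cA - aA >= 1
        dnOkA <- cA + aA - 1 <= lA
        useUpA <- ifelse(upOkA & dnOkA, sideAU[i], upOkA)
        aA <- ifelse(useUpA, pmin(aA, cA - 1), pmin(aA, lA - cA + 1))
        aA <- pmax(aA, 1)
        armAseq <- character(length(i))
        up <- useUpA
        armAseq[up] <- substring(chromStr[chromA[i][up]],
                                 cA[up] - aA[up], cA[up] - 1)
        if (any(!up))
            armAseq[!up] <- revComp(substring(chromStr[chromA[i][!up]],
                                              cA[!up], cA[!up] + aA[!up] - 1))
        ## arm B runs OUT of cut B: forward from the cut, or the upstream
        ## side reverse-complemented
        fwOkB <- cB + aB - 1 <= lB
        rvOkB <- cB - aB >= 1
        useFwB <- ifelse(fwOkB & rvOkB, sideBU[i], fwOkB)
        aB <- ifelse(useFwB, pmin(aB, lB - cB + 1), pmin(aB, cB - 1))
        aB <- pmax(aB, 1)
        armBseq <- character(length(i))
        fw <- useFwB
        armBseq[fw] <- substring(chromStr[chromB[i][fw]],
                                 cB[fw], cB[fw] + aB[fw] - 1)
        if (any(!fw))
            armBseq[!fw] <- revComp(substring(chromStr[chromB[i][!fw]],
                                              cB[!fw] - aB[!fw], cB[!fw] - 1))
        insert[i] <- paste0(armAseq, armBseq)
        ## truth loci are the cut sites (clamped into chromosome bounds: the
        ## terminal cut L+1 is virtual)
        posA[i] <- pmin(cA, lA)
        posB[i] <- pmin(cB, lB)
    }
    if (any(!chim)) {
        i <- which(!chim)
        s0 <- posA[i]
        if (restriction) s0 <- snapToCuts(chromA[i], s0, cuts)
        s0 <- pmin(pmax(s0, 1), L[chromA[i]] - len[i] + 1)
        insert[i] <- substring(chromStr[chromA[i]], s0, s0 + len[i] - 1)
        posA[i] <- s0
        chromB[i] <- chromA[i]
        posB[i] <- s0 + len[i] - 1
    }

    lenAct <- nchar(insert)
    read1 <- substring(insert, 1, pmin(rl, lenAct))
    read2 <- revComp(substring(insert, pmax(1, lenAct - rl + 1), lenAct))
    read1 <- injectErrors(read1, config@errorRate)
    read2 <- injectErrors(read2, config@errorRate)
    qch <- rawToChar(as.raw(config@baseQuality + 33L))
    qual1 <- strrep(qch, nchar(read1))
    qual2 <- strrep(qch, nchar(read2))
    ids <- sprintf("SIM%07d", seq_len(n))

    ## PCR duplicates: re-emitted immediately after the original, new id,
    ## same truth loci
    dup <- stats::runif(n) < config@duplicateFraction
    ord <- rep(seq_len(n), times = 1L + dup)
    isDup <- duplicated(ord)
    outIds <- ids[ord]
    outIds[isDup] <- paste0(outIds[isDup], "D")

    truth <- data.frame(read_id = outIds,
                        chrom1 = names(genome)[chromA[ord]],
                        pos1 = posA[ord],
                        chrom2 = names(genome)[chromB[ord]],
                        pos2 = posB[ord],
                        is_chimeric = chim[ord])
    reads1 <- data.frame(id = outIds, seq = read1[ord], qual = qual1[ord])
    reads2 <- data.frame(id = outIds, seq = read2[ord], qual = qual2[ord])

    res <- list(reads1 = reads1, reads2 = reads2, truth = truth,
                chromOrder = ChromOrder(names(genome), L))
    if (!is.null(outPrefix)) {
        res$fq1 <- writeFastq(reads1, paste0(outPrefix, "_1.fq.gz"))
        res$fq2 <- writeFastq(reads2, paste0(outPrefix, "_2.fq.gz"))
        res$truthFile <- paste0(outPrefix, ".truth.tsv")
        utils::write.table(truth, res$truthFile, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        res$chromSizesFile <- writeChromSizes(res$chromOrder,
                                              paste0(outPrefix, ".chrom.sizes"))
    }
    res
}
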