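## Shared low-level helpers: sequence ops, FASTQ/FASTA/chrom-sizes I/O.

#' Reverse-complement character sequences
#'
#' Vectorised reverse complement of plain character DNA sequences.
#'
#' @param x character vector of A/C/G/T/N sequences.
#' @return character vector of reverse complements.
#' @examples
#' revComp(c("GATC", "AAAC"))
#' @export
revComp <- function(x) {
    if (!length(x)) return(character())
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## reverse a plain character string (for qualities)
revString <- function(x) {
    vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file, plain or gzip.
#' @return data.frame with columns `id`, `seq`, `qual`. The id is the text
#'   between `@` and the first whitespace.
#' @export
readFastq <- function(path) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    lines <- readLines(con)
    if (length(lines) %% 4L != 0L)
        stop("truncated FASTQ file: ", path)
    n <- length(lines) %/% 4L
    idx <- seq_len(n) * 4L - 3L
    ids <- sub("\\s.*$", "", sub("^@", "", lines[idx]))
    data.frame(id = ids, seq = lines[idx + 1L], qual = lines[idx + 3L])
}

#' Write a read table to FASTQ
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path output path; a `.gz` suffix selects gzip compression.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    if (nrow(reads))
        writeLines(as.vector(rbind(paste0("@", reads$id), reads$seq, "+",
                                   reads$qual)), con)
    invisible(path)
}

#' Load a reference genome
#'
#' Accepts a FASTA path or an existing `DNAStringSet` and returns an
#' uppercase `DNAStringSet` whose order defines genome-wide coordinate
#' ranking. FASTA ids are truncated at the first whitespace.
#'
#' @param genome FASTA file path or `Biostrings::DNAStringSet`.
#' @return named `DNAStringSet`.
#' @export
loadGenome <- function(genome) {
    if (is.character(genome))
        genome <- Biostrings::readDNAStringSet(genome)
    if (!methods::is(genome, "DNAStringSet"))
        stop("genome must be a FASTA path or a DNAStringSet")
    if (!length(genome)) stop("genome is empty")
    names(genome) <- sub("\\s.*$", "", names(genome))
    if (anyDuplicated(names(genome))) stop("duplicate chromosome names")
    genome
}

#' Chromosome order from a genome or chrom-sizes file
#'
#' @param genome FASTA path or `DNAStringSet`.
#' @return a \linkS4class{ChromOrder} in genome order.
#' @export
genomeChromOrder <- function(genome) {
    genome <- loadGenome(genome)
    ChromOrder(names(genome), Biostrings::width(genome))
}

#' Read / write a chrom-sizes table
#'
#' Standard two-column (name, length) tab-separated table without header;
#' row order is the chromosome order authority.
#'
#' @param path chrom-sizes file.
#' @return `readChromSizes()` returns a \linkS4class{ChromOrder}.
#' @export
readChromSizes <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("name", "length"),
                             colClasses = c("character", "numeric"))
    ChromOrder(tab$name, tab$length)
}

#' @param x a \linkS4class{ChromOrder}.
#' @rdname readChromSizes
#' @return `writeChromSizes()` returns `path`, invisibly.
#' @export
writeChromSizes <- function(x, path) {
    utils::write.table(data.frame(seqNames(x), format(x@seqlengths,
                                                      scientific = FALSE,
                                                      trim = TRUE)),
                       path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

## format positions without scientific notation
fmtPos <- function(x) format(x, scientific = FALSE, trim = TRUE)
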