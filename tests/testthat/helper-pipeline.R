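## One full-scale simulated run, shared by the acceptance-level tests.
## 1.5 Mb random genome, 50,000 PE150 pairs, restriction mode (GATC),
## insert 300 +/- 50, error rate 0.001 -- the simulator's study conditions.

.sp_cache <- new.env(parent = emptyenv())

fullScaleRun <- function() {
    if (!is.null(.sp_cache$full)) return(.sp_cache$full)
    dir <- file.path(tempdir(), "sp-fullscale")
    dir.create(dir, showWarnings = FALSE)
    genome <- randomGenome(c(chr1 = 900000, chr2 = 600000), seed = 7)
    ref <- file.path(dir, "ref.fa")
    Biostrings::writeXStringSet(genome, ref)
    sim <- simulateDataset(genome, SimConfig(nPairs = 50000L, seed = 1234L),
                           file.path(dir, "sim"))
    run <- runPipeline(sim$fq1, sim$fq2, ref, file.path(dir, "run"))
    .sp_cache$full <- list(dir = dir, genome = genome, ref = ref,
                           sim = sim, run = run)
    .sp_cache$full
}
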