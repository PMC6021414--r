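# Shared fixtures: tiny in-memory references and a mid-sized synthetic
# circular genome, built in code at test time.

toyRef <- function(seq = "ATCGA", circular = TRUE) {
    mitoReference(seq, circular = circular)
}

# mitochondrial-scale synthetic circular reference (cached per session)
mtRef <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) cache <<- simulateReference(16569L, seed = 7L)
        cache
    }
})

# small reference + region for fast pipeline-level tests
smallRef <- function(len = 1200L, seed = 42L) simulateReference(len, seed = seed)

# printed per-read load table rows (D-loop-ND1 amplicon)
tab1Row1300 <- function() {
    histogramFromCounts(
        c("0 to 3" = 2382107, "4" = 8, "5" = 8, "6" = 4, "7" = 2,
          "8" = 0, "10" = 1, "22" = 0),
        libraryId = "CIN1_1300")
}

tab1RowPlasmid <- function() {
    histogramFromCounts(
        c("0 to 3" = 2423061, "4" = 0, "5" = 0, "6" = 0, "7" = 0,
          "8" = 0, "10" = 0, "22" = 0),
        libraryId = "plasmid")
}

# run the calling stage (align -> consensus -> calls -> loads) on a library
callStage <- function(lib, ref, minFraction = 0.8, minDepth = 10L,
                      downsample = Inf) {
    al <- alignReads(lib, ref)
    if (is.finite(downsample)) al <- downsampleReads(al, downsample)
    cons <- buildConsensus(al, ref, minFraction = minFraction,
                           minDepth = minDepth)
    calls <- callMutations(al, cons, ref)
    list(aligned = al, consensus = cons, calls = calls,
         loads = readLoads(al, calls))
}
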