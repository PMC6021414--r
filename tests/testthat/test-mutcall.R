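# hand-built fixture: consensus over a small region plus a few reads
.fixtureCons <- function(ref, reg) {
    win <- extractRegion(ref, reg)
    new("ConsensusSequence", seq = win, region = reg, nReadsUsed = 10L,
        minFraction = 0.8, minDepth = 10L,
        columnStats = data.frame(ref_pos = regionPositions(ref, reg),
                                 depth = 10L, modal_fraction = 1))
}

.fixtureAligned <- function(ids, starts, seqs, reg) {
    new("AlignedReads", ids = ids, starts = as.integer(starts), seqs = seqs,
        mismatches = rep(0L, length(ids)), region = reg,
        rejected = data.frame())
}

test_that("calls are emitted per mismatching non-N position", {
    ref <- toyRef("AACGTT")
    reg <- genomeRegion(1, 6)
    cons <- .fixtureCons(ref, reg)      # AACGTT
    al <- .fixtureAligned(c("same", "ct", "masked"), c(1, 1, 1),
                          c("AACGTT", "AATGTT", "AANGTT"), reg)
    calls <- callMutations(al, cons, ref)
    expect_identical(nrow(calls), 1L)
    expect_identical(calls$read_id, "ct")
    expect_identical(calls$position, 3L)
    expect_identical(calls$klass, "C>T")
    expect_true(calls$is_ct_ga)
    expect_identical(calls$context, "ApC")

    # N in the consensus masks the column for every read
    consN <- cons
    consN@seq <- "AANGTT"
    callsN <- callMutations(al, consN, ref)
    expect_identical(nrow(callsN), 0L)
})

test_that("G->A calls carry the complement-strand context", {
    ref <- toyRef("AACGTT")
    reg <- genomeRegion(1, 6)
    cons <- .fixtureCons(ref, reg)
    al <- .fixtureAligned("ga", 1, "AACATT", reg)
    calls <- callMutations(al, cons, ref)
    expect_identical(calls$klass, "G>A")
    expect_true(calls$is_ct_ga)
    # 5' neighbour on the complement strand = complement of T at pos 5
    expect_identical(calls$context, "ApC")
    # non-deamination substitutions are recorded without context
    al2 <- .fixtureAligned("cg", 1, "AAGGTT", reg)
    calls2 <- callMutations(al2, cons, ref)
    expect_identical(calls2$klass, "C>G")
    expect_false(calls2$is_ct_ga)
    expect_true(is.na(calls2$context))
})

test_that("histograms bin reads by deamination-type load only", {
    loads <- c(a = 0, b = 0, c = 1, d = 4, e = 4)
    h <- buildHistogram(loads, "toy")
    expect_identical(unname(loadCounts(h)), c(2, 1, 2))
    expect_identical(names(loadCounts(h)), c("0", "1", "4"))
    expect_identical(totalReads(h), 5)

    h0 <- buildHistogram(integer(0), "empty")
    expect_identical(totalReads(h0), 0)

    ref <- smallRef()
    cfg <- simulationConfig(genomeRegion(1, 500), nReads = 60,
                            readLength = 100, pHyper = 0, errorRate = 0,
                            seed = 2)
    st <- callStage(simulateLibrary(cfg, ref), ref, minDepth = 5)
    h2 <- buildHistogram(st$loads, "clean")
    expect_identical(loadCounts(h2), c("0" = 60))

    # non-deamination substitutions never contribute to the load
    reg <- genomeRegion(1, 6)
    ref2 <- toyRef("AACGTT")
    cons <- .fixtureCons(ref2, reg)
    al <- .fixtureAligned("cg", 1, "AAGGTT", reg)
    calls <- callMutations(al, cons, ref2)
    expect_identical(unname(readLoads(al, calls)), 0L)
})

test_that("threshold calibration finds the smallest clean k", {
    expect_identical(threshold(calibrateThreshold(
        histogramFromCounts(c("0" = 100)))), 1L)
    expect_identical(threshold(calibrateThreshold(
        histogramFromCounts(c("0" = 90, "5" = 10)))), 6L)
    expect_identical(threshold(calibrateThreshold(
        histogramFromCounts(c("0" = 90, "5" = 10)), alpha = 10)), 1L)
    # printed plasmid row: lumped 0-3 mass, zero beyond -> k = 4
    cal <- calibrateThreshold(tab1RowPlasmid(), alpha = 0)
    expect_identical(threshold(cal), 4L)
    expect_identical(cal@controlId, "plasmid")
    expect_error(calibrateThreshold(histogramFromCounts(c("0" = 0))),
                 "empty")
    # Poisson mean on a full-resolution histogram
    cal2 <- calibrateThreshold(histogramFromCounts(c("0" = 50, "1" = 40,
                                                     "2" = 10)))
    expect_equal(cal2@lambdaHat, 0.6)
})

test_that("flagging reproduces brute-force per-read counting", {
    ref <- smallRef()
    cfg <- simulationConfig(genomeRegion(1, 1000), nReads = 1000,
                            readLength = 150, pHyper = 0.05,
                            errorRate = 1e-3, seed = 17)
    st <- callStage(simulateLibrary(cfg, ref), ref, minDepth = 5)
    # brute force: count C->T/G->A calls per read straight off the call table
    brute <- vapply(names(st$loads), function(id) {
        sub <- st$calls[st$calls$read_id == id, , drop = FALSE]
        sum((sub$ref_base == "C" & sub$alt_base == "T") |
            (sub$ref_base == "G" & sub$alt_base == "A"))
    }, 0L)
    expect_identical(unname(st$loads), unname(brute))
    for (k in 1:5) {
        cs <- flagHypermutated(st$loads, k)
        expect_identical(sort(hyperReadIds(cs)), sort(names(brute)[brute >= k]))
        expect_equal(cs@nHyper, sum(brute >= k))
    }
    # histogram route agrees with the per-read route
    h <- buildHistogram(st$loads, "sim")
    expect_identical(flagHypermutated(h, 4)@nHyper,
                     flagHypermutated(st$loads, 4)@nHyper)
    expect_identical(totalReads(h), sum(unname(loadCounts(h))))
})

test_that("ppm frequencies follow the printed-table arithmetic", {
    cs <- flagHypermutated(tab1Row1300(), 4)
    expect_identical(cs@nHyper, 23)
    expect_identical(totalReads(cs), 2382130)
    expect_equal(round(frequencyPpm(cs), 2), 9.66)

    tiny <- flagHypermutated(c(a = 0, b = 4), 4)
    expect_equal(frequencyPpm(tiny), 500000)
    expect_identical(hyperReadIds(tiny), "b")

    none <- flagHypermutated(c(a = 0, b = 4), 5)
    expect_identical(none@nHyper, 0)
    empty <- flagHypermutated(setNames(numeric(0), character(0)), 4)
    expect_true(is.na(frequencyPpm(empty)))
    expect_error(flagHypermutated(tab1Row1300(), 2), "lumped")
})

test_that("error-only loads are Poisson-like and decay log-linearly", {
    ref <- mtRef()
    reg <- genomeRegion(16331, 3729)
    eps <- 3e-3
    cfg <- simulationConfig(reg, nReads = 30000, readLength = 250,
                            pHyper = 0, errorRate = eps, seed = 23)
    lib <- simulateLibrary(cfg, ref)
    st <- callStage(lib, ref)
    # expected mean load: per-read (nC + nG) * eps / 3 over true windows
    offs <- readOffsets(lib)
    posv <- regionPositions(ref, reg)
    local <- match(offs, posv)
    win <- extractRegion(ref, reg)
    cg <- cumsum(strsplit(win, "")[[1]] %in% c("C", "G"))
    nCG <- cg[local + 249L] - c(0, cg)[local]
    expMean <- mean(nCG) * eps / 3
    se <- sd(st$loads) / sqrt(length(st$loads))
    expect_lt(abs(mean(st$loads) - expMean), 3 * se + 1e-4)
    # exponential decay of the control histogram over occupied bins
    h <- loadCounts(buildHistogram(st$loads, "ctrl"))
    occ <- h[h > 0]
    expect_gte(length(occ), 3)
    expect_true(all(diff(occ) < 0))
    fit <- lm(log(occ) ~ as.numeric(names(occ)))
    expect_lt(coef(fit)[2], -1)
    expect_gt(summary(fit)$r.squared, 0.9)
})

test_that("haplotype exclusion removes reads closer to a known sequence", {
    ref <- smallRef()
    reg <- genomeRegion(1, 200)
    cons <- .fixtureCons(ref, reg)
    win <- extractRegion(ref, reg)
    # read: 5 substitutions vs consensus, identical to haplotype H1
    hap <- win
    for (p in c(10, 30, 50, 70, 90)) {
        substr(hap, p, p) <- setdiff(c("A", "C", "G", "T"),
                                     substr(hap, p, p))[1]
    }
    al <- .fixtureAligned("r1", 1, substr(hap, 1, 200), reg)
    haps <- c(H1 = hap, H2 = win)
    out <- haplotypeFilter(al, "r1", cons, ref, haps)
    expect_false(out$keep)
    expect_identical(out$best_haplotype, "H1")
    expect_identical(out$dist_consensus, 5L)
    expect_identical(out$dist_best_haplotype, 0L)

    # empty database keeps everything
    out2 <- haplotypeFilter(al, "r1", cons, ref, character(0))
    expect_true(out2$keep)

    # equal distances keep the read (tie rule)
    mix <- win
    for (p in c(10, 30, 50, 70, 90)) {
        substr(mix, p, p) <- setdiff(c("A", "C", "G", "T"),
                                     substr(mix, p, p))[1]
    }
    other <- win
    for (p in c(11, 31, 51, 71, 91, 111, 131, 151, 171, 191)) {
        substr(other, p, p) <- setdiff(c("A", "C", "G", "T"),
                                       substr(other, p, p))[1]
    }
    al3 <- .fixtureAligned("r3", 1, substr(mix, 1, 200), reg)
    out3 <- haplotypeFilter(al3, "r3", cons, ref, c(HX = mix))
    expect_false(out3$keep)            # strictly closer haplotype
    out4 <- haplotypeFilter(al3, "r3", cons, ref, c(HY = other))
    # 5 vs consensus, 15 vs HY -> keep
    expect_true(out4$keep)
    # short record covering nothing -> kept with warning
    expect_warning(
        out5 <- haplotypeFilter(al3, "r3", cons, ref, c(HS = "ACGT")),
        "covers")
    expect_true(out5$keep)
})

test_that("malformed haplotype FASTA is rejected", {
    fa <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">H1", "ACGTX"), fa)
    expect_error(loadHaplotypes(fa), "malformed")
    writeLines(c(">H1", "acgt", ">H2", "ggcc"), fa)
    h <- loadHaplotypes(fa)
    expect_identical(unname(h), c("ACGT", "GGCC"))
})
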