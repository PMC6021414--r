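#' @include AllClasses.R spectrum.R
NULL

#' Compare a consensus with a reference standard
#'
#' Lists every position where a called consensus base differs from the
#' standard (e.g. the rCRS), rendered in the conventional
#' `<standard base><position><consensus base>` notation. Consensus N columns
#' are not comparable and are only counted.
#'
#' @param consensus A [ConsensusSequence].
#' @param standard A [MitoReference] sharing the consensus coordinate
#'   system.
#' @param region Region to resolve in standard coordinates; defaults to the
#'   consensus region.
#' @return A [VariantReport], positions strictly increasing.
#' @export
compareToStandard <- function(consensus, standard, region = NULL) {
    if (is.null(region)) region <- consensus@region
    win <- extractRegion(standard, region)
    if (nchar(win) != nchar(consensus@seq))
        stop(sprintf("length mismatch: consensus %d nt vs standard window %d nt",
                     nchar(consensus@seq), nchar(win)))
    u <- utf8ToInt(consensus@seq)
    w <- utf8ToInt(win)
    posv <- .regionPositions(standard, region)
    nN <- sum(u == .N_INT)
    d <- which(u != w & u != .N_INT & w != .N_INT)
    cons <- strsplit(intToUtf8(u[d]), "")[[1L]]
    std <- strsplit(intToUtf8(w[d]), "")[[1L]]
    df <- data.frame(position = posv[d],
                     standard = if (length(d)) std else character(0),
                     consensus = if (length(d)) cons else character(0),
                     stringsAsFactors = FALSE)
    df <- df[order(df$position), , drop = FALSE]
    rownames(df) <- NULL
    df$label <- paste0(df$standard, df$position, df$consensus)
    new("VariantReport", variants = df, nPositionsN = nN)
}

#' Write a mutation-load histogram TSV mirroring the published tables
#'
#' Columns: `library`, a lumped `0 to 3` bin, then one column per occupied
#' load of 4 or more.
#'
#' @param hist A [MutationLoadHistogram].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
writeHistogramTsv <- function(hist, path) {
    b <- .histBins(hist)
    low <- sum(hist@counts[b$isLump | (!b$isLump & b$load <= 3L)])
    hiIdx <- which(!b$isLump & b$load >= 4L)
    bins <- c("0 to 3", names(hist@counts)[hiIdx])
    vals <- c(low, hist@counts[hiIdx])
    df <- as.data.frame(as.list(c(library = hist@libraryId,
                                  stats::setNames(vals, bins))),
                        check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a mutation-load histogram TSV
#'
#' Accepts the shape written by [writeHistogramTsv()] (and hence the
#' published tables): a `library` column plus load-bin columns, one of which
#' may be lumped (`"0 to 3"`).
#'
#' @param path TSV file; the first data row is used.
#' @return A [MutationLoadHistogram].
#' @export
readHistogramTsv <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (!nrow(df))
        stop("empty histogram table: ", path)
    if (!"library" %in% names(df))
        stop("histogram table needs a 'library' column: ", path)
    row <- df[1L, , drop = FALSE]
    bins <- setdiff(names(df), "library")
    counts <- as.numeric(row[1L, bins])
    names(counts) <- bins
    histogramFromCounts(counts, libraryId = as.character(row$library))
}

# ---- pipeline -------------------------------------------------------------

.cfgGet <- function(cfg, key, default = NULL, required = FALSE) {
    v <- cfg[[key]]
    if (is.null(v)) {
        if (required) stop("config key missing: ", key)
        return(default)
    }
    v
}

.resolveReference <- function(spec, what = "reference") {
    if (is.null(spec)) stop("config key missing: ", what)
    circular <- !identical(spec$circular, FALSE)
    if (!is.null(spec$fasta))
        return(loadReference(spec$fasta, circular = circular))
    if (!is.null(spec$synthetic)) {
        s <- spec$synthetic
        return(simulateReference(
            length = .cfgGet(s, "length", 16569L),
            seed = .cfgGet(s, "seed", 1L),
            circular = circular))
    }
    stop("config key missing: ", what, ".fasta (or ", what, ".synthetic)")
}

.simConfigFromList <- function(s, region, defaultSeed) {
    w <- .cfgGet(s, "context_weights",
                 c(TpC = 0.7, CpC = 0.25, ApC = 0.025, GpC = 0.025))
    simulationConfig(
        region = region,
        nReads = .cfgGet(s, "n_reads", required = TRUE),
        readLength = .cfgGet(s, "read_length", 250L),
        pHyper = .cfgGet(s, "p_hyper", 0),
        strand = .cfgGet(s, "strand", "complement"),
        contextWeights = unlist(w),
        errorRate = .cfgGet(s, "error_rate", 1e-4),
        seed = .cfgGet(s, "seed", defaultSeed))
}

# align/downsample/consensus/call for one reads-backed library
.callStage <- function(lib, ref, region, params, libSeed) {
    if (is(lib, "ReadLibrary")) {
        aligned <- alignReads(lib, ref,
            maxMismatchFraction = params$max_mismatch_fraction)
        nInput <- length(lib)
    } else {
        aligned <- alignReads(lib, ref, region = region,
            maxMismatchFraction = params$max_mismatch_fraction)
        nInput <- nrow(lib)
    }
    nAligned <- length(aligned)
    aligned <- downsampleReads(aligned, params$downsample, seed = libSeed)
    consensus <- buildConsensus(aligned, ref,
        minFraction = params$min_fraction, minDepth = params$min_depth)
    calls <- callMutations(aligned, consensus, ref)
    loads <- readLoads(aligned, calls)
    list(nInput = nInput, nAligned = nAligned,
         nRejected = nrow(aligned@rejected), aligned = aligned,
         consensus = consensus, calls = calls, loads = loads)
}

#' Run the full hypermutation-detection pipeline from a config
#'
#' Orchestrates, per library: alignment, downsampling, N-masked consensus,
#' mutation calling, control-calibrated hypermutation flagging with ppm
#' frequency, optional haplotype exclusion of flagged reads, substitution
#' matrix and dinucleotide spectrum of the hypermutated reads, and a
#' consensus-vs-standard variant report. All tabular outputs plus a
#' machine-readable `summary.json` are written under `outDir`. Deterministic
#' given the config (all seeds derive from the config seed).
#'
#' The config (YAML/JSON file or an equivalent nested list) names the
#' reference (`fasta` or `synthetic`), the `region` (`"START-END"`, wrap
#' permitted on a circular reference), a `control` and `libraries` (each
#' either a `simulate` block, a `reads` FASTA with `offset=` headers, or a
#' pre-computed `histogram` TSV), optional `haplotypes` and `standard`
#' FASTAs, and `params` (`min_fraction`, `min_depth`, `downsample`, `alpha`
#' or fixed `k`, `max_mismatch_fraction`).
#'
#' @param config Path to a YAML/JSON config, or a nested list.
#' @param outDir Output directory (created; must not already contain a
#'   `summary.json`).
#' @return The summary, invisibly (also written as `summary.json`).
#' @export
runPipeline <- function(config, outDir) {
    if (is.character(config)) {
        config <- if (grepl("\\.json$", config, ignore.case = TRUE))
            jsonlite::read_json(config, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE,
                                simplifyMatrix = FALSE)
        else yaml::read_yaml(config)
    }
    if (!is.list(config)) stop("config must be a file path or a list")
    if (file.exists(file.path(outDir, "summary.json")))
        stop("output directory already contains a summary.json: ", outDir)
    createdDir <- !dir.exists(outDir)
    ok <- FALSE
    on.exit({
        if (!ok && createdDir) unlink(outDir, recursive = TRUE)
    }, add = TRUE)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

    seed <- .cfgGet(config, "seed", 1L)
    ref <- .resolveReference(.cfgGet(config, "reference", required = TRUE))
    region <- parseRegion(.cfgGet(config, "region", required = TRUE))
    p0 <- .cfgGet(config, "params", list())
    params <- list(
        min_fraction = .cfgGet(p0, "min_fraction", 0.8),
        min_depth = .cfgGet(p0, "min_depth", 10L),
        downsample = .cfgGet(p0, "downsample", 100000L),
        alpha = .cfgGet(p0, "alpha", 0),
        k = .cfgGet(p0, "k", NULL),
        max_mismatch_fraction = .cfgGet(p0, "max_mismatch_fraction", 0.1))

    haplotypes <- character(0)
    if (!is.null(config$haplotypes))
        haplotypes <- loadHaplotypes(config$haplotypes)
    standard <- if (!is.null(config$standard))
        .resolveReference(config$standard, "standard") else NULL

    loadLibrary <- function(spec, idx) {
        id <- .cfgGet(spec, "id", required = TRUE)
        libSeed <- .childSeed(seed, 1000000 + idx)
        if (!is.null(spec$histogram)) {
            h <- readHistogramTsv(spec$histogram)
            h@libraryId <- id
            return(list(id = id, mode = "histogram", hist = h))
        }
        if (!is.null(spec$simulate)) {
            sc <- .simConfigFromList(spec$simulate, region, libSeed)
            lib <- simulateLibrary(sc, ref)
            return(list(id = id, mode = "simulate", lib = lib,
                        seed = sc@seed))
        }
        if (!is.null(spec$reads)) {
            rl <- readLibraryFile(spec$reads)
            df <- data.frame(read_id = rl$ids,
                             offset = if (is.null(rl$offsets)) NA_integer_
                                      else rl$offsets,
                             sequence = rl$reads, stringsAsFactors = FALSE)
            return(list(id = id, mode = "reads", lib = df, seed = libSeed))
        }
        stop("config key missing: libraries[", idx,
             "] needs one of 'simulate', 'reads', 'histogram'")
    }

    runOne <- function(entry, k, writeOutputs = TRUE) {
        dirLib <- file.path(outDir, entry$id)
        if (writeOutputs)
            dir.create(dirLib, recursive = TRUE, showWarnings = FALSE)
        if (entry$mode == "histogram") {
            hist <- entry$hist
            cs <- flagHypermutated(hist, k)
            if (writeOutputs)
                writeHistogramTsv(hist, file.path(dirLib, "histogram.tsv"))
            return(list(
                library = entry$id, mode = entry$mode,
                total_reads = totalReads(hist), n_hyper = cs@nHyper,
                frequency_ppm = round(frequencyPpm(cs), 2), k_used = k))
        }
        st <- .callStage(entry$lib, ref, region, params, entry$seed)
        hist <- buildHistogram(st$loads, libraryId = entry$id)
        cs <- flagHypermutated(st$loads, k)
        excluded <- data.frame()
        keptIds <- hyperReadIds(cs)
        if (length(haplotypes) && length(keptIds)) {
            hf <- haplotypeFilter(st$aligned, keptIds, st$consensus, ref,
                                  haplotypes)
            excluded <- hf[!hf$keep, , drop = FALSE]
            keptIds <- hf$read_id[hf$keep]
        }
        nHyper <- length(keptIds)
        ppm <- if (length(st$loads)) nHyper / length(st$loads) * 1e6
               else NA_real_
        hyperCalls <- st$calls[st$calls$read_id %in% keptIds, , drop = FALSE]
        mat <- mutationMatrix(hyperCalls)
        sb <- strandBias(mat)
        spec <- if (sum(hyperCalls$is_ct_ga) > 0)
            dinucleotideSpectrum(hyperCalls, ref, region) else NULL
        vr <- if (!is.null(standard))
            compareToStandard(st$consensus, standard) else NULL

        if (writeOutputs) {
            consSet <- Biostrings::DNAStringSet(consensusSeq(st$consensus))
            names(consSet) <- sprintf("%s_consensus %d-%d", entry$id,
                                      region@start, region@end)
            Biostrings::writeXStringSet(
                consSet, file.path(dirLib, "consensus.fasta"))
            utils::write.table(columnStats(st$consensus),
                file.path(dirLib, "consensus_columns.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
            writeHistogramTsv(hist, file.path(dirLib, "histogram.tsv"))
            callsOut <- st$calls
            utils::write.table(callsOut, file.path(dirLib, "calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
            loadsOut <- data.frame(read_id = names(st$loads),
                                   load = as.integer(st$loads),
                                   flagged = names(st$loads) %in% keptIds)
            utils::write.table(loadsOut, file.path(dirLib, "read_loads.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
            utils::write.table(as.data.frame.table(mat, responseName = "count"),
                file.path(dirLib, "mutation_matrix.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
            if (!is.null(spec)) {
                utils::write.table(
                    data.frame(context = .CTX_KEYS,
                               observed = spec@observed[.CTX_KEYS],
                               expected_fraction =
                                   spec@expectedFraction[.CTX_KEYS]),
                    file.path(dirLib, "spectrum.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
                jsonlite::write_json(
                    list(chi2_tpc = spec@chi2Tpc, p_tpc = spec@pTpc,
                         chi2_cpc = spec@chi2Cpc, p_cpc = spec@pCpc,
                         n_calls = spec@nCalls,
                         n_dropped_context = spec@nDroppedContext),
                    file.path(dirLib, "spectrum_stats.json"),
                    auto_unbox = TRUE, digits = NA)
            }
            if (!is.null(vr))
                utils::write.table(variantTable(vr),
                    file.path(dirLib, "variants.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        }
        list(library = entry$id, mode = entry$mode,
             total_reads = st$nInput, aligned = st$nAligned,
             rejected_unmapped = st$nRejected,
             reads_used = length(st$loads),
             n_hyper_before_haplotype_filter = cs@nHyper,
             excluded_by_haplotype = nrow(excluded),
             n_hyper = nHyper,
             frequency_ppm = if (is.na(ppm)) NA else round(ppm, 2),
             k_used = k,
             strand_bias_ga_fraction = sb$biasFraction,
             p_tpc = if (is.null(spec)) NA else spec@pTpc,
             p_cpc = if (is.null(spec)) NA else spec@pCpc,
             n_variants = if (is.null(vr)) NA else nrow(variantTable(vr)),
             n_positions_N = if (is.null(vr)) NA else vr@nPositionsN)
    }

    # control first: it fixes k unless the config pins one
    calibration <- NULL
    k <- params$k
    ctrlSpec <- .cfgGet(config, "control")
    ctrlSummary <- NULL
    if (!is.null(ctrlSpec)) {
        entry <- loadLibrary(ctrlSpec, 0L)
        if (entry$mode == "histogram") {
            ctrlHist <- entry$hist
        } else {
            st <- .callStage(entry$lib, ref, region, params, entry$seed)
            ctrlHist <- buildHistogram(st$loads, libraryId = entry$id)
        }
        calibration <- calibrateThreshold(ctrlHist, alpha = params$alpha)
        if (is.null(k)) k <- threshold(calibration)
        ctrlDir <- file.path(outDir, entry$id)
        dir.create(ctrlDir, recursive = TRUE, showWarnings = FALSE)
        writeHistogramTsv(ctrlHist, file.path(ctrlDir, "histogram.tsv"))
        jsonlite::write_json(
            list(k = threshold(calibration), alpha = params$alpha,
                 lambda_hat = calibration@lambdaHat,
                 control = calibration@controlId),
            file.path(ctrlDir, "calibration.json"),
            auto_unbox = TRUE, digits = NA)
        ctrlSummary <- list(library = entry$id, mode = entry$mode,
                            total_reads = totalReads(ctrlHist))
    }
    if (is.null(k))
        stop("config key missing: either params.k or a control library ",
             "is required to fix the hypermutation threshold")
    k <- as.integer(k)

    libSpecs <- .cfgGet(config, "libraries", required = TRUE)
    if (!is.null(libSpecs$id)) libSpecs <- list(libSpecs)
    libSummaries <- lapply(seq_along(libSpecs), function(i)
        runOne(loadLibrary(libSpecs[[i]], i), k))

    summary <- list(
        software = "mitoHyperMut",
        version = as.character(utils::packageVersion("mitoHyperMut")),
        k_used = k,
        calibration = if (is.null(calibration)) NULL else list(
            k = threshold(calibration), alpha = calibration@alpha,
            lambda_hat = calibration@lambdaHat,
            control = calibration@controlId),
        control = ctrlSummary,
        libraries = libSummaries,
        config = config)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    ok <- TRUE
    invisible(summary)
}
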