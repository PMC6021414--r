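#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `refSeq()`/`isCircular()` for references, `reads()`/`readOffsets()`/
#' `truthLabels()` for simulated libraries, `consensusSeq()`/`columnStats()`
#' for consensus objects, `loadCounts()`/`totalReads()`/`libraryId()` for
#' histograms, `threshold()` for calibrations, `hyperReadIds()`/
#' `frequencyPpm()` for call sets and `variantTable()` for reports.
#'
#' @param x An object of the corresponding class.
#' @return The slot value (see each method).
#' @name accessors
#' @aliases refSeq isCircular reads readOffsets truthLabels consensusSeq
#'   columnStats loadCounts totalReads libraryId threshold hyperReadIds
#'   frequencyPpm variantTable
NULL

#' @rdname accessors
#' @export
setGeneric("refSeq", function(x) standardGeneric("refSeq"))
#' @rdname accessors
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))
#' @rdname accessors
#' @export
setGeneric("reads", function(x) standardGeneric("reads"))
#' @rdname accessors
#' @export
setGeneric("readOffsets", function(x) standardGeneric("readOffsets"))
#' @rdname accessors
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))
#' @rdname accessors
#' @export
setGeneric("consensusSeq", function(x) standardGeneric("consensusSeq"))
#' @rdname accessors
#' @export
setGeneric("columnStats", function(x) standardGeneric("columnStats"))
#' @rdname accessors
#' @export
setGeneric("loadCounts", function(x) standardGeneric("loadCounts"))
#' @rdname accessors
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))
#' @rdname accessors
#' @export
setGeneric("libraryId", function(x) standardGeneric("libraryId"))
#' @rdname accessors
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))
#' @rdname accessors
#' @export
setGeneric("hyperReadIds", function(x) standardGeneric("hyperReadIds"))
#' @rdname accessors
#' @export
setGeneric("frequencyPpm", function(x) standardGeneric("frequencyPpm"))
#' @rdname accessors
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))

#' Flag hypermutated reads at a load threshold
#'
#' @param x Named per-read loads (numeric) or a [MutationLoadHistogram].
#' @param k Integer threshold; reads with `>= k` C->T/G->A calls are flagged.
#' @return A [HypermutationCallSet].
#' @seealso [calibrateThreshold()]
#' @export
setGeneric("flagHypermutated", function(x, k) standardGeneric("flagHypermutated"))

setMethod("refSeq", "MitoReference", function(x) x@seq)
setMethod("isCircular", "MitoReference", function(x) x@circular)
setMethod("length", "MitoReference", function(x) nchar(x@seq))

setMethod("reads", "ReadLibrary", function(x) setNames(x@reads, x@ids))
setMethod("readOffsets", "ReadLibrary", function(x) setNames(x@offsets, x@ids))
setMethod("truthLabels", "ReadLibrary", function(x) x@truth)
setMethod("length", "ReadLibrary", function(x) length(x@ids))

setMethod("length", "AlignedReads", function(x) length(x@ids))

setMethod("consensusSeq", "ConsensusSequence", function(x) x@seq)
setMethod("columnStats", "ConsensusSequence", function(x) x@columnStats)

setMethod("loadCounts", "MutationLoadHistogram", function(x) x@counts)
setMethod("totalReads", "MutationLoadHistogram", function(x) x@totalReads)
setMethod("libraryId", "MutationLoadHistogram", function(x) x@libraryId)

setMethod("threshold", "ThresholdCalibration", function(x) x@k)

setMethod("hyperReadIds", "HypermutationCallSet", function(x) x@readIds)
setMethod("frequencyPpm", "HypermutationCallSet", function(x) x@frequencyPpm)
setMethod("totalReads", "HypermutationCallSet", function(x) x@totalReads)

setMethod("variantTable", "VariantReport", function(x) x@variants)

setMethod("show", "MitoReference", function(object) {
    cat(sprintf("MitoReference '%s': %d nt, %s\n", object@name, length(object),
                if (object@circular) "circular" else "linear"))
})

setMethod("show", "GenomeRegion", function(object) {
    cat(sprintf("GenomeRegion %d-%d%s\n", object@start, object@end,
                if (object@wraps) " (wraps origin)" else ""))
})

setMethod("show", "ReadLibrary", function(object) {
    cat(sprintf(
        "ReadLibrary: %d reads of %d nt, %d hypermutated (truth)\n",
        length(object), object@config@readLength,
        sum(object@truth$is_hypermutated)))
})

setMethod("show", "TmModel", function(object) {
    cat(sprintf("TmModel: Tm(m) = %.2f - %.4f * m degC\n",
                object@tm0, object@delta))
})

setMethod("show", "AlignedReads", function(object) {
    cat(sprintf("AlignedReads: %d mapped, %d rejected\n",
                length(object), nrow(object@rejected)))
})

setMethod("show", "ConsensusSequence", function(object) {
    cat(sprintf(
        "ConsensusSequence: %d nt, %d N (minFraction=%.2f, minDepth=%d, reads=%d)\n",
        nchar(object@seq),
        sum(utf8ToInt(object@seq) == utf8ToInt("N")),
        object@minFraction, object@minDepth, object@nReadsUsed))
})

setMethod("show", "MutationLoadHistogram", function(object) {
    cat(sprintf("MutationLoadHistogram '%s': %s reads\n", object@libraryId,
                format(object@totalReads, big.mark = ",")))
    print(object@counts)
})

setMethod("show", "ThresholdCalibration", function(object) {
    cat(sprintf(
        "ThresholdCalibration: k = %d (alpha = %g, lambda_hat = %.4g, control '%s')\n",
        object@k, object@alpha, object@lambdaHat, object@controlId))
})

setMethod("show", "HypermutationCallSet", function(object) {
    cat(sprintf(
        "HypermutationCallSet: %d / %s reads at k >= %d (%s ppm)\n",
        object@nHyper, format(object@totalReads, big.mark = ","),
        object@kUsed,
        if (is.na(object@frequencyPpm)) "NA"
        else sprintf("%.2f", object@frequencyPpm)))
})

setMethod("show", "DinucleotideSpectrum", function(object) {
    cat(sprintf("DinucleotideSpectrum: %d context-bearing calls\n",
                object@nCalls))
    df <- data.frame(observed = object@observed[.CTX_KEYS],
                     expected_fraction = object@expectedFraction[.CTX_KEYS])
    print(df)
    cat(sprintf("TpC vs rest: chi2 = %.3f, p = %.3g\n",
                object@chi2Tpc, object@pTpc))
    cat(sprintf("CpC vs rest: chi2 = %.3f, p = %.3g\n",
                object@chi2Cpc, object@pCpc))
})

setMethod("show", "VariantReport", function(object) {
    cat(sprintf("VariantReport: %d variants, %d N positions\n",
                nrow(object@variants), object@nPositionsN))
    if (nrow(object@variants))
        cat(" ", paste(object@variants$label, collapse = ", "), "\n")
})
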