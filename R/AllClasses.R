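#' @import methods
NULL

.BASES <- c("A", "C", "G", "T")
.CTX_KEYS <- c("ApC", "CpC", "GpC", "TpC")
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Circular (or linear) reference sequence
#'
#' Holds a single DNA sequence over \{A,C,G,T,N\} together with its name and
#' topology. All coordinates in the package are 1-based inclusive positions in
#' `[1, length]`, matching rCRS nt numbering; on a circular reference,
#' neighbours and regions may wrap the origin.
#'
#' @slot name Record identifier.
#' @slot seq Uppercase DNA string over \{A,C,G,T,N\}.
#' @slot circular Whether position arithmetic wraps around the origin.
#'
#' @seealso [loadReference()], [simulateReference()], [extractRegion()]
#' @export
setClass("MitoReference",
    slots = c(name = "character", seq = "character", circular = "logical"))

setValidity("MitoReference", function(object) {
    if (length(object@seq) != 1L || is.na(object@seq) || !nzchar(object@seq))
        return("'seq' must be a single non-empty string")
    bad <- .illegalBase(object@seq)
    if (!is.na(bad))
        return(sprintf("illegal character '%s' at position %d",
                       substr(object@seq, bad, bad), bad))
    if (length(object@circular) != 1L || is.na(object@circular))
        return("'circular' must be TRUE or FALSE")
    TRUE
})

# position (or NA) of the first character outside {A,C,G,T,N}
.illegalBase <- function(seq) {
    u <- utf8ToInt(seq)
    bad <- which(!(u %in% utf8ToInt("ACGTN")))
    if (length(bad)) bad[1L] else NA_integer_
}

#' Genomic region in 1-based inclusive coordinates
#'
#' A region `start..end` on a reference. When `start > end` the region wraps
#' the origin of a circular reference (e.g. the D-loop amplicon
#' nt16331--nt3729 of the 16,569 nt mitochondrial genome).
#'
#' @slot start,end 1-based inclusive bounds.
#' @slot wraps TRUE iff `start > end` (only valid on a circular reference).
#' @export
setClass("GenomeRegion",
    slots = c(start = "integer", end = "integer", wraps = "logical"))

setValidity("GenomeRegion", function(object) {
    if (length(object@start) != 1L || length(object@end) != 1L ||
        is.na(object@start) || is.na(object@end))
        return("'start' and 'end' must be single integers")
    if (object@start < 1L || object@end < 1L)
        return("positions are 1-based; 'start' and 'end' must be >= 1")
    if (!identical(object@wraps, object@start > object@end))
        return("'wraps' must equal start > end")
    TRUE
})

#' Simulation settings for a synthetic amplicon library
#'
#' Defines the generative model: reads of fixed length drawn uniformly from a
#' region; a fraction `pHyper` of reads is exposed to cytidine deamination on
#' one strand, each eligible site mutating independently with the probability
#' assigned to its 5'-dinucleotide context; every base is then substituted
#' uniformly at random with probability `errorRate` (sequencing/PCR error).
#'
#' @slot region [GenomeRegion] reads are drawn from.
#' @slot nReads,readLength Library size and read length (nt).
#' @slot pHyper Fraction of reads exposed to deamination, in `[0,1]`.
#' @slot strand `"reference"` (C->T as written) or `"complement"`
#'   (deamination of complement-strand Cs, seen as G->A on the reference).
#' @slot contextWeights Named per-site deamination probabilities for
#'   `ApC`, `CpC`, `GpC`, `TpC`, each in `[0,1]`.
#' @slot errorRate Per-base substitution error probability in `[0,1]`.
#' @slot seed Integer seed; identical config + seed gives identical output.
#' @export
setClass("SimulationConfig",
    slots = c(region = "GenomeRegion", nReads = "integer",
              readLength = "integer", pHyper = "numeric", strand = "character",
              contextWeights = "numeric", errorRate = "numeric",
              seed = "integer"))

setValidity("SimulationConfig", function(object) {
    if (object@nReads < 0L) return("'nReads' must be >= 0")
    if (object@readLength < 1L) return("'readLength' must be >= 1")
    if (is.na(object@pHyper) || object@pHyper < 0 || object@pHyper > 1)
        return("'pHyper' must be in [0,1]")
    if (!object@strand %in% c("reference", "complement"))
        return("'strand' must be 'reference' or 'complement'")
    if (!setequal(names(object@contextWeights), .CTX_KEYS))
        return(sprintf("'contextWeights' must be named exactly %s",
                       paste(.CTX_KEYS, collapse = ", ")))
    if (any(is.na(object@contextWeights)) ||
        any(object@contextWeights < 0 | object@contextWeights > 1))
        return("'contextWeights' must all be in [0,1]")
    if (is.na(object@errorRate) || object@errorRate < 0 || object@errorRate > 1)
        return("'errorRate' must be in [0,1]")
    TRUE
})

#' Simulated read library with truth labels
#'
#' Reads produced by [simulateLibrary()]. Each read records the reference
#' coordinate of its first base (its true offset) and the library carries a
#' truth table (read id, hypermutated or not, deaminated reference positions)
#' enabling parameter-recovery tests downstream.
#'
#' @slot ids,reads,offsets Parallel vectors: read id, sequence, 1-based
#'   reference coordinate of the first base.
#' @slot truth data.frame with `read_id`, `is_hypermutated`,
#'   `deaminated_positions` (comma-separated reference coordinates).
#' @slot region Region the reads were drawn from.
#' @slot config The [SimulationConfig] used.
#' @export
setClass("ReadLibrary",
    slots = c(ids = "character", reads = "character", offsets = "integer",
              truth = "data.frame", region = "GenomeRegion",
              config = "SimulationConfig"))

setValidity("ReadLibrary", function(object) {
    n <- length(object@ids)
    if (length(object@reads) != n || length(object@offsets) != n)
        return("'ids', 'reads' and 'offsets' must have equal length")
    if (nrow(object@truth) != n)
        return("'truth' must have one row per read")
    hyper <- object@truth$is_hypermutated
    pos <- object@truth$deaminated_positions
    if (!is.null(hyper) && !is.null(pos) && any(hyper != nzchar(pos)))
        return("deaminated_positions must be non-empty iff is_hypermutated")
    TRUE
})

#' Linear model of 3D-PCR denaturation temperature vs mutation load
#'
#' Differential-denaturation PCR amplifies AT-enriched (mutated) templates at
#' lower denaturation temperatures. The model is the least-squares line
#' `Tm(m) = tm0 - delta * m` fitted to (mutation count, lowest amplification
#' temperature) calibration pairs.
#'
#' @slot tm0 Denaturation threshold of the unmutated amplicon (degrees C).
#' @slot delta Temperature decrease per C->T (or G->A) mutation (> 0).
#' @export
setClass("TmModel", slots = c(tm0 = "numeric", delta = "numeric"))

setValidity("TmModel", function(object) {
    if (!is.finite(object@tm0)) return("'tm0' must be finite")
    if (!is.finite(object@delta) || object@delta <= 0)
        return("'delta' must be > 0 (Tm strictly decreasing in load)")
    TRUE
})

#' Reads aligned to a reference region
#'
#' Substitution-only (Hamming) alignments: each read has a start column within
#' the region; reads exceeding the mismatch tolerance are kept in a
#' rejected-reads tally rather than raising an error.
#'
#' @slot ids,starts,seqs,mismatches Parallel vectors: read id, 1-based start
#'   column within the region, sequence, mismatches vs the region sequence.
#' @slot region The aligned-to [GenomeRegion].
#' @slot rejected data.frame (`read_id`, `mismatches`) of unmapped reads.
#' @export
setClass("AlignedReads",
    slots = c(ids = "character", starts = "integer", seqs = "character",
              mismatches = "integer", region = "GenomeRegion",
              rejected = "data.frame"))

setValidity("AlignedReads", function(object) {
    n <- length(object@ids)
    if (length(object@starts) != n || length(object@seqs) != n ||
        length(object@mismatches) != n)
        return("parallel slots must have equal length")
    if (n && any(object@starts < 1L))
        return("'starts' are 1-based positions within the region")
    TRUE
})

#' Per-library consensus with ambiguous bases masked as N
#'
#' Column-wise consensus of aligned reads: the modal base is called only where
#' depth and modal fraction reach their thresholds; every other column is N,
#' so bases not determined to be single never seed mutation calls.
#'
#' @slot seq Consensus string over \{A,C,G,T,N\}, one character per region
#'   column.
#' @slot region Region the consensus covers.
#' @slot nReadsUsed Number of (downsampled) reads tallied.
#' @slot minFraction Minimal modal-base fraction, in (0.5, 1].
#' @slot minDepth Minimal depth for a call.
#' @slot columnStats data.frame (`ref_pos`, `depth`, `modal_fraction`).
#' @export
setClass("ConsensusSequence",
    slots = c(seq = "character", region = "GenomeRegion",
              nReadsUsed = "integer", minFraction = "numeric",
              minDepth = "integer", columnStats = "data.frame"))

setValidity("ConsensusSequence", function(object) {
    if (object@minFraction <= 0.5 || object@minFraction > 1)
        return("'minFraction' must be in (0.5, 1]")
    if (object@minDepth < 1L) return("'minDepth' must be >= 1")
    if (nrow(object@columnStats) != nchar(object@seq))
        return("'columnStats' must have one row per consensus column")
    TRUE
})

#' Per-read C->T/G->A mutation-load histogram
#'
#' Counts of reads binned by their number of C->T/G->A calls (other
#' substitution classes never contribute to the load). Printed tables lump
#' loads 0--3 into one bin; a histogram read back from such a table records
#' the lump in `lumpedMax` so threshold calibration stays conservative.
#'
#' @slot counts Named numeric vector; names are loads (`"0"`, `"4"`, ...) or a
#'   single lumped lowest bin (`"0 to 3"`).
#' @slot lumpedMax Upper load of the lumped lowest bin, or NA when the
#'   histogram is at full resolution.
#' @slot totalReads Total reads tallied (== sum of counts).
#' @slot libraryId Library label.
#' @export
setClass("MutationLoadHistogram",
    slots = c(counts = "numeric", lumpedMax = "integer", totalReads = "numeric",
              libraryId = "character"))

setValidity("MutationLoadHistogram", function(object) {
    if (any(object@counts < 0)) return("counts must be >= 0")
    if (!isTRUE(all.equal(sum(object@counts), object@totalReads)))
        return("sum of counts must equal totalReads")
    TRUE
})

#' Control-calibrated hypermutation threshold
#'
#' The smallest integer load `k` such that at most `alpha` control reads carry
#' `k` or more C->T/G->A calls; reads at or above `k` are classed as
#' hypermutated. `lambdaHat` is the maximum-likelihood Poisson mean of the
#' control load distribution, a diagnostic of the error process only.
#'
#' @slot k Integer threshold.
#' @slot alpha Tolerated control reads at or above `k` (default 0).
#' @slot lambdaHat Fitted mean per-read error-derived C->T/G->A count.
#' @slot controlId Control library label.
#' @export
setClass("ThresholdCalibration",
    slots = c(k = "integer", alpha = "numeric", lambdaHat = "numeric",
              controlId = "character"))

setValidity("ThresholdCalibration", function(object) {
    if (object@k < 1L) return("'k' must be >= 1")
    if (object@alpha < 0) return("'alpha' must be >= 0")
    if (!is.na(object@lambdaHat) && object@lambdaHat < 0)
        return("'lambdaHat' must be >= 0")
    TRUE
})

#' Set of reads flagged as hypermutated
#'
#' @slot readIds Flagged read ids (empty for histogram-only input).
#' @slot nHyper,totalReads Flagged and total read counts.
#' @slot frequencyPpm Hypermutated reads per million reads
#'   (`nHyper / totalReads * 1e6`; NA when `totalReads` is 0).
#' @slot kUsed Threshold applied.
#' @export
setClass("HypermutationCallSet",
    slots = c(readIds = "character", nHyper = "numeric", totalReads = "numeric",
              frequencyPpm = "numeric", kUsed = "integer"))

setValidity("HypermutationCallSet", function(object) {
    if (object@nHyper > object@totalReads)
        return("'nHyper' cannot exceed 'totalReads'")
    if (object@totalReads > 0 &&
        !isTRUE(all.equal(object@frequencyPpm,
                          object@nHyper / object@totalReads * 1e6)))
        return("'frequencyPpm' must equal nHyper/totalReads * 1e6")
    TRUE
})

#' 5'-dinucleotide context spectrum of C->T/G->A calls
#'
#' Observed context counts among deamination-type calls, the expected context
#' fractions under the deamination-opportunity null (every eligible C in the
#' region, both strands pooled, classified by 5' neighbour), and 1-df
#' chi-square goodness-of-fit statistics for TpC vs non-TpC and CpC vs
#' non-CpC.
#'
#' @slot observed Named counts over `ApC`, `CpC`, `GpC`, `TpC`.
#' @slot expectedFraction Named expected fractions (sum 1).
#' @slot chi2Tpc,pTpc,chi2Cpc,pCpc Test statistics and p-values (NA when no
#'   context-bearing calls were available).
#' @slot nCalls Context-bearing calls tallied.
#' @slot nDroppedContext Calls dropped for lacking a resolvable context
#'   (N neighbour or off-end on a linear reference).
#' @export
setClass("DinucleotideSpectrum",
    slots = c(observed = "numeric", expectedFraction = "numeric",
              chi2Tpc = "numeric", pTpc = "numeric", chi2Cpc = "numeric",
              pCpc = "numeric", nCalls = "numeric",
              nDroppedContext = "numeric"))

setValidity("DinucleotideSpectrum", function(object) {
    if (!setequal(names(object@observed), .CTX_KEYS) ||
        !setequal(names(object@expectedFraction), .CTX_KEYS))
        return("'observed' and 'expectedFraction' must cover the 4 contexts")
    if (abs(sum(object@expectedFraction) - 1) > 1e-9)
        return("'expectedFraction' must sum to 1")
    if (!is.na(object@chi2Tpc) && object@chi2Tpc < 0)
        return("chi-square statistics must be >= 0")
    TRUE
})

#' Consensus-vs-standard discordance report
#'
#' Positions where a consensus differs from a reference standard, rendered in
#' `<standard base><position><consensus base>` notation (e.g. `A73G`).
#' Consensus N columns are not comparable and are counted separately.
#'
#' @slot variants data.frame (`position`, `standard`, `consensus`, `label`),
#'   positions strictly increasing.
#' @slot nPositionsN Consensus columns masked as N.
#' @export
setClass("VariantReport",
    slots = c(variants = "data.frame", nPositionsN = "numeric"))

setValidity("VariantReport", function(object) {
    v <- object@variants
    if (nrow(v)) {
        if (any(v$standard == v$consensus))
            return("variants must differ from the standard base")
        if (any(v$consensus == "N"))
            return("N consensus columns are not variants")
        if (is.unsorted(v$position, strictly = TRUE))
            return("variant positions must be strictly increasing")
    }
    TRUE
})
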