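#' @include AllClasses.R consensus.R
NULL

# context of a deamination-type call from the consensus, with reference
# fallback for the 5'/3' neighbour at window edges
.callContext <- function(isCT, localPos, consInt, posv, ref) {
    Lr <- length(consInt)
    len <- length(ref)
    refInt <- utf8ToInt(ref@seq)
    nbInt <- integer(length(localPos))
    for (i in seq_along(localPos)) {
        l <- localPos[i]
        if (isCT[i]) {            # C->T: 5' neighbour on the written strand
            if (l > 1L) nbInt[i] <- consInt[l - 1L]
            else {
                p <- posv[1L] - 1L
                if (p < 1L) {
                    if (!ref@circular) { nbInt[i] <- .N_INT; next }
                    p <- len
                }
                nbInt[i] <- refInt[p]
            }
        } else {                  # G->A: complement of the 3' neighbour
            if (l < Lr) nbInt[i] <- consInt[l + 1L]
            else {
                p <- posv[Lr] + 1L
                if (p > len) {
                    if (!ref@circular) { nbInt[i] <- .N_INT; next }
                    p <- 1L
                }
                nbInt[i] <- refInt[p]
            }
        }
    }
    nb <- strsplit(intToUtf8(nbInt), "")[[1L]]
    nb[!isCT] <- unname(.COMP[nb[!isCT]])
    ifelse(nb == "N" | is.na(nb), NA_character_, paste0(nb, "pC"))
}

#' Call per-read substitutions against the consensus
#'
#' One call is emitted for every position where the read base and the
#' consensus base are both in \{A,C,G,T\} and differ; N on either side masks
#' the position. C->T and G->A calls (as written on the reference strand)
#' carry their 5'-dinucleotide context, taken from the consensus (the
#' calling reference), with the genome reference supplying the neighbour at
#' window edges.
#'
#' @param x An [AlignedReads].
#' @param consensus The library's [ConsensusSequence] over the same region.
#' @param ref A [MitoReference] (coordinates and edge neighbours).
#' @return data.frame with one row per call: `read_id`, `position`
#'   (reference coordinate), `ref_base`, `alt_base`, `klass` (e.g. `"C>T"`),
#'   `is_ct_ga`, `context` (NA for non-deamination calls or unresolvable
#'   contexts).
#' @export
callMutations <- function(x, consensus, ref) {
    region <- x@region
    if (region@start != consensus@region@start ||
        region@end != consensus@region@end)
        stop("aligned reads and consensus cover different regions")
    posv <- .regionPositions(ref, region)
    consInt <- utf8ToInt(consensus@seq)
    Lr <- length(consInt)

    idL <- list(); posL <- list(); refL <- list(); altL <- list()
    m <- 0L
    for (i in seq_len(length(x))) {
        u <- utf8ToInt(x@seqs[i])
        s <- x@starts[i]
        if (s + length(u) - 1L > Lr)
            stop("read interval outside the consensus region")
        w <- consInt[s + seq_along(u) - 1L]
        d <- which(u != w & u != .N_INT & w != .N_INT)
        if (length(d)) {
            m <- m + 1L
            idL[[m]] <- rep.int(x@ids[i], length(d))
            posL[[m]] <- s + d - 1L
            refL[[m]] <- w[d]
            altL[[m]] <- u[d]
        }
    }
    if (m == 0L) {
        return(data.frame(read_id = character(0), position = integer(0),
                          ref_base = character(0), alt_base = character(0),
                          klass = character(0), is_ct_ga = logical(0),
                          context = character(0), stringsAsFactors = FALSE))
    }
    localPos <- unlist(posL, use.names = FALSE)
    refB <- strsplit(intToUtf8(unlist(refL, use.names = FALSE)), "")[[1L]]
    altB <- strsplit(intToUtf8(unlist(altL, use.names = FALSE)), "")[[1L]]
    isCT <- refB == "C" & altB == "T"
    isGA <- refB == "G" & altB == "A"
    ctga <- isCT | isGA
    context <- rep(NA_character_, length(localPos))
    if (any(ctga))
        context[ctga] <- .callContext(isCT[ctga], localPos[ctga], consInt,
                                      posv, ref)
    data.frame(read_id = unlist(idL, use.names = FALSE),
               position = posv[localPos], ref_base = refB, alt_base = altB,
               klass = paste0(refB, ">", altB), is_ct_ga = ctga,
               context = context, stringsAsFactors = FALSE)
}

#' Per-read C->T/G->A mutation loads
#'
#' @param x The [AlignedReads] the calls came from (supplies the zero-load
#'   reads).
#' @param calls Call table from [callMutations()].
#' @return Named integer vector of loads, one entry per aligned read.
#' @export
readLoads <- function(x, calls) {
    loads <- integer(length(x))
    names(loads) <- x@ids
    if (nrow(calls)) {
        t <- table(factor(calls$read_id[calls$is_ct_ga], levels = x@ids))
        loads[] <- as.integer(t)
    }
    loads
}

#' Bin reads by C->T/G->A mutation load
#'
#' @param loads Named per-read loads from [readLoads()] (only
#'   deamination-type calls count toward the load).
#' @param libraryId Library label.
#' @return A [MutationLoadHistogram] at full load resolution.
#' @export
buildHistogram <- function(loads, libraryId = "") {
    counts <- as.numeric(table(loads))
    names(counts) <- names(table(loads))
    new("MutationLoadHistogram", counts = counts, lumpedMax = NA_integer_,
        totalReads = as.numeric(length(loads)), libraryId = libraryId)
}

#' Build a histogram from printed table counts
#'
#' Accepts the shape of published per-read load tables: bin names are loads
#' (`"0"`, `"4"`, ...) with optionally one lumped lowest bin such as
#' `"0 to 3"` or `"0-3"`.
#'
#' @param counts Named numeric vector of read counts per load bin.
#' @param libraryId Library label.
#' @return A [MutationLoadHistogram]; `lumpedMax` records the lumped bin's
#'   upper load.
#' @examples
#' histogramFromCounts(
#'   c("0 to 3" = 2382107, "4" = 8, "5" = 8, "6" = 4, "7" = 2,
#'     "8" = 0, "10" = 1, "22" = 0), libraryId = "CIN1_1300")
#' @export
histogramFromCounts <- function(counts, libraryId = "") {
    nm <- trimws(names(counts))
    if (is.null(nm) || any(!nzchar(nm)))
        stop("'counts' must be named by load bin")
    lump <- regmatches(nm, regexec("^(\\d+)\\s*(?:-|to)\\s*(\\d+)$", nm))
    isLump <- lengths(lump) == 3L
    lumpedMax <- NA_integer_
    if (sum(isLump) > 1L)
        stop("at most one lumped bin is supported")
    if (any(isLump)) {
        lo <- as.integer(lump[isLump][[1L]][2L])
        hi <- as.integer(lump[isLump][[1L]][3L])
        if (lo != 0L || hi < lo)
            stop("the lumped bin must be the lowest bin, starting at load 0")
        lumpedMax <- hi
        plain <- suppressWarnings(as.integer(nm[!isLump]))
        if (any(is.na(plain)))
            stop("unparseable load bin name: ",
                 nm[!isLump][which(is.na(plain))[1L]])
        if (length(plain) && any(plain <= hi))
            stop("plain bins must lie above the lumped bin")
    } else {
        plain <- suppressWarnings(as.integer(nm))
        if (any(is.na(plain)))
            stop("unparseable load bin name: ", nm[which(is.na(plain))[1L]])
    }
    counts <- as.numeric(counts)
    names(counts) <- nm
    ord <- order(ifelse(isLump, -1L,
                        suppressWarnings(as.integer(nm))))
    new("MutationLoadHistogram", counts = counts[ord], lumpedMax = lumpedMax,
        totalReads = sum(counts), libraryId = libraryId)
}

# numeric load of each bin; a lumped bin contributes its bounds separately
.histBins <- function(hist) {
    nm <- names(hist@counts)
    isLump <- !is.na(hist@lumpedMax) &
        grepl("^(\\d+)\\s*(?:-|to)\\s*(\\d+)$", nm)
    load <- suppressWarnings(as.integer(nm))
    list(load = load, isLump = isLump)
}

#' Calibrate the hypermutation threshold from a control library
#'
#' Error-only control reads decay roughly exponentially in load; `k` is the
#' smallest integer threshold with at most `alpha` control reads at load
#' `>= k` (default `alpha = 0`: no control read may reach the threshold).
#' For a histogram read back from a lumped table, the lumped mass is treated
#' as occupying loads up to the bin's upper bound, which keeps the tail
#' conservative. `lambdaHat`, the maximum-likelihood Poisson mean of the
#' control loads, is diagnostic only (lumped mass placed at load 0, a lower
#' bound).
#'
#' @param hist Control [MutationLoadHistogram] with `totalReads > 0`.
#' @param alpha Tolerated control reads at or above `k`.
#' @return A [ThresholdCalibration].
#' @export
calibrateThreshold <- function(hist, alpha = 0) {
    if (hist@totalReads <= 0)
        stop("control histogram is empty; cannot calibrate a threshold")
    stopifnot(alpha >= 0)
    b <- .histBins(hist)
    maxLoad <- max(c(b$load[!b$isLump], hist@lumpedMax, 0L), na.rm = TRUE)
    k <- NA_integer_
    for (cand in seq_len(maxLoad + 1L)) {
        tail <- sum(hist@counts[!b$isLump & b$load >= cand])
        if (!is.na(hist@lumpedMax) && cand <= hist@lumpedMax)
            tail <- tail + sum(hist@counts[b$isLump])
        if (tail <= alpha) { k <- cand; break }
    }
    loadForMean <- ifelse(b$isLump, 0L, b$load)
    lambda <- sum(loadForMean * hist@counts) / hist@totalReads
    new("ThresholdCalibration", k = k, alpha = alpha, lambdaHat = lambda,
        controlId = hist@libraryId)
}

.newCallSet <- function(readIds, nHyper, total, k) {
    nHyper <- as.numeric(nHyper)
    total <- as.numeric(total)
    new("HypermutationCallSet", readIds = readIds, nHyper = nHyper,
        totalReads = total,
        frequencyPpm = if (total > 0) nHyper / total * 1e6 else NA_real_,
        kUsed = as.integer(k))
}

#' @describeIn flagHypermutated Flag named per-read loads; the frequency is
#'   `nHyper / totalReads * 1e6` ppm (NA for an empty library).
#' @export
setMethod("flagHypermutated", "numeric", function(x, k) {
    k <- as.integer(k)
    if (k < 1L) stop("'k' must be >= 1")
    ids <- names(x)[x >= k]
    if (is.null(ids)) ids <- character(0)
    .newCallSet(ids, sum(x >= k), length(x), k)
})

#' @describeIn flagHypermutated Flag from a histogram (read identities
#'   unavailable); `k` must lie above any lumped bin.
#' @export
setMethod("flagHypermutated", "MutationLoadHistogram", function(x, k) {
    k <- as.integer(k)
    if (k < 1L) stop("'k' must be >= 1")
    if (!is.na(x@lumpedMax) && k <= x@lumpedMax)
        stop("'k' must exceed the lumped bin's upper load (",
             x@lumpedMax, ")")
    b <- .histBins(x)
    nHyper <- sum(x@counts[!b$isLump & b$load >= k])
    .newCallSet(character(0), nHyper, x@totalReads, k)
})

# Hamming distance over the aligned window, skipping N on either side
.hamN <- function(u, v) sum(u != v & u != .N_INT & v != .N_INT)

#' Exclude flagged reads better explained by a known haplotype
#'
#' A local, deterministic replacement for a BLAST-vs-database check: a
#' flagged read is excluded iff some haplotype window (same coordinate
#' system as the reference) is strictly closer to the read, in Hamming
#' distance, than the consensus window is; ties keep the read. Reads whose
#' interval no haplotype record covers are kept with a warning.
#'
#' @param x The [AlignedReads] the flagged reads belong to.
#' @param readIds Ids of the flagged reads to test.
#' @param consensus The library [ConsensusSequence].
#' @param ref A [MitoReference].
#' @param haplotypes Named character vector of haplotype sequences aligned
#'   to the reference coordinate system (e.g. from [loadHaplotypes()]);
#'   empty to keep every read.
#' @return data.frame: `read_id`, `keep`, `best_haplotype`,
#'   `dist_consensus`, `dist_best_haplotype`.
#' @export
haplotypeFilter <- function(x, readIds, consensus, ref, haplotypes) {
    idx <- match(readIds, x@ids)
    if (anyNA(idx))
        stop("unknown read id: ", readIds[which(is.na(idx))[1L]])
    posv <- .regionPositions(ref, x@region)
    consInt <- utf8ToInt(consensus@seq)
    hapInt <- lapply(haplotypes, utf8ToInt)
    out <- data.frame(read_id = readIds, keep = TRUE,
                      best_haplotype = NA_character_,
                      dist_consensus = NA_integer_,
                      dist_best_haplotype = NA_integer_,
                      stringsAsFactors = FALSE)
    for (j in seq_along(idx)) {
        i <- idx[j]
        u <- utf8ToInt(x@seqs[i])
        cols <- x@starts[i] + seq_along(u) - 1L
        dCons <- .hamN(u, consInt[cols])
        out$dist_consensus[j] <- dCons
        if (!length(hapInt)) next
        refPos <- posv[cols]
        dBest <- NA_integer_
        best <- NA_character_
        covered <- FALSE
        for (h in names(hapInt)) {
            hv <- hapInt[[h]]
            if (max(refPos) > length(hv)) next   # record does not cover read
            covered <- TRUE
            d <- .hamN(u, hv[refPos])
            if (is.na(dBest) || d < dBest) { dBest <- d; best <- h }
        }
        if (!covered) {
            warning("no haplotype record covers read ", readIds[j],
                    "; read kept")
            next
        }
        out$dist_best_haplotype[j] <- dBest
        out$best_haplotype[j] <- best
        if (dBest < dCons) out$keep[j] <- FALSE
    }
    out
}

#' Load a haplotype database from multi-FASTA
#'
#' Records must share the reference coordinate system (column i of a record
#' is reference position i).
#'
#' @param path Multi-FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
loadHaplotypes <- function(path) {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L)
        stop("no haplotype records in ", path)
    seqs <- toupper(as.character(set))
    for (i in seq_along(seqs)) {
        bad <- .illegalBase(seqs[i])
        if (!is.na(bad))
            stop(sprintf("malformed haplotype record '%s': illegal character at position %d",
                         names(set)[i], bad))
    }
    names(seqs) <- sub("\\s.*$", "", names(set))
    seqs
}
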