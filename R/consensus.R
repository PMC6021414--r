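#' @include AllClasses.R simulate.R
NULL

#' Align one read to a region sequence by Hamming scan
#'
#' Substitution-only mapping: every start column is scanned and the offset
#' minimizing the Hamming distance is chosen (ties go to the smallest
#' offset). A read whose best distance exceeds
#' `maxMismatchFraction * length` is reported unmapped.
#'
#' @param seq Read sequence.
#' @param regionSeq Region sequence the read is mapped against.
#' @param maxMismatchFraction Rejection threshold as a fraction of read
#'   length.
#' @return `list(start, mismatches, mapped)`; `start` is the 1-based column
#'   within the region.
#' @export
alignRead <- function(seq, regionSeq, maxMismatchFraction = 0.1) {
    L <- nchar(seq)
    Lr <- nchar(regionSeq)
    if (L > Lr)
        stop("read longer than the region")
    u <- utf8ToInt(seq)
    r <- utf8ToInt(regionSeq)
    best <- L + 1L
    bestStart <- 1L
    for (s in seq_len(Lr - L + 1L)) {
        d <- sum(u != r[s:(s + L - 1L)])
        if (d < best) {
            best <- d
            bestStart <- s
            if (best == 0L) break
        }
    }
    list(start = bestStart, mismatches = best,
         mapped = best <= maxMismatchFraction * L)
}

#' Align a read set to a reference region
#'
#' Header-declared offsets (synthetic libraries, pre-aligned tabular input)
#' are used directly; otherwise each read is mapped by full Hamming scan via
#' [alignRead()]. Reads exceeding the mismatch tolerance are recorded in a
#' rejected-reads tally, never an error.
#'
#' @param x A [ReadLibrary], or a data.frame with columns `read_id`,
#'   `offset` (1-based reference coordinate, NA to scan) and `sequence`.
#' @param ref A [MitoReference].
#' @param region Region to align within (taken from `x` for a
#'   [ReadLibrary]).
#' @param maxMismatchFraction Rejection threshold as a fraction of read
#'   length.
#' @param useDeclaredOffsets Set FALSE to force a scan even when offsets are
#'   declared.
#' @return An [AlignedReads].
#' @export
alignReads <- function(x, ref, region = NULL, maxMismatchFraction = 0.1,
                       useDeclaredOffsets = TRUE) {
    if (is(x, "ReadLibrary")) {
        region <- x@region
        df <- data.frame(read_id = x@ids, offset = x@offsets,
                         sequence = x@reads, stringsAsFactors = FALSE)
    } else {
        df <- x
        if (is.null(region))
            stop("'region' is required for data.frame input")
        if (!all(c("read_id", "sequence") %in% names(df)))
            stop("data.frame input needs 'read_id' and 'sequence' columns")
        if (is.null(df$offset)) df$offset <- NA_integer_
    }
    posv <- .regionPositions(ref, region)
    Lr <- length(posv)
    # reference coordinate -> region column
    localOf <- integer(length(ref))
    localOf[posv] <- seq_len(Lr)
    regionSeq <- extractRegion(ref, region)
    regInt <- utf8ToInt(regionSeq)

    n <- nrow(df)
    starts <- integer(n)
    mism <- integer(n)
    keep <- logical(n)
    for (i in seq_len(n)) {
        sq <- df$sequence[i]
        L <- nchar(sq)
        off <- df$offset[i]
        if (useDeclaredOffsets && !is.na(off)) {
            s <- localOf[off]
            if (s == 0L || s + L - 1L > Lr) {
                keep[i] <- FALSE
                mism[i] <- L
                next
            }
            d <- sum(utf8ToInt(sq) != regInt[s:(s + L - 1L)])
            starts[i] <- s
            mism[i] <- d
            keep[i] <- d <= maxMismatchFraction * L
        } else {
            hit <- alignRead(sq, regionSeq, maxMismatchFraction)
            starts[i] <- hit$start
            mism[i] <- hit$mismatches
            keep[i] <- hit$mapped
        }
    }
    new("AlignedReads",
        ids = df$read_id[keep], starts = starts[keep],
        seqs = df$sequence[keep], mismatches = mism[keep], region = region,
        rejected = data.frame(read_id = df$read_id[!keep],
                              mismatches = mism[!keep],
                              stringsAsFactors = FALSE))
}

#' Downsample aligned reads
#'
#' Uniform sampling without replacement, deterministic given the seed;
#' libraries of at most `n` reads are returned unchanged. Relative read
#' order is preserved.
#'
#' @param x An [AlignedReads].
#' @param n Target read count.
#' @param seed Integer seed.
#' @return An [AlignedReads] with at most `n` reads.
#' @export
downsampleReads <- function(x, n, seed = 1L) {
    stopifnot(n >= 0)
    if (length(x) <= n) return(x)
    set.seed(as.integer(seed))
    idx <- sort(sample.int(length(x), n))
    new("AlignedReads", ids = x@ids[idx], starts = x@starts[idx],
        seqs = x@seqs[idx], mismatches = x@mismatches[idx],
        region = x@region, rejected = x@rejected)
}

#' Build a consensus with N-masking of ambiguous columns
#'
#' Per region column, the modal base is called iff the column is covered by
#' at least `minDepth` reads (read Ns excluded from the tally) and the modal
#' base reaches a fraction of at least `minFraction`; every other column is
#' masked as N, so bases not determined to be single never seed mutation
#' calls.
#'
#' @param x An [AlignedReads] (typically after [downsampleReads()]).
#' @param ref A [MitoReference].
#' @param minFraction Minimal modal-base fraction, in (0.5, 1].
#' @param minDepth Minimal depth for a call.
#' @return A [ConsensusSequence].
#' @export
buildConsensus <- function(x, ref, minFraction = 0.8, minDepth = 10L) {
    if (minFraction <= 0.5 || minFraction > 1)
        stop("'minFraction' must be in (0.5, 1]")
    minDepth <- as.integer(minDepth)
    if (minDepth < 1L) stop("'minDepth' must be >= 1")
    region <- x@region
    posv <- .regionPositions(ref, region)
    Lr <- length(posv)
    counts <- matrix(0, nrow = 5L, ncol = Lr)
    n <- length(x)
    chunk <- 2000L
    i <- 1L
    while (i <= n) {
        j <- min(i + chunk - 1L, n)
        idxs <- lapply(i:j, function(r) {
            u <- .CODE[utf8ToInt(x@seqs[r])]
            (x@starts[r] + seq_along(u) - 2L) * 5L + u
        })
        tb <- tabulate(unlist(idxs, use.names = FALSE), nbins = 5L * Lr)
        counts <- counts + matrix(tb, nrow = 5L)
        i <- j + 1L
    }
    acgt <- counts[1:4, , drop = FALSE]
    depth <- colSums(acgt)
    mi <- max.col(t(acgt), ties.method = "first")
    modal <- acgt[cbind(mi, seq_len(Lr))]
    frac <- ifelse(depth > 0, modal / depth, 0)
    call <- ifelse(depth >= minDepth & frac >= minFraction, .BASES[mi], "N")
    new("ConsensusSequence", seq = paste(call, collapse = ""),
        region = region, nReadsUsed = n, minFraction = minFraction,
        minDepth = minDepth,
        columnStats = data.frame(ref_pos = posv, depth = as.integer(depth),
                                 modal_fraction = frac))
}
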