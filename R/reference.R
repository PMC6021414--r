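#' @include AllClasses.R
NULL

#' Load a reference sequence from FASTA
#'
#' Reads the first record of a (plain or gzip-compressed) FASTA file,
#' normalizes bases to uppercase and validates them against \{A,C,G,T,N\}.
#'
#' @param path FASTA file with at least one record.
#' @param circular Whether coordinates wrap the origin (TRUE for the
#'   mitochondrial genome).
#' @param name Optional identifier; defaults to the first word of the header.
#' @return A [MitoReference].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">toy", "atcga"), fa)
#' loadReference(fa)
#' @export
loadReference <- function(path, circular = TRUE, name = NULL) {
    if (!file.exists(path))
        stop("reference FASTA not found: ", path)
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L)
        stop("no sequence records in ", path)
    seq <- toupper(as.character(set[[1L]]))
    bad <- .illegalBase(seq)
    if (!is.na(bad))
        stop(sprintf("illegal character '%s' at position %d in %s",
                     substr(seq, bad, bad), bad, path))
    if (is.null(name))
        name <- sub("\\s.*$", "", names(set)[1L])
    new("MitoReference", name = name, seq = seq, circular = isTRUE(circular))
}

#' Construct a reference from an in-memory sequence
#'
#' @param seq DNA string over \{A,C,G,T,N\} (lowercase accepted).
#' @inheritParams loadReference
#' @return A [MitoReference].
#' @export
mitoReference <- function(seq, circular = TRUE, name = "ref") {
    new("MitoReference", name = name, seq = toupper(seq),
        circular = isTRUE(circular))
}

#' Define a region in 1-based inclusive coordinates
#'
#' `start > end` denotes a region wrapping the origin of a circular
#' reference, e.g. `genomeRegion(16331, 3729)` for the D-loop amplicon.
#'
#' @param start,end 1-based inclusive bounds.
#' @return A [GenomeRegion].
#' @export
genomeRegion <- function(start, end) {
    start <- as.integer(start); end <- as.integer(end)
    new("GenomeRegion", start = start, end = end, wraps = start > end)
}

#' Parse a region from "START-END" text
#'
#' @param text Region in `"START-END"` form, 1-based inclusive.
#' @return A [GenomeRegion].
#' @export
parseRegion <- function(text) {
    m <- regmatches(text, regexec("^\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", text))[[1L]]
    if (length(m) != 3L)
        stop("cannot parse region '", text, "'; expected \"START-END\"")
    genomeRegion(as.integer(m[2L]), as.integer(m[3L]))
}

# reference coordinates covered by a region, in region order
.regionPositions <- function(ref, region) {
    len <- length(ref)
    if (region@start > len || region@end > len)
        stop(sprintf("region %d-%d exceeds reference length %d",
                     region@start, region@end, len))
    if (region@wraps) {
        if (!ref@circular)
            stop("wrapping region on a linear reference")
        c(region@start:len, 1:region@end)
    } else {
        region@start:region@end
    }
}

#' Reference coordinates covered by a region
#'
#' @param ref A [MitoReference].
#' @param region A [GenomeRegion]; wrapping regions require a circular
#'   reference.
#' @return Integer vector of 1-based reference coordinates, in region order.
#' @export
regionPositions <- function(ref, region) .regionPositions(ref, region)

#' Length of a region on a reference
#'
#' `end - start + 1` for non-wrapping regions and
#' `length(ref) - start + 1 + end` when the region wraps the origin.
#'
#' @inheritParams regionPositions
#' @return Integer length in nt.
#' @export
regionLength <- function(ref, region) {
    len <- length(ref)
    if (region@start > len || region@end > len)
        stop(sprintf("region %d-%d exceeds reference length %d",
                     region@start, region@end, len))
    if (region@wraps) {
        if (!ref@circular)
            stop("wrapping region on a linear reference")
        len - region@start + 1L + region@end
    } else {
        region@end - region@start + 1L
    }
}

#' Extract a region's sequence, honouring circular wrap-around
#'
#' @inheritParams regionPositions
#' @return DNA string of [regionLength()] characters.
#' @examples
#' ref <- mitoReference("ATCGA")
#' extractRegion(ref, genomeRegion(4, 2))  # "GAAT"
#' @export
extractRegion <- function(ref, region) {
    len <- length(ref)
    if (region@start > len || region@end > len)
        stop(sprintf("region %d-%d exceeds reference length %d",
                     region@start, region@end, len))
    if (region@wraps) {
        if (!ref@circular)
            stop("wrapping region on a linear reference")
        paste0(substr(ref@seq, region@start, len),
               substr(ref@seq, 1L, region@end))
    } else {
        substr(ref@seq, region@start, region@end)
    }
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over \{A,C,G,T,N\}.
#' @return The reverse complement string.
#' @export
reverseComplement <- function(seq) {
    intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", seq))))
}

#' 5'-dinucleotide context of a deaminated cytosine
#'
#' For a C on the reference strand the context is the base immediately 5' of
#' it followed by C (ApC/CpC/GpC/TpC). A G on the reference strand marks a C
#' on the complement strand; its 5' neighbour on that strand is the
#' complement of the reference base immediately 3' of the G. Neighbours are
#' resolved circularly on circular references.
#'
#' @param ref A [MitoReference].
#' @param pos 1-based position(s); the base there must be C
#'   (`deaminatedStrand = "reference"`) or G (`"complement"`).
#' @param deaminatedStrand Strand carrying the deaminated C.
#' @return Character vector over `ApC`, `CpC`, `GpC`, `TpC`; NA where the
#'   neighbour is N.
#' @examples
#' ref <- mitoReference("ATCGA")
#' dinucleotideContext(ref, 3, "reference")   # "TpC"
#' dinucleotideContext(ref, 4, "complement")  # "TpC"
#' @export
dinucleotideContext <- function(ref, pos,
                                deaminatedStrand = c("reference", "complement")) {
    deaminatedStrand <- match.arg(deaminatedStrand)
    len <- length(ref)
    pos <- as.integer(pos)
    if (any(pos < 1L | pos > len))
        stop("positions must be in [1, ", len, "]")
    b <- substring(ref@seq, pos, pos)
    if (deaminatedStrand == "reference") {
        off <- which(b != "C")
        if (length(off))
            stop(sprintf("base at position %d is '%s', not C on the reference strand",
                         pos[off[1L]], b[off[1L]]))
        nb <- pos - 1L
        if (any(nb < 1L)) {
            if (!ref@circular)
                stop("no 5' neighbour at position 1 on a linear reference")
            nb[nb < 1L] <- len
        }
        ctx <- substring(ref@seq, nb, nb)
    } else {
        off <- which(b != "G")
        if (length(off))
            stop(sprintf("base at position %d is '%s', not G (no complement-strand C)",
                         pos[off[1L]], b[off[1L]]))
        nb <- pos + 1L
        if (any(nb > len)) {
            if (!ref@circular)
                stop("no 5' neighbour at the final position on a linear reference")
            nb[nb > len] <- 1L
        }
        ctx <- unname(.COMP[substring(ref@seq, nb, nb)])
    }
    ifelse(ctx == "N", NA_character_, paste0(ctx, "pC"))
}
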