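#' @include AllClasses.R mutcall.R
NULL

#' 12-class substitution matrix
#'
#' Tally of calls by (reference base, alternate base) as written on the
#' reference strand; the diagonal is structurally zero.
#'
#' @param calls Call table from [callMutations()].
#' @return 4x4 numeric matrix with `ref`/`alt` dimnames.
#' @export
mutationMatrix <- function(calls) {
    m <- table(factor(calls$ref_base, levels = .BASES),
               factor(calls$alt_base, levels = .BASES))
    m <- unclass(m)
    storage.mode(m) <- "numeric"
    dimnames(m) <- list(ref = .BASES, alt = .BASES)
    m
}

#' Strand bias of deamination-type calls
#'
#' G->A calls mark deamination of complement-strand cytosines; an excess of
#' G->A over C->T therefore localizes the deaminated strand.
#'
#' @param mat Matrix from [mutationMatrix()].
#' @return `list(nCt, nGa, biasFraction = nGa / (nCt + nGa))`;
#'   `biasFraction` is NA when there are no deamination-type calls.
#' @export
strandBias <- function(mat) {
    nCt <- mat["C", "T"]
    nGa <- mat["G", "A"]
    list(nCt = unname(nCt), nGa = unname(nGa),
         biasFraction = if (nCt + nGa > 0) unname(nGa / (nCt + nGa))
                        else NA_real_)
}

# 1-df two-cell goodness of fit (optionally Yates-corrected)
.gof2 <- function(x1, n, p1, correct = FALSE) {
    o <- c(x1, n - x1)
    e <- c(n * p1, n * (1 - p1))
    if (any(e <= 0))
        return(list(chi2 = NA_real_, p = NA_real_))
    adj <- if (correct) pmin(abs(o - e), 0.5) else 0
    chi2 <- sum((abs(o - e) - adj)^2 / e)
    list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' 5'-dinucleotide context spectrum with chi-square enrichment tests
#'
#' Observed contexts of C->T/G->A calls are compared with the expected
#' context fractions under the deamination-opportunity null: every eligible
#' C in the region -- reference-strand Cs and complement-strand Cs (i.e.
#' reference Gs) pooled -- classified by its 5' neighbour on the deaminated
#' strand. Two 1-df goodness-of-fit tests collapse the 4 contexts to TpC vs
#' rest and CpC vs rest (no continuity correction by default).
#'
#' @param calls Call table from [callMutations()].
#' @param ref A [MitoReference].
#' @param region Analyzed [GenomeRegion].
#' @param correct Apply the Yates continuity correction.
#' @param expectedFrom `"region"` (default; all eligible Cs in the region)
#'   or `"mutated"` (contexts of exactly the distinct mutated sites).
#' @return A [DinucleotideSpectrum]; tests are NA when there are no
#'   context-bearing calls.
#' @export
dinucleotideSpectrum <- function(calls, ref, region, correct = FALSE,
                                 expectedFrom = c("region", "mutated")) {
    expectedFrom <- match.arg(expectedFrom)
    cc <- calls[calls$is_ct_ga, , drop = FALSE]
    dropped <- sum(is.na(cc$context))
    ctx <- cc$context[!is.na(cc$context)]
    obs <- as.numeric(table(factor(ctx, levels = .CTX_KEYS)))
    names(obs) <- .CTX_KEYS

    if (expectedFrom == "region") {
        posv <- .regionPositions(ref, region)
        bases <- substring(ref@seq, posv, posv)
        ec <- character(0)
        cpos <- posv[bases == "C"]
        gpos <- posv[bases == "G"]
        edgeDrop <- function(p, strand) {
            # linear references: edge sites without a 5' neighbour excluded
            if (ref@circular) return(p)
            if (strand == "reference") p[p > 1L] else p[p < length(ref)]
        }
        cpos <- edgeDrop(cpos, "reference")
        gpos <- edgeDrop(gpos, "complement")
        if (length(cpos))
            ec <- c(ec, dinucleotideContext(ref, cpos, "reference"))
        if (length(gpos))
            ec <- c(ec, dinucleotideContext(ref, gpos, "complement"))
        ec <- ec[!is.na(ec)]
        if (!length(ec))
            stop("no eligible C in the region on either strand")
        ef <- as.numeric(table(factor(ec, levels = .CTX_KEYS))) / length(ec)
    } else {
        sites <- unique(cc[!is.na(cc$context),
                           c("position", "ref_base", "context")])
        if (!nrow(sites))
            stop("no context-bearing mutated sites to build the null from")
        ef <- as.numeric(table(factor(sites$context, levels = .CTX_KEYS))) /
            nrow(sites)
    }
    names(ef) <- .CTX_KEYS

    n <- sum(obs)
    if (n > 0) {
        tpc <- .gof2(obs["TpC"], n, ef["TpC"], correct)
        cpc <- .gof2(obs["CpC"], n, ef["CpC"], correct)
    } else {
        tpc <- cpc <- list(chi2 = NA_real_, p = NA_real_)
    }
    new("DinucleotideSpectrum", observed = obs, expectedFraction = ef,
        chi2Tpc = unname(tpc$chi2), pTpc = unname(tpc$p),
        chi2Cpc = unname(cpc$chi2), pCpc = unname(cpc$p),
        nCalls = n, nDroppedContext = dropped)
}
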